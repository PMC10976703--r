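#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: cohort composition,
#' generator overrides, phantom geometry, reference mode, Z orientation
#' and threshold, prediction rules and visit count. The effective config
#' (with its hash and seed) is serialized next to the outputs so a run
#' is fully reproducible.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param group_sizes Named counts per diagnostic group.
#' @param grid_shape,voxel_size_mm Phantom geometry.
#' @param noise_sd_fraction Multiplicative voxel noise fraction.
#' @param pons_activity Reference activity of the rendered phantoms.
#' @param reference_mode `"label"` or `"box"` (see [reference_spec()]).
#' @param box_edge_mm Reference box edge for `"box"` mode.
#' @param orientation Z orientation (see [z_transform()]).
#' @param threshold Hypometabolism calling threshold.
#' @param rules Character vector of prediction rules to evaluate.
#' @param n_visits Longitudinal measurements per subject.
#' @param severity_loading Shared severity-factor loading of the cohort
#'   generator.
#' @param output_dir Where [run_pipeline()] writes its artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            group_sizes = default_group_sizes(),
                            grid_shape = c(48L, 48L, 48L),
                            voxel_size_mm = c(2, 2, 2),
                            noise_sd_fraction = 0.05,
                            pons_activity = 1000,
                            reference_mode = c("label", "box"),
                            box_edge_mm = 16,
                            orientation = c("subject_minus_db",
                                            "db_minus_subject"),
                            threshold = -2,
                            rules = c("MTL", "PCC", "MTL&PCC", "MTL|PCC"),
                            n_visits = 5L,
                            severity_loading = 0,
                            output_dir = tempfile("fdgvoi_run_")) {
  cfg <- list(
    seed = as.integer(seed), group_sizes = group_sizes,
    grid_shape = as.integer(grid_shape),
    voxel_size_mm = as.numeric(voxel_size_mm),
    noise_sd_fraction = noise_sd_fraction,
    pons_activity = pons_activity,
    reference_mode = match.arg(reference_mode),
    box_edge_mm = box_edge_mm,
    orientation = match.arg(orientation),
    threshold = threshold, rules = rules,
    n_visits = as.integer(n_visits),
    severity_loading = severity_loading,
    output_dir = output_dir
  )
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), "output_dir")])
}

write_stamped_tsv <- function(df, path, seed, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# seed: %d", seed),
               sprintf("# config_hash: %s", hash)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV, skipping the stamp header
#'
#' @param path Path written by [run_pipeline()].
#' @return A tibble.
#' @export
read_pipeline_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, comment.char = "#",
                               stringsAsFactors = FALSE))
}

stage_log <- function(verbose, stage, t0) {
  if (verbose) {
    message(sprintf("[fdgvoi] %-12s %6.2f s", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, in order: cohort simulation, conversion-interval
#' assignment, phantom atlas construction, per-subject PET rendering,
#' pons-referenced SUVr extraction, normative-database construction from
#' the control group, Z transformation and hypometabolism calling for
#' the MCI subjects, conversion prediction and diagnostic evaluation for
#' every configured rule, per-group hypometabolism prevalence,
#' longitudinal score generation and the marginal trajectory model.
#' All tables are written as TSV (stamped with the seed and config
#' hash), metrics and config as JSON, into `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log per-stage timings to stderr (default TRUE).
#' @return Invisibly, a list with every intermediate product: `cohort`,
#'   `atlas`, `measurements`, `db`, `z_records`, `calls`, `metrics`
#'   (per rule), `prevalence`, `scores`, `trajectory_fit`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  t0 <- as.numeric(Sys.time())

  step <- function(stage, expr) {
    t <- as.numeric(Sys.time())
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stage_log(verbose, stage, t)
    out
  }

  cohort <- step("simulate", {
    generate_cohort(config$group_sizes, seed = seed,
                    severity_loading = config$severity_loading) |>
      assign_conversion_times(seed = seed + 1L)
  })

  atlas <- step("atlas", generate_atlas_phantom(config$grid_shape,
                                                config$voxel_size_mm))

  measurements <- step("suvr", {
    suvr_cols <- paste0("suvr_", voi_names())
    refspec <- reference_spec(config$reference_mode, config$box_edge_mm)
    dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
      truth <- setNames(unlist(cohort[i, suvr_cols]), voi_names())
      vol <- render_pet_volume(truth, atlas,
                               pons_activity = config$pons_activity,
                               noise_sd_fraction = config$noise_sd_fraction,
                               seed = seed + 100L + i)
      measure_subject_suvr(vol, atlas, cohort$subject_id[i], refspec)
    }))
  })

  db <- step("normative", {
    controls <- measurements[
      measurements$subject_id %in%
        cohort$subject_id[cohort$group == "CN"], ]
    if (nrow(controls) == 0) {
      stop("no control subjects available to build the normative ",
           "database; set group_sizes['CN'] >= 2")
    }
    build_normative_db(controls)
  })

  z_records <- step("zscore",
                    z_transform(measurements, db, config$orientation))
  calls <- step("classify",
                call_hypometabolism(z_records, config$threshold))

  metrics <- step("evaluate", {
    mci <- cohort[cohort$group %in% c("MCI_C", "MCI_NC"), ]
    truth <- tibble::tibble(subject_id = mci$subject_id,
                            converter = mci$group == "MCI_C")
    mci_calls <- calls[calls$subject_id %in% mci$subject_id, ]
    setNames(lapply(config$rules, function(r) {
      evaluate_predictions(predict_conversion(mci_calls, r), truth)
    }), config$rules)
  })

  prevalence <- step("prevalence",
                     hypometabolism_prevalence(calls, cohort))

  scores <- step("trajectories",
                 generate_longitudinal_scores(cohort,
                                              n_visits = config$n_visits,
                                              seed = seed + 2L))
  fit <- step("gee", fit_marginal_trajectory(scores, cohort, "MMSE"))

  paths <- step("write", {
    od <- config$output_dir
    p <- list(
      cohort = file.path(od, "cohort.tsv"),
      measurements = file.path(od, "voi_measurements.tsv"),
      zscores = file.path(od, "zscores.tsv"),
      calls = file.path(od, "hypometabolism_calls.tsv"),
      prevalence = file.path(od, "prevalence.tsv"),
      scores = file.path(od, "longitudinal_scores.tsv"),
      trajectory = file.path(od, "trajectory_mmse.tsv"),
      metrics = file.path(od, "metrics.json"),
      normative_db = file.path(od, "normative_db.json"),
      config = file.path(od, "config.json")
    )
    write_stamped_tsv(cohort, p$cohort, seed, hash)
    write_stamped_tsv(measurements, p$measurements, seed, hash)
    write_stamped_tsv(z_records, p$zscores, seed, hash)
    write_stamped_tsv(calls, p$calls, seed, hash)
    write_stamped_tsv(prevalence, p$prevalence, seed, hash)
    write_stamped_tsv(scores, p$scores, seed, hash)
    write_stamped_tsv(fit$coefficients, p$trajectory, seed, hash)
    jsonlite::write_json(
      lapply(metrics, function(m) {
        list(confusion = as.list(m$confusion),
             metrics = m$metrics)
      }),
      p$metrics, auto_unbox = TRUE, digits = NA, na = "null"
    )
    write_normative_db(db, p$normative_db)
    jsonlite::write_json(
      c(unclass(config), list(config_hash = hash)),
      p$config, auto_unbox = TRUE, digits = NA
    )
    p
  })
  stage_log(verbose, "total", t0)

  invisible(list(cohort = cohort, atlas = atlas,
                 measurements = measurements, db = db,
                 z_records = z_records, calls = calls, metrics = metrics,
                 prevalence = prevalence, scores = scores,
                 trajectory_fit = fit, paths = paths,
                 config = config, config_hash = hash))
}
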