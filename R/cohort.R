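#' Generate a synthetic cross-sectional cohort
#'
#' Draws one row per subject: diagnostic group, demographics (age, sex,
#' education, APOE e4 carrier status), baseline cognition (MMSE, CASI)
#' and the subject's "true" baseline SUVr in each of the seven VOIs,
#' drawn from the per-(group, VOI) normal profile truncated at zero.
#'
#' Regional values are independent across VOIs by default. Setting
#' `severity_loading` to a value in `(0, 1)` introduces a common
#' subject-level severity factor: a subject one SD "more severe" is
#' shifted `-loading` SDs in every VOI and in baseline MMSE/CASI, which
#' induces realistic co-hypometabolism and a positive correlation between
#' regional uptake and cognition.
#'
#' @param group_sizes Named vector of subject counts per group; names
#'   must be a subset of [group_levels()].
#' @param profile Regional SUVr profile, as [default_regional_profile()].
#' @param seed Integer seed; fixed seeds give bit-identical cohorts.
#' @param demographics Group demographic parameters, as
#'   [default_demographics()].
#' @param severity_loading Loading of the shared severity factor on
#'   regional SUVr and baseline cognition, in `[0, 1)`. Default 0
#'   (independence).
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `age_years`, `sex` (`"M"`/`"F"`), `education_years`,
#'   `apoe4_carrier`, `baseline_mmse` (integer 0-30), `baseline_casi`
#'   (0-100), `conversion_interval_years` and `followup_years`
#'   (`NA` until [assign_conversion_times()] is applied), and one
#'   `suvr_<VOI>` column per VOI.
#' @seealso [assign_conversion_times()], [generate_longitudinal_scores()]
#' @export
generate_cohort <- function(group_sizes,
                            profile = default_regional_profile(),
                            seed = 1L,
                            demographics = default_demographics(),
                            severity_loading = 0) {
  stopifnot(is.numeric(group_sizes), length(group_sizes) >= 1,
            !is.null(names(group_sizes)),
            severity_loading >= 0, severity_loading < 1)
  unknown <- setdiff(names(group_sizes), group_levels())
  if (length(unknown) > 0) {
    stop("unknown group name(s): ", paste(unknown, collapse = ", "))
  }
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")
  check_profile(profile)

  set.seed(as.integer(seed))
  lam <- severity_loading
  res <- sqrt(1 - lam^2)

  rows <- lapply(names(group_sizes), function(g) {
    n <- as.integer(group_sizes[[g]])
    if (n == 0) return(NULL)
    d <- demographics[demographics$group == g, ]
    f <- rnorm(n)  # shared severity factor, higher = more severe
    mmse <- d$mmse_mean + d$mmse_sd * (-lam * f + res * rnorm(n))
    casi <- d$casi_mean + d$casi_sd * (-lam * f + res * rnorm(n))
    out <- tibble::tibble(
      subject_id = sprintf("%s_%03d", g, seq_len(n)),
      group = g,
      age_years = rtruncnorm(n, d$age_mean, d$age_sd, lower = 18),
      sex = ifelse(rbinom(n, 1, d$male_fraction) == 1, "M", "F"),
      education_years = rtruncnorm(n, d$edu_mean, d$edu_sd, lower = 0),
      apoe4_carrier = rbinom(n, 1, d$apoe4_fraction) == 1,
      baseline_mmse = as.integer(pmin(pmax(round(mmse), 0), 30)),
      baseline_casi = pmin(pmax(casi, 0), 100),
      conversion_interval_years = NA_real_,
      followup_years = NA_real_
    )
    for (v in voi_names()) {
      p <- profile[profile$group == g & profile$voi == v, ]
      x <- p$suvr_mean + p$suvr_sd * (-lam * f + res * rnorm(n))
      # truncate at zero: redraw the (very rare) non-positive values
      bad <- which(x <= 0)
      while (length(bad) > 0) {
        x[bad] <- rtruncnorm(length(bad), p$suvr_mean, p$suvr_sd, lower = 0)
        bad <- which(x <= 0)
      }
      out[[paste0("suvr_", v)]] <- x
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    # typed empty table with the full schema
    out <- generate_cohort(c(CN = 1L), profile, seed, demographics)[0, ]
  }
  out
}

check_profile <- function(profile) {
  need <- c("group", "voi", "suvr_mean", "suvr_sd")
  if (!all(need %in% names(profile))) {
    stop("profile must have columns ", paste(need, collapse = ", "))
  }
  if (any(profile$suvr_sd <= 0)) stop("profile SDs must be positive")
  if (any(profile$suvr_mean <= 0)) stop("profile means must be positive")
  key <- paste(profile$group, profile$voi)
  if (anyDuplicated(key)) stop("duplicate (group, voi) entries in profile")
  invisible(TRUE)
}

#' Assign conversion intervals and follow-up durations
#'
#' Fills `conversion_interval_years` (MCI converters only) and
#' `followup_years` for every subject. Converter intervals are drawn from
#' a normal distribution truncated to the observed clinical range;
#' non-converter follow-up likewise. The defaults encode a cohort in
#' which dementia conversion occurred on average 3.70 (SD 1.68) years
#' after the baseline scan, within 1-8 years, and non-converters were
#' followed 4.34 (SD 1.26) years, within 2-7 years. Control and AD
#' follow-up are drawn from their group follow-up statistics; converter
#' follow-up is floored at the conversion interval so follow-up never
#' ends before conversion.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param seed Integer seed.
#' @param interval_mean,interval_sd,interval_range Truncated-normal
#'   parameters of the converter's scan-to-conversion interval (years).
#' @param nc_followup_mean,nc_followup_sd,nc_followup_range Same for the
#'   non-converter observation period.
#' @param demographics Source of the control/AD follow-up statistics.
#' @return The cohort with `conversion_interval_years` and
#'   `followup_years` filled.
#' @export
assign_conversion_times <- function(cohort, seed = 1L,
                                    interval_mean = 3.70,
                                    interval_sd = 1.68,
                                    interval_range = c(1, 8),
                                    nc_followup_mean = 4.34,
                                    nc_followup_sd = 1.26,
                                    nc_followup_range = c(2, 7),
                                    demographics = default_demographics()) {
  if (!all(c("subject_id", "group") %in% names(cohort))) {
    stop("cohort must have subject_id and group columns")
  }
  set.seed(as.integer(seed))
  cohort$conversion_interval_years <- NA_real_
  cohort$followup_years <- NA_real_
  for (g in unique(cohort$group)) {
    idx <- which(cohort$group == g)
    n <- length(idx)
    if (g == "MCI_C") {
      iv <- rtruncnorm(n, interval_mean, interval_sd,
                       interval_range[1], interval_range[2])
      d <- demographics[demographics$group == g, ]
      fu <- rtruncnorm(n, d$followup_mean, d$followup_sd, lower = 0.5)
      cohort$conversion_interval_years[idx] <- iv
      cohort$followup_years[idx] <- pmax(fu, iv)
    } else if (g == "MCI_NC") {
      cohort$followup_years[idx] <-
        rtruncnorm(n, nc_followup_mean, nc_followup_sd,
                   nc_followup_range[1], nc_followup_range[2])
    } else {
      d <- demographics[demographics$group == g, ]
      cohort$followup_years[idx] <-
        rtruncnorm(n, d$followup_mean, d$followup_sd, lower = 0.5)
    }
  }
  cohort
}

#' Reshape a cohort's true SUVr columns to long format
#'
#' @param cohort A cohort tibble with `suvr_<VOI>` columns.
#' @return Tibble `subject_id`, `group`, `voi`, `mean_suvr` — the same
#'   schema produced by [aggregate_vois()], so the normative/Z pipeline
#'   can run directly on generator truth without rendered images.
#' @export
cohort_suvr_long <- function(cohort) {
  cols <- paste0("suvr_", voi_names())
  stopifnot(all(cols %in% names(cohort)))
  out <- tidyr::pivot_longer(
    cohort[, c("subject_id", "group", cols)],
    cols = dplyr::all_of(cols),
    names_to = "voi", names_prefix = "suvr_", values_to = "mean_suvr"
  )
  out
}
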