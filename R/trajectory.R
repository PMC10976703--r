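#' Generate longitudinal MMSE/CASI trajectories
#'
#' Simulates approximately annual repeated cognitive measurements for
#' every subject in a cohort under a marginal model: the expected score
#' at visit `v` is the subject's baseline anchor plus the group-specific
#' visit offset, where the anchor is the cohort-drawn baseline score
#' shifted by group-centered education and male-sex effects. Residuals
#' are exchangeably correlated within subject (`within_subject_corr`)
#' with total SD `residual_sd`, realized as a subject-level intercept
#' plus independent visit noise. MMSE is rounded to the nearest integer
#' and clipped to 0-30; CASI is clipped to 0-100.
#'
#' Because covariate effects are centered within group, group means at
#' every visit follow baseline-mean + offset; the realized visit-1 value
#' is the subject's operative baseline (with all effects and noise at
#' zero it equals `baseline_mmse`/`baseline_casi` exactly).
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param spec A `trajectory_spec`, see [default_trajectory_spec()].
#' @param n_visits Number of measurements per subject (>= 2, and at most
#'   the number of visits configured in `spec$offsets`; there is no
#'   extrapolation rule beyond the configured offsets).
#' @param seed Integer seed.
#' @param visit_interval_years Nominal spacing between measurements
#'   (default 1 year); realized times get a small uniform jitter.
#' @return Tibble with columns `subject_id`, `group`, `visit_number`,
#'   `years_from_baseline`, `mmse` (integer), `casi`, sorted by subject
#'   then visit.
#' @export
generate_longitudinal_scores <- function(cohort,
                                         spec = default_trajectory_spec(),
                                         n_visits = 5,
                                         seed = 1L,
                                         visit_interval_years = 1) {
  stopifnot(inherits(spec, "trajectory_spec"), n_visits >= 2)
  max_visit <- max(spec$offsets$visit)
  if (n_visits > max_visit) {
    stop("n_visits = ", n_visits, " exceeds the ", max_visit,
         " visits configured in the trajectory spec; no extrapolation rule")
  }
  need <- c("subject_id", "group", "education_years", "sex",
            "baseline_mmse", "baseline_casi")
  stopifnot(all(need %in% names(cohort)))
  if (nrow(cohort) == 0) {
    return(tibble::tibble(subject_id = character(), group = character(),
                          visit_number = integer(),
                          years_from_baseline = numeric(),
                          mmse = integer(), casi = numeric()))
  }
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  rho <- spec$within_subject_corr

  # group-centered covariate deviations (keeps Table-style group means)
  edu_dev <- cohort$education_years -
    stats::ave(cohort$education_years, cohort$group)
  male <- as.numeric(cohort$sex == "M")
  male_dev <- male - stats::ave(male, cohort$group)

  anchors <- list(
    mmse = cohort$baseline_mmse + spec$beta_education[["mmse"]] * edu_dev +
      spec$beta_male[["mmse"]] * male_dev,
    casi = cohort$baseline_casi + spec$beta_education[["casi"]] * edu_dev +
      spec$beta_male[["casi"]] * male_dev
  )
  subj_int <- list(
    mmse = rnorm(n, 0, spec$residual_sd[["mmse"]] * sqrt(rho)),
    casi = rnorm(n, 0, spec$residual_sd[["casi"]] * sqrt(rho))
  )

  off <- spec$offsets
  rows <- vector("list", n_visits)
  for (v in seq_len(n_visits)) {
    ov <- off[off$visit == v, ]
    omm <- setNames(ov$mmse, ov$group)[cohort$group]
    oca <- setNames(ov$casi, ov$group)[cohort$group]
    mm <- anchors$mmse + omm + subj_int$mmse +
      rnorm(n, 0, spec$residual_sd[["mmse"]] * sqrt(1 - rho))
    ca <- anchors$casi + oca + subj_int$casi +
      rnorm(n, 0, spec$residual_sd[["casi"]] * sqrt(1 - rho))
    yrs <- if (v == 1) rep(0, n) else
      (v - 1) * visit_interval_years + runif(n, -0.15, 0.15)
    rows[[v]] <- tibble::tibble(
      subject_id = cohort$subject_id,
      group = cohort$group,
      visit_number = as.integer(v),
      years_from_baseline = yrs,
      mmse = as.integer(pmin(pmax(round(mm), 0), 30)),
      casi = pmin(pmax(ca, 0), 100)
    )
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$subject_id, .data$visit_number)
}

#' First visit at which a subject meets the dementia criterion
#'
#' Conversion is operationalized as the MMSE falling below 20 points.
#'
#' @param scores Longitudinal scores from
#'   [generate_longitudinal_scores()].
#' @param mmse_cutoff Dementia threshold (strictly below; default 20).
#' @return Tibble `subject_id`, `converted` (logical), `conversion_visit`
#'   (first visit with MMSE below the cutoff; `NA` if never).
#' @export
first_conversion_visit <- function(scores, mmse_cutoff = 20) {
  stopifnot(all(c("subject_id", "visit_number", "mmse") %in% names(scores)))
  scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      converted = any(.data$mmse < mmse_cutoff),
      conversion_visit = if (any(.data$mmse < mmse_cutoff))
        min(.data$visit_number[.data$mmse < mmse_cutoff]) else NA_integer_,
      .groups = "drop"
    )
}
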