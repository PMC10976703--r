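#' Diagnostic groups and regional VOI names
#'
#' The pipeline works with four diagnostic groups — cognitively normal
#' controls (`CN`), MCI non-converters (`MCI_NC`), MCI converters (`MCI_C`)
#' and Alzheimer's dementia (`AD`) — and seven signature volumes of
#' interest (VOIs) commonly assessed on FDG-PET in the AD continuum:
#' frontal lobe, parietal lobe, medial temporal lobe (MTL), lateral
#' temporal lobe, posterior cingulate cortex (PCC), precuneus and
#' occipital lobe.
#'
#' @return Character vector of group levels or VOI names, in canonical
#'   order.
#' @export
group_levels <- function() {
  c("CN", "MCI_NC", "MCI_C", "AD")
}

#' @rdname group_levels
#' @export
voi_names <- function() {
  c("FRONTAL", "PARIETAL", "MTL", "LAT_TEMPORAL", "PCC", "PRECUNEUS",
    "OCCIPITAL")
}

#' Default regional SUVr profile
#'
#' Per-(group, VOI) mean and standard deviation of the pons-referenced
#' SUVr used to draw each subject's "true" regional uptake. The defaults
#' encode the published group statistics of a clinical cohort of 40
#' controls, 38 MCI non-converters, 44 MCI converters and 42 AD patients:
#' uptake is progressively lower from controls through converters to AD
#' in the AD-signature regions (MTL, PCC, precuneus, lateral temporal,
#' parietal), while the occipital lobe is relatively spared.
#'
#' @return A tibble with columns `group`, `voi`, `suvr_mean`, `suvr_sd`,
#'   one row per (group, VOI) pair (28 rows).
#' @export
default_regional_profile <- function() {
  g <- group_levels()
  # rows: FRONTAL, MTL, LAT_TEMPORAL, PCC, PRECUNEUS, PARIETAL, OCCIPITAL
  # cols: CN, MCI_NC, MCI_C, AD (mean then sd)
  tab <- rbind(
    FRONTAL      = c(1.41, 0.10, 1.45, 0.04, 1.35, 0.06, 1.30, 0.07),
    MTL          = c(1.10, 0.07, 1.06, 0.05, 0.91, 0.07, 0.86, 0.02),
    LAT_TEMPORAL = c(1.40, 0.12, 1.38, 0.04, 1.23, 0.08, 1.19, 0.11),
    PCC          = c(1.61, 0.13, 1.60, 0.20, 1.37, 0.14, 1.20, 0.07),
    PRECUNEUS    = c(1.61, 0.12, 1.61, 0.05, 1.48, 0.09, 1.31, 0.08),
    PARIETAL     = c(1.50, 0.10, 1.49, 0.04, 1.36, 0.08, 1.21, 0.06),
    OCCIPITAL    = c(1.60, 0.11, 1.59, 0.05, 1.56, 0.08, 1.39, 0.12)
  )
  out <- do.call(rbind, lapply(seq_along(g), function(i) {
    tibble::tibble(
      group = g[i],
      voi = rownames(tab),
      suvr_mean = tab[, 2 * i - 1],
      suvr_sd = tab[, 2 * i]
    )
  }))
  out$voi <- factor(out$voi, levels = voi_names())
  out <- out[order(match(out$group, g), out$voi), ]
  out$voi <- as.character(out$voi)
  tibble::as_tibble(out)
}

#' Default group demographic and cognitive parameters
#'
#' Group-level means and SDs used to draw age, education, baseline MMSE
#' (0-30) and CASI (0-100), plus the male and APOE e4 carrier fractions
#' and the clinical follow-up duration of each group.
#'
#' @return A tibble with one row per group.
#' @export
default_demographics <- function() {
  tibble::tibble(
    group         = group_levels(),
    age_mean      = c(62.6, 72.1, 74.7, 77.0),
    age_sd        = c(11.6, 7.60, 7.04, 7.6),
    male_fraction = c(23 / 40, 15 / 38, 19 / 44, 21 / 42),
    edu_mean      = c(13.6, 6.9, 7.1, 7.5),
    edu_sd        = c(3.7, 5.0, 4.9, 5.3),
    apoe4_fraction = c(0.238, 0.378, 0.609, 0.579),
    mmse_mean     = c(28.1, 23.5, 21.8, 17.4),
    mmse_sd       = c(2.1, 4.36, 3.7, 2.9),
    casi_mean     = c(92.6, 77.84, 74.9, 63.1),
    casi_sd       = c(6.1, 13.9, 12.2, 15.3),
    followup_mean = c(4.4, 6.4, 6.7, 6.6),
    followup_sd   = c(1.8, 3.8, 3.6, 3.2)
  )
}

#' Default published group sizes
#'
#' @return Named integer vector of the default cohort composition
#'   (40 CN, 38 MCI non-converters, 44 MCI converters, 42 AD; 164 total).
#' @export
default_group_sizes <- function() {
  c(CN = 40L, MCI_NC = 38L, MCI_C = 44L, AD = 42L)
}

#' Default longitudinal trajectory specification
#'
#' Marginal-model parameters generating annual MMSE and CASI
#' measurements. Visit effects are coded against visit 1 (baseline) with
#' the control group as reference: `offsets` holds the per-group,
#' per-visit mean change from baseline (visit 1 offset is 0 for every
#' group; control offsets are 0 at every visit). The non-converter group
#' shows a transient improvement at the third measurement (+0.557 MMSE
#' points, +4.240 CASI points) before a mild late decline, while the
#' converter and AD groups decline steadily down to about -5 MMSE points
#' by the sixth measurement.
#'
#' Education (points per year of schooling) and male sex enter as
#' subject-level covariate effects, centered within group so group means
#' of the baseline scores are unchanged. Residual noise has a
#' within-subject exchangeable correlation (`within_subject_corr`) and a
#' total SD per instrument (`residual_sd`).
#'
#' @param within_subject_corr Exchangeable correlation between repeated
#'   scores of one subject, in `[0, 1)`. Default 0.5.
#' @param mmse_residual_sd,casi_residual_sd Total residual SD of a single
#'   MMSE / CASI measurement (points). Defaults 1.5 and 5.
#' @return A list of class `trajectory_spec` with elements `offsets`
#'   (tibble: group, visit, mmse, casi), `beta_education`, `beta_male`
#'   (named vectors with `mmse`/`casi` entries), `residual_sd`, and
#'   `within_subject_corr`.
#' @export
default_trajectory_spec <- function(within_subject_corr = 0.5,
                                    mmse_residual_sd = 1.5,
                                    casi_residual_sd = 5) {
  stopifnot(within_subject_corr >= 0, within_subject_corr < 1,
            mmse_residual_sd >= 0, casi_residual_sd >= 0)
  mmse <- rbind(
    CN     = c(0, 0, 0, 0, 0, 0),
    MCI_NC = c(0, -0.687, 0.557, -0.076, -0.237, -1.206),
    MCI_C  = c(0, -0.339, -0.888, -1.990, -2.730, -5.116),
    AD     = c(0, -0.847, -1.020, -2.256, -3.004, -5.325)
  )
  casi <- rbind(
    CN     = c(0, 0, 0, 0, 0, 0),
    MCI_NC = c(0, -1.890, 4.240, 0.248, -2.682, -8.594),
    MCI_C  = c(0, -1.260, -2.628, -7.282, -15.957, -22.565),
    AD     = c(0, -1.573, -3.177, -8.341, -15.092, -21.842)
  )
  offsets <- do.call(rbind, lapply(group_levels(), function(g) {
    tibble::tibble(group = g, visit = 1:6,
                   mmse = mmse[g, ], casi = casi[g, ])
  }))
  spec <- list(
    offsets = tibble::as_tibble(offsets),
    beta_education = c(mmse = 0.415, casi = 1.376),
    beta_male = c(mmse = 1.198, casi = 4.694),
    residual_sd = c(mmse = mmse_residual_sd, casi = casi_residual_sd),
    within_subject_corr = within_subject_corr
  )
  class(spec) <- "trajectory_spec"
  spec
}

#' Null trajectory specification
#'
#' All visit offsets and covariate effects zero — useful for null
#' calibration and flat-trajectory checks.
#'
#' @param residual_sd Total residual SD applied to both instruments.
#' @param within_subject_corr Exchangeable within-subject correlation.
#' @return A `trajectory_spec`.
#' @export
null_trajectory_spec <- function(residual_sd = 0, within_subject_corr = 0) {
  spec <- default_trajectory_spec(
    within_subject_corr = within_subject_corr,
    mmse_residual_sd = residual_sd,
    casi_residual_sd = residual_sd
  )
  spec$offsets$mmse <- 0
  spec$offsets$casi <- 0
  spec$beta_education[] <- 0
  spec$beta_male[] <- 0
  spec
}
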