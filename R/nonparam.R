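#' Visit-wise two-group rank-sum comparison
#'
#' Mann-Whitney (Wilcoxon rank-sum) comparison of an outcome between two
#' groups at one measurement. The exact null distribution is used when
#' both groups have at most `exact_max` observations and there are no
#' ties; otherwise the tie-corrected normal approximation (without
#' continuity correction) is used.
#'
#' @param scores Longitudinal scores table (`subject_id`, `group`,
#'   `visit_number`, `mmse`, `casi`).
#' @param group_a,group_b Group labels to compare.
#' @param visit Measurement number.
#' @param outcome `"MMSE"` or `"CASI"`.
#' @param exact_max Largest group size for which the exact distribution
#'   is used (default 10).
#' @return Tibble `visit`, `group_a`, `group_b`, `outcome`, `n_a`,
#'   `n_b`, `statistic` (Mann-Whitney U for group_a), `p_value`,
#'   `method`.
#' @export
visitwise_group_test <- function(scores, group_a, group_b, visit,
                                 outcome = c("MMSE", "CASI"),
                                 exact_max = 10) {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "MMSE") "mmse" else "casi"
  x <- scores[[ycol]][scores$group == group_a &
                        scores$visit_number == visit]
  y <- scores[[ycol]][scores$group == group_b &
                        scores$visit_number == visit]
  if (length(x) == 0 || length(y) == 0) {
    stop("empty group at visit ", visit, ": ",
         if (length(x) == 0) group_a else group_b)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = FALSE)
  )
  tibble::tibble(
    visit = as.integer(visit), group_a = group_a, group_b = group_b,
    outcome = outcome, n_a = length(x), n_b = length(y),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (use_exact) "exact" else "normal_tie_corrected"
  )
}

#' First visit with a significant group difference
#'
#' Scans the measurements in order and reports the first at which the
#' rank-sum comparison rejects at `alpha`.
#'
#' @inheritParams visitwise_group_test
#' @param alpha Significance level (default 0.05).
#' @return List with `first_significant_visit` (integer or `NA`) and
#'   `by_visit` (tibble of all per-visit comparisons).
#' @export
first_significant_visit <- function(scores, group_a, group_b,
                                    outcome = c("MMSE", "CASI"),
                                    alpha = 0.05, exact_max = 10) {
  outcome <- match.arg(outcome)
  visits <- sort(unique(scores$visit_number))
  res <- dplyr::bind_rows(lapply(visits, function(v) {
    visitwise_group_test(scores, group_a, group_b, v, outcome, exact_max)
  }))
  sig <- which(res$p_value < alpha)
  list(
    first_significant_visit = if (length(sig)) res$visit[min(sig)]
      else NA_integer_,
    by_visit = res
  )
}

#' Paired two-scan comparison of regional Z scores
#'
#' Wilcoxon signed-rank test of follow-up versus baseline Z per VOI over
#' the subjects present in both scans. Zero differences are dropped
#' (standard signed-rank convention); when every difference is zero the
#' statistic and p-value are reported as `NA`. The exact null
#' distribution is used for at most `exact_max` non-zero pairs without
#' ties in the absolute differences; otherwise the tie-corrected normal
#' approximation.
#'
#' @param z_baseline,z_followup Tibbles `subject_id`, `voi`, `z`.
#' @param exact_max Exact-distribution cutoff (default 10).
#' @return Tibble `voi`, `n_pairs`, `n_nonzero`, `statistic` (V, the sum
#'   of positive ranks of follow-up minus baseline), `p_value`,
#'   `method`.
#' @export
paired_scan_test <- function(z_baseline, z_followup, exact_max = 10) {
  need <- c("subject_id", "voi", "z")
  stopifnot(all(need %in% names(z_baseline)),
            all(need %in% names(z_followup)))
  m <- dplyr::inner_join(
    z_baseline[, need], z_followup[, need],
    by = c("subject_id", "voi"), suffix = c("_base", "_fu")
  )
  if (nrow(m) == 0) stop("no paired subjects present in both scans")
  rows <- lapply(sort(unique(m$voi)), function(v) {
    d <- m$z_fu[m$voi == v] - m$z_base[m$voi == v]
    nz <- d[d != 0]
    if (length(nz) == 0) {
      return(tibble::tibble(voi = v, n_pairs = length(d),
                            n_nonzero = 0L, statistic = NA_real_,
                            p_value = NA_real_, method = "all_zero"))
    }
    ties <- anyDuplicated(abs(nz)) > 0
    use_exact <- !ties && length(nz) <= exact_max
    wt <- suppressWarnings(
      wilcox.test(nz, exact = use_exact, correct = FALSE)
    )
    tibble::tibble(voi = v, n_pairs = length(d),
                   n_nonzero = length(nz),
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   method = if (use_exact) "exact"
                     else "normal_tie_corrected")
  })
  dplyr::bind_rows(rows)
}

#' Spearman correlation of regional Z with cognition, by group
#'
#' Rank correlation (average ranks for ties) between each VOI's baseline
#' Z score and a baseline cognitive score, computed within diagnostic
#' group. Pairs with fewer than 3 observations, or with a constant
#' vector (undefined rank correlation), are reported as `NA` with a
#' warning.
#'
#' @param z_records Tibble `subject_id`, `voi`, `z`.
#' @param cohort Cohort table supplying `group` and the baseline score.
#' @param outcome `"MMSE"` or `"CASI"`.
#' @return Tibble `group`, `voi`, `n`, `rho`, `p_value`.
#' @export
correlate_z_cognition <- function(z_records, cohort,
                                  outcome = c("MMSE", "CASI")) {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "MMSE") "baseline_mmse" else "baseline_casi"
  stopifnot(all(c("subject_id", "group", ycol) %in% names(cohort)))
  m <- dplyr::inner_join(
    z_records[, c("subject_id", "voi", "z")],
    cohort[, c("subject_id", "group", ycol)],
    by = "subject_id"
  )
  if (nrow(m) == 0) stop("no subjects shared between z records and cohort")
  combos <- unique(m[, c("group", "voi")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$group[i]; v <- combos$voi[i]
    sub <- m[m$group == g & m$voi == v, ]
    z <- sub$z; y <- as.numeric(sub[[ycol]])
    ok <- complete.cases(z, y)
    z <- z[ok]; y <- y[ok]
    if (length(z) < 3 || length(unique(z)) < 2 || length(unique(y)) < 2) {
      warning("Spearman correlation undefined for group ", g, ", VOI ", v,
              " (fewer than 3 pairs or constant input)")
      return(tibble::tibble(group = g, voi = v, n = length(z),
                            rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(z, y, method = "spearman",
                                    exact = FALSE))
    tibble::tibble(group = g, voi = v, n = length(z),
                   rho = unname(ct$estimate), p_value = ct$p.value)
  })
  dplyr::bind_rows(rows)
}
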