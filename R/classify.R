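#' Call regional hypometabolism from Z scores
#'
#' A VOI is hypometabolic when its Z score is strictly below the
#' threshold (default -2); a boundary value of exactly -2 is normal.
#'
#' @param z_records Tibble `subject_id`, `voi`, `z` (finite).
#' @param threshold Calling threshold (default -2).
#' @return The input with logical `is_hypometabolic` and the
#'   `threshold` recorded per row.
#' @export
call_hypometabolism <- function(z_records, threshold = -2) {
  stopifnot(all(c("subject_id", "voi", "z") %in% names(z_records)))
  if (any(!is.finite(z_records$z))) {
    stop("non-finite z values cannot be classified")
  }
  out <- z_records
  out$is_hypometabolic <- out$z < threshold
  out$threshold <- threshold
  out
}

#' Parse a conversion-prediction rule
#'
#' Rules are a single VOI name, a conjunction joined by `&`, or a
#' disjunction joined by `|` (e.g. `"MTL"`, `"MTL&PCC"`, `"MTL|PCC"`);
#' mixing the two operators is not supported.
#'
#' @param rule Rule string (or an already-parsed `prediction_rule`).
#' @return A `prediction_rule` with elements `vois` and `op`
#'   (`"single"`, `"and"`, `"or"`) and the original `label`.
#' @export
parse_rule <- function(rule) {
  if (inherits(rule, "prediction_rule")) return(rule)
  stopifnot(is.character(rule), length(rule) == 1, nzchar(rule))
  txt <- gsub("[[:space:]]", "", rule)
  has_and <- grepl("&", txt, fixed = TRUE)
  has_or <- grepl("|", txt, fixed = TRUE)
  if (has_and && has_or) {
    stop("rule '", rule, "' mixes '&' and '|'; use one operator")
  }
  op <- if (has_and) "and" else if (has_or) "or" else "single"
  vois <- strsplit(txt, "[&|]")[[1]]
  if (any(!nzchar(vois))) stop("malformed rule: '", rule, "'")
  structure(list(vois = vois, op = op, label = txt),
            class = "prediction_rule")
}

#' Predict conversion from hypometabolism calls
#'
#' Evaluates a rule over each subject's per-VOI calls: a single-VOI rule
#' predicts conversion when that VOI is hypometabolic; `&` requires all
#' listed VOIs, `|` any of them.
#'
#' @param calls Output of [call_hypometabolism()].
#' @param rule A rule string or `prediction_rule`; every referenced VOI
#'   must have a call for every subject.
#' @return Tibble `subject_id`, `predicted_converter` (logical), `rule`.
#' @export
predict_conversion <- function(calls, rule) {
  rule <- parse_rule(rule)
  stopifnot(all(c("subject_id", "voi", "is_hypometabolic") %in%
                  names(calls)))
  missing_voi <- setdiff(rule$vois, unique(calls$voi))
  if (length(missing_voi) > 0) {
    stop("rule references VOI(s) without calls: ",
         paste(missing_voi, collapse = ", "))
  }
  sub <- calls[calls$voi %in% rule$vois, ]
  counts <- table(sub$subject_id)
  if (any(counts < length(rule$vois))) {
    stop("subject(s) missing a call for a rule VOI: ",
         paste(names(counts)[counts < length(rule$vois)], collapse = ", "))
  }
  agg <- sub |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      predicted_converter = if (rule$op == "and")
        all(.data$is_hypometabolic) else any(.data$is_hypometabolic),
      .groups = "drop"
    )
  agg$rule <- rule$label
  agg
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Evaluate conversion predictions against observed outcomes
#'
#' Cross-tabulates predictions with true converter labels and reports
#' sensitivity, specificity, positive and negative predictive value and
#' accuracy, each with an exact (Clopper-Pearson) binomial 95% CI.
#' Metrics with a zero denominator (e.g. PPV when nothing is predicted
#' positive) are reported as `NA` with a warning, never coerced to 0.
#'
#' @param predictions Tibble `subject_id`, `predicted_converter`.
#' @param truth Tibble `subject_id`, `converter` (logical observed
#'   outcome), covering exactly the predicted subjects.
#' @param conf_level CI coverage (default 0.95).
#' @return A list of class `diagnostic_metrics`: `confusion` (tp, fp,
#'   fn, tn) and `metrics` (tibble metric, estimate, ci_lower, ci_upper,
#'   numerator, denominator).
#' @export
evaluate_predictions <- function(predictions, truth, conf_level = 0.95) {
  stopifnot(all(c("subject_id", "predicted_converter") %in%
                  names(predictions)),
            all(c("subject_id", "converter") %in% names(truth)))
  if (nrow(predictions) == 0) stop("no predictions to evaluate")
  if (!setequal(predictions$subject_id, truth$subject_id) ||
      anyDuplicated(predictions$subject_id) ||
      anyDuplicated(truth$subject_id)) {
    stop("predictions and truth must cover the same subjects exactly once")
  }
  m <- dplyr::inner_join(predictions, truth, by = "subject_id")
  tp <- sum(m$predicted_converter & m$converter)
  fp <- sum(m$predicted_converter & !m$converter)
  fn <- sum(!m$predicted_converter & m$converter)
  tn <- sum(!m$predicted_converter & !m$converter)
  defs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv = c(tp, tp + fp),
    npv = c(tn, tn + fn),
    accuracy = c(tp + tn, tp + fp + fn + tn)
  )
  rows <- lapply(names(defs), function(nm) {
    x <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n == 0) {
      warning(nm, " is undefined (zero denominator); reported as NA")
      tibble::tibble(metric = nm, estimate = NA_real_,
                     ci_lower = NA_real_, ci_upper = NA_real_,
                     numerator = x, denominator = n)
    } else {
      ci <- clopper_pearson(x, n, conf_level)
      tibble::tibble(metric = nm, estimate = x / n,
                     ci_lower = ci[1], ci_upper = ci[2],
                     numerator = x, denominator = n)
    }
  })
  structure(
    list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
         metrics = dplyr::bind_rows(rows),
         conf_level = conf_level),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cf <- x$confusion
  cat(sprintf("Confusion: TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              cf["tp"], cf["fp"], cf["fn"], cf["tn"], sum(cf)))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined (0 denominator)\n", m$metric[i]))
    } else {
      cat(sprintf("  %-12s %5.1f%%  (%d/%d, %.0f%% CI %.1f-%.1f%%)\n",
                  m$metric[i], 100 * m$estimate[i], m$numerator[i],
                  m$denominator[i], 100 * x$conf_level,
                  100 * m$ci_lower[i], 100 * m$ci_upper[i]))
    }
  }
  invisible(x)
}

#' Per-group, per-VOI hypometabolism prevalence
#'
#' @param calls Output of [call_hypometabolism()].
#' @param cohort Cohort tibble supplying each subject's group.
#' @return Tibble `group`, `voi`, `n_hypometabolic`, `n`, `fraction`.
#' @export
hypometabolism_prevalence <- function(calls, cohort) {
  stopifnot(all(c("subject_id", "group") %in% names(cohort)))
  m <- dplyr::inner_join(calls[, setdiff(names(calls), "group")],
                         cohort[, c("subject_id", "group")],
                         by = "subject_id")
  if (nrow(m) == 0) stop("no subjects in common between calls and cohort")
  m |>
    dplyr::group_by(.data$group, .data$voi) |>
    dplyr::summarise(
      n_hypometabolic = sum(.data$is_hypometabolic),
      n = dplyr::n(),
      fraction = sum(.data$is_hypometabolic) / dplyr::n(),
      .groups = "drop"
    )
}
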