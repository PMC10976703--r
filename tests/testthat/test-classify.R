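test_that("hypometabolism calls use a strict threshold", {
  z <- tibble::tibble(subject_id = c("a", "b", "c"), voi = "MTL",
                      z = c(-2.0, -2.71, -1.5))
  calls <- call_hypometabolism(z)
  expect_equal(calls$is_hypometabolic, c(FALSE, TRUE, FALSE))
  expect_true(all(calls$threshold == -2))

  calls1 <- call_hypometabolism(z, threshold = -1)
  expect_equal(calls1$is_hypometabolic, c(TRUE, TRUE, TRUE))

  expect_error(call_hypometabolism(
    tibble::tibble(subject_id = "a", voi = "MTL", z = NaN)), "non-finite")

  # monotonicity: a more negative threshold never flags more subjects
  set.seed(30)
  zr <- tibble::tibble(subject_id = sprintf("s%02d", 1:50), voi = "MTL",
                       z = rnorm(50, -1, 1.5))
  n_flagged <- vapply(c(-1, -1.5, -2, -2.5, -3), function(th) {
    sum(call_hypometabolism(zr, th)$is_hypometabolic)
  }, numeric(1))
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("rule engine matches an exhaustive truth table", {
  grid <- expand.grid(mtl = c(TRUE, FALSE), pcc = c(TRUE, FALSE))
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    tibble::tibble(subject_id = paste0("s", i), voi = c("MTL", "PCC"),
                   z = 0, is_hypometabolic = c(grid$mtl[i], grid$pcc[i]),
                   threshold = -2)
  }))
  for (rule in c("MTL", "PCC", "MTL&PCC", "MTL|PCC")) {
    pred <- predict_conversion(calls, rule)
    pred <- pred[order(pred$subject_id), ]
    expected <- switch(rule,
      "MTL" = grid$mtl, "PCC" = grid$pcc,
      "MTL&PCC" = grid$mtl & grid$pcc,
      "MTL|PCC" = grid$mtl | grid$pcc
    )
    expect_equal(pred$predicted_converter, expected, info = rule)
  }
  expect_error(predict_conversion(calls, "MTL&OCC"), "without calls")
  expect_error(parse_rule("MTL&PCC|MTL"), "mixes")
  expect_error(parse_rule("&MTL"), "malformed")
})

test_that("diagnostic metrics match their defining ratios", {
  # counts chosen to exercise the formulas: 36/38 sens, 33/41 spec
  truth <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:79),
    converter = rep(c(TRUE, FALSE), c(38, 41))
  )
  pred <- tibble::tibble(
    subject_id = truth$subject_id,
    predicted_converter = c(rep(TRUE, 36), rep(FALSE, 2),
                            rep(TRUE, 8), rep(FALSE, 33))
  )
  ev <- evaluate_predictions(pred, truth)
  expect_equal(unname(ev$confusion), c(36, 8, 2, 33))
  m <- setNames(ev$metrics$estimate, ev$metrics$metric)
  expect_equal(round(100 * m[["sensitivity"]], 1), 94.7)
  expect_equal(round(100 * m[["specificity"]], 1), 80.5)
  expect_equal(m[["ppv"]], 36 / 44)
  expect_equal(m[["npv"]], 33 / 35)
  expect_equal(sum(ev$confusion), nrow(truth))

  # exact binomial CI against binom.test (independent route)
  bt <- binom.test(36, 38)$conf.int
  sens_row <- ev$metrics[ev$metrics$metric == "sensitivity", ]
  expect_equal(sens_row$ci_lower, bt[1], tolerance = 1e-9)
  expect_equal(sens_row$ci_upper, bt[2], tolerance = 1e-9)
})

test_that("degenerate predictors: perfect and all-negative", {
  truth <- tibble::tibble(subject_id = letters[1:10],
                          converter = rep(c(TRUE, FALSE), 5))
  perfect <- tibble::tibble(subject_id = letters[1:10],
                            predicted_converter = truth$converter)
  ev <- evaluate_predictions(perfect, truth)
  m <- setNames(ev$metrics$estimate, ev$metrics$metric)
  expect_equal(unname(m[c("sensitivity", "specificity")]), c(1, 1))

  allneg <- tibble::tibble(subject_id = letters[1:10],
                           predicted_converter = FALSE)
  expect_warning(ev2 <- evaluate_predictions(allneg, truth), "ppv")
  m2 <- setNames(ev2$metrics$estimate, ev2$metrics$metric)
  expect_equal(unname(m2[["sensitivity"]]), 0)
  expect_equal(unname(m2[["specificity"]]), 1)
  expect_true(is.na(m2[["ppv"]]))

  expect_error(evaluate_predictions(perfect, truth[1:5, ]),
               "same subjects")
})

test_that("prevalence equals brute-force counting", {
  co <- tiny_cohort(c(MCI_C = 10L, MCI_NC = 10L), seed = 21)
  set.seed(22)
  z <- cohort_suvr_long(co)
  z$z <- rnorm(nrow(z), -1.5, 1)
  z$mean_suvr <- NULL
  calls <- call_hypometabolism(z)
  prev <- hypometabolism_prevalence(calls, co)
  for (i in seq_len(nrow(prev))) {
    manual <- calls$is_hypometabolic[
      calls$voi == prev$voi[i] &
        calls$subject_id %in% co$subject_id[co$group == prev$group[i]]]
    expect_equal(prev$fraction[i], mean(manual))
    expect_equal(prev$n_hypometabolic[i], sum(manual))
  }
  all_true <- calls
  all_true$is_hypometabolic <- TRUE
  expect_true(all(hypometabolism_prevalence(all_true, co)$fraction == 1))
})

test_that("end-to-end threshold equivalence: flag iff SUVr below mu - 2 sd", {
  at <- small_atlas()
  co <- generate_cohort(c(CN = 20L, MCI_C = 15L), seed = 23)
  meas <- dplyr::bind_rows(lapply(seq_len(nrow(co)), function(i) {
    truth <- setNames(unlist(co[i, paste0("suvr_", voi_names())]),
                      voi_names())
    measure_subject_suvr(render_pet_volume(truth, at, 1000, 0), at,
                         co$subject_id[i])
  }))
  db <- build_normative_db(
    meas[meas$subject_id %in% co$subject_id[co$group == "CN"], ])
  calls <- call_hypometabolism(z_transform(meas, db))
  joined <- dplyr::inner_join(meas, db, by = "voi") |>
    dplyr::inner_join(calls[, c("subject_id", "voi", "is_hypometabolic")],
                      by = c("subject_id", "voi"))
  expect_equal(joined$is_hypometabolic,
               joined$mean_suvr < joined$mu_db - 2 * joined$sigma_db)
})
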