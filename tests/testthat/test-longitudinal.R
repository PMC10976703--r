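test_that("GEE equals OLS under working independence", {
  co <- tiny_cohort(c(CN = 20L, AD = 20L), seed = 31)
  sc <- generate_longitudinal_scores(co, n_visits = 3, seed = 32)
  dat <- dplyr::inner_join(sc, co[, c("subject_id", "sex",
                                      "education_years")],
                           by = "subject_id")
  dat$visit <- factor(dat$visit_number)
  fit <- gee_gaussian(mmse ~ sex + education_years + group * visit, dat,
                      id = "subject_id", corstr = "independence")
  ols <- lm(mmse ~ sex + education_years + group * visit, dat)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-8)
  expect_error(gee_gaussian(mmse ~ group + I(2 * as.numeric(group == "AD")),
                            dat, id = "subject_id"), "singular")
})

test_that("null simulation: interaction estimates center on zero", {
  co <- generate_cohort(c(CN = 60L, MCI_C = 60L), seed = 33)
  sc <- generate_longitudinal_scores(
    co, null_trajectory_spec(residual_sd = 2, within_subject_corr = 0.5),
    n_visits = 4, seed = 34
  )
  fit <- fit_marginal_trajectory(sc, co, "MMSE")
  co_tab <- fit$coefficients
  inter <- co_tab[grepl(":", co_tab$term), ]
  expect_true(all(abs(inter$estimate) < 3 * inter$robust_se))
})

test_that("trajectory model recovers seeded visit and covariate effects", {
  co <- generate_cohort(c(CN = 400L, MCI_NC = 380L, MCI_C = 440L,
                          AD = 420L), seed = 35)
  sc <- generate_longitudinal_scores(co, n_visits = 6, seed = 36)
  fit <- fit_marginal_trajectory(sc, co, "MMSE")
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$robust_se, fit$coefficients$term)

  expect_lt(abs(est[["groupMCI_C:visit6"]] - (-5.116)),
            3 * se[["groupMCI_C:visit6"]])
  expect_lt(abs(est[["groupMCI_NC:visit3"]] - 0.557),
            3 * se[["groupMCI_NC:visit3"]] + 0.15)
  expect_lt(abs(est[["education_years"]] - 0.415),
            3 * se[["education_years"]] + 0.05)
  expect_equal(fit$n_subjects, 1640)
  expect_gt(fit$rho, 0.5)  # baseline heterogeneity dominates
})

test_that("rank-sum test: identical samples, exact enumeration oracle", {
  sc <- tibble::tibble(
    subject_id = as.character(1:6),
    group = rep(c("A", "B"), each = 3),
    visit_number = 1L,
    mmse = c(1L, 2L, 3L, 10L, 11L, 12L),
    casi = c(1, 2, 3, 10, 11, 12)
  )
  res <- visitwise_group_test(sc, "A", "B", 1, "MMSE")
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, exact_ranksum_p(c(1, 2, 3), c(10, 11, 12)))

  same <- sc
  same$mmse <- rep(c(5L, 6L, 7L), 2)
  res2 <- visitwise_group_test(same, "A", "B", 1, "MMSE")
  expect_gte(res2$p_value, 0.99)

  # random no-tie cases agree with enumeration
  set.seed(40)
  for (i in 1:5) {
    x <- sample(100, 5); y <- sample(200:300, 6)
    sc3 <- tibble::tibble(subject_id = as.character(1:11),
                          group = rep(c("A", "B"), c(5, 6)),
                          visit_number = 1L, mmse = c(x, y),
                          casi = c(x, y))
    res3 <- visitwise_group_test(sc3, "A", "B", 1, "CASI")
    expect_equal(res3$p_value, exact_ranksum_p(x, y), tolerance = 1e-12)
  }
  expect_error(visitwise_group_test(sc, "A", "C", 1), "empty group")
})

test_that("converter/non-converter separation emerges by the third visit", {
  # at the enrolled group sizes the baseline gap (21.8 vs 23.5) sits just
  # short of significance, the gap narrows at visit 2, and the opposing
  # visit-3 offsets (-0.888 vs +0.557) open a ~3-point difference
  pmat <- vapply(1:30, function(i) {
    co <- generate_cohort(c(MCI_C = 44L, MCI_NC = 38L), seed = 4100 + i)
    sc <- generate_longitudinal_scores(co, n_visits = 4, seed = 4200 + i)
    first_significant_visit(sc, "MCI_C", "MCI_NC", "MMSE")$
      by_visit$p_value
  }, numeric(4))
  med <- apply(pmat, 1, median)
  expect_gt(med[2], 0.05)   # visit 2 typically not significant
  expect_lt(med[3], 0.05)   # visit 3 typically significant
  expect_lt(med[3], med[1]) # visit 3 stronger than baseline
  expect_lt(med[3], med[2])
})

test_that("signed-rank test: zero differences, shift, enumeration oracle", {
  z0 <- tibble::tibble(subject_id = rep(letters[1:8], 2),
                       voi = rep(c("MTL", "PCC"), each = 8),
                       z = rnorm(16))
  same <- paired_scan_test(z0, z0)
  expect_true(all(is.na(same$p_value)))
  expect_true(all(same$method == "all_zero"))

  shifted <- z0
  shifted$z <- shifted$z - 1
  res <- paired_scan_test(z0, shifted)
  # all differences -1: maximal one-sided statistic, ties in |d| force
  # the normal approximation; p small
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p_value < 0.05))

  set.seed(43)
  base <- tibble::tibble(subject_id = letters[1:9], voi = "MTL",
                         z = rnorm(9))
  fu <- base
  fu$z <- base$z + rnorm(9, -0.8, 0.7)
  res2 <- paired_scan_test(base, fu)
  expect_equal(res2$method, "exact")
  expect_equal(res2$p_value, exact_signedrank_p(fu$z - base$z),
               tolerance = 1e-12)
  expect_error(paired_scan_test(base, base[0, ]), "no paired subjects")
})

test_that("signed-rank power: converter decline detected across VOIs", {
  detect <- replicate(60, {
    co <- generate_cohort(c(MCI_C = 24L),
                          seed = sample.int(1e6, 1))
    z_b <- cohort_suvr_long(co)
    z_b$z <- rnorm(nrow(z_b), 0, 0.5)
    z_f <- z_b
    z_f$z <- z_b$z + rnorm(nrow(z_b), -0.6, 0.5)  # configured decline
    res <- paired_scan_test(z_b[, c("subject_id", "voi", "z")],
                            z_f[, c("subject_id", "voi", "z")])
    sum(res$p_value < 0.05)
  })
  expect_gt(mean(detect >= 6), 0.9)
})

test_that("rank tests are invariant to monotone transforms", {
  set.seed(44)
  x <- rnorm(12); y <- rnorm(14, 0.8)
  mk <- function(v) tibble::tibble(
    subject_id = as.character(seq_along(v)),
    group = rep(c("A", "B"), c(12, 14))[seq_along(v)],
    visit_number = 1L, mmse = 0L, casi = v)
  sc1 <- mk(c(x, y))
  sc2 <- mk(exp(c(x, y)))  # strictly monotone transform
  p1 <- visitwise_group_test(sc1, "A", "B", 1, "CASI")$p_value
  p2 <- visitwise_group_test(sc2, "A", "B", 1, "CASI")$p_value
  expect_equal(p1, p2)
})

test_that("visit-wise test rejects at about the nominal 5% under the null", {
  set.seed(45)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(i) {
    sc <- tibble::tibble(subject_id = as.character(1:40),
                         group = rep(c("A", "B"), each = 20),
                         visit_number = 1L,
                         mmse = 0L, casi = rnorm(40))
    visitwise_group_test(sc, "A", "B", 1, "CASI")$p_value < 0.05
  }, logical(1))
  rate <- mean(rej)
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * mc_se)
})

test_that("Spearman correlation: hand formula, severity-factor link", {
  z <- tibble::tibble(subject_id = c("a", "b", "c"), voi = "PCC",
                      z = c(1, 2, 3))
  co <- tibble::tibble(subject_id = c("a", "b", "c"), group = "AD",
                       baseline_mmse = c(2L, 1L, 3L),
                       baseline_casi = c(2, 1, 3))
  res <- correlate_z_cognition(z, co, "MMSE")
  # ranks (1,2,3) vs (2,1,3): rho = 1 - 6*2/(3*8) = 0.5
  expect_equal(res$rho, 0.5)

  mono <- co
  mono$baseline_mmse <- c(10L, 20L, 30L)
  expect_equal(correlate_z_cognition(z, mono, "MMSE")$rho, 1)

  const <- co
  const$baseline_mmse <- 5L
  expect_warning(res_c <- correlate_z_cognition(z, const, "MMSE"),
                 "undefined")
  expect_true(is.na(res_c$rho))

  # cohort severity factor links PCC Z to MMSE in AD
  pos <- replicate(20, {
    coh <- generate_cohort(c(CN = 40L, AD = 42L),
                           seed = sample.int(1e6, 1),
                           severity_loading = 0.6)
    db <- build_normative_db(
      cohort_suvr_long(coh[coh$group == "CN", ]))
    zr <- z_transform(cohort_suvr_long(coh[coh$group == "AD", ]), db)
    r <- correlate_z_cognition(zr, coh, "MMSE")
    r$rho[r$voi == "PCC"] > 0
  })
  expect_gt(mean(pos), 0.9)
})
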