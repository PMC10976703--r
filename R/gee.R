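#' Gaussian GEE with exchangeable working correlation
#'
#' Solves the generalized estimating equations for a Gaussian outcome
#' with identity link and an exchangeable (or independence) working
#' correlation, returning cluster-robust (sandwich) standard errors.
#' With working independence the point estimates coincide with ordinary
#' least squares. The correlation parameter is estimated by the usual
#' moment estimator on Pearson residuals and the mean model re-solved
#' until convergence.
#'
#' @param formula Model formula for the marginal mean.
#' @param data Data frame of observations (long format).
#' @param id Name of the cluster (subject) identifier column.
#' @param corstr `"exchangeable"` (default) or `"independence"`.
#' @param maxit,tol Iteration controls.
#' @return A list of class `gee_fit`: `coefficients` (tibble term,
#'   estimate, robust_se, statistic, p_value), `rho`, `corstr`,
#'   `n_subjects`, `n_obs`, `vbeta` (robust covariance).
#' @export
gee_gaussian <- function(formula, data, id,
                         corstr = c("exchangeable", "independence"),
                         maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  stopifnot(id %in% names(data))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  X <- model.matrix(formula, mf)
  y <- stats::model.response(mf)
  cl <- as.character(data[[id]][keep])
  p <- ncol(X)
  N <- length(y)
  if (qr(X)$rank < p) stop("singular design matrix in GEE fit")
  clusters <- split(seq_len(N), cl)
  K <- length(clusters)

  beta <- qr.solve(X, y)
  rho <- 0
  rinv_cache <- new.env(parent = emptyenv())
  rinv_for <- function(m, rho) {
    key <- as.character(m)
    if (is.null(rinv_cache[[key]])) {
      R <- matrix(rho, m, m); diag(R) <- 1
      rinv_cache[[key]] <- solve(R)
    }
    rinv_cache[[key]]
  }

  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in clusters) {
        m <- length(ix)
        if (m < 2) next
        s <- sum(r[ix])^2 - sum(r[ix]^2)
        num <- num + s / 2
        npairs <- npairs + m * (m - 1) / 2
      }
      rho_new <- if (npairs > p) num / phi / (npairs - p) else 0
      rho_new <- min(max(rho_new, 0), 0.95)
    } else {
      rho_new <- 0
    }
    if (abs(rho_new - rho) > 1e-12) {
      rho <- rho_new
      rm(list = ls(rinv_cache), envir = rinv_cache)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in clusters) {
      m <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      Ri <- rinv_for(m, rho)
      XtR <- crossprod(Xi, Ri)
      A <- A + XtR %*% Xi
      b <- b + XtR %*% y[ix]
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }

  # sandwich variance
  r <- as.numeric(y - X %*% beta)
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in clusters) {
    m <- length(ix)
    Xi <- X[ix, , drop = FALSE]
    Ri <- rinv_for(m, rho)
    XtR <- crossprod(Xi, Ri)
    A <- A + XtR %*% Xi
    u <- XtR %*% r[ix]
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(V))
  est <- as.numeric(beta)
  zstat <- est / se
  out <- list(
    coefficients = tibble::tibble(
      term = colnames(X), estimate = est, robust_se = se,
      statistic = zstat, p_value = 2 * pnorm(-abs(zstat))
    ),
    rho = rho, corstr = corstr,
    n_subjects = K, n_obs = N, vbeta = V
  )
  class(out) <- "gee_fit"
  out
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian GEE (%s working correlation, rho = %.3f)\n%d subjects, %d observations\n",
    x$corstr, x$rho, x$n_subjects, x$n_obs))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Marginal trajectory model for longitudinal cognitive scores
#'
#' Fits the GEE marginal model used for repeated MMSE/CASI measurements:
#' outcome ~ sex + education + group x measurement-number, with
#' measurement number categorical, the control group and first
#' measurement as reference levels, exchangeable working correlation and
#' robust standard errors. The group-by-visit interaction coefficients
#' estimate each patient group's mean change from baseline at each
#' visit relative to controls.
#'
#' @param scores Longitudinal scores from
#'   [generate_longitudinal_scores()] (or any table with `subject_id`,
#'   `visit_number` and the outcome column).
#' @param cohort Cohort table supplying `sex`, `education_years`,
#'   `group`.
#' @param outcome `"MMSE"` or `"CASI"`.
#' @param terms Right-hand-side formula for the marginal mean. The
#'   default matches the published model structure; `visit` is the
#'   categorical measurement number, `group` the diagnostic group.
#' @param corstr Working correlation, as [gee_gaussian()].
#' @return A `gee_fit`.
#' @export
fit_marginal_trajectory <- function(scores, cohort,
                                    outcome = c("MMSE", "CASI"),
                                    terms = ~ sex + education_years +
                                      group * visit,
                                    corstr = "exchangeable") {
  outcome <- match.arg(outcome)
  ycol <- if (outcome == "MMSE") "mmse" else "casi"
  stopifnot(all(c("subject_id", "visit_number", ycol) %in% names(scores)),
            all(c("subject_id", "sex", "education_years", "group") %in%
                  names(cohort)))
  nv <- scores |>
    dplyr::count(.data$subject_id)
  if (all(nv$n < 2)) stop("at least 2 visits per subject are required")
  dat <- dplyr::inner_join(
    scores[, c("subject_id", "visit_number", ycol)],
    cohort[, c("subject_id", "sex", "education_years", "group")],
    by = "subject_id"
  )
  if (all(is.na(dat[[ycol]]))) stop("outcome is entirely missing")
  dat$group <- factor(dat$group,
                      levels = intersect(group_levels(),
                                         unique(dat$group)))
  dat$visit <- factor(dat$visit_number)
  dat$sex <- factor(dat$sex, levels = c("F", "M"))
  dat$y <- dat[[ycol]]
  f <- stats::update(terms, y ~ .)
  gee_gaussian(f, dat, id = "subject_id", corstr = corstr)
}
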