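# Shared fixtures: everything is generated in code at test time.

small_atlas <- function() {
  generate_atlas_phantom(grid_shape = c(36L, 36L, 36L),
                         voxel_size_mm = c(2, 2, 2))
}

uniform_suvr <- function(value = 1) {
  setNames(rep(value, length(voi_names())), voi_names())
}

mci_c_true_suvr <- function() {
  p <- default_regional_profile()
  p <- p[p$group == "MCI_C", ]
  setNames(p$suvr_mean, p$voi)
}

tiny_cohort <- function(sizes = c(CN = 10L, MCI_C = 8L), seed = 7L) {
  generate_cohort(sizes, seed = seed) |>
    assign_conversion_times(seed = seed + 1L)
}

# Exact two-sided rank-sum p-value by enumeration of all group
# assignments (independent oracle for small samples, no ties).
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# patterns (independent oracle; assumes no zeros / tied magnitudes).
exact_signedrank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(vs - mu) >= abs(v_obs - mu) - 1e-12)
}
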