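# Brute-force nested sums of squares by explicit triple loops over the
# deviation definitions; independent of the vectorized implementation.
brute_nested_ss <- function(y) {
  d <- dim(y)
  a <- d[1]; b <- d[2]; c_ <- d[3]
  grand <- mean(y)
  ssa <- 0; ssba <- 0; sscb <- 0; sst <- 0
  for (i in seq_len(a)) {
    yi <- mean(y[i, , ])
    ssa <- ssa + b * c_ * (yi - grand)^2
    for (j in seq_len(b)) {
      yij <- mean(y[i, j, ])
      ssba <- ssba + c_ * (yij - yi)^2
      for (k in seq_len(c_)) {
        sscb <- sscb + (y[i, j, k] - yij)^2
        sst <- sst + (y[i, j, k] - grand)^2
      }
    }
  }
  list(ssa = ssa, ss_b_a = ssba, ss_c_b = sscb, sst = sst)
}

# OLS slope straight from lm(), as an independent cross-check of the
# covariance-based estimator.
lm_slope <- function(pairs) {
  unname(stats::coef(stats::lm(pairs[[2]] ~ pairs[[1]]))[2])
}

# Small, fast simulation setup used across tests.
tiny_params <- function(...) {
  defaults <- list(sigma = 0.2, sigma_env = 0.05, n_bar = 8,
                   generations = 3, n_genotypes = 4, seed = 11L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}
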