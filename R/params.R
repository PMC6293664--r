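#' Simulation parameters for the clonal growth model
#'
#' Bundles every generative knob of the multilevel growth simulation: the
#' two non-genetic noise sources, the (genetic mean) number of cells per
#' collective and its coefficient of variation, the run length, and the
#' genetic composition of the founding population.
#'
#' @param sigma Developmental instability: standard deviation of a daughter
#'   cell's size draw around its genotype's genetic mean size. Non-negative.
#' @param sigma_env Environmental heterogeneity: standard deviation of the
#'   multiplicative size modifier (centred on 1) assigned independently to
#'   each collective. Non-negative.
#' @param cv_n Coefficient of variation (SD/mean) of the number of cells per
#'   collective. `0` gives the fixed-size model in which every collective has
#'   exactly `round(n_bar)` cells.
#' @param n_bar Genetic mean number of cells per collective (>= 1).
#' @param generations Number of doubling generations to simulate (>= 0).
#' @param n_genotypes Number of genetically distinct founding clones.
#' @param genetic_mean_range Length-2 numeric `(low, high)`, `low < high`;
#'   genotype mean sizes are spaced evenly over this closed interval. With a
#'   single genotype the lower bound is used.
#' @param seed Integer master seed. All randomness in a run is derived from
#'   it; per-genotype streams are sub-seeded so lineages are independent.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(sigma = 0.25, sigma_env = 1e-4, seed = 1)
#' p$n_bar
#' @export
sim_params <- function(sigma = 0.25, sigma_env = 1e-4, cv_n = 0,
                       n_bar = 32, generations = 7, n_genotypes = 10,
                       genetic_mean_range = c(1, 2), seed = 1L) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L,
            is.numeric(sigma_env), length(sigma_env) == 1L,
            is.numeric(cv_n), length(cv_n) == 1L,
            is.numeric(n_bar), length(n_bar) == 1L,
            is.numeric(generations), length(generations) == 1L,
            is.numeric(n_genotypes), length(n_genotypes) == 1L,
            is.numeric(genetic_mean_range), length(genetic_mean_range) == 2L)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma_env < 0) stop("`sigma_env` must be non-negative", call. = FALSE)
  if (cv_n < 0) stop("`cv_n` must be non-negative", call. = FALSE)
  if (n_bar < 1) stop("`n_bar` must be >= 1", call. = FALSE)
  if (generations < 0 || generations != round(generations))
    stop("`generations` must be a non-negative integer", call. = FALSE)
  if (n_genotypes < 1 || n_genotypes != round(n_genotypes))
    stop("`n_genotypes` must be a positive integer", call. = FALSE)
  if (n_genotypes > 1 && genetic_mean_range[1] >= genetic_mean_range[2])
    stop("`genetic_mean_range` must satisfy low < high", call. = FALSE)
  if (any(c(sigma, sigma_env, cv_n) > 0.25))
    message("note: noise parameter above 0.25, outside the usual regime")
  structure(
    list(sigma = as.numeric(sigma), sigma_env = as.numeric(sigma_env),
         cv_n = as.numeric(cv_n), n_bar = as.numeric(n_bar),
         generations = as.integer(generations),
         n_genotypes = as.integer(n_genotypes),
         genetic_mean_range = as.numeric(genetic_mean_range),
         seed = as.integer(seed)),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Clonal growth simulation parameters\n")
  cat(sprintf("  sigma (developmental)  : %g\n", x$sigma))
  cat(sprintf("  sigma' (environmental) : %g\n", x$sigma_env))
  cat(sprintf("  CV_N (cells/collective): %g\n", x$cv_n))
  cat(sprintf("  N-bar                  : %g\n", x$n_bar))
  cat(sprintf("  generations            : %d\n", x$generations))
  cat(sprintf("  genotypes              : %d over [%g, %g]\n",
              x$n_genotypes, x$genetic_mean_range[1], x$genetic_mean_range[2]))
  cat(sprintf("  seed                   : %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-seed from a master seed and integer tags.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(master, ...) {
  tags <- c(...)
  s <- as.double(master) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 104729 + 1) %% 2147483647
  as.integer(s)
}

# Normal draw resampled until strictly positive (> eps). Sizes, modifiers
# and their products must stay positive; at the model's usual parameter
# ranges (means >= 1, SD <= 0.25) resampling is a negligible perturbation.
rnorm_positive <- function(n, mean, sd, eps = 1e-6) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= eps)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) == 1L) mean else mean[bad], sd)
    bad <- bad[x[bad] <= eps]
  }
  x
}
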