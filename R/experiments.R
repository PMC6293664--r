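#' Noise levels used by the size-series experiments
#'
#' The five developmental / environmental noise levels plotted in the
#' collective-size series: `1e-4` (the visual floor standing in for 0),
#' then evenly spaced up to 0.25.
#' @export
noise_levels_five <- c(1e-4, 0.0625, 0.125, 0.1875, 0.25)

#' Evenly spaced noise grid
#'
#' Grid of noise values for the parameter sweeps: `n` evenly spaced points
#' from `floor` to `max`. The default floor is `1e-4` rather than 0 so
#' that the degenerate zero-noise population (undefined regression
#' slopes) stays off the grid while remaining visually indistinguishable
#' from zero.
#'
#' @param n Number of grid points.
#' @param max Upper end of the grid.
#' @param floor Lower end of the grid.
#' @return Numeric vector of length `n`.
#' @export
noise_grid <- function(n = 32, max = 0.25, floor = 1e-4) {
  seq(floor, max, length.out = n)
}

#' Sweep configuration
#'
#' Bundles the axes and bookkeeping of a parameter sweep. Defaults match
#' the standard study design: a 32 x 32 grid of noise values on
#' `[1e-4, 0.25]`, ten replicates, seven generations, ten genotypes with
#' genetic mean sizes evenly spaced on [1, 2], and 32-celled collectives.
#' The size series conventionally uses nine generations and collective
#' sizes in powers of two; pass those explicitly.
#'
#' @param sigma_values Developmental-instability axis.
#' @param sigma_env_values Environmental-modifier axis.
#' @param cv_n_values Cell-number CV axis (used by [run_cvn_sweep()]).
#' @param collective_sizes Cells per collective; a vector for
#'   [run_size_series()], a single value otherwise.
#' @param replicates Replicate runs per parameter combination.
#' @param generations Generations per run.
#' @param trait_map Trait-map name, see [trait_map()].
#' @param n_genotypes,genetic_mean_range Founding-population makeup.
#' @param sigma_env_fixed Environmental-modifier SD held fixed during the
#'   cell-number-CV sweep (default 0: that sweep isolates the interplay
#'   of developmental noise and cell-number variation).
#' @param seed Master seed; every run's seed is derived from it together
#'   with the combination and replicate indices, so replicates are
#'   independent and execution order is irrelevant.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(sigma_values = noise_grid(),
                       sigma_env_values = noise_grid(),
                       cv_n_values = noise_grid(),
                       collective_sizes = 32,
                       replicates = 10, generations = 7,
                       trait_map = "volume",
                       n_genotypes = 10, genetic_mean_range = c(1, 2),
                       sigma_env_fixed = 0,
                       seed = 1L) {
  stopifnot(replicates >= 1, generations >= 1,
            length(collective_sizes) >= 1, all(collective_sizes >= 1))
  trait_map <- match.arg(trait_map, c("volume", "diameter", "swim", "survival"))
  structure(list(sigma_values = sigma_values,
                 sigma_env_values = sigma_env_values,
                 cv_n_values = cv_n_values,
                 collective_sizes = collective_sizes,
                 replicates = as.integer(replicates),
                 generations = as.integer(generations),
                 trait_map = trait_map,
                 n_genotypes = as.integer(n_genotypes),
                 genetic_mean_range = genetic_mean_range,
                 sigma_env_fixed = sigma_env_fixed,
                 seed = as.integer(seed)),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("<sweep_grid: %d sigma x %d sigma' x %d CV_N, sizes {%s}, %d reps, %d generations, trait '%s', seed %d>\n",
              length(x$sigma_values), length(x$sigma_env_values),
              length(x$cv_n_values), paste(x$collective_sizes, collapse = ","),
              x$replicates, x$generations, x$trait_map, x$seed))
  invisible(x)
}

# One simulation run + heritability estimates; degenerate populations
# (zero parent variance) give NA slopes rather than an error.
run_one <- function(sigma, sigma_env, cv_n, n_cells, grid, seed) {
  params <- sim_params(sigma = sigma, sigma_env = sigma_env, cv_n = cv_n,
                       n_bar = n_cells, generations = grid$generations,
                       n_genotypes = grid$n_genotypes,
                       genetic_mean_range = grid$genetic_mean_range,
                       seed = seed)
  run <- grow_population(params)
  tryCatch(relative_heritability(run, grid$trait_map),
           error = function(e) list(slope_cell = NA_real_,
                                    slope_collective = NA_real_,
                                    ratio = NA_real_))
}

run_combos <- function(combos, grid) {
  reps <- grid$replicates
  n <- nrow(combos) * reps
  out <- data.frame(trait_map = rep(grid$trait_map, n),
                    sigma = rep(combos$sigma, each = reps),
                    sigma_env = rep(combos$sigma_env, each = reps),
                    cv_n = rep(combos$cv_n, each = reps),
                    n_cells = rep(combos$n_cells, each = reps),
                    replicate = rep(seq_len(reps), nrow(combos)),
                    run_seed = NA_integer_,
                    slope_cell = NA_real_, slope_collective = NA_real_,
                    ratio = NA_real_)
  row <- 1L
  for (ci in seq_len(nrow(combos))) {
    for (r in seq_len(reps)) {
      s <- derive_seed(grid$seed, ci, r)
      rh <- run_one(combos$sigma[ci], combos$sigma_env[ci], combos$cv_n[ci],
                    combos$n_cells[ci], grid, s)
      out$run_seed[row] <- s
      out$slope_cell[row] <- rh$slope_cell
      out$slope_collective[row] <- rh$slope_collective
      out$ratio[row] <- rh$ratio
      row <- row + 1L
    }
  }
  structure(out, class = c("sweep_result", "data.frame"), grid = grid)
}

#' Sweep developmental and environmental noise
#'
#' Runs the growth model over every combination of `sigma_values` and
#' `sigma_env_values` at fixed cell number (`cv_n = 0`), estimating
#' cell-level and collective-level heritability by parent-offspring
#' regression for the grid's trait map. This is the heatmap experiment:
#' the default 32 x 32 grid gives 1024 combinations.
#'
#' @param grid A [sweep_grid()].
#' @return A `sweep_result` data.frame, one row per (combination,
#'   replicate) with both slopes and their ratio; degenerate combinations
#'   are reported as NA, never dropped. The grid is attached as an
#'   attribute.
#' @export
run_sigma_sweep <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  combos <- expand.grid(sigma = grid$sigma_values,
                        sigma_env = grid$sigma_env_values,
                        KEEP.OUT.ATTRS = FALSE)
  combos$cv_n <- 0
  combos$n_cells <- grid$collective_sizes[1]
  run_combos(combos, grid)
}

#' Sweep developmental noise against cell-number variation
#'
#' Runs the growth model over every combination of `sigma_values` and
#' `cv_n_values` with the environmental modifier held at
#' `grid$sigma_env_fixed` and a genetic mean of `collective_sizes[1]`
#' cells. Variation in cell number leaves cell-level heritability
#' untouched but erodes collective-level heritability, pushing the ratio
#' below one when developmental noise is comparatively small.
#'
#' @inheritParams run_sigma_sweep
#' @return A `sweep_result` data.frame.
#' @export
run_cvn_sweep <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  combos <- expand.grid(sigma = grid$sigma_values,
                        cv_n = grid$cv_n_values,
                        KEEP.OUT.ATTRS = FALSE)
  combos$sigma_env <- grid$sigma_env_fixed
  combos$n_cells <- grid$collective_sizes[1]
  run_combos(combos, grid)
}

#' Heritability ratio as a function of collective size
#'
#' Varies the number of cells per collective (the grid's
#' `collective_sizes`) while one noise source takes the values of its
#' grid axis and the other is held fixed. With `vary = "sigma"` the
#' environmental modifier is fixed (default 0.25, the patchy-environment
#' setting) and developmental instability varies; with
#' `vary = "sigma_env"` developmental instability is fixed (default
#' 0.25) and the environmental modifier varies.
#'
#' @inheritParams run_sigma_sweep
#' @param vary Which noise source varies across series.
#' @param fixed_value Value of the noise source held fixed.
#' @return A `sweep_result` data.frame.
#' @export
run_size_series <- function(grid, vary = c("sigma", "sigma_env"),
                            fixed_value = 0.25) {
  stopifnot(inherits(grid, "sweep_grid"))
  vary <- match.arg(vary)
  levels <- if (vary == "sigma") grid$sigma_values else grid$sigma_env_values
  combos <- expand.grid(level = levels,
                        n_cells = grid$collective_sizes,
                        KEEP.OUT.ATTRS = FALSE)
  if (vary == "sigma") {
    combos$sigma <- combos$level
    combos$sigma_env <- fixed_value
  } else {
    combos$sigma <- fixed_value
    combos$sigma_env <- combos$level
  }
  combos$cv_n <- 0
  combos$level <- NULL
  run_combos(combos, grid)
}

#' Aggregate a sweep over replicates
#'
#' Per-combination means of the two slopes and their ratio, with the
#' number of non-degenerate replicates that contributed.
#'
#' @param result A `sweep_result`.
#' @return data.frame with one row per parameter combination:
#'   mean_slope_cell, mean_slope_collective, mean_ratio, n_ok.
#' @export
aggregate_sweep <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  key <- interaction(result$trait_map, result$sigma, result$sigma_env,
                     result$cv_n, result$n_cells, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(result)), key)
  rows <- lapply(idx, function(i) {
    data.frame(trait_map = result$trait_map[i[1]],
               sigma = result$sigma[i[1]],
               sigma_env = result$sigma_env[i[1]],
               cv_n = result$cv_n[i[1]],
               n_cells = result$n_cells[i[1]],
               mean_slope_cell = mean(result$slope_cell[i], na.rm = TRUE),
               mean_slope_collective = mean(result$slope_collective[i], na.rm = TRUE),
               mean_ratio = mean(result$ratio[i], na.rm = TRUE),
               n_ok = sum(!is.na(result$ratio[i])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sigma, out$sigma_env, out$cv_n, out$n_cells), ]
  rownames(out) <- NULL
  out
}

#' Export sweep results
#'
#' Writes `results.csv` (per-replicate rows, fixed column order),
#' `aggregate.csv` (per-combination means) and `manifest.json` (trait
#' map, axes, replicate count, generations, master seed and the derived
#' per-run seeds) into `dir`. Output is byte-identical for identical
#' input.
#'
#' @param result A `sweep_result`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"), nrow(result) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- attr(result, "grid")
  paths <- file.path(dir, c("results.csv", "aggregate.csv", "manifest.json"))
  res <- as.data.frame(result)
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) trimws(formatC(x, format = "g", digits = 12)))
  utils::write.csv(res, paths[1], row.names = FALSE, quote = FALSE)
  agg <- aggregate_sweep(result)
  num <- vapply(agg, is.numeric, logical(1))
  agg[num] <- lapply(agg[num], function(x) trimws(formatC(x, format = "g", digits = 12)))
  utils::write.csv(agg, paths[2], row.names = FALSE, quote = FALSE)
  manifest <- list(trait_map = grid$trait_map,
                   sigma_values = grid$sigma_values,
                   sigma_env_values = grid$sigma_env_values,
                   cv_n_values = grid$cv_n_values,
                   collective_sizes = grid$collective_sizes,
                   replicates = grid$replicates,
                   generations = grid$generations,
                   n_genotypes = grid$n_genotypes,
                   genetic_mean_range = grid$genetic_mean_range,
                   sigma_env_fixed = grid$sigma_env_fixed,
                   master_seed = grid$seed,
                   run_seeds = unique(result[c("sigma", "sigma_env", "cv_n",
                                               "n_cells", "replicate", "run_seed")]))
  jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(paths)
}

#' Re-import exported sweep results
#'
#' Reads a `results.csv` written by [export_results()] back into a
#' `sweep_result` data.frame (without the grid attribute).
#'
#' @param path Path to a `results.csv`.
#' @return A `sweep_result` data.frame.
#' @export
import_results <- function(path) {
  res <- utils::read.csv(path)
  structure(res, class = c("sweep_result", "data.frame"))
}
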