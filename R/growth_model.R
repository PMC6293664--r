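#' Draw realized daughter-cell sizes
#'
#' Daughter cell size is sampled from a normal distribution centred on the
#' genotype's genetic mean size (not on the parent cell's realized
#' phenotype) with standard deviation `sigma`, the developmental
#' instability. Draws are resampled until strictly positive.
#'
#' @param genetic_mean Positive genetic mean size of the genotype.
#' @param sigma Non-negative standard deviation of the draw.
#' @param n Number of draws.
#' @return Numeric vector of `n` positive sizes; exactly `genetic_mean`
#'   when `sigma = 0`.
#' @examples
#' draw_cell_size(1.5, 0)          # 1.5 exactly
#' set.seed(1); draw_cell_size(1.5, 0.25, n = 5)
#' @export
draw_cell_size <- function(genetic_mean, sigma, n = 1L) {
  if (any(genetic_mean <= 0)) stop("`genetic_mean` must be positive", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma == 0) return(rep_len(as.numeric(genetic_mean), n))
  rnorm_positive(n, genetic_mean, sigma)
}

#' Draw per-collective environmental size modifiers
#'
#' Each collective independently experiences an environment that rescales
#' the size of every cell it contains by the same multiplicative factor,
#' drawn from a normal distribution centred on 1 with standard deviation
#' `sigma_env` and resampled until strictly positive.
#'
#' @param sigma_env Non-negative standard deviation of the modifier.
#' @param n Number of draws (one per collective).
#' @return Numeric vector of `n` positive modifiers; exactly 1 when
#'   `sigma_env = 0`.
#' @export
draw_env_modifier <- function(sigma_env, n = 1L) {
  if (sigma_env < 0) stop("`sigma_env` must be non-negative", call. = FALSE)
  if (sigma_env == 0) return(rep_len(1, n))
  rnorm_positive(n, 1, sigma_env)
}

#' Draw the number of cells of a new collective
#'
#' Cell number is drawn from a normal distribution with mean `n_bar` (the
#' genetic mean, not the parent collective's realized count) and standard
#' deviation `cv_n * n_bar`, rounded to the nearest integer and floored
#' at 1.
#'
#' @param n_bar Genetic mean cell number (>= 1).
#' @param cv_n Non-negative coefficient of variation of cell number.
#' @param n Number of draws.
#' @return Integer vector of `n` counts, all >= 1.
#' @export
draw_cell_count <- function(n_bar, cv_n, n = 1L) {
  if (n_bar < 1) stop("`n_bar` must be >= 1", call. = FALSE)
  if (cv_n < 0) stop("`cv_n` must be non-negative", call. = FALSE)
  if (cv_n == 0) return(rep_len(as.integer(round(n_bar)), n))
  pmax(1L, as.integer(round(stats::rnorm(n, n_bar, cv_n * n_bar))))
}

# One collective as a plain record.
new_collective_record <- function(id, genotype_id, generation, env_modifier,
                                  cells, parent_id, genetic_mean) {
  structure(list(id = id, genotype_id = genotype_id, generation = generation,
                 env_modifier = env_modifier, cells = cells,
                 parent_id = parent_id, genetic_mean = genetic_mean),
            class = "collective_record")
}

#' @export
print.collective_record <- function(x, ...) {
  cat(sprintf("<collective %s: genotype %s, generation %d, %d cells, env modifier %.4f>\n",
              x$id, x$genotype_id, x$generation, length(x$cells), x$env_modifier))
  invisible(x)
}

#' Found the initial population
#'
#' Creates one founder collective per genotype. Genotype genetic mean sizes
#' are spaced evenly over `genetic_mean_range` (inclusive); with a single
#' genotype the lower bound is used. Founder cells are drawn around the
#' genetic mean and scaled by a fresh environmental modifier, so
#' generation-0 phenotypes have the same noise structure as later
#' generations.
#'
#' @param params A [sim_params()] object.
#' @return List of `collective_record` founders, one per genotype.
#' @examples
#' founders <- init_population(sim_params(n_genotypes = 3, seed = 7))
#' sapply(founders, function(x) x$genetic_mean)
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  means <- genotype_means(params)
  founders <- vector("list", params$n_genotypes)
  for (i in seq_len(params$n_genotypes)) {
    set.seed(derive_seed(params$seed, i))
    founders[[i]] <- make_founder(i, means[i], params)
  }
  founders
}

genotype_means <- function(params) {
  lo <- params$genetic_mean_range[1]
  hi <- params$genetic_mean_range[2]
  if (params$n_genotypes == 1L) return(lo)
  seq(lo, hi, length.out = params$n_genotypes)
}

make_founder <- function(genotype_id, gmean, params) {
  n0 <- draw_cell_count(params$n_bar, params$cv_n, 1L)
  modifier <- draw_env_modifier(params$sigma_env, 1L)
  cells <- draw_cell_size(gmean, params$sigma, n0) * modifier
  new_collective_record(id = 1L, genotype_id = genotype_id, generation = 0L,
                        env_modifier = modifier, cells = cells,
                        parent_id = NA_integer_, genetic_mean = gmean)
}

# Reproduce every collective of one generation (all same genotype).
# gen_cells: list of realized cell-size vectors, one per parent collective.
# Returns offspring cell lists, modifiers, counts, pedigree pieces and
# event counts. Each parent cell divides exactly once, contributing one
# daughter to EACH of the two offspring collectives; with cv_n > 0 the
# offspring's cell slots are matched to parent cells by cycling through a
# random permutation of the parent's cells.
reproduce_generation <- function(gen_cells, gmean, params) {
  P <- length(gen_cells)
  n_p <- lengths(gen_cells)
  if (any(n_p < 1L)) stop("parent collective with no cells", call. = FALSE)
  n_off <- if (params$cv_n == 0) rep(n_p, each = 2L)
           else draw_cell_count(params$n_bar, params$cv_n, 2L * P)
  mods <- draw_env_modifier(params$sigma_env, 2L * P)
  realized <- draw_cell_size(gmean, params$sigma, sum(n_off)) * rep(mods, n_off)

  off_parent <- rep(seq_len(P), each = 2L)
  if (params$cv_n == 0) {
    idx_local <- sequence(n_off)
  } else {
    idx_local <- unlist(lapply(seq_len(2L * P), function(o) {
      np <- n_p[off_parent[o]]
      rep_len(sample.int(np), n_off[o])
    }), use.names = FALSE)
  }
  pc_flat <- unlist(gen_cells, use.names = FALSE)
  offsets <- cumsum(c(0L, n_p[-P]))
  parent_vals <- pc_flat[rep(offsets[off_parent], n_off) + idx_local]

  grp <- factor(rep(seq_along(n_off), n_off), levels = seq_along(n_off))
  list(off_cells = unname(split(realized, grp)),
       off_parent = off_parent,
       modifiers = mods,
       n_off = n_off,
       cell_parent_vals = parent_vals,
       cell_offspring_vals = realized,
       n_collective_events = P,
       n_cell_events = sum(n_p))
}

#' Reproduce a single collective
#'
#' A collective reproduces by forming two new collectives; with
#' `cv_n = 0` each offspring has exactly as many cells as its parent.
#' Each offspring receives its own fresh environmental modifier, daughter
#' cell sizes are drawn around the genotype's genetic mean and multiplied
#' by that modifier, and each parent cell contributes one daughter to each
#' offspring (one division per parent cell). This is one collective-level
#' reproductive event and, with fixed cell number, `N` cell-level division
#' events producing `2 N` parent-offspring cell pairs.
#'
#' @param parent A `collective_record` with at least one cell.
#' @param params A [sim_params()] object.
#' @param next_id Integer id assigned to the first offspring (the second
#'   gets `next_id + 1`).
#' @return List with elements `offspring` (two `collective_record`s),
#'   `cell_pairs` (data.frame of parent/offspring realized phenotypes) and
#'   `collective_pairs` (data.frame of parent/offspring collective ids).
#' @export
reproduce_collective <- function(parent, params, next_id = parent$id + 1L) {
  stopifnot(inherits(parent, "collective_record"), inherits(params, "sim_params"))
  if (length(parent$cells) < 1L) stop("parent collective has no cells", call. = FALSE)
  rg <- reproduce_generation(list(parent$cells), parent$genetic_mean, params)
  offspring <- lapply(1:2, function(k)
    new_collective_record(id = next_id + (k - 1L),
                          genotype_id = parent$genotype_id,
                          generation = parent$generation + 1L,
                          env_modifier = rg$modifiers[k],
                          cells = rg$off_cells[[k]],
                          parent_id = parent$id,
                          genetic_mean = parent$genetic_mean))
  list(offspring = offspring,
       cell_pairs = data.frame(parent = rg$cell_parent_vals,
                               offspring = rg$cell_offspring_vals),
       collective_pairs = data.frame(parent_id = rep(parent$id, 2L),
                                     offspring_id = next_id + 0:1))
}

#' Grow a clonal multilevel population
#'
#' Founds one collective per genotype and grows the population for
#' `params$generations` doubling generations: every collective reproduces
#' into two offspring, so a single founder yields `2^g` leaf collectives
#' and `2^g - 1` collective-level reproductive events after `g`
#' generations. Parent-offspring phenotype pairs are recorded at both
#' levels for every reproductive event, pooled across all generations.
#' Each genotype is grown on its own RNG stream derived from the master
#' seed, so lineages are independent and the whole pedigree is reproduced
#' bit-for-bit by a fixed seed.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `growth_run`: list with
#' \describe{
#'   \item{collectives}{data.frame with one row per collective ever alive
#'     (id, genotype_id, generation, env_modifier, n_cells, parent_id,
#'     genetic_mean).}
#'   \item{cells}{list of realized cell-size vectors, indexed by
#'     collective id.}
#'   \item{pedigree}{a `pedigree_table`: `cell_pairs` (parent/offspring
#'     realized cell phenotypes), `collective_pairs` (parent/offspring
#'     collective ids; trait values are filled in later by a trait map),
#'     and the event counts `n_cell_events`, `n_collective_events`.}
#'   \item{params}{the input parameters.}
#' }
#' @examples
#' run <- grow_population(sim_params(n_genotypes = 2, generations = 3, seed = 1))
#' run$pedigree$n_collective_events  # 2 * (2^3 - 1)
#' @export
grow_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  means <- genotype_means(params)
  per_geno <- vector("list", params$n_genotypes)
  for (i in seq_len(params$n_genotypes)) {
    set.seed(derive_seed(params$seed, i))
    per_geno[[i]] <- grow_genotype(i, means[i], params)
  }

  # renumber local ids into one global sequence, genotype-major
  sizes <- vapply(per_geno, function(g) nrow(g$collectives), integer(1))
  offset <- cumsum(c(0L, sizes[-length(sizes)]))
  collectives <- do.call(rbind, lapply(seq_along(per_geno), function(i) {
    d <- per_geno[[i]]$collectives
    d$id <- d$id + offset[i]
    d$parent_id <- d$parent_id + offset[i]
    d
  }))
  rownames(collectives) <- NULL
  cells <- do.call(c, lapply(per_geno, `[[`, "cells"))
  collective_pairs <- do.call(rbind, lapply(seq_along(per_geno), function(i) {
    d <- per_geno[[i]]$collective_pairs
    if (nrow(d)) d + offset[i] else d
  }))
  rownames(collective_pairs) <- NULL
  cell_pairs <- do.call(rbind, lapply(per_geno, `[[`, "cell_pairs"))
  rownames(cell_pairs) <- NULL

  pedigree <- structure(
    list(cell_pairs = cell_pairs,
         collective_pairs = collective_pairs,
         n_cell_events = sum(vapply(per_geno, `[[`, numeric(1), "n_cell_events")),
         n_collective_events = sum(vapply(per_geno, `[[`, numeric(1), "n_collective_events"))),
    class = "pedigree_table")

  structure(list(collectives = collectives, cells = cells,
                 pedigree = pedigree, params = params),
            class = "growth_run")
}

grow_genotype <- function(genotype_id, gmean, params) {
  founder <- make_founder(genotype_id, gmean, params)
  rec_id <- 1L
  col_rows <- list(data.frame(id = 1L, genotype_id = genotype_id,
                              generation = 0L, env_modifier = founder$env_modifier,
                              n_cells = length(founder$cells),
                              parent_id = NA_integer_, genetic_mean = gmean))
  cells_all <- list(founder$cells)
  gen_cells <- list(founder$cells)
  gen_ids <- 1L
  pair_parent <- list(); pair_off <- list()
  cpair_parent <- list(); cpair_off <- list()
  ev_col <- 0; ev_cell <- 0

  g <- 0L
  while (g < params$generations) {
    rg <- reproduce_generation(gen_cells, gmean, params)
    n_new <- length(rg$off_cells)
    new_ids <- rec_id + seq_len(n_new)
    col_rows[[length(col_rows) + 1L]] <- data.frame(
      id = new_ids, genotype_id = genotype_id, generation = g + 1L,
      env_modifier = rg$modifiers, n_cells = rg$n_off,
      parent_id = gen_ids[rg$off_parent], genetic_mean = gmean)
    cells_all <- c(cells_all, rg$off_cells)
    pair_parent[[length(pair_parent) + 1L]] <- rg$cell_parent_vals
    pair_off[[length(pair_off) + 1L]] <- rg$cell_offspring_vals
    cpair_parent[[length(cpair_parent) + 1L]] <- gen_ids[rg$off_parent]
    cpair_off[[length(cpair_off) + 1L]] <- new_ids
    ev_col <- ev_col + rg$n_collective_events
    ev_cell <- ev_cell + rg$n_cell_events
    gen_cells <- rg$off_cells
    gen_ids <- new_ids
    rec_id <- rec_id + n_new
    g <- g + 1L
  }

  list(collectives = do.call(rbind, col_rows),
       cells = cells_all,
       cell_pairs = data.frame(parent = unlist(pair_parent, use.names = FALSE),
                               offspring = unlist(pair_off, use.names = FALSE)),
       collective_pairs = data.frame(parent_id = unlist(cpair_parent, use.names = FALSE),
                                     offspring_id = unlist(cpair_off, use.names = FALSE)),
       n_cell_events = ev_cell,
       n_collective_events = ev_col)
}

#' @export
print.growth_run <- function(x, ...) {
  cat(sprintf("<growth_run: %d genotypes, %d generations, %d collectives, %s cell pairs>\n",
              x$params$n_genotypes, x$params$generations,
              nrow(x$collectives), format(nrow(x$pedigree$cell_pairs), big.mark = ",")))
  invisible(x)
}

#' @export
print.pedigree_table <- function(x, ...) {
  cat(sprintf("<pedigree_table: %d collective events, %d cell division events, %d collective pairs, %d cell pairs>\n",
              x$n_collective_events, x$n_cell_events,
              nrow(x$collective_pairs), nrow(x$cell_pairs)))
  invisible(x)
}

#' Export a population in long format
#'
#' One row per collective (`level = "collective"`, `value` is the
#' environmental modifier) and one row per cell (`level = "cell"`,
#' `value` is the realized cell phenotype, `id` is the enclosing
#' collective's id). Fixed column order:
#' level, id, parent_id, genotype, generation, value.
#'
#' @param run A `growth_run`.
#' @param path Optional file path; when supplied the table is written as
#'   CSV and the path returned invisibly.
#' @return The long-format data.frame (invisibly when `path` is given).
#' @export
population_long <- function(run, path = NULL) {
  stopifnot(inherits(run, "growth_run"))
  d <- run$collectives
  col_rows <- data.frame(level = "collective", id = d$id, parent_id = d$parent_id,
                         genotype = d$genotype_id, generation = d$generation,
                         value = d$env_modifier)
  nc <- lengths(run$cells)
  cell_rows <- data.frame(level = "cell",
                          id = rep(d$id, nc),
                          parent_id = rep(d$parent_id, nc),
                          genotype = rep(d$genotype_id, nc),
                          generation = rep(d$generation, nc),
                          value = unlist(run$cells, use.names = FALSE))
  out <- rbind(col_rows, cell_rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
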