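#' Balanced nested phenotype table
#'
#' Container for a balanced clone / collective / particle phenotype
#' design: `a` clones, each with `b` collectives, each with `c`
#' particles. The phenotype of particle `k` in collective `j` of clone `i`
#' decomposes as `y_ijk = m + A_i + B_j(i) + C_k(ij)` (grand mean, clone
#' deviation, collective-within-clone deviation, particle-within-
#' collective deviation), the model underlying the nested-ANOVA
#' heritability estimators.
#'
#' @param values Either a 3-d numeric array with dimensions
#'   `(a, b, c)` = (clone, collective, particle), or a long-format
#'   data.frame with columns `clone`, `collective`, `particle`, `value`.
#'   Long input must be balanced: every clone the same number of
#'   collectives, every collective the same number of particles;
#'   unbalanced input is rejected, not approximated.
#' @return Object of class `nested_table` with elements `y` (the array),
#'   `a`, `b`, `c`.
#' @examples
#' toy <- nested_table(array(c(1, 5, 3, 7), dim = c(2, 1, 2)))
#' nested_ss(toy)
#' @export
nested_table <- function(values) {
  if (is.data.frame(values)) {
    req <- c("clone", "collective", "particle", "value")
    if (!all(req %in% names(values)))
      stop("long input needs columns clone, collective, particle, value", call. = FALSE)
    cl <- factor(values$clone)
    co <- factor(paste(values$clone, values$collective, sep = "\r"))
    per_clone <- tapply(values$collective, cl, function(x) length(unique(x)))
    per_coll <- table(co)
    if (length(unique(per_clone)) != 1L || length(unique(per_coll)) != 1L)
      stop("unbalanced design: every clone needs the same number of collectives and every collective the same number of particles",
           call. = FALSE)
    a <- nlevels(cl); b <- unname(per_clone[1]); c_ <- unname(per_coll[1])
    y <- array(NA_real_, dim = c(a, b, c_))
    ord <- order(cl, values$collective, values$particle)
    y[] <- aperm(array(values$value[ord], dim = c(c_, b, a)), c(3, 2, 1))
    values <- y
  }
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-d array (clone x collective x particle) or a long data.frame",
         call. = FALSE)
  if (any(!is.finite(values))) stop("phenotypes must be finite", call. = FALSE)
  d <- dim(values)
  if (any(d < 1L)) stop("empty table", call. = FALSE)
  structure(list(y = values, a = d[1], b = d[2], c = d[3]),
            class = "nested_table")
}

#' @export
print.nested_table <- function(x, ...) {
  cat(sprintf("<nested_table: %d clones x %d collectives x %d particles>\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Simulate a balanced nested table with known variance components
#'
#' Draws `y_ijk = m + A_i + B_j(i) + C_k(ij)` with independent normal
#' effects `A ~ N(0, sqrt(var_a))`, `B ~ N(0, sqrt(var_b))`,
#' `C ~ N(0, sqrt(var_c))`, so the variance components of the generated
#' design are known exactly. Used to study estimator behaviour and as a
#' test fixture.
#'
#' @param a,b,c Numbers of clones, collectives per clone, particles per
#'   collective.
#' @param var_a,var_b,var_c Variances of the clone, collective and
#'   particle effects.
#' @param mean Grand mean `m`.
#' @param seed Optional seed.
#' @return A [nested_table()].
#' @export
simulate_nested_table <- function(a, b, c, var_a, var_b, var_c,
                                  mean = 0, seed = NULL) {
  stopifnot(a >= 1, b >= 1, c >= 1,
            var_a >= 0, var_b >= 0, var_c >= 0)
  if (!is.null(seed)) set.seed(seed)
  A <- stats::rnorm(a, 0, sqrt(var_a))
  B <- array(stats::rnorm(a * b, 0, sqrt(var_b)), dim = c(a, b))
  C <- array(stats::rnorm(a * b * c, 0, sqrt(var_c)), dim = c(a, b, c))
  y <- mean + array(A, dim = c(a, b, c)) +
    array(rep(B, times = c), dim = c(a, b, c)) + C
  nested_table(y)
}

#' Read a long-format nested phenotype CSV
#'
#' Expects columns `clone`, `collective`, `particle`, `value` and a
#' balanced design; see [nested_table()].
#'
#' @param path CSV file path.
#' @return A [nested_table()].
#' @export
read_nested_csv <- function(path) {
  nested_table(utils::read.csv(path))
}

#' Nested sums of squares of a particle-level phenotype
#'
#' Partitions the total sum of squared deviations from the grand mean
#' into among-clone (`ssa`), among-collectives-within-clone (`ss_b_a`) and
#' among-particles-within-collective (`ss_c_b`) components:
#' \deqn{SSA = bc \sum_i (\bar y_{i..} - \bar y_{...})^2}
#' \deqn{SS(B/A) = c \sum_i \sum_j (\bar y_{ij.} - \bar y_{i..})^2}
#' \deqn{SS(C/B) = \sum_i \sum_j \sum_k (y_{ijk} - \bar y_{ij.})^2}
#' with `sst = ssa + ss_b_a + ss_c_b` exactly.
#'
#' @param table A [nested_table()].
#' @return Object of class `ss_components` with fields `ssa`, `ss_b_a`,
#'   `ss_c_b`, `sst` and the design sizes `a`, `b`, `c`.
#' @examples
#' toy <- nested_table(array(c(1, 5, 3, 7), dim = c(2, 1, 2)))
#' nested_ss(toy)  # SSA = 16, SS(B/A) = 0, SS(C/B) = 4
#' @export
nested_ss <- function(table) {
  stopifnot(inherits(table, "nested_table"))
  y <- table$y
  a <- table$a; b <- table$b; c_ <- table$c
  grand <- mean(y)
  clone_means <- apply(y, 1, mean)
  coll_means <- apply(y, c(1, 2), mean)
  ssa <- b * c_ * sum((clone_means - grand)^2)
  ss_b_a <- c_ * sum((coll_means - clone_means)^2)  # recycles by clone (rows)
  ss_c_b <- sum((y - array(coll_means, dim = dim(y)))^2)
  structure(list(ssa = ssa, ss_b_a = ss_b_a, ss_c_b = ss_c_b,
                 sst = ssa + ss_b_a + ss_c_b,
                 a = a, b = b, c = c_),
            class = "ss_components")
}

#' @export
print.ss_components <- function(x, ...) {
  cat("Nested sums of squares\n")
  cat(sprintf("  SSA      (among clones)                : %g\n", x$ssa))
  cat(sprintf("  SS(B/A)  (collectives within clones)   : %g\n", x$ss_b_a))
  cat(sprintf("  SS(C/B)  (particles within collectives): %g\n", x$ss_c_b))
  cat(sprintf("  SST                                    : %g\n", x$sst))
  invisible(x)
}

#' Sums of squares of a collective-level trait
#'
#' For collective trait values `z_ij` (clone `i`, collective `j`),
#' partitions total variation into among-clone and within-clone parts:
#' \deqn{SS\alpha = b \sum_i (\bar z_{i.} - \bar z_{..})^2}
#' \deqn{SS(\beta/\alpha) = \sum_i \sum_j (z_{ij} - \bar z_{i.})^2}
#' with `sst_z = ss_alpha + ss_beta_alpha`. When `z` is the
#' within-collective mean of a particle table, `ss_alpha = ssa / c` and
#' `ss_beta_alpha = ss_b_a / c`, so the two levels share a common scale
#' factor that cancels from every heritability ratio.
#'
#' @param z Numeric matrix of collective trait values, one row per clone,
#'   one column per collective (balanced: same number per clone).
#' @return Object of class `collective_ss` with `ss_alpha`,
#'   `ss_beta_alpha`, `sst_z`, `a`, `b`.
#' @export
collective_ss <- function(z) {
  if (is.data.frame(z)) z <- as.matrix(z)
  if (!is.matrix(z)) {
    if (is.list(z)) {
      if (length(unique(lengths(z))) != 1L)
        stop("unbalanced input: every clone needs the same number of collectives", call. = FALSE)
      z <- do.call(rbind, z)
    } else stop("`z` must be a clones x collectives matrix or per-clone list", call. = FALSE)
  }
  if (any(!is.finite(z))) stop("collective traits must be finite", call. = FALSE)
  a <- nrow(z); b <- ncol(z)
  clone_means <- rowMeans(z)
  ss_alpha <- b * sum((clone_means - mean(z))^2)
  ss_beta_alpha <- sum((z - clone_means)^2)
  structure(list(ss_alpha = ss_alpha, ss_beta_alpha = ss_beta_alpha,
                 sst_z = ss_alpha + ss_beta_alpha, a = a, b = b),
            class = "collective_ss")
}

new_h2 <- function(h2, method) {
  structure(list(h2 = h2, method = method), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H^2 = %.6g  (method: %s)\n", x$h2, x$method))
  invisible(x)
}

#' Particle-level broad-sense heritability from sums of squares
#'
#' `H_y^2 ~ SSA / (SSA + SS(B/A) + SS(C/B))`: the fraction of total
#' phenotypic sum of squares attributable to differences among clones.
#' Structurally bounded in [0, 1].
#'
#' @param ss An `ss_components` object from [nested_ss()].
#' @return A `heritability_estimate` (fields `h2`, `method`).
#' @export
particle_H2 <- function(ss) {
  stopifnot(inherits(ss, "ss_components"))
  if (ss$sst <= 0)
    stop("no phenotypic variance: particle-level heritability undefined", call. = FALSE)
  new_h2(ss$ssa / ss$sst, "ss_ratio")
}

#' Collective-level broad-sense heritability from sums of squares
#'
#' `H_z^2 ~ SSalpha / (SSalpha + SS(beta/alpha))`. When the collective
#' trait is the within-collective mean (or any other linear function of
#' member phenotypes) this equals `SSA / (SSA + SS(B/A))` computed from
#' the particle table, because the linear map rescales both sums by the
#' same constant.
#'
#' @param ss Either a `collective_ss` object from [collective_ss()], or an
#'   `ss_components` object from [nested_ss()] (the linear-trait shortcut).
#' @return A `heritability_estimate`.
#' @export
collective_H2 <- function(ss) {
  if (inherits(ss, "collective_ss")) {
    if (ss$sst_z <= 0)
      stop("no phenotypic variance: collective-level heritability undefined", call. = FALSE)
    return(new_h2(ss$ss_alpha / ss$sst_z, "ss_ratio"))
  }
  stopifnot(inherits(ss, "ss_components"))
  denom <- ss$ssa + ss$ss_b_a
  if (denom <= 0)
    stop("no phenotypic variance: collective-level heritability undefined", call. = FALSE)
  new_h2(ss$ssa / denom, "ss_ratio")
}

#' Ratio of collective-level to particle-level heritability
#'
#' For a linear collective trait with fixed particle number the
#' heritability ratio reduces to sums of squares of the particle table:
#' \deqn{H_z^2 / H_y^2 = (SSA + SS(B/A) + SS(C/B)) / (SSA + SS(B/A))}
#' This is structurally >= 1 and equals 1 exactly when `SS(C/B) = 0`,
#' i.e. when particles within each collective have identical phenotype:
#' collectives can only gain heritability by averaging out
#' within-collective phenotypic noise.
#'
#' @param ss An `ss_components` object from [nested_ss()].
#' @return The ratio (scalar >= 1).
#' @export
heritability_ratio <- function(ss) {
  stopifnot(inherits(ss, "ss_components"))
  denom <- ss$ssa + ss$ss_b_a
  if (denom <= 0) stop("SSA + SS(B/A) = 0: heritability ratio undefined", call. = FALSE)
  ss$sst / denom
}

#' Parent-offspring regression slope
#'
#' Ordinary least-squares slope of offspring phenotype on parent
#' phenotype, the classical heritability estimator for the simulation
#' output. Slopes are reported unclipped: sampling noise can push them
#' above 1 or below 0.
#'
#' @param pairs Two-column data.frame or matrix, parent values first;
#'   at least two pairs with non-constant parent values.
#' @return OLS slope (scalar).
#' @examples
#' po_slope(data.frame(parent = c(1, 2, 3), offspring = c(2, 2.5, 4)))  # 1
#' @export
po_slope <- function(pairs) {
  p <- as.numeric(pairs[[1]])
  o <- as.numeric(pairs[[2]])
  if (length(p) < 2L) stop("need at least two parent-offspring pairs", call. = FALSE)
  vp <- stats::var(p)
  if (!is.finite(vp) || vp == 0)
    stop("parent values have zero variance: regression slope undefined", call. = FALSE)
  stats::cov(p, o) / vp
}

#' Relative heritability of a collective trait from a simulation run
#'
#' Fills in the collective-level parent-offspring pairs of a pedigree by
#' applying a trait map to the member cells of each collective, then
#' estimates heritability at both levels as parent-offspring regression
#' slopes (pooled over all generations of the run) and returns their
#' ratio, collective over cell.
#'
#' @param run A `growth_run` from [grow_population()].
#' @param map A trait-map name (see [trait_map()]) or a function mapping a
#'   cell-size vector to a scalar trait value.
#' @return List with `slope_cell`, `slope_collective`, `ratio`.
#' @examples
#' run <- grow_population(sim_params(generations = 4, seed = 3))
#' relative_heritability(run, "volume")
#' @export
relative_heritability <- function(run, map = "volume") {
  stopifnot(inherits(run, "growth_run"))
  if (is.character(map)) map <- trait_map(map)
  stopifnot(is.function(map))
  ped <- run$pedigree
  if (nrow(ped$collective_pairs) == 0L)
    stop("pedigree has no collective-level pairs (zero generations?)", call. = FALSE)
  traits <- vapply(run$cells, map, numeric(1))
  slope_cell <- po_slope(ped$cell_pairs)
  slope_collective <- po_slope(data.frame(
    parent = traits[ped$collective_pairs$parent_id],
    offspring = traits[ped$collective_pairs$offspring_id]))
  list(slope_cell = slope_cell, slope_collective = slope_collective,
       ratio = slope_collective / slope_cell)
}

#' Error of the sums-of-squares approximation to the heritability ratio
#'
#' Heritability is a ratio of variances; the sums-of-squares estimators
#' replace it by a ratio of expected sums of squares, which converges to
#' the variance ratio as the numbers of clones and collectives grow. This
#' function quantifies the finite-design discrepancy deterministically,
#' using the closed-form expectations for a balanced nested design with
#' variance components `(var_a, var_b, var_c)`:
#' \deqn{E[SSA] = (a-1)(\sigma^2_C + c\,\sigma^2_B + bc\,\sigma^2_A)}
#' \deqn{E[SS(B/A)] = a(b-1)(\sigma^2_C + c\,\sigma^2_B)}
#' \deqn{E[SS(C/B)] = ab(c-1)\,\sigma^2_C}
#' The variance-definition ratio, for a collective trait equal to the
#' within-collective mean, is
#' `(var_a + var_b + var_c) / (var_a + var_b + var_c / c)`.
#'
#' @param var_a,var_b,var_c Variance components (clone, collective,
#'   particle), not all zero.
#' @param a,b,c Design sizes: clones (>= 2), collectives per clone,
#'   particles per collective.
#' @return Relative error of the sums-of-squares ratio versus the
#'   variance ratio, in percent.
#' @examples
#' ss_vs_variance_error(1, 0.5, 2, a = 10, b = 10, c = 32)
#' @export
ss_vs_variance_error <- function(var_a, var_b, var_c, a, b, c) {
  stopifnot(var_a >= 0, var_b >= 0, var_c >= 0,
            a >= 2, b >= 1, c >= 1)
  if (var_a + var_b + var_c <= 0)
    stop("all variance components zero: ratio undefined", call. = FALSE)
  e_ssa <- (a - 1) * (var_c + c * var_b + b * c * var_a)
  e_ssb <- a * (b - 1) * (var_c + c * var_b)
  e_ssc <- a * b * (c - 1) * var_c
  if (e_ssa + e_ssb <= 0)
    stop("expected SSA + SS(B/A) is zero: ratio undefined", call. = FALSE)
  ratio_ss <- (e_ssa + e_ssb + e_ssc) / (e_ssa + e_ssb)
  ratio_var <- (var_a + var_b + var_c) / (var_a + var_b + var_c / c)
  abs(ratio_ss - ratio_var) / ratio_var * 100
}

#' Nested phenotype table from a simulation generation
#'
#' Extracts one generation of a fixed-cell-number growth run as a
#' balanced clone / collective / particle table: clones are the founding
#' genotypes, collectives are that generation's collectives (each
#' genotype has the same number), particles are their member cells. This
#' is the bridge from the generative model to the nested-ANOVA
#' estimators.
#'
#' @param run A `growth_run` grown with `cv_n = 0` (variable cell number
#'   gives an unbalanced design, which the estimators reject).
#' @param generation Which generation to extract (default: the last).
#' @return A [nested_table()].
#' @examples
#' run <- grow_population(sim_params(n_genotypes = 3, generations = 3, seed = 1))
#' nested_ss(as_nested_table(run))
#' @export
as_nested_table <- function(run, generation = NULL) {
  stopifnot(inherits(run, "growth_run"))
  if (run$params$cv_n != 0)
    stop("variable cell number (`cv_n` > 0) gives an unbalanced design", call. = FALSE)
  d <- run$collectives
  if (is.null(generation)) generation <- max(d$generation)
  keep <- d$generation == generation
  if (!any(keep)) stop("no collectives in that generation", call. = FALSE)
  ids <- d$id[keep]
  geno <- d$genotype_id[keep]
  ord <- order(geno, ids)
  ids <- ids[ord]; geno <- geno[ord]
  a <- length(unique(geno))
  b <- length(ids) / a
  c_ <- length(run$cells[[ids[1]]])
  y <- array(NA_real_, dim = c(a, b, c_))
  for (i in seq_along(ids)) {
    gi <- match(geno[i], unique(geno))
    bi <- sum(geno[seq_len(i)] == geno[i])
    y[gi, bi, ] <- run$cells[[ids[i]]]
  }
  nested_table(y)
}
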