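#' Hydrodynamic constants for the upward-swimming-speed trait
#'
#' Constants of the colony swimming model for undifferentiated volvocine
#' algae: per-cell upward swimming force `f` (g cm/s^2), water viscosity
#' `eta_w` (g/(cm s)), cell-water density difference `delta_rho_c`
#' (g/cm^3), gravitational acceleration `g_accel` (cm/s^2) and cell number
#' `N`. Defaults are the standard printed constants for 32-celled
#' colonies.
#'
#' @param f Per-cell upward swimming force.
#' @param eta_w Water viscosity.
#' @param delta_rho_c Cell-water density difference.
#' @param g_accel Gravitational acceleration.
#' @param N Cells per collective.
#' @return Object of class `swim_params`.
#' @export
swim_params <- function(f = 2.4e-7, eta_w = 0.01, delta_rho_c = 0.047,
                        g_accel = 980, N = 32) {
  vals <- c(f = f, eta_w = eta_w, delta_rho_c = delta_rho_c,
            g_accel = g_accel, N = N)
  if (any(vals <= 0)) stop("all swim parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "swim_params")
}

#' Parameters of the predation-survival trait
#'
#' Survival under size-selective predation is a logistic function of the
#' collective's radius `r` and cell number `N`:
#' `survival = 1 / (1 + exp(-steepness * (radius_coeff * r * sqrt(N) - offset)))`.
#' Defaults give the standard form with steepness 0.5, radius coefficient
#' 0.5 and offset 25, i.e. a survival of one half when
#' `0.5 * r * sqrt(N) = 25`.
#'
#' @param steepness Logistic slope.
#' @param radius_coeff Coefficient on `r * sqrt(N)` inside the logistic.
#' @param offset Logistic offset.
#' @param N Cells per collective.
#' @return Object of class `predation_params`.
#' @export
predation_params <- function(steepness = 0.5, radius_coeff = 0.5,
                             offset = 25, N = 32) {
  structure(list(steepness = steepness, radius_coeff = radius_coeff,
                 offset = offset, N = N),
            class = "predation_params")
}

#' Collective volume
#'
#' The simplest (linear) trait map: collective volume is the sum of the
#' member cell volumes.
#'
#' @param cell_sizes Non-empty numeric vector of positive cell sizes,
#'   interpreted as cell volumes.
#' @return Total volume (positive scalar).
#' @examples
#' collective_volume(rep(1.5, 32))  # 48
#' @export
collective_volume <- function(cell_sizes) {
  check_cell_sizes(cell_sizes)
  sum(cell_sizes)
}

#' Collective diameter
#'
#' Assuming the member cells are pressed tightly together into a sphere,
#' the collective's diameter is `d = 2 * (3 V / (4 pi))^(1/3)` where `V`
#' is the collective volume (sum of cell volumes).
#'
#' @inheritParams collective_volume
#' @return Diameter (positive scalar).
#' @examples
#' collective_diameter(4 * pi / 3)  # a single unit sphere: d = 2
#' @export
collective_diameter <- function(cell_sizes) {
  check_cell_sizes(cell_sizes)
  2 * (3 * sum(cell_sizes) / (4 * pi))^(1 / 3)
}

#' Upward swimming speed of a colony
#'
#' In the volvocine hydrodynamics model the per-cell swimming force is
#' independent of cell size, so larger cells make the colony more
#' negatively buoyant without adding thrust: upward speed is a
#' monotonically declining function of mean cell radius `r`, of the form
#' `c1 / r - c2 * r^2`, and may be negative (the colony sinks).
#'
#' Two modes are available. The default (`params = NULL`) evaluates the
#' operative simplified form for 32-celled colonies with the standard
#' constants baked in:
#' `V_up = (0.02 / pi) / r - (400 / 3) * r^2`.
#' Supplying a [swim_params()] object instead evaluates the general form
#' `V_up = f sqrt(N) / (3 pi eta_w r) - g delta_rho_c (4/3) N^2 r^2 / (3 eta_w)`.
#' The two forms share their shape but their constants follow different
#' unit conventions and are not numerically reconciled here.
#'
#' @param mean_cell_radius Positive mean radius of the cells in the
#'   collective.
#' @param params `NULL` for the simplified default, or a [swim_params()]
#'   object for the general form.
#' @return Upward swimming speed (may be negative).
#' @examples
#' upward_swim_speed(0.01)
#' upward_swim_speed((1.5e-4 / pi)^(1 / 3))  # ~0: buoyancy balances thrust
#' @export
upward_swim_speed <- function(mean_cell_radius, params = NULL) {
  if (any(mean_cell_radius <= 0)) stop("`mean_cell_radius` must be positive", call. = FALSE)
  r <- mean_cell_radius
  if (is.null(params)) return((0.02 / pi) / r - (400 / 3) * r^2)
  stopifnot(inherits(params, "swim_params"))
  with(params,
       f * sqrt(N) / (3 * pi * eta_w) / r -
         g_accel * delta_rho_c * (4 / 3) * N^2 / (3 * eta_w) * r^2)
}

#' Survival rate under size-selective predation
#'
#' Survival of a collective facing a gape-limited predator is a logistic
#' function of its radius: predation efficiency drops off quickly once
#' collectives pass a threshold size. With the default parameters
#' `survival = 1 / (1 + exp(-0.5 * (0.5 * r * sqrt(N) - 25)))`,
#' strictly increasing in `r` and bounded in (0, 1).
#'
#' @param mean_cell_radius Non-negative mean radius of the cells in the
#'   collective.
#' @param params A [predation_params()] object.
#' @return Survival rate in (0, 1).
#' @examples
#' survival_rate(25 / (0.5 * sqrt(32)))  # logistic midpoint: 0.5
#' @export
survival_rate <- function(mean_cell_radius, params = predation_params()) {
  if (any(mean_cell_radius < 0)) stop("`mean_cell_radius` must be non-negative", call. = FALSE)
  stopifnot(inherits(params, "predation_params"))
  with(params,
       1 / (1 + exp(-steepness * (radius_coeff * mean_cell_radius * sqrt(N) - offset))))
}

#' Mean cell radius of a collective
#'
#' Adapter between the growth model's generic positive "cell size"
#' phenotype and the radius `r` used by the swimming-speed and
#' predation-survival maps: the arithmetic mean of the member sizes,
#' interpreted as the average cell radius.
#'
#' @inheritParams collective_volume
#' @return Arithmetic mean of the member sizes.
#' @export
mean_cell_radius <- function(cell_sizes) {
  check_cell_sizes(cell_sizes)
  mean(cell_sizes)
}

check_cell_sizes <- function(cell_sizes) {
  if (length(cell_sizes) == 0L) stop("`cell_sizes` must be non-empty", call. = FALSE)
  if (any(!is.finite(cell_sizes)) || any(cell_sizes <= 0))
    stop("`cell_sizes` must be positive and finite", call. = FALSE)
  invisible(cell_sizes)
}

#' Look up a trait map by name
#'
#' Returns a function mapping a collective's member cell sizes to a single
#' collective-level trait value. The volume and diameter maps interpret
#' the size phenotype as cell volume; the swimming and survival maps
#' interpret its collective mean as cell radius. For `"survival"` the
#' logistic uses the collective's own cell count as `N`, so variable cell
#' number feeds through to the trait.
#'
#' @param name One of `"volume"`, `"diameter"`, `"swim"`, `"survival"`.
#' @param swim Optional [swim_params()] passed to the swim map (default:
#'   the simplified standard form).
#' @param predation [predation_params()] used by the survival map.
#' @return A function `cell_sizes -> trait value`.
#' @examples
#' f <- trait_map("diameter")
#' f(rep(4 * pi / 3, 8))  # 4
#' @export
trait_map <- function(name = c("volume", "diameter", "swim", "survival"),
                      swim = NULL, predation = predation_params()) {
  name <- match.arg(name)
  switch(name,
    volume = collective_volume,
    diameter = collective_diameter,
    swim = function(cell_sizes) upward_swim_speed(mean_cell_radius(cell_sizes), swim),
    survival = function(cell_sizes) {
      p <- predation
      p$N <- length(cell_sizes)
      survival_rate(mean_cell_radius(cell_sizes), p)
    })
}
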