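#' Quasi-steady-state level of the partner repressor
#'
#' In the one-variable reduction of the mutual repression core, the level of
#' the non-focal repressor is slaved to the focal one: with the focal species
#' held at `y` (and the signal off, so y1 = 0), the partner's rate equation
#' is solved for its steady level. For the MRN-NA the balance is quadratic in
#' the partner level (the autoregulation term introduces a `K/(y+K)` factor)
#' and the unique non-negative root has a closed form; for the MRN it
#' collapses to the synthesis/degradation quotient.
#'
#' @param y focal species level(s), >= 0.
#' @param params a [kinetic_params()] object.
#' @param species focal species, `"y2"` or `"y3"`.
#' @return the partner's steady level(s), same length as `y`.
#' @export
qss_partner <- function(y, params, species = c("y2", "y3")) {
  species <- match.arg(species)
  if (any(y < 0)) stop("y must be >= 0")
  p <- params
  # synthesis into the partner, excluding its autoregulation term, at y1 = 0
  if (species == "y2") {
    # partner is y3: its basal channel is competitively repressed by the
    # focal y2 (y1 = 0 contributes nothing), plus the cooperative mutual
    # repression by y2
    syn <- p$k6 * p$K3 / (y + p$K3) + p$k7 * hill_repression(y, p$K4, p$n)
    kdeg <- p$k8; kauto <- p$k10; Kauto <- p$K6
  } else {
    # partner is y2: activation term vanishes at y1 = 0
    syn <- p$k3 * 0 + p$k4 * hill_repression(y, p$K2, p$n)
    kdeg <- p$k5; kauto <- p$k9; Kauto <- p$K5
  }
  if (kauto == 0) return(syn / kdeg)
  # kdeg*x^2 + (kdeg*Kauto - syn)*x - Kauto*(syn + kauto) = 0, positive root
  b <- syn - kdeg * Kauto
  disc <- b^2 + 4 * kdeg * Kauto * (syn + kauto)
  if (any(disc < 0)) stop("negative discriminant in quasi-steady-state root")
  (b + sqrt(disc)) / (2 * kdeg)
}

#' Drift of the reduced one-variable process
#'
#' Birth minus death rate of the focal species once its partner is slaved by
#' the quasi-steady-state assumption (signal off): synthesis through the
#' mutual repression term evaluated at the partner's slaved level, plus the
#' negative-autoregulation term at `y` itself, minus linear degradation.
#'
#' @inheritParams qss_partner
#' @return drift A(y), same length as `y`.
#' @export
reduced_drift <- function(y, params, species = c("y2", "y3")) {
  species <- match.arg(species)
  reduced_birth(y, params, species) - reduced_death(y, params, species)
}

#' Noise function of the reduced one-variable process
#'
#' Birth plus death rate of the reduced process; the diffusion coefficient
#' of the associated Fokker-Planck equation. Strictly positive for all
#' `y >= 0` (synthesis never fully shuts off).
#'
#' @inheritParams qss_partner
#' @return noise B(y), same length as `y`.
#' @export
reduced_noise <- function(y, params, species = c("y2", "y3")) {
  species <- match.arg(species)
  reduced_birth(y, params, species) + reduced_death(y, params, species)
}

reduced_birth <- function(y, params, species) {
  p <- params
  yss <- qss_partner(y, params, species)
  if (species == "y2") {
    p$k4 * hill_repression(yss, p$K2, p$n) + p$k9 * p$K5 / (y + p$K5)
  } else {
    p$k6 * p$K3 / (yss + p$K3) + p$k7 * hill_repression(yss, p$K4, p$n) +
      p$k10 * p$K6 / (y + p$K6)
  }
}

reduced_death <- function(y, params, species) {
  if (species == "y2") params$k5 * y else params$k8 * y
}

#' Reduced one-variable system
#'
#' Packages the drift, noise and quasi-steady-state partner map of the
#' chosen focal species into one object, together with the default analysis
#' range `[0, y_max]` where `y_max = 1.5 x` (maximal synthesis rate /
#' degradation constant), beyond which the process has negligible stationary
#' mass.
#'
#' @inheritParams qss_partner
#' @return a `reduced_system` object: list with functions `drift`, `noise`,
#'   `birth`, `death`, `qss`, and fields `species`, `variant`, `y_max`.
#' @export
reduced_system <- function(params, species = c("y2", "y3")) {
  species <- match.arg(species)
  validate_params(params)
  p <- params
  y_max <- if (species == "y2") 1.5 * (p$k3 + p$k4 + p$k9) / p$k5
           else 1.5 * (p$k6 + p$k7 + p$k10) / p$k8
  structure(list(
    drift = function(y) reduced_drift(y, p, species),
    noise = function(y) reduced_noise(y, p, species),
    birth = function(y) reduced_birth(y, p, species),
    death = function(y) reduced_death(y, p, species),
    qss = function(y) qss_partner(y, p, species),
    params = p, species = species, variant = p$variant, y_max = y_max),
    class = "reduced_system")
}

#' Fixed points of the reduced drift
#'
#' Locates all roots of the reduced drift A(y) on `[0, y_max]` by a dense
#' sign scan followed by bisection polish, and classifies them by the sign
#' of the numerical derivative of A: stable where A decreases through zero,
#' unstable (the barrier between basins) where it increases.
#'
#' @inheritParams qss_partner
#' @param n_scan number of scan points for sign-change bracketing.
#' @param tol absolute tolerance of the root polish.
#' @return a `steady_state_set` object: list with `y_l` (lower stable root),
#'   `y_b` (unstable barrier), `y_u` (upper stable root) — `y_b`/`y_u` are
#'   `NA` when monostable — plus `roots`, `stable` and `monostable`.
#' @export
fixed_points <- function(params, species = c("y2", "y3"), n_scan = 4000,
                         tol = 1e-9) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  grid <- seq(0, rs$y_max, length.out = n_scan)
  a <- rs$drift(grid)
  roots <- numeric(0)
  sgn <- sign(a)
  for (i in seq_len(n_scan - 1)) {
    if (sgn[i] == 0) next
    if (sgn[i] * sgn[i + 1] < 0) {
      r <- stats::uniroot(rs$drift, c(grid[i], grid[i + 1]), tol = tol)
      roots <- c(roots, r$root)
    } else if (sgn[i + 1] == 0) {
      roots <- c(roots, grid[i + 1])
    }
  }
  roots <- sort(unique(roots))
  if (length(roots) > 3)
    stop("found ", length(roots),
         " fixed points; the reduced model should have at most 3")
  h <- rs$y_max * 1e-6
  dA <- (rs$drift(roots + h) - rs$drift(pmax(roots - h, 0))) /
    (roots + h - pmax(roots - h, 0))
  stable <- dA < 0
  out <- list(roots = roots, stable = stable,
              monostable = length(roots) == 1,
              y_l = NA_real_, y_b = NA_real_, y_u = NA_real_,
              species = species, variant = params$variant)
  if (length(roots) == 1) {
    out$y_l <- roots
  } else if (length(roots) == 3) {
    if (!identical(stable, c(TRUE, FALSE, TRUE)))
      stop("unexpected stability pattern at the three fixed points")
    out$y_l <- roots[1]; out$y_b <- roots[2]; out$y_u <- roots[3]
  } else {
    # tangency (saddle-node) grid case: keep the stable root as y_l
    out$y_l <- roots[which(stable)[1]]
  }
  class(out) <- "steady_state_set"
  out
}

#' @export
print.steady_state_set <- function(x, ...) {
  if (x$monostable)
    cat(sprintf("<steady_state_set %s/%s: monostable at %.4f>\n",
                x$variant, x$species, x$y_l))
  else
    cat(sprintf(
      "<steady_state_set %s/%s: y_l = %.4f, y_b = %.4f, y_u = %.4f>\n",
      x$variant, x$species, x$y_l, x$y_b, x$y_u))
  invisible(x)
}

#' Stationary density and stochastic potential of the reduced process
#'
#' Computes the stationary solution of the one-variable Fokker-Planck
#' equation, `P_st(y) = N_c / B(y) * exp(2 * int A/B dy)`, by cumulative
#' trapezoid integration of `2A/B`, exponentiation with max-subtraction, and
#' trapezoid normalization; and the stochastic potential
#' `Phi_s(y) = 1/2 log B(y) - int A/B dy`, so that `P_st` is proportional to
#' `exp(-2 Phi_s)`. The integration constant is anchored at `y = 0` (it only
#' shifts the potential and cancels in the normalization).
#'
#' @inheritParams qss_partner
#' @param grid increasing numeric grid over `[0, y_max]`; default 4000
#'   uniform points on the system's own range.
#' @return a `stationary_density` object: list with `grid`, `density`
#'   (normalized), `potential`, `log_density` (unnormalized), `Nc`, and the
#'   generating `species`/`variant`.
#' @export
stationary_density <- function(params, species = c("y2", "y3"), grid = NULL) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  if (is.null(grid)) grid <- seq(0, rs$y_max, length.out = 4000)
  if (length(grid) < 2000)
    stop("grid must have at least 2000 points")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  A <- rs$drift(grid)
  B <- rs$noise(grid)
  if (any(!is.finite(A)) || any(!is.finite(B)))
    stop("non-finite drift/noise at y = ",
         grid[which(!is.finite(A) | !is.finite(B))[1]])
  if (any(B <= 0)) stop("noise function must be positive")
  intAB <- cumtrapz(grid, A / B)
  logP <- 2 * intAB - log(B)
  logP <- logP - max(logP)
  dens <- exp(logP)
  Z <- trapz(grid, dens)
  structure(list(grid = grid, density = dens / Z, potential = 0.5 * log(B) - intAB,
                 log_density = logP, Nc = 1 / Z,
                 species = species, variant = params$variant),
            class = "stationary_density")
}

#' @export
print.stationary_density <- function(x, ...) {
  cat(sprintf(
    "<stationary_density %s/%s: %d grid points on [0, %.1f], %d mode(s)>\n",
    x$variant, x$species, length(x$grid), max(x$grid),
    length(local_maxima(x$density))))
  invisible(x)
}

#' @export
plot.stationary_density <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = x$species, ylab = "stationary density", ...)
  invisible(x)
}

#' Double-well (bistability) test of the reduced system
#'
#' The reduced system is called bistable when the drift has three fixed
#' points (two stable separated by a barrier) *and* the stochastic potential
#' has two local minima separated by a local maximum. The two detectors
#' agree except within a grid step of the saddle-node boundary.
#'
#' @inheritParams qss_partner
#' @return `TRUE`/`FALSE`.
#' @export
is_bistable <- function(params, species = c("y2", "y3")) {
  species <- match.arg(species)
  fp <- fixed_points(params, species)
  if (length(fp$roots) != 3) return(FALSE)
  sd <- stationary_density(params, species)
  pot <- sd$potential
  n_min <- length(local_maxima(-pot))
  n_max <- length(local_maxima(pot))
  n_min >= 2 && n_max >= 1
}

# indices of strict interior local maxima
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(v[i] > v[i - 1] & v[i] >= v[i + 1]) + 1L
}

# trapezoid rule and cumulative trapezoid on an arbitrary grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Exact stationary law of the reduced birth-death chain
#'
#' The reduced process is, exactly, a birth-death chain on the non-negative
#' integers with birth rate `W_birth(y)` and death rate `W_death(y)`. Its
#' chemical master equation has the product-form stationary distribution
#' `pi(y) / pi(0) = prod_{i=1..y} W_birth(i-1) / W_death(i)`, computed here in
#' the log domain. This is the exact benchmark against which the
#' Fokker-Planck approximation [stationary_density()] is validated.
#'
#' @inheritParams qss_partner
#' @param y_max largest state; defaults to the reduced system's own range.
#' @return numeric vector of probabilities over states `0..y_max`.
#' @export
birth_death_stationary <- function(params, species = c("y2", "y3"),
                                   y_max = NULL) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  if (is.null(y_max)) y_max <- floor(rs$y_max)
  states <- 0:y_max
  lr <- log(rs$birth(states[-length(states)])) - log(rs$death(states[-1]))
  logpi <- c(0, cumsum(lr))
  logpi <- logpi - max(logpi)
  pi <- exp(logpi)
  pi / sum(pi)
}

#' Total-variation distance between two discrete distributions
#' @param p,q probability vectors of equal length (renormalized internally).
#' @return TV distance in \[0, 1\].
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

#' Discretize a stationary density onto integer states
#'
#' Evaluates the Fokker-Planck density at integer points `0..y_max` (by
#' linear interpolation on its grid) and renormalizes to a probability
#' vector, for comparison with integer-state distributions such as
#' [birth_death_stationary()] or SSA occupancy histograms.
#'
#' @param sd a [stationary_density()] object.
#' @param y_max largest state (default: floor of the grid maximum).
#' @return probability vector over `0..y_max`.
#' @export
density_to_pmf <- function(sd, y_max = NULL) {
  if (is.null(y_max)) y_max <- floor(max(sd$grid))
  states <- 0:y_max
  v <- stats::approx(sd$grid, sd$density, xout = states, rule = 2)$y
  v / sum(v)
}
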