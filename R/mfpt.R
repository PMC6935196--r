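#' Integrating factor of the reduced process
#'
#' `Psi(y) = exp( int_{y0}^{y} 2 A(w) / B(w) dw )`, the integrating factor of
#' the stationary first-passage equation. `Psi(y0) = 1` by construction; the
#' choice of anchor `y0` multiplies `Psi` by a constant that cancels inside
#' the first-passage integrals (the conventional anchors are `y0 = 0` for
#' the escape from the upper basin and `y0 = y_b` for the escape from the
#' lower one). Values are computed in the log domain and can span hundreds
#' of orders of magnitude; see `log_psi` in the result for overflow-free
#' work.
#'
#' @inheritParams qss_partner
#' @param y evaluation points (>= 0).
#' @param y0 anchor where Psi equals 1.
#' @param n_grid quadrature resolution.
#' @return list with `psi` and `log_psi`, each the length of `y`.
#' @export
psi_reduced <- function(y, params, species = c("y2", "y3"), y0 = 0,
                        n_grid = 4000) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  top <- max(y, y0, rs$y_max)
  grid <- sort(unique(c(seq(0, top, length.out = n_grid), y, y0)))
  L <- cumtrapz(grid, 2 * rs$drift(grid) / rs$noise(grid))
  L0 <- stats::approx(grid, L, xout = y0)$y
  lp <- stats::approx(grid, L, xout = y)$y - L0
  list(psi = exp(lp), log_psi = lp)
}

# Shared machinery: grid, log-Psi and the two nested quadratures, all with
# max-subtraction so that barrier factors of hundreds of orders of magnitude
# stay representable. Returns times on both the natural and log10 scale.
mfpt_quadrature <- function(params, species, n_grid = 4000,
                            truncation_factor = 1) {
  fp <- fixed_points(params, species)
  if (fp$monostable || is.na(fp$y_b))
    stop("mean first-passage analysis requires a bistable reduced system (",
         params$variant, "/", species, ", n = ", params$n, ")")
  T_L <- mfpt_between(params, species, from = fp$y_l, to = fp$y_b,
                      n_grid = n_grid, truncation_factor = truncation_factor)
  T_U <- mfpt_between(params, species, from = fp$y_u, to = fp$y_b,
                      n_grid = n_grid, truncation_factor = truncation_factor)
  list(T_L = T_L$value, T_U = T_U$value,
       log10_T_L = T_L$log10, log10_T_U = T_U$log10,
       steady_states = fp, n_grid = n_grid,
       y_trunc = reduced_system(params, species)$y_max * truncation_factor)
}

#' Mean first-passage time between two arbitrary points
#'
#' Continuum first-passage time of the reduced process from `from` to an
#' absorbing point `to`. For `from < to` the process is reflected at 0 (the
#' escape from the lower basin); for `from > to` the basin extends to
#' +infinity, truncated where the stationary density is negligible. Used by
#' [mfpt_lower()] / [mfpt_upper()] with the fixed points as endpoints, and
#' directly when comparing against first-passage simulations of the integer
#' chain (whose absorbing state is a whole number).
#'
#' @inheritParams mfpt_lower
#' @param from starting point (>= 0).
#' @param to absorbing point.
#' @return list with `value` and `log10`.
#' @export
mfpt_between <- function(params, species = c("y2", "y3"), from, to,
                         n_grid = 4000, truncation_factor = 1) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  if (from == to) return(list(value = 0, log10 = -Inf))
  y_trunc <- max(rs$y_max * truncation_factor, from, to)
  grid <- sort(unique(c(seq(0, y_trunc, length.out = n_grid), from, to)))
  B <- rs$noise(grid)
  L <- cumtrapz(grid, 2 * rs$drift(grid) / B)
  if (from < to) {
    i_a <- which(grid == from)[1]; i_b <- which(grid == to)[1]
    M <- max(L[1:i_b])
    inner <- cumtrapz(grid, exp(L - M) / B)   # ~ int_0^x Psi/B / e^M
    e <- log(pmax(inner[i_a:i_b], .Machine$double.xmin)) + M - L[i_a:i_b]
    trapz_exp(grid[i_a:i_b], e, factor = 2)
  } else {
    i_b <- which(grid == to)[1]; i_a <- which(grid == from)[1]
    M <- max(L[i_b:length(grid)])
    # rev_inner[i] = int_{grid[i]}^{y_trunc} exp(L - M)/B
    rev_inner <- rev(cumtrapz(rev(grid) * -1, rev(exp(L - M) / B)))
    e <- log(pmax(rev_inner[i_b:i_a], .Machine$double.xmin)) + M -
      L[i_b:i_a]
    trapz_exp(grid[i_b:i_a], e, factor = 2)
  }
}

# factor * trapezoid integral of exp(e) over x, as value and log10
trapz_exp <- function(x, e, factor = 1) {
  m <- max(e)
  v <- factor * trapz(x, exp(e - m))
  list(value = exp(m) * v, log10 = (m + log(v)) / log(10))
}

#' Mean first-passage time out of the lower basin
#'
#' Expected time for the reduced process, started at the lower stable state
#' `y_l`, to first reach the barrier `y_b`:
#' `T_L = 2 int_{y_l}^{y_b} Psi(x)^{-1} int_0^x Psi(z)/B(z) dz dx`,
#' evaluated by nested cumulative trapezoid quadrature in the log domain.
#'
#' @inheritParams qss_partner
#' @param n_grid quadrature resolution.
#' @param truncation_factor multiple of the default range used as the upper
#'   quadrature bound (only relevant for [mfpt_upper()]; shared for
#'   symmetry).
#' @return an `mfpt_result` with `T_L` (and `log10_T_L`), the
#'   `steady_states`, and quadrature metadata.
#' @export
mfpt_lower <- function(params, species = c("y2", "y3"), n_grid = 4000,
                       truncation_factor = 1) {
  species <- match.arg(species)
  q <- mfpt_quadrature(params, species, n_grid, truncation_factor)
  structure(c(q["T_L"], q["log10_T_L"], q["steady_states"],
              list(n_grid = q$n_grid, y_trunc = q$y_trunc,
                   species = species)),
            class = "mfpt_result")
}

#' Mean first-passage time out of the upper basin
#'
#' Expected time from the upper stable state `y_u` to the barrier `y_b`,
#' whose basin extends to +infinity:
#' `T_U = 2 int_{y_b}^{y_u} Psi(x)^{-1} int_x^{Inf} Psi(z)/B(z) dz dx`.
#' The infinite limit is truncated at 1.5x the maximal synthesis/degradation
#' balance (times `truncation_factor`), where the stationary density is
#' negligible; doubling the truncation changes the result by well under
#' 0.1%.
#'
#' @inheritParams mfpt_lower
#' @return an `mfpt_result` with `T_U` (and `log10_T_U`).
#' @export
mfpt_upper <- function(params, species = c("y2", "y3"), n_grid = 4000,
                       truncation_factor = 1) {
  species <- match.arg(species)
  q <- mfpt_quadrature(params, species, n_grid, truncation_factor)
  structure(c(q["T_U"], q["log10_T_U"], q["steady_states"],
              list(n_grid = q$n_grid, y_trunc = q$y_trunc,
                   species = species)),
            class = "mfpt_result")
}

#' Both mean first-passage times of a reduced system
#'
#' @inheritParams mfpt_lower
#' @return an `mfpt_result` with `T_L`, `T_U`, their log10 values, the
#'   steady states and quadrature metadata.
#' @export
#' @examples
#' p <- with_params(standard_params("MRN-NA"), n = 3, K = 15)
#' mfpt(p, "y3")
mfpt <- function(params, species = c("y2", "y3"), n_grid = 4000,
                 truncation_factor = 1) {
  species <- match.arg(species)
  q <- mfpt_quadrature(params, species, n_grid, truncation_factor)
  structure(c(q, list(species = species)), class = "mfpt_result")
}

#' @export
print.mfpt_result <- function(x, ...) {
  cat("<mfpt_result", paste0(x$species, ":"))
  if (!is.null(x$T_L)) cat(sprintf(" log10 T_L = %.3f", x$log10_T_L))
  if (!is.null(x$T_U)) cat(sprintf(" log10 T_U = %.3f", x$log10_T_U))
  cat(">\n")
  invisible(x)
}
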