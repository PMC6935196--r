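#' Kinetic parameter set for the mutual repression network models
#'
#' Bundles the rate constants, dissociation constants and Hill coefficient of
#' the three-protein mutual repression network (MRN) and its variant with
#' negative autoregulation (MRN-NA). The species are y1 (the signal-induced
#' transcription factor), y2 and y3 (the mutually repressing pair). Rates are
#' per unit of simulation time; concentrations are in molecule-count units.
#'
#' The wiring: the signal S drives y1 synthesis; y1 activates y2 (channel
#' `k3`, constant `K1`); y2 and y3 repress each other cooperatively (Hill
#' coefficient `n`) through the channels `k4`/`K2` (y3 on y2) and `k7`/`K4`
#' (y2 on y3); y3's basal channel `k6`/`K3` is under competitive repression
#' by y1 and y2 jointly. The MRN-NA additionally lets y2 and y3 inhibit
#' their own synthesis (channels `k9`/`K5` and `k10`/`K6`).
#'
#' The MRN-NA adds two synthesis channels in which y2 and y3 each inhibit
#' their own production (rate constants `k9`, `k10`; dissociation constants
#' `K5`, `K6`). Setting `k9 = k10 = 0` recovers the plain MRN, and the `MRN`
#' variant enforces that.
#'
#' @param variant `"MRN"` or `"MRN_NA"`.
#' @param k1,k2 synthesis (from the signal S) and degradation rate constants
#'   of y1.
#' @param k3,k4,k5 y2 kinetics: activation by y1, repression-gated basal
#'   synthesis, degradation.
#' @param k6,k7,k8 y3 kinetics: basal synthesis (competitively repressed by
#'   y1 and y2), cooperative repression by y2, degradation.
#' @param k9,k10 negative-autoregulation synthesis rate constants of y2 and
#'   y3 (must be 0 for the MRN).
#' @param K1,K3 dissociation constants of y1 acting on y2 (activation) and y3
#'   (repression).
#' @param K2,K4 dissociation constants of the mutual repression cycle (y3
#'   repressing y2, y2 repressing y3).
#' @param K5,K6 dissociation constants of the negative autoregulation.
#' @param n Hill coefficient of the mutual repression terms.
#'
#' @return An object of class `kinetic_params`: a named list with the fields
#'   above.
#' @seealso [standard_params()] for the canonical published parameter sets.
#' @export
#' @examples
#' p <- standard_params("MRN-NA")
#' p$k9
kinetic_params <- function(variant = c("MRN_NA", "MRN"),
                           k1 = 100, k2 = 1,
                           k3 = 18.1, k4 = 61.23, k5 = 0.8,
                           k6 = 18.1, k7 = 43.1, k8 = 0.8,
                           k9 = 4.1, k10 = 4.1,
                           K1 = 9, K2 = 43, K3 = 9, K4 = 43,
                           K5 = 9, K6 = 9,
                           n = 8) {
  variant <- match.arg(variant)
  if (variant == "MRN") {
    if (missing(k9)) k9 <- 0
    if (missing(k10)) k10 <- 0
  }
  p <- list(variant = variant,
            k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5,
            k6 = k6, k7 = k7, k8 = k8, k9 = k9, k10 = k10,
            K1 = K1, K2 = K2, K3 = K3, K4 = K4, K5 = K5, K6 = K6,
            n = n)
  class(p) <- "kinetic_params"
  validate_params(p)
  p
}

#' Validate a kinetic parameter set
#'
#' Checks non-negativity of rate constants, positivity of dissociation
#' constants, `n >= 1`, and that the MRN variant carries no autoregulation
#' (`k9 == k10 == 0`).
#'
#' @param p a [kinetic_params()] object.
#' @return `p`, invisibly; errors if a constraint is violated.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "kinetic_params"))
  ks <- unlist(p[paste0("k", 1:10)])
  Ks <- unlist(p[paste0("K", 1:6)])
  if (any(!is.finite(ks)) || any(ks < 0))
    stop("rate constants k1..k10 must be finite and >= 0")
  if (any(!is.finite(Ks)) || any(Ks <= 0))
    stop("dissociation constants K1..K6 must be finite and > 0")
  if (!is.finite(p$n) || p$n < 1)
    stop("Hill coefficient n must be >= 1")
  if (p$variant == "MRN" && (p$k9 != 0 || p$k10 != 0))
    stop("MRN variant requires k9 = k10 = 0")
  if (!p$variant %in% c("MRN", "MRN_NA"))
    stop("variant must be 'MRN' or 'MRN_NA'")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params: %s, n = %g, K2 = K4 = %g/%g>\n",
              x$variant, x$n, x$K2, x$K4))
  v <- unlist(x[-1])
  print(v)
  invisible(x)
}

#' Inductive signal schedule
#'
#' A rectangular pulse of the input signal S: amplitude `amplitude` on
#' `[t_on, t_off)`, zero elsewhere, over a total simulated time `t_end`.
#' The canonical protocol applies S from time 250 to 500 of a 1000-step run;
#' see [default_schedule()].
#'
#' @param amplitude signal level S while on (dimensionless driver of y1
#'   synthesis); the default 1 puts the induced y1 plateau at `k1/k2 = 100`.
#' @param t_on,t_off pulse start / end times.
#' @param t_end total simulated time.
#' @return A `signal_schedule` object.
#' @export
signal_schedule <- function(amplitude = 1, t_on = 250, t_off = 500,
                            t_end = 1000) {
  stopifnot(amplitude >= 0, t_on >= 0, t_on <= t_off, t_off <= t_end)
  structure(list(amplitude = amplitude, t_on = t_on, t_off = t_off,
                 t_end = t_end),
            class = "signal_schedule")
}

#' Signal value at given times
#' @param schedule a [signal_schedule()].
#' @param t numeric vector of times.
#' @return numeric vector of S values.
#' @export
signal_at <- function(schedule, t) {
  ifelse(t >= schedule$t_on & t < schedule$t_off, schedule$amplitude, 0)
}

#' Hill activation fraction
#'
#' Hyperbolic (Michaelis-Menten) activation `y / (y + K)`: the fractional
#' occupancy of an activator binding site.
#'
#' @param y activator level (>= 0).
#' @param K dissociation constant (> 0).
#' @return fraction in \[0, 1\], monotone increasing in `y`.
#' @export
#' @examples
#' hill_activation(9, 9)   # half saturation at y = K
hill_activation <- function(y, K) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(y < 0)) stop("y must be >= 0")
  y / (y + K)
}

#' Hill repression fraction
#'
#' Cooperative repression `K^n / (y^n + K^n)`, evaluated in a form that is
#' stable for large `y^n` (works up to the largest representable doubles).
#'
#' @param y repressor level (>= 0).
#' @param K dissociation constant (> 0).
#' @param n Hill coefficient (>= 1).
#' @return fraction in \[0, 1\], monotone decreasing in `y`; 1 at `y = 0`.
#' @export
#' @examples
#' hill_repression(43, 43, 8)  # half repression at y = K for any n
hill_repression <- function(y, K, n) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(y < 0)) stop("y must be >= 0")
  if (any(n < 1)) stop("n must be >= 1")
  # 1 / (1 + (y/K)^n), via exp/log so y^n cannot overflow
  r <- (y / K)^n
  big <- !is.finite(r)
  out <- 1 / (1 + r)
  out[big] <- 0
  out
}

#' Right-hand side of the rate equations
#'
#' Time derivatives of (y1, y2, y3) under the mutual repression model:
#' y1 is made at `k1*S` and degraded at `k2*y1`; y2 is synthesised through
#' activation by y1, cooperative repression by y3 (Hill coefficient n) and,
#' in the MRN-NA, negative autoregulation, and degraded at `k5*y2`; y3 is
#' synthesised through its basal channel (competitively repressed by y1 and
#' y2), cooperative repression by y2, and autoregulation, and degraded at
#' `k8*y3`.
#'
#' @param state numeric length-3 vector `c(y1, y2, y3)`, all >= 0.
#' @param params a [kinetic_params()] object.
#' @param S current signal value (>= 0).
#' @return numeric length-3 vector of derivatives.
#' @export
dydt <- function(state, params, S = 0) {
  pr <- propensities(state, params, S)
  c(pr[["y1_birth"]] - pr[["y1_death"]],
    pr[["y2_birth"]] - pr[["y2_death"]],
    pr[["y3_birth"]] - pr[["y3_death"]])
}

#' Reaction propensities of the six birth-death channels
#'
#' The stochastic counterpart of the rate equations lumps each species'
#' synthesis terms into one birth channel and keeps linear degradation as the
#' death channel, giving six channels: y1 birth `k1*S`, y1 death `k2*y1`,
#' y2 birth (activation + mutual repression + autoregulation terms), y2 death
#' `k5*y2`, y3 birth (competitively repressed basal + mutual repression +
#' autoregulation terms), y3 death `k8*y3`. By construction, birth minus
#' death per species equals the corresponding deterministic derivative.
#'
#' @inheritParams dydt
#' @return named numeric vector with elements `y1_birth`, `y1_death`,
#'   `y2_birth`, `y2_death`, `y3_birth`, `y3_death`, all >= 0.
#' @export
propensities <- function(state, params, S = 0) {
  stopifnot(length(state) == 3)
  if (any(state < 0)) stop("state must be non-negative")
  if (S < 0) stop("S must be >= 0")
  p <- params
  y1 <- state[[1]]; y2 <- state[[2]]; y3 <- state[[3]]
  c(y1_birth = p$k1 * S,
    y1_death = p$k2 * y1,
    y2_birth = p$k3 * hill_activation(y1, p$K1) +
      p$k4 * hill_repression(y3, p$K2, p$n) +
      p$k9 * p$K5 / (y2 + p$K5),
    y2_death = p$k5 * y2,
    y3_birth = p$k6 * p$K3 / (y1 + y2 + p$K3) +
      p$k7 * hill_repression(y2, p$K4, p$n) +
      p$k10 * p$K6 / (y3 + p$K6),
    y3_death = p$k8 * y3)
}
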