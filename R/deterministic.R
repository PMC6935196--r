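#' Numerically integrate the rate equations
#'
#' Solves the three-species ODE system with a stiff-capable solver
#' (`deSolve::lsoda`) under a rectangular signal pulse. The pulse edges are
#' passed to the solver as hard discontinuity times so the switching is
#' resolved exactly.
#'
#' @param params a [kinetic_params()] object.
#' @param schedule a [signal_schedule()].
#' @param init initial state `c(y1, y2, y3)`; default the origin.
#' @param times output grid; default unit-spaced `0:t_end` (the "simulation
#'   step" granularity of the protocol).
#' @param rtol,atol solver tolerances.
#' @return a `trajectory` object: list with `times`, `y1`, `y2`, `y3`,
#'   `method = "ODE"`.
#' @export
#' @examples
#' tr <- integrate_model(standard_params("MRN-NA"), default_schedule())
#' utils::tail(as.data.frame(tr))
integrate_model <- function(params, schedule, init = c(0, 0, 0),
                            times = NULL, rtol = 1e-8, atol = 1e-10) {
  validate_params(params)
  if (is.null(times)) times <- seq(0, schedule$t_end, by = 1)
  stopifnot(all(diff(times) > 0), all(init >= 0))
  rhs <- function(t, y, parms) {
    list(dydt(pmax(y, 0), params, signal_at(schedule, t)))
  }
  evt <- unique(c(schedule$t_on, schedule$t_off))
  evt <- evt[evt > min(times) & evt < max(times)]
  sol <- try(deSolve::lsoda(y = init, times = times, func = rhs,
                            rtol = rtol, atol = atol,
                            events = if (length(evt)) list(
                              func = function(t, y, parms) y,
                              time = evt) else NULL),
             silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(times))
    stop("ODE integration failed for variant ", params$variant,
         " (n = ", params$n, ", K2 = ", params$K2, ", K4 = ", params$K4, ")")
  structure(list(times = sol[, 1], y1 = pmax(sol[, 2], 0),
                 y2 = pmax(sol[, 3], 0), y3 = pmax(sol[, 4], 0),
                 method = "ODE", seed = NA_integer_),
            class = "trajectory")
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = x$times, y1 = x$y1, y2 = x$y2, y3 = x$y3)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s, %d points on [%g, %g]%s>\n", x$method,
              length(x$times), min(x$times), max(x$times),
              if (!is.na(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$y1, x$y2, x$y3), type = "l", lty = 1,
                    xlab = "time", ylab = "molecules", ...)
  graphics::legend("topright", c("y1", "y2", "y3"), lty = 1, col = 1:3,
                   bty = "n")
  invisible(x)
}

#' Deterministic steady state at fixed signal
#'
#' Integrates from `init` at constant signal `S` until the right-hand side
#' is below tolerance in the sup norm. Which attractor is reached depends on
#' `init`: in the bistable regime the origin relaxes to the off state
#' (low y2 / high y3) while an end-of-signal state relaxes to the induced
#' state (high y2 / low y3).
#'
#' @inheritParams integrate_model
#' @param S constant signal value.
#' @param tol convergence tolerance on the sup norm of the derivatives.
#' @param chunk integration time per convergence check.
#' @param max_chunks maximum number of chunks before giving up.
#' @return named numeric steady state `c(y1, y2, y3)`.
#' @export
steady_state <- function(params, S = 0, init = c(0, 0, 0), tol = 1e-8,
                         chunk = 500, max_chunks = 200) {
  sched <- signal_schedule(amplitude = S, t_on = 0, t_off = chunk,
                           t_end = chunk)
  y <- init
  for (i in seq_len(max_chunks)) {
    tr <- integrate_model(params, sched, init = y,
                          times = seq(0, chunk, length.out = 11))
    y <- c(tr$y1[11], tr$y2[11], tr$y3[11])
    if (max(abs(dydt(y, params, S))) < tol)
      return(stats::setNames(y, c("y1", "y2", "y3")))
  }
  stop("steady_state did not converge after ", max_chunks * chunk,
       " time units")
}

#' Hysteresis scan over the signal amplitude
#'
#' Continuation sweep of the steady state over a grid of constant signal
#' values: the ascending branch seeds each step with the previous steady
#' state starting from the off state at the lowest S, and the descending
#' branch retraces the grid from the attained state at the highest S. A
#' non-empty set of S values where the branches disagree is the hysteresis
#' loop that signals bistability.
#'
#' @param params a [kinetic_params()] object.
#' @param S_values increasing grid of signal amplitudes.
#' @param tol_rel relative disagreement between branches (in y2) above which
#'   an S value is counted as bistable.
#' @return a `hysteresis_curve` object: list with `S_values`, matrices
#'   `branch_up` / `branch_down` (columns y2, y3), and the logical
#'   `bistable_S` marking the loop.
#' @export
hysteresis_scan <- function(params, S_values = seq(0, 1, by = 0.05),
                            tol_rel = 0.01) {
  stopifnot(all(diff(S_values) > 0))
  m <- length(S_values)
  up <- down <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("y2", "y3")))
  # ascend from the uninduced resting state so the scan traces the lower
  # branch until the switching threshold
  y <- off_state(params)
  for (i in seq_len(m)) {
    y <- steady_state(params, S = S_values[i], init = y)
    up[i, ] <- y[c("y2", "y3")]
  }
  for (i in rev(seq_len(m))) {
    y <- steady_state(params, S = S_values[i], init = y)
    down[i, ] <- y[c("y2", "y3")]
  }
  scale <- pmax(up[, "y2"], down[, "y2"], 1)
  bist <- abs(up[, "y2"] - down[, "y2"]) / scale > tol_rel
  structure(list(S_values = S_values, branch_up = up, branch_down = down,
                 bistable_S = bist),
            class = "hysteresis_curve")
}

#' @export
print.hysteresis_curve <- function(x, ...) {
  if (any(x$bistable_S)) {
    rng <- range(x$S_values[x$bistable_S])
    cat(sprintf("<hysteresis_curve: bistable for S in [%g, %g]>\n",
                rng[1], rng[2]))
  } else cat("<hysteresis_curve: no bistable range>\n")
  invisible(x)
}

#' Pre-signal resting state of the network
#'
#' The uninduced (off) steady state at S = 0: low y2, high y3. It is found
#' by relaxing from a y3-dominant initial condition (y3 at its maximal
#' synthesis/degradation balance), representing the network's history
#' before any inductive signal; in the bistable regime this selects the
#' y3-high attractor regardless of which basin the origin happens to fall
#' into.
#'
#' @param params a [kinetic_params()] object.
#' @return named steady state `c(y1, y2, y3)`.
#' @export
off_state <- function(params) {
  y3_top <- (params$k6 + params$k7 + params$k10) / params$k8
  steady_state(params, S = 0, init = c(0, 0, y3_top))
}

#' Separatrix thresholds for memory classification
#'
#' The induced state (high y2, low y3) is separated from the off state by
#' the unstable fixed point of each species' reduced one-variable system at
#' S = 0; a trajectory "remembers" the signal while y2 stays above its
#' barrier and y3 below its own. When a reduced system is monostable the
#' midpoint of the two stable deterministic steady levels is used instead,
#' and when the full system itself is monostable no memory is possible.
#'
#' @param params a [kinetic_params()] object.
#' @param schedule a [signal_schedule()] (used to find the end-of-pulse
#'   state that seeds the induced attractor).
#' @return list with `m2`, `m3` (thresholds; `NA` when the S = 0 system is
#'   monostable and memory is impossible), `on_state`, `off_state` (full
#'   steady states from the induced and origin initial conditions).
#' @export
memory_thresholds <- function(params, schedule = default_schedule()) {
  off <- off_state(params)
  pulse_end <- integrate_model(params, schedule, init = off,
                               times = c(0, seq(schedule$t_on,
                                                schedule$t_off, by = 5)))
  k <- length(pulse_end$times)
  on <- steady_state(params, S = 0,
                     init = c(pulse_end$y1[k], pulse_end$y2[k],
                              pulse_end$y3[k]))
  bistable_full <- max(abs(on - off) / pmax(abs(off), 1)) > 0.01
  if (!bistable_full)
    return(list(m2 = NA_real_, m3 = NA_real_, on_state = on,
                off_state = off))
  fp2 <- fixed_points(params, "y2")
  fp3 <- fixed_points(params, "y3")
  m2 <- if (!fp2$monostable && !is.na(fp2$y_b)) fp2$y_b
        else (off["y2"] + on["y2"]) / 2
  m3 <- if (!fp3$monostable && !is.na(fp3$y_b)) fp3$y_b
        else (off["y3"] + on["y3"]) / 2
  list(m2 = unname(m2), m3 = unname(m3), on_state = on, off_state = off)
}

# shared classifier: does the trajectory hold the induced state throughout
# [t_off + settle, t_end]?
classify_memory <- function(traj, schedule, thresholds, settle = 20) {
  if (is.na(thresholds$m2) || is.na(thresholds$m3)) return(FALSE)
  sel <- traj$times >= schedule$t_off + settle & traj$times <= schedule$t_end
  if (!any(sel)) return(FALSE)
  all(traj$y2[sel] > thresholds$m2) && all(traj$y3[sel] < thresholds$m3)
}

#' Deterministic memory verdict
#'
#' Integrates the rate equations from the pre-signal off state under the
#' pulse schedule and asks whether, from 20 time units after signal removal
#' to the end of the run, y2 stays on the induced side of its separatrix and
#' y3 on the induced side of its own (see [memory_thresholds()]).
#'
#' @inheritParams integrate_model
#' @param settle settling time excluded after signal removal.
#' @return a `memory_verdict` object: list with `has_memory`,
#'   `per_trajectory` (length 1), `on_state`, `off_state`, `thresholds`.
#' @export
#' @examples
#' deterministic_memory(standard_params("MRN-NA"))$has_memory
deterministic_memory <- function(params, schedule = default_schedule(),
                                 settle = 20) {
  th <- memory_thresholds(params, schedule)
  traj <- integrate_model(params, schedule, init = th$off_state)
  ok <- classify_memory(traj, schedule, th, settle)
  structure(list(has_memory = ok, per_trajectory = ok,
                 on_state = th$on_state, off_state = th$off_state,
                 thresholds = th[c("m2", "m3")], mode = "deterministic"),
            class = "memory_verdict")
}

#' @export
print.memory_verdict <- function(x, ...) {
  cat(sprintf("<memory_verdict (%s): %s; %d/%d trajectories persistent>\n",
              x$mode, if (x$has_memory) "memory" else "no memory",
              sum(x$per_trajectory), length(x$per_trajectory)))
  invisible(x)
}
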