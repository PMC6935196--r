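#' Exact stochastic simulation of the full network
#'
#' Gillespie (direct-method) simulation of the six birth-death channels of
#' [propensities()], with the signal switching at the pulse edges (the
#' waiting time is regenerated there; between switches the propensity set is
#' time-homogeneous). The state is recorded on a unit-step grid as the state
#' at the latest event at or before each grid time. The whole trajectory is
#' a deterministic function of `seed`.
#'
#' @param params a [kinetic_params()] object.
#' @param schedule a [signal_schedule()].
#' @param init integer initial counts `c(y1, y2, y3)`; default the
#'   integer-rounded deterministic off state.
#' @param seed positive integer seed.
#' @param times recording grid; default unit-spaced `0:t_end`.
#' @return a `trajectory` object with integer counts, `method = "SSA"`.
#' @export
#' @examples
#' p <- standard_params("MRN-NA")
#' tr <- ssa_run(p, default_schedule(), seed = 1)
ssa_run <- function(params, schedule, init = NULL, seed = 1, times = NULL) {
  validate_params(params)
  if (is.null(init)) init <- round(off_state(params))
  if (any(init < 0) || any(init != round(init)))
    stop("init must be non-negative integer counts")
  if (is.null(times)) times <- seq(0, schedule$t_end, by = 1)
  stopifnot(all(diff(times) > 0), seed == round(seed), seed > 0)
  m <- ssa_trajectory_cpp(
    k = unlist(params[paste0("k", 1:10)], use.names = FALSE),
    K = unlist(params[paste0("K", 1:6)], use.names = FALSE),
    n = params$n,
    amplitude = schedule$amplitude, t_on = schedule$t_on,
    t_off = schedule$t_off,
    record_times = as.numeric(times),
    init = as.integer(init), seed = as.numeric(seed))
  structure(list(times = as.numeric(times), y1 = m[, 1], y2 = m[, 2],
                 y3 = m[, 3], method = "SSA", seed = as.integer(seed)),
            class = "trajectory")
}

#' Stochastic memory verdict over replicate simulations
#'
#' Runs `n_reps` independent Gillespie replicates (seeds `seed`,
#' `seed + 1`, ..., so each replicate is reproducible in isolation) of the
#' pulse protocol, classifies each by the same separatrix rule as the
#' deterministic verdict — y2 above its barrier and y3 below its own over
#' the whole post-settling window — and declares memory when at least
#' `pass_count` replicates persist (the canonical criterion is 18 of 20,
#' i.e. 90%).
#'
#' @inheritParams ssa_run
#' @param n_reps number of replicates.
#' @param pass_count minimum number of persistent replicates for a positive
#'   verdict.
#' @param settle settling time excluded after signal removal.
#' @return a `memory_verdict` object (see [deterministic_memory()]) with
#'   `per_trajectory` of length `n_reps` and `pass_count` attached.
#' @export
stochastic_memory <- function(params, schedule = default_schedule(),
                              n_reps = 20, pass_count = 18, seed = 1,
                              settle = 20) {
  stopifnot(n_reps >= pass_count, pass_count >= 1)
  th <- memory_thresholds(params, schedule)
  init <- round(th$off_state)
  per <- vapply(seq_len(n_reps), function(r) {
    tr <- ssa_run(params, schedule, init = init, seed = seed + r - 1)
    classify_memory(tr, schedule, th, settle)
  }, logical(1))
  structure(list(has_memory = sum(per) >= pass_count, per_trajectory = per,
                 on_state = th$on_state, off_state = th$off_state,
                 thresholds = th[c("m2", "m3")], pass_count = pass_count,
                 mode = "stochastic"),
            class = "memory_verdict")
}

#' Coefficient of variation of y2 and y3 over a time window
#'
#' Sample standard deviation over sample mean of the recorded levels with
#' times inside `[t_start, t_end]` — the intrinsic-noise summary used to
#' compare the network variants. A species whose windowed mean is zero gets
#' an `NA` CV and is flagged rather than raising an error.
#'
#' @param traj a `trajectory` (usually from [ssa_run()]).
#' @param window numeric length-2 `c(t_start, t_end)`; the canonical choices
#'   are `c(270, 500)` (signal period, skipping 20 settling steps) and
#'   `c(500, 750)` (post-signal).
#' @return a `cv_report`: list with `window`, `cv_y2`, `cv_y3`, `mean_y2`,
#'   `mean_y3`, `n_samples`, `undefined` (logical per species).
#' @export
coefficient_of_variation <- function(traj, window = c(270, 500)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (window[1] < min(traj$times) || window[2] > max(traj$times))
    stop("window must lie within the trajectory span")
  sel <- traj$times >= window[1] & traj$times <= window[2]
  cv1 <- function(x) {
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::sd(x) / m
  }
  cvs <- c(cv1(traj$y2[sel]), cv1(traj$y3[sel]))
  structure(list(window = window, cv_y2 = cvs[1], cv_y3 = cvs[2],
                 mean_y2 = mean(traj$y2[sel]), mean_y3 = mean(traj$y3[sel]),
                 n_samples = sum(sel), undefined = is.na(cvs)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report [%g, %g]: cv(y2) = %.4f, cv(y3) = %.4f (%d samples)>\n",
              x$window[1], x$window[2], x$cv_y2, x$cv_y3, x$n_samples))
  invisible(x)
}

#' Simulate the reduced birth-death chain
#'
#' Exact simulation of the one-variable chain whose birth rate is the
#' reduced system's `W_birth` (tabulated on the integer states) and whose
#' death rate is linear degradation — the stochastic process that the
#' Fokker-Planck reduction approximates. Returns the time-weighted occupancy
#' distribution after `n_events` events.
#'
#' @inheritParams qss_partner
#' @param n_events number of reaction events to simulate.
#' @param init initial integer state; default the rounded lower fixed point.
#' @param seed positive integer seed.
#' @param burnin_events events discarded before occupancy is accumulated.
#' @param cap largest state of the tabulation (default: the reduced range).
#' @return numeric probability vector over states `0..cap`.
#' @export
chain_occupancy <- function(params, species = c("y2", "y3"),
                            n_events = 1e6, init = NULL, seed = 1,
                            burnin_events = n_events / 10, cap = NULL) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  if (is.null(cap)) cap <- ceiling(rs$y_max)
  if (is.null(init)) init <- round(fixed_points(params, species)$y_l)
  birth <- rs$birth(0:cap)
  kdeath <- if (species == "y2") params$k5 else params$k8
  chain_occupancy_cpp(birth, kdeath, as.integer(init), n_events,
                      as.numeric(seed), burnin_events)
}

#' First-passage times of the reduced chain (Monte-Carlo)
#'
#' Simulates the reduced birth-death chain from `start` until it first hits
#' `absorb`, `n_reps` times — the simulation benchmark for the quadrature
#' mean first-passage times of [mfpt_lower()] / [mfpt_upper()].
#'
#' @inheritParams chain_occupancy
#' @param start,absorb integer start and absorbing states (e.g. the rounded
#'   stable state and barrier).
#' @param n_reps number of replicates.
#' @param max_events per-replicate event budget before aborting.
#' @return numeric vector of `n_reps` first-passage times.
#' @export
chain_first_passage <- function(params, species = c("y2", "y3"), start,
                                absorb, n_reps = 1000, seed = 1,
                                cap = NULL, max_events = 1e9) {
  species <- match.arg(species)
  rs <- reduced_system(params, species)
  if (is.null(cap)) cap <- ceiling(2 * rs$y_max)
  birth <- rs$birth(0:cap)
  kdeath <- if (species == "y2") params$k5 else params$k8
  chain_first_passage_cpp(birth, kdeath, as.integer(start),
                          as.integer(absorb), as.integer(n_reps),
                          as.numeric(seed), max_events)
}
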