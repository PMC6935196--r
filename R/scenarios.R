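#' Canonical published parameter sets
#'
#' Named presets of the kinetic parameters used throughout the analyses:
#'
#' * `"MRN-baseline"` — mutual repression network without autoregulation
#'   (`k9 = k10 = 0`, `k4 = 61.23`).
#' * `"MRN-NA"` — MRN with negative autoregulation
#'   (`k9 = k10 = 4.1`, `K5 = K6 = 9`) at the shared `k4 = 61.23`.
#' * `"MRN-NA-calibrated"` — the MRN-NA with `k4 = 61.04`, the published
#'   steady-state-conserving tuning of k4 (the same tuning can be recomputed
#'   with [calibrate_match()]).
#'
#' All presets share `k1 = 100`, `k2 = 1`, `k3 = k6 = 18.1`, `k7 = 43.1`,
#' `k5 = k8 = 0.8`, `K1 = K3 = 9`, `K2 = K4 = 43`, `n = 8`.
#'
#' @param preset preset name (see above).
#' @return a [kinetic_params()] object.
#' @export
#' @examples
#' standard_params("MRN-NA-calibrated")$k4
standard_params <- function(preset = c("MRN-NA", "MRN-baseline",
                                       "MRN-NA-calibrated")) {
  if (!is.character(preset) || length(preset) != 1 ||
      !preset %in% c("MRN-NA", "MRN-baseline", "MRN-NA-calibrated"))
    stop("unknown preset; available: 'MRN-baseline', 'MRN-NA', ",
         "'MRN-NA-calibrated'")
  switch(preset,
    "MRN-baseline" = kinetic_params("MRN", k4 = 61.23, k9 = 0, k10 = 0),
    "MRN-NA" = kinetic_params("MRN_NA", k4 = 61.23),
    "MRN-NA-calibrated" = kinetic_params("MRN_NA", k4 = 61.04))
}

#' Canonical signal schedule
#'
#' The standard inductive protocol: amplitude-1 pulse applied from time 250
#' to 500 of a 1000-step simulation.
#'
#' @return a [signal_schedule()].
#' @export
default_schedule <- function() {
  signal_schedule(amplitude = 1, t_on = 250, t_off = 500, t_end = 1000)
}

#' Modify a parameter set
#'
#' Convenience wrapper returning a copy of `params` with the named fields
#' replaced (and `K2`/`K4` or `k9`/`k10` set jointly via the shorthands
#' `K` and `k9_k10`), then revalidated.
#'
#' @param params a [kinetic_params()] object.
#' @param ... fields to replace, e.g. `n = 3`, `K = 15` (sets K2 and K4),
#'   `k9_k10 = 2` (sets k9 and k10).
#' @return a new `kinetic_params` object.
#' @export
#' @examples
#' with_params(standard_params("MRN-baseline"), n = 3, K = 15)
with_params <- function(params, ...) {
  stopifnot(inherits(params, "kinetic_params"))
  upd <- list(...)
  if (!is.null(upd$K)) {
    upd$K2 <- upd$K4 <- upd$K
    upd$K <- NULL
  }
  if (!is.null(upd$k9_k10)) {
    upd$k9 <- upd$k10 <- upd$k9_k10
    upd$k9_k10 <- NULL
  }
  bad <- setdiff(names(upd), names(params))
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "))
  params[names(upd)] <- upd
  validate_params(params)
  params
}

#' Match the MRN-NA high steady state to the MRN's
#'
#' The MRN and MRN-NA are compared at conserved steady-state levels: one
#' kinetic parameter of the MRN-NA is tuned so that the upper stable steady
#' state of y2 (reduced system at S = 0) equals the MRN's. The low states
#' cannot be matched simultaneously; their residual mismatch is reported.
#'
#' @param mrn MRN reference parameter set.
#' @param mrnna MRN-NA parameter set to adjust.
#' @param knob which parameter to tune: `"k4"` (default), `"k7"`, or
#'   `"k9_k10"` (joint autoregulation strength).
#' @param bracket search interval for the knob.
#' @param tol relative tolerance on the matched high state.
#' @return the adjusted `kinetic_params`, with attributes `knob_value` (the
#'   tuned value) and `low_state_mismatch` (relative difference of the lower
#'   stable y2 states after matching).
#' @export
calibrate_match <- function(mrn, mrnna, knob = c("k4", "k7", "k9_k10"),
                            bracket = NULL, tol = 1e-6) {
  knob <- match.arg(knob)
  stopifnot(mrn$variant == "MRN", mrnna$variant == "MRN_NA")
  target <- fixed_points(mrn, "y2")$y_u
  if (is.null(bracket)) {
    bracket <- switch(knob,
      k4 = c(0.9 * mrn$k4, 1.01 * mrn$k4),
      k7 = c(0.9 * mrn$k7, 1.5 * mrn$k7),
      k9_k10 = c(0, 20))
  }
  upper_of <- function(v) {
    fixed_points(set_knob(mrnna, knob, v), "y2")$y_u
  }
  f <- function(v) upper_of(v) - target
  r <- stats::uniroot(f, interval = bracket, tol = tol * target)
  out <- set_knob(mrnna, knob, r$root)
  fp <- fixed_points(out, "y2")
  fp_mrn <- fixed_points(mrn, "y2")
  if (abs(fp$y_u - target) / target > 1e-3)
    stop("calibration failed to match the high steady state")
  attr(out, "knob_value") <- r$root
  attr(out, "low_state_mismatch") <-
    abs(fp$y_l - fp_mrn$y_l) / max(fp_mrn$y_l, .Machine$double.eps)
  out
}

set_knob <- function(params, knob, value) {
  if (knob == "k9_k10") with_params(params, k9_k10 = value)
  else do.call(with_params, c(list(params), stats::setNames(list(value), knob)))
}

#' Randomly perturbed parameter scenarios
#'
#' Generates test scenarios by applying independent log-normal multiplicative
#' jitter with relative standard deviation `rel_sd` to every nonzero rate and
#' dissociation constant of `base` (the Hill coefficient is kept fixed at its
#' integer value). Deterministic given `seed`.
#'
#' @param base a [kinetic_params()] object.
#' @param n_scenarios number of scenarios to draw.
#' @param rel_sd relative standard deviation of the jitter (0.05 keeps the
#'   canonical sets almost always inside their bistable regime).
#' @param seed integer seed.
#' @param schedule signal schedule attached to each scenario.
#' @return a list of scenario bundles, each a list with elements `params`,
#'   `schedule`, `seed` and `label`.
#' @export
perturbed_scenarios <- function(base, n_scenarios = 50, rel_sd = 0.05,
                                seed = 1, schedule = default_schedule()) {
  stopifnot(n_scenarios >= 1, rel_sd >= 0)
  fields <- c(paste0("k", 1:10), paste0("K", 1:6))
  sdlog <- sqrt(log(1 + rel_sd^2))
  out <- with_preserved_seed(seed, {
    lapply(seq_len(n_scenarios), function(i) {
      p <- base
      fac <- exp(stats::rnorm(length(fields)) * sdlog)
      for (j in seq_along(fields)) {
        f <- fields[[j]]
        if (p[[f]] > 0) p[[f]] <- p[[f]] * fac[[j]]
      }
      validate_params(p)
      list(params = p, schedule = schedule, seed = seed + i - 1L,
           label = sprintf("%s-perturbed-%03d (rel_sd=%g)",
                           base$variant, i, rel_sd))
    })
  })
  out
}

# Evaluate expr under set.seed(seed) without clobbering the caller's RNG
# stream.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Serialize a parameter set (plus optional schedule) to a config file
#'
#' Flat key-value YAML with keys `k1..k10`, `K1..K6`, `n`, `variant`, and,
#' when a schedule is given, `S`, `t_on`, `t_off`, `t_end`.
#'
#' @param params a [kinetic_params()] object.
#' @param file path to write; if `NULL`, returns the YAML text.
#' @param schedule optional [signal_schedule()].
#' @return the file path (or YAML string), invisibly.
#' @export
write_params_config <- function(params, file = NULL, schedule = NULL) {
  x <- unclass(params)
  if (!is.null(schedule)) {
    x$S <- schedule$amplitude
    x$t_on <- schedule$t_on
    x$t_off <- schedule$t_off
    x$t_end <- schedule$t_end
  }
  txt <- yaml::as.yaml(x)
  if (is.null(file)) return(invisible(txt))
  writeLines(txt, file)
  invisible(file)
}

#' Read a parameter config file
#'
#' @param file path to a YAML config written by [write_params_config()] (or
#'   YAML text).
#' @return a list with elements `params` ([kinetic_params()]) and `schedule`
#'   ([signal_schedule()] or `NULL` if the file has no schedule keys).
#' @export
read_params_config <- function(file) {
  x <- if (file.exists(file)) yaml::read_yaml(file) else yaml::yaml.load(file)
  pargs <- x[intersect(names(x), c("variant", paste0("k", 1:10),
                                   paste0("K", 1:6), "n"))]
  params <- do.call(kinetic_params, pargs)
  schedule <- NULL
  if (all(c("S", "t_on", "t_off", "t_end") %in% names(x)))
    schedule <- signal_schedule(x$S, x$t_on, x$t_off, x$t_end)
  list(params = params, schedule = schedule)
}
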