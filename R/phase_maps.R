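#' Default dissociation-constant sweep grid
#'
#' The K values (applied jointly to K2 = K4) used by the sweep pipelines;
#' includes every value the canonical analyses name (12, 15, 43).
#' @return numeric vector.
#' @export
default_K_grid <- function() c(5, 10, 12, 15, 20, 25, 30, 35, 40, 43, 45, 50)

sweep_cell_params <- function(variant, n, K) {
  base <- if (variant == "MRN") standard_params("MRN-baseline")
          else standard_params("MRN-NA")
  with_params(base, n = n, K = K)
}

#' Memory region over the (n, K) plane
#'
#' Evaluates the memory verdict — deterministic ([deterministic_memory()])
#' or stochastic ([stochastic_memory()], 20 replicates / 18 passing per cell
#' by default — on every cell of an (n, K2 = K4) grid for one network
#' variant under the canonical pulse schedule. Stochastic cells use seeds
#' derived from the master seed and the cell index, so the sweep is
#' reproducible and independent of evaluation order.
#'
#' @param variant `"MRN"` or `"MRN_NA"`.
#' @param n_values integer Hill-coefficient grid.
#' @param K_values dissociation-constant grid (K2 = K4 jointly).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param schedule the pulse protocol.
#' @param seed master seed (stochastic mode).
#' @param n_reps,pass_count stochastic criterion (defaults 20 and 18).
#' @return a `phase_diagram`: list with `n_values`, `K_values`, logical
#'   matrix `verdicts` (rows = n, columns = K), `mode`, `variant`, and
#'   `min_n` (smallest n with any positive cell, `NA` if none).
#' @export
memory_region <- function(variant = c("MRN_NA", "MRN"),
                          n_values = 2:6, K_values = default_K_grid(),
                          mode = c("deterministic", "stochastic"),
                          schedule = default_schedule(), seed = 1,
                          n_reps = 20, pass_count = 18) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  verdict <- matrix(FALSE, length(n_values), length(K_values),
                    dimnames = list(paste0("n", n_values),
                                    paste0("K", K_values)))
  for (i in seq_along(n_values)) {
    for (j in seq_along(K_values)) {
      p <- sweep_cell_params(variant, n_values[i], K_values[j])
      verdict[i, j] <- if (mode == "deterministic") {
        deterministic_memory(p, schedule)$has_memory
      } else {
        cell_seed <- seed + ((i - 1) * length(K_values) + (j - 1)) * n_reps
        stochastic_memory(p, schedule, n_reps = n_reps,
                          pass_count = pass_count,
                          seed = cell_seed)$has_memory
      }
    }
  }
  new_phase_diagram(n_values, K_values, verdict, mode, variant)
}

#' Bistable region of the reduced systems over the (n, K) plane
#'
#' Per-cell double-well test ([is_bistable()]) of the quasi-steady-state
#' reduced system of one species.
#'
#' @inheritParams memory_region
#' @param species `"y2"` or `"y3"`.
#' @return a `phase_diagram` with mode `"bistable_y2"` or `"bistable_y3"`.
#' @export
bistable_region <- function(variant = c("MRN_NA", "MRN"),
                            species = c("y2", "y3"),
                            n_values = 1:6, K_values = default_K_grid()) {
  variant <- match.arg(variant)
  species <- match.arg(species)
  verdict <- matrix(FALSE, length(n_values), length(K_values),
                    dimnames = list(paste0("n", n_values),
                                    paste0("K", K_values)))
  for (i in seq_along(n_values))
    for (j in seq_along(K_values))
      verdict[i, j] <- is_bistable(
        sweep_cell_params(variant, n_values[i], K_values[j]), species)
  new_phase_diagram(n_values, K_values, verdict,
                    paste0("bistable_", species), variant)
}

new_phase_diagram <- function(n_values, K_values, verdicts, mode, variant) {
  pos <- apply(verdicts, 1, any)
  structure(list(n_values = n_values, K_values = K_values,
                 verdicts = verdicts, mode = mode, variant = variant,
                 min_n = if (any(pos)) min(n_values[pos]) else NA_integer_,
                 cell_count = sum(verdicts)),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("<phase_diagram %s/%s: %d of %d cells positive, min n = %s>\n",
              x$variant, x$mode, x$cell_count, length(x$verdicts),
              if (is.na(x$min_n)) "none" else x$min_n))
  print(x$verdicts)
  invisible(x)
}

#' Mean first-passage time sweep curves
#'
#' Reproduces the three canonical first-passage sweeps as a long table:
#' over the Hill coefficient `n` at K2 = K4 = 15; over K2 = K4 at n = 3; and
#' over the autoregulation strength k9 = k10 (MRN-NA only) at K = 15, n = 3.
#' Each row holds `T_L` and `T_U` (and their log10) for one model, species
#' and swept value.
#'
#' @param sweep `"n"`, `"K"`, or `"k9"`.
#' @param values swept values; defaults are `2:5` for n, `c(10, 12, 15, 20,
#'   25)` for K, and `c(0, 1, 2, 4.1, 6, 8)` for k9 = k10.
#' @param n_grid quadrature resolution per cell.
#' @return data.frame with columns `sweep`, `value`, `variant`, `species`,
#'   `T_L`, `T_U`, `log10_T_L`, `log10_T_U`.
#' @export
mfpt_curves <- function(sweep = c("n", "K", "k9"), values = NULL,
                        n_grid = 4000) {
  sweep <- match.arg(sweep)
  if (is.null(values))
    values <- switch(sweep, n = 2:5, K = c(10, 12, 15, 20, 25),
                     k9 = c(0, 1, 2, 4.1, 6, 8))
  variants <- if (sweep == "k9") "MRN_NA" else c("MRN", "MRN_NA")
  rows <- list()
  for (v in values) {
    for (variant in variants) {
      base <- if (variant == "MRN") standard_params("MRN-baseline")
              else standard_params("MRN-NA")
      p <- switch(sweep,
        n = with_params(base, n = v, K = 15),
        K = with_params(base, n = 3, K = v),
        k9 = with_params(base, n = 3, K = 15, k9_k10 = v))
      for (sp in c("y2", "y3")) {
        q <- mfpt(p, sp, n_grid = n_grid)
        rows[[length(rows) + 1]] <- data.frame(
          sweep = sweep, value = v, variant = variant, species = sp,
          T_L = q$T_L, T_U = q$T_U,
          log10_T_L = q$log10_T_L, log10_T_U = q$log10_T_U)
      }
    }
  }
  do.call(rbind, rows)
}

#' Noise comparison between the MRN and the calibrated MRN-NA
#'
#' For each dissociation constant, simulates replicate stochastic
#' trajectories of the MRN and of the MRN-NA (with its k4 re-tuned per K so
#' the high y2 steady state matches the MRN's, see [calibrate_match()]),
#' and reports the replicate-mean coefficients of variation of y2 and y3 in
#' the requested window.
#'
#' @param K_values dissociation constants K2 = K4 to compare at.
#' @param window `"signal"` (time 270-500) or `"post"` (500-750).
#' @param n_reps replicates per model and K.
#' @param seed master seed.
#' @param n Hill coefficient (canonical comparison uses 8).
#' @param schedule pulse protocol.
#' @return data.frame with columns `K`, `variant`, `cv_y2`, `cv_y3`.
#' @export
cv_comparison <- function(K_values = c(35, 43, 50),
                          window = c("signal", "post"), n_reps = 10,
                          seed = 1, n = 8, schedule = default_schedule()) {
  window <- match.arg(window)
  win <- if (window == "signal") c(270, 500) else c(500, 750)
  rows <- list()
  idx <- 0
  for (K in K_values) {
    mrn <- with_params(standard_params("MRN-baseline"), n = n, K = K)
    mrnna <- calibrate_match(
      mrn, with_params(standard_params("MRN-NA"), n = n, K = K),
      knob = "k4")
    for (p in list(mrn, mrnna)) {
      th <- memory_thresholds(p, schedule)
      init <- round(th$off_state)
      cvs <- vapply(seq_len(n_reps), function(r) {
        tr <- ssa_run(p, schedule, init = init,
                      seed = seed + idx * n_reps + r - 1)
        cv <- coefficient_of_variation(tr, win)
        c(cv$cv_y2, cv$cv_y3)
      }, numeric(2))
      idx <- idx + 1
      rows[[length(rows) + 1]] <- data.frame(
        K = K, variant = p$variant, window = window,
        cv_y2 = mean(cvs[1, ]), cv_y3 = mean(cvs[2, ]))
    }
  }
  do.call(rbind, rows)
}

#' Stationary-density panels across parameter values
#'
#' Families of Fokker-Planck stationary densities of one species on a
#' shared grid, across network variants and a sweep of either the Hill
#' coefficient or the dissociation constant; optionally with pooled SSA
#' occupancy histograms of the full system attached for validation.
#'
#' @param variants character vector of `"MRN"`, `"MRN_NA"`.
#' @param species `"y2"` or `"y3"`.
#' @param n_values Hill coefficients to sweep (at fixed `K`), or `NULL`.
#' @param K_values dissociation constants to sweep (at fixed `n`), or
#'   `NULL`; exactly one of `n_values` / `K_values` must be given.
#' @param K,n the fixed value of the non-swept parameter.
#' @param ssa_attach if `TRUE`, attach a pooled occupancy histogram from
#'   `ssa_reps` full-system Gillespie runs (initial counts 1, signal off)
#'   per panel.
#' @param ssa_reps,ssa_t_end,seed SSA validation settings.
#' @return list of panels; each has `variant`, `label`, the swept `value`,
#'   and a [stationary_density()] (`density`), plus `ssa_pmf` when attached.
#' @export
density_panels <- function(variants = c("MRN", "MRN_NA"),
                           species = c("y2", "y3"),
                           n_values = NULL, K_values = NULL,
                           K = 12, n = 3,
                           ssa_attach = FALSE, ssa_reps = 3,
                           ssa_t_end = 2000, seed = 1) {
  species <- match.arg(species)
  if (is.null(n_values) == is.null(K_values))
    stop("give exactly one of n_values or K_values")
  sweep_vals <- if (!is.null(n_values)) n_values else K_values
  panels <- list()
  for (variant in variants) {
    for (v in sweep_vals) {
      p <- if (!is.null(n_values)) sweep_cell_params(variant, v, K)
           else sweep_cell_params(variant, n, v)
      sd <- stationary_density(p, species)
      panel <- list(variant = variant, species = species,
                    value = v,
                    label = sprintf("%s %s=%g", variant,
                                    if (!is.null(n_values)) "n" else "K", v),
                    density = sd)
      if (ssa_attach) {
        sched <- signal_schedule(amplitude = 0, t_on = 0, t_off = 0,
                                 t_end = ssa_t_end)
        cap <- floor(max(sd$grid))
        counts <- numeric(cap + 1)
        for (r in seq_len(ssa_reps)) {
          tr <- ssa_run(p, sched, init = c(1, 1, 1),
                        seed = seed + length(panels) * ssa_reps + r - 1)
          lev <- pmin(tr[[species]][tr$times >= ssa_t_end / 4], cap)
          tb <- tabulate(lev + 1, nbins = cap + 1)
          counts <- counts + tb
        }
        panel$ssa_pmf <- counts / sum(counts)
      }
      panels[[length(panels) + 1]] <- panel
    }
  }
  panels
}

#' Upper-state probability mass of a stationary density
#'
#' Probability that the reduced process sits above the barrier: the
#' integral of the stationary density above `y_b` (or above the density's
#' interior minimum if a barrier is not supplied).
#'
#' @param sd a [stationary_density()].
#' @param y_b barrier position.
#' @return numeric in \[0, 1\].
#' @export
upper_state_mass <- function(sd, y_b) {
  sel <- sd$grid >= y_b
  trapz(sd$grid[sel], sd$density[sel])
}
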