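test_that("integration respects the closed-form y1 dynamics", {
  p <- na_base()
  # no signal ever: y1 stays at 0
  tr0 <- integrate_model(p, signal_schedule(0, 0, 0, 100), times = 0:100)
  expect_equal(max(abs(tr0$y1)), 0)
  # during a long pulse y1 relaxes to k1*S/k2 = 100 with rate k2 = 1
  tr <- integrate_model(p, default_schedule())
  y1_end <- tr$y1[tr$times == 500]
  expect_lt(abs(y1_end - 100) / 100, 1e-3)
  expect_true(all(tr$y1 >= 0 & tr$y2 >= 0 & tr$y3 >= 0))
})

test_that("steady states depend on the basin of the initial condition", {
  p <- na_base()
  expect_equal(unname(steady_state(p, S = 1)[1]), 100, tolerance = 1e-6)
  expect_equal(unname(steady_state(p, S = 0)[1]), 0, tolerance = 1e-6)
  off <- off_state(p)
  induced <- steady_state(p, S = 0, init = c(0, 100, 0))
  # the resting state is low-y2/high-y3; the induced attractor is the
  # mirror image, and both coexist at S = 0
  expect_lt(off["y2"], off["y3"])
  expect_gt(induced["y2"], induced["y3"])
  expect_gt(abs(induced["y2"] - off["y2"]), 50)
  expect_lt(max(abs(dydt(off, p, 0))), 1e-8)
  expect_lt(max(abs(dydt(induced, p, 0))), 1e-8)
})

test_that("steady levels are insensitive to halving the solver tolerances", {
  p <- na_base()
  sched <- default_schedule()
  a <- integrate_model(p, sched, init = off_state(p), rtol = 1e-8,
                       atol = 1e-10)
  b <- integrate_model(p, sched, init = off_state(p), rtol = 5e-9,
                       atol = 5e-11)
  k <- length(a$times)
  expect_lt(abs(a$y2[k] - b$y2[k]) / b$y2[k], 1e-4)
  expect_lt(abs(a$y3[k] - b$y3[k]) / b$y3[k], 1e-4)
})

test_that("the canonical pulse leaves persistent deterministic memory", {
  for (n in c(7, 8)) {
    p <- with_params(na_base(), n = n)
    v <- deterministic_memory(p)
    expect_true(v$has_memory)
  }
  # nothing to remember without a signal
  p8 <- na_base()
  v0 <- deterministic_memory(p8, signal_schedule(0, 250, 500, 1000))
  expect_false(v0$has_memory)
})

test_that("deterministic memory verdicts follow bistability across cells", {
  # strong binding sustains memory at low cooperativity; at the canonical
  # K = 43 the switch needs high cooperativity
  r_mrn <- memory_region("MRN", n_values = c(2, 3, 8), K_values = c(12, 43),
                         mode = "deterministic")
  expect_identical(unname(r_mrn$verdicts),
                   matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE), ncol = 2))
  # memory implies bistability of the signal-free system
  for (i in seq_along(r_mrn$n_values)) {
    for (j in seq_along(r_mrn$K_values)) {
      if (!r_mrn$verdicts[i, j]) next
      p <- with_params(mrn_base(), n = r_mrn$n_values[i],
                       K = r_mrn$K_values[j])
      off <- off_state(p)
      induced <- steady_state(p, S = 0, init = c(0, 100, 0))
      expect_gt(max(abs(induced - off)), 1)
    }
  }
})

test_that("hysteresis appears with cooperativity and vanishes without", {
  h8 <- hysteresis_scan(na_base(), S_values = seq(0, 1, by = 0.125))
  expect_true(any(h8$bistable_S))
  # both branches coincide at the top of the sweep
  m <- length(h8$S_values)
  expect_equal(h8$branch_up[m, ], h8$branch_down[m, ], tolerance = 1e-6)
  h1 <- hysteresis_scan(with_params(na_base(), n = 1),
                        S_values = seq(0, 1, by = 0.25))
  expect_false(any(h1$bistable_S))
})
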