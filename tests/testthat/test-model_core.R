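test_that("Hill activation and repression match their closed forms", {
  expect_equal(hill_activation(9, 9), 0.5)
  expect_equal(hill_activation(0, 9), 0)
  expect_equal(hill_activation(100, 9), 100 / 109)

  expect_equal(hill_repression(0, 43, 8), 1)
  expect_equal(hill_repression(43, 43, 8), 0.5)
  expect_equal(hill_repression(86, 43, 1), 1 / 3)

  expect_error(hill_activation(1, 0), "K")
  expect_error(hill_repression(-1, 9, 2), "y")
  expect_error(hill_repression(1, 9, 0.5), "n")
})

test_that("Hill repression is overflow-safe and complements activation", {
  # y^n far beyond double range must cleanly give 0
  expect_equal(hill_repression(1e300, 43, 12), 0)
  expect_false(is.nan(hill_repression(1e155, 10, 2)))

  y <- c(0, 0.3, 1, 9, 43, 77, 160, 1e4)
  for (n in c(1, 3, 8)) {
    act <- (y / 43)^n / (1 + (y / 43)^n)
    expect_equal(hill_repression(y, 43, n) + act, rep(1, length(y)),
                 tolerance = 1e-12)
  }
})

test_that("rate equations evaluate term-by-term at the origin", {
  # all Hill repressions are fully open at the origin, so the derivatives
  # are plain sums of synthesis constants
  expect_equal(dydt(c(0, 0, 0), na_cal(), S = 0), c(0, 65.14, 65.3))
  expect_equal(dydt(c(0, 0, 0), mrn_base(), S = 0), c(0, 61.23, 61.2))
  expect_equal(dydt(c(0, 0, 0), na_base(), S = 0), c(0, 65.33, 65.3))
})

test_that("y1 has its fixed point at k1*S/k2", {
  p <- na_base()
  for (S in c(0, 0.3, 1, 2)) {
    st <- c(p$k1 * S / p$k2, 20, 20)
    expect_equal(dydt(st, p, S)[1], 0)
  }
})

test_that("propensities are the birth-death decomposition of the rates", {
  p <- na_base()
  pr0 <- propensities(c(0, 0, 0), p, S = 0)
  expect_equal(unname(pr0[c("y1_birth", "y1_death", "y2_death", "y3_death")]),
               c(0, 0, 0, 0))
  pr <- propensities(c(100, 0, 0), p, S = 1)
  expect_equal(unname(pr[["y1_birth"]]), 100)
  expect_equal(unname(pr[["y1_death"]]), 100)

  states <- random_states(1000, seed = 42)
  for (params in list(mrn_base(), na_base())) {
    for (i in seq_len(nrow(states))) {
      pr <- propensities(states[i, ], params, S = 0.5)
      expect_true(all(pr >= 0))
      net <- pr[c(1, 3, 5)] - pr[c(2, 4, 6)]
      expect_equal(unname(net), dydt(states[i, ], params, S = 0.5),
                   tolerance = 1e-12)
    }
  }
})

test_that("the MRN is the MRN-NA with the autoregulation channels removed", {
  na <- na_base()
  mrn_like <- with_params(na, k9 = 0, k10 = 0)
  mrn <- mrn_base()
  states <- random_states(50, seed = 7)
  for (i in seq_len(nrow(states))) {
    expect_identical(dydt(states[i, ], mrn_like, S = 0.7),
                     dydt(states[i, ], mrn, S = 0.7))
  }
})

test_that("parameter validation enforces the model invariants", {
  expect_error(kinetic_params("MRN", k9 = 1), "k9")
  expect_error(with_params(na_base(), K2 = 0), "dissociation")
  expect_error(with_params(na_base(), k4 = -1), "rate")
  expect_error(with_params(na_base(), n = 0.5), "Hill")
  expect_error(with_params(na_base(), bogus = 1), "unknown")
  # signal schedule ordering
  expect_error(signal_schedule(1, t_on = 300, t_off = 200))
  expect_equal(signal_at(default_schedule(), c(100, 250, 499, 500, 900)),
               c(0, 1, 1, 0, 0))
})
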