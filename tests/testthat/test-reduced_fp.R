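# local copy of the trapezoid rule so the normalization check does not rely
# on the same helper the implementation uses
trapz_oracle <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# direct root-find on the partner's full balance equation, used as the
# independent oracle for the closed-form quasi-steady-state expressions
qss_oracle <- function(y, params, species) {
  p <- params
  bal <- if (species == "y2") {
    function(x) p$k6 * p$K3 / (y + p$K3) +
      p$k7 * hill_repression(y, p$K4, p$n) +
      p$k10 * p$K6 / (x + p$K6) - p$k8 * x
  } else {
    function(x) p$k4 * hill_repression(y, p$K2, p$n) +
      p$k9 * p$K5 / (x + p$K5) - p$k5 * x
  }
  stats::uniroot(bal, c(0, 500), tol = 1e-12)$root
}

test_that("closed-form partner levels solve the partner's balance equation", {
  for (params in list(mrn_base(), na_base(), na_n3K15())) {
    for (species in c("y2", "y3")) {
      for (y in c(0, 1, 5, 20, 43, 77, 120, 200)) {
        expect_equal(qss_partner(y, params, species),
                     qss_oracle(y, params, species), tolerance = 1e-8)
      }
    }
  }
  # at a silent focal species the partner runs at full synthesis
  p <- mrn_base()
  expect_equal(qss_partner(0, p, "y2"), (p$k6 + p$k7) / p$k8)
  expect_error(qss_partner(-1, p, "y2"), "y")
})

test_that("drift and noise have the birth-death structure", {
  for (params in list(mrn_base(), na_base())) {
    for (species in c("y2", "y3")) {
      rs <- reduced_system(params, species)
      y <- seq(0, rs$y_max, length.out = 200)
      A <- rs$drift(y); B <- rs$noise(y)
      expect_gt(A[1], 0)                  # pure synthesis at y = 0
      expect_equal(B[1], A[1])            # no deaths at y = 0
      expect_true(all(B >= abs(A) - 1e-12))
      expect_true(all(B > 0))
      expect_lt(rs$drift(rs$y_max), 0)    # degradation dominates far out
    }
  }
  # at a fixed point births equal deaths, so B = 2 * death
  fp <- fixed_points(na_base(), "y2")
  rs <- reduced_system(na_base(), "y2")
  expect_equal(rs$noise(fp$y_u), 2 * na_base()$k5 * fp$y_u,
               tolerance = 1e-6)
})

test_that("MRN reduced functions equal the MRN-NA's with k9 = k10 = 0", {
  na0 <- with_params(na_base(), k9 = 0, k10 = 0)
  y <- seq(0, 150, by = 0.5)
  for (species in c("y2", "y3")) {
    expect_identical(reduced_drift(y, na0, species),
                     reduced_drift(y, mrn_base(), species))
    expect_identical(reduced_noise(y, na0, species),
                     reduced_noise(y, mrn_base(), species))
  }
})

test_that("fully symmetric parameters make the two reductions identical", {
  # the y1-facing channels must be silenced (k3 = k6 = 0) for the two
  # species to play interchangeable roles at S = 0
  p <- kinetic_params("MRN_NA", k3 = 0, k4 = 50, k6 = 0, k7 = 50,
                      k9 = 3, k10 = 3, K1 = 9, K3 = 9, K2 = 20, K4 = 20,
                      K5 = 7, K6 = 7, k5 = 0.8, k8 = 0.8, n = 4)
  y <- seq(0, 90, by = 0.5)
  expect_equal(reduced_drift(y, p, "y2"), reduced_drift(y, p, "y3"),
               tolerance = 1e-12)
  expect_equal(reduced_noise(y, p, "y2"), reduced_noise(y, p, "y3"),
               tolerance = 1e-12)
})

test_that("fixed points are located, ordered and classified", {
  fp1 <- fixed_points(with_params(na_base(), n = 1), "y2")
  expect_true(fp1$monostable)
  for (species in c("y2", "y3")) {
    fp <- fixed_points(na_base(), species)
    expect_length(fp$roots, 3)
    expect_true(fp$y_l < fp$y_b && fp$y_b < fp$y_u)
    rs <- reduced_system(na_base(), species)
    expect_true(all(abs(rs$drift(fp$roots)) < 1e-6))
    expect_identical(fp$stable, c(TRUE, FALSE, TRUE))
  }
})

test_that("the stationary density is normalized with modes where theory puts them", {
  for (params in list(na_base(), na_n3K15())) {
    for (species in c("y2", "y3")) {
      sd1 <- stationary_density(params, species)
      expect_equal(trapz_oracle(sd1$grid, sd1$density), 1, tolerance = 1e-6)
      expect_true(all(sd1$density >= 0))
      # modes of P_st solve 2A(y) = B'(y)
      rs <- reduced_system(params, species)
      g <- sd1$grid
      h <- diff(g[1:2])
      Bp <- c(NA, (rs$noise(g[-(1:2)]) - rs$noise(g[1:(length(g) - 2)])) /
                (2 * h), NA)
      cond <- 2 * rs$drift(g) - Bp
      sign_flips <- which(diff(sign(cond[-1])) != 0) + 1
      modes <- which(diff(sign(diff(sd1$density))) < 0) + 1
      modes <- modes[sd1$density[modes] > 1e-10 * max(sd1$density)]
      for (m in modes) expect_lt(min(abs(m - sign_flips)), 3)
    }
  }
  expect_error(stationary_density(na_base(), "y2", grid = seq(0, 10, 1)),
               "grid")
})

test_that("the density is bimodal exactly where the drift has three roots", {
  expect_false(is_bistable(with_params(na_base(), n = 1), "y2"))
  expect_true(is_bistable(na_n3K15(), "y2"))
  expect_true(is_bistable(na_n3K15(), "y3"))
  expect_true(is_bistable(na_base(), "y2"))
  expect_true(is_bistable(na_base(), "y3"))
  # stochastic bistability (double-well potential) is at least as strict as
  # the deterministic root count: a double well never appears without three
  # drift roots
  for (n in c(1, 2, 4, 8)) {
    for (K in c(10, 15, 43)) {
      p <- with_params(mrn_base(), n = n, K = K)
      if (is_bistable(p, "y3"))
        expect_length(fixed_points(p, "y3")$roots, 3)
      if (length(fixed_points(p, "y3")$roots) < 3)
        expect_false(is_bistable(p, "y3"))
    }
  }
})

test_that("the Fokker-Planck density approximates the exact chain law", {
  for (params in list(mrn_base(), na_base())) {
    for (species in c("y2", "y3")) {
      sd1 <- stationary_density(params, species)
      exact <- birth_death_stationary(params, species)
      expect_lt(tv_distance(density_to_pmf(sd1), exact), 0.05)
    }
  }
})
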