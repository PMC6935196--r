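test_that("bistable regions have the expected low-n structure", {
  r <- bistable_region("MRN_NA", "y3", n_values = 1:3,
                       K_values = c(10, 12, 15, 43))
  expect_identical(dim(r$verdicts), c(3L, 4L))
  expect_false(any(r$verdicts[1, ]))          # no bistability without
                                              # cooperativity
  expect_true(any(r$verdicts[3, ]))           # strong binding rescues n = 3
  expect_false(r$verdicts["n3", "K43"])       # weak binding does not
  expect_identical(r$min_n, min(r$n_values[apply(r$verdicts, 1, any)]))
})

test_that("stochastic sweeps are reproducible and seed-independent per cell", {
  a <- memory_region("MRN_NA", n_values = 8, K_values = 43,
                     mode = "stochastic", seed = 31, n_reps = 5,
                     pass_count = 4)
  b <- memory_region("MRN_NA", n_values = 8, K_values = 43,
                     mode = "stochastic", seed = 31, n_reps = 5,
                     pass_count = 4)
  expect_identical(a$verdicts, b$verdicts)
  expect_true(a$verdicts[1, 1])
})

test_that("the stochastic memory region is monotone in the pass criterion", {
  strict <- memory_region("MRN_NA", n_values = c(7, 8), K_values = 43,
                          mode = "stochastic", seed = 13, n_reps = 6,
                          pass_count = 6)
  lax <- memory_region("MRN_NA", n_values = c(7, 8), K_values = 43,
                       mode = "stochastic", seed = 13, n_reps = 6,
                       pass_count = 3)
  expect_true(all(lax$verdicts | !strict$verdicts))
})

test_that("first-passage sweep tables cover the requested grid", {
  tab <- mfpt_curves("n", values = 2:3, n_grid = 2000)
  expect_identical(nrow(tab), 2L * 2L * 2L)   # values x variants x species
  expect_setequal(unique(tab$variant), c("MRN", "MRN_NA"))
  # residence times lengthen with cooperativity for every model and basin
  for (v in c("MRN", "MRN_NA")) {
    for (sp in c("y2", "y3")) {
      sub <- tab[tab$variant == v & tab$species == sp, ]
      sub <- sub[order(sub$value), ]
      expect_true(all(diff(sub$log10_T_L) > 0))
      expect_true(all(diff(sub$log10_T_U) > 0))
    }
  }
  # the autoregulation sweep only applies to the MRN-NA
  tab9 <- mfpt_curves("k9", values = c(0, 4.1), n_grid = 2000)
  expect_setequal(unique(tab9$variant), "MRN_NA")
})

test_that("autoregulation suppresses intrinsic noise in the repressed species", {
  tab <- cv_comparison(K_values = c(43, 50), window = "signal", n_reps = 6,
                       seed = 19)
  for (K in c(43, 50)) {
    mrn <- tab[tab$K == K & tab$variant == "MRN", ]
    na <- tab[tab$K == K & tab$variant == "MRN_NA", ]
    # the species held low by the signal carries the noise, and the
    # autoregulation cuts it roughly in half
    expect_lt(na$cv_y3, 0.7 * mrn$cv_y3)
    expect_gt(mrn$cv_y3, mrn$cv_y2)
    expect_gt(na$cv_y3, na$cv_y2)
  }
})

test_that("density panels integrate to one and show the autoregulation shift", {
  pans <- density_panels(c("MRN", "MRN_NA"), "y2", n_values = c(3, 4),
                         K = 12)
  expect_length(pans, 4)
  for (pp in pans) {
    g <- pp$density$grid; d <- pp$density$density
    expect_equal(sum(diff(g) * (d[-length(d)] + d[-1]) / 2), 1,
                 tolerance = 1e-6)
  }
  # negative autoregulation makes the induced (upper) y2 state more
  # dominant at matched cooperativity
  mass <- vapply(pans, function(pp) {
    fp <- fixed_points(with_params(
      if (pp$variant == "MRN") mrn_base() else na_base(),
      n = pp$value, K = 12), "y2")
    upper_state_mass(pp$density, fp$y_b)
  }, numeric(1))
  expect_gt(mass[3], mass[1])   # n = 3
  expect_gt(mass[4], mass[2])   # n = 4
})

test_that("the reduced theory matches full-system simulation where the QSS holds", {
  # y3-side validation at the canonical parameters: pooled occupancy of
  # three long signal-free runs against the Fokker-Planck density
  pan <- density_panels("MRN_NA", "y3", n_values = 8, K = 43,
                        ssa_attach = TRUE, ssa_reps = 3, ssa_t_end = 4000,
                        seed = 23)[[1]]
  tv <- tv_distance(density_to_pmf(pan$density,
                                   y_max = length(pan$ssa_pmf) - 1),
                    pan$ssa_pmf)
  expect_lt(tv, 0.1)
})
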