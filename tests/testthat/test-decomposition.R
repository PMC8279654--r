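test_that("constant energies across windows give identically zero profiles", {
  wins <- lapply(c(1.0, 1.5, 2.0), function(r)
    energy_window(r, 500, means = c(3, -2, 1), noise = 0, seed = 1))
  comp <- enthalpy_components_profile(wins, 1.0)
  expect_equal(comp$dH, rep(0, 3))
  expect_equal(comp$dE_ww, rep(0, 3))
  prof <- enthalpy_profile(wins, 1.0)
  expect_equal(prof$dH, rep(0, 3))
})

test_that("the reference window compared to itself is exactly zero", {
  wins <- list(energy_window(1.0, 1000, c(5, 5, 5), noise = 2, seed = 2),
               energy_window(2.0, 1000, c(-10, 8, -1), noise = 2, seed = 3))
  comp <- enthalpy_components_profile(wins, 1.0)
  ref <- comp[comp$r == 1.0, ]
  expect_identical(ref$dH, 0)
  expect_identical(ref$dE_ww, 0)
  expect_identical(ref$se_dH, 0)
  expect_error(enthalpy_components_profile(wins, 5.0), "half a window")
})

test_that("components sum to the enthalpy exactly on every window", {
  set.seed(4)
  wins <- lapply(seq(1, 2, by = 0.25), function(r)
    energy_window(r, 2000, means = rnorm(3, 0, 10), noise = 5,
                  seed = round(r * 100)))
  comp <- enthalpy_components_profile(wins, 1.0)
  expect_lt(max(abs(comp$dE_ww + comp$dE_aaw + comp$dE_aaaa - comp$dH)),
            1e-9)
})

test_that("missing energies are an input error", {
  w <- gaussian_window(1.0, 500, 100, seed = 5)
  expect_error(enthalpy_profile(list(w), 1.0), "no per-frame energies")
})

test_that("entropy is the PMF minus the enthalpy, pinned at the reference", {
  set.seed(6)
  pmf <- set_reference(boltzmann_invert(runif(2e4, 0.9, 2.2), 26), 1.0)
  # dH equal to the interpolated dG makes -TdS vanish identically
  r <- c(1.2, 1.6, 2.0)
  dg <- approx(pmf$centers[pmf$defined], pmf$values[pmf$defined],
               xout = r)$y
  ent <- entropy_profile(pmf, data.frame(r = r, dH = dg))
  expect_equal(ent$minus_TdS, rep(0, 3), tolerance = 1e-12)
  # at the reference coordinate both terms vanish
  ent0 <- entropy_profile(pmf, data.frame(r = 1.0, dH = 0))
  expect_identical(ent0$minus_TdS, 0)
  expect_identical(ent0$dG, 0)
  # window centres outside the defined profile are a range error
  expect_error(entropy_profile(pmf, data.frame(r = 5, dH = 0)),
               "outside the defined PMF range")
  # an unreferenced PMF is refused
  expect_error(entropy_profile(boltzmann_invert(runif(100, 1, 2), 5),
                               data.frame(r = 1.5, dH = 0)),
               "referenced")
})

test_that("surface-minimum search respects region, ties and interiority", {
  bins <- seq(1, 3, length.out = 22)
  mk <- function(vals) {
    p <- boltzmann_invert(runif(1000, 1, 3), 21)
    p$values <- vals; p$defined <- !is.na(vals)
    p$counts <- ifelse(p$defined, 10, 0)
    p
  }
  # monotonically increasing: minimum flagged at the region's left edge
  p <- mk(seq(0, 2.1, length.out = 21))
  m <- find_surface_minimum(p, c(1.5, 2.5))
  expect_false(m$interior)
  expect_equal(m$r_min, min(p$centers[p$centers >= 1.5]))
  # two equal minima: the smaller r wins
  vals <- rep(1, 21); vals[c(8, 12)] <- -2
  m2 <- find_surface_minimum(mk(vals), c(1, 3))
  expect_equal(m2$bin_index, 8)
  # interior well is flagged interior
  vals <- (seq(1, 3, length.out = 21) - 2)^2
  expect_true(find_surface_minimum(mk(vals), c(1.5, 2.5))$interior)
  expect_error(find_surface_minimum(mk(rep(NA_real_, 21)), c(1, 3)),
               "no defined")
})

test_that("component recovery at the well matches ground truth within errors", {
  pot <- true_potential_params()
  dyn <- langevin_params()
  wins <- sample_windows(pot, dyn, c(1.0, 2.0), 1000, n_steps = 2e6,
                         master_seed = 70)
  comp <- enthalpy_components_profile(wins, 1.0)
  at_well <- comp[comp$r == 2.0, ]
  # conditional ground truth: amp * (mean S over the window's frames minus
  # mean S over the reference frames)
  s_well <- mean(true_enthalpy_components(wins[[2]]$samples, pot)$mean_ww) / pot$amp_ww
  s_ref <- mean(true_enthalpy_components(wins[[1]]$samples, pot)$mean_ww) / pot$amp_ww
  ds <- s_well - s_ref
  expect_lt(abs(at_well$dE_ww - pot$amp_ww * ds), 4 * at_well$se_ww)
  expect_lt(abs(at_well$dE_aaw - pot$amp_aaw * ds), 4 * at_well$se_aaw)
  expect_lt(abs(at_well$dE_aaaa - pot$amp_aaaa * ds), 4 * at_well$se_aaaa)
})

test_that("standard errors shrink like one over root n", {
  se_at <- function(n) {
    wins <- list(energy_window(1.0, n, c(0, 0, 0), noise = 5, seed = 8),
                 energy_window(2.0, n, c(-10, 5, -1), noise = 5, seed = 9))
    enthalpy_profile(wins, 1.0)$se_dH[2]
  }
  ratio <- se_at(4000) / se_at(8000)
  expect_equal(ratio, sqrt(2), tolerance = 0.2)
})

test_that("the decomposition record satisfies both identities", {
  pot <- true_potential_params()
  dyn <- langevin_params()
  wins <- sample_windows(pot, dyn, seq(1.0, 2.6, by = 0.2), 1000,
                         n_steps = 5e5, master_seed = 80)
  rng <- range(c(1.0, unlist(lapply(wins, `[[`, "samples"))))
  pmf <- set_reference(wham(wins, n_bins = 33, bin_range = rng), 1.0)
  rec <- decomposition_at_minimum(pmf, wins, 1.0, c(1.4, 2.6))
  expect_identical(rec$minus_TdS, rec$dG - rec$dH)
  expect_lt(abs(rec$dE_ww + rec$dE_aaw + rec$dE_aaaa - rec$dH), 1e-9)
  expect_true(rec$interior)
  expect_equal(rec$r_min, pot$well_center, tolerance = 0.11)
  # degenerate request: reference at the minimum makes everything zero
  flat_wins <- lapply(c(1.0, 1.2), function(r)
    energy_window(r, 500, c(0, 0, 0), noise = 0, seed = 10))
  p2 <- set_reference(boltzmann_invert(runif(5000, 0.9, 1.3), 8), 1.0)
  # force the minimum onto the reference bin
  p2$values[] <- abs(p2$centers - 1.0)
  rec2 <- decomposition_at_minimum(p2, flat_wins, 1.0,
                                   c(0.95, 1.25))
  expect_equal(rec2$dG, 0, tolerance = 1e-12)
  expect_identical(rec2$dH, 0)
  expect_identical(rec2$minus_TdS, rec2$dG - rec2$dH)
})
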