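test_that("zero-bias WHAM reduces to histogram inversion", {
  set.seed(31)
  w <- structure(list(center = 1.5, spring = 0,
                      samples = runif(1e5, 1, 2), label = "u"),
                 class = "umbrella_window")
  pmf <- wham(list(w), n_bins = 20, temperature = 300)
  pmf <- set_reference(pmf, 1.5)
  # flat profile: deviations bounded by the Poisson error of -kT ln(count)
  se <- kB * 300 / sqrt(pmf$counts)
  dev <- abs(pmf$values - mean(pmf$values))
  expect_true(all(dev < 3 * (se + kB * 300 / sqrt(mean(pmf$counts)))))
})

test_that("exact Gaussian windows on a flat landscape give a flat PMF", {
  wins <- list(gaussian_window(1.4, 500, 1e5, seed = 41),
               gaussian_window(1.5, 500, 1e5, seed = 42))
  # bin over the well-covered region between the two centres
  pmf <- wham(wins, n_bins = 20, temperature = 300,
              bin_range = c(1.3, 1.6))
  pmf <- set_reference(pmf, 1.45)
  expect_lt(sqrt(mean(pmf$values[pmf$defined]^2)), 0.2)
})

test_that("WHAM recovers the synthetic landscape from umbrella windows", {
  pot <- true_potential_params()
  dyn <- langevin_params()
  wins <- sample_windows(pot, dyn, seq(1.6, 2.6, by = 0.1), 1000,
                         n_steps = 2e6, master_seed = 50,
                         with_energies = FALSE)
  pmf <- set_reference(wham(wins, n_bins = 25, temperature = 300), 1.65)
  ref_bin <- which.min(abs(pmf$centers - 1.65))
  truth <- true_pmf(pmf$centers, pot) - true_pmf(pmf$centers[ref_bin], pot)
  ok <- pmf$defined & pmf$counts > 500
  expect_lt(sqrt(mean((pmf$values[ok] - truth[ok])^2)), 0.5)
})

test_that("referencing is exact, idempotent and guarded", {
  set.seed(33)
  pmf <- boltzmann_invert(rnorm(5000, 2, 0.2), n_bins = 15)
  p1 <- set_reference(pmf, 2.0)
  bin <- which(p1$bin_edges[-1] >= 2.0 & p1$bin_edges[-16] <= 2.0)[1]
  expect_identical(p1$values[bin], 0)
  p2 <- set_reference(p1, 2.0)
  expect_equal(p2$values, p1$values)
  expect_error(set_reference(pmf, 10), "outside")
})

test_that("WHAM equals Boltzmann inversion on a single unbiased window", {
  set.seed(34)
  samples <- runif(5e4, 1, 2)
  w <- structure(list(center = 1.5, spring = 0, samples = samples,
                      label = "u"), class = "umbrella_window")
  a <- set_reference(wham(list(w), n_bins = 41), 1.5)
  b <- set_reference(boltzmann_invert(samples, n_bins = 41), 1.5)
  expect_identical(a$defined, b$defined)
  expect_lt(max(abs(a$values[a$defined] - b$values[b$defined])), 1e-10)
})

test_that("the profile is invariant under window reordering", {
  pot <- true_potential_params()
  dyn <- langevin_params()
  wins <- sample_windows(pot, dyn, seq(1.8, 2.2, by = 0.1), 1000,
                         n_steps = 5e5, master_seed = 60,
                         with_energies = FALSE)
  rng <- range(unlist(lapply(wins, `[[`, "samples")))
  a <- wham(wins, n_bins = 21, tol = 1e-8, bin_range = rng)
  b <- wham(rev(wins), n_bins = 21, tol = 1e-8, bin_range = rng)
  a <- set_reference(a, 2.0); b <- set_reference(b, 2.0)
  expect_lt(max(abs(a$values[a$defined] - b$values[b$defined])), 1e-6)
})

test_that("the convergence residual is monotone over the final iterations", {
  pot <- true_potential_params()
  dyn <- langevin_params()
  wins <- sample_windows(pot, dyn, seq(1.8, 2.2, by = 0.1), 1000,
                         n_steps = 5e5, master_seed = 61,
                         with_energies = FALSE)
  pmf <- wham(wins, n_bins = 21)
  hist <- tail(pmf$residual_history, 10)
  expect_true(all(diff(hist) <= 1e-12))
  expect_lt(pmf$residual, 1e-6)
})

test_that("degenerate and broken inputs are diagnosed", {
  # all samples in one bin: that bin is zero after referencing, rest undefined
  pmf <- boltzmann_invert(rep(1.5, 100), n_bins = 5, bin_range = c(1, 2))
  expect_equal(sum(pmf$defined), 1)
  pmf <- set_reference(pmf, 1.5)
  expect_identical(pmf$values[pmf$defined], 0)
  expect_error(set_reference(pmf, 1.1), "undefined")

  # a window with no samples in the binning range is named
  w1 <- gaussian_window(1.5, 500, 1000, seed = 1)
  w2 <- gaussian_window(5.0, 500, 1000, seed = 2)
  expect_error(wham(list(w1, w2), n_bins = 10, bin_range = c(1.2, 1.8)),
               "g5.00")

  # non-convergence carries the residual
  expect_error(wham(list(gaussian_window(1.4, 500, 5e4, seed = 3),
                         gaussian_window(1.6, 500, 5e4, seed = 4)),
                    n_bins = 30, max_iter = 2),
               "did not converge")
})
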