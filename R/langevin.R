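#' Parameters of the overdamped Langevin sampler
#'
#' Configures the Brownian-dynamics (Euler-Maruyama) integrator used to draw
#' biased and unbiased samples of the reaction coordinate. Only the
#' stationary (Boltzmann) distribution matters for PMF reconstruction, so an
#' overdamped integrator is sufficient; the diffusion coefficient and time
#' step set the sampling time scale, not the thermodynamics.
#'
#' If `potential` is supplied, the constructor scans a grid over the domain
#' and asserts the drift-step stability invariant
#' `D * dt * |G'(r)| / kT < 0.1` everywhere, rejecting configurations whose
#' deterministic displacement per step is too large for faithful sampling.
#'
#' @param temperature temperature, K (> 0).
#' @param diffusion_coeff diffusion coefficient, nm^2/ps (> 0).
#' @param timestep integration time step, ps (> 0).
#' @param domain_min,domain_max reflecting boundaries of the coordinate, nm.
#' @param stride store every `stride`-th step (>= 1). The default (100, i.e.
#'   stored frames 1 ps apart) keeps successive stored frames only weakly
#'   correlated relative to the in-window relaxation time kT/(D k) of a
#'   typical umbrella restraint.
#' @param equil_steps discarded equilibration steps before recording (>= 0);
#'   the default corresponds to 100 ps.
#' @param potential optional [true_potential_params()] to validate the
#'   drift-step invariant against at construction.
#'
#' @return An object of class `langevin_params`.
#' @export
#' @examples
#' langevin_params(potential = true_potential_params())
langevin_params <- function(temperature = 300, diffusion_coeff = 0.001,
                            timestep = 0.01, domain_min = 1.0,
                            domain_max = 3.0, stride = 100L,
                            equil_steps = 10000L, potential = NULL) {
  .check_scalar(temperature, "temperature", positive = TRUE)
  .check_scalar(diffusion_coeff, "diffusion_coeff", positive = TRUE)
  .check_scalar(timestep, "timestep", positive = TRUE)
  .check_scalar(domain_min, "domain_min")
  .check_scalar(domain_max, "domain_max")
  if (!(domain_min < domain_max))
    stop("'domain_min' must be smaller than 'domain_max'", call. = FALSE)
  stride <- .check_count(stride, "stride", min = 1L)
  equil_steps <- .check_count(equil_steps, "equil_steps", min = 0L)
  dyn <- structure(list(temperature = temperature,
                        diffusion_coeff = diffusion_coeff,
                        timestep = timestep, domain_min = domain_min,
                        domain_max = domain_max, stride = stride,
                        equil_steps = equil_steps),
                   class = "langevin_params")
  if (!is.null(potential)) .assert_drift_stable(potential, dyn)
  dyn
}

#' @export
print.langevin_params <- function(x, ...) {
  cat("Overdamped Langevin sampler (langevin_params)\n")
  cat(sprintf("  T = %g K, D = %g nm^2/ps, dt = %g ps, stride %d (%g ps/frame)\n",
              x$temperature, x$diffusion_coeff, x$timestep, x$stride,
              x$stride * x$timestep))
  cat(sprintf("  domain [%g, %g] nm (reflecting), %d equilibration steps\n",
              x$domain_min, x$domain_max, x$equil_steps))
  invisible(x)
}

## drift-step stability scan: D*dt*|U'(r)|/kT < 0.1 on a fine grid, for the
## landscape plus (optionally) the harmonic bias
.assert_drift_stable <- function(pot, dyn, spring = 0, center = NA_real_) {
  kT <- .kT(dyn$temperature)
  grid <- seq(dyn$domain_min, dyn$domain_max, length.out = 2001L)
  slope <- abs(true_pmf_deriv(grid, pot))
  if (spring > 0) slope <- slope + abs(spring * (grid - center))
  drift <- dyn$diffusion_coeff * dyn$timestep * slope / kT
  if (max(drift) >= 0.1)
    stop(sprintf(paste0("unstable configuration: drift step D*dt*|U'|/kT ",
                        "reaches %.3g (>= 0.1) at r = %.3f nm; reduce the ",
                        "timestep or the domain"),
                 max(drift), grid[which.max(drift)]), call. = FALSE)
  invisible(TRUE)
}

#' Sample one umbrella window
#'
#' Runs overdamped Langevin dynamics on the synthetic landscape restrained
#' by the harmonic bias `0.5 * spring * (r - center)^2` (GROMACS pull
#' convention), with reflecting boundaries at the domain edges, and stores
#' every `stride`-th coordinate after the equilibration phase. Per-frame
#' component energies are drawn as the ground-truth mean at the frame's
#' coordinate plus independent Gaussian noise; the total is their exact sum
#' on every frame. Identical `seed` gives bitwise-identical output.
#'
#' @param pot a [true_potential_params()] landscape.
#' @param dyn a [langevin_params()] sampler configuration.
#' @param center bias centre, nm.
#' @param spring bias spring constant, kJ/mol/nm^2 (>= 0; 0 = unbiased).
#' @param n_steps number of integration steps after equilibration (>= 1);
#'   `n_steps / stride` frames are stored.
#' @param seed integer RNG seed.
#' @param with_energies attach per-frame component energies (default TRUE).
#' @param label window label; defaults to the bias centre.
#'
#' @return An object of class `umbrella_window`: list with `center`,
#'   `spring`, `time` (ps), `samples` (nm), `energies` (data frame `e_ww`,
#'   `e_aaw`, `e_aaaa`, `e_total` in kJ/mol, or NULL), `label`, `seed`.
#' @export
#' @examples
#' w <- sample_window(true_potential_params(), langevin_params(),
#'                    center = 2.0, spring = 1000, n_steps = 5000, seed = 1)
#' var(w$samples)
sample_window <- function(pot, dyn, center, spring, n_steps, seed,
                          with_energies = TRUE, label = NULL) {
  stopifnot(inherits(pot, "true_potential_params"),
            inherits(dyn, "langevin_params"))
  .check_scalar(center, "center")
  .check_scalar(spring, "spring", nonneg = TRUE)
  n_steps <- .check_count(n_steps, "n_steps", min = 1L)
  seed <- .check_count(seed, "seed", min = -.Machine$integer.max)
  .assert_drift_stable(pot, dyn, spring = spring, center = center)

  r0 <- if (spring > 0) min(max(center, dyn$domain_min), dyn$domain_max)
        else (dyn$domain_min + dyn$domain_max) / 2
  set.seed(seed)
  samples <- .langevin_sample_cpp(r0, n_steps, dyn$stride, dyn$equil_steps,
                                  dyn$timestep, dyn$diffusion_coeff,
                                  .kT(dyn$temperature), dyn$domain_min,
                                  dyn$domain_max, pot$well_depth,
                                  pot$well_center, pot$well_width,
                                  pot$wall_position, pot$wall_scale,
                                  spring, center)
  n <- length(samples)
  time <- seq_len(n) * dyn$stride * dyn$timestep

  energies <- NULL
  if (isTRUE(with_energies)) {
    s <- switch_fraction(samples, pot)
    e_ww <- pot$amp_ww * s + rnorm(n, sd = pot$noise_sd)
    e_aaw <- pot$amp_aaw * s + rnorm(n, sd = pot$noise_sd)
    e_aaaa <- pot$amp_aaaa * s + rnorm(n, sd = pot$noise_sd)
    energies <- data.frame(e_ww = e_ww, e_aaw = e_aaw, e_aaaa = e_aaaa,
                           e_total = e_ww + e_aaw + e_aaaa)
  }
  structure(list(center = center, spring = spring, time = time,
                 samples = samples, energies = energies,
                 label = if (is.null(label)) sprintf("r%.3f", center)
                         else as.character(label),
                 seed = seed),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("Umbrella window '%s': center %.3f nm, k = %g kJ/mol/nm^2, %d frames%s\n",
              x$label, x$center, x$spring, length(x$samples),
              if (is.null(x$energies)) "" else " (+energies)"))
  invisible(x)
}

#' Sample a full set of umbrella windows
#'
#' Convenience wrapper running [sample_window()] at each bias centre;
#' per-window seeds derive deterministically as `master_seed + index - 1`.
#'
#' @inheritParams sample_window
#' @param centers bias centres, nm (strictly increasing).
#' @param master_seed integer master seed.
#' @return List of `umbrella_window` objects.
#' @export
sample_windows <- function(pot, dyn, centers, spring, n_steps, master_seed,
                           with_energies = TRUE) {
  if (length(centers) < 1L || is.unsorted(centers, strictly = TRUE))
    stop("'centers' must be strictly increasing", call. = FALSE)
  lapply(seq_along(centers), function(i)
    sample_window(pot, dyn, centers[i], spring, n_steps,
                  seed = master_seed + i - 1L, with_energies = with_energies))
}
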