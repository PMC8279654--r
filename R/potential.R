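#' Ground-truth free-energy landscape of the synthetic slab system
#'
#' Parameterises the synthetic potential of mean force along the reaction
#' coordinate r (solute to slab-centre distance, nm) and the matching
#' component-enthalpy means. The landscape is a single Gaussian surface well
#' plus an exponential wall toward the vacuum side,
#' \deqn{G(r) = -D\, e^{-(r-r_w)^2 / 2w^2} + e^{(r-r_\mathrm{wall})/s},}
#' which is flat (zero) in bulk, has a minimum just below the Gibbs dividing
#' surface and rises steeply as the solute is pulled out of the slab. Mean
#' component interaction energies (water-water, solute-water, solute-solute)
#' follow a common logistic switch \eqn{S(r) = 1/(1+e^{-(r-c)/\sigma})} that
#' vanishes in bulk, so every component enthalpy is zero at the bulk
#' reference.
#'
#' @param well_depth depth of the surface well, kJ/mol (>= 0).
#' @param well_center location of the well, nm.
#' @param well_width Gaussian width of the well, nm (> 0).
#' @param wall_position onset of the vacuum-side wall, nm.
#' @param wall_scale exponential decay length of the wall, nm (> 0).
#' @param switch_center midpoint of the component-energy switch, nm.
#' @param switch_width width of the component-energy switch, nm (> 0).
#' @param amp_ww,amp_aaw,amp_aaaa asymptotic component-energy amplitudes at
#'   the surface (water-water, solute-water, solute-solute), kJ/mol.
#' @param noise_sd standard deviation of the per-frame Gaussian noise added
#'   to each component energy, kJ/mol (>= 0).
#'
#' @return An object of class `true_potential_params`.
#' @seealso [true_pmf()], [true_enthalpy_components()], [sample_window()]
#' @export
#' @examples
#' pot <- true_potential_params()
#' true_pmf(pot$well_center, pot)
true_potential_params <- function(well_depth = 5, well_center = 2.05,
                                  well_width = 0.15, wall_position = 2.6,
                                  wall_scale = 0.1, switch_center = 2.0,
                                  switch_width = 0.15, amp_ww = -20,
                                  amp_aaw = 15, amp_aaaa = -2,
                                  noise_sd = 5) {
  .check_scalar(well_depth, "well_depth", nonneg = TRUE)
  .check_scalar(well_center, "well_center")
  .check_scalar(well_width, "well_width", positive = TRUE)
  .check_scalar(wall_position, "wall_position")
  .check_scalar(wall_scale, "wall_scale", positive = TRUE)
  .check_scalar(switch_center, "switch_center")
  .check_scalar(switch_width, "switch_width", positive = TRUE)
  .check_scalar(amp_ww, "amp_ww")
  .check_scalar(amp_aaw, "amp_aaw")
  .check_scalar(amp_aaaa, "amp_aaaa")
  .check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  structure(list(well_depth = well_depth, well_center = well_center,
                 well_width = well_width, wall_position = wall_position,
                 wall_scale = wall_scale, switch_center = switch_center,
                 switch_width = switch_width, amp_ww = amp_ww,
                 amp_aaw = amp_aaw, amp_aaaa = amp_aaaa,
                 noise_sd = noise_sd),
            class = "true_potential_params")
}

#' @export
print.true_potential_params <- function(x, ...) {
  cat("Synthetic free-energy landscape (true_potential_params)\n")
  cat(sprintf("  well: depth %.3g kJ/mol at %.3g nm (width %.3g nm)\n",
              x$well_depth, x$well_center, x$well_width))
  cat(sprintf("  wall: onset %.3g nm, scale %.3g nm\n",
              x$wall_position, x$wall_scale))
  cat(sprintf("  switch: center %.3g nm, width %.3g nm\n",
              x$switch_center, x$switch_width))
  cat(sprintf("  amplitudes (ww, aa-w, aa-aa): %.3g, %.3g, %.3g kJ/mol; noise sd %.3g\n",
              x$amp_ww, x$amp_aaw, x$amp_aaaa, x$noise_sd))
  invisible(x)
}

.check_r <- function(r) {
  if (!is.numeric(r) || length(r) < 1L || any(!is.finite(r)))
    stop("reaction coordinate 'r' must be finite numeric", call. = FALSE)
  invisible(r)
}

#' Evaluate the ground-truth PMF
#'
#' Closed-form free energy of the synthetic landscape, relative to bulk
#' (G -> 0 for r well below the interface).
#'
#' @param r reaction coordinate(s), nm.
#' @param params a [true_potential_params()] object.
#' @return Free energy in kJ/mol, same length as `r`.
#' @export
#' @examples
#' true_pmf(c(1, 2.05, 2.6), true_potential_params())
true_pmf <- function(r, params) {
  stopifnot(inherits(params, "true_potential_params"))
  .check_r(r)
  -params$well_depth *
    exp(-(r - params$well_center)^2 / (2 * params$well_width^2)) +
    exp((r - params$wall_position) / params$wall_scale)
}

## dG/dr of the landscape (internal; used by the integrator and the
## drift-step stability scan)
true_pmf_deriv <- function(r, params) {
  params$well_depth *
    exp(-(r - params$well_center)^2 / (2 * params$well_width^2)) *
    (r - params$well_center) / params$well_width^2 +
    exp((r - params$wall_position) / params$wall_scale) / params$wall_scale
}

## logistic switch S(r): 0 in bulk, 1 at the surface side
switch_fraction <- function(r, params) {
  1 / (1 + exp(-(r - params$switch_center) / params$switch_width))
}

#' Ground-truth mean component energies
#'
#' Mean water-water, solute-water and solute-solute interaction energies at
#' coordinate r: each is `amp * S(r)` with the logistic switch S, so all
#' components vanish at the bulk reference.
#'
#' @inheritParams true_pmf
#' @return A data frame with columns `r`, `mean_ww`, `mean_aaw`,
#'   `mean_aaaa` and the total `mean_total` (kJ/mol).
#' @export
#' @examples
#' true_enthalpy_components(c(1, 2, 2.6), true_potential_params())
true_enthalpy_components <- function(r, params) {
  stopifnot(inherits(params, "true_potential_params"))
  .check_r(r)
  s <- switch_fraction(r, params)
  data.frame(r = r,
             mean_ww = params$amp_ww * s,
             mean_aaw = params$amp_aaw * s,
             mean_aaaa = params$amp_aaaa * s,
             mean_total = (params$amp_ww + params$amp_aaw +
                             params$amp_aaaa) * s)
}

#' Ground-truth enthalpy and entropy terms
#'
#' The true enthalpy profile is the sum of the component means; the true
#' entropy term is defined by the identity `-T dS = G - dH`, which therefore
#' holds at machine precision on any grid.
#'
#' @inheritParams true_pmf
#' @return Data frame with columns `r`, `dG`, `dH`, `minus_TdS` (kJ/mol).
#' @export
true_decomposition <- function(r, params) {
  comp <- true_enthalpy_components(r, params)
  g <- true_pmf(r, params)
  data.frame(r = r, dG = g, dH = comp$mean_total,
             minus_TdS = g - comp$mean_total)
}
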