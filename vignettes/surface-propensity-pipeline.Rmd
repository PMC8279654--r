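---
title: "Methods: PMF reconstruction and free-energy decomposition at a slab interface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMF reconstruction and free-energy decomposition at a slab interface}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfpmf)
```

## Scope and model

`surfpmf` reconstructs a potential of mean force (PMF) along a slab-normal
reaction coordinate `r` — the distance between a solute and the slab's
centre of mass — from harmonically biased umbrella windows, decomposes the
adsorption free energy into enthalpic and entropic contributions, splits
the enthalpy into water–water, solute–water and solute–solute interaction
components, and provides the structural analyses that normally accompany
slab studies (density profile and Gibbs dividing surface, geometric
hydrogen bonds, orientation distributions, intramolecular close pairs).

The package deliberately contains no MD engine. Instead it carries a
synthetic system with exact ground truth, so that every estimator can be
validated by parameter recovery rather than by comparison with another
black box. This vignette records the model, the defaults, the numerical
choices, and what the validation does and does not demonstrate.

## The synthetic landscape

The ground-truth free energy is a single Gaussian surface well plus an
exponential wall toward the vacuum side,

$$G(r) = -D\,e^{-(r - r_w)^2 / 2w^2} + e^{(r - r_\mathrm{wall})/s},$$

with defaults $D = 5$ kJ/mol, $r_w = 2.05$ nm, $w = 0.15$ nm,
$r_\mathrm{wall} = 2.6$ nm, $s = 0.1$ nm. This shape captures the three
features that matter for the inference chain: a flat bulk plateau (the
reference state), a minimum just inside the Gibbs dividing surface
(surface propensity), and a steep rise as the solute is pulled into the
vacuum. Component interaction-energy means follow one logistic switch
$S(r) = 1/(1 + e^{-(r - c)/\sigma})$ ($c = 2.0$ nm, $\sigma = 0.15$ nm),
scaled by amplitudes (−20, +15, −2) kJ/mol for the water–water,
solute–water and solute–solute terms: all components vanish in bulk, as
they must for a difference-to-bulk decomposition. Per-frame energies add
independent Gaussian noise (sd 5 kJ/mol per component). Real interaction
energies are serially correlated and mutually coupled; independence is a
deliberate simplification that is sufficient for mean-recovery testing
(see *Limitations*).

The entropic term of the truth is defined by the identity
$-T\Delta S = G - \Delta H$, so the identity holds at machine precision on
any grid — the pipeline's own identity checks therefore test bookkeeping,
not modelling.

## Sampling: overdamped Langevin dynamics

Umbrella windows are drawn with an Euler–Maruyama Brownian integrator on
$U(r) = G(r) + \tfrac12 k (r - r_0)^2$ with reflecting domain boundaries.
Only the stationary (Boltzmann) distribution matters for PMF estimation,
so inertia and a realistic friction model are unnecessary. Defaults:
$T = 300$ K with $k_B = 0.0083144621$ kJ mol⁻¹ K⁻¹,
$D = 0.001$ nm²/ps (a typical small-solute diffusivity in water),
time step 0.01 ps, spring $k = 1000$ kJ/mol/nm², window spacing 0.1 nm
over 1.0–3.0 nm, and 100 ps of discarded equilibration.

Two numerical guards apply:

- **Drift-step stability.** At construction (and again per window, with
  the bias included) the package scans a fine grid and requires
  $D\,\Delta t\,|U'(r)|/k_BT < 0.1$ everywhere; configurations violating
  it are rejected rather than silently producing a biased stationary
  distribution.
- **Stored-frame spacing.** Frames are stored every 100 steps (1 ps) by
  default. The coordinate relaxation time inside a window is
  $\tau = k_BT/(Dk) \approx 2.5$ ps at the default spring, so 0.1 ps
  spacing would store ~50 near-copies of each independent sample and leave
  the window-to-window free-energy matching error near the recovery
  tolerance itself; 1 ps spacing keeps the statistical inefficiency at
  ~5 and the 21-window PMF error comfortably within the 0.3 kJ/mol
  recovery target. The stride is a parameter, not a constraint: totals of
  integration steps, not stored frames, set the runtime.

Per-window seeds derive deterministically as `master_seed + index`, and
every generator is a pure function of its parameters and seed.

## WHAM

The estimator solves the standard self-consistency equations with the
bias evaluated at bin centres and all accumulation in log space
(log-sum-exp), iterating from $f_i = 0$ until $\max_i |\Delta f_i|$ drops
below 10⁻⁶ kJ/mol (configurable; the fixed point is unique up to an
additive constant, so initialisation affects only the iteration count).
Convergence diagnostics (iteration count, final residual, the residual
history of the last iterations) travel with the profile. Choices worth
recording:

- **Bins.** 41 equal-width bins spanning the observed sample range by
  default, values at bin centres. Empty bins are flagged undefined and
  excluded from referencing, interpolation and minimum search — never
  interpolated over.
- **Referencing.** `set_reference()` subtracts the value of the bin
  containing the reference coordinate (bulk, r = 1.0 nm by convention),
  making it exactly zero, and is idempotent. The pipeline widens the
  binning range when necessary so the reference bin exists even when the
  reflecting boundary leaves no sample below it.
- **Discretisation bias.** Evaluating the bias at bin centres and
  reporting $-k_BT\ln P_j$ at centres leaves an $O(\text{width}^2)$
  systematic component (of order 0.1 kJ/mol at the default spring and
  41 bins over 2 nm); the minimum-over-bins readout of well depth also
  selects downward noise fluctuations. Both are visible as a slight
  deepening of the recovered well and are covered by the 0.3 kJ/mol
  recovery tolerance.
- **No autocorrelation correction.** Every stored frame counts once. With
  1 ps storage spacing this inflates no estimate; it only makes nominal
  per-window counts optimistic by the residual inefficiency (~5), a
  variance — not bias — simplification, which is why quoted standard
  errors elsewhere in the package treat frames as independent.
- **Failure modes.** A window with no samples in the binning range aborts
  with the window named (broken overlap); non-convergence carries the
  final residual.

`boltzmann_invert()` (direct histogram inversion of an unbiased run) is
kept as an independent oracle: on a single zero-bias window WHAM must
reduce to it bin-for-bin, and does so to below 10⁻¹⁰ kJ/mol in the tests.

## Decomposition

$\Delta H$ at a window is the difference in time-averaged potential energy
between that window and the bulk reference window; $-T\Delta S$ is defined
by subtraction from the interpolated PMF. Decisions:

- The PMF lives on bins but $\Delta H$ on windows; $\Delta G$ is linearly
  interpolated from bin centres to window centres (0.1 nm spacing is fine
  relative to the landscape curvature). At the reference coordinate the
  free energy is pinned to zero by definition rather than interpolated.
- $\Delta H$ is assembled as the exact sum of the three component
  differences, so $\Delta H = \Delta E_{ww} + \Delta E_{aaw} +
  \Delta E_{aaaa}$ holds to the last bit on every row, and
  $-T\Delta S := \Delta G - \Delta H$ makes the first identity structural
  as well.
- Standard errors combine the two windows' frame-wise errors in
  quadrature; the reference row is identically zero with zero error.
- The surface minimum is the defined bin of minimal free energy inside
  the interphase region; ties break toward smaller r, and the result
  carries an `interior` flag so a minimum pinned at a region edge is
  never mistaken for a genuine well.
- The interphase region defaults to the GDS ± 0.6 nm and is fully
  configurable.
- **Recovery truth for the components.** The harmonic bias displaces a
  window's sampled ensemble from its nominal centre by $-G'(r_0)/k$
  (≈0.01 nm here), and the ensemble mean of $S(r)$ differs from
  $S(r_0)$ by a curvature term of several noise standard errors at
  2×10⁵ frames. Recovery tests therefore compare each recovered component
  against its conditional ground truth
  $\mathrm{amp}\,(\overline{S(r_t)}_\mathrm{win} -
  \overline{S(r_t)}_\mathrm{ref})$ over the realised coordinates — the
  exact expectation of the estimator given the trajectory — so the
  residual is the i.i.d. noise mean and the 3-standard-error criterion
  tests what it claims to test. Comparing against $S$ at the nominal
  centre would conflate bias displacement with estimator error.

## Structural analyses

- **Density and GDS.** Profiles are binned along z (0.05 nm default bin
  width over a 12 nm box), frame-averaged and volume-normalised; bulk
  density is the mean over the central 2 nm of the slab (both defaults
  configurable; nothing in the chain is sensitive to them at the tested
  interface widths). The GDS is found by linear interpolation at the
  half-bulk crossing on the outward flank; a profile that never crosses —
  no interface — is an error, not a zero.
- **Hydrogen bonds.** Geometric criteria: donor–acceptor distance
  ≤ 0.35 nm and angular deviation ≤ 30°, minimum-image distances under
  the orthorhombic box, donor ≠ acceptor. The angular convention is
  genuinely ambiguous in the literature — deviation of the D–H–A angle
  from linearity versus the H–D–A angle at the donor — so both are
  implemented (`angle_vertex = "hydrogen"` is the default, the stricter
  and more common choice); the convention is recorded in run metadata.
  Correctness is established against a brute-force all-pairs recount on
  random fixtures, exactly, not statistically.
- **Orientations.** Vectors are normalised, $\cos\theta$ is the
  z-component, histograms are probability densities over [−1, 1] (they
  integrate to one within 10⁻⁹). The isotropic fixture exploits the
  uniform-cosine law of the sphere as its oracle.
- **Close pairs.** All intra-residue pairs within a cutoff, optionally
  excluding pairs below a bonded-graph separation when a topology is
  supplied; sorted by distance; validated against an O(n²) recount.

## What the synthetic system does and does not show

The generator emulates: harmonically biased Boltzmann sampling of a 1D
coordinate with a realistic well/wall shape; component energies with the
correct bulk-vanishing structure; tanh slab density profiles with Poisson
placement noise; exact-geometry hydrogen-bond triplets; and the three
canonical orientation populations. Passing recovery tests therefore
demonstrates that the estimators are correct *as estimators*.

It does not emulate: correlated component energies, 3D solute dynamics,
capillary-wave roughening of the interface, finite water structure (no
explicit solvent), or force-field physics. Agreement here says nothing
about force-field adequacy for any real amino acid, and the package makes
no attempt to reproduce experimental or published per-residue adsorption
energies.

## Validation problem sizes

The test suite runs the chain at the sizes the estimators are designed
for: the headline recovery study uses 21 windows × 2×10⁵ stored frames
(2×10⁷ integration steps per window, a few seconds each in the compiled
kernel), with an RMS PMF-error target of 0.3 kJ/mol over the interphase
region and the same tolerance on the recovered well depth. Component
recovery runs 20 seeded replicates of the well/reference window pair at
the same depth. Sampler calibration uses 2×10⁷ steps for the harmonic
variance (target: within 2% of $k_BT/k$) and a 10⁶-step unbiased run for
Boltzmann consistency. Statistical goodness-of-fit tests (Pearson χ²)
are only valid on approximately independent draws, so the Boltzmann and
uniformity checks run on reduced domains and thin stored frames to
several times the slowest diffusive relaxation time
$\tau_1 = L^2/(\pi^2 D)$ before testing; without thinning the statistic
is inflated by the statistical inefficiency and the test answers the
wrong question. Unit tests use smaller sizes with proportionally looser,
pre-derived bounds.

## Limitations

- Enthalpy standard errors assume independent frames; with correlated
  input (real MD) they understate the true uncertainty and a block
  bootstrap over frames should be preferred.
- The WHAM implementation is 1D, aperiodic, and bin-based by design; no
  MBAR, no umbrella integration, no 2D coordinates.
- GRO coordinates carry three decimals (0.001 nm); geometry read back
  from disk is only as precise as the format, and angle recovery from
  file round-trips degrades accordingly (in-memory fixtures are exact).
- The synthetic noise model is Gaussian and uncorrelated; recovery
  targets quoted for it transfer to real data only where effective sample
  sizes are computed honestly.
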