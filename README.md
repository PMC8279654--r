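# surfpmf

Umbrella sampling, WHAM and free-energy decomposition for solute surface
propensity at a slab interface.

## The problem

Whether a small solute (an amino acid, an organic molecule, an ion)
*prefers the surface* of an aqueous slab over its bulk is read off a
potential of mean force (PMF): the free energy ΔG(r) along the distance r
between the solute and the slab's centre of mass. Surface propensity shows
up as a free-energy minimum in the interphase region around the Gibbs
dividing surface (GDS), the plane where the water density falls to half its
bulk value. Understanding *why* the minimum exists requires splitting it:

- **ΔG = ΔH − TΔS**, with the enthalpy ΔH taken as the difference in
  time-averaged potential energy between an umbrella window and the bulk
  reference window, and the entropy term −TΔS obtained by subtraction;
- **ΔH = ΔE(w–w) + ΔE(aa–w) + ΔE(aa–aa)**, the pairwise interaction-energy
  changes among water and solute.

`surfpmf` implements this full inference chain in R for people who analyse
slab simulations: a WHAM estimator with log-space accumulation and
convergence diagnostics, the enthalpy/entropy and component decomposition,
and the accompanying structural analyses (slab density profile and GDS,
geometric hydrogen-bond counting under the 3.5 Å / 30° criteria,
side-chain orientation cos θ distributions, intramolecular close pairs).
It reads GROMACS-pull-style two-column `.xvg` series and fixed-column
`.gro` snapshots.

Because validating such estimators against an MD engine is circular, the
package ships a first-class synthetic system: overdamped Langevin dynamics
on a known landscape — a Gaussian surface well of depth 5 kJ/mol at
2.05 nm plus an exponential vacuum wall — with matched component-energy
means that follow a logistic switch. Every stage of the chain is therefore
testable by parameter recovery against exact ground truth.

## The estimator at its core

Given umbrella windows i with bias ½kᵢ(r − rᵢ)², Nᵢ frames and histogram
counts n₍ᵢⱼ₎ over bins j, WHAM iterates

    P_j = Σᵢ n_ij / Σᵢ Nᵢ exp[(fᵢ − c_ij)/k_BT],
    fᵢ  = −k_BT ln Σⱼ P_j exp(−c_ij/k_BT),   c_ij = ½kᵢ(x_j − rᵢ)²

until max|Δfᵢ| falls below a tolerance (10⁻⁶ kJ/mol by default), then
reports ΔG_j = −k_BT ln P_j, anchored to zero at the bulk reference
(r = 1.0 nm by convention). Empty bins stay flagged undefined rather than
being interpolated.

## Worked example

Generate a 21-window umbrella study on the default landscape, reconstruct
the PMF and decompose the adsorption free energy at the surface minimum:

```r
library(surfpmf)
pot <- true_potential_params()            # 5 kJ/mol well at 2.05 nm
dyn <- langevin_params()
wins <- sample_windows(pot, dyn, seq(1.0, 3.0, 0.1), spring = 1000,
                       n_steps = 2e6, master_seed = 1)
rng <- range(c(1.0, unlist(lapply(wins, `[[`, "samples"))))
pmf <- set_reference(wham(wins, n_bins = 41, bin_range = rng), 1.0)
pmf
#> PMF profile: 41 bins over [1.000, 2.987] nm, T = 300 K
#>   41 defined bins; reference: 1.000 nm
#>   WHAM: 1841 iterations, final residual 9.98e-07 kJ/mol

rec <- decomposition_at_minimum(pmf, wins, 1.0, interphase_region(2.0, 0.6))
print(rec, digits = 3)
#>   r r_min   dG    dH minus_TdS dE_ww dE_aaw dE_aaaa  se_dH interior
#> 1 2  2.04 -4.6 -3.55     -1.05 -10.2   7.67   -1.05 0.0866     TRUE
```

Reading the record: the PMF minimum sits at r = 2.04 nm (the configured
well is at 2.05 nm), interior to the interphase region, with an adsorption
free energy of −4.6 kJ/mol at the nearest window (r = 2.0 nm). The
enthalpy (−3.55 kJ/mol) and entropy term (−1.05 kJ/mol) sum to ΔG exactly,
and the water–water (−10.2), solute–water (+7.67) and solute–solute
(−1.05) components sum to ΔH exactly — each recovering its configured
ground truth (amp·S(r), with S the logistic switch) within the quoted
standard errors.

The same chain is available from a shell:

```sh
Rscript inst/cli/surfpmf.R all --config my_run.yaml --seed 7 --verbose
```

which writes window files, `pmf.csv`, `decomposition.csv`,
`minimum_record.json`, structure CSVs and a `run_metadata.json` with a QC
block (WHAM residual, window-overlap counts, interior-minimum flag).

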