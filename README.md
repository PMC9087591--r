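# fepcycle

Alchemical free-energy analysis for protonation and tautomer equilibria in
protein–cofactor complexes.

## What it is for

Enzymes that bind pyridoxal-5′-phosphate (PLP) — such as methionine
γ-lyase (MGL), a candidate therapeutic protein — hold the cofactor through a
lysine Schiff base whose catalytically relevant ionization states are hard
to measure: the phosphate can be −1 or −2, and the Schiff-base proton can
sit on the linking nitrogen (keto form) or the phenolic oxygen (enol form).
Free-energy perturbation (FEP) simulations settle such questions by
transforming one state into the other along a coupling variable
λ ∈ [0, 1] and post-processing the sampled perturbation energies.
`fepcycle` is that post-processing pipeline, for computational chemists
running alchemical FEP on proteins:

- **Estimators** — Bennett acceptance ratio (BAR) per window pair, solving
  Σ_F f(β(ΔU_F − ΔG) + M) = Σ_B f(β(ΔU_B + ΔG) − M) with f the Fermi
  function and M = ln(n_F/n_B); finite-difference thermodynamic
  integration, with ∂G/∂λ ≈ [G(λ+δ) − G(λ−δ)]/2δ from exponential
  averaging; and closed-form **not-a-knot cubic-spline quadrature** of
  derivative profiles (plus Simpson/trapezoid cross-checks).
- **Multi-run combination** — per-λ, sampling-length-weighted consensus
  derivatives over user-chosen run subsets (`combine_profiles()`), and
  forward/backward hysteresis diagnostics.
- **Thermodynamic cycles** — pKa shifts,
  ΔpKa = (ΔG_P − ΔG_S)/(ln 10 · kT), protonation-state populations, and
  the keto/enol gas-phase-corrected cycle
  ΔG = ΔG_prot(MM) − ΔG_gas(MM) + ΔG_gas(QM).
- **Finite-size corrections** for charged transformations under periodic
  boundary conditions: the PME bulk-potential shift qΦ (bulk region =
  grid points > 12 Å from any protein atom, minimum image) and the
  dielectric-scaled periodic Wigner self-energy, computed by Ewald
  summation for cubic and truncated-octahedral cells.
- **Torsion parametrization** — cosine-series fits to energy scans and
  iterative Boltzmann inversion (`match_distribution()`) to make a
  dihedral's simulated distribution match an observed one.
- **Structure metrics** — dihedrals, distances, hydrogen-bond occupancies,
  Schiff-base orientation classes and χ-peak assignment over structural
  ensembles.
- **Synthetic data** — seeded generators with analytic ground truth
  (Crooks-Gaussian work samples, harmonic alchemy, toy Schiff-base
  geometries, potential grids) that stand in for MD output in every test.

The package ships the published TI/BAR reference tables for PLP phosphate
deprotonation in MGL (`deprotonation_reference()`, `tautomer_reference()`),
so the complete reference analysis runs offline.

## Worked example

The reference deprotonation analysis, end to end:

```r
library(fepcycle)
ref <- deprotonation_reference()

# solution leg: spline-TI total of the model compound column
spline_integrate(ref$profiles$solution)
#> dG = -80.3917 kcal/mol  [TI_spline]

# protein leg: combine the runs under the shipped per-lambda scheme
prot <- ref$profiles[setdiff(names(ref$profiles), "solution")]
consensus <- combine_profiles(prot, deprotonation_scheme())
consensus
#> <derivative_profile> 5 points on [0, 1]
#>   lambda dG_dlambda
#> 1   0.00   -24.6600
#> 2   0.25   -51.0000
#> 3   0.50   -81.0875
#> 4   0.75  -104.9000
#> 5   1.00  -129.0500

# finite-size correction and thermodynamic cycle
dG_P <- spline_integrate(consensus)$value +
  shift_correction(ref$phi_bulk, ref$q_removed)   # -78.29 + (-2.9) = -81.19
cyc <- thermo_cycle(dG_P, -80.39, model_pKa = 6.3, temperature_K = 295)
protein_pka(cyc)
#> [1] 5.71
deprotonated_fraction(protein_pka(cyc), pH = 7.5)
#> [1] 0.984
```

So the phosphate pKa in the protein is about 5.7 — below the solution value
of 6.3 — and the dinegative phosphate dominates (98%) at physiological pH.

Validating the estimators on an exactly solvable transformation:

```r
run <- gen_harmonic_alchemy(k0 = 1, k1 = 4, n_frames = 20000, seed = 11)
bar_run_total(run)
#> dG = 0.4056 +/- 0.001488 kcal/mol  [window_sum]
spline_integrate(run_derivative_profile(run))
#> dG = 0.4058 +/- 0.002121 kcal/mol  [TI_spline]
ground_truth(run)$true_dG            # closed form (kT/2) ln(k1/k0)
#> [1] 0.4063404
```

BAR and TI agree with each other and with the closed form within their
standard errors.

## Documentation

The methods vignette (`vignettes/free-energy-analysis.Rmd`) describes the
estimators, the numerical choices (spline end conditions, Ewald parameters,
iterative-Boltzmann-inversion settings), what the synthetic generators do
and do not demonstrate, and the package's known limitations.
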