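# Reference free-energy tables

Values transcribed from the published alchemical free-energy study of
pyridoxal-5'-phosphate (PLP) bound to methionine gamma-lyase (MGL) that this
package's reference analyses reproduce. All energies in kcal/mol; runs at
295 K.

- `deprot_ti_derivatives.tsv` — TI free-energy derivatives dG/dlambda for
  phosphate deprotonation at lambda = 0, 0.25, 0.5, 0.75, 1 for the solution
  model compound and protein runs A/A'/B/B'/C/C' (40 ns windows) and the
  half-range runs d/d' (80 ns windows, lambda >= 0.5). `weight_ns` is the
  window sampling length.
- `deprot_ti_mean.tsv` — the published per-lambda consensus (run-averaged)
  derivatives.
- `deprot_bar_windows.tsv` — per-lambda-interval BAR free-energy
  contributions for the same runs.
- `deprot_totals.tsv` — published totals per run and method, including the
  consensus total (-78.3) and the finite-size-corrected total (-81.2).
- `tautomer_ti.tsv` — endpoint TI derivatives for the keto/enol (N2 -> Z2)
  transformation in the protein, two 600 ns replicates per endpoint.

Scalar reference inputs that accompany these tables (bulk potential
Phi = -2.9 kcal/mol/e, model-compound pKa 6.3, box dielectric 40, gas-phase
MM and QM tautomer values -44.0 and -0.4) are exposed by
`deprotonation_reference()` and `tautomer_reference()`.
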