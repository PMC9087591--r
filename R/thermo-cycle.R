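## Thermodynamic-cycle arithmetic: pKa shifts from deprotonation free
## energies, protonation-state populations, and the keto/enol tautomer cycle.

#' Construct a pKa thermodynamic cycle
#'
#' The cycle compares deprotonation of a titratable group in the protein
#' complex against the same deprotonation of a model compound in solution.
#' The pKa shift is proportional to the difference of the two horizontal-leg
#' free energies.
#'
#' @param dG_P Deprotonation free energy in the protein, kcal/mol.
#' @param dG_S Deprotonation free energy of the model compound in solution,
#'   kcal/mol.
#' @param model_pKa Measured solution pKa of the model compound (default 6.3,
#'   the phosphate monoester value used for PLP).
#' @param temperature_K Temperature, K.
#' @return An object of class `thermo_cycle`.
#' @export
thermo_cycle <- function(dG_P, dG_S, model_pKa = 6.3, temperature_K = 295) {
  if (temperature_K <= 0) stop("temperature_K must be > 0")
  structure(list(dG_P = dG_P, dG_S = dG_S, model_pKa = model_pKa,
                 temperature_K = temperature_K),
            class = "thermo_cycle")
}

#' pKa shift from a thermodynamic cycle
#'
#' \eqn{\Delta pK_a = (\Delta G_P - \Delta G_S) / (\ln(10)\, kT)}.
#' The conversion factor ln(10) kT is 1.3499 kcal/mol at 295 K.
#'
#' @param cycle A [thermo_cycle()].
#' @return The shift in pK units.
#' @examples
#' pka_shift(thermo_cycle(-81.2, -80.4))   # about -0.59
#' @export
pka_shift <- function(cycle) {
  stopifnot(inherits(cycle, "thermo_cycle"))
  (cycle$dG_P - cycle$dG_S) / (log(10) * kT(cycle$temperature_K))
}

#' Site pKa in the protein
#'
#' Model-compound solution pKa plus the cycle's pKa shift.
#'
#' @param cycle A [thermo_cycle()].
#' @return pKa in the protein, pK units.
#' @examples
#' protein_pka(thermo_cycle(-81.2, -80.4, model_pKa = 6.3))  # about 5.7
#' @export
protein_pka <- function(cycle) {
  stopifnot(inherits(cycle, "thermo_cycle"))
  cycle$model_pKa + pka_shift(cycle)
}

#' Deprotonated population fraction
#'
#' Henderson-Hasselbalch population of the deprotonated state,
#' \eqn{1 / (1 + 10^{pK_a - pH})}; strictly increasing in pH.
#'
#' @param pKa Site pKa, pK units.
#' @param pH Solution pH.
#' @return Fraction in (0, 1).
#' @examples
#' deprotonated_fraction(5.7, 7.5)   # over 98%
#' @export
deprotonated_fraction <- function(pKa, pH) {
  1 / (1 + 10^(pKa - pH))
}

#' Construct a tautomer thermodynamic cycle
#'
#' Cycle for a tautomerization free energy in the protein when no solution
#' reference exists: the molecular-mechanics (MM) free energy in the protein
#' is corrected by the gas-phase MM value and a gas-phase quantum-mechanical
#' (QM) value taken from external calculations.
#'
#' @param dG_prot_MM MM tautomerization free energy in the protein, kcal/mol.
#' @param dG_gas_MM MM tautomerization energy in the gas phase, kcal/mol.
#' @param dG_gas_QM QM tautomerization free energy in the gas phase, kcal/mol
#'   (an external input, never computed here).
#' @return An object of class `tautomer_cycle`.
#' @export
tautomer_cycle <- function(dG_prot_MM, dG_gas_MM, dG_gas_QM) {
  vals <- c(dG_prot_MM, dG_gas_MM, dG_gas_QM)
  if (any(!is.finite(vals))) stop("cycle terms must be finite")
  structure(list(dG_prot_MM = dG_prot_MM, dG_gas_MM = dG_gas_MM,
                 dG_gas_QM = dG_gas_QM),
            class = "tautomer_cycle")
}

#' Tautomerization free energy in the protein
#'
#' \eqn{\Delta G = \Delta G_{prot}(MM) - \Delta G_{gas}(MM) +
#' \Delta G_{gas}(QM)}.
#'
#' @param cycle A [tautomer_cycle()].
#' @return Delta G in kcal/mol.
#' @examples
#' tautomer_free_energy(tautomer_cycle(-44.9, -44.0, -0.4))   # -1.3
#' @export
tautomer_free_energy <- function(cycle) {
  stopifnot(inherits(cycle, "tautomer_cycle"))
  cycle$dG_prot_MM - cycle$dG_gas_MM + cycle$dG_gas_QM
}
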