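## Accessors for the packaged reference tables: the published TI/BAR results
## for PLP phosphate deprotonation in the MGL complex and for the keto/enol
## tautomer transformation (see inst/extdata/README.md).

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "fepcycle")
  if (path == "") stop("packaged data file not found: ", name)
  path
}

#' Reference phosphate-deprotonation dataset
#'
#' The published free-energy results for deprotonating the PLP phosphate in
#' the MGL complex and in solution: per-run TI derivative profiles, the
#' published consensus derivative column, per-interval BAR contributions,
#' published totals, and the scalar finite-size / cycle inputs.
#'
#' @return A list:
#' \describe{
#'   \item{ti}{data frame `run_id`, `lambda`, `dG_dlambda_kcal_mol`,
#'     `weight_ns`.}
#'   \item{profiles}{named list of [derivative_profile()] objects per run.}
#'   \item{ti_mean}{[derivative_profile()] of the published consensus column.}
#'   \item{bar}{data frame of per-interval BAR contributions.}
#'   \item{totals}{data frame of published totals per run and method.}
#'   \item{phi_bulk}{mean bulk potential, kcal/mol/e (-2.9).}
#'   \item{q_removed}{charge change of the deprotonation (+1 e).}
#'   \item{model_pKa}{solution pKa of the model compound (6.3).}
#'   \item{temperature_K}{simulation temperature (295 K).}
#'   \item{eps_box}{effective box dielectric (40).}
#'   \item{box_edge_A}{water box edge (78 A).}
#' }
#' @export
deprotonation_reference <- function() {
  ti <- utils::read.table(.extdata("deprot_ti_derivatives.tsv"),
                          header = TRUE, sep = "\t", quote = "")
  profiles <- lapply(split(ti, ti$run_id), function(d)
    derivative_profile(d$lambda, d$dG_dlambda_kcal_mol, weights = d$weight_ns))
  mean_df <- utils::read.table(.extdata("deprot_ti_mean.tsv"),
                               header = TRUE, sep = "\t")
  list(ti = ti,
       profiles = profiles,
       ti_mean = derivative_profile(mean_df$lambda, mean_df$dG_dlambda_kcal_mol),
       bar = utils::read.table(.extdata("deprot_bar_windows.tsv"),
                               header = TRUE, sep = "\t", quote = ""),
       totals = utils::read.table(.extdata("deprot_totals.tsv"),
                                  header = TRUE, sep = "\t", quote = ""),
       phi_bulk = -2.9, q_removed = 1, model_pKa = 6.3,
       temperature_K = 295, eps_box = 40, box_edge_A = 78)
}

#' Reference keto/enol tautomer dataset
#'
#' The published endpoint TI derivatives for the N2 -> Z2 (enol -> keto)
#' transformation of the PLP Schiff base in the protein, plus the gas-phase
#' molecular-mechanics and quantum-mechanics cycle terms.
#'
#' @return A list with `derivatives` (data frame `lambda`, `rep`,
#'   `dG_dlambda_kcal_mol`), `dG_gas_MM` (-44.0 kcal/mol) and `dG_gas_QM`
#'   (-0.4 kcal/mol, external QM input).
#' @export
tautomer_reference <- function() {
  list(derivatives = utils::read.table(.extdata("tautomer_ti.tsv"),
                                       header = TRUE, sep = "\t"),
       dG_gas_MM = -44.0, dG_gas_QM = -0.4)
}
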