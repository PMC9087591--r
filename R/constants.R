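## Physical constants (kcal-based units used throughout the package).

.kB <- 0.0019872041   # Boltzmann constant, kcal/mol/K
.ke <- 332.0637       # Coulomb constant, kcal*Angstrom/mol/e^2

#' Thermal energy kT
#'
#' Boltzmann constant times temperature, in kcal/mol. The package default
#' temperature is 295 K, the temperature at which the reference simulations
#' were thermostatted.
#'
#' @param temperature_K Temperature in Kelvin (default 295).
#' @return kT in kcal/mol.
#' @examples
#' kT()          # 0.586 kcal/mol at 295 K
#' 1 / kT(295)   # beta in mol/kcal
#' @export
kT <- function(temperature_K = 295) {
  if (!is.numeric(temperature_K) || temperature_K <= 0)
    stop("temperature_K must be > 0")
  .kB * temperature_K
}

## log(mean(exp(x))) computed stably
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
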