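## Physical constants (CODATA) used across the package.

#' Boltzmann constant in kcal mol^-1 K^-1
#' @keywords internal
.kB <- 0.0019872041

#' Faraday constant, C mol^-1
#' @keywords internal
.FARADAY <- 96485.33212

#' Molar gas constant, J mol^-1 K^-1
#' @keywords internal
.RGAS <- 8.314462618

#' Elementary charge, C
#' @keywords internal
.ECHARGE <- 1.602176634e-19

## 1 kcal mol^-1 e^-1 expressed in volts (4184 J per kcal / Faraday)
.KCALMOL_PER_E_IN_VOLT <- 4184 / .FARADAY

#' Thermal energy kT in kcal/mol
#'
#' @param temperature temperature in kelvin (default 300 K).
#' @return kT in kcal mol^-1.
#' @examples
#' thermal_energy(300)  # ~0.596 kcal/mol
#' @export
thermal_energy <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  .kB * temperature
}
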