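# Physical constants (CODATA) and unit conversions used across the package.
# Internal convention: continuum bubble models work in SI; trajectory analysis
# works in MD units (Angstrom, ps, amu, atm.A^3 for per-atom stress) and
# converts at the interface.

.kB <- 1.380649e-23      # Boltzmann constant, J/K
.planck <- 6.62607015e-34 # Planck constant, J s
.amu_kg <- 1.66053906660e-27
.atm_MPa <- 0.101325     # 1 atm in MPa
.A3_to_cm3 <- 1e-24
.A3_to_m3 <- 1e-30
.A2ps_to_m2s <- 1e-8     # 1 A^2/ps in m^2/s

#' Unit conversion helpers
#'
#' Small named conversions between the MD-style units used for trajectories
#' (Angstrom, ps, amu, atm) and SI. Exposed because downstream scripts need
#' the same constants the package uses internally.
#'
#' @return A named list of conversion factors and physical constants.
#' @export
#' @examples
#' cav_constants()$kB
cav_constants <- function() {
  list(
    kB = .kB, planck = .planck, amu_kg = .amu_kg,
    atm_MPa = .atm_MPa, A3_to_cm3 = .A3_to_cm3, A3_to_m3 = .A3_to_m3,
    A2ps_to_m2s = .A2ps_to_m2s
  )
}
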