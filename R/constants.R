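#' Physical constants used by the coupling calculations
#'
#' The Coulomb factor is e^2/(4 pi eps0) expressed in cm^-1 * Angstrom, so
#' that a sum of q_i q_j / r_ij terms (charges in units of the elementary
#' charge, distances in Angstrom) comes out directly in wavenumbers. The
#' dipole factor converts e*Angstrom to Debye. Both are fixed module-level
#' values; no function accepts user overrides for them.
#'
#' @return Named list with elements `coulomb_cm1_A` (1.16140e5 cm^-1 Angstrom
#'   per e^2) and `debye_per_eA` (4.80320 D per e Angstrom).
#' @export
#' @examples
#' tresp_constants()$coulomb_cm1_A
tresp_constants <- function() {
  list(coulomb_cm1_A = 1.16140e5, debye_per_eA = 4.80320)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
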