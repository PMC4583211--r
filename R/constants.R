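#' Physical constants in wavenumber units
#'
#' The Bohr magneton expressed in cm^-1 per Tesla and the Boltzmann constant
#' in cm^-1 per Kelvin, the two constants that set the scale of the Zeeman
#' interaction and of thermal populations in magnetic spectroscopy. Their
#' ratio defines the dimensionless saturation variable beta*B/(k*T) against
#' which VTVH magnetization curves are plotted.
#'
#' @return A named list with elements `bohr_magneton_cm1_per_T` and
#'   `boltzmann_cm1_per_K`.
#' @examples
#' mcd_constants()$bohr_magneton_cm1_per_T
#' @export
mcd_constants <- function() {
  list(
    bohr_magneton_cm1_per_T = 0.4668645,
    boltzmann_cm1_per_K     = 0.6950348
  )
}

# internal shorthands
.BETA_CM1_T <- 0.4668645
.KB_CM1_K   <- 0.6950348

#' Convert between wavelength (nm) and wavenumber (cm^-1)
#'
#' @param lambda_nm wavelength in nanometres
#' @param energy_cm1 energy in wavenumbers
#' @return the converted quantity; the transformation E = 1e7 / lambda is an
#'   involution so the two functions are inverses.
#' @examples
#' nm_to_cm1(414)   # 24155 cm^-1
#' cm1_to_nm(7280)
#' @export
nm_to_cm1 <- function(lambda_nm) {
  stopifnot(is.numeric(lambda_nm), all(lambda_nm > 0))
  1e7 / lambda_nm
}

#' @rdname nm_to_cm1
#' @export
cm1_to_nm <- function(energy_cm1) {
  stopifnot(is.numeric(energy_cm1), all(energy_cm1 > 0))
  1e7 / energy_cm1
}
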