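## Physical constants and unit conversions.
##
## All internals of the package run in Hartree atomic units
## (Hartree / Bohr / electron mass / atomic time, hbar = 1); the
## user-facing layers speak kcal/mol, Angstrom, fs, amu and cm^-1.

## CODATA-style fixed conversion factors.
.zn <- list(
  kcal_per_hartree = 627.509474,
  angstrom_per_bohr = 0.529177210903,
  autime_per_fs = 41.341374575751,
  me_per_amu = 1822.888486209,
  cm1_per_hartree = 219474.6313632,
  hc_evnm = 1239.841984
)

#' Unit conversion helpers
#'
#' Fixed-factor conversions between the atomic units used internally
#' (Hartree, Bohr, electron mass, atomic time unit) and the laboratory
#' units used at the interfaces (kcal/mol, Angstrom, amu, fs, cm^-1).
#'
#' @param x numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' hartree_to_kcal(1)     # 627.509474
#' angstrom_to_bohr(0.529177210903)
#' @name unit-conversions
NULL

#' @rdname unit-conversions
#' @export
hartree_to_kcal <- function(x) x * .zn$kcal_per_hartree

#' @rdname unit-conversions
#' @export
kcal_to_hartree <- function(x) x / .zn$kcal_per_hartree

#' @rdname unit-conversions
#' @export
bohr_to_angstrom <- function(x) x * .zn$angstrom_per_bohr

#' @rdname unit-conversions
#' @export
angstrom_to_bohr <- function(x) x / .zn$angstrom_per_bohr

#' @rdname unit-conversions
#' @export
fs_to_au <- function(x) x * .zn$autime_per_fs

#' @rdname unit-conversions
#' @export
au_to_fs <- function(x) x / .zn$autime_per_fs

#' @rdname unit-conversions
#' @export
amu_to_au <- function(x) x * .zn$me_per_amu

#' @rdname unit-conversions
#' @export
au_to_amu <- function(x) x / .zn$me_per_amu

#' @rdname unit-conversions
#' @export
wavenumber_to_hartree <- function(x) x / .zn$cm1_per_hartree

#' @rdname unit-conversions
#' @export
hartree_to_wavenumber <- function(x) x * .zn$cm1_per_hartree

#' Photon energy / wavelength conversion
#'
#' Converts between photon energy in electron volts and vacuum wavelength
#' in nanometres via lambda = hc / E with hc = 1239.841984 eV nm.
#' Rounding to whole nanometres, as spectra are usually quoted, is left
#' to the caller.
#'
#' @param energy_ev photon energy in eV; must be positive.
#' @param wavelength_nm wavelength in nm; must be positive.
#' @return `ev_to_nm()` returns the wavelength in nm; `nm_to_ev()` the
#'   photon energy in eV.
#' @examples
#' round(ev_to_nm(4.38))  # UV band of the open-form photoswitch, ~283 nm
#' round(ev_to_nm(2.64))  # visible band of the closed form, ~470 nm
#' @export
ev_to_nm <- function(energy_ev) {
  stopifnot(is.numeric(energy_ev))
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0))
    stop("photon energy must be positive and finite")
  .zn$hc_evnm / energy_ev
}

#' @rdname ev_to_nm
#' @export
nm_to_ev <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm))
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    stop("wavelength must be positive and finite")
  .zn$hc_evnm / wavelength_nm
}
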