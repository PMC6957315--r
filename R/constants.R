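# Single source of unit truth for the whole package.
# Energies are kcal/mol, lengths Angstrom, tensions are supplied in mN/m and
# converted centrally to kcal/mol/A^2.

#' Physical constants and unit conversions
#'
#' Returns the constants table used throughout the package: the Boltzmann
#' constant in kcal/mol/K (CODATA), the thermal energy at 298.15 K, and the
#' conversion factor from mN/m to kcal/mol/A^2 used for membrane tension.
#'
#' The tension conversion derives from first principles:
#' 1 mN/m = 1e-3 J/m^2 = 1e-23 J/A^2; multiplying by Avogadro's number
#' (6.02214076e23 / mol) and dividing by the thermochemical calorie
#' (4184 J/kcal) gives 1.439326e-3 kcal/mol/A^2.
#'
#' @return Named list with elements `kB` (kcal/mol/K), `kBT_298` (kcal/mol at
#'   298.15 K), `avogadro` (1/mol), `joule_per_kcal`, and
#'   `mNm_to_kcal_mol_A2`.
#' @examples
#' memmorph_constants()$kB * 298.15  # ~0.5925 kcal/mol
#' @export
memmorph_constants <- function() {
  avogadro <- 6.02214076e23
  joule_per_kcal <- 4184
  kB_J <- 1.380649e-23                       # J/K, exact SI
  kB <- kB_J * avogadro / joule_per_kcal     # 1.987204e-3 kcal/mol/K
  list(
    kB = kB,
    kBT_298 = kB * 298.15,                   # 0.5925 kcal/mol
    avogadro = avogadro,
    joule_per_kcal = joule_per_kcal,
    mNm_to_kcal_mol_A2 = 1e-23 * avogadro / joule_per_kcal
  )
}

#' Thermal energy k_B*T
#'
#' @param temperature Temperature in kelvin.
#' @return k_B*T in kcal/mol.
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  memmorph_constants()$kB * temperature
}

#' Convert membrane tension from mN/m to kcal/mol/A^2
#'
#' @param sigma_mN_m Tension in mN/m (may be a vector).
#' @return Tension in kcal/mol/A^2.
#' @export
tension_to_kcal <- function(sigma_mN_m) {
  stopifnot(is.numeric(sigma_mN_m))
  sigma_mN_m * memmorph_constants()$mNm_to_kcal_mol_A2
}
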