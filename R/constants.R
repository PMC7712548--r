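## Physical constants (CODATA 2018, SI) and the internal unit system.
##
## Internal units throughout the package: lengths in nm, time in ns, energy
## in kBT at the configured temperature, voltage in V, rates in ions/ns,
## concentration in ions/nm^3.  These are the units in which every
## back-of-the-envelope number in the analysis is naturally expressed.

#' Physical constants used by the package
#'
#' A named list of SI constants: `kB` (Boltzmann, J/K), `e` (elementary
#' charge, C), `N_A` (Avogadro, 1/mol), `eps0` (vacuum permittivity, F/m),
#' and `coulomb_eV_nm` (e^2/(4 pi eps0), in eV nm).
#'
#' @examples
#' phys_constants$kB
#' @export
phys_constants <- list(
  kB   = 1.380649e-23,
  e    = 1.602176634e-19,
  N_A  = 6.02214076e23,
  eps0 = 8.8541878128e-12,
  coulomb_eV_nm = 1.602176634e-19 / (4 * pi * 8.8541878128e-12) * 1e9
)

#' Convert a molar concentration to ions per cubic nanometre
#'
#' 1 mol/L corresponds to 0.6022 ions/nm^3 for a fully dissociated species.
#'
#' @param mol_per_L concentration in mol/L.
#' @return Concentration in ions/nm^3.
#' @examples
#' mol_per_L_to_per_nm3(1) # ~0.602
#' @export
mol_per_L_to_per_nm3 <- function(mol_per_L) {
  stopifnot(is.numeric(mol_per_L), all(mol_per_L >= 0))
  mol_per_L * phys_constants$N_A * 1e-24
}

#' @rdname mol_per_L_to_per_nm3
#' @param per_nm3 concentration in ions/nm^3.
#' @export
per_nm3_to_mol_per_L <- function(per_nm3) {
  stopifnot(is.numeric(per_nm3), all(per_nm3 >= 0))
  per_nm3 / (phys_constants$N_A * 1e-24)
}

## kBT in joules at temperature T (K)
kBT_joule <- function(temperature) phys_constants$kB * temperature

## kBT in eV at temperature T (K)
kBT_eV <- function(temperature) {
  kBT_joule(temperature) / phys_constants$e
}
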