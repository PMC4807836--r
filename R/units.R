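#' Physical constants and unit conversions
#'
#' All unit handling in the package funnels through this table so that the
#' mixed unit systems of the pipeline stay consistent: atomic units for
#' Hessians, electric fields and multipoles; Angstrom for geometry I/O;
#' atomic mass units for masses; cm^-1 for vibrational frequencies;
#' kcal/mol for sampled potential energies.
#'
#' Values are CODATA 2018.
#'
#' @format A named list of conversion factors and constants:
#' \describe{
#'   \item{bohr_to_angstrom}{Bohr radius in Angstrom}
#'   \item{hartree_to_kcal_mol}{Hartree in kcal/mol}
#'   \item{hartree_to_cm1}{Hartree in cm^-1 (hc nu-tilde = E)}
#'   \item{hartree_to_ev}{Hartree in eV}
#'   \item{amu_to_me}{atomic mass unit in electron masses}
#'   \item{cm1_to_mev}{1 cm^-1 in meV}
#'   \item{kB_kcal_mol_K}{Boltzmann constant expressed per mole, kcal/(mol K)}
#'   \item{R_kcal_mol_K}{gas constant, kcal/(mol K)}
#'   \item{hbar_Js}{reduced Planck constant, J s}
#'   \item{kB_JK}{Boltzmann constant, J/K}
#'   \item{avogadro}{Avogadro number}
#'   \item{kcal_mol_to_J}{1 kcal/mol in J per molecule}
#'   \item{coulomb_kcal}{electrostatic constant, kcal mol^-1 Angstrom e^-2}
#' }
#' @export
vibrolf_constants <- list(
  bohr_to_angstrom    = 0.529177210903,
  hartree_to_kcal_mol = 627.509474063,
  hartree_to_cm1      = 219474.6313632,
  hartree_to_ev       = 27.211386245988,
  amu_to_me           = 1822.888486209,
  cm1_to_mev          = 0.1239841984,
  kB_kcal_mol_K       = 0.0019872043,
  R_kcal_mol_K        = 0.0019872043,
  hbar_Js             = 1.054571817e-34,
  kB_JK               = 1.380649e-23,
  avogadro            = 6.02214076e23,
  kcal_mol_to_J       = 4184 / 6.02214076e23,
  coulomb_kcal        = 332.0636,
  # IR intensity prefactor: km/mol per (e^2/amu) of |dmu/dQ|^2, from
  # A = N_A e^2 / (12 eps0 c^2 amu) (SI), expressed in km/mol.
  ir_km_mol_per_e2_amu = local({
    NA_  <- 6.02214076e23      # 1/mol
    e    <- 1.602176634e-19    # C
    amu  <- 1.66053906660e-27  # kg
    c    <- 299792458          # m/s
    eps0 <- 8.8541878128e-12   # F/m
    NA_ * e^2 / (12 * eps0 * c^2 * amu) / 1000
  })
)

#' Convert energies between supported units
#'
#' @param x numeric vector of energies.
#' @param from,to one of `"hartree"`, `"kcal_mol"`, `"ev"`, `"cm1"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "kcal_mol")
#' @export
convert_energy <- function(x, from, to) {
  to_hartree <- c(
    hartree = 1,
    kcal_mol = 1 / vibrolf_constants$hartree_to_kcal_mol,
    ev = 1 / vibrolf_constants$hartree_to_ev,
    cm1 = 1 / vibrolf_constants$hartree_to_cm1
  )
  from <- match.arg(from, names(to_hartree))
  to <- match.arg(to, names(to_hartree))
  x * to_hartree[[from]] / to_hartree[[to]]
}

#' Convert lengths between Bohr and Angstrom
#'
#' @param x numeric vector of lengths.
#' @param from,to `"bohr"` or `"angstrom"`.
#' @return numeric vector in the target unit.
#' @export
convert_length <- function(x, from = c("angstrom", "bohr"),
                           to = c("bohr", "angstrom")) {
  from <- match.arg(from)
  to <- match.arg(to)
  if (from == to) return(x)
  if (from == "angstrom") x / vibrolf_constants$bohr_to_angstrom
  else x * vibrolf_constants$bohr_to_angstrom
}
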