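#' Physical parameter table for the coarse-grained model
#'
#' Bundles the constants the bead model needs: average residue masses,
#' the titration reaction list with pKa values, the average amino-acid
#' density used to size beads, the solvent dielectric constant,
#' temperature, and the monomer hydrodynamic radius used to normalise
#' the second virial coefficient.
#'
#' @param temperature Temperature in kelvin.
#' @param epsilon_r Relative dielectric constant of the solvent
#'   (dimensionless); 80 corresponds to water treated as a homogeneous
#'   continuum.
#' @param density Average amino-acid density in g/mol/A^3 used to derive
#'   bead diameters from residue masses.
#' @param hydrodynamic_radius Monomer hydrodynamic radius R_h in angstrom.
#'
#' @return An object of class `parameter_table`: a list with elements
#'   `residue_mass` (named numeric, g/mol, average masses of the 20
#'   standard residues), `pka_table` (data frame with columns `species`,
#'   `pka`, `kind` where `kind` is `"acid"` or `"base"`), `density`,
#'   `epsilon_r`, `temperature`, `hydrodynamic_radius`, and `water_mass`
#'   (mass of one water, added once when reporting a protein molecular
#'   weight).
#' @export
#' @examples
#' p <- parameter_table()
#' p$pka_table
parameter_table <- function(temperature = 298.15, epsilon_r = 80,
                            density = 1, hydrodynamic_radius = 22.71) {
  stopifnot(temperature > 0, epsilon_r > 0, density > 0,
            hydrodynamic_radius > 0)
  structure(list(
    residue_mass = .residue_masses,
    pka_table = .pka_table(),
    density = density,
    epsilon_r = epsilon_r,
    temperature = temperature,
    hydrodynamic_radius = hydrodynamic_radius,
    water_mass = 18.01528
  ), class = "parameter_table")
}

# average (not monoisotopic) residue masses, g/mol
.residue_masses <- c(
  ALA = 71.0788,  ARG = 156.1875, ASN = 114.1038, ASP = 115.0886,
  CYS = 103.1388, GLN = 128.1307, GLU = 129.1155, GLY = 57.0519,
  HIS = 137.1411, ILE = 113.1594, LEU = 113.1594, LYS = 128.1741,
  MET = 131.1926, PHE = 147.1766, PRO = 97.1167,  SER = 87.0782,
  THR = 101.1051, TRP = 186.2132, TYR = 163.1760, VAL = 99.1326
)

# element masses for residue centre-of-mass weighting
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, SE = 78.971, P = 30.974)

# nine titration reactions HA <-> H + A with their pKa values; acids carry
# charge 0 protonated / -1 deprotonated, bases +1 / 0
.pka_table <- function() {
  data.frame(
    species = c("CTR", "ASP", "GLU", "HIS", "NTR", "CYS", "TYR", "LYS", "ARG"),
    pka     = c(3.67,  3.67,  4.25,  6.54,  8.0,   8.55,  9.84,  10.4,  12.0),
    kind    = c("acid", "acid", "acid", "base", "base", "acid", "acid",
                "base", "base"),
    stringsAsFactors = FALSE
  )
}

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
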