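#' Solution condition
#'
#' Fixes pH, ionic strength, dielectric constant and temperature, and
#' derives the Debye screening length and Bjerrum length used by every
#' energy routine.
#'
#' @param ph Solution pH.
#' @param ionic_strength Ionic strength in mol/L (1:1 electrolyte);
#'   0 means unscreened Coulomb electrostatics.
#' @param epsilon_r Relative dielectric constant.
#' @param temperature Temperature, K.
#' @return A `solution_condition` list with `ph`, `ionic_strength`,
#'   `debye_length` (A, `Inf` when unscreened), `kappa` (1/A, inverse Debye
#'   length, 0 when unscreened), `bjerrum` (A), `epsilon_r`, `temperature`.
#' @export
solution_condition <- function(ph, ionic_strength = 0, epsilon_r = 80,
                               temperature = 298.15) {
  lambda <- debye_length(ionic_strength)
  structure(list(
    ph = ph, ionic_strength = ionic_strength,
    debye_length = lambda,
    kappa = if (is.finite(lambda)) 1 / lambda else 0,
    bjerrum = bjerrum_length(epsilon_r, temperature),
    epsilon_r = epsilon_r, temperature = temperature
  ), class = "solution_condition")
}

#' Debye screening length of a 1:1 electrolyte
#'
#' `lambda = 3.04 / sqrt(I)` angstrom for water at room temperature, with
#' `I` in molar units; at `I = 0` the electrostatics are unscreened and
#' `Inf` is returned.
#'
#' @param ionic_strength Ionic strength, mol/L.
#' @return Debye length in angstrom (`Inf` for 0 ionic strength).
#' @export
#' @examples
#' debye_length(0.140) # physiological saline, ~8.13 A
debye_length <- function(ionic_strength) {
  if (any(ionic_strength < 0))
    stop("ionic strength must be >= 0", call. = FALSE)
  ifelse(ionic_strength == 0, Inf, 3.04 / sqrt(ionic_strength))
}

#' Bjerrum length
#'
#' Separation at which two unit charges interact with exactly k_B T:
#' `lambda_B = e^2 / (4 pi eps0 eps_r k_B T)`; about 7.0 A in water at
#' 298.15 K.
#'
#' @param epsilon_r Relative dielectric constant.
#' @param temperature Temperature, K.
#' @return Bjerrum length in angstrom.
#' @export
bjerrum_length <- function(epsilon_r = 80, temperature = 298.15) {
  stopifnot(epsilon_r > 0, temperature > 0)
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  kb <- 1.380649e-23        # J/K
  1e10 * e^2 / (4 * pi * eps0 * epsilon_r * kb * temperature)
}

#' Screened Coulomb pair energy between two point charges
#'
#' `u = lambda_B z_i z_j exp(-r / lambda) / r` in units of k_B T; the
#' exponential factor is 1 when the condition is unscreened.
#'
#' @param z_i,z_j Charges in units of e.
#' @param r Separation, A (> 0).
#' @param cond A [solution_condition()].
#' @return Energy in k_B T.
#' @export
pair_electrostatic <- function(z_i, z_j, r, cond) {
  if (any(r <= 0)) stop("overlapping point charges (r <= 0)", call. = FALSE)
  cond$bjerrum * z_i * z_j * exp(-cond$kappa * r) / r
}

#' Lorentz-Berthelot mixing rules
#'
#' Arithmetic mean for the contact distance, geometric mean for the well
#' depth.
#'
#' @param sigma_ii,sigma_jj Self contact distances, A.
#' @param eps_ii,eps_jj Self well depths, k_B T.
#' @return List with `sigma` and `eps`.
#' @export
mix_pair_params <- function(sigma_ii, sigma_jj, eps_ii, eps_jj) {
  stopifnot(all(sigma_ii > 0), all(sigma_jj > 0),
            all(eps_ii > 0), all(eps_jj > 0))
  list(sigma = (sigma_ii + sigma_jj) / 2, eps = sqrt(eps_ii * eps_jj))
}

#' Lennard-Jones pair energy (van der Waals + excluded volume)
#'
#' `u = 4 eps [(sigma/r)^12 - (sigma/r)^6]`; the repulsive r^-12 branch
#' plays the role of the excluded-volume term, the r^-6 branch the
#' dispersion attraction.
#'
#' @param r Separation, A (> 0).
#' @param sigma_ij Mixed contact distance, A.
#' @param eps_ij Mixed well depth, k_B T.
#' @return Energy in k_B T.
#' @export
pair_vdw <- function(r, sigma_ij, eps_ij) {
  stopifnot(all(r > 0))
  sr6 <- (sigma_ij / r)^6
  4 * eps_ij * (sr6^2 - sr6)
}

#' Total cross energy between two rigid proteins
#'
#' Sum of screened-Coulomb plus Lennard-Jones terms over all inter-protein
#' bead pairs (intra-protein terms are constant for rigid bodies and
#' excluded). Evaluated in compiled code; symmetric in its arguments.
#'
#' @param model_a,model_b `protein_model` objects with charges assigned.
#' @param cond A [solution_condition()].
#' @param eps Uniform Lennard-Jones self well depth eps_ii, k_B T.
#' @return Energy in k_B T.
#' @export
cross_energy <- function(model_a, model_b, cond, eps = 0.05) {
  a <- model_a$beads; b <- model_b$beads
  u <- cpp_cross_energy(
    as.matrix(a[, c("x", "y", "z")]), a$charge, a$sigma,
    as.matrix(b[, c("x", "y", "z")]), b$charge, b$sigma,
    cond$bjerrum, cond$kappa, eps)
  if (!is.finite(u)) stop("coincident inter-protein beads", call. = FALSE)
  u
}
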