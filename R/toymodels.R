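#' Toy charge-distribution models
#'
#' Deterministic miniature "proteins" with known multipoles, plus seeded
#' random charge sets, used as oracles for the energy, multipole and
#' virial machinery. Beads default to unit LJ diameter and carry fixed
#' charges (no titratable sites).
#'
#' @param kind One of `"point-charge"`, `"ideal-dipole"`,
#'   `"linear-quadrupole"`, `"random-charge-set"`.
#' @param q Charge magnitude, e.
#' @param d Geometric spacing, A.
#' @param n Number of beads for the random kind.
#' @param extent Half-width of the random coordinate cube, A.
#' @param sigma Bead diameter, A.
#' @param mass Bead mass, g/mol (bookkeeping only).
#' @param seed Seed for the random kind.
#' @return A `protein_model` (with an empty site table).
#' @export
#' @examples
#' geometry(make_toy("ideal-dipole", q = 1, d = 10))
make_toy <- function(kind = c("point-charge", "ideal-dipole",
                              "linear-quadrupole", "random-charge-set"),
                     q = 1, d = 10, n = 4, extent = 5, sigma = 4,
                     mass = 110, seed = 1) {
  kind <- match.arg(kind)
  if (kind != "point-charge" && d <= 0)
    stop("coincident charges: spacing must be positive", call. = FALSE)
  tab <- switch(kind,
    "point-charge" = data.frame(x = 0, y = 0, z = 0, charge = q),
    "ideal-dipole" = data.frame(x = 0, y = 0, z = c(d / 2, -d / 2),
                                charge = c(q, -q)),
    "linear-quadrupole" = data.frame(x = 0, y = 0, z = c(-d, 0, d),
                                     charge = c(q, -2 * q, q)),
    "random-charge-set" = {
      rng <- .lcg_runif(6 * n, seed)
      data.frame(x = extent * (2 * rng[1:n] - 1),
                 y = extent * (2 * rng[n + 1:n] - 1),
                 z = extent * (2 * rng[2 * n + 1:n] - 1),
                 charge = round(2 * (2 * rng[3 * n + 1:n] - 1)) / 2)
    })
  .toy_model(tab, sigma, mass)
}

# tiny deterministic uniform generator so toys do not disturb R's RNG
.lcg_runif <- function(n, seed) {
  s <- as.double(seed %% 2147483647)
  if (s <= 0) s <- s + 2147483646
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- (s * 16807) %% 2147483647
    out[i] <- s / 2147483647
  }
  out
}

.toy_model <- function(tab, sigma, mass) {
  n <- nrow(tab)
  beads <- data.frame(index = seq_len(n), resno = seq_len(n),
                      resid = rep("TOY", n), x = tab$x, y = tab$y,
                      z = tab$z, mass = mass, sigma = sigma,
                      charge = tab$charge, stringsAsFactors = FALSE)
  sites <- data.frame(bead = integer(), species = character(),
                      pka = numeric(), kind = character(),
                      occupancy = numeric(), stringsAsFactors = FALSE)
  structure(list(beads = beads, sites = sites, mass = n * mass,
                 mw = n * mass, n_residues = n,
                 params = parameter_table()),
            class = "protein_model")
}

#' Minimal PDB text for a toy peptide
#'
#' Writes backbone (N, CA, C, O) plus CB atoms of an extended chain for a
#' one-letter sequence; valid enough to round-trip through
#' [parse_structure()] and [coarsen()]. Geometry is an idealized extended
#' template, not stereochemistry.
#'
#' @param sequence One-letter amino-acid string.
#' @return Character scalar of PDB-format text.
#' @export
make_toy_peptide_pdb <- function(sequence) {
  aa1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa1) < 1) stop("empty sequence", call. = FALSE)
  bad <- setdiff(aa1, names(.aa1to3))
  if (length(bad)) stop("unknown amino acid letter(s): ",
                        paste(unique(bad), collapse = ", "), call. = FALSE)
  res3 <- .aa1to3[aa1]
  # extended template: residue i spans x = 3.5 * i, small offsets per atom
  offs <- list(N = c(-1.2, 0.5, 0), CA = c(0, 0, 0), C = c(1.3, 0.4, 0),
               O = c(1.4, 1.6, 0.2), CB = c(-0.2, -1.0, 1.1))
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(res3)) {
    atoms <- if (res3[i] == "GLY") c("N", "CA", "C", "O")
             else c("N", "CA", "C", "O", "CB")
    for (a in atoms) {
      serial <- serial + 1L
      p <- c(3.5 * i, 0.8 * (i %% 2), 0) + offs[[a]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, a, res3[i], i, p[1], p[2], p[3], substr(a, 1, 1)))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Brute-force Coulomb cross energy (oracle)
#'
#' Explicit double loop over all inter-protein bead pairs, written in R
#' independently of the compiled energy path; screened or unscreened
#' according to the condition. Electrostatics only (no Lennard-Jones).
#'
#' @param model_a,model_b `protein_model` objects.
#' @param cond A [solution_condition()].
#' @return Energy in k_B T.
#' @export
brute_force_coulomb <- function(model_a, model_b, cond) {
  a <- model_a$beads; b <- model_b$beads
  u <- 0
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      r <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (r < 1e-9) stop("coincident beads", call. = FALSE)
      u <- u + cond$bjerrum * a$charge[i] * b$charge[j] *
        exp(-cond$kappa * r) / r
    }
  u
}

#' Closed-form second virial coefficients (oracle)
#'
#' Hard sphere: `B2 = 2 pi sigma^3 / 3`. Square well of depth `eps0`
#' (k_B T) on `(sigma, lambda sigma)`:
#' `B2 = (2 pi sigma^3 / 3) [1 - (lambda^3 - 1)(exp(eps0) - 1)]`.
#'
#' @param kind `"hard-sphere"` or `"square-well"`.
#' @param sigma Hard-core diameter, A.
#' @param lambda Well width multiplier (> 1), square-well only.
#' @param eps0 Well depth, k_B T, square-well only.
#' @return B2 in A^3.
#' @export
closed_form_b2 <- function(kind = c("hard-sphere", "square-well"),
                           sigma, lambda = 1.5, eps0 = 0.5) {
  kind <- match.arg(kind)
  stopifnot(sigma > 0)
  hs <- 2 * pi * sigma^3 / 3
  if (kind == "hard-sphere") return(hs)
  if (lambda <= 1) stop("square well needs lambda > 1", call. = FALSE)
  hs * (1 - (lambda^3 - 1) * (exp(eps0) - 1))
}
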