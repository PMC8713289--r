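#' Parse ATOM records from PDB text
#'
#' Thin wrapper around [bio3d::read.pdb()] that applies the conventions the
#' coarse-graining step expects: only `ATOM` records of the first model are
#' kept (a warning is emitted when several NMR models are present), waters
#' and `HETATM` records are dropped, and for alternate locations only the
#' first one ("A" or blank) is retained.
#'
#' @param pdb_text Character scalar (or vector of lines) holding PDB-format
#'   text, or a path to a PDB file.
#' @return A data frame of atom records with columns `resno`, `resid`,
#'   `chain`, `elety` (atom name), `elesy` (element symbol), `x`, `y`, `z`,
#'   `o` (occupancy), ordered as in the file and grouped per residue.
#' @export
parse_structure <- function(pdb_text) {
  path <- pdb_text
  if (length(pdb_text) > 1L || grepl("\n", pdb_text, fixed = TRUE) ||
      !file.exists(pdb_text[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb_text) > 1L) pdb_text
               else strsplit(pdb_text, "\n", fixed = TRUE)[[1]], path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("no parseable ATOM records in PDB input: ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (nrow(at) == 0L)
    stop("no parseable ATOM records in PDB input", call. = FALSE)
  # first alternate location only
  if (!is.null(at$alt)) {
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep, , drop = FALSE]
  }
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    warning("multiple models in PDB input; using model 1", call. = FALSE)
  at$elesy <- .infer_element(at$elesy, at$elety)
  rownames(at) <- NULL
  at[, c("resno", "resid", "chain", "elety", "elesy", "x", "y", "z", "o")]
}

.infer_element <- function(elesy, elety) {
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  bad <- !(elesy %in% names(.element_masses))
  # fall back on the first alphabetic character of the atom name
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                               sub("^[0-9]*", "", elety)), 1, 1))
  elesy[bad] <- guess[bad]
  elesy
}

#' Bead diameter from residue mass
#'
#' The bead representing a residue is the sphere whose volume equals the
#' residue's molar volume `M_w / rho`, so the diameter is
#' `sigma = 2 * (3 M_w / (4 pi rho))^(1/3)`.
#'
#' @param m_w Residue mass, g/mol.
#' @param rho Average amino-acid density, g/mol/A^3 (default 1).
#' @return Bead diameter in angstrom.
#' @export
#' @examples
#' bead_sigma(57.05) # glycine, about 4.78 A
bead_sigma <- function(m_w, rho = 1) {
  if (any(m_w <= 0) || any(rho <= 0))
    stop("bead_sigma() needs positive mass and density", call. = FALSE)
  2 * (3 * m_w / (4 * pi * rho))^(1 / 3)
}

#' Coarse-grain parsed atoms to one bead per residue
#'
#' Each residue becomes a spherical bead at the element-mass-weighted mean
#' position of its atoms; the bead mass is the average residue mass of its
#' amino-acid type and its diameter follows from [bead_sigma()]. Titratable
#' sites (side chains of ASP, GLU, HIS, CYS, TYR, LYS, ARG plus the N- and
#' C-terminal sites on the first and last bead) are annotated for the
#' constant-pH machinery.
#'
#' @param atoms Data frame from [parse_structure()].
#' @param params A [parameter_table()].
#' @param exclude_sites Integer vector of residue ordinals whose side-chain
#'   site should not titrate (e.g. disulfide-bonded cysteines); terminal
#'   sites are never excluded this way.
#' @return A `protein_model`: list with `beads` (data frame: `index`,
#'   `resno`, `resid`, `x`, `y`, `z`, `mass`, `sigma`, `charge`), `sites`
#'   (data frame of titratable sites: `bead`, `species`, `pka`, `kind`,
#'   `occupancy`), `mass` (total, g/mol), `mw` (protein molecular weight,
#'   total + one water) and `n_residues`.
#' @export
coarsen <- function(atoms, params = parameter_table(),
                    exclude_sites = integer()) {
  key <- paste(atoms$chain, atoms$resno)
  key <- factor(key, levels = unique(key))
  resid3 <- tapply(atoms$resid, key, function(r) r[1])
  unknown <- setdiff(unique(resid3), names(params$residue_mass))
  if (length(unknown))
    stop("unknown residue type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  groups <- split(seq_len(nrow(atoms)), key)
  pos <- t(vapply(groups, function(idx) {
    w <- .element_masses[atoms$elesy[idx]]
    if (any(is.na(w)) || sum(w) <= 0)
      stop("residue with unweighable atoms at rows ",
           paste(idx, collapse = ","), call. = FALSE)
    c(sum(w * atoms$x[idx]), sum(w * atoms$y[idx]), sum(w * atoms$z[idx])) /
      sum(w)
  }, numeric(3)))
  n <- length(groups)
  mass <- unname(params$residue_mass[resid3])
  beads <- data.frame(
    index = seq_len(n),
    resno = vapply(groups, function(idx) atoms$resno[idx][1], numeric(1)),
    resid = as.character(resid3),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    mass = mass,
    sigma = bead_sigma(mass, params$density),
    charge = 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  sites <- .titratable_sites(beads$resid, params, exclude_sites)
  model <- structure(list(
    beads = beads, sites = sites,
    mass = sum(mass), mw = sum(mass) + params$water_mass,
    n_residues = n, params = params
  ), class = "protein_model")
  set_site_occupancy(model, sites$occupancy)
}

# side-chain + terminal titratable sites, in bead order
.titratable_sites <- function(resid3, params, exclude_sites = integer()) {
  pka <- params$pka_table
  rownames(pka) <- pka$species
  n <- length(resid3)
  side <- which(resid3 %in% pka$species & !(seq_len(n) %in% exclude_sites))
  sites <- data.frame(
    bead = c(1L, side, n),
    species = c("NTR", resid3[side], "CTR"),
    stringsAsFactors = FALSE
  )
  sites$pka <- pka[sites$species, "pka"]
  sites$kind <- pka[sites$species, "kind"]
  # start fully protonated: acids neutral, bases +1
  sites$occupancy <- 1
  sites[order(sites$bead, sites$species), , drop = FALSE] -> sites
  rownames(sites) <- NULL
  sites
}

#' Set protonation occupancies and refresh bead charges
#'
#' @param model A `protein_model`.
#' @param occupancy Numeric vector in `[0, 1]`, one entry per titratable
#'   site (1 = protonated). Fractional values encode fixed average charges.
#' @return The model with updated `sites$occupancy` and `beads$charge`.
#' @export
set_site_occupancy <- function(model, occupancy) {
  stopifnot(length(occupancy) == nrow(model$sites),
            all(occupancy >= 0 & occupancy <= 1))
  model$sites$occupancy <- occupancy
  z_site <- ifelse(model$sites$kind == "acid", occupancy - 1, occupancy)
  z <- numeric(nrow(model$beads))
  agg <- tapply(z_site, model$sites$bead, sum)
  z[as.integer(names(agg))] <- agg
  model$beads$charge <- z
  model
}

#' Centre of mass, radius of gyration, net charge and dipole of a model
#'
#' @param model A `protein_model`.
#' @return List with `com` (length-3, A), `rg` (A), `q` (net charge, e) and
#'   `mu` (dipole vector about the centre of mass, eA).
#' @export
geometry <- function(model) {
  b <- model$beads
  if (nrow(b) == 0L) stop("empty model", call. = FALSE)
  r <- as.matrix(b[, c("x", "y", "z")])
  com <- colSums(b$mass * r) / sum(b$mass)
  d <- sweep(r, 2, com)
  list(
    com = com,
    rg = sqrt(sum(b$mass * rowSums(d^2)) / sum(b$mass)),
    q = sum(b$charge),
    mu = colSums(b$charge * d)
  )
}

#' @export
print.protein_model <- function(x, ...) {
  g <- geometry(x)
  cat(sprintf(
    "protein_model: %d beads, MW %.2f kDa, Rg %.2f A, %d titratable sites\n",
    x$n_residues, x$mw / 1000, g$rg, nrow(x$sites)))
  cat(sprintf("  net charge %+.3f e, |dipole| %.2f eA\n",
              g$q, sqrt(sum(g$mu^2))))
  invisible(x)
}

#' Write the bead table to CSV
#'
#' @param model A `protein_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bead_table <- function(model, path) {
  tab <- model$beads
  sp <- tapply(model$sites$species, model$sites$bead,
               paste, collapse = "+")
  tab$titratable <- ""
  tab$titratable[as.integer(names(sp))] <- sp
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
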