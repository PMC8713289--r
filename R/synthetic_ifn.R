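#' Synthetic interferon alpha-2a reference structure
#'
#' The package's reference protein is human interferon alpha-2a
#' (IFN-alpha-2a), a 165-residue, 19.24 kDa five-helix-bundle cytokine.
#' Because the experimental coordinates are an external download, the
#' package ships a SYNTHETIC stand-in built at run time: the true mature
#' amino-acid sequence threaded onto an idealized five-helix-bundle CA
#' trace (ideal alpha-helix geometry on helix segments, straight
#' interpolated loops). Sequence-derived properties (residue count,
#' molecular weight, titratable-site composition, charge-vs-pH, pI) are
#' those of the real protein; the three-dimensional charge geometry, and
#' hence dipole and quadrupole magnitudes, are an idealization.
#'
#' @return `ifn_alpha2a_sequence()`: the one-letter mature sequence
#'   (character scalar, 165 residues).
#' @export
ifn_alpha2a_sequence <- function() {
  paste0(
    "CDLPQTHSLGSRRTLMLLAQMRKISLFSCLKDRHDFGFPQEEFGNQFQKA",
    "ETIPVLHEMIQQIFNLFSTKDSSAAWDETLLDKFYTELYQQLNDLEACVI",
    "QGVGVTETPLMKEDSILAVRKYFQRITLYLKEKKYSPCAWEVVRAEIMRS",
    "FSLSTNLQESLRSKE")
}

# approximate helix segments of the five-helix bundle (residue ranges)
.ifn_helices <- list(A = c(10, 21), B = c(53, 68), C = c(78, 100),
                     D = c(110, 132), E = c(137, 158))

#' @describeIn ifn_alpha2a_sequence PDB-format text of the synthetic CA
#'   trace (one CA atom per residue). Deterministic.
#' @export
ifn_alpha2a_synthetic_pdb <- function() {
  seq1 <- strsplit(ifn_alpha2a_sequence(), "")[[1]]
  n <- length(seq1)
  coords <- .helix_bundle_trace(n, .ifn_helices)
  res3 <- .aa1to3[seq1]
  lines <- vapply(seq_len(n), function(i) sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    i, res3[i], i, coords[i, 1], coords[i, 2], coords[i, 3]),
    character(1))
  paste(c(lines, "END"), collapse = "\n")
}

# idealized bundle trace: helices wound around five axes placed on a
# circle, alternating up/down; loops interpolated with an outward bow;
# terminal tails wrapped along the bundle surface (real termini pack
# against the bundle; rigid protruding tails would be unphysical). Each
# bead is displaced ~1.9 A outward from its local helix axis (helices) or
# from the molecular axis (loops/tails) to approximate the residue
# centre of mass sitting beyond the backbone towards the side chain.
.helix_bundle_trace <- function(n, helices) {
  bundle_r <- 9.5   # bundle radius, A
  helix_r <- 2.3    # alpha-helix CA radius, A
  side_off <- 1.9   # backbone -> residue-centroid outward offset, A
  rise <- 1.5       # rise per residue, A
  turn <- 100 * pi / 180
  nh <- length(helices)
  phis <- 2 * pi * (seq_len(nh) - 1) / nh
  coords <- matrix(NA_real_, n, 3)
  for (h in seq_len(nh)) {
    rng <- helices[[h]]
    len <- rng[2] - rng[1] + 1
    up <- (h %% 2) == 1
    cx <- bundle_r * cos(phis[h]); cy <- bundle_r * sin(phis[h])
    for (k in seq_len(len)) {
      i <- rng[1] + k - 1
      zk <- (k - (len + 1) / 2) * rise * (if (up) 1 else -1)
      ang <- turn * k + phis[h]
      coords[i, ] <- c(cx + (helix_r + side_off) * cos(ang),
                       cy + (helix_r + side_off) * sin(ang), zk)
    }
  }
  assigned <- which(!is.na(coords[, 1]))
  first <- assigned[1]; last <- assigned[length(assigned)]
  surf_r <- bundle_r + helix_r + side_off
  wrap_tail <- function(anchor, steps, z_dir) {
    # walk along the cylinder surface from the anchor's azimuth
    phi0 <- atan2(anchor[2], anchor[1])
    out <- matrix(0, steps, 3)
    for (s in seq_len(steps)) {
      phi <- phi0 + 3.8 / surf_r * s
      out[s, ] <- c(surf_r * cos(phi), surf_r * sin(phi),
                    anchor[3] + z_dir * 1.2 * s)
    }
    out
  }
  if (first > 1) {
    tail <- wrap_tail(coords[first, ], first - 1,
                      z_dir = -sign(coords[first, 3] + 1e-9))
    coords[(first - 1):1, ] <- tail
  }
  if (last < n) {
    tail <- wrap_tail(coords[last, ], n - last,
                      z_dir = -sign(coords[last, 3] + 1e-9))
    coords[(last + 1):n, ] <- tail
  }
  gaps <- which(is.na(coords[, 1]))
  while (length(gaps)) {
    g0 <- gaps[1]
    g1 <- g0
    while ((g1 + 1) %in% gaps) g1 <- g1 + 1
    a <- coords[g0 - 1, ]; b <- coords[g1 + 1, ]
    m <- g1 - g0 + 2
    for (i in g0:g1) {
      t <- (i - g0 + 1) / m
      # outward bow so loop beads skirt the bundle surface
      mid <- a + t * (b - a)
      out <- mid[1:2]
      nrm <- sqrt(sum(out^2))
      if (nrm > 1e-6) mid[1:2] <- out * (1 + 0.25 * sin(pi * t) * 8 / nrm)
      coords[i, ] <- mid
    }
    gaps <- setdiff(gaps, g0:g1)
  }
  # fixed deterministic irregularity: real residue centroids scatter about
  # any idealized fold; a perfectly periodic bundle would let two copies
  # dock in unphysical complementary register
  jit <- 1.4 * (2 * matrix(.lcg_runif(3 * n, seed = 20130), n, 3) - 1)
  coords + jit
}

#' @describeIn ifn_alpha2a_sequence Coarse-grained `protein_model` of the
#'   synthetic structure (parsed and coarsened through the standard
#'   pipeline).
#' @param params A [parameter_table()].
#' @param exclude_sites Residue ordinals excluded from titration (see
#'   [coarsen()]); all four cysteines titrate by default.
#' @export
ifn_alpha2a_model <- function(params = parameter_table(),
                              exclude_sites = integer()) {
  coarsen(parse_structure(ifn_alpha2a_synthetic_pdb()), params,
          exclude_sites = exclude_sites)
}
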