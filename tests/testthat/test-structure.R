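test_that("bead diameter is the volume-equivalent sphere diameter", {
  expect_equal(bead_sigma(4 * pi / 3, 1), 2)
  expect_equal(bead_sigma(57.05), 2 * (3 * 57.05 / (4 * pi))^(1 / 3),
               tolerance = 1e-12)
  expect_equal(bead_sigma(57.05), 4.776, tolerance = 1e-3)
  m <- seq(50, 200, by = 10)
  expect_true(all(diff(bead_sigma(m)) > 0))
  expect_error(bead_sigma(-1), "positive")
  expect_error(bead_sigma(10, 0), "positive")
  # all 20 residue diameters within the physically sensible window
  sig <- bead_sigma(parameter_table()$residue_mass)
  expect_true(all(sig > 3 & sig < 8))
})

test_that("parameter table carries the nine titration reactions", {
  p <- parameter_table()
  expect_equal(nrow(p$pka_table), 9)
  expect_setequal(p$pka_table$species,
                  c("CTR", "ASP", "GLU", "HIS", "NTR", "CYS", "TYR",
                    "LYS", "ARG"))
  expect_equal(p$pka_table$pka[p$pka_table$species == "HIS"], 6.54)
  expect_equal(p$pka_table$pka[p$pka_table$species == "ARG"], 12.0)
  expect_true(all(p$residue_mass > 0))
})

test_that("toy peptide fixture parses and coarsens with conservation", {
  txt <- two_bead_pdb()
  at <- parse_structure(txt)
  expect_equal(length(unique(at$resno)), 2)
  expect_setequal(unique(at$resid), c("GLY", "ALA"))
  p <- parameter_table()
  m <- coarsen(at, p)
  expect_equal(m$n_residues, 2)
  expect_equal(m$mass, unname(p$residue_mass["GLY"] + p$residue_mass["ALA"]))
  # model COM is the bead-mass-weighted mean of bead positions
  g <- geometry(m)
  expect_equal(g$com,
               colSums(m$beads$mass * as.matrix(m$beads[, c("x", "y", "z")])) /
                 sum(m$beads$mass))
  # coarsening is deterministic
  expect_identical(m$beads, coarsen(parse_structure(txt), p)$beads)
})

test_that("residue bead sits at the element-mass-weighted mean position", {
  # hand-built glycine with four heavy atoms at chosen coordinates
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       1.000   2.000   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.000   2.000   4.000  1.00  0.00           O",
    "END")
  m <- coarsen(parse_structure(paste(lines, collapse = "\n")))
  w <- c(N = 14.007, C = 12.011, C = 12.011, O = 15.999)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0), c(1, 2, 4))
  expected <- colSums(w * xyz) / sum(w)
  expect_equal(unlist(m$beads[1, c("x", "y", "z")], use.names = FALSE),
               expected, tolerance = 1e-6)
})

test_that("alternate locations keep only the first conformer", {
  lines <- c(
    "ATOM      1  N   SER A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BSER A   1       9.000   9.000   9.000  0.50  0.00           C",
    "END")
  at <- parse_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(at), 2)
  expect_false(any(at$x == 9))
})

test_that("parse errors are structured", {
  expect_error(parse_structure("REMARK nothing here\nEND"), "ATOM")
  bad <- "ATOM      1  CA  XXX A   1       0.000   0.000   0.000  1.00  0.00           C"
  expect_error(coarsen(parse_structure(bad)), "XXX")
})

test_that("terminal beads carry NTR/CTR sites on top of side-chain sites", {
  m <- coarsen(parse_structure(make_toy_peptide_pdb("KKD")))
  expect_setequal(m$sites$species, c("NTR", "LYS", "ASP", "CTR"))
  expect_equal(sum(m$sites$species == "LYS"), 2)
  expect_equal(m$sites$bead[m$sites$species == "NTR"], 1)
  expect_equal(m$sites$bead[m$sites$species == "CTR"], 3)
  # per-bead site multiplicity bounds the charge
  m2 <- set_site_occupancy(m, rep(1, nrow(m$sites)))
  expect_true(all(abs(m2$beads$charge) <= 2))
})

test_that("geometry returns charge, dipole and Rg as defined", {
  toy <- make_toy("ideal-dipole", q = 1, d = 10)
  g <- geometry(toy)
  expect_equal(g$q, 0)
  expect_equal(sqrt(sum(g$mu^2)), 10)
  one <- make_toy("point-charge", q = 2)
  expect_equal(sqrt(sum(geometry(one)$mu^2)), 0)
  # |mu| of a neutral model is invariant under rigid translation
  for (s in 1:5) {
    t1 <- make_toy("linear-quadrupole", q = 1, d = 4 + s)
    t2 <- shift_model(t1, dx = 3 * s, dy = -7, dz = 11)
    expect_equal(sqrt(sum(geometry(t1)$mu^2)), sqrt(sum(geometry(t2)$mu^2)),
                 tolerance = 1e-10)
  }
})

test_that("synthetic reference structure round-trips through the pipeline", {
  m <- ifn_model_cached()
  expect_equal(m$n_residues, 165)
  expect_equal(m$mw / 1000, 19.24, tolerance = 1e-3)
  expect_true(all(m$beads$sigma > 3 & m$beads$sigma < 8))
  expect_equal(nrow(m$sites),
               sum(m$beads$resid %in%
                     parameter_table()$pka_table$species) + 2)
  # excluding the four cysteines removes exactly four side-chain sites
  cys <- which(m$beads$resid == "CYS")
  expect_length(cys, 4)
  m2 <- ifn_alpha2a_model(exclude_sites = cys)
  expect_equal(nrow(m2$sites), nrow(m$sites) - 4)
})

test_that("bead table export is a readable CSV", {
  m <- coarsen(parse_structure(make_toy_peptide_pdb("KAD")))
  path <- tempfile(fileext = ".csv")
  write_bead_table(m, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 3)
  expect_true(grepl("NTR", tab$titratable[1]))
})
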