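test_that("molecular multipoles of canonical charge arrangements", {
  # single charge at the centre of mass
  one <- make_toy("point-charge", q = 2)
  mp <- molecular_multipoles(one)
  expect_equal(mp$q, 2)
  expect_equal(sqrt(sum(mp$mu^2)), 0)
  expect_equal(mp$theta, matrix(0, 3, 3))
  # ideal dipole
  dip <- molecular_multipoles(make_toy("ideal-dipole", q = 1, d = 10))
  expect_equal(dip$q, 0)
  expect_equal(sqrt(sum(dip$mu^2)), 10)
  # linear quadrupole (+q, -2q, +q) along z at spacing d:
  # theta = diag(-q d^2, -q d^2, 2 q d^2)
  quad <- molecular_multipoles(make_toy("linear-quadrupole", q = 1, d = 5))
  expect_equal(quad$q, 0)
  expect_equal(sqrt(sum(quad$mu^2)), 0)
  expect_equal(quad$theta, diag(c(-25, -25, 50)), tolerance = 1e-10)
})

test_that("quadrupole tensor is symmetric and traceless for random toys", {
  for (s in 1:10) {
    th <- molecular_multipoles(five_bead_toy(seed = s))$theta
    expect_equal(th, t(th), tolerance = 1e-10)
    expect_lt(abs(sum(diag(th))), 1e-9)
  }
})

test_that("pair terms reduce to textbook limits", {
  cond <- solution_condition(7, 0)
  lb <- cond$bjerrum
  mono1 <- molecular_multipoles(make_toy("point-charge", q = 2))
  mono2 <- molecular_multipoles(make_toy("point-charge", q = -3))
  tt <- multipole_pair_energy(mono1, mono2, 20, cond)
  expect_equal(unname(tt["ion_ion"]), lb * 2 * -3 / 20, tolerance = 1e-12)
  expect_equal(unname(tt["ion_dipole"]), 0)
  expect_equal(unname(tt["dipole_dipole"]), 0)
  expect_equal(unname(tt["ion_quadrupole"]), 0)
  expect_equal(unname(tt["total"]), sum(tt[1:4]))
  # collinear head-to-tail dipoles: -2 lB mu1 mu2 / z^3
  dz <- molecular_multipoles(make_toy("ideal-dipole", q = 1, d = 8))
  hh <- multipole_pair_energy(dz, dz, 30, cond)
  expect_equal(unname(hh["dipole_dipole"]), -2 * lb * 64 / 30^3,
               tolerance = 1e-10)
  # side-by-side antiparallel: - lB mu1 mu2 / z^3
  mx <- structure(list(q = 0, mu = c(8, 0, 0), theta = matrix(0, 3, 3)),
                  class = "multipole_set")
  mxa <- structure(list(q = 0, mu = c(-8, 0, 0), theta = matrix(0, 3, 3)),
                   class = "multipole_set")
  ap <- multipole_pair_energy(mx, mxa, 30, cond)
  expect_equal(unname(ap["dipole_dipole"]), -lb * 64 / 30^3,
               tolerance = 1e-10)
  expect_error(multipole_pair_energy(mx, mxa, c(0, 0, 0), cond), "zero")
})

test_that("head-to-tail and antiparallel are dipole-dipole energy minima", {
  cond <- solution_condition(7, 0)
  mu <- 8; z <- 30
  dd <- function(m1, m2) unname(
    multipole_pair_energy(m1, m2, z, cond)["dipole_dipole"])
  mk <- function(v) structure(list(q = 0, mu = v, theta = matrix(0, 3, 3)),
                              class = "multipole_set")
  e_ht <- dd(mk(c(0, 0, mu)), mk(c(0, 0, mu)))       # head-to-tail
  e_ap <- dd(mk(c(mu, 0, 0)), mk(c(-mu, 0, 0)))      # antiparallel lateral
  # scan random orientations: none beats head-to-tail; no lateral
  # arrangement beats antiparallel
  angs <- seq(0, 2 * pi, length.out = 60)
  for (a in angs) {
    m1 <- mk(mu * c(sin(a), 0, cos(a)))
    for (b in angs) {
      m2 <- mk(mu * c(sin(b), 0, cos(b)))
      expect_gte(dd(m1, m2), e_ht - 1e-9)
    }
    # purely lateral dipoles (perpendicular to the separation axis)
    expect_gte(dd(mk(mu * c(cos(a), sin(a), 0)),
                  mk(mu * c(-1, 0, 0))), e_ap - 1e-9)
  }
})

test_that("multipole series converges to the brute-force energy", {
  cond <- solution_condition(7, 0)
  errs <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    a <- make_toy("random-charge-set", n = 4, extent = 4, seed = s)
    b <- make_toy("random-charge-set", n = 4, extent = 4, seed = s + 50)
    ma <- molecular_multipoles(a)
    mb <- molecular_multipoles(b)
    for (k in 1:2) {
      z <- c(60, 120)[k]
      bshift <- shift_model(b, dz = z)
      exact <- brute_force_coulomb(a, bshift, cond)
      rvec <- geometry(a)$com - geometry(bshift)$com
      approx <- unname(multipole_pair_energy(ma, mb, rvec, cond)["total"])
      errs[s, k] <- abs(approx - exact) / max(abs(exact), 1e-12)
    }
  }
  expect_lt(mean(errs[, 1]), 0.05)
  # error shrinks with distance on average
  expect_lt(mean(errs[, 2]), mean(errs[, 1]))
})

test_that("ensemble decomposition of fixed monopoles isolates ion-ion", {
  z <- rep(seq(30, 60, by = 2), each = 20)
  n <- length(z)
  samples <- data.frame(z = z, u = 0, du = 0, q_a = 1, q_b = 1,
                        theta_a_zz = 0, theta_b_zz = 0,
                        mu_ax = 0, mu_ay = 0, mu_az = 0,
                        mu_bx = 0, mu_by = 0, mu_bz = 0)
  ens <- structure(list(samples = samples,
                        bins = seq(29, 61, by = 2),
                        cond = solution_condition(7, 0),
                        config = list(dl = 0.2)),
                   class = "separation_ensemble")
  dec <- average_decomposition(ens)
  expect_gt(dec$mean[dec$term == "ion_ion"], 0)
  expect_equal(dec$mean[dec$term == "ion_dipole"], 0)
  expect_equal(dec$mean[dec$term == "dipole_dipole"], 0)
  expect_equal(dec$mean[dec$term == "total"],
               sum(dec$mean[dec$term != "total"]), tolerance = 1e-12)
  expect_error(average_decomposition(ens, z_range = c(100, 200)), "empty")
})
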