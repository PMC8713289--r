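fake_ensemble <- function(z, du, u = 0, dl = 0.2, bin = 2) {
  bins <- seq(min(z) - bin / 2, max(z) + bin / 2, by = bin)
  structure(list(samples = data.frame(z = z, du = du, u = u),
                 bins = bins, config = list(dl = dl),
                 cond = solution_condition(7, 0)),
            class = "separation_ensemble")
}

test_that("zero perturbation gives zero force; sparse bins are dropped", {
  z <- rep(c(10, 12, 14), each = 50)
  f <- estimate_force(fake_ensemble(z, du = rep(0, 150)))
  expect_equal(f$force, rep(0, 3))
  f2 <- estimate_force(fake_ensemble(c(z, 16), du = rep(0, 151)),
                       min_samples = 10)
  expect_false(16 %in% f2$z)
})

test_that("PMF integration is exact for linear force and anchored at z_max", {
  z <- seq(10, 50, by = 2)
  alpha <- -0.03
  f <- data.frame(z = z, force = alpha * z)
  pmf <- integrate_pmf(f)
  expect_equal(pmf$u[length(z)], 0)
  expect_equal(pmf$u, alpha * (max(z)^2 - z^2) / 2, tolerance = 1e-12)
  # constant force: linear PMF
  f2 <- data.frame(z = z, force = 0.1)
  expect_equal(integrate_pmf(f2)$u, 0.1 * (max(z) - z), tolerance = 1e-12)
  expect_error(integrate_pmf(data.frame(z = c(1, 2, 3, 40),
                                        force = 0)), "gap")
})

test_that("hard-sphere identity: flat PMF beyond sigma = 2 R_h gives B2* = 1", {
  r_h <- 22.71
  pmf <- data.frame(z = seq(2 * r_h, 160, by = 0.5), u = 0)
  v <- second_virial(pmf, sigma = 2 * r_h, r_h = r_h)
  expect_equal(v$b2_star, 1, tolerance = 1e-12)
  expect_equal(v$b2_hs, 2 * pi * (2 * r_h)^3 / 3)
})

test_that("square-well PMF reproduces the closed-form virial", {
  sigma <- 40; lambda <- 1.5; eps0 <- 0.8
  z <- seq(sigma, 220, by = 0.1)
  # the step at lambda*sigma is represented by its one-sided mean at the
  # edge node, the standard quadrature treatment of a discontinuity
  u <- ifelse(z < lambda * sigma, -eps0,
              ifelse(z == lambda * sigma, -eps0 / 2, 0))
  v <- second_virial(data.frame(z = z, u = u), sigma = sigma, r_h = 22.71)
  expect_equal(v$b2, closed_form_b2("square-well", sigma = sigma,
                                    lambda = lambda, eps0 = eps0),
               tolerance = 0.005)
})

test_that("repulsive-only PMF bounds B2* from below", {
  z <- seq(30, 150, by = 0.5)
  u <- 5 * exp(-(z - 30) / 10)
  v <- second_virial(data.frame(z = z, u = u), sigma = 30, r_h = 22.71)
  expect_gte(v$b2_star, (30 / (2 * 22.71))^3 - 1e-9)
})

test_that("automatic contact distance sits just outside the steric wall", {
  z <- seq(20, 100, by = 2)
  u <- ifelse(z < 30, 50, 0)
  v <- second_virial(data.frame(z = z, u = u), r_h = 22.71)
  expect_equal(v$sigma, min(z[z >= 30]))
  expect_error(second_virial(data.frame(z = 1:10, u = 100), r_h = 22.71),
               "Boltzmann")
})

test_that("non-interacting pair records zero energies", {
  toy <- make_toy("point-charge", q = 0, sigma = 2)
  cfg <- twobody_config(z_min = 10, z_max = 30, bin_width = 2,
                        steps_equil = 500, steps_prod = 2000,
                        sample_stride = 5, eps = 1e-12, titrate = FALSE,
                        replicas = 1)
  ens <- run_twobody(toy, solution_condition(7, 0), cfg, seed = 1)
  expect_lt(max(abs(ens$samples$u)), 1e-8)
  expect_lt(max(abs(ens$samples$du)), 1e-8)
})

test_that("windowed sampling of a fixed charge pair matches the closed form", {
  toy <- make_toy("point-charge", q = 1, sigma = 2)
  cond <- solution_condition(7, 0.140)
  cfg <- twobody_config(z_min = 10, z_max = 60, bin_width = 2,
                        steps_equil = 2e3, steps_prod = 2e4,
                        sample_stride = 5, eps = 1e-12, titrate = FALSE,
                        replicas = 1)
  ens <- run_twobody(toy, cond, cfg, rotate_a = FALSE, rotate_b = FALSE,
                     seed = 3)
  # with no rotations or titration the recorded u is the exact pair energy
  expect_equal(ens$samples$u,
               pair_electrostatic(1, 1, ens$samples$z, cond),
               tolerance = 1e-8)
  # charge is conserved when titration is off
  expect_equal(unique(ens$samples$q_a), 1)
})

test_that("translate mode samples the separation range reproducibly", {
  toy <- make_toy("ideal-dipole", q = 0.5, d = 6, sigma = 4)
  cond <- solution_condition(7, 0.1)
  cfg <- twobody_config(z_min = 10, z_max = 50, bin_width = 2,
                        steps_equil = 2e3, steps_prod = 2e4,
                        sample_stride = 5, eps = 0.05, titrate = FALSE,
                        replicas = 1, mode = "translate")
  e1 <- run_twobody(toy, cond, cfg, seed = 4)
  e2 <- run_twobody(toy, cond, cfg, seed = 4)
  expect_identical(e1$samples, e2$samples)
  expect_gt(diff(range(e1$samples$z)), 20)
})

test_that("replica scatter of B2* does not grow with longer production", {
  toy <- make_toy("ideal-dipole", q = 1, d = 8, sigma = 6)
  cond <- solution_condition(7, 0)
  mk <- function(steps) twobody_config(z_min = 8, z_max = 60, bin_width = 2,
                                       steps_equil = 2e3, steps_prod = steps,
                                       sample_stride = 5, eps = 0.05,
                                       titrate = FALSE, replicas = 3)
  short <- twobody_virial(toy, cond, mk(1e4), seed = 21)
  long <- twobody_virial(toy, cond, mk(4e4), seed = 21)
  expect_lte(sd(long$b2_star), sd(short$b2_star) + 1e-9)
})
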