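test_that("box side reproduces the stated concentrations", {
  expect_equal(box_side(1, 19240, 30), 986, tolerance = 1e-3)
  expect_equal(box_side(30, 19240, 30), 986 / 30^(1 / 3), tolerance = 1e-3)
  expect_equal(box_side(2, 19240, 30), box_side(1, 19240, 30) / 2^(1 / 3),
               tolerance = 1e-12)
})

test_that("cluster partition implements the transitive growing rule", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(100, 0, 0))
  lab <- cluster_partition(pos, threshold = 12)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[2], lab[3])   # A-B and B-C link A to C transitively
  expect_false(lab[1] == lab[4])
  # all singletons
  expect_equal(length(unique(cluster_partition(pos, threshold = 5))), 4)
  # permutation invariance of the partition
  perm <- c(3, 1, 4, 2)
  lab2 <- cluster_partition(pos[perm, ], threshold = 12)
  same <- outer(lab, lab, "==")
  same2 <- outer(lab2, lab2, "==")[order(perm), order(perm)]
  expect_identical(same, same2)
  # minimum image joins across the boundary
  posb <- rbind(c(1, 0, 0), c(99, 0, 0))
  expect_equal(length(unique(cluster_partition(posb, 5, box = 100))), 1)
})

test_that("shape anisotropy identities", {
  expect_equal(shape_anisotropy(rbind(c(0, 0, 0), c(7, 3, -2))), 1,
               tolerance = 1e-12)
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(shape_anisotropy(tri), 0.25, tolerance = 1e-12)
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(shape_anisotropy(tet), 0, tolerance = 1e-12)
  lin <- cbind(c(0, 5, 10), 0, 0)
  expect_equal(shape_anisotropy(lin), 1, tolerance = 1e-12)
  expect_error(shape_anisotropy(rbind(c(0, 0, 0))), "at least 2")
  for (s in 1:10) {
    set.seed(s)
    k2 <- shape_anisotropy(matrix(rnorm(15), 5, 3))
    expect_gte(k2, 0); expect_lte(k2, 1)
  }
})

test_that("replica-exchange acceptance matches the two-state closed form", {
  expect_equal(replica_exchange_probability(3, 3, 5, 5), 1)
  expect_equal(replica_exchange_probability(1, 2, 4, 3), 1)
  expect_equal(replica_exchange_probability(0, 2, 0, 1),
               exp(-3), tolerance = 1e-12)
  # two particles in quadratic wells e_a x^2 and e_b x^2: empirical mean
  # swap acceptance vs numerical double integral
  ea <- 0.6; eb <- 1.1
  p_fun <- function(xa, xb) pmin(1, exp(-(eb - ea) * (xa^2 - xb^2)))
  # oracle: Gauss-Legendre style grid integration over both Boltzmann
  # densities (sd = 1/sqrt(2 e))
  xs <- seq(-6, 6, length.out = 401)
  wa <- dnorm(xs, sd = 1 / sqrt(2 * ea)); wa <- wa / sum(wa)
  wb <- dnorm(xs, sd = 1 / sqrt(2 * eb)); wb <- wb / sum(wb)
  oracle <- sum(outer(wa, wb) * outer(xs, xs, p_fun))
  set.seed(42)
  xa <- rnorm(4e4, sd = 1 / sqrt(2 * ea))
  xb <- rnorm(4e4, sd = 1 / sqrt(2 * eb))
  emp <- mean(vapply(seq_along(xa), function(i)
    replica_exchange_probability(ea * xa[i]^2, eb * xa[i]^2,
                                 eb * xb[i]^2, ea * xb[i]^2),
    numeric(1)))
  expect_equal(emp, oracle, tolerance = 0.01)
})

test_that("cluster statistics count by definition", {
  # one trimer plus 27 singletons in a huge box
  set.seed(7)
  pos <- matrix(runif(30 * 3, 0, 5000), 30, 3)
  pos[1:3, ] <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 9, 0))
  frames <- array(t(pos), dim = c(3, 30, 1))
  attr(frames, "box") <- 5000
  st <- cluster_statistics(frames, threshold = 15)
  expect_equal(st$mean_size, 30 / 28, tolerance = 1e-12)
  expect_equal(sum(as.integer(names(st$size_hist)) *
                     as.integer(st$size_hist)), 30)
  expect_length(st$k2, 1)   # only the trimer qualifies
  # all singletons: mean size one and no shape entries
  frames2 <- array(t(matrix(runif(30, 0, 5000), 10, 3)), dim = c(3, 10, 1))
  attr(frames2, "box") <- 5000
  st2 <- cluster_statistics(frames2, threshold = 1)
  expect_equal(st2$mean_size, 1)
  expect_true(is.na(st2$mean_k2))
})

test_that("periodic unwrapping gives correct shape across the boundary", {
  # collinear trimer straddling the periodic boundary
  pos <- rbind(c(98, 0, 0), c(3, 0, 0), c(8, 0, 0))
  frames <- array(t(pos), dim = c(3, 3, 1))
  attr(frames, "box") <- 100
  st <- cluster_statistics(frames, threshold = 7)
  expect_equal(st$mean_size, 3)
  expect_equal(st$k2, 1, tolerance = 1e-12)
})

test_that("ideal gas limit: neutral non-attracting proteins stay monomeric", {
  toy <- make_toy("point-charge", q = 0, sigma = 6, mass = 19240)
  cond <- solution_condition(7, 0)
  cfg <- manybody_config(n = 12, conc = 1, threshold = 45.42,
                         ladder = c(1e-9, 1e-9), sweeps = 2000,
                         equil_sweeps = 400, frame_stride = 20,
                         cluster_move_freq = 0.1)
  res <- run_manybody(toy, cond, cfg, seed = 5)
  st <- cluster_statistics(res, rung = 1)
  expect_lt(st$mean_size, 1.2)
})

test_that("energy bookkeeping matches a from-scratch recomputation", {
  m <- ifn_model_cached()
  cond <- solution_condition(6.5, 0)
  ti <- equilibrate_mean_charges(m, cond, steps = 2e4, seed = 7)
  cfg <- manybody_config(n = 6, conc = 30, ladder = c(0.05, 0.07),
                         sweeps = 400, equil_sweeps = 100,
                         frame_stride = 50)
  res <- run_manybody(ti$model, cond, cfg, seed = 9)
  expect_equal(res$energy_el, res$energy_el_check, tolerance = 1e-8)
  expect_equal(res$energy_vdw_base, res$energy_vdw_check, tolerance = 1e-8)
})

test_that("pair statistics agree with and without cluster moves", {
  toy <- make_toy("ideal-dipole", q = 1, d = 6, sigma = 8, mass = 19240)
  cond <- solution_condition(7, 0)
  mean_pair_dist <- function(freq, seed) {
    cfg <- manybody_config(n = 3, conc = 25, threshold = 30,
                           ladder = 0.05, sweeps = 8000,
                           equil_sweeps = 2000, frame_stride = 10,
                           cluster_move_freq = freq)
    res <- run_manybody(toy, cond, cfg, seed = seed)
    fr <- res$frames[[1]]
    mean(vapply(seq_len(dim(fr)[3]), function(f) {
      d <- beadmc:::.pairwise_minimage(t(fr[, , f]), res$box)
      mean(d[upper.tri(d)])
    }, numeric(1)))
  }
  with_cl <- mean(vapply(1:3, function(s) mean_pair_dist(0.25, s),
                         numeric(1)))
  without <- mean(vapply(1:3, function(s) mean_pair_dist(0, s + 10),
                         numeric(1)))
  expect_equal(with_cl, without, tolerance = 0.08)
})

test_that("trajectory export writes valid XYZ frames", {
  toy <- make_toy("point-charge", q = 0, sigma = 6, mass = 19240)
  cfg <- manybody_config(n = 4, conc = 10, ladder = 0.05, sweeps = 200,
                         equil_sweeps = 50, frame_stride = 50)
  res <- run_manybody(toy, solution_condition(7, 0), cfg, seed = 2)
  path <- tempfile(fileext = ".xyz")
  write_xyz(res, path)
  ln <- readLines(path)
  expect_equal(ln[1], "4")
  expect_match(ln[3], "^P ")
})
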