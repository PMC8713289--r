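#' Configuration for the two-protein cell simulation
#'
#' @param cell_radius Spherical cell radius, A.
#' @param dl Virtual displacement for the force estimator, A.
#' @param z_min,z_max Range of centre-of-mass separations sampled, A;
#'   `z_max` defaults to `cell_radius - 5`.
#' @param bin_width Width of the separation windows/bins, A.
#' @param steps_equil,steps_prod Equilibration and production move attempts
#'   (totals over all windows in windowed mode).
#' @param sample_stride Moves between recorded samples.
#' @param replicas Number of independent replicas.
#' @param eps Lennard-Jones baseline well depth, k_B T.
#' @param mode `"windows"` (fixed-z windows, even coverage; default) or
#'   `"translate"` (z sampled by MC translation moves).
#' @param titrate Sample protonation states during the run.
#' @param seed Base seed.
#' @return A `twobody_config` list.
#' @export
twobody_config <- function(cell_radius = 120, dl = 0.2, z_min = 25,
                           z_max = cell_radius - 5, bin_width = 2,
                           steps_equil = 1e5, steps_prod = 1e6,
                           sample_stride = 10, replicas = 5, eps = 0.05,
                           mode = c("windows", "translate"), titrate = TRUE,
                           seed = 1) {
  mode <- match.arg(mode)
  stopifnot(dl > 0, dl < bin_width, z_min > 0, z_max > z_min,
            z_max < cell_radius, steps_prod > 0)
  structure(list(cell_radius = cell_radius, dl = dl, z_min = z_min,
                 z_max = z_max, bin_width = bin_width,
                 steps_equil = steps_equil, steps_prod = steps_prod,
                 sample_stride = sample_stride, replicas = replicas,
                 eps = eps, mode = mode, titrate = titrate, seed = seed),
            class = "twobody_config")
}

#' Two-protein cell simulation
#'
#' One protein rotates about its centre of mass in the middle of the cell;
#' an identical copy sits at centre-of-mass separation z on the z axis and
#' also rotates (and, in `"translate"` mode, translates along z). Both may
#' titrate. For every recorded state the cross energy `u`, the energy
#' perturbation `du` after a virtual displacement `dl` of the second
#' protein, and the instantaneous multipoles of both proteins are stored,
#' binned by z.
#'
#' @param model A `protein_model` (the same rigid model is used for both
#'   copies; charge states are sampled independently).
#' @param cond A [solution_condition()].
#' @param config A [twobody_config()].
#' @param rotate_a,rotate_b Enable rotation moves of either protein.
#' @param seed Seed for this run (defaults to `config$seed`).
#' @return A `separation_ensemble`: list with `samples` (data frame with
#'   columns `z`, `u`, `du`, `q_a`, `q_b`, `mu_a*`, `mu_b*`, `theta_a_zz`,
#'   `theta_b_zz`), `bins` (bin edges), `config`, `cond`.
#' @export
run_twobody <- function(model, cond, config = twobody_config(),
                        rotate_a = TRUE, rotate_b = TRUE,
                        seed = config$seed) {
  g <- geometry(model)
  xyz <- sweep(as.matrix(model$beads[, c("x", "y", "z")]), 2, g$com)
  sites <- model$sites
  titrate <- config$titrate && nrow(sites) > 0
  args <- list(xyz = xyz, charge0 = model$beads$charge,
               sigma = model$beads$sigma,
               site_bead = as.integer(sites$bead - 1L),
               site_acid = as.integer(sites$kind == "acid"),
               site_pka = as.numeric(sites$pka),
               ph = cond$ph, bjerrum = cond$bjerrum, kappa = cond$kappa,
               eps = config$eps, dL = config$dl, titrate = titrate,
               rotate_a = rotate_a, rotate_b = rotate_b,
               sample_stride = as.integer(config$sample_stride))
  edges <- seq(config$z_min, config$z_max, by = config$bin_width)
  if (edges[length(edges)] < config$z_max)
    edges <- c(edges, config$z_max)
  if (config$mode == "windows") {
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    nw <- length(centers)
    per_eq <- max(200L, as.integer(ceiling(config$steps_equil / nw)))
    per_pr <- max(config$sample_stride,
                  as.integer(ceiling(config$steps_prod / nw)))
    # sweep windows from the far end inward, seeding each window's chain
    # from the last state of its outer neighbour (quasi-static approach:
    # keeps the pair on the physically connected branch of configurations)
    occ0 <- as.integer(round(sites$occupancy))
    state <- list(rot_a = numeric(), rot_b = numeric(),
                  occ_a = occ0, occ_b = occ0)
    out <- vector("list", nw)
    for (w in rev(seq_len(nw))) {
      r <- do.call(cpp_twobody, c(args, list(
        z0 = centers[w], z_min = centers[w], z_max = centers[w],
        translate = FALSE, n_equil = per_eq, n_prod = per_pr,
        seed = as.integer((seed * 1009 + w) %% 2147483647),
        rot_a_init = state$rot_a, rot_b_init = state$rot_b,
        occ_a_init = state$occ_a, occ_b_init = state$occ_b)))
      state <- r[c("rot_a", "rot_b", "occ_a", "occ_b")]
      names(state) <- c("rot_a", "rot_b", "occ_a", "occ_b")
      out[[w]] <- cbind(
        as.data.frame(r[c("u", "du", "z", "q_a", "q_b",
                          "theta_a_zz", "theta_b_zz")]),
        mu_ax = r$mu_a[, 1], mu_ay = r$mu_a[, 2], mu_az = r$mu_a[, 3],
        mu_bx = r$mu_b[, 1], mu_by = r$mu_b[, 2], mu_bz = r$mu_b[, 3])
    }
    samples <- do.call(rbind, out)
  } else {
    r <- do.call(cpp_twobody, c(args, list(
      z0 = (config$z_min + config$z_max) / 2, z_min = config$z_min,
      z_max = config$z_max, translate = TRUE,
      n_equil = as.integer(config$steps_equil),
      n_prod = as.integer(config$steps_prod),
      seed = as.integer(seed %% 2147483647),
      rot_a_init = numeric(), rot_b_init = numeric(),
      occ_a_init = as.integer(round(sites$occupancy)),
      occ_b_init = as.integer(round(sites$occupancy)))))
    samples <- cbind(
      as.data.frame(r[c("u", "du", "z", "q_a", "q_b",
                        "theta_a_zz", "theta_b_zz")]),
      mu_ax = r$mu_a[, 1], mu_ay = r$mu_a[, 2], mu_az = r$mu_a[, 3],
      mu_bx = r$mu_b[, 1], mu_by = r$mu_b[, 2], mu_bz = r$mu_b[, 3])
  }
  structure(list(samples = samples, bins = edges, config = config,
                 cond = cond), class = "separation_ensemble")
}

#' Force profile from virtual-displacement samples
#'
#' Free-energy-perturbation estimator per separation bin:
#' `F(z) = (1/dL) ln < exp(-du) >` (k_B T / A, energies already in k_B T).
#' The first-order estimator `-<du>/dL` is returned alongside for
#' comparison. Bins with fewer than `min_samples` entries are dropped.
#'
#' @param ensemble A `separation_ensemble` from [run_twobody()].
#' @param dl Virtual displacement used in the run, A.
#' @param min_samples Minimum samples per analysed bin.
#' @return A `force_profile` data frame with columns `z` (bin centre),
#'   `force`, `force_lin`, `u_mean`, `n`.
#' @export
estimate_force <- function(ensemble, dl = ensemble$config$dl,
                           min_samples = 10) {
  stopifnot(dl > 0)
  s <- ensemble$samples
  bin <- cut(s$z, ensemble$bins, include.lowest = TRUE)
  agg <- lapply(split(s, bin), function(d) {
    if (nrow(d) < min_samples) return(NULL)
    # log-mean-exp, guarded for large -du
    m <- max(-d$du)
    lme <- m + log(mean(exp(-d$du - m)))
    data.frame(force = lme / dl, force_lin = -mean(d$du) / dl,
               u_mean = mean(d$u), n = nrow(d))
  })
  keep <- !vapply(agg, is.null, logical(1))
  centers <- (ensemble$bins[-1] + ensemble$bins[-length(ensemble$bins)]) / 2
  out <- cbind(z = centers[keep], do.call(rbind, agg[keep]))
  rownames(out) <- NULL
  class(out) <- c("force_profile", "data.frame")
  out
}

#' Integrate a force profile to the potential of mean force
#'
#' `U(z) = integral from z to z_max of F(z') dz'` by the trapezoidal rule,
#' anchored at `U(z_max) = 0` (so `dU/dz = -F`).
#'
#' @param force A `force_profile` from [estimate_force()] (or any data
#'   frame with columns `z` and `force` on a contiguous grid).
#' @param max_gap Largest tolerated spacing between consecutive z values,
#'   as a multiple of the median spacing.
#' @return A `pmf_curve` data frame with columns `z` and `u` (k_B T).
#' @export
integrate_pmf <- function(force, max_gap = 2.5) {
  z <- force$z; f <- force$force
  o <- order(z); z <- z[o]; f <- f[o]
  if (length(z) < 2) stop("force profile too short", call. = FALSE)
  dz <- diff(z)
  if (any(dz > max_gap * stats::median(dz)))
    stop("non-contiguous force grid; gaps after z = ",
         paste(signif(z[which(dz > max_gap * stats::median(dz))], 4),
               collapse = ", "), call. = FALSE)
  # cumulative trapezoid from the far end
  n <- length(z)
  u <- numeric(n)
  for (i in (n - 1):1)
    u[i] <- u[i + 1] + 0.5 * (f[i] + f[i + 1]) * (z[i + 1] - z[i])
  out <- data.frame(z = z, u = u)
  if (!is.null(force$u_mean)) out$u_mean <- force$u_mean[o]
  class(out) <- c("pmf_curve", "data.frame")
  out
}

#' Second osmotic virial coefficient from a PMF
#'
#' `B2 = 2 pi sigma^3 / 3 - 2 pi * integral from sigma to z_max of
#' (exp(-U(z)) - 1) z^2 dz`, with the contact distance `sigma` treated as a
#' hard core. The hard-sphere reference is `B2_hs = 2 pi (2 R_h)^3 / 3` and
#' `B2* = B2 / B2_hs`.
#'
#' @param pmf A `pmf_curve` (columns `z`, `u`; `u` in k_B T).
#' @param sigma Minimum contact distance, A. `NULL` (default) determines it
#'   as the smallest sampled z whose Boltzmann factor `exp(-U)` exceeds
#'   `boltzmann_floor`; z values below `sigma` are discarded from the
#'   integral.
#' @param r_h Hydrodynamic radius, A.
#' @param boltzmann_floor Floor for the automatic contact distance.
#' @return A `virial_result` list with `sigma`, `b2`, `b2_hs`, `b2_star`.
#' @export
second_virial <- function(pmf, sigma = NULL, r_h = 22.71,
                          boltzmann_floor = exp(-10)) {
  z <- pmf$z; u <- pmf$u
  o <- order(z); z <- z[o]; u <- u[o]
  if (is.null(sigma)) {
    # a bin counts as "in contact range" only if both the integrated PMF
    # and (when carried along) the directly sampled mean energy are below
    # the Boltzmann floor, i.e. not inside the steric wall
    ok <- exp(-u) > boltzmann_floor
    if (!is.null(pmf$u_mean)) ok <- ok & exp(-pmf$u_mean[o]) > boltzmann_floor
    if (!any(ok)) stop("no separation below the Boltzmann floor",
                       call. = FALSE)
    # contact distance: first bin beyond the outermost bin still inside the
    # steric wall (bins inside or below the wall are part of the hard core)
    bad <- which(!ok)
    sigma <- if (length(bad)) z[max(bad) + 1] else z[1]
    if (is.na(sigma)) stop("no separation below the Boltzmann floor",
                           call. = FALSE)
  }
  if (sigma >= max(z)) stop("sigma >= z_max", call. = FALSE)
  keep <- z >= sigma
  z <- z[keep]; u <- u[keep]
  integrand <- (exp(-u) - 1) * z^2
  tail_int <- sum(diff(z) * (integrand[-1] + integrand[-length(z)]) / 2)
  b2 <- 2 * pi * sigma^3 / 3 - 2 * pi * tail_int
  b2_hs <- 2 * pi * (2 * r_h)^3 / 3
  structure(list(sigma = sigma, b2 = b2, b2_hs = b2_hs,
                 b2_star = b2 / b2_hs, r_h = r_h),
            class = "virial_result")
}

#' @export
print.virial_result <- function(x, ...) {
  cat(sprintf("B2 = %.4g A^3  B2_hs = %.4g A^3  B2* = %.4f  (sigma = %.1f A)\n",
              x$b2, x$b2_hs, x$b2_star, x$sigma))
  invisible(x)
}

#' Full two-body pipeline: run, force, PMF, virial
#'
#' Convenience wrapper running [run_twobody()] for `config$replicas`
#' replicas and reducing each to a `virial_result`.
#'
#' @inheritParams run_twobody
#' @param r_h Hydrodynamic radius for the hard-sphere normalisation, A.
#' @return List with `replicas` (per-replica list: `ensemble`, `force`,
#'   `pmf`, `virial`), `b2_star` (per-replica values), `b2_star_mean`, and
#'   `b2_star_se`.
#' @export
twobody_virial <- function(model, cond, config = twobody_config(),
                           r_h = 22.71, seed = config$seed) {
  reps <- lapply(seq_len(config$replicas), function(k) {
    ens <- run_twobody(model, cond, config, seed = seed + 7919L * k)
    f <- estimate_force(ens)
    pmf <- integrate_pmf(f)
    list(ensemble = ens, force = f, pmf = pmf,
         virial = second_virial(pmf, r_h = r_h))
  })
  b2s <- vapply(reps, function(r) r$virial$b2_star, numeric(1))
  # pooled estimate: free-energy-perturbation force over the samples of
  # all replicas per window (the combined window ensemble mixes basins a
  # single finite chain can be trapped in), then one PMF and virial
  pooled_ens <- reps[[1]]$ensemble
  pooled_ens$samples <- do.call(rbind, lapply(reps, function(r)
    r$ensemble$samples))
  pooled_f <- estimate_force(pooled_ens)
  pooled_pmf <- integrate_pmf(pooled_f)
  pooled <- second_virial(pooled_pmf, r_h = r_h)
  list(replicas = reps, b2_star = b2s, b2_star_mean = mean(b2s),
       b2_star_se = stats::sd(b2s) / sqrt(length(b2s)),
       pooled_force = pooled_f, pooled_pmf = pooled_pmf,
       pooled_virial = pooled, b2_star_pooled = pooled$b2_star)
}
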