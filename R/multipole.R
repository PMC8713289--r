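#' Molecular multipoles of a charged model
#'
#' Monopole `Q = sum z_i`, dipole `mu = sum z_i d_i` and traceless
#' quadrupole tensor `Theta = sum z_i (3 d_i d_i^T - |d_i|^2 I) / 2`, with
#' `d_i` the bead displacement from the centre of mass.
#'
#' @param model A `protein_model` with charges assigned.
#' @return A `multipole_set` list with `q` (e), `mu` (eA, length 3) and
#'   `theta` (eA^2, 3x3 symmetric traceless).
#' @export
molecular_multipoles <- function(model) {
  g <- geometry(model)
  b <- model$beads
  d <- sweep(as.matrix(b[, c("x", "y", "z")]), 2, g$com)
  z <- b$charge
  theta <- matrix(0, 3, 3)
  for (i in which(z != 0)) {
    di <- d[i, ]
    theta <- theta + z[i] * (3 * tcrossprod(di) - sum(di^2) * diag(3)) / 2
  }
  structure(list(q = sum(z), mu = colSums(z * d), theta = theta),
            class = "multipole_set")
}

#' Multipole decomposition of the pair interaction energy
#'
#' Unscreened Cartesian multipole series through order `1/r^3`, in k_B T
#' with the Bjerrum length as prefactor. With `rhat` the unit separation
#' vector `r_1 - r_2` pointing from protein 2 to protein 1:
#' ion-ion `Q1 Q2 / r`; ion-dipole `[Q1 (mu2.rhat) - Q2 (mu1.rhat)] / r^2`;
#' dipole-dipole `[mu1.mu2 - 3 (mu1.rhat)(mu2.rhat)] / r^3`;
#' ion-quadrupole `[Q1 (rhat.Theta2.rhat) + Q2 (rhat.Theta1.rhat)] / r^3`.
#'
#' @param m1,m2 `multipole_set` objects (protein 1 and protein 2).
#' @param r Separation vector `r_1 - r_2` (length 3, A), or a scalar z
#'   interpreted as protein 2 displaced by +z along the z axis from
#'   protein 1 (so the vector is `c(0, 0, -z)`).
#' @param cond A [solution_condition()]; only the Bjerrum length is used
#'   unless `screened = TRUE`.
#' @param screened Multiply every term by `exp(-|r|/lambda)` (off by
#'   default; the decomposition is analysed at zero added salt).
#' @return Named numeric vector with components `ion_ion`, `ion_dipole`,
#'   `dipole_dipole`, `ion_quadrupole` and `total` (their sum), k_B T.
#' @export
multipole_pair_energy <- function(m1, m2, r, cond, screened = FALSE) {
  if (length(r) == 1) r <- c(0, 0, -r)
  rn <- sqrt(sum(r^2))
  if (rn <= 0) stop("zero separation", call. = FALSE)
  rhat <- r / rn
  lb <- cond$bjerrum
  scr <- if (screened && cond$kappa > 0) exp(-cond$kappa * rn) else 1
  ii <- lb * m1$q * m2$q / rn
  id <- lb * (m1$q * sum(m2$mu * rhat) - m2$q * sum(m1$mu * rhat)) / rn^2
  dd <- lb * (sum(m1$mu * m2$mu) -
                3 * sum(m1$mu * rhat) * sum(m2$mu * rhat)) / rn^3
  iq <- lb * (m1$q * drop(rhat %*% m2$theta %*% rhat) +
                m2$q * drop(rhat %*% m1$theta %*% rhat)) / rn^3
  out <- scr * c(ion_ion = ii, ion_dipole = id, dipole_dipole = dd,
                 ion_quadrupole = iq)
  c(out, total = sum(out))
}

#' Ensemble-averaged multipole decomposition
#'
#' Evaluates the four multipole terms for every recorded state of a
#' two-body run from the stored instantaneous multipoles and separation,
#' then averages over a z range. In the two-body geometry protein 1 (A)
#' sits at the origin and protein 2 (B) at +z, so `rhat = -zhat` and the
#' projections reduce to the stored z components (the recorded
#' `theta_*_zz` equals `rhat.Theta.rhat` either way).
#'
#' @param ensemble A `separation_ensemble` from [run_twobody()].
#' @param z_range Length-2 numeric: separations to average over. Default
#'   spans the sampled range.
#' @param cond Solution condition (defaults to the ensemble's).
#' @param weight `"boltzmann"` weights each sample by
#'   `exp(-u) z^2` (configurational weight of the separation shell, used
#'   for single-number summaries); `"flat"` averages samples as recorded.
#' @return A `term_decomposition` data frame with columns `term`, `mean`,
#'   `mc_error` (standard error over samples) and `sign`.
#' @export
average_decomposition <- function(ensemble, z_range = NULL,
                                  cond = ensemble$cond,
                                  weight = c("boltzmann", "flat")) {
  weight <- match.arg(weight)
  s <- ensemble$samples
  if (is.null(z_range)) z_range <- range(s$z)
  s <- s[s$z >= z_range[1] & s$z <= z_range[2], , drop = FALSE]
  if (nrow(s) == 0L) stop("empty z range", call. = FALSE)
  lb <- cond$bjerrum
  # rhat = -zhat: mu.rhat = -mu_z
  mua_r <- -s$mu_az; mub_r <- -s$mu_bz
  mudot <- s$mu_ax * s$mu_bx + s$mu_ay * s$mu_by + s$mu_az * s$mu_bz
  terms <- data.frame(
    ion_ion = lb * s$q_a * s$q_b / s$z,
    ion_dipole = lb * (s$q_a * mub_r - s$q_b * mua_r) / s$z^2,
    dipole_dipole = lb * (mudot - 3 * mua_r * mub_r) / s$z^3,
    ion_quadrupole = lb * (s$q_a * s$theta_b_zz + s$q_b * s$theta_a_zz) /
      s$z^3
  )
  w <- if (weight == "boltzmann") exp(-s$u + min(s$u)) * s$z^2
       else rep(1, nrow(s))
  w <- w / sum(w)
  mean_w <- vapply(terms, function(t) sum(w * t), numeric(1))
  se <- vapply(terms, function(t) {
    sqrt(sum(w^2 * (t - sum(w * t))^2))
  }, numeric(1))
  out <- data.frame(term = names(mean_w), mean = unname(mean_w),
                    mc_error = unname(se),
                    sign = ifelse(mean_w < 0, "attractive", "repulsive"),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(term = "total", mean = sum(mean_w),
                               mc_error = sqrt(sum(se^2)),
                               sign = ifelse(sum(mean_w) < 0, "attractive",
                                             "repulsive")))
  class(out) <- c("term_decomposition", "data.frame")
  out
}
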