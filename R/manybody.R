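#' Cubic box side for a target mass concentration
#'
#' `side = (N M_w / (N_A c))^(1/3)`, with the concentration converted from
#' mg/mL to g/A^3.
#'
#' @param conc Protein concentration, mg/mL.
#' @param m_w Protein molecular weight, g/mol.
#' @param n Number of proteins in the box.
#' @return Box side in angstrom.
#' @export
#' @examples
#' box_side(1, 19240, 30) # about 986 A
box_side <- function(conc, m_w, n = 30) {
  stopifnot(conc > 0, m_w > 0, n > 0)
  na <- 6.02214076e23
  (n * m_w / (na * conc * 1e-3))^(1 / 3) * 1e8 # cm -> A
}

#' Many-body run configuration
#'
#' @param n Number of proteins.
#' @param conc Concentration, mg/mL (sets the box side together with the
#'   protein molecular weight).
#' @param threshold Cluster distance threshold on centre-of-mass
#'   separations, A (default twice the hydrodynamic radius).
#' @param ladder Lennard-Jones epsilon ladder for Hamiltonian parallel
#'   tempering, k_B T; default 10 rungs from 0.05 in steps of 0.01.
#' @param sweeps,equil_sweeps Production / equilibration sweeps (one sweep
#'   = `n` attempted moves per replica).
#' @param swap_interval Sweeps between replica-exchange attempts.
#' @param frame_stride Sweeps between recorded frames.
#' @param cluster_move_freq Fraction of move attempts that are cluster
#'   moves.
#' @param seed Base seed.
#' @return A `manybody_config` list.
#' @export
manybody_config <- function(n = 30, conc = 10, threshold = 2 * 22.71,
                            ladder = 0.05 + 0.01 * (0:9), sweeps = 2e4,
                            equil_sweeps = ceiling(sweeps / 5),
                            swap_interval = 10, frame_stride = 25,
                            cluster_move_freq = 0.1, seed = 1) {
  stopifnot(n > 1, conc > 0, threshold > 0, length(ladder) >= 1,
            all(ladder > 0), sweeps > 0)
  structure(list(n = n, conc = conc, threshold = threshold, ladder = ladder,
                 sweeps = sweeps, equil_sweeps = equil_sweeps,
                 swap_interval = swap_interval, frame_stride = frame_stride,
                 cluster_move_freq = cluster_move_freq, seed = seed),
            class = "manybody_config")
}

#' Single-linkage cluster partition of centre-of-mass positions
#'
#' Connected components of the graph joining proteins whose minimum-image
#' centre-of-mass distance is below the threshold (the transitive "cluster
#' growing" rule).
#'
#' @param pos N x 3 matrix of COM positions, A.
#' @param threshold Distance threshold, A.
#' @param box Box side for minimum image, A (`Inf` for open boundaries).
#' @return Integer vector of cluster labels (1-based).
#' @export
cluster_partition <- function(pos, threshold, box = Inf) {
  n <- nrow(pos)
  if (n == 0L) return(integer())
  d <- .pairwise_minimage(pos, box)
  adj <- d < threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

.pairwise_minimage <- function(pos, box) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(pos[, k], pos[, k], "-")
    if (is.finite(box)) dk <- dk - box * round(dk / box)
    d <- d + dk^2
  }
  sqrt(d)
}

#' Relative shape anisotropy of a point cluster
#'
#' `k^2 = 1 - 3 (l1 l2 + l1 l3 + l2 l3) / (l1 + l2 + l3)^2` from the
#' sorted eigenvalues of the gyration tensor of the centre-of-mass
#' positions. 0 for spherically symmetric arrangements, 1 for a collinear
#' chain (hence always 1 for a dimer).
#'
#' @param points n x 3 matrix of positions, unwrapped to a common periodic
#'   image.
#' @return `k^2` in `[0, 1]`.
#' @export
#' @examples
#' shape_anisotropy(rbind(c(0, 0, 0), c(10, 0, 0))) # dimer: exactly 1
shape_anisotropy <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points", call. = FALSE)
  d <- sweep(points, 2, colMeans(points))
  s <- crossprod(d) / nrow(points)
  l <- sort(eigen(s, symmetric = TRUE, only.values = TRUE)$values,
            decreasing = TRUE)
  1 - 3 * (l[1] * l[2] + l[1] * l[3] + l[2] * l[3]) / sum(l)^2
}

# unwrap the members of one cluster to a common image by minimum-image
# growth from the first member
.unwrap_cluster <- function(pos, members, threshold, box) {
  idx <- members
  out <- pos[idx, , drop = FALSE]
  done <- c(1L)
  todo <- setdiff(seq_along(idx), 1L)
  while (length(todo)) {
    progressed <- FALSE
    for (t in todo) {
      for (s in done) {
        dv <- out[t, ] - out[s, ]
        dv <- dv - box * round(dv / box)
        if (sqrt(sum(dv^2)) < threshold) {
          out[t, ] <- out[s, ] + dv
          done <- c(done, t)
          todo <- setdiff(todo, t)
          progressed <- TRUE
          break
        }
      }
      if (progressed) break
    }
    if (!progressed) { # disconnected under threshold; anchor as-is
      t <- todo[1]
      dv <- out[t, ] - out[done[1], ]
      out[t, ] <- out[done[1], ] + dv - box * round(dv / box)
      done <- c(done, t); todo <- setdiff(todo, t)
    }
  }
  out
}

#' Acceptance probability for a replica-exchange swap
#'
#' For configurations a and b at ladder values `eps_a`, `eps_b`:
#' `min(1, exp(-[U_a(eps_b) + U_b(eps_a) - U_a(eps_a) - U_b(eps_b)]))`
#' with energies in k_B T. With a uniform epsilon the Lennard-Jones energy
#' is linear in epsilon, so cross-ladder energies follow by rescaling the
#' vdW component.
#'
#' @param u_a_a,u_a_b Energy of configuration a at its own / the partner's
#'   ladder value.
#' @param u_b_b,u_b_a Likewise for configuration b.
#' @return Acceptance probability in `[0, 1]`.
#' @export
replica_exchange_probability <- function(u_a_a, u_a_b, u_b_b, u_b_a) {
  min(1, exp(-(u_a_b + u_b_a - u_a_a - u_b_b)))
}

#' N-protein periodic-box simulation with parallel tempering
#'
#' Metropolis chain of single-protein translations/rotations plus cluster
#' moves over `length(config$ladder)` replicas that exchange along the
#' Lennard-Jones epsilon ladder. Charges are fixed (use the fractional
#' average charges from [equilibrate_mean_charges()]); electrostatics use
#' molecule-based minimum image with a half-box truncation.
#'
#' @param model A `protein_model` with (fractional) charges assigned.
#' @param cond A [solution_condition()].
#' @param config A [manybody_config()].
#' @param seed Seed for this run.
#' @return A `manybody_result`: list with `frames` (per rung: array
#'   3 x N x n_frames of COM positions), `box`, `ladder`, acceptance rates
#'   and the final per-replica energies.
#' @export
run_manybody <- function(model, cond, config = manybody_config(),
                         seed = config$seed) {
  g <- geometry(model)
  xyz <- sweep(as.matrix(model$beads[, c("x", "y", "z")]), 2, g$com)
  box <- box_side(config$conc, model$mw, config$n)
  ext <- max(sqrt(rowSums(xyz^2)))
  if (box <= 2 * (ext + config$threshold))
    stop("box side too small for the protein extent plus threshold",
         call. = FALSE)
  res <- cpp_manybody(
    xyz, model$beads$charge, model$beads$sigma,
    as.integer(config$n), box, config$ladder,
    cond$bjerrum, cond$kappa, config$threshold,
    as.integer(config$sweeps), as.integer(config$equil_sweeps),
    as.integer(config$swap_interval), as.integer(config$frame_stride),
    config$cluster_move_freq, as.integer(seed %% 2147483647L))
  structure(list(frames = res$frames, box = res$box,
                 ladder = config$ladder, threshold = config$threshold,
                 acc_move = res$acc_move, acc_cluster = res$acc_cluster,
                 acc_swap = res$acc_swap, energy_el = res$energy_el,
                 energy_vdw_base = res$energy_vdw_base,
                 energy_el_check = res$energy_el_check,
                 energy_vdw_check = res$energy_vdw_check, config = config,
                 cond = cond), class = "manybody_result")
}

#' Cluster size and shape statistics of a trajectory
#'
#' Per frame: single-linkage partition under the threshold, the cluster
#' size histogram, the number-average cluster size (total proteins divided
#' by number of clusters; the mass-average is reported alongside), and the
#' relative shape anisotropy of every cluster with three or more members
#' (dimers are identically 1 and excluded).
#'
#' @param result A `manybody_result`, or a single rung's frame array.
#' @param threshold Cluster threshold, A (defaults to the run's).
#' @param rung Ladder rung to analyse when `result` is a full run.
#' @return List with `mean_size` (number-average), `mean_size_mass`
#'   (mass-average), `mean_k2` (`NA` if no cluster of size >= 3 occurred),
#'   `k2` (all per-cluster values), `size_hist` (table over frames) and
#'   `n_frames`.
#' @export
cluster_statistics <- function(result, threshold = NULL, rung = 1) {
  if (inherits(result, "manybody_result")) {
    frames <- result$frames[[rung]]
    box <- result$box
    if (is.null(threshold)) threshold <- result$threshold
  } else {
    frames <- result
    box <- attr(frames, "box")
    if (is.null(box)) box <- Inf
    if (is.null(threshold)) stop("threshold required", call. = FALSE)
  }
  nf <- dim(frames)[3]
  n <- dim(frames)[2]
  sizes_all <- integer()
  navg <- numeric(nf)
  mavg <- numeric(nf)
  k2 <- numeric()
  for (f in seq_len(nf)) {
    pos <- t(frames[, , f])
    lab <- cluster_partition(pos, threshold, box)
    sz <- as.integer(table(lab))
    stopifnot(sum(sz) == n)
    sizes_all <- c(sizes_all, sz)
    navg[f] <- n / length(sz)
    mavg[f] <- sum(sz^2) / n
    for (cl in which(sz >= 3)) {
      pts <- .unwrap_cluster(pos, which(lab == cl), threshold, box)
      k2 <- c(k2, shape_anisotropy(pts))
    }
  }
  list(mean_size = mean(navg), mean_size_mass = mean(mavg),
       mean_k2 = if (length(k2)) mean(k2) else NA_real_,
       k2 = k2, size_hist = table(sizes_all), n_frames = nf)
}

#' Write trajectory frames as XYZ pseudo-atoms
#'
#' One pseudo-atom per protein centre of mass per frame.
#'
#' @param result A `manybody_result`.
#' @param path Output path.
#' @param rung Ladder rung to export.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(result, path, rung = 1) {
  frames <- result$frames[[rung]]
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(frames)[2]
  for (f in seq_len(dim(frames)[3])) {
    writeLines(c(as.character(n), sprintf("frame %d box %.3f", f,
                                          result$box)), con)
    pos <- t(frames[, , f])
    writeLines(sprintf("P %.3f %.3f %.3f", pos[, 1], pos[, 2], pos[, 3]),
               con)
  }
  invisible(path)
}
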