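#' Ideal (non-interacting) titration curve
#'
#' Henderson-Hasselbalch net charge of a set of independent titratable
#' sites: bases contribute `1 / (1 + 10^(pH - pKa))`, acids
#' `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param composition Data frame with columns `species` and optionally `n`
#'   (site counts, default 1 each); species must appear in the pKa table.
#'   A character vector of species labels is also accepted.
#' @param ph Solution pH (vectorised).
#' @param params A [parameter_table()].
#' @return Net charge Z in units of e, one value per `ph`.
#' @export
#' @examples
#' ideal_titration_curve(c("LYS", "LYS", "ASP", "NTR", "CTR"), ph = 7)
ideal_titration_curve <- function(composition, ph,
                                  params = parameter_table()) {
  if (is.character(composition))
    composition <- data.frame(species = composition,
                              stringsAsFactors = FALSE)
  if (nrow(composition) == 0L) stop("empty composition", call. = FALSE)
  if (is.null(composition$n)) composition$n <- 1
  pka <- params$pka_table
  rownames(pka) <- pka$species
  bad <- setdiff(composition$species, pka$species)
  if (length(bad))
    stop("species without titration reaction: ",
         paste(bad, collapse = ", "), call. = FALSE)
  vapply(ph, function(p) {
    k <- pka[composition$species, ]
    z <- ifelse(k$kind == "base",
                1 / (1 + 10^(p - k$pka)),
                -1 / (1 + 10^(k$pka - p)))
    sum(composition$n * z)
  }, numeric(1))
}

#' Henderson-Hasselbalch protonated fraction for a single site
#'
#' @param pka Site pKa.
#' @param ph Solution pH.
#' @return Protonated fraction in `[0, 1]`.
#' @export
hh_protonated_fraction <- function(pka, ph) 1 / (1 + 10^(ph - pka))

#' Constant-pH equilibration of site charges
#'
#' Runs reactive Monte Carlo over the titratable sites of a single protein
#' at fixed pH and ionic strength: a uniformly chosen site's protonation is
#' flipped with Metropolis acceptance on the ideal term
#' `ln(10) (pH - pKa)` per released proton plus the change in screened
#' electrostatic energy against all other charged beads (sites sharing a
#' bead do not interact with each other). The per-site mean occupancies can
#' then be frozen as fractional charges for many-body runs.
#'
#' @param model A `protein_model`.
#' @param cond A [solution_condition()].
#' @param steps Production flip attempts (default 1e5).
#' @param equil Equilibration flip attempts discarded first.
#' @param interact If `FALSE`, inter-site electrostatics are switched off
#'   and every site titrates ideally (oracle mode).
#' @param seed Integer seed for the sampler's own RNG.
#' @return List with `sites` (the model's site table plus `mean_occupancy`
#'   and `mean_charge` columns), `mean_z`, `mean_mu` (mean |dipole|, eA),
#'   `mean_mu_vec`, `acceptance`, and `model` — the input model with the
#'   mean fractional charges fixed (rounded to 3 decimals).
#' @export
equilibrate_mean_charges <- function(model, cond, steps = 1e5,
                                     equil = ceiling(steps / 10),
                                     interact = TRUE, seed = 1) {
  if (nrow(model$sites) == 0L) stop("model has no titratable sites",
                                    call. = FALSE)
  b <- model$beads
  g <- geometry(model)
  xyz <- sweep(as.matrix(b[, c("x", "y", "z")]), 2, g$com)
  res <- cpp_titrate(
    xyz, b$charge, b$sigma,
    as.integer(model$sites$bead - 1L),
    as.integer(model$sites$kind == "acid"),
    model$sites$pka,
    as.integer(round(model$sites$occupancy)),
    cond$ph, cond$bjerrum, cond$kappa, interact,
    as.integer(equil), as.integer(steps), as.integer(seed %% .Machine$integer.max))
  sites <- model$sites
  sites$mean_occupancy <- res$occupancy
  sites$mean_charge <- ifelse(sites$kind == "acid",
                              res$occupancy - 1, res$occupancy)
  fixed <- set_site_occupancy(model, round(res$occupancy, 3))
  list(sites = sites, mean_z = res$mean_z, mean_mu = res$mean_mu,
       mean_mu_vec = res$mean_mu_vec, acceptance = res$acceptance,
       model = fixed)
}

#' Write a per-site occupancy table and JSON summary
#'
#' @param titr Result of [equilibrate_mean_charges()].
#' @param cond The [solution_condition()] used.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return Invisibly, a list with the two paths.
#' @export
write_titration_summary <- function(titr, cond, csv_path = NULL,
                                    json_path = NULL) {
  if (!is.null(csv_path)) {
    tab <- titr$sites[, c("bead", "species", "pka", "mean_occupancy",
                          "mean_charge")]
    utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(ph = cond$ph, ionic_strength =
                                cond$ionic_strength, mean_z = titr$mean_z,
                              mean_mu = titr$mean_mu),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv_path, json = json_path))
}
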