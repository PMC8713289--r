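#' Read a run configuration file
#'
#' YAML key/value file with nested sections mirroring the defaults of the
#' two screening campaigns: pH grid 5-9 in steps of 0.5, ionic strengths
#' 0 and 0.140 M, concentrations 1/10/30 mg/mL, two-body cell radius
#' 120 A with 5 replicas, many-body box of 30 proteins with a 10-rung
#' epsilon ladder. Every numeric field is validated against its physical
#' range.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return A validated `run_config` list with elements `ph`, `salt`,
#'   `conc`, `twobody` (a [twobody_config()]), `manybody` (a
#'   [manybody_config()]), `seed`, and `structure` (path to a PDB file or
#'   `NULL` for the built-in synthetic reference).
#' @export
run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- list(
    ph = raw$ph %||% seq(5, 9, by = 0.5),
    salt = raw$salt %||% c(0, 0.140),
    conc = raw$conc %||% c(1, 10, 30),
    seed = raw$seed %||% 1L,
    structure = raw$structure
  )
  fix_n <- function(x) {
    # YAML 1.1 parses a bare `n:` key as boolean FALSE; map it back
    names(x)[names(x) %in% c("FALSE", "F")] <- "n"
    x
  }
  cfg$twobody <- do.call(twobody_config, raw$twobody %||% list())
  cfg$manybody <- do.call(manybody_config, fix_n(raw$manybody %||% list()))
  if (any(cfg$ph < 0 | cfg$ph > 14)) stop("pH outside [0, 14]",
                                          call. = FALSE)
  if (any(cfg$salt < 0)) stop("negative ionic strength", call. = FALSE)
  if (any(cfg$conc <= 0)) stop("non-positive concentration", call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_structure <- function(cfg) {
  if (is.null(cfg$structure)) ifn_alpha2a_model()
  else coarsen(parse_structure(cfg$structure))
}

#' pH x salt two-body screening campaign
#'
#' One two-body run per (pH, ionic strength, replica): constant-pH
#' equilibration for the reported mean charge and dipole, then the cell
#' simulation reduced to B2*. Per-task seeds are derived from the top
#' seed and recorded so any row can be re-run independently.
#'
#' @param config A [run_config()].
#' @param model Optional `protein_model` (defaults to the configured
#'   structure).
#' @return Data frame with one row per (pH, I, replica): columns `ph`,
#'   `ionic_strength`, `replica`, `seed`, `z`, `mu`, `sigma`, `b2`,
#'   `b2_star`.
#' @export
scan_twobody <- function(config = run_config(), model = NULL) {
  if (is.null(model)) model <- .load_structure(config)
  grid <- expand.grid(ph = config$ph, salt = config$salt)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- solution_condition(grid$ph[g], grid$salt[g])
    titr <- equilibrate_mean_charges(model, cond,
                                     seed = config$seed + 131L * g)
    for (k in seq_len(config$twobody$replicas)) {
      seed_k <- config$seed + 10007L * g + k
      row <- tryCatch({
        ens <- run_twobody(titr$model, cond, config$twobody, seed = seed_k)
        vir <- second_virial(integrate_pmf(estimate_force(ens)),
                             r_h = model$params$hydrodynamic_radius)
        data.frame(ph = cond$ph, ionic_strength = cond$ionic_strength,
                   replica = k, seed = seed_k, z = titr$mean_z,
                   mu = titr$mean_mu, sigma = vir$sigma, b2 = vir$b2,
                   b2_star = vir$b2_star, failed = FALSE)
      }, error = function(e) {
        data.frame(ph = cond$ph, ionic_strength = cond$ionic_strength,
                   replica = k, seed = seed_k, z = titr$mean_z,
                   mu = titr$mean_mu, sigma = NA, b2 = NA, b2_star = NA,
                   failed = TRUE)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' pH x salt x concentration many-body screening campaign
#'
#' Fixed average charges are equilibrated per condition, then the
#' periodic-box parallel-tempering run is reduced to mean cluster size
#' and mean shape anisotropy per ladder rung.
#'
#' @param config A [run_config()].
#' @param model Optional `protein_model`.
#' @return Data frame with one row per (pH, I, concentration, rung):
#'   columns `ph`, `ionic_strength`, `conc`, `epsilon`,
#'   `mean_cluster_size`, `mean_k2`, `frames`, `seed`.
#' @export
scan_manybody <- function(config = run_config(), model = NULL) {
  if (is.null(model)) model <- .load_structure(config)
  grid <- expand.grid(ph = config$ph, salt = config$salt,
                      conc = config$conc)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cond <- solution_condition(grid$ph[g], grid$salt[g])
    titr <- equilibrate_mean_charges(model, cond,
                                     seed = config$seed + 131L * g)
    mb <- config$manybody
    mb$conc <- grid$conc[g]
    seed_g <- config$seed + 20011L * g
    res <- tryCatch(run_manybody(titr$model, cond, mb, seed = seed_g),
                    error = function(e) NULL)
    for (k in seq_along(mb$ladder)) {
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- data.frame(
          ph = cond$ph, ionic_strength = cond$ionic_strength,
          conc = grid$conc[g], epsilon = mb$ladder[k],
          mean_cluster_size = NA, mean_k2 = NA, frames = 0, seed = seed_g,
          failed = TRUE)
        next
      }
      st <- cluster_statistics(res, rung = k)
      rows[[length(rows) + 1]] <- data.frame(
        ph = cond$ph, ionic_strength = cond$ionic_strength,
        conc = grid$conc[g], epsilon = mb$ladder[k],
        mean_cluster_size = st$mean_size, mean_k2 = st$mean_k2,
        frames = st$n_frames, seed = seed_g, failed = FALSE)
    }
  }
  do.call(rbind, rows)
}
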