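# Run configuration: flat JSON/YAML files driving any of the package's
# experiments, plus a dispatcher that writes result artifacts. Every run
# echoes its fully-resolved configuration so it can be reproduced exactly.

default_config <- function() {
  list(
    params = unclass(notch_params()),
    lattice = list(n_rows = 5L, n_cols = 12L, wrap_columns = TRUE,
                   n_dorsal_rows = 3L),
    t_end = 1500,
    solver = list(rtol = 1e-8, atol = 1e-10),
    threshold = 1.0,
    seed = NULL,
    experiment = list(kind = "simulate")
  )
}

# Recursively overlay user values on the defaults; unknown keys error.
merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    here <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base) && !identical(path, "experiment"))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !identical(nm, "experiment"))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], here)
    else base[[nm]] <- user[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  cfg$params <- unclass(as_notch_params(cfg$params))
  lat <- cfg$lattice
  if (lat$n_dorsal_rows < 0 || lat$n_dorsal_rows > lat$n_rows)
    stop("n_dorsal_rows out of range", call. = FALSE)
  hex_lattice(lat$n_rows, lat$n_cols, lat$wrap_columns)  # dimension checks
  if (cfg$t_end < 0) stop("t_end must be >= 0", call. = FALSE)
  if (is.null(cfg$experiment$kind)) cfg$experiment$kind <- "simulate"
  kinds <- c("simulate", "sweep", "perturb", "noise", "stability")
  if (!cfg$experiment$kind %in% kinds)
    stop("experiment kind must be one of: ", paste(kinds, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Load a run configuration
#'
#' Reads a JSON (or YAML, if the file ends in `.yml`/`.yaml`) configuration
#' file, fills every omitted entry with the package defaults (reference
#' parameter values, 5x12 wrapped lattice with 3 dorsal rows, `t_end` 1500,
#' solver tolerances 1e-8/1e-10) and validates it. Unknown keys and
#' out-of-range values are errors.
#'
#' @param path Path to the configuration file.
#' @return A validated configuration list of class `"notch_config"`.
#' @seealso [run_config()], [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  as_notch_config(user)
}

#' Build a configuration from a list
#'
#' @param x Named list with any subset of the configuration entries
#'   (`params`, `lattice`, `t_end`, `solver`, `threshold`, `seed`,
#'   `experiment`).
#' @return A validated `"notch_config"`.
#' @export
as_notch_config <- function(x = list()) {
  if (inherits(x, "notch_config")) return(x)
  cfg <- validate_config(merge_config(default_config(), x))
  structure(cfg, class = "notch_config")
}

#' Save a configuration as JSON
#'
#' @param cfg A `"notch_config"` (or plain list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Execute a configured experiment and write its artifacts
#'
#' Dispatches on `cfg$experiment$kind`:
#' \describe{
#'   \item{simulate}{one deterministic run; writes `final_state.csv` (cell,
#'     row, col, D, N, A, boundary) and `phenotype.json`.}
#'   \item{sweep}{phenotype sweep over `lam` or `lamN`
#'     (`experiment$swept`, `$lo`, `$hi`, `$step`); writes `sweep.csv` and
#'     `transitions.csv`.}
#'   \item{perturb}{replicate perturbation study (`experiment$target`,
#'     `$epsilons`, `$K`); writes `perturb_replicates.csv` and
#'     `perturb_summary.csv`.}
#'   \item{noise}{noisy-`lamN` run (`experiment$half_width`); writes
#'     `final_state.csv` and `phenotype.json`.}
#'   \item{stability}{two-cell equilibrium/stability analysis at the
#'     configured parameters; writes `stability.json`.}
#' }
#' Every run also writes `config_echo.json`, sufficient to reproduce it.
#'
#' @param cfg A `"notch_config"` (or list coercible to one).
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress the one-line progress messages.
#' @return The computed result object, invisibly.
#' @export
run_config <- function(cfg, out_dir, quiet = FALSE) {
  cfg <- as_notch_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- as_notch_params(cfg$params)
  lat <- hex_lattice(cfg$lattice$n_rows, cfg$lattice$n_cols,
                     cfg$lattice$wrap_columns)
  pp <- prepattern(lat, params$lam, cfg$lattice$n_dorsal_rows)
  ex <- cfg$experiment
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()

  result <- switch(
    ex$kind,
    simulate = {
      sim <- simulate_lattice(params, lat, pp, t_end = cfg$t_end,
                              rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      df <- as.data.frame(sim, threshold = cfg$threshold)
      utils::write.csv(df, file.path(out_dir, "final_state.csv"),
                       row.names = FALSE)
      ph <- summarize_phenotype(classify_boundary(sim, cfg$threshold), lat)
      jsonlite::write_json(
        list(boundary_count = ph$boundary_count,
             boundary_rows = ph$boundary_rows,
             partial_rows = ph$partial_rows),
        file.path(out_dir, "phenotype.json"), auto_unbox = TRUE, digits = NA)
      ph
    },
    sweep = {
      sw <- sweep_parameter(params, lat, ex$swept, lo = ex$lo, hi = ex$hi,
                            step = ex$step,
                            n_dorsal_rows = cfg$lattice$n_dorsal_rows,
                            t_end = cfg$t_end, threshold = cfg$threshold,
                            rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      utils::write.csv(sw$results, file.path(out_dir, "sweep.csv"),
                       row.names = FALSE)
      utils::write.csv(sw$transitions, file.path(out_dir, "transitions.csv"),
                       row.names = FALSE)
      sw
    },
    perturb = {
      st <- perturbation_study(params, lat, pp, target = ex$target,
                               epsilons = as.numeric(ex$epsilons),
                               K = if (is.null(ex$K)) 50L else ex$K,
                               seed = cfg$seed, t_end = cfg$t_end,
                               threshold = cfg$threshold,
                               rtol = cfg$solver$rtol, atol = cfg$solver$atol)
      reps <- data.frame(target = st$target,
                         epsilon = rep(st$epsilons, each = st$K),
                         replicate = rep(seq_len(st$K),
                                         times = length(st$epsilons)),
                         seed = as.vector(st$seeds),
                         count = as.vector(st$counts))
      utils::write.csv(reps, file.path(out_dir, "perturb_replicates.csv"),
                       row.names = FALSE)
      utils::write.csv(st$summary, file.path(out_dir, "perturb_summary.csv"),
                       row.names = FALSE)
      st
    },
    noise = {
      ph <- simulate_with_lamN_noise(params, lat, pp,
                                     half_width = ex$half_width,
                                     seed = cfg$seed, t_end = cfg$t_end,
                                     threshold = cfg$threshold,
                                     rtol = cfg$solver$rtol,
                                     atol = cfg$solver$atol)
      sim <- attr(ph, "sim")
      utils::write.csv(as.data.frame(sim, threshold = cfg$threshold),
                       file.path(out_dir, "final_state.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(boundary_count = ph$boundary_count,
             boundary_rows = ph$boundary_rows,
             partial_rows = ph$partial_rows,
             lamN_offsets = attr(ph, "override")$offsets),
        file.path(out_dir, "phenotype.json"), auto_unbox = TRUE, digits = NA)
      ph
    },
    stability = {
      rep <- if (params$lam == 0) stability_E0(params)
             else stability_E1(params)
      out <- list(kind = rep$equilibrium$kind,
                  equilibrium = rep$equilibrium$state,
                  eigenvalues_re = Re(rep$eigenvalues),
                  eigenvalues_im = Im(rep$eigenvalues),
                  M1 = rep$M1, M2 = rep$M2, M3 = rep$M3,
                  M3prime = rep$M3prime, ratio = rep$ratio,
                  verdict = rep$verdict)
      jsonlite::write_json(out, file.path(out_dir, "stability.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      rep
    })

  save_config(cfg, file.path(out_dir, "config_echo.json"))
  say(sprintf("%s experiment finished in %.1f s; artifacts in %s",
              ex$kind, as.numeric(difftime(Sys.time(), t0, units = "secs")),
              out_dir))
  invisible(result)
}
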