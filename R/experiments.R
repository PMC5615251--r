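# Phenotype sweeps, per-cell parameter perturbation studies and noisy
# Notch-production runs.

# Derive per-replicate child seeds reproducibly from a master seed.
# Counter-based: each (epsilon index, replicate) pair gets its own seed, so
# any single replicate can be re-run in isolation.
derive_seeds <- function(master_seed, n) {
  if (is.null(master_seed)) return(rep(NA_integer_, n))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

#' Sweep a production rate and record the phenotype
#'
#' Runs one deterministic simulation per grid value of `lam` (ventral Delta
#' production; the prepattern is rebuilt for each value) or `lamN` (Notch
#' production) and summarizes each final state into a row phenotype.
#' The reference sweeps are `lam` from 0 to 12 in steps of 0.1 at
#' `lamN = 5e-4`, and `lamN` from 0 to 0.1 in steps of 1e-4 at `lam = 9`.
#'
#' @param params A [notch_params()]; the swept entry is replaced per grid
#'   value.
#' @param lattice A [hex_lattice()].
#' @param swept `"lam"` or `"lamN"`.
#' @param values Numeric grid (strictly increasing); alternatively give
#'   `lo`, `hi`, `step`.
#' @param lo,hi,step Used to build `values = seq(lo, hi, by = step)` when
#'   `values` is missing.
#' @param n_dorsal_rows Dorsal rows of the prepattern (default 3).
#' @param t_end,threshold,... Passed to [simulate_phenotype()].
#' @return An object of class `"notch_sweep"`: list with `swept`, `grid`,
#'   `phenotypes` (list of `"notch_phenotype"`), `results` (data frame:
#'   value, boundary_count, boundary_rows, partial_rows, error), and
#'   `transitions` (data frame: value, before, after).
#' @examples
#' \donttest{
#' lat <- hex_lattice(5, 12)
#' sw <- sweep_parameter(notch_params(lam = 9), lat, "lamN",
#'                       values = c(0, 1e-4, 2e-4))
#' sw$results
#' }
#' @export
sweep_parameter <- function(params, lattice, swept = c("lam", "lamN"),
                            values = NULL, lo = NULL, hi = NULL, step = NULL,
                            n_dorsal_rows = 3, t_end = 1500, threshold = 1.0,
                            ...) {
  swept <- match.arg(swept)
  if (is.null(values)) {
    stopifnot(!is.null(lo), !is.null(hi), !is.null(step), step > 0)
    values <- if (lo > hi) numeric(0) else seq(lo, hi, by = step)
  }
  if (is.unsorted(values, strictly = TRUE))
    stop("sweep grid must be strictly increasing", call. = FALSE)

  phenotypes <- vector("list", length(values))
  errs <- rep(NA_character_, length(values))
  for (k in seq_along(values)) {
    p <- params
    p[[swept]] <- values[k]
    p <- as_notch_params(unclass(p))
    pp <- prepattern(lattice, p$lam, n_dorsal_rows)
    ph <- tryCatch(
      simulate_phenotype(p, lattice, pp, t_end = t_end,
                         threshold = threshold, ...),
      error = function(e) e)
    if (inherits(ph, "error")) {
      errs[k] <- conditionMessage(ph)
      phenotypes[k] <- list(NULL)
    } else {
      attr(ph, "sim") <- NULL  # keep the sweep object light
      phenotypes[[k]] <- ph
    }
  }

  lab <- vapply(phenotypes,
                function(p) if (is.null(p)) NA_character_ else p$label,
                character(1))
  res <- data.frame(
    value = values,
    boundary_count = vapply(phenotypes, function(p)
      if (is.null(p)) NA_integer_ else p$boundary_count, integer(1)),
    boundary_rows = vapply(phenotypes, function(p)
      if (is.null(p)) NA_character_
      else paste(p$boundary_rows, collapse = ","), character(1)),
    partial_rows = vapply(phenotypes, function(p)
      if (is.null(p)) NA_character_
      else paste(p$partial_rows, collapse = ","), character(1)),
    error = errs)

  chg <- which(lab[-1] != lab[-length(lab)])
  transitions <- data.frame(value = values[chg + 1L],
                            before = lab[chg], after = lab[chg + 1L])

  structure(list(swept = swept, grid = values, phenotypes = phenotypes,
                 results = res, transitions = transitions,
                 params = params, n_dorsal_rows = n_dorsal_rows,
                 t_end = t_end, threshold = threshold),
            class = "notch_sweep")
}

#' @export
print.notch_sweep <- function(x, ...) {
  cat(sprintf("Phenotype sweep over %s: %d grid points in [%g, %g]\n",
              x$swept, length(x$grid), min(x$grid), max(x$grid)))
  if (nrow(x$transitions)) {
    cat("  phenotype transitions:\n")
    for (k in seq_len(nrow(x$transitions)))
      cat(sprintf("    at %s = %g: %s -> %s\n", x$swept,
                  x$transitions$value[k], x$transitions$before[k],
                  x$transitions$after[k]))
  } else cat("  no phenotype transitions\n")
  invisible(x)
}

#' @export
plot.notch_sweep <- function(x, ...) {
  graphics::plot(x$results$value, x$results$boundary_count, type = "s",
                 xlab = x$swept, ylab = "boundary cells", ...)
  if (nrow(x$transitions))
    graphics::abline(v = x$transitions$value, lty = 3)
  invisible(x)
}

#' Rows whose cells are all boundary cells, per sweep point
#'
#' Helper for reading off phenotype thresholds from a sweep: the largest or
#' smallest grid value whose phenotype has a given set of fully-boundary
#' rows.
#'
#' @param sweep A `"notch_sweep"`.
#' @param rows Integer vector of rows that must all be fully boundary.
#' @param from `"smallest"` or `"largest"` matching grid value.
#' @return The matching grid value, or `NA` if none matches.
#' @export
sweep_threshold <- function(sweep, rows, from = c("smallest", "largest")) {
  from <- match.arg(from)
  ok <- vapply(sweep$phenotypes, function(p)
    !is.null(p) && all(rows %in% p$boundary_rows), logical(1))
  if (!any(ok)) return(NA_real_)
  if (from == "smallest") min(sweep$grid[ok]) else max(sweep$grid[ok])
}

#' One perturbed simulation
#'
#' Samples an independent per-cell uniform perturbation `eps * beta_i`,
#' `beta_i ~ Uniform[-1, 1]`, of the chosen parameter (`a`, `b`, or the
#' binding pair `f`), holds it constant through one simulation and returns
#' the boundary-cell count. Deterministic given `seed`.
#'
#' @param params,lattice,lam_per_cell,t_end,threshold As in
#'   [simulate_phenotype()].
#' @param target `"a"`, `"b"` or `"f"`.
#' @param epsilon Disturbance intensity (`>= 0`).
#' @param seed Integer seed for the beta draw (or `NULL` to use the current
#'   RNG state).
#' @param ... Passed to [simulate_lattice()].
#' @return Integer boundary-cell count, with the sampled
#'   [cellwise_override()] as attribute `"override"`.
#' @export
perturb_once <- function(params, lattice, lam_per_cell = NULL,
                         target = c("a", "b", "f"), epsilon, seed = NULL,
                         t_end = 1500, threshold = 1.0, ...) {
  target <- match.arg(target)
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  ov <- sample_override(target, epsilon, lattice$n_cells, params)
  ph <- simulate_phenotype(params, lattice, lam_per_cell, t_end = t_end,
                           overrides = ov, threshold = threshold, ...)
  structure(ph$boundary_count, override = ov)
}

#' Replicate perturbation study of a parameter
#'
#' For each disturbance intensity `epsilon`, runs `K` seeded replicate
#' simulations with fresh per-cell uniform perturbations of the target
#' parameter and summarizes the boundary-cell counts: mean
#' `Ybar = sum(Y_k)/K`, variance `S2 = sum((Y_k - Ybar)^2)/(K - 1)` and
#' standard error `sqrt(S2/K)`. The reference study uses `K = 50`
#' replicates per intensity at the Notch-over-expression setting
#' (`lam = 9`, `lamN = 0.008`).
#'
#' @inheritParams perturb_once
#' @param epsilons Numeric vector of disturbance intensities.
#' @param K Replicates per intensity (`>= 2`).
#' @param seed Master seed; per-replicate child seeds are derived from it
#'   (counter-based) and recorded in the result.
#' @return An object of class `"notch_perturbation"`: list with `target`,
#'   `epsilons`, `K`, `counts` (K x length(epsilons) matrix), `seeds`
#'   (same shape), and `summary` (data frame: epsilon, mean, variance,
#'   standard_error).
#' @export
perturbation_study <- function(params, lattice, lam_per_cell = NULL,
                               target = c("a", "b", "f"), epsilons,
                               K = 50, seed = 1, t_end = 1500,
                               threshold = 1.0, ...) {
  target <- match.arg(target)
  stopifnot(K >= 2, all(epsilons >= 0))
  seeds <- matrix(derive_seeds(seed, K * length(epsilons)),
                  nrow = K, ncol = length(epsilons))
  counts <- matrix(NA_integer_, K, length(epsilons))
  for (j in seq_along(epsilons)) for (k in seq_len(K)) {
    counts[k, j] <- perturb_once(params, lattice, lam_per_cell,
                                 target = target, epsilon = epsilons[j],
                                 seed = seeds[k, j], t_end = t_end,
                                 threshold = threshold, ...)
  }
  mu <- colMeans(counts)
  s2 <- apply(counts, 2, function(y) sum((y - mean(y))^2) / (length(y) - 1))
  structure(list(target = target, epsilons = epsilons, K = K,
                 counts = counts, seeds = seeds,
                 summary = data.frame(epsilon = epsilons, mean = mu,
                                      variance = s2,
                                      standard_error = sqrt(s2 / K))),
            class = "notch_perturbation")
}

#' @export
print.notch_perturbation <- function(x, ...) {
  cat(sprintf("Perturbation study of '%s': K = %d replicates per intensity\n",
              x$target, x$K))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.notch_perturbation <- function(x, ...) {
  s <- x$summary
  graphics::plot(seq_along(s$epsilon), s$mean,
                 ylim = range(c(s$mean - 2 * s$standard_error,
                                s$mean + 2 * s$standard_error)),
                 xaxt = "n", xlab = "disturbance intensity",
                 ylab = "boundary cells (mean +- 2 SE)", pch = 19, ...)
  graphics::axis(1, at = seq_along(s$epsilon), labels = s$epsilon)
  graphics::arrows(seq_along(s$epsilon), s$mean - 2 * s$standard_error,
                   seq_along(s$epsilon), s$mean + 2 * s$standard_error,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}

#' Simulation with noisy Notch production
#'
#' Adds an independent per-cell noise `e_i ~ Uniform[-half_width,
#' half_width]` to the Notch production rate `lamN`, sampled once at the
#' start and constant in time (cells whose effective rate would be negative
#' are resampled). Returns the classified phenotype. The reference noisy
#' setting is `lamN = 5e-4`, `lam = 0.3`, `half_width = 5e-4`.
#'
#' @inheritParams simulate_phenotype
#' @param half_width Noise half-width (`>= 0`).
#' @param seed Integer seed (or `NULL`).
#' @return A `"notch_phenotype"`; the sampled override is attached as
#'   attribute `"override"`.
#' @export
simulate_with_lamN_noise <- function(params, lattice, lam_per_cell = NULL,
                                     half_width, seed = NULL, t_end = 1500,
                                     threshold = 1.0, ...) {
  stopifnot(half_width >= 0)
  if (!is.null(seed)) set.seed(seed)
  ov <- sample_override("lamN", half_width, lattice$n_cells, params)
  ph <- simulate_phenotype(params, lattice, lam_per_cell, t_end = t_end,
                           overrides = ov, threshold = threshold, ...)
  attr(ph, "override") <- ov
  ph
}
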