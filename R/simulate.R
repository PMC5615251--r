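#' Integrate the lattice system
#'
#' Runs the coupled per-cell dynamics from an initial state (all
#' concentrations zero by default) to `t_end` with an implicit stiff
#' integrator (`deSolve::lsode`, BDF) supplied with the analytic Jacobian.
#' The Delta-production term `lam / (1 + Delta_inh * A)` is sharply
#' switching (`Delta_inh = 1e6`), which makes the onset of patterning stiff;
#' the BDF method with the exact Jacobian integrates the 5x12 reference
#' lattice in well under a second. The run is fully deterministic given
#' `(params, lattice, prepattern, overrides)`.
#'
#' @param params A [notch_params()].
#' @param lattice A [hex_lattice()].
#' @param lam_per_cell A [prepattern()] or numeric vector of per-cell Delta
#'   production rates. Defaults to `prepattern(lattice, params$lam, 3)`
#'   when the lattice has more than 3 rows, otherwise all-ventral.
#' @param t_end End of the integration interval `[0, t_end]` (default 1500,
#'   the reference patterning horizon).
#' @param overrides Optional [cellwise_override()]; sampled by the caller
#'   (e.g. [perturb_once()]), never in here.
#' @param init Initial state: `"zero"` (default), a single number (uniform
#'   constant for all components), or a full numeric vector of length
#'   `3 * n_cells` in `(D, N, A)` block layout.
#' @param times Optional vector of sample times for the stored trajectory;
#'   defaults to `c(0, t_end)`. `t_end` is appended if missing.
#' @param rtol,atol Relative/absolute integration tolerances (defaults
#'   `1e-8` / `1e-10`). Boundary thresholds in the production-rate sweeps
#'   sit close to the classification threshold, so tolerances are part of
#'   any reported configuration.
#' @param maxsteps Maximum internal solver steps between output times.
#' @return An object of class `"notch_sim"`: list with `final_state`
#'   (n x 3 matrix, columns D, N, A), `trajectory` (deSolve output matrix),
#'   `t_end`, `params`, `lattice`, `lam_per_cell`, `overrides`, `solver`.
#' @examples
#' lat <- hex_lattice(5, 12)
#' sim <- simulate_lattice(notch_params(lam = 9, lamN = 0.008), lat)
#' summary(sim)
#' @export
simulate_lattice <- function(params, lattice,
                             lam_per_cell = NULL,
                             t_end = 1500, overrides = NULL,
                             init = "zero", times = NULL,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 5e5) {
  stopifnot(inherits(params, "notch_params"), inherits(lattice, "hex_lattice"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end < 0)
    stop("t_end must be a single non-negative number", call. = FALSE)
  n <- lattice$n_cells
  if (is.null(lam_per_cell)) {
    ndr <- if (lattice$n_rows > 3L) 3L else 0L
    lam_per_cell <- prepattern(lattice, params$lam, ndr)
  }
  if (length(lam_per_cell) != n)
    stop("lam_per_cell length does not match the lattice", call. = FALSE)

  y0 <- if (identical(init, "zero")) rep(0, 3L * n)
        else if (is.numeric(init) && length(init) == 1L) rep(init, 3L * n)
        else if (is.numeric(init) && length(init) == 3L * n) as.numeric(init)
        else stop("init must be \"zero\", one number, or length 3*n_cells",
                  call. = FALSE)

  vf <- make_vector_field(params, lattice, lam_per_cell, overrides)

  if (t_end == 0) {
    traj <- matrix(c(0, y0), nrow = 1,
                   dimnames = list(NULL, c("time", paste0("y", 1:(3 * n)))))
  } else {
    tt <- if (is.null(times)) c(0, t_end) else sort(unique(c(times, t_end)))
    tt <- tt[tt >= 0 & tt <= t_end]
    if (tt[1] != 0) tt <- c(0, tt)
    traj <- deSolve::lsode(y0, tt, vf$rhs, parms = NULL,
                           jacfunc = vf$jac, jactype = "fullusr",
                           rtol = rtol, atol = atol, maxsteps = maxsteps)
    istate <- attr(traj, "istate")
    if (!is.null(istate) && istate[1] < 0)
      stop("integration failed at t = ", traj[nrow(traj), 1],
           " (istate = ", istate[1], ")", call. = FALSE)
  }

  structure(list(
    final_state = state_to_matrix(traj[nrow(traj), -1], n),
    trajectory = traj, t_end = t_end,
    params = params, lattice = lattice, lam_per_cell = lam_per_cell,
    overrides = overrides,
    solver = list(method = "lsode", rtol = rtol, atol = atol)),
    class = "notch_sim")
}

#' Integrate the two-cell reduction
#'
#' Convenience wrapper: the two-cell system (two mutually neighbouring
#' ventral cells) integrated with the same solver settings as
#' [simulate_lattice()]. Used to check convergence towards the closed-form
#' equilibria.
#'
#' @inheritParams simulate_lattice
#' @return A `"notch_sim"` whose `final_state` has 2 rows; additionally
#'   `$final_e` gives the state in `(D1, N1, A1, D2, N2, A2)` layout.
#' @export
simulate_two_cell <- function(params, t_end = 1500, init = "zero",
                              times = NULL, rtol = 1e-10, atol = 1e-12) {
  lat2 <- hex_lattice(1, 2, wrap_columns = TRUE)
  sim <- simulate_lattice(params, lat2,
                          lam_per_cell = rep(params$lam, 2),
                          t_end = t_end, init = init, times = times,
                          rtol = rtol, atol = atol)
  fs <- sim$final_state
  sim$final_e <- c(fs[1, ], fs[2, ])
  names(sim$final_e) <- c("D1", "N1", "A1", "D2", "N2", "A2")
  sim
}

#' Classify boundary cells
#'
#' A cell is a boundary cell when its active-Notch concentration is at or
#' above the threshold (1.0 by default, inclusive).
#'
#' @param state A `"notch_sim"`, an n x 3 state matrix, or a numeric vector
#'   of active-Notch concentrations.
#' @param threshold Classification threshold (inclusive).
#' @return Logical vector, one entry per cell.
#' @examples
#' classify_boundary(c(1.0, 0.999, 1.2))
#' @export
classify_boundary <- function(state, threshold = 1.0) {
  A <- if (inherits(state, "notch_sim")) state$final_state[, "A"]
       else if (is.matrix(state)) state[, "A"]
       else as.numeric(state)
  A >= threshold
}

#' Summarize a boundary mask into a row phenotype
#'
#' Reduces a per-cell boundary mask to the row-level phenotype used to
#' compare simulation outcomes: which rows consist entirely of boundary
#' cells, which contain some but not all, and the total count.
#'
#' @param mask Logical vector (per cell), e.g. from [classify_boundary()].
#' @param lattice The [hex_lattice()] the mask lives on.
#' @return An object of class `"notch_phenotype"`: list with
#'   `boundary_mask`, `boundary_count`, `boundary_rows` (rows fully
#'   boundary), `partial_rows`, `n_rows`, and a compact `label` string.
#' @export
summarize_phenotype <- function(mask, lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (length(mask) != lattice$n_cells)
    stop("mask length does not match the lattice", call. = FALSE)
  mask <- as.logical(mask)
  by_row_all <- tapply(mask, lattice$row_of, all)
  by_row_any <- tapply(mask, lattice$row_of, any)
  rows <- as.integer(names(by_row_all))
  full <- rows[by_row_all]
  partial <- rows[by_row_any & !by_row_all]
  label <- paste0(
    "full:", if (length(full)) paste(full, collapse = ",") else "-",
    "|partial:", if (length(partial)) paste(partial, collapse = ",") else "-")
  structure(list(boundary_mask = mask, boundary_count = sum(mask),
                 boundary_rows = full, partial_rows = partial,
                 n_rows = lattice$n_rows, label = label),
            class = "notch_phenotype")
}

#' Simulate and classify in one call
#'
#' @inheritParams simulate_lattice
#' @param threshold Boundary threshold passed to [classify_boundary()].
#' @return A `"notch_phenotype"` (the simulation itself is attached as
#'   attribute `"sim"`).
#' @export
simulate_phenotype <- function(params, lattice, lam_per_cell = NULL,
                               t_end = 1500, overrides = NULL,
                               threshold = 1.0, ...) {
  sim <- simulate_lattice(params, lattice, lam_per_cell, t_end, overrides,
                          ...)
  ph <- summarize_phenotype(classify_boundary(sim, threshold), lattice)
  attr(ph, "sim") <- sim
  ph
}

#' @export
print.notch_phenotype <- function(x, ...) {
  cat("Boundary phenotype:", x$boundary_count, "boundary cells\n")
  cat("  fully boundary rows:",
      if (length(x$boundary_rows)) paste(x$boundary_rows, collapse = ", ")
      else "none", "\n")
  if (length(x$partial_rows))
    cat("  partially boundary rows:",
        paste(x$partial_rows, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.notch_sim <- function(x, ...) {
  cat(sprintf("Delta-Notch lattice simulation: %d cells, t in [0, %g]\n",
              x$lattice$n_cells, x$t_end))
  cat(sprintf("  final ranges: D [%.3g, %.3g]  N [%.3g, %.3g]  A [%.3g, %.3g]\n",
              min(x$final_state[, "D"]), max(x$final_state[, "D"]),
              min(x$final_state[, "N"]), max(x$final_state[, "N"]),
              min(x$final_state[, "A"]), max(x$final_state[, "A"])))
  invisible(x)
}

#' @export
summary.notch_sim <- function(object, threshold = 1.0, ...) {
  ph <- summarize_phenotype(classify_boundary(object, threshold),
                            object$lattice)
  print(object)
  print(ph)
  invisible(ph)
}

#' Final state as a data frame
#'
#' One row per cell: index, lattice position, concentrations and boundary
#' flag. This is the flat table the command-line interface writes as CSV.
#'
#' @param x A `"notch_sim"`.
#' @param threshold Boundary threshold.
#' @param ... Unused.
#' @return A `data.frame` with columns `cell, row, col, D, N, A, boundary`.
#' @export
as.data.frame.notch_sim <- function(x, ..., threshold = 1.0) {
  fs <- x$final_state
  data.frame(cell = seq_len(x$lattice$n_cells),
             row = x$lattice$row_of, col = x$lattice$col_of,
             D = fs[, "D"], N = fs[, "N"], A = fs[, "A"],
             boundary = classify_boundary(x, threshold))
}

#' Plot the final active-Notch pattern
#'
#' Draws the lattice with one point per cell (odd rows offset right by half
#' a cell), shaded by active-Notch level; boundary cells are ringed.
#'
#' @param x A `"notch_sim"`.
#' @param threshold Boundary threshold for the rings.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot.notch_sim <- function(x, threshold = 1.0, ...) {
  df <- as.data.frame(x, threshold = threshold)
  xo <- df$col + ifelse(df$row %% 2 == 1, 0.5, 0)
  yo <- x$lattice$n_rows - df$row + 1
  rel <- pmin(df$A / max(max(df$A), .Machine$double.eps), 1)
  graphics::plot(xo, yo, pch = 21, cex = 2.2,
                 bg = grDevices::gray(1 - 0.8 * rel),
                 xlab = "column", ylab = "row (1 = dorsal, at top)",
                 yaxt = "n", main = "active Notch", ...)
  graphics::axis(2, at = rev(seq_len(x$lattice$n_rows)),
                 labels = seq_len(x$lattice$n_rows))
  if (any(df$boundary))
    graphics::points(xo[df$boundary], yo[df$boundary], pch = 1, cex = 2.8,
                     lwd = 2)
  invisible(df)
}
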