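# Numerical cutoff below which a cell is treated as containing no molecules.
# The conversion term a*N/(b*D + N) has a removable discontinuity at the
# origin (it equals a for any N != 0 when D = 0); without a cutoff, implicit
# solvers leak denormal-scale roundoff into cells resting at (0,0,0) and the
# ratio N/N then switches their conversion on spuriously. 1e-20 is far below
# every concentration scale of the model (~1e-6 .. 1e2) and far above the
# observed leak scale (~1e-40), so the empty state is exactly invariant
# while any real trajectory crosses the cutoff in a single solver step.
.empty_cutoff <- 1e-20

#' Notch conversion flux
#'
#' The saturating rate `a * N / (b * D + N)` at which inactive Notch is
#' converted to active Notch, cis-inhibited by the cell's own Delta. The
#' flux is bounded by `a` in the physical region and equals `a` exactly for
#' a Delta-free cell with any non-zero Notch level. A cell with (numerically)
#' no molecules at all (`b*|D| + |N|` below a 1e-20 cutoff) converts nothing.
#'
#' Arguments recycle to a common length, so the flux can be evaluated for a
#' whole lattice at once.
#'
#' @param D,N Delta and inactive-Notch concentrations.
#' @param a Conversion rate (possibly per-cell).
#' @param b Cis-inhibition coefficient (possibly per-cell).
#' @return Conversion rate(s), same length as the recycled arguments.
#' @examples
#' conversion_flux(0, 0.5, 0.012, 69)  # Delta-free: full rate a
#' conversion_flux(0, 0,   0.012, 69)  # empty cell: 0
#' conversion_flux(1, 1,   0.012, 69)  # 0.012 / 70
#' @export
conversion_flux <- function(D, N, a, b) {
  den <- b * D + N
  out <- ifelse(b * abs(D) + abs(N) <= .empty_cutoff | den == 0,
                0, a * N / den)
  as.numeric(out)
}

# Partial derivatives of the conversion flux wrt D and N (same guard).
conversion_flux_grad <- function(D, N, a, b) {
  den <- b * D + N
  empty <- b * abs(D) + abs(N) <= .empty_cutoff | den == 0
  list(dD = as.numeric(ifelse(empty, 0, -a * b * N / den^2)),
       dN = as.numeric(ifelse(empty, 0, a * b * D / den^2)))
}

#' Per-cell additive parameter override
#'
#' Represents the perturbed systems in which one parameter receives a
#' constant per-cell additive term: `a + eps*beta_i` (conversion-rate
#' perturbation), `b + eps*beta_i`, `f + eps*beta_i` (applied to both binding
#' rates `f1` and `f2` of cell `i`), or `lamN + e_i` (noisy Notch
#' production). Offsets are sampled once by the caller and held constant
#' through the integration.
#'
#' @param target One of `"a"`, `"b"`, `"f"`, `"lamN"`.
#' @param offsets Numeric vector of per-cell additive terms (length = number
#'   of cells).
#' @return An object of class `"cellwise_override"`.
#' @seealso [sample_override()] for the seeded uniform sampling used by the
#'   perturbation experiments.
#' @export
cellwise_override <- function(target = c("a", "b", "f", "lamN"), offsets) {
  target <- match.arg(target)
  if (!is.numeric(offsets) || any(!is.finite(offsets)))
    stop("offsets must be finite numeric", call. = FALSE)
  structure(list(target = target, offsets = as.numeric(offsets)),
            class = "cellwise_override")
}

#' Sample a uniform per-cell override
#'
#' Draws `beta_i ~ Uniform[-1, 1]` independently per cell and returns the
#' override with offsets `epsilon * beta_i`. Draws that would push the
#' effective parameter negative are resampled (for `lamN`, offsets are drawn
#' from `Uniform[-epsilon, epsilon]` with the same resampling rule), which
#' preserves the conditional uniform shape; at the reference intensities
#' violations cannot occur because `epsilon` is far below each parameter.
#'
#' @param target One of `"a"`, `"b"`, `"f"`, `"lamN"`.
#' @param epsilon Disturbance intensity (half-width of the additive noise),
#'   `>= 0`.
#' @param n_cells Number of cells.
#' @param params A [notch_params()]; used to enforce non-negativity of the
#'   effective per-cell parameter.
#' @return A [cellwise_override()]. Uses the current RNG state; seed it with
#'   `set.seed()` for reproducibility.
#' @export
sample_override <- function(target = c("a", "b", "f", "lamN"), epsilon,
                            n_cells, params) {
  target <- match.arg(target)
  stopifnot(epsilon >= 0)
  base <- switch(target, a = params$a, b = params$b,
                 f = min(params$f1, params$f2), lamN = params$lamN)
  off <- epsilon * stats::runif(n_cells, -1, 1)
  bad <- base + off < 0
  while (any(bad)) {
    off[bad] <- epsilon * stats::runif(sum(bad), -1, 1)
    bad <- base + off < 0
  }
  cellwise_override(target, off)
}

# Resolve per-cell effective parameter vectors given an optional override.
effective_params <- function(params, n_cells, lam_per_cell,
                             overrides = NULL) {
  eff <- list(lam = rep_len(as.numeric(lam_per_cell), n_cells),
              lamN = rep(params$lamN, n_cells),
              a = rep(params$a, n_cells),
              b = rep(params$b, n_cells),
              f1 = rep(params$f1, n_cells),
              f2 = rep(params$f2, n_cells))
  if (!is.null(overrides)) {
    stopifnot(inherits(overrides, "cellwise_override"))
    off <- overrides$offsets
    if (length(off) != n_cells)
      stop("override offsets length (", length(off),
           ") does not match cell count (", n_cells, ")", call. = FALSE)
    switch(overrides$target,
           a = { eff$a <- eff$a + off },
           b = { eff$b <- eff$b + off },
           f = { eff$f1 <- eff$f1 + off; eff$f2 <- eff$f2 + off },
           lamN = { eff$lamN <- eff$lamN + off })
    for (nm in c("a", "b", "f1", "f2", "lamN"))
      if (any(eff[[nm]] < 0))
        stop("override drives effective '", nm, "' negative", call. = FALSE)
  }
  eff
}

# Build the vector field and its analytic Jacobian for a lattice.
# State layout: y = (D_1..D_n, N_1..N_n, A_1..A_n).
# Returns list(rhs, jac, n) with deSolve-style signatures.
make_vector_field <- function(params, lattice, lam_per_cell,
                              overrides = NULL) {
  stopifnot(inherits(params, "notch_params"), inherits(lattice, "hex_lattice"))
  n <- lattice$n_cells
  eff <- effective_params(params, n, lam_per_cell, overrides)
  adj <- lattice$adjacency
  deg <- lengths(lattice$neighbors)
  d1 <- params$d1; d2 <- params$d2; d3 <- params$d3
  Dl <- params$Delta_inh
  iD <- seq_len(n); iN <- n + iD; iA <- 2L * n + iD

  rhs <- function(t, y, parms) {
    D <- y[iD]; N <- y[iN]; A <- y[iA]
    cf <- conversion_flux(D, N, eff$a, eff$b)
    dD <- eff$lam / (1 + Dl * A) - (d1 + deg * eff$f1) * D
    dN <- eff$lamN - d2 * N + eff$f2 * as.vector(adj %*% D) - cf
    dA <- -d3 * A + cf
    list(c(dD, dN, dA))
  }

  jac <- function(t, y, parms) {
    D <- y[iD]; N <- y[iN]; A <- y[iA]
    g <- conversion_flux_grad(D, N, eff$a, eff$b)
    J <- matrix(0, 3L * n, 3L * n)
    J[cbind(iD, iD)] <- -(d1 + deg * eff$f1)
    J[cbind(iD, iA)] <- -Dl * eff$lam / (1 + Dl * A)^2
    J[iN, iD] <- eff$f2 * adj
    J[cbind(iN, iD)] <- J[cbind(iN, iD)] - g$dD
    J[cbind(iN, iN)] <- -d2 - g$dN
    J[cbind(iA, iD)] <- g$dD
    J[cbind(iA, iN)] <- g$dN
    J[cbind(iA, iA)] <- -d3
    J
  }

  list(rhs = rhs, jac = jac, n = n)
}

#' Right-hand side of the lattice system
#'
#' Evaluates the time derivative of the full state for the coupled per-cell
#' dynamics: for each cell `i`,
#' \deqn{dD_i/dt = \lambda_i/(1 + \Delta A_i) - d_1 D_i - |NG(i)| f_1 D_i,}
#' \deqn{dN_i/dt = \lambda_N - d_2 N_i + \sum_{j \in NG(i)} f_2 D_j -
#'   a N_i/(b D_i + N_i),}
#' \deqn{dA_i/dt = -d_3 A_i + a N_i/(b D_i + N_i),}
#' where `NG(i)` are the lattice neighbours of `i` and `lambda_i` is the
#' prepattern production rate. Mostly useful for testing and for inspecting
#' the field; [simulate_lattice()] integrates it.
#'
#' @param state Numeric vector `c(D, N, A)` of length `3 * n_cells`, or a
#'   3-column matrix with columns D, N, A.
#' @param params A [notch_params()].
#' @param lattice A [hex_lattice()].
#' @param lam_per_cell A [prepattern()] (or numeric vector) of per-cell Delta
#'   production rates.
#' @param overrides Optional [cellwise_override()].
#' @return Numeric vector of derivatives, length `3 * n_cells`, in the same
#'   `(D, N, A)` block layout.
#' @export
notch_rhs <- function(state, params, lattice, lam_per_cell,
                      overrides = NULL) {
  if (is.matrix(state)) state <- c(state[, 1], state[, 2], state[, 3])
  n <- lattice$n_cells
  if (length(state) != 3L * n)
    stop("state length (", length(state), ") does not match 3 * n_cells (",
         3L * n, ")", call. = FALSE)
  vf <- make_vector_field(params, lattice, lam_per_cell, overrides)
  vf$rhs(0, state, NULL)[[1]]
}

#' Right-hand side of the two-cell reduction
#'
#' The two-cell system used for the equilibrium and stability analysis: two
#' cells that are each other's sole neighbour, both producing Delta at rate
#' `lam`. Coded directly from the six scalar equations (independently of the
#' lattice machinery, which must agree with it on a 1x2 wrapped lattice).
#'
#' @param state Numeric vector `(D1, N1, A1, D2, N2, A2)`.
#' @param params A [notch_params()].
#' @return Numeric vector of the six derivatives, same layout.
#' @export
two_cell_rhs <- function(state, params) {
  stopifnot(length(state) == 6L, inherits(params, "notch_params"))
  D1 <- state[1]; N1 <- state[2]; A1 <- state[3]
  D2 <- state[4]; N2 <- state[5]; A2 <- state[6]
  c1 <- conversion_flux(D1, N1, params$a, params$b)
  c2 <- conversion_flux(D2, N2, params$a, params$b)
  with(params, c(
    lam / (1 + Delta_inh * A1) - d1 * D1 - f1 * D1,
    lamN - d2 * N1 + f2 * D2 - c1,
    -d3 * A1 + c1,
    lam / (1 + Delta_inh * A2) - d1 * D2 - f1 * D2,
    lamN - d2 * N2 + f2 * D1 - c2,
    -d3 * A2 + c2))
}

# Internal: state layout helpers shared by simulate/stability code.
state_to_matrix <- function(y, n) {
  cbind(D = y[seq_len(n)], N = y[n + seq_len(n)], A = y[2L * n + seq_len(n)])
}
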