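# Shared fixtures and independent oracles.

ref_params <- function(...) notch_params(...)

ref_lattice <- function() hex_lattice(5, 12, wrap_columns = TRUE)

# Independent adjacency oracle: place hexagon centres geometrically
# (odd rows shifted right by half a cell, row spacing sqrt(3)/2) and call
# two cells adjacent iff their centre distance is 1 (up to fp tolerance),
# minimizing over +-n_cols column shifts when the lattice wraps.
oracle_neighbors <- function(n_rows, n_cols, wrap) {
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  x <- col + ifelse(row %% 2 == 1, 0.5, 0)
  y <- row * sqrt(3) / 2
  shifts <- if (wrap) c(-n_cols, 0, n_cols) else 0
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    hits <- integer(0)
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- min(vapply(shifts, function(s)
        (x[i] - x[j] - s)^2 + (y[i] - y[j])^2, numeric(1)))
      if (abs(d2 - 1) < 1e-9) hits <- c(hits, j)
    }
    nb[[i]] <- hits
  }
  nb
}

# Random strictly-positive interior state for derivative checks, away from
# the conversion-term discontinuity.
random_state <- function(n, min = 0.05, max = 3) {
  matrix(stats::runif(3 * n, min, max), ncol = 3,
         dimnames = list(NULL, c("D", "N", "A")))
}

# Central finite differences of a vector field.
numeric_jacobian <- function(f, y, h = 1e-6) {
  m <- length(f(y))
  J <- matrix(0, m, length(y))
  for (k in seq_along(y)) {
    e <- rep(0, length(y)); e[k] <- h
    J[, k] <- (f(y + e) - f(y - e)) / (2 * h)
  }
  J
}

# Random parameter draw with lam = 0 (for E0 checks); lamN kept away from a
# so the E0 Jacobian is non-singular.
random_params_E0 <- function() {
  repeat {
    a <- stats::runif(1, 0.005, 0.05)
    lamN <- stats::runif(1, 0, 0.1)
    if (abs(lamN - a) > 1e-3) break
  }
  notch_params(lam = 0, lamN = lamN,
               d1 = stats::runif(1, 0.005, 0.05),
               d2 = stats::runif(1, 0.005, 0.05),
               d3 = stats::runif(1, 0.005, 0.05),
               f1 = stats::runif(1, 0.1, 1), f2 = stats::runif(1, 0.1, 1),
               a = a, b = stats::runif(1, 10, 100),
               Delta_inh = 10^stats::runif(1, 4, 7))
}

# Random parameter draw with lam > 0 that admits an E1 equilibrium.
random_params_E1 <- function() {
  repeat {
    p <- notch_params(lam = stats::runif(1, 0.5, 40),
                      lamN = stats::runif(1, 0.0005, 0.09),
                      d1 = stats::runif(1, 0.005, 0.05),
                      d2 = stats::runif(1, 0.005, 0.05),
                      d3 = stats::runif(1, 0.005, 0.05),
                      f1 = stats::runif(1, 0.1, 1),
                      f2 = stats::runif(1, 0.1, 1),
                      a = stats::runif(1, 0.005, 0.05),
                      b = stats::runif(1, 10, 100),
                      Delta_inh = 10^stats::runif(1, 4, 7))
    eq <- tryCatch(equilibrium_E1(p), error = function(e) NULL)
    if (!is.null(eq)) return(p)
  }
}
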