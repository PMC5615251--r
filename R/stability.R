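# Two-cell equilibria, Jacobians and Routh-Hurwitz stability verdicts.
# All states here use the (D1, N1, A1, D2, N2, A2) layout of the two-cell
# reduction; equilibria are symmetric (cell 1 = cell 2).

new_equilibrium <- function(kind, state, cubic = NULL, params,
                            residual_tol = 1e-8, check = TRUE) {
  res <- if (check) max(abs(two_cell_rhs(state, params))) else NA_real_
  if (check && res > residual_tol)
    stop(kind, " construction failed the residual check (residual = ",
         signif(res, 3), ")", call. = FALSE)
  structure(list(kind = kind, state = state, cubic_coefficients = cubic,
                 residual = res, params = params),
            class = "notch_equilibrium")
}

#' @export
print.notch_equilibrium <- function(x, ...) {
  cat(sprintf("Two-cell equilibrium %s (residual %.2e)\n", x$kind,
              x$residual))
  s <- x$state
  cat(sprintf("  D = %.6g, N = %.6g, A = %.6g (both cells)\n",
              s[1], s[2], s[3]))
  invisible(x)
}

#' Delta-free equilibrium E0 of the two-cell system
#'
#' At `lam = 0` (Delta mis-expression) the symmetric equilibrium is
#' `D = 0`, `N = (lamN - a)/d2`, `A = a/d3` in both cells. When `lamN < a`
#' the Notch component is negative: the conversion term `a N/(b D + N)`
#' equals `a` for any non-zero `N` of a Delta-free cell, so the algebraic
#' equilibrium sits outside the non-negative orthant. It is still an exact
#' equilibrium of the model and is returned with a warning.
#'
#' @param params A [notch_params()] with `lam = 0`.
#' @return A `"notch_equilibrium"` of kind `"E0"` with `state`
#'   `(D1, N1, A1, D2, N2, A2)`.
#' @export
equilibrium_E0 <- function(params) {
  stopifnot(inherits(params, "notch_params"))
  if (params$lam != 0)
    stop("E0 requires lam = 0 (use equilibrium_E1 for lam > 0)",
         call. = FALSE)
  N0 <- (params$lamN - params$a) / params$d2
  A0 <- params$a / params$d3
  if (N0 < 0)
    warning("lamN < a: equilibrium E0 lies outside the non-negative orthant",
            call. = FALSE)
  # at the knife edge lamN = a the state has N = 0 with D = 0, i.e. it sits
  # on the conversion term's removable discontinuity; the residual identity
  # holds only as a limit there, so the numeric check is skipped
  new_equilibrium("E0", c(0, N0, A0, 0, N0, A0), params = params,
                  residual_tol = 1e-8, check = N0 != 0)
}

#' Cubic coefficients for the active-Notch equilibrium level
#'
#' The symmetric equilibrium of the two-cell system at `lam > 0` has an
#' active-Notch level `A` solving the cubic
#' `m1 A^3 + m2 A^2 + m3 A + m4 = 0` with
#' \deqn{m_1 = -d_3^2 (d_1 + f_1) \Delta,}
#' \deqn{m_2 = d_3 (d_1+f_1)(a\Delta - d_3) + \Delta d_3 \lambda_N (d_1+f_1),}
#' \deqn{m_3 = a d_3 (d_1+f_1) - \lambda_N (d_1+f_1)(a\Delta - d_3) +
#'   d_3 f_2 \lambda + b d_2 d_3 \lambda,}
#' \deqn{m_4 = -a \lambda_N (d_1+f_1) - a f_2 \lambda.}
#' `m1` is always negative and `m4` is negative whenever `a`, `lam` and `f2`
#' are positive.
#'
#' @param params A [notch_params()] with `lam > 0`.
#' @return Named numeric vector `c(m1, m2, m3, m4)`.
#' @export
cubic_coefficients <- function(params) {
  stopifnot(inherits(params, "notch_params"))
  if (params$lam <= 0)
    stop("the cubic applies to lam > 0 (use equilibrium_E0 at lam = 0)",
         call. = FALSE)
  with(params, {
    df <- d1 + f1
    c(m1 = -d3^2 * df * Delta_inh,
      m2 = d3 * df * (a * Delta_inh - d3) + Delta_inh * d3 * lamN * df,
      m3 = a * d3 * df - lamN * df * (a * Delta_inh - d3) +
        d3 * f2 * lam + b * d2 * d3 * lam,
      m4 = -a * lamN * df - a * f2 * lam)
  })
}

# All roots of the monic depressed form via Cardano with complex
# intermediates (handles the casus irreducibilis); m = c(m1, m2, m3, m4).
cardano_roots <- function(m) {
  p2 <- m[[2]] / m[[1]]; p1 <- m[[3]] / m[[1]]; p0 <- m[[4]] / m[[1]]
  p <- p1 - p2^2 / 3
  q <- 2 * p2^3 / 27 - p2 * p1 / 3 + p0
  s <- sqrt(as.complex(q^2 / 4 + p^3 / 27))
  u <- (-q / 2 + s)^(1 / 3)
  if (Mod(u) < 1e-300) u <- (-q / 2 - s)^(1 / 3)
  if (Mod(u) < 1e-300) return(rep(-p2 / 3, 3))  # triple root
  om <- exp(2i * pi / 3)
  uk <- u * om^(0:2)
  roots <- uk - p / (3 * uk) - p2 / 3
  roots
}

#' Positive admissible root of the equilibrium cubic
#'
#' Solves the cubic of [cubic_coefficients()] for the active-Notch level of
#' the symmetric `lam > 0` equilibrium. The admissible root must lie in
#' `(0, a/d3)` so that the back-substituted Notch level is positive. Two
#' independent routes are computed: the closed-form Cardano expression
#' (complex intermediates, real-root extraction) and a companion-matrix
#' polynomial solve (`polyroot`); they must agree to `1e-9`, and the
#' `polyroot` result is authoritative if the Cardano branch degenerates.
#'
#' @param params A [notch_params()] with `lam > 0`.
#' @param method `"both"` (default, with cross-check), `"cardano"` or
#'   `"polyroot"`.
#' @return The admissible root (single number) with attribute `"all_real"`
#'   listing every real root of the cubic.
#' @export
solve_A1 <- function(params, method = c("both", "cardano", "polyroot")) {
  method <- match.arg(method)
  m <- cubic_coefficients(params)
  A_sup <- params$a / params$d3

  real_of <- function(z) {
    rl <- Re(z[abs(Im(z)) <= 1e-8 * pmax(1, Mod(z))])
    sort(rl)
  }
  pick <- function(rr) {
    adm <- rr[rr > 0 & rr < A_sup]
    if (!length(adm))
      stop("no admissible equilibrium: no cubic root in (0, a/d3)",
           call. = FALSE)
    # polish with Newton and keep the smallest admissible root
    r <- min(adm)
    for (k in 1:4) {
      f <- ((m[[1]] * r + m[[2]]) * r + m[[3]]) * r + m[[4]]
      fp <- (3 * m[[1]] * r + 2 * m[[2]]) * r + m[[3]]
      if (fp == 0) break
      r <- r - f / fp
    }
    r
  }

  roots_pr <- real_of(polyroot(rev(unname(m))))
  if (method == "polyroot") {
    r <- pick(roots_pr)
  } else {
    roots_ca <- real_of(cardano_roots(m))
    if (method == "cardano") {
      r <- pick(roots_ca)
    } else {
      # companion-matrix route is authoritative; Cardano cross-checks it
      r <- pick(roots_pr)
      rc <- tryCatch(pick(roots_ca), error = function(e) NULL)
      if (!is.null(rc) && abs(rc - r) > 1e-9 * max(1, abs(r)))
        warning("Cardano and companion-matrix roots disagree beyond 1e-9; ",
                "using the companion-matrix root", call. = FALSE)
    }
  }
  structure(r, all_real = roots_pr)
}

#' Delta-expressing equilibrium E1 of the two-cell system
#'
#' At `lam > 0` the symmetric equilibrium is obtained by back-substituting
#' the admissible cubic root `A1`:
#' `D1 = lam / ((1 + Delta_inh*A1) (d1 + f1))` and
#' `N1 = b d3 lam A1 / ((1 + Delta_inh*A1) (d1 + f1) (a - d3 A1))`,
#' identical in both cells.
#'
#' @param params A [notch_params()] with `lam > 0`.
#' @return A `"notch_equilibrium"` of kind `"E1"` carrying the cubic
#'   coefficients.
#' @export
equilibrium_E1 <- function(params) {
  stopifnot(inherits(params, "notch_params"))
  A1 <- as.numeric(solve_A1(params))
  m <- cubic_coefficients(params)
  with(params, {
    w <- (1 + Delta_inh * A1) * (d1 + f1)
    D1 <- lam / w
    N1 <- b * d3 * lam * A1 / (w * (a - d3 * A1))
    new_equilibrium("E1", c(D1, N1, A1, D1, N1, A1), cubic = m,
                    params = params, residual_tol = 1e-8)
  })
}

#' Analytic Jacobian of the two-cell system
#'
#' The 6x6 Jacobian of [two_cell_rhs()] at a given state, from the
#' closed-form partial derivatives (the conversion-term derivatives are
#' `-abN/(bD+N)^2` w.r.t. `D` and `abD/(bD+N)^2` w.r.t. `N`).
#'
#' @param params A [notch_params()].
#' @param state Two-cell state `(D1, N1, A1, D2, N2, A2)` with
#'   `b*D + N != 0` in each cell.
#' @return A 6x6 numeric matrix.
#' @export
jacobian_two_cell <- function(params, state) {
  stopifnot(length(state) == 6L)
  blocks <- lapply(c(0L, 3L), function(off) {
    D <- state[off + 1]; N <- state[off + 2]; A <- state[off + 3]
    if (params$b * D + N == 0)
      stop("singular point: b*D + N = 0 in a cell", call. = FALSE)
    g <- conversion_flux_grad(D, N, params$a, params$b)
    with(params, matrix(c(
      -(d1 + f1), 0, -Delta_inh * lam / (1 + Delta_inh * A)^2,
      -g$dD, -d2 - g$dN, 0,
      g$dD, g$dN, -d3), 3, 3, byrow = TRUE))
  })
  J <- matrix(0, 6, 6)
  J[1:3, 1:3] <- blocks[[1]]
  J[4:6, 4:6] <- blocks[[2]]
  J[2, 4] <- params$f2   # N1 gains from D2
  J[5, 1] <- params$f2   # N2 gains from D1
  J
}

new_stability_report <- function(equilibrium, J, M = NULL, verdict) {
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(equilibrium = equilibrium, jacobian = J,
                 eigenvalues = ev,
                 max_re = max(Re(ev)),
                 M1 = M$M1, M2 = M$M2, M3 = M$M3, M3prime = M$M3prime,
                 ratio = M$ratio, verdict = verdict),
            class = "notch_stability_report")
}

#' @export
print.notch_stability_report <- function(x, digits = 6, ...) {
  cat("Stability report for", x$equilibrium$kind, "\n")
  s <- x$equilibrium$state
  cat(sprintf("  equilibrium: D = %.6g, N = %.6g, A = %.6g\n",
              s[1], s[2], s[3]))
  cat("  eigenvalues:\n")
  for (ev in x$eigenvalues)
    cat(sprintf("    %s\n", format(signif(ev, digits))))
  if (!is.null(x$ratio))
    cat(sprintf("  M1 = %.6g, M2 = %.6g, M3 = %.6g, M3' = %.6g\n  M3/(M1*M2) = %.6g\n",
                x$M1, x$M2, x$M3, x$M3prime, x$ratio))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Stability of the Delta-free equilibrium E0
#'
#' The characteristic polynomial at E0 factorizes as
#' `(S + d1 + f1)^2 (S + d2)^2 (S + d3)^2`, so the eigenvalues are
#' `-(d1+f1)` (twice), `-d2` (twice) and `-d3` (twice) -- all negative:
#' E0 is always locally asymptotically stable. The closed-form multiset is
#' cross-checked against the numeric eigendecomposition of the Jacobian.
#'
#' @param params A [notch_params()] with `lam = 0`.
#' @return A `"notch_stability_report"` with the extra element
#'   `closed_form_eigenvalues`.
#' @export
stability_E0 <- function(params) {
  eq <- withCallingHandlers(equilibrium_E0(params),
                            warning = function(w) invokeRestart("muffleWarning"))
  J <- jacobian_two_cell(params, eq$state)
  rep <- new_stability_report(eq, J, verdict = "stable")
  rep$closed_form_eigenvalues <-
    with(params, rep(c(-(d1 + f1), -d2, -d3), each = 2))
  rep
}

#' Routh-Hurwitz stability of the Delta-expressing equilibrium E1
#'
#' By the exchange symmetry of the two cells the characteristic polynomial
#' factorizes into a symmetric-mode cubic `S^3 + M1 S^2 + M2 S + M3` and an
#' antisymmetric-mode cubic `S^3 + M1 S^2 + M2 S + M3'`. Writing
#' `q = abD/(bD+N)^2` (flux sensitivity to Notch), `r = abN/(bD+N)^2`
#' (magnitude of the flux sensitivity to Delta) and
#' `w = Delta_inh*lam/(1+Delta_inh*A)^2` (magnitude of the Delta-production
#' sensitivity to active Notch), expanding the block determinants gives
#' \deqn{M_1 = d_2 + q + d_1 + f_1 + d_3,}
#' \deqn{M_2 = (d_1+f_1) d_3 + (d_1+f_1+d_3)(d_2+q) - w r,}
#' \deqn{M_3 = (d_1+f_1) d_3 (d_2+q) + w (q (r+f_2) - r (d_2+q)),}
#' and `M3'` replaces `(r+f2)` by `(r-f2)`. The `-wr` contributions carry
#' the destabilizing feedback of the mutual inhibition between a cell's
#' Delta and its own active Notch (A represses D production, D represses
#' conversion: a positive two-cycle). The coefficients are verified here
#' against a numeric characteristic polynomial in the test suite.
#'
#' `M3 - M3' = 2 w q f2 > 0` whenever `f2 > 0`, so the Routh-Hurwitz
#' condition `M1*M2 - M3 > 0` (equivalently `ratio = M3/(M1*M2) < 1`) for
#' the symmetric factor implies the corresponding condition for the
#' antisymmetric one. The remaining conditions `M2 > 0`, `M3 > 0` and
#' `M3' > 0` do not follow automatically: in particular `M3' < 0` signals
#' the lateral-inhibition patterning instability in which the two cells
#' diverge (the antisymmetric mode grows). The verdict therefore requires
#' all Routh-Hurwitz conditions of both factors; at the reference parameter
#' settings they reduce to `ratio < 1`. The verdict is cross-checked against
#' the sign of the maximal real part of the numeric eigenvalues.
#'
#' @param params A [notch_params()] with `lam > 0`.
#' @param tie_tol Margin below which the verdict is `"inconclusive"`.
#' @return A `"notch_stability_report"` with `M1, M2, M3, M3prime, ratio`
#'   and `margin` (the smallest Routh-Hurwitz margin; positive means
#'   stable).
#' @export
stability_E1 <- function(params, tie_tol = 1e-9) {
  eq <- equilibrium_E1(params)
  D <- eq$state[1]; N <- eq$state[2]; A <- eq$state[3]
  with(params, {
    den2 <- (b * D + N)^2
    q <- a * b * D / den2
    r <- a * b * N / den2
    w <- Delta_inh * lam / (1 + Delta_inh * A)^2
    M1 <- d2 + q + d1 + f1 + d3
    M2 <- (d1 + f1) * d3 + (d1 + f1 + d3) * (d2 + q) - w * r
    M3 <- (d1 + f1) * d3 * (d2 + q) + w * (q * (r + f2) - r * (d2 + q))
    M3p <- (d1 + f1) * d3 * (d2 + q) + w * (q * (r - f2) - r * (d2 + q))
    ratio <- M3 / (M1 * M2)
    # Routh-Hurwitz margins for both cubic factors (M1 > 0 always)
    margin <- min(M2, M3, M3p, M1 * M2 - M3, M1 * M2 - M3p)
    verdict <- if (abs(margin) <= tie_tol) "inconclusive"
               else if (margin > 0) "stable" else "unstable"
    J <- jacobian_two_cell(params, eq$state)
    rep <- new_stability_report(eq, J,
                                M = list(M1 = M1, M2 = M2, M3 = M3,
                                         M3prime = M3p, ratio = ratio),
                                verdict = verdict)
    rep$margin <- margin
    rep
  })
}
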