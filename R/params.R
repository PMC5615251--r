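#' Model parameters for the Delta-Notch boundary-formation system
#'
#' Container for the ten rate and shape constants of the per-cell
#' Delta/Notch/active-Notch dynamics. Defaults are the reference values used
#' throughout the package: degradation rates `d1 = d2 = d3 = 0.01`, binding
#' rates `f1 = f2 = 0.665`, conversion rate `a = 0.012`, cis-inhibition
#' coefficient `b = 69` and Delta-production inhibition coefficient
#' `Delta_inh = 1e6`. The two production rates `lam` (Delta, the ventral
#' prepattern level) and `lamN` (inactive Notch) are the experiment dials;
#' their reference ranges are `lam` in `[0, 12]` and `lamN` in `[0, 0.1]`.
#'
#' @param lam Delta production rate (concentration/time) applied to ventral
#'   cells by the prepattern. Must be `>= 0`.
#' @param lamN Inactive-Notch production rate, identical in every cell unless
#'   perturbed. Must be `>= 0`.
#' @param d1,d2,d3 First-order degradation rates of Delta, inactive Notch and
#'   active Notch. Must be `> 0`.
#' @param f1 Rate at which a cell's Delta is lost to binding with each
#'   neighbouring cell's Notch.
#' @param f2 Rate at which a cell's inactive Notch pool gains activation
#'   input from each neighbouring cell's Delta.
#' @param a Maximal conversion rate of inactive to active Notch.
#' @param b Cis-inhibition coefficient: strength with which a cell's own
#'   Delta suppresses its Notch conversion. Must be `> 0`.
#' @param Delta_inh Inhibition coefficient of active Notch on Delta
#'   production (the `1/(1 + Delta_inh * A)` factor). Must be `> 0`.
#'
#' @return An object of class `"notch_params"`: a named list of the ten
#'   validated numeric constants.
#' @examples
#' p <- notch_params(lam = 9, lamN = 0.008)
#' p$a / p$d3   # saturated active-Notch level of a Delta-free cell
#' @export
notch_params <- function(lam = 9, lamN = 0, d1 = 0.01, d2 = 0.01, d3 = 0.01,
                         f1 = 0.665, f2 = 0.665, a = 0.012, b = 69,
                         Delta_inh = 1e6) {
  p <- list(lam = lam, lamN = lamN, d1 = d1, d2 = d2, d3 = d3,
            f1 = f1, f2 = f2, a = a, b = b, Delta_inh = Delta_inh)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative (got ", v, ")",
           call. = FALSE)
  }
  for (nm in c("d1", "d2", "d3", "b", "Delta_inh"))
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  structure(p, class = "notch_params")
}

#' @export
print.notch_params <- function(x, ...) {
  cat("Delta-Notch model parameters\n")
  cat(sprintf("  production   lam = %g, lamN = %g\n", x$lam, x$lamN))
  cat(sprintf("  degradation  d1 = %g, d2 = %g, d3 = %g\n", x$d1, x$d2, x$d3))
  cat(sprintf("  binding      f1 = %g, f2 = %g\n", x$f1, x$f2))
  cat(sprintf("  conversion   a = %g, cis-inhibition b = %g\n", x$a, x$b))
  cat(sprintf("  Delta inhibition by active Notch  Delta_inh = %g\n",
              x$Delta_inh))
  invisible(x)
}

# Coerce a named list (e.g. parsed config) to notch_params, filling defaults.
# Unknown names are an error so config typos cannot pass silently.
as_notch_params <- function(x) {
  if (inherits(x, "notch_params")) return(x)
  stopifnot(is.list(x))
  known <- names(formals(notch_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(notch_params, x)
}
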