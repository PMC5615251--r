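#' Hexagonal cell lattice with offset-row adjacency
#'
#' Builds the regular hexagonal lattice the tissue model lives on. Cells are
#' arranged in `n_rows` rows of `n_cols` cells; odd rows are offset half a
#' cell to the right ("odd-r" offset convention), so each interior cell
#' touches six neighbours: two in its own row, two in the row above and two
#' in the row below. Rows are numbered from the dorsal side (row 1 is
#' dorsal-most). With `wrap_columns = TRUE` the lattice is periodic in the
#' column direction, matching the tubular geometry of the large intestine
#' and giving every cell of a given row the same neighbour count.
#'
#' Cell indices are row-major: cell `i` sits at row `row_of[i]`, column
#' `col_of[i]`, with `i = (row - 1) * n_cols + col`.
#'
#' @param n_rows Number of cell rows (`>= 1`).
#' @param n_cols Number of cells per row (`>= 2`).
#' @param wrap_columns Logical; make the column direction periodic.
#'
#' @return An object of class `"hex_lattice"` with elements
#'   `n_rows`, `n_cols`, `wrap_columns`, `n_cells`,
#'   `neighbors` (list of sorted neighbour index vectors, one per cell),
#'   `row_of`, `col_of` (integer vectors), and
#'   `adjacency` (dense 0/1 matrix, used internally by the integrator).
#' @examples
#' lat <- hex_lattice(5, 12)
#' table(lengths(lat$neighbors), lat$row_of)  # 4 neighbours on edge rows, 6 inside
#' @export
hex_lattice <- function(n_rows = 5, n_cols = 12, wrap_columns = TRUE) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1 ||
      n_rows != round(n_rows))
    stop("n_rows must be a positive integer", call. = FALSE)
  if (!is.numeric(n_cols) || length(n_cols) != 1L || n_cols < 2 ||
      n_cols != round(n_cols))
    stop("n_cols must be an integer >= 2", call. = FALSE)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  idx <- function(r, c) (r - 1L) * n_cols + c
  wrapc <- function(c) ((c - 1L) %% n_cols) + 1L

  neighbors <- vector("list", n)
  for (r in seq_len(n_rows)) {
    # odd rows are shifted right, so their vertical neighbours sit at
    # columns c and c+1; even rows' sit at c-1 and c
    voff <- if (r %% 2L == 1L) c(0L, 1L) else c(-1L, 0L)
    for (cc in seq_len(n_cols)) {
      cand_r <- c(r, r, r - 1L, r - 1L, r + 1L, r + 1L)
      cand_c <- c(cc - 1L, cc + 1L, cc + voff, cc + voff)
      keep <- cand_r >= 1L & cand_r <= n_rows
      if (wrap_columns) {
        cand_c <- wrapc(cand_c)
      } else {
        keep <- keep & cand_c >= 1L & cand_c <= n_cols
      }
      ns <- sort(unique(idx(cand_r[keep], cand_c[keep])))
      neighbors[[idx(r, cc)]] <- ns[ns != idx(r, cc)]
    }
  }

  adjacency <- matrix(0, n, n)
  for (i in seq_len(n)) adjacency[i, neighbors[[i]]] <- 1

  structure(
    list(n_rows = n_rows, n_cols = n_cols, wrap_columns = wrap_columns,
         n_cells = n, neighbors = neighbors,
         row_of = rep(seq_len(n_rows), each = n_cols),
         col_of = rep(seq_len(n_cols), times = n_rows),
         adjacency = adjacency),
    class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("Hexagonal lattice: %d rows x %d cols = %d cells (%s columns)\n",
              x$n_rows, x$n_cols, x$n_cells,
              if (x$wrap_columns) "wrapped" else "open"))
  deg <- lengths(x$neighbors)
  cat("  neighbour counts by row:",
      paste(tapply(deg, x$row_of, function(d) paste(sort(unique(d)),
                                                    collapse = "/")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Edge list of a hexagonal lattice
#'
#' Returns each undirected adjacency once, as a two-column data frame with
#' `i < j`, suitable for CSV export.
#'
#' @param lattice A [hex_lattice()].
#' @return A `data.frame` with integer columns `i` and `j`.
#' @export
lattice_edges <- function(lattice) {
  stopifnot(inherits(lattice, "hex_lattice"))
  e <- do.call(rbind, lapply(seq_len(lattice$n_cells), function(i) {
    j <- lattice$neighbors[[i]]
    j <- j[j > i]
    if (length(j)) cbind(i = i, j = j) else NULL
  }))
  as.data.frame(e)
}

#' Dorsal/ventral Delta-production prepattern
#'
#' Assigns the per-cell Delta production rate: 0 for cells in the first
#' `n_dorsal_rows` rows (the dorsal domain, which does not express Delta)
#' and `lam` for all remaining (ventral) rows. The dorsal/ventral prepattern
#' is the spatial input from which boundary patterning develops.
#'
#' @param lattice A [hex_lattice()].
#' @param lam Ventral Delta production rate (`>= 0`).
#' @param n_dorsal_rows Number of dorsal (Delta-free) rows, between 0 and
#'   `lattice$n_rows`. Default 3, matching the reference tissue layout.
#' @return An object of class `"notch_prepattern"`: a numeric vector of
#'   per-cell production rates with attributes `n_dorsal_rows` and `lam`.
#' @examples
#' lat <- hex_lattice(5, 12)
#' pp <- prepattern(lat, lam = 9)
#' table(pp)  # 36 dorsal cells at 0, 24 ventral cells at 9
#' @export
prepattern <- function(lattice, lam, n_dorsal_rows = 3) {
  stopifnot(inherits(lattice, "hex_lattice"))
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0)
    stop("lam must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n_dorsal_rows) || length(n_dorsal_rows) != 1L ||
      n_dorsal_rows != round(n_dorsal_rows) ||
      n_dorsal_rows < 0 || n_dorsal_rows > lattice$n_rows)
    stop("n_dorsal_rows must be an integer in [0, n_rows]", call. = FALSE)
  lam_per_cell <- ifelse(lattice$row_of <= n_dorsal_rows, 0, lam)
  structure(lam_per_cell, class = "notch_prepattern",
            n_dorsal_rows = as.integer(n_dorsal_rows), lam = lam)
}

#' @export
print.notch_prepattern <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf(
    "Delta prepattern: %d cells at rate 0, %d cells at rate %g (%d dorsal rows)\n",
    sum(v == 0), sum(v > 0), attr(x, "lam"), attr(x, "n_dorsal_rows")))
  invisible(x)
}
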