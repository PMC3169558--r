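#' Field geometry of the two overlaid lattices
#'
#' The model tiles one cortical sheet twice: a somatic field of
#' `n_soma_side^2` spiking units and a dendritic field of `n_dend_side^2`
#' plateau units, squarely arrayed with periodic boundaries. Both lattices
#' must span the same physical extent, so the spacings are derived from a
#' single sheet size.
#'
#' @param n_soma_side Integer, somatic units per side (>= 2).
#' @param n_dend_side Integer, dendritic units per side (>= 2); defaults to
#'   the somatic value.
#' @param extent Side length of the sheet in mm. The default 5 mm matches the
#'   scale of rat primary visual cortex that the model is meant to cover.
#' @param periodic Logical; the model is defined on a torus and all distance
#'   computations wrap. Only `TRUE` is supported.
#' @return An object of class `field_geometry` with elements `n_soma_side`,
#'   `n_dend_side`, `soma_spacing`, `dend_spacing`, `extent`, `periodic`.
#' @examples
#' geom <- field_geometry(48)
#' geom$soma_spacing * geom$n_soma_side  # == extent
#' @export
field_geometry <- function(n_soma_side, n_dend_side = n_soma_side,
                           extent = 5, periodic = TRUE) {
  n_soma_side <- as.integer(n_soma_side)
  n_dend_side <- as.integer(n_dend_side)
  if (n_soma_side < 2L || n_dend_side < 2L)
    stop("lattice sides must be >= 2")
  if (!isTRUE(periodic))
    stop("only periodic (torus) geometry is supported")
  if (extent <= 0) stop("extent must be positive")
  structure(list(n_soma_side = n_soma_side,
                 n_dend_side = n_dend_side,
                 soma_spacing = extent / n_soma_side,
                 dend_spacing = extent / n_dend_side,
                 extent = extent,
                 periodic = TRUE),
            class = "field_geometry")
}

#' @export
print.field_geometry <- function(x, ...) {
  cat(sprintf("<field_geometry> %dx%d somatic / %dx%d dendritic units on a %.3g x %.3g mm torus\n",
              x$n_soma_side, x$n_soma_side, x$n_dend_side, x$n_dend_side,
              x$extent, x$extent))
  invisible(x)
}

#' Lattice unit positions in mm
#'
#' Units are indexed column-major (R convention): unit `i` sits at row
#' `((i - 1) %% n) + 1`, column `((i - 1) %/% n) + 1`, at physical position
#' `(row - 1, col - 1) * spacing`.
#'
#' @param geometry A [field_geometry()].
#' @param field `"soma"` or `"dendrite"`.
#' @return A numeric matrix with one row per unit and columns `x`, `y` (mm).
#' @export
unit_positions <- function(geometry, field = c("soma", "dendrite")) {
  field <- match.arg(field)
  n <- if (field == "soma") geometry$n_soma_side else geometry$n_dend_side
  sp <- if (field == "soma") geometry$soma_spacing else geometry$dend_spacing
  g <- expand.grid(row = seq_len(n), col = seq_len(n))
  cbind(x = (g$row - 1) * sp, y = (g$col - 1) * sp)
}

#' Minimal-image distance on the periodic sheet
#'
#' Euclidean distance between two points on the torus, minimized over all
#' periodic images. Symmetric and satisfies the triangle inequality on the
#' torus.
#'
#' @param p,q Numeric length-2 positions in mm, or matrices with two columns
#'   (rows are paired).
#' @param geometry A [field_geometry()]; its `extent` sets the wrap length.
#' @return Distance(s) in mm.
#' @examples
#' g <- field_geometry(10, extent = 1)
#' wrapped_distance(c(0, 0), c(0.9, 0), g)  # 0.1, not 0.9
#' @export
wrapped_distance <- function(p, q, geometry) {
  L <- geometry$extent
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  q <- if (is.matrix(q)) q else matrix(q, ncol = 2)
  if (any(p < 0 | p >= L) || any(q < 0 | q >= L))
    stop("positions must lie within [0, extent)")
  d <- abs(p - q)
  d <- pmin(d, L - d)
  sqrt(rowSums(d^2))
}

# signed minimal-image displacement a - b on a circle of circumference L
wrap_signed <- function(a, b, L) {
  d <- (a - b) %% L
  ifelse(d > L / 2, d - L, d)
}

# unit index <-> (row, col) helpers (column-major, 1-based)
unit_to_rowcol <- function(i, n) cbind(row = (i - 1L) %% n + 1L,
                                       col = (i - 1L) %/% n + 1L)
rowcol_to_unit <- function(row, col, n) (col - 1L) * n + row
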