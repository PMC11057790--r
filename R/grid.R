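#' Pixel-grid geometry of a well
#'
#' Describes the square pixel lattice onto which cell centroids are binned:
#' by default a 15 x 15 grid of 430 um pixels covering a 6450 um field of
#' view. Row-major indexing, origin at the top-left corner; pixel (r, c)
#' covers the half-open square `[ (c-1)*px, c*px ) x [ (r-1)*px, r*px )` um.
#'
#' @param n_rows,n_cols Number of pixel rows and columns (>= 1).
#' @param pixel_size Pixel side length in micrometres.
#' @param field_of_view Full side length of the imaged field in micrometres.
#'   Must equal `n_rows * pixel_size` up to rounding.
#' @return A `grid_spec` object (list with the four fields above).
#' @examples
#' grid_spec()            # the default 15 x 15 / 430 um grid
#' grid_spec(5, 5, 1290)  # a coarse grid over the same field of view
#' @export
grid_spec <- function(n_rows = 15L, n_cols = 15L, pixel_size = 430,
                      field_of_view = n_rows * pixel_size) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0)
  if (abs(n_rows * pixel_size - field_of_view) > 0.5 * pixel_size) {
    stop("field_of_view is inconsistent with n_rows * pixel_size", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = pixel_size, field_of_view = field_of_view),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %g um/pixel (%g um field of view)\n",
              x$n_rows, x$n_cols, x$pixel_size, x$field_of_view))
  invisible(x)
}

n_pixels <- function(grid) grid$n_rows * grid$n_cols

#' Discrete Laplacian with no-flux boundaries
#'
#' Five-point central-difference Laplacian on a matrix of cell counts, with
#' zero-flux (mirrored ghost node) boundary conditions so that no cells cross
#' the well edge. The returned grid sums to zero exactly, which is what makes
#' pure diffusion conserve total cell count.
#'
#' @param values Numeric matrix of cell counts (finite).
#' @param pixel_size Pixel side length (same length unit as the diffusion
#'   coefficient; the solver uses millimetres).
#' @return Matrix of the same shape, units counts / length^2.
#' @export
laplacian_noflux <- function(values, pixel_size) {
  if (!is.matrix(values) || !all(is.finite(values))) {
    stop("`values` must be a finite numeric matrix", call. = FALSE)
  }
  stopifnot(pixel_size > 0)
  nr <- nrow(values); nc <- ncol(values)
  up    <- values[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- values[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left  <- values[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- values[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (up + down + left + right - 4 * values) / pixel_size^2
}

#' Explicit-scheme stability (CFL) diagnostic
#'
#' The forward-Euler diffusion update is stable in 2D when
#' `D * dt / dx^2 <= 1/4`. With the default grid (0.43 mm pixels, dt = 1 h)
#' and the largest admissible diffusion coefficient 0.005 mm^2/h the CFL
#' number is about 0.027, far below the limit.
#'
#' @param d_coeff Diffusion coefficient in mm^2/h.
#' @param cfg A [solver_config()].
#' @param grid A [grid_spec()].
#' @return A list with `cfl` (the number) and `pass` (logical).
#' @export
check_stability <- function(d_coeff, cfg = solver_config(), grid = grid_spec()) {
  dx_mm <- grid$pixel_size / 1000
  cfl <- max(d_coeff) * cfg$dt / dx_mm^2
  list(cfl = cfl, pass = cfl <= 0.25)
}
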