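#' Construct a landscape grid
#'
#' A regular planar grid of cell centres carrying an integer "ecoregion"
#' label per cell. Cells are stored row-major from the lower-left origin
#' (x varies fastest), which is the order used by every layer vector in a
#' [predictor_stack()] and by stock maps.
#'
#' @param nx,ny Cell counts along x and y (each at least 2).
#' @param cell_size Cell edge length in metres.
#' @param region_labels Integer vector of length `nx * ny`, one label per
#'   cell, in grid cell order.
#' @param origin_x,origin_y Planar coordinates of the lower-left cell centre.
#' @return An object of class `landscape_grid`.
#' @seealso [generate_landscape()] for the random Voronoi partition.
#' @export
landscape_grid <- function(nx, ny, cell_size, region_labels,
                           origin_x = 0, origin_y = 0) {
  if (!is_count(nx, 2L) || !is_count(ny, 2L)) {
    stop_invalid("nx and ny must be integer cell counts >= 2")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop_invalid("cell_size must be a positive length in metres")
  }
  region_labels <- as.integer(region_labels)
  if (length(region_labels) != nx * ny || anyNA(region_labels)) {
    stop_invalid("region_labels must supply one finite label per cell")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), cell_size = cell_size,
         origin_x = origin_x, origin_y = origin_y,
         region_labels = region_labels),
    class = "landscape_grid"
  )
}

#' Cell-centre coordinates of a landscape grid
#'
#' @param grid A [landscape_grid()].
#' @return A two-column matrix (`x`, `y`) with one row per cell, in grid
#'   cell order.
#' @export
cell_coords <- function(grid) {
  ix <- rep(seq_len(grid$nx), times = grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  cbind(x = grid$origin_x + (ix - 1) * grid$cell_size,
        y = grid$origin_y + (iy - 1) * grid$cell_size)
}

n_cells <- function(grid) grid$nx * grid$ny

same_geometry <- function(a, b) {
  isTRUE(all.equal(
    c(a$nx, a$ny, a$cell_size, a$origin_x, a$origin_y),
    c(b$nx, b$ny, b$cell_size, b$origin_x, b$origin_y)
  ))
}

# cell-order vector <-> [ny, nx] matrix (row iy = 1 is the bottom row)
vec_to_mat <- function(v, grid) matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
mat_to_vec <- function(m) as.vector(t(m))

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("landscape_grid: %d x %d cells of %g m, %d region(s)\n",
              x$nx, x$ny, x$cell_size, length(unique(x$region_labels))))
  invisible(x)
}

# Gaussian-kernel smoothing of a matrix field, separable along rows and
# columns with row-normalized (edge-corrected) banded weights. `sigma` is
# the kernel standard deviation in cells and acts as the correlation length.
gaussian_smooth <- function(m, sigma) {
  band <- function(n) {
    K <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(j - i, sd = sigma))
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# Smooth standardized Gaussian random field on the grid, in cell order.
# Exactly mean 0, variance 1 over the grid.
smooth_field <- function(grid, smoothness) {
  noise <- matrix(rnorm(n_cells(grid)), nrow = grid$ny, ncol = grid$nx)
  f <- mat_to_vec(gaussian_smooth(noise, smoothness))
  (f - mean(f)) / sd(f)
}
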