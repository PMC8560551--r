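#' Axisymmetric (z-r half-plane) grid
#'
#' Uniform node-centered grid for quasi-3D simulations: radial nodes
#' `r_i = i*dx`, `i = 0, ..., nr-1` with the symmetry axis on the first
#' sample, and axial nodes `z_k = k*dx`. Fields on this grid are plain
#' `nr x nz` matrices.
#'
#' @param nr,nz node counts in r and z.
#' @param dx grid spacing (um), equal in both directions.
#' @return An object of class `"axisym_grid"`.
#' @export
axisym_grid <- function(nr, nz, dx) {
  stopifnot(nr >= 4, nz >= 4, dx > 0)
  structure(list(kind = "axisym", nr = as.integer(nr), nz = as.integer(nz),
                 dx = dx, Lr = (nr - 1) * dx, Lz = (nz - 1) * dx,
                 r = (seq_len(nr) - 1) * dx, z = (seq_len(nz) - 1) * dx),
            class = "axisym_grid")
}

#' Cartesian 3-D grid
#'
#' Uniform cubic-cell grid; fields on it are `nx x ny x nz` arrays. Node
#' `(i, j, k)` (1-based) sits at `origin + (i-1, j-1, k-1) * dx`.
#'
#' @param nx,ny,nz node counts.
#' @param dx grid spacing (um).
#' @param origin physical coordinate of the first node (um).
#' @return An object of class `"cart_grid3"`.
#' @export
cart_grid3 <- function(nx, ny, nz, dx, origin = c(0, 0, 0)) {
  stopifnot(nx >= 4, ny >= 4, nz >= 4, dx > 0, length(origin) == 3)
  structure(list(kind = "cart3", nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), dx = dx, origin = as.numeric(origin),
                 x = origin[1] + (seq_len(nx) - 1) * dx,
                 y = origin[2] + (seq_len(ny) - 1) * dx,
                 z = origin[3] + (seq_len(nz) - 1) * dx),
            class = "cart_grid3")
}

#' Default grids implied by a parameter set
#'
#' The axisymmetric domain is `Lr x Lz` with the cell centered on the axis
#' at `z = Lz/2`; the 3-D domain is a cube of edge `L3` with the cell at the
#' center.
#'
#' @param params a [sim_params()] object.
#' @return A grid object.
#' @export
default_axisym_grid <- function(params) {
  axisym_grid(nr = round(params$Lr / params$dx) + 1,
              nz = round(params$Lz / params$dx) + 1, dx = params$dx)
}

#' @rdname default_axisym_grid
#' @export
default_cart_grid3 <- function(params) {
  n <- round(params$L3 / params$dx) + 1
  cart_grid3(n, n, n, params$dx)
}

#' @export
print.axisym_grid <- function(x, ...) {
  cat(sprintf("<axisym_grid> %d x %d nodes, dx = %g um (Lr = %g, Lz = %g)\n",
              x$nr, x$nz, x$dx, x$Lr, x$Lz))
  invisible(x)
}

#' @export
print.cart_grid3 <- function(x, ...) {
  cat(sprintf("<cart_grid3> %d x %d x %d nodes, dx = %g um\n",
              x$nx, x$ny, x$nz, x$dx))
  invisible(x)
}

# default axial position of the cell center: 5 um clearance below the
# lower pole, capped at the domain midpoint for short domains
cell_center_z <- function(params, grid) {
  min(params$R0 + 5, grid$Lz / 2)
}
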