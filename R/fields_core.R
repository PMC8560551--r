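#' Spherical-cell phase field
#'
#' Initializes the phase field for a sphere of radius `R0` using the tanh
#' interface kernel `phi = (1 - tanh(2 n / eps)) / 2`, where `n` is the
#' exact signed distance to the sphere (positive outside). The kernel
#' steepness 2 is the value consistent with the quartic double well whose
#' derivative is `G'(phi) = 16 phi (1-phi)(1-2 phi)`.
#'
#' @param grid an [axisym_grid()] or [cart_grid3()] object.
#' @param center sphere center: `(r, z)` with r = 0 for the axisymmetric
#'   grid (the cell must sit on the axis), or `(x, y, z)` in 3-D.
#' @param R0 sphere radius (um).
#' @param eps interface width (um).
#' @return A field (matrix or 3-D array) on `grid`.
#' @export
init_sphere_phi <- function(grid, center, R0, eps) {
  margin <- 3 * eps
  if (inherits(grid, "axisym_grid")) {
    stopifnot(length(center) == 2)
    if (abs(center[1]) > 1e-12)
      stop("axisymmetric cells must be centered on the axis (r = 0)")
    if (center[2] - R0 < margin || center[2] + R0 > grid$Lz - margin ||
        R0 > grid$Lr - margin)
      stop("sphere of radius ", R0, " does not fit in the grid with a ",
           margin, " um margin")
    n <- sqrt(outer(grid$r^2, (grid$z - center[2])^2, "+")) - R0
  } else {
    stopifnot(length(center) == 3)
    lo <- c(grid$x[1], grid$y[1], grid$z[1])
    hi <- c(grid$x[grid$nx], grid$y[grid$ny], grid$z[grid$nz])
    if (any(center - R0 < lo + margin) || any(center + R0 > hi - margin))
      stop("sphere of radius ", R0, " does not fit in the grid with a ",
           margin, " um margin")
    dx2 <- outer(grid$x - center[1], grid$y - center[2],
                 function(a, b) a^2 + b^2)
    n <- sqrt(outer(dx2, (grid$z - center[3])^2, "+")) - R0
  }
  (1 - tanh(2 * n / eps)) / 2
}

#' Derivative of the interface double-well potential
#'
#' `G'(phi) = 16 phi (1 - phi)(1 - 2 phi)`: zero at the two bulk states and
#' at the interface midpoint, antisymmetric about phi = 1/2.
#'
#' @param phi phase-field values.
#' @return Same shape as `phi`.
#' @export
double_well_prime <- function(phi) {
  16 * phi * (1 - phi) * (1 - 2 * phi)
}

#' Membrane indicator field
#'
#' The auxiliary logistic field
#' `psi = 1 / (1 + exp(-beta (phi (1 - phi) - theta)))`, equal to 1 in a
#' band of width ~eps around the interface and ~0 in the bulk; it confines
#' the membrane-bound species and defines the surface-area quadrature.
#'
#' @param phi phase field.
#' @param beta logistic sharpness.
#' @param theta band threshold (`theta < 1/4`).
#' @return Field of the same shape, values in (0, 1).
#' @export
compute_psi <- function(phi, beta = 100, theta = 0.105) {
  1 / (1 + exp(-beta * (phi * (1 - phi) - theta)))
}

#' Field integrals: cell volume and surface area
#'
#' Midpoint-rule integrals. On the axisymmetric grid the Jacobian
#' `2 pi r` is evaluated at the node. `volume_of` integrates the field
#' itself (`V = int phi dr`); `surface_area_of` integrates `psi / eps`
#' (the membrane band of width eps counts the interface once).
#'
#' @param f field to integrate (phi for volumes, psi for areas).
#' @param grid grid the field lives on.
#' @param eps interface width, for `surface_area_of`.
#' @return A scalar (um^3 or um^2).
#' @export
volume_of <- function(f, grid) {
  if (inherits(grid, "axisym_grid")) {
    sum(f * (2 * pi * grid$r) * grid$dx^2)
  } else {
    sum(f) * grid$dx^3
  }
}

#' @rdname volume_of
#' @export
surface_area_of <- function(f, grid, eps) {
  volume_of(f, grid) / eps
}

#' Discrete Laplacian
#'
#' Second-order central stencils: the 7-point stencil in 3-D, and the
#' cylindrical form `r^-1 d/dr (r d/dr) + d2/dz2` on the axisymmetric grid
#' with the on-axis limit `2 d2/dr2 + d2/dz2`. Domain edges use mirror
#' ghosts; solvers impose their own boundary conditions internally.
#'
#' @param f field.
#' @param grid grid the field lives on.
#' @return Field of the same shape.
#' @export
laplacian <- function(f, grid) {
  if (inherits(grid, "axisym_grid")) {
    cpp_lap_axisym(f, grid$dx)
  } else {
    cpp_lap_cart3(f, grid$dx)
  }
}

#' Axisymmetric divergence
#'
#' `div v = r^-1 d(r v_r)/dr + d(v_z)/dz`, with the on-axis limit
#' `2 d(v_r)/dr + d(v_z)/dz`.
#'
#' @param vr,vz radial and axial velocity components (matrices).
#' @param grid an [axisym_grid()].
#' @return Matrix of the same shape.
#' @export
divergence_axisym <- function(vr, vz, grid) {
  cpp_div_axisym(vr, vz, grid$dx)
}

#' Gradient and regularized magnitude
#'
#' Central-difference gradient and its magnitude. Nodes where
#' `|grad f| <= grad_cut` are flagged so that interface velocities are set
#' to zero there.
#'
#' @param f field on an axisymmetric grid.
#' @param grid an [axisym_grid()].
#' @param grad_cut regularization threshold.
#' @return List with `gr`, `gz`, `gmag`, and logical `active`
#'   (`gmag > grad_cut`).
#' @export
grad_and_magnitude <- function(f, grid, grad_cut = 1e-3) {
  g <- cpp_grad_axisym(f, grid$dx)
  g$active <- g$gmag > grad_cut
  g
}
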