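#' Protrusive force laws
#'
#' Actin polymerization pushes the membrane outward at the edge of the
#' active patch. The window force law promotes protrusion for
#' `K <~ A <~ Kp`:
#' `Fpoly = F * (A/K)^nh / (1 + (A/K)^nh) * 1 / (1 + (A^2/Kp)^nh)`
#' (the suppression factor uses `A^2/Kp`, as defined). The competitive
#' variant lets the inhibitor switch the force off instead:
#' `Fpoly = F * (A/K)^nh / (1 + (A/K)^nh) * 1 / (1 + (I/Kp)^nh)`,
#' which sharpens force localization to the leading edge where A is high
#' and I has not yet accumulated.
#'
#' @param A activator concentration (any shape).
#' @param I inhibitor concentration (for the competitive law).
#' @param F force magnitude (nN/um^2).
#' @param K activation half-maximum.
#' @param Kp suppression half-maximum.
#' @param nh Hill coefficient.
#' @return Force density, same shape as `A`.
#' @export
protrusive_force <- function(A, F = 2.0, K = 0.005, Kp = 0.25, nh = 3) {
  x <- (A / K)^nh
  F * (x / (1 + x)) / (1 + (A^2 / Kp)^nh)
}

#' @rdname protrusive_force
#' @export
protrusive_force_inhibited <- function(A, I, F = 2.0, K = 0.005, Kp = 0.25,
                                       nh = 3) {
  x <- (A / K)^nh
  F * (x / (1 + x)) / (1 + (I / Kp)^nh)
}

#' Normal interface speed
#'
#' The interface moves along its outward normal `n = -grad(phi)/|grad(phi)|`
#' at speed
#' `s = (1/tau) [ eta (lap(phi) - G'(phi)/eps^2)/|grad phi| - MV (V - V0) + Fpoly ]`;
#' positive `s` moves the membrane outward. Where `|grad phi| <= grad_cut`
#' the velocity is set to zero. The phase-field update is the advection of
#' phi by this velocity, `dphi/dt = s |grad phi|`.
#'
#' @param phi phase field on an axisymmetric grid.
#' @param Fpoly protrusive force density field (same shape).
#' @param V current cell volume (um^3); computed from `phi` when `NULL`.
#' @param params a [sim_params()] object.
#' @param grid an [axisym_grid()].
#' @return List with the speed field `s`, velocity components `vr`, `vz`,
#'   and the gradient magnitude `gmag`.
#' @export
normal_speed <- function(phi, Fpoly, params, grid, V = NULL) {
  if (is.null(V)) V <- volume_of(phi, grid)
  lap <- cpp_lap_axisym(phi, grid$dx)
  g <- cpp_grad_axisym(phi, grid$dx)
  curv <- params$eta * (lap - double_well_prime(phi) / params$eps^2)
  s <- matrix(0, grid$nr, grid$nz)
  act <- g$gmag > params$grad_cut
  s[act] <- (curv[act] / g$gmag[act] - params$MV * (V - params$V0) +
               Fpoly[act]) / params$tau
  list(s = s,
       vr = ifelse(act, -s * g$gr / g$gmag, 0),
       vz = ifelse(act, -s * g$gz / g$gmag, 0),
       gmag = g$gmag)
}

#' Explicit Euler steps of the phase-field equation
#'
#' Advances phi under tension, the global volume constraint, and a
#' prescribed protrusive force field, with the cell volume recomputed once
#' per step. Boundary conditions are Neumann at the axis and Dirichlet
#' phi = 0 on the outer edges.
#'
#' @param phi phase field on an axisymmetric grid.
#' @param Fpoly force density field (static over the call).
#' @param params a [sim_params()] object.
#' @param n_steps number of Euler steps of size `params$dt`.
#' @return List with the updated `phi` and the last-step volume `V`.
#' @export
advance_phi <- function(phi, Fpoly, params, n_steps = 1) {
  res <- cpp_phi_relax_axisym(phi, Fpoly, unclass(params), as.integer(n_steps))
  if (any(!is.finite(res$phi)))
    stop("advance_phi produced non-finite values (blow-up)")
  res
}

#' Minimal protrusive force and protrusion width estimates
#'
#' A protrusion of width `2R` has a semicircular head of arc length
#' `l_h = pi R`; sustaining it against line tension requires
#' `F*/eta = 1/R = pi/l_h`. Conversely, for given tension and force the
#' minimal sustainable width is `2R = 2 eta / F`.
#'
#' @param lh head arc length (um).
#' @param eta cortical tension (nN/um).
#' @param F protrusive force density (nN/um^2).
#' @return `minimal_force_ratio`: F*/eta (1/um);
#'   `minimal_protrusion_width`: width (um).
#' @export
minimal_force_ratio <- function(lh) {
  stopifnot(lh > 0)
  pi / lh
}

#' @rdname minimal_force_ratio
#' @export
minimal_protrusion_width <- function(eta, F) {
  stopifnot(eta > 0, F > 0)
  2 * eta / F
}

#' Bending-to-surface energy ratio of a membrane tube
#'
#' For a cylindrical protrusion of radius `r` and length `l`, bending
#' energy `Gb ~ pi Kb l / r` and surface energy `Gs ~ 2 pi eta r l` give
#' `Gb/Gs = Kb / (2 eta r^2)`; at micrometer scale this is ~1e-3, which is
#' why bending is neglected in the membrane equation.
#'
#' @param Kb bending modulus (nN um; 1.6e-3 nN um = 1.6 pN um).
#' @param eta cortical tension (nN/um).
#' @param r protrusion radius (um).
#' @return Dimensionless energy ratio.
#' @export
bending_surface_ratio <- function(Kb, eta, r) {
  stopifnot(eta > 0, r > 0)
  Kb / (2 * eta * r^2)
}
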