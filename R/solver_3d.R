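#' Static bead indicator field
#'
#' `chi(r) = (1 + tanh((Rb - |r - rb|) / (eps/2))) / 2`: 1 inside the bead,
#' 0 outside, with an interface of width ~eps/2. The field never changes
#' during a run.
#'
#' @param grid an [axisym_grid()] or [cart_grid3()].
#' @param bead a [bead_spec()] with a resolved `center`.
#' @param eps interface width (um).
#' @return Field on `grid`.
#' @export
bead_field <- function(grid, bead, eps) {
  if (is.null(bead$center))
    stop("bead center not set; see resolve_bead_center()")
  if (inherits(grid, "axisym_grid")) {
    stopifnot(length(bead$center) == 2)
    d <- sqrt(outer((grid$r - bead$center[1])^2,
                    (grid$z - bead$center[2])^2, "+"))
  } else {
    stopifnot(length(bead$center) == 3)
    dxy <- outer((grid$x - bead$center[1])^2, (grid$y - bead$center[2])^2, "+")
    d <- sqrt(outer(dxy, (grid$z - bead$center[3])^2, "+"))
  }
  (1 + tanh((bead$Rb - d) / (eps / 2))) / 2
}

#' Place a bead tangent to the undeformed membrane
#'
#' Default placement on the seed-patch axis: the bead surface sits a gap
#' `eps/2` above the top pole of the resting sphere.
#'
#' @param bead a [bead_spec()].
#' @param params a [sim_params()] object.
#' @param grid the simulation grid.
#' @return The bead with `center` filled in.
#' @export
resolve_bead_center <- function(bead, params, grid) {
  if (!is.null(bead$center)) return(bead)
  zc <- if (inherits(grid, "axisym_grid")) cell_center_z(params, grid)
    else (grid$z[grid$nz] - grid$z[1]) / 2
  ztop <- zc + params$R0 + bead$Rb + params$eps / 2
  if (inherits(grid, "axisym_grid")) {
    bead$center <- c(0, ztop)
  } else {
    mid <- c(mean(range(grid$x)), mean(range(grid$y)))
    bead$center <- c(mid, grid$z[1] + ztop)
  }
  bead
}

#' Bead engulfment fraction
#'
#' Fraction of the bead taken up by the cell; complete engulfment is
#' declared at 0.95. The default `"enclosed"` method counts the part of
#' the bead that no longer communicates with the extracellular space: a
#' bead node is engulfed unless it lies in (or is, for its vacant pocket)
#' the `phi < 0.5` region connected to the domain boundary. This is the
#' right notion for an impenetrable bead, which always sits in a vacant
#' pocket -- once the membrane seals around it, the pocket disconnects
#' from the exterior and the fraction reaches 1. The `"overlap"` method is
#' the plain indicator overlap `int(chi * phi) / int(chi)`, useful for
#' constructed geometries without exclusion.
#'
#' @param chi bead indicator field.
#' @param phi phase field.
#' @param grid grid the fields live on.
#' @param method `"enclosed"` (default) or `"overlap"`.
#' @return Value in `[0, 1]`.
#' @export
engulfment_fraction <- function(chi, phi, grid,
                                method = c("enclosed", "overlap")) {
  method <- match.arg(method)
  if (method == "overlap")
    return(volume_of(chi * phi, grid) / volume_of(chi, grid))
  ext <- if (inherits(grid, "axisym_grid")) cpp_exterior_mask_axisym(phi)
         else cpp_exterior_mask_3d(phi)
  covered <- chi
  covered[ext] <- 0
  volume_of(covered, grid) / volume_of(chi, grid)
}

#' Count distinct active patches on the membrane
#'
#' Connected components (6-connectivity) of the membrane-band region with
#' activator above a threshold; the operational measure of patch splitting.
#'
#' @param A activator field (3-D array).
#' @param psi membrane indicator field.
#' @param thresh activator threshold.
#' @return Integer patch count.
#' @export
patch_count_3d <- function(A, psi, thresh = 0.5) {
  cpp_count_components_3d(psi > 0.5 & A > thresh)
}

#' Interior cavities of a 3-D phase field
#'
#' Labels the connected components (6-connectivity) of the vacant region
#' `phi < 0.5`; components not touching the domain boundary are enclosed
#' extracellular cavities (sealed macropinosomes).
#'
#' @param phi 3-D phase field array.
#' @param grid a [cart_grid3()].
#' @return List with total cavity `volume` (um^3) and `n_cavities`.
#' @export
closure_detect_3d <- function(phi, grid) {
  cpp_cavity_3d(phi, grid$dx)
}

#' Initial 3-D cell state
#'
#' @param params a [sim_params()] object.
#' @param grid a [cart_grid3()]; defaults to the cube implied by `params`.
#' @param seed_patch seed the initial activator patch at the top pole.
#' @return A list of class `"cell_state3"` with `phi`, `A`, `I`, `psi`,
#'   `grid`, and scalars `t`, `V`, `S`, `B`.
#' @export
init_cell_state_3d <- function(params, grid = NULL, seed_patch = TRUE) {
  if (is.null(grid)) grid <- default_cart_grid3(params)
  ctr <- c(mean(range(grid$x)), mean(range(grid$y)), mean(range(grid$z)))
  phi <- init_sphere_phi(grid, ctr, params$R0, params$eps)
  psi <- compute_psi(phi, params$beta, params$theta)
  A <- array(0, dim(phi))
  if (seed_patch && params$rinit > 0)
    A <- seed_initial_patch(A, psi, grid, params$rinit)
  gB <- global_B(params$at, params$R0, A, psi, params$eps, grid)
  structure(list(phi = phi, A = A, I = array(0, dim(phi)), psi = psi,
                 grid = grid, t = 0, V = volume_of(phi, grid),
                 S = gB$S, B = gB$B),
            class = "cell_state3")
}

#' @export
print.cell_state3 <- function(x, ...) {
  cat(sprintf("<cell_state3> t = %.3f s, V = %.1f um^3, S = %.1f um^2, B = %.4f, max A = %.3f\n",
              x$t, x$V, x$S, x$B, max(x$A)))
  invisible(x)
}

#' Advance a 3-D cell state
#'
#' Runs `n` coupled explicit-Euler steps of the full model in 3-D, with
#' optional bead interaction (excluded volume + adhesion and the
#' zero-net-force drift correction) and stochastic nucleation.
#'
#' @param state a `cell_state3` from [init_cell_state_3d()].
#' @param params a [sim_params()] object.
#' @param n number of steps.
#' @param bead optional [bead_spec()].
#' @param noise optional [noise_params()].
#' @param drift apply the drift correction; defaults to on when a bead is
#'   present.
#' @param record_every series cadence in steps.
#' @return Updated state; diagnostics in `attr(, "series")`.
#' @export
step_3d <- function(state, params, n = 1, bead = NULL, noise = NULL,
                    drift = !is.null(bead), record_every = NULL,
                    freeze_phi = FALSE, extinct_tol = -1) {
  chi <- NULL; Aatt <- 0; Arep <- 0
  if (!is.null(bead)) {
    bead <- resolve_bead_center(bead, params, state$grid)
    chi <- bead_field(state$grid, bead, params$eps)
    Aatt <- bead$Aatt; Arep <- bead$Arep
  }
  if (is.null(record_every)) record_every <- max(1L, as.integer(n))
  ctl <- make_control(params, n_steps = n, record_every = record_every,
                      drift = drift, freeze_phi = freeze_phi, chi = chi,
                      Aatt = Aatt, Arep = Arep, noise = noise, t0 = state$t,
                      extinct_tol = extinct_tol)
  res <- cpp_run_cart3(state$phi, state$A, state$I, unclass(params), ctl)
  out <- state
  out$phi <- res$phi; out$A <- res$A; out$I <- res$I; out$psi <- res$psi
  out$t <- res$t
  gB <- global_B(params$at, params$R0, out$A, out$psi, params$eps, state$grid)
  out$V <- volume_of(out$phi, state$grid); out$S <- gB$S; out$B <- gB$B
  attr(out, "series") <- as.data.frame(res$series)
  out
}

#' Run a full 3-D simulation
#'
#' Integrates the coupled model in 3-D from a seeded spherical cell,
#' recording cell volume, surface, pool, interior-cavity volume (the 3-D
#' closure criterion), bead engulfment fraction (when a bead is present),
#' and the cell centroid.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @param grid optional [cart_grid3()] override.
#' @param bead optional [bead_spec()].
#' @param noise optional [noise_params()].
#' @param t_max simulated horizon (s).
#' @param record_every_s series cadence (s).
#' @param drift apply the zero-net-force drift correction.
#' @return An object of class `"cart3_run"` with `state`, `series`, and
#'   `params`.
#' @export
run_3d <- function(params, seed = params$seed, grid = NULL, bead = NULL,
                   noise = NULL, t_max = params$t_max, record_every_s = 1,
                   drift = !is.null(bead)) {
  set.seed(seed)
  state <- init_cell_state_3d(params, grid = grid)
  n_steps <- ceiling(t_max / params$dt)
  state <- step_3d(state, params, n = n_steps, bead = bead, noise = noise,
                   drift = drift, extinct_tol = 1e-3,
                   record_every = max(1L, round(record_every_s / params$dt)))
  out <- list(state = state, series = attr(state, "series"),
              params = params, seed = seed, bead = bead, noise = noise)
  class(out) <- "cart3_run"
  out
}

#' @export
print.cart3_run <- function(x, ...) {
  s <- x$series
  cat(sprintf("<cart3_run> t = %.1f s, V/V0 = %.3f, cavity fraction %.3g\n",
              x$state$t, x$state$V / x$params$V0,
              s$cavity_frac[nrow(s)]))
  if (!is.null(x$bead))
    cat(sprintf("  engulfment fraction %.3f\n", s$engulf_frac[nrow(s)]))
  invisible(x)
}
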