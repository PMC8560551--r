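#' Extract the membrane contour
#'
#' Piecewise-linear phi = 0.5 level set in the (r, z) half-plane, via
#' marching-segments contouring. Returns the longest contour line (the
#' cell membrane) as an ordered polyline with cumulative arc length.
#'
#' @param phi phase field.
#' @param grid an [axisym_grid()].
#' @return Data frame with columns `r`, `z`, `s` (arc length, um), ordered
#'   so the last vertex is the endpoint of maximal z (the top pole).
#' @export
interface_contour <- function(phi, grid) {
  cl <- grDevices::contourLines(x = grid$r, y = grid$z, z = phi,
                                levels = 0.5)
  if (length(cl) == 0) stop("no phi = 0.5 contour found")
  lens <- vapply(cl, function(l) length(l$x), 0L)
  ln <- cl[[which.max(lens)]]
  r <- ln$x; z <- ln$y
  if (z[1] > z[length(z)]) { r <- rev(r); z <- rev(z) }
  ds <- sqrt(diff(r)^2 + diff(z)^2)
  data.frame(r = r, z = z, s = c(0, cumsum(ds)))
}

#' Normalized patch area in the reduced model
#'
#' The active patch is the surface of revolution swept by the contour
#' between the boundary marker `rb` and the top pole (the on-axis end of
#' the contour): `A = 2 pi int_C r ds / (4 pi R0^2)`.
#'
#' @param phi phase field.
#' @param grid an [axisym_grid()].
#' @param rb boundary marker `(r, z)` (um); projected onto the contour
#'   (nearest point on the polyline segments, preserving sub-cell
#'   tangential position).
#' @param R0 resting cell radius (um).
#' @return List: normalized area `A`, the projected marker `rb`, its arc
#'   position `s` along the contour, the local unit tangent `Tvec`
#'   (oriented toward the patch, i.e. toward the pole end), and the
#'   `contour`.
#' @export
patch_area <- function(phi, grid, rb, R0) {
  ct <- interface_contour(phi, grid)
  n <- nrow(ct)
  if (ct$r[n] > 2 * grid$dx)
    stop("contour does not reach the symmetry axis at its upper end")
  pr <- project_on_contour(ct, rb)
  # integrate 2 pi r ds from the projected arc position to the pole end
  smax <- ct$s[n]
  sgrid <- c(pr$s, ct$s[ct$s > pr$s])
  rgrid <- c(pr$p[1], ct$r[ct$s > pr$s])
  if (length(sgrid) > 1) {
    rmid <- (rgrid[-length(rgrid)] + rgrid[-1]) / 2
    area <- 2 * pi * sum(rmid * diff(sgrid))
  } else area <- 0
  list(A = area / (4 * pi * R0^2), rb = pr$p, s = pr$s, Tvec = pr$Tvec,
       contour = ct)
}

# nearest point on the polyline: returns the projected point, its arc
# position, and the segment unit tangent (pointing toward the pole end)
project_on_contour <- function(ct, p) {
  n <- nrow(ct)
  ax <- ct$r[-n]; ay <- ct$z[-n]
  bx <- ct$r[-1]; by <- ct$z[-1]
  dxs <- bx - ax; dys <- by - ay
  len2 <- pmax(dxs^2 + dys^2, 1e-300)
  tpar <- pmin(pmax(((p[1] - ax) * dxs + (p[2] - ay) * dys) / len2, 0), 1)
  px <- ax + tpar * dxs; py <- ay + tpar * dys
  d2 <- (p[1] - px)^2 + (p[2] - py)^2
  i <- which.min(d2)
  Tv <- c(dxs[i], dys[i]) / sqrt(len2[i])
  list(p = c(px[i], py[i]), s = ct$s[i] + tpar[i] * sqrt(len2[i]),
       Tvec = Tv, seg = i)
}

# point at arc position starget along the contour (linear interpolation)
point_at_arc <- function(ct, starget) {
  n <- nrow(ct)
  starget <- min(max(starget, ct$s[1]), ct$s[n])
  i <- findInterval(starget, ct$s, rightmost.closed = TRUE)
  i <- min(max(i, 1), n - 1)
  w <- (starget - ct$s[i]) / max(ct$s[i + 1] - ct$s[i], 1e-300)
  c(ct$r[i] + w * (ct$r[i + 1] - ct$r[i]),
    ct$z[i] + w * (ct$z[i + 1] - ct$z[i]))
}

#' Sigmoidal protrusion force profile
#'
#' `Fpoly(x) = F / (1 + exp(-slope (rf - dist)))`: approximately F within
#' distance `rf` of the protrusion site and 0 beyond it.
#'
#' @param dist distance from the protrusion site (um; any shape).
#' @param F force magnitude.
#' @param rf protrusion half-width (um).
#' @param slope sigmoid slope.
#' @return Force density, same shape as `dist`.
#' @export
force_profile_reduced <- function(dist, F, rf, slope = 2.5) {
  F / (1 + exp(-slope * (rf - dist)))
}

#' Advance the patch boundary marker
#'
#' `d(rb)/dt = v + vt (A - A0) T`, where `v` is the membrane normal
#' velocity at the marker and `T` the unit tangent pointing toward the
#' patch interior, so the patch expands (the marker slides away from the
#' pole) while `A < A0`. The marker is re-projected onto the phi = 0.5
#' contour by the caller each cycle.
#'
#' @param rb marker position `(r, z)`.
#' @param v normal-velocity vector `(vr, vz)` at the marker.
#' @param Tvec unit tangent at the marker, oriented toward the patch.
#' @param A current normalized patch area.
#' @param rpar a [reduced_params()] object.
#' @param dt time increment (s).
#' @return Updated `(r, z)`.
#' @export
advance_boundary <- function(rb, v, Tvec, A, rpar, dt) {
  rb + dt * (v + rpar$vt * (A - rpar$A0) * Tvec)
}

#' Run the reduced patch-boundary model
#'
#' Replaces the reaction-diffusion patch with a single boundary marker on
#' the interface: the marker is advected with the membrane, slides
#' tangentially until the patch area reaches `A0`, and drives a sigmoidal
#' protrusive force centered an arc length `dl` outside the marker. The
#' phase field evolves under tension, volume constraint, and this force;
#' closure detection and enclosed-volume estimation are identical to the
#' full solver.
#'
#' @param params a [sim_params()] object (mechanics + numerics are used;
#'   the kinetic parameters are ignored).
#' @param rpar a [reduced_params()] object.
#' @param grid optional [axisym_grid()] override.
#' @param t_max simulated horizon (s).
#' @param update_every boundary/force refresh cadence in Euler steps.
#' @param stop_after_closures stop early after this many closure events.
#' @return An object of class `"reduced_run"`: final `phi`, marker track,
#'   `events` data frame, `outcome` list, `series` of (t, V, A).
#' @export
run_reduced <- function(params, rpar = reduced_params(), grid = NULL,
                        t_max = params$t_max, update_every = 20,
                        stop_after_closures = 0) {
  if (is.null(grid)) grid <- default_axisym_grid(params)
  zc <- cell_center_z(params, grid)
  phi <- init_sphere_phi(grid, c(0, zc), params$R0, params$eps)
  # start the marker a seed-patch arc below the top pole
  theta0 <- max(params$rinit, grid$dx) / params$R0
  rb <- c(params$R0 * sin(theta0), zc + params$R0 * cos(theta0))
  t <- 0; dt_outer <- update_every * params$dt
  events <- data.frame(t = numeric(0), volume = numeric(0),
                       fraction = numeric(0))
  track <- list(); ser <- list()
  in_closed <- FALSE; status <- "t_max"
  while (t < t_max) {
    pa <- tryCatch(patch_area(phi, grid, rb, params$R0),
                   error = function(e) NULL)
    if (is.null(pa)) { status <- "contour-lost"; break }
    ct <- pa$contour; rb <- pa$rb; Tvec <- pa$Tvec
    rp <- point_at_arc(ct, pa$s - rpar$dl)   # protrusion site outside the patch
    dist <- sqrt(outer((grid$r - rp[1])^2, (grid$z - rp[2])^2, "+"))
    Fpoly <- force_profile_reduced(dist, params$F, rpar$rf, rpar$slope)
    res <- cpp_phi_relax_axisym(phi, Fpoly, unclass(params),
                                as.integer(update_every))
    phi <- res$phi
    ns <- normal_speed(phi, Fpoly, params, grid, V = res$V)
    ii <- round(rb[1] / grid$dx) + 1; kk <- round(rb[2] / grid$dx) + 1
    ii <- min(max(ii, 1), grid$nr); kk <- min(max(kk, 1), grid$nz)
    v <- c(ns$vr[ii, kk], ns$vz[ii, kk])
    rb <- advance_boundary(rb, v, Tvec, pa$A, rpar, dt_outer)
    t <- t + dt_outer
    sc <- cpp_closure_scan(phi)
    if (sc$count >= 2 && !in_closed) {
      vol <- cpp_enclosed_volume(phi, grid$dx, sc$kb, sc$kt)
      events <- rbind(events, data.frame(t = t, volume = vol,
                                         fraction = vol / params$V0))
      if (stop_after_closures > 0 &&
          nrow(events) >= stop_after_closures) {
        in_closed <- TRUE; status <- "closures"
        ser[[length(ser) + 1]] <- c(t = t, V = res$V, A = pa$A)
        track[[length(track) + 1]] <- c(t = t, r = rb[1], z = rb[2])
        break
      }
    }
    in_closed <- sc$count >= 2
    track[[length(track) + 1]] <- c(t = t, r = rb[1], z = rb[2])
    ser[[length(ser) + 1]] <- c(t = t, V = res$V, A = pa$A)
  }
  out <- list(phi = phi, grid = grid,
              track = as.data.frame(do.call(rbind, track)),
              series = as.data.frame(do.call(rbind, ser)),
              events = events,
              outcome = classify_outcome(
                as.list(events), status, params$V0),
              params = params, rpar = rpar)
  class(out) <- "reduced_run"
  out
}

#' @export
print.reduced_run <- function(x, ...) {
  cat(sprintf("<reduced_run> outcome: %s, %d closure event(s)\n",
              x$outcome$label, nrow(x$events)))
  invisible(x)
}
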