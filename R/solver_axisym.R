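#' Initial axisymmetric cell state
#'
#' A spherical cell of radius `R0` centered on the axis, with A = I = 0 and
#' optionally a seeded activator patch of radius `rinit` at the top pole.
#'
#' @param params a [sim_params()] object.
#' @param grid an [axisym_grid()]; defaults to the domain implied by
#'   `params`.
#' @param seed_patch seed the initial patch (uses the session RNG).
#' @param center_z axial position of the cell center (um); by default the
#'   cell sits 5 um above the bottom boundary so that extra domain height
#'   is headroom for the cup growing from the top pole.
#' @return A list of class `"cell_state"` with fields `phi`, `A`, `I`,
#'   `psi`, the `grid`, and scalars `t`, `V`, `S`, `B`.
#' @export
init_cell_state <- function(params, grid = NULL, seed_patch = TRUE,
                            center_z = NULL) {
  if (is.null(grid)) grid <- default_axisym_grid(params)
  if (is.null(center_z)) center_z <- cell_center_z(params, grid)
  phi <- init_sphere_phi(grid, c(0, center_z), params$R0, params$eps)
  psi <- compute_psi(phi, params$beta, params$theta)
  A <- matrix(0, grid$nr, grid$nz)
  if (seed_patch && params$rinit > 0)
    A <- seed_initial_patch(A, psi, grid, params$rinit)
  gB <- global_B(params$at, params$R0, A, psi, params$eps, grid)
  structure(list(phi = phi, A = A, I = matrix(0, grid$nr, grid$nz),
                 psi = psi, grid = grid, t = 0,
                 V = volume_of(phi, grid), S = gB$S, B = gB$B),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> t = %.3f s, V = %.1f um^3, S = %.1f um^2, B = %.4f, max A = %.3f\n",
              x$t, x$V, x$S, x$B, max(x$A)))
  invisible(x)
}

make_control <- function(params, n_steps, record_every = NULL,
                         stop_after_closures = 0L, drift = FALSE,
                         freeze_phi = FALSE, react_off = FALSE,
                         chi = NULL, Aatt = 0, Arep = 0, noise = NULL,
                         t0 = 0, extinct_tol = 1e-3, extinct_window = 5,
                         patch_thresh = 0.5) {
  if (is.null(record_every))
    record_every <- max(1L, as.integer(round(0.2 / params$dt)))
  list(n_steps = as.numeric(n_steps), record_every = as.integer(record_every),
       stop_after_closures = as.integer(stop_after_closures),
       extinct_tol = extinct_tol, extinct_window = extinct_window,
       patch_thresh = patch_thresh, t0 = t0, drift = isTRUE(drift),
       freeze_phi = isTRUE(freeze_phi), react_off = isTRUE(react_off),
       chi = chi, Aatt = Aatt, Arep = Arep,
       noise = if (is.null(noise)) NULL else unclass(noise))
}

#' Advance an axisymmetric cell state
#'
#' Runs `n` coupled explicit-Euler steps of the full model (membrane
#' mechanics, advection, membrane-confined reaction-diffusion, global pool
#' bookkeeping, decay and clamping) and returns the updated state.
#'
#' @param state a `cell_state` from [init_cell_state()].
#' @param params a [sim_params()] object.
#' @param n number of steps of size `params$dt`.
#' @param freeze_phi hold the geometry fixed (static-membrane kinetics).
#' @param react_off disable the reaction terms (pure transport).
#' @param bead optional [bead_spec()]; adds excluded-volume repulsion and
#'   adhesion, with the zero-net-force drift correction.
#' @param noise optional [noise_params()].
#' @return The updated `cell_state` (diagnostic series in
#'   `attr(, "series")`).
#' @export
step_axisym <- function(state, params, n = 1, freeze_phi = FALSE,
                        react_off = FALSE, bead = NULL, noise = NULL) {
  chi <- NULL; Aatt <- 0; Arep <- 0
  if (!is.null(bead)) {
    chi <- bead_field(state$grid, bead, params$eps)
    Aatt <- bead$Aatt; Arep <- bead$Arep
  }
  ctl <- make_control(params, n_steps = n, record_every = max(1L, as.integer(n)),
                      freeze_phi = freeze_phi, react_off = react_off,
                      chi = chi, Aatt = Aatt, Arep = Arep, noise = noise,
                      drift = !is.null(bead), t0 = state$t,
                      extinct_tol = -1)  # fixed-step call: never terminate early
  res <- cpp_run_axisym(state$phi, state$A, state$I, unclass(params), ctl)
  out <- state
  out$phi <- res$phi; out$A <- res$A; out$I <- res$I; out$psi <- res$psi
  out$t <- res$t
  gB <- global_B(params$at, params$R0, out$A, out$psi, params$eps, state$grid)
  out$V <- volume_of(out$phi, state$grid); out$S <- gB$S; out$B <- gB$B
  attr(out, "series") <- as.data.frame(res$series)
  out
}

#' Cup-closure detection on the axisymmetric field
#'
#' Scans the line `r = dx` (the innermost off-axis node column) from the
#' top of the domain downward and counts transitions of phi across 0.5
#' from vacant to occupied. A plain cell yields one transition; an
#' enclosed extracellular region (a sealed cup) yields two.
#'
#' @param phi phase field.
#' @param grid an [axisym_grid()].
#' @return List: transition `count`, logical `closed` (`count >= 2`), and
#'   the axial coordinates `zt`, `zb` (um) of the first and second
#'   transitions (NA when absent).
#' @export
detect_closure <- function(phi, grid) {
  sc <- cpp_closure_scan(phi)
  list(count = sc$count, closed = sc$count >= 2,
       zt = if (sc$kt >= 0) grid$z[sc$kt + 1] else NA_real_,
       zb = if (sc$kb >= 0) grid$z[sc$kb + 1] else NA_real_)
}

#' Enclosed extracellular volume of a sealed cup
#'
#' Integrates the vacant (`phi < 0.5`) region bounded by cell material,
#' slice by slice between the two closure transitions: a disk around the
#' axis, or an annulus when the slice has cell material at the center.
#' Errors if called on a state without a detected closure.
#'
#' @param phi phase field.
#' @param grid an [axisym_grid()].
#' @return Enclosed volume (um^3).
#' @export
enclosed_volume <- function(phi, grid) {
  sc <- cpp_closure_scan(phi)
  if (sc$count < 2)
    stop("no enclosed region: closure scan found ", sc$count,
         " transition(s)")
  cpp_enclosed_volume(phi, grid$dx, sc$kb, sc$kt)
}

classify_outcome <- function(events, status, V0) {
  n_ev <- length(events$t)
  success <- n_ev > 0 && any(events$fraction >= 1e-5)
  label <- if (n_ev >= 2) "repetitive"
    else if (success) "closure"
    else if (n_ev > 0) "small-closure"
    else "no-closure"
  list(label = label,
       n_closures = n_ev,
       t_first_closure = if (n_ev > 0) events$t[1] else NA_real_,
       intake_fraction = if (n_ev > 0) events$fraction[n_ev] else 0,
       efficiency = if (n_ev > 0)
         events$fraction[n_ev] / (events$t[n_ev] / 60) else 0,
       status = status)
}

#' Run a full axisymmetric cup simulation
#'
#' Integrates the coupled model from a seeded spherical cell to `t_max`,
#' a terminal patch extinction (max A below `1e-3` for 5 s), or an optional
#' closure-count limit, recording a diagnostic time series and every
#' debounced cup-closure event with its enclosed volume.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed for the run (patch seeding and nucleation noise).
#' @param grid optional [axisym_grid()] override.
#' @param noise optional [noise_params()].
#' @param bead optional [bead_spec()] (on-axis bead).
#' @param t_max override of `params$t_max` (s).
#' @param record_every_s series cadence (s).
#' @param stop_after_closures stop early after this many closures
#'   (0 = run to the end).
#' @param freeze_phi hold the geometry fixed.
#' @return An object of class `"axisym_run"`: final `state`, `series`
#'   data frame, `events` data frame, `outcome` list (label in
#'   closure / small-closure / repetitive / no-closure, first-closure
#'   time, intake fraction, efficiency per minute), and the run `params`.
#' @export
run_axisym <- function(params, seed = params$seed, grid = NULL, noise = NULL,
                       bead = NULL, t_max = params$t_max,
                       record_every_s = 0.2, stop_after_closures = 0,
                       freeze_phi = FALSE) {
  set.seed(seed)
  state <- init_cell_state(params, grid = grid)
  grid <- state$grid
  chi <- NULL; Aatt <- 0; Arep <- 0
  if (!is.null(bead)) {
    bead <- resolve_bead_center(bead, params, grid)
    chi <- bead_field(grid, bead, params$eps)
    Aatt <- bead$Aatt; Arep <- bead$Arep
  }
  n_steps <- ceiling(t_max / params$dt)
  ctl <- make_control(params, n_steps = n_steps,
                      record_every = max(1L, round(record_every_s / params$dt)),
                      stop_after_closures = stop_after_closures,
                      drift = !is.null(bead), freeze_phi = freeze_phi,
                      chi = chi, Aatt = Aatt, Arep = Arep, noise = noise)
  res <- cpp_run_axisym(state$phi, state$A, state$I, unclass(params), ctl)
  state$phi <- res$phi; state$A <- res$A; state$I <- res$I
  state$psi <- res$psi; state$t <- res$t
  state$V <- volume_of(state$phi, grid)
  events <- as.data.frame(res$events)
  out <- list(state = state,
              series = as.data.frame(res$series),
              events = events,
              outcome = classify_outcome(res$events, res$status, params$V0),
              n_Bclip = res$n_Bclip,
              params = params, seed = seed,
              bead = bead, noise = noise)
  class(out) <- "axisym_run"
  out
}

#' @export
print.axisym_run <- function(x, ...) {
  oc <- x$outcome
  cat(sprintf("<axisym_run> t = %.1f s (%s), outcome: %s\n",
              x$state$t, oc$status, oc$label))
  if (oc$n_closures > 0)
    cat(sprintf("  %d closure(s); first at t = %.1f s; intake fraction %.3g (%.3g / min)\n",
                oc$n_closures, oc$t_first_closure, oc$intake_fraction,
                oc$efficiency))
  invisible(x)
}

#' Phase-diagram sweep over force and patch amount
#'
#' Repeats [run_axisym()] over a grid of `F/eta` and `at` values with
#' `reps` independent seeds (alternating the two documented seed radii),
#' and tabulates per-cell success rate, mean intake fraction over
#' successes, mean first-closure time, efficiency, and the phase label:
#' I (all runs enclose), II (some do), III (repetitive closures observed),
#' IV (none close).
#'
#' @param F_over_eta,at_values grid axes.
#' @param params baseline [sim_params()].
#' @param reps runs per cell.
#' @param rinit_values seed radii cycled across reps (um).
#' @param seed base seed; run seeds are derived deterministically.
#' @param ... passed to [run_axisym()] (e.g. `t_max`).
#' @return Data frame, one row per grid cell.
#' @export
sweep_phase_diagram <- function(F_over_eta, at_values, params = sim_params(),
                                reps = 6, rinit_values = c(1.0, 1.5),
                                seed = 1, ...) {
  cells <- expand.grid(F_over_eta = F_over_eta, at = at_values)
  rows <- lapply(seq_len(nrow(cells)), function(ic) {
    fr <- cells$F_over_eta[ic]; atv <- cells$at[ic]
    runs <- lapply(seq_len(reps), function(r) {
      rin <- rinit_values[((r - 1) %% length(rinit_values)) + 1]
      p <- utils::modifyList(unclass(params),
                             list(F = fr * params$eta, at = atv, rinit = rin))
      class(p) <- "sim_params"
      run_axisym(p, seed = seed * 1000L + ic * 100L + r, ...)
    })
    fracs <- vapply(runs, function(x) x$outcome$intake_fraction, 0)
    succ <- fracs >= 1e-5
    labels <- vapply(runs, function(x) x$outcome$label, "")
    phase <- if (any(labels == "repetitive")) "III"
      else if (all(succ)) "I" else if (any(succ)) "II" else "IV"
    data.frame(
      F_over_eta = fr, at = atv,
      success_rate = mean(succ),
      mean_fraction = if (any(succ)) mean(fracs[succ]) else 0,
      mean_t_closure = mean(vapply(runs, function(x)
        x$outcome$t_first_closure, 0), na.rm = TRUE),
      efficiency = mean(vapply(runs, function(x) x$outcome$efficiency, 0)),
      phase = phase)
  })
  do.call(rbind, rows)
}
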