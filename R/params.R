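#' Simulation parameters
#'
#' Bundles every physical and numerical constant of the coupled
#' membrane/reaction-diffusion model. Defaults are the reference conditions
#' used throughout the cup phase diagrams (a 10 um cell with surface tension
#' 0.5 nN/um, membrane thickness 0.8 um, deformation timescale 10 s nN/um^3,
#' protrusive force F/eta = 4 and total signalling amount a_t = 2.8, no
#' inhibitor production).
#'
#' @param tau deformation timescale (s nN/um^3); 1/tau is the membrane
#'   velocity per unit stress.
#' @param eta cortical surface tension (nN/um).
#' @param eps effective membrane thickness, the phase-field interface
#'   width (um).
#' @param MV volume-constraint stiffness (nN/um^5).
#' @param R0 resting cell radius (um); the target volume is `4*pi*R0^3/3`.
#' @param F protrusive force magnitude (nN/um^2).
#' @param K,Kp lower and upper half-maximal concentrations of the force
#'   window: protrusion is promoted for `K <~ A <~ Kp` (concentration units).
#' @param nh Hill coefficient of the force law.
#' @param DA,DI diffusion constants of the activator A and inhibitor I
#'   (um^2/s).
#' @param at total amount of activator + inactive pool per unit resting
#'   surface area, `at = At / (4*pi*R0^2)` (concentration units).
#' @param alpha half-saturation of the autocatalytic activation; `Inf` is a
#'   first-class value giving the unsaturated (excitable-capable) kinetics.
#' @param k1 inhibitor production rate (1/s/c^p).
#' @param k2 inhibitor degradation rate (1/s/c).
#' @param p exponent of A in the inhibitor production term `k1 * A^p`;
#'   the quadratic default is required for patch splitting, the linear
#'   variant is exposed for comparison.
#' @param beta sharpness of the logistic membrane indicator psi.
#' @param theta threshold of the membrane indicator; with the tanh interface
#'   kernel, `theta = 0.105` makes the `psi > 1/2` band exactly `eps` wide.
#' @param dx grid spacing (um), identical in all directions.
#' @param dt time step (s). Defaults to `4e-4 * (dx / 0.1)^2`, the diffusive
#'   scaling of the reference step; larger values are rejected.
#' @param gamma2 off-membrane decay rate of A and I (1/s).
#' @param psi_cut membrane-band cutoff: the reaction-advection-diffusion
#'   update is applied where `psi > psi_cut`, elsewhere A and I decay.
#' @param grad_cut gradient regularization: the interface velocity is set to
#'   zero where `|grad phi| <= grad_cut`.
#' @param clamp_max upper clamp applied to the activator after each step
#'   (guards against the concentration spike on shrinking internalized
#'   vesicles).
#' @param clamp_max_I upper clamp for the inhibitor. Kept well above the
#'   natural inhibitor excursion (which reaches ~500 in the unsaturated
#'   excitable regime): clamping I at the activator's value creates a
#'   spurious stable state that freezes the excitable dynamics.
#' @param rinit radius of the initial seeded patch (um).
#' @param t_max simulated time horizon (s).
#' @param force_law `"edge"` for the A-window force as defined (the
#'   suppression factor uses `A^2/Kp`), `"edge_linear"` for the variant
#'   with `A/Kp` (force high strictly for `K < A < Kp`), `"inhibited"`
#'   for the competitive I-inhibition force.
#' @param Lr,Lz axisymmetric domain extents (um); the axis r = 0 is the
#'   left edge. The cell sits near the bottom (5 um clearance below its
#'   lower pole) so the extra height is headroom for the cup, which grows
#'   from the top pole.
#' @param L3 3-D cubic box edge (um).
#' @param seed integer RNG seed for the run.
#'
#' @return An object of class `"sim_params"` (a validated named list, with
#'   derived quantities `V0` and `kappa = k1/k2` attached).
#' @export
sim_params <- function(tau = 10, eta = 0.5, eps = 0.8, MV = 5.0, R0 = 10,
                       F = 2.0, K = 0.005, Kp = 0.25, nh = 3,
                       DA = 0.1, DI = 0.01, at = 2.8, alpha = 1.0,
                       k1 = 0, k2 = 2.0e-4, p = 2,
                       beta = 100, theta = 0.105,
                       dx = 0.1, dt = NULL, gamma2 = 10.0,
                       psi_cut = 1e-3, grad_cut = 1e-3, clamp_max = 50.0,
                       clamp_max_I = 1000,
                       rinit = 1.5, t_max = 600,
                       force_law = c("edge", "edge_linear", "inhibited"),
                       Lr = 15, Lz = 40, L3 = 25.6, seed = 1L) {
  force_law <- match.arg(force_law)
  dt_ref <- 4.0e-4 * (dx / 0.1)^2
  if (is.null(dt)) dt <- dt_ref
  stopifnot(
    tau > 0, eta > 0, eps > 0, MV >= 0, R0 > 0, F >= 0, K > 0, Kp > 0,
    nh > 0, DA >= 0, DI >= 0, at > 0, alpha > 0, k1 >= 0, k2 >= 0,
    p %in% c(1, 2), beta > 0, dx > 0, dt > 0, gamma2 >= 0,
    psi_cut > 0, grad_cut > 0, clamp_max > 0, clamp_max_I > 0,
    rinit >= 0, t_max > 0,
    Lr > 0, Lz > 0, L3 > 0
  )
  if (theta >= 0.25)
    stop("theta must be < 1/4 so that a psi = 1 membrane band exists")
  if (dt > dt_ref * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stable step %g for dx = %g",
                 dt, dt_ref, dx))
  out <- list(
    tau = tau, eta = eta, eps = eps, MV = MV, R0 = R0,
    V0 = 4 * pi * R0^3 / 3,
    F = F, K = K, Kp = Kp, nh = nh, DA = DA, DI = DI, at = at,
    alpha = alpha, k1 = k1, k2 = k2, p = as.integer(p),
    kappa = if (k2 > 0) k1 / k2 else 0,
    beta = beta, theta = theta, dx = dx, dt = dt, gamma2 = gamma2,
    psi_cut = psi_cut, grad_cut = grad_cut, clamp_max = clamp_max,
    clamp_max_I = clamp_max_I,
    rinit = rinit, t_max = t_max, force_law = force_law,
    Lr = Lr, Lz = Lz, L3 = L3, seed = as.integer(seed)
  )
  class(out) <- "sim_params"
  out
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  mechanics : tau=%g eta=%g eps=%g MV=%g R0=%g\n",
              x$tau, x$eta, x$eps, x$MV, x$R0))
  cat(sprintf("  force     : %s law, F=%g (F/eta=%g) K=%g Kp=%g nh=%g\n",
              x$force_law, x$F, x$F / x$eta, x$K, x$Kp, x$nh))
  cat(sprintf("  kinetics  : at=%g alpha=%s k1=%g k2=%g p=%d DA=%g DI=%g\n",
              x$at, format(x$alpha), x$k1, x$k2, x$p, x$DA, x$DI))
  cat(sprintf("  numerics  : dx=%g dt=%g t_max=%g domain %gx%g (axisym) %g^3 (3D)\n",
              x$dx, x$dt, x$t_max, x$Lr, x$Lz, x$L3))
  invisible(x)
}

#' Stochastic nucleation parameters
#'
#' Parameters of random patch nucleation: events arrive as a Poisson process
#' at rate `lambda` per unit volume per unit time; each event adds a Gaussian
#' bump `N0 * exp(-|x - xc|^2 / (2 d^2))` of activator to the membrane band,
#' with amplitude `N0` exponentially distributed with mean `sigma` and
#' center `xc` uniform in the domain.
#'
#' @param sigma mean of the exponential amplitude distribution
#'   (concentration units).
#' @param d Gaussian envelope width (um).
#' @param lambda nucleation rate (events / um^3 / s).
#' @return An object of class `"noise_params"`.
#' @export
noise_params <- function(sigma = 8.0, d = 1.5, lambda = 3e-5) {
  stopifnot(sigma >= 0, d >= 0, lambda >= 0)
  structure(list(sigma = sigma, d = d, lambda = lambda),
            class = "noise_params")
}

#' Solid bead specification
#'
#' A rigid spherical particle described by a static indicator field
#' `chi(r) = (1 + tanh((Rb - |r - rb|) / (eps/2))) / 2`. The membrane feels
#' a soft-core repulsion `-Arep * chi^2 * phi` (excluded volume) and an
#' adhesion `+Aatt * |grad chi| |grad phi|`.
#'
#' @param Rb bead radius (um).
#' @param center bead center: numeric of length 3 (3-D, um) or length 2
#'   `(r, z)` with r = 0 for an on-axis bead in the axisymmetric solver;
#'   `NULL` places the bead tangent to the undeformed membrane on the seed
#'   axis at run time.
#' @param Aatt adhesion strength.
#' @param Arep repulsion strength.
#' @return An object of class `"bead_spec"`.
#' @export
bead_spec <- function(Rb = 2.0, center = NULL, Aatt = 0.8, Arep = 5.0) {
  stopifnot(Rb > 0, Aatt >= 0, Arep >= 0)
  if (!is.null(center)) stopifnot(is.numeric(center), length(center) %in% c(2, 3))
  structure(list(Rb = Rb, center = center, Aatt = Aatt, Arep = Arep),
            class = "bead_spec")
}

#' Reduced patch-boundary model parameters
#'
#' In the reduced model the reaction-diffusion patch is replaced by a single
#' boundary marker on the interface contour. The marker moves with the
#' membrane and slides tangentially at speed `vt * (A0 - A)` until the
#' normalized patch area A reaches `A0`; the protrusive force is a sigmoidal
#' bump of half-width `rf` centered a fixed arc length `dl` outside the
#' marker. These values are artifact defaults (not printed in the source
#' model description), chosen to reproduce the qualitative closure /
#' repetitive / no-closure regimes.
#'
#' @param vt tangential boundary speed coefficient (um/s per unit area
#'   mismatch).
#' @param A0 target patch area, normalized by the resting cell surface.
#' @param dl arc-length offset of the protrusion site from the boundary
#'   marker (um).
#' @param rf protrusion-site half-width (um).
#' @param slope slope of the sigmoid force profile (fixed at 2.5).
#' @return An object of class `"reduced_params"`.
#' @export
reduced_params <- function(vt = 0.3, A0 = 0.35, dl = 0.8, rf = 0.5,
                           slope = 2.5) {
  stopifnot(vt > 0, A0 > 0, A0 <= 1, dl > 0, rf > 0, slope > 0)
  structure(list(vt = vt, A0 = A0, dl = dl, rf = rf, slope = slope),
            class = "reduced_params")
}

#' Named parameter presets
#'
#' Ready-made `sim_params` (plus optional noise/bead blocks) for the
#' documented reference conditions of the model: representative cup-closure
#' and failure points of the phase diagram, the three flat-membrane patch
#' regimes, the stochastic-nucleation condition, bead engulfment, and the
#' two patch-splitting conditions.
#'
#' @param name preset name; one of `"fig2A"`, `"fig2C"`, `"fig2D"`,
#'   `"fig2E"`, `"fig2F"`, `"fig2G"`, `"fig1D-top"`, `"fig1D-mid"`,
#'   `"fig1D-bottom"`, `"fig4A"`, `"fig5A"`, `"fig6CD"`, `"fig6EF"`.
#' @param ... overrides passed on to [sim_params()].
#' @return A list with elements `params` (`sim_params`), and where the
#'   preset defines them, `noise` (`noise_params`) and `bead` (`bead_spec`).
#' @export
preset <- function(name, ...) {
  base <- switch(
    name,
    "fig2A" = list(F = 2.0, at = 2.8, tau = 10, k1 = 0),
    "fig2C" = list(F = 2.6, at = 2.6, tau = 10, k1 = 0),
    "fig2D" = list(F = 0.8, at = 2.8, tau = 10, k1 = 0),
    "fig2E" = list(F = 1.6, at = 2.5, tau = 10, k1 = 0),
    "fig2F" = list(F = 1.4, at = 2.8, tau = 10, k1 = 0),
    "fig2G" = list(F = 1.2, at = 2.7, tau = 10, k1 = 0),
    "fig1D-top" = list(DA = 0.1, alpha = 1.0, at = 2.6, k1 = 0),
    "fig1D-mid" = list(DA = 0.1, DI = 0.01, alpha = 1.0, at = 2.6,
                       k1 = 2e-4, k2 = 2e-4),
    "fig1D-bottom" = list(DA = 0.085, DI = 0.11, alpha = 50.0, at = 1.985,
                          k1 = 0.088, k2 = 0.54),
    "fig4A" = list(F = 2.0, at = 2.8, tau = 10, k1 = 0),
    "fig5A" = list(F = 2.0, at = 2.8, tau = 10, k1 = 2e-4, k2 = 2e-4),
    "fig6CD" = list(at = 1.985, k1 = 0.088, k2 = 0.54, DA = 0.085,
                    DI = 0.11, alpha = Inf, tau = 7, F = 3.7, K = 0.01,
                    Kp = 0.1, nh = 5, force_law = "inhibited"),
    "fig6EF" = list(at = 1.94, k1 = 0.088, k2 = 0.54, DA = 0.26,
                    DI = 0.87, alpha = Inf, tau = 20, F = 3.0, K = 0.086,
                    Kp = 1.8, nh = 3, force_law = "inhibited"),
    stop("unknown preset: ", name)
  )
  args <- utils::modifyList(base, list(...))
  out <- list(params = do.call(sim_params, args))
  if (name == "fig4A") out$noise <- noise_params(sigma = 8.0, d = 1.5, lambda = 3e-5)
  if (name == "fig5A") out$bead <- bead_spec(Rb = 2.0, Aatt = 0.8, Arep = 5.0)
  out
}
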