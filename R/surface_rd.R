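#' Reaction terms of the membrane patch kinetics
#'
#' Pointwise reaction rates: autocatalytic activation from the shared pool
#' B with saturation `alpha` and competitive inhibition by I, first-order
#' inactivation of A, and inhibitor production `k1 A^p` with linear decay
#' `k2 I`.
#'
#' @param A,I concentration fields (any shape).
#' @param B global pool concentration.
#' @param alpha activation half-saturation (`Inf` for the unsaturated
#'   limit).
#' @param k1,k2 inhibitor rates.
#' @param p inhibitor production exponent.
#' @return List with `dA` and `dI`, the local reaction rates.
#' @export
reaction_terms <- function(A, I, B, alpha = Inf, k1 = 0, k2 = 0, p = 2) {
  sat <- if (is.finite(alpha)) 1 + A^2 / alpha^2 else 1
  list(dA = A^2 * B / (sat * (1 + I)) - A,
       dI = k1 * A^p - k2 * I)
}

#' Global inactive-pool concentration
#'
#' In the fast-cytosolic-diffusion limit the inactive pool is spatially
#' uniform and algebraically slaved to the membrane activator:
#' `B = At/S - <A>` with `At = at * 4 pi R0^2`, surface area
#' `S = int psi/eps dr` and mean membrane activator
#' `<A> = (int A psi/eps dr) / S`. Negative values (which would indicate a
#' conservation violation) are clipped to zero with a warning.
#'
#' @param at total amount per unit resting area.
#' @param R0 resting cell radius (um).
#' @param A activator field.
#' @param psi membrane indicator field.
#' @param eps interface width (um).
#' @param grid grid the fields live on.
#' @return List with `B`, `S`, `meanA`, and the conserved total
#'   `mass = <A> S + B S` (equal to `At` unless clipping occurred).
#' @export
global_B <- function(at, R0, A, psi, eps, grid) {
  S <- surface_area_of(psi, grid, eps)
  if (S <= 0) stop("degenerate membrane: surface area is zero")
  At <- at * 4 * pi * R0^2
  meanA <- volume_of(A * psi, grid) / eps / S
  B <- At / S - meanA
  if (B < 0) {
    warning("global pool B clipped at 0 (conservation violation)")
    B <- 0
  }
  list(B = B, S = S, meanA = meanA, mass = meanA * S + B * S)
}

#' Seed the initial activator patch
#'
#' Sets A to i.i.d. uniform values in `[0, 5]` on membrane-band nodes
#' (`psi > 0.5`) within Euclidean distance `rinit` of a surface point
#' (default: the top pole of the cell), leaving A elsewhere unchanged.
#' Uses the session RNG.
#'
#' @param A activator field.
#' @param psi membrane indicator field.
#' @param grid grid the fields live on.
#' @param rinit seed radius (um); `rinit = 0` leaves the state untouched.
#' @param point seed center: `(r, z)` or `(x, y, z)`; `NULL` picks the
#'   node of maximal z within the membrane band on the axis.
#' @return The modified activator field.
#' @export
seed_initial_patch <- function(A, psi, grid, rinit, point = NULL) {
  if (rinit <= 0) return(A)
  if (inherits(grid, "axisym_grid")) {
    if (is.null(point)) {
      kz <- max(which(psi[1, ] > 0.5))
      point <- c(0, grid$z[kz])
    }
    d2 <- outer((grid$r - point[1])^2, (grid$z - point[2])^2, "+")
  } else {
    if (is.null(point)) {
      nzc <- which(psi > 0.5, arr.ind = TRUE)
      kz <- nzc[which.max(nzc[, 3]), ]
      point <- c(grid$x[kz[1]], grid$y[kz[2]], grid$z[kz[3]])
    }
    dx2 <- outer((grid$x - point[1])^2, (grid$y - point[2])^2, "+")
    d2 <- outer(dx2, (grid$z - point[3])^2, "+")
  }
  sel <- (psi > 0.5) & (d2 <= rinit^2)
  A[sel] <- stats::runif(sum(sel), 0, 5)
  A
}

#' Stochastic patch nucleation (single step)
#'
#' Draws `Poisson(lambda * V_domain * dt)` nucleation events; each adds a
#' Gaussian bump `N0 * exp(-|x - xc|^2 / (2 d^2))` to A on membrane-band
#' nodes (`psi > psi_cut`), with `N0 ~ Exponential(mean sigma)` and `xc`
#' uniform in the domain volume. The result is clamped at `clamp_max`.
#' The solver cores apply the identical scheme internally every step; this
#' function exposes one step for analysis.
#'
#' @param A activator field.
#' @param psi membrane indicator field.
#' @param grid grid the fields live on.
#' @param noise a [noise_params()] object.
#' @param dt time step (s).
#' @param psi_cut membrane-band cutoff.
#' @param clamp_max concentration clamp.
#' @return List with the updated `A` and the event count `n_events`.
#' @export
nucleate <- function(A, psi, grid, noise, dt, psi_cut = 1e-3,
                     clamp_max = 50) {
  if (noise$lambda <= 0) return(list(A = A, n_events = 0L))
  Vdom <- if (inherits(grid, "axisym_grid")) {
    pi * grid$Lr^2 * grid$Lz
  } else {
    (grid$nx - 1) * (grid$ny - 1) * (grid$nz - 1) * grid$dx^3
  }
  n <- stats::rpois(1, noise$lambda * Vdom * dt)
  if (n > 0) {
    for (e in seq_len(n)) {
      N0 <- stats::rexp(1, 1 / noise$sigma)
      if (inherits(grid, "axisym_grid")) {
        rc <- grid$Lr * sqrt(stats::runif(1))   # volume-uniform in r
        zc <- grid$Lz * stats::runif(1)
        d2 <- outer((grid$r - rc)^2, (grid$z - zc)^2, "+")
      } else {
        xc <- c(grid$x[grid$nx], grid$y[grid$ny], grid$z[grid$nz]) *
          stats::runif(3)
        dxy <- outer((grid$x - xc[1])^2, (grid$y - xc[2])^2, "+")
        d2 <- outer(dxy, (grid$z - xc[3])^2, "+")
      }
      bump <- N0 * exp(-d2 / (2 * noise$d^2))
      bump[psi <= psi_cut] <- 0
      A <- pmin(A + bump, clamp_max)
    }
  }
  list(A = A, n_events = as.integer(n))
}
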