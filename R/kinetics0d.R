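#' Nondimensionalize the dimensional patch kinetics
#'
#' Maps the dimensional activation/inactivation scheme (autocatalytic
#' activation at rate `kA` with half-saturation `KA`, inhibition scale `KI`,
#' constant inactivation `dA`) onto the dimensionless two-variable model via
#' `alpha = kA / (KI * dA)`, `A~ = alpha * A / KA`, `t~ = dA * t`. The
#' mapping of the remaining parameters is `at~ = at * alpha / KA`,
#' `k1~ = k1 * KA^2 / kA`, `k2~ = k2 / dA`, `DA~ = DA / dA`, `DI~ = DI / dA`.
#'
#' @param kA autocatalysis rate; @param KA half-saturation of A;
#' @param KI inhibitor scale; @param dA inactivation rate;
#' @param at_dim dimensional total amount per area;
#' @param k1_dim,k2_dim dimensional inhibitor rates;
#' @param DA_dim,DI_dim dimensional diffusivities.
#' @return List with `alpha`, `at`, `k1`, `k2`, `DA`, `DI`.
#' @export
nondimensionalize <- function(kA, KA, KI, dA, at_dim,
                              k1_dim = 0, k2_dim = 0,
                              DA_dim = 0, DI_dim = 0) {
  stopifnot(kA > 0, KA > 0, KI > 0, dA > 0, at_dim > 0)
  alpha <- kA / (KI * dA)
  list(alpha = alpha,
       at = at_dim * alpha / KA,
       k1 = k1_dim * KA^2 / kA,
       k2 = k2_dim / dA,
       DA = DA_dim / dA,
       DI = DI_dim / dA)
}

fp_jacobian <- function(a, I, B, alpha, k1, k2, p = 2) {
  sat <- if (is.finite(alpha)) 1 + a^2 / alpha^2 else 1
  dsat <- if (is.finite(alpha)) 2 * a / alpha^2 else 0
  fa <- (2 * a * B * sat - a^2 * B * dsat) / (sat^2 * (1 + I)) - 1
  fI <- -a^2 * B / (sat * (1 + I)^2)
  ga <- p * k1 * a^(p - 1)
  gI <- -k2
  matrix(c(fa, ga, fI, gI), 2, 2)
}

#' Fixed points of the well-mixed patch kinetics
#'
#' Finds all nonnegative fixed points of the space-free two-variable system
#' `dA/dt = A^2 B / ((1 + A^2/alpha^2)(1 + I)) - A`,
#' `dI/dt = k1 A^p - k2 I` at fixed pool concentration `B`, together with
#' the Jacobian eigenvalues and a regime label. `A = 0` is always a fixed
#' point; in the unsaturated limit (`alpha = Inf`, `p = 2`) the nonzero
#' pair is `A+- = (B +- sqrt(B^2 - 4 k1/k2)) / (2 k1/k2)`.
#'
#' @param B inactive-pool concentration.
#' @param k1,k2 inhibitor production/degradation rates.
#' @param alpha activation half-saturation (`Inf` allowed).
#' @param p inhibitor production exponent (1 or 2).
#' @return List of class `"fixed_point_report"`: data frame `points`
#'   (columns A, I, re1, re2, stable) and `regime` in
#'   `c("mono-stable", "bistable", "excitable")`.
#' @export
fixed_points <- function(B, k1, k2, alpha = Inf, p = 2) {
  stopifnot(B >= 0, k1 >= 0, k2 >= 0, p %in% c(1, 2))
  kap <- if (k2 > 0) k1 / k2 else 0
  if (k1 > 0 && k2 == 0)
    stop("k1 > 0 with k2 = 0 has no finite inhibitor steady state")
  # nonzero fixed points: a B = (1 + a^2/alpha^2) (1 + kap a^p)
  if (is.finite(alpha)) {
    ia2 <- 1 / alpha^2
    coefs <- if (p == 2) c(1, -B, ia2 + kap, 0, kap * ia2)
             else c(1, kap - B, ia2, kap * ia2)
  } else {
    coefs <- if (p == 2) c(1, -B, kap) else c(1, kap - B)
  }
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  roots <- if (length(coefs) > 1) polyroot(coefs) else complex(0)
  a <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + Mod(roots)) & Re(roots) > 1e-12])
  a <- sort(unique(round(a, 12)))
  rows <- lapply(c(0, a), function(ai) {
    Ii <- if (k2 > 0) k1 * ai^p / k2 else 0
    J <- fp_jacobian(ai, Ii, B, alpha, k1, k2, p)
    ev <- eigen(J, only.values = TRUE)$values
    re <- sort(Re(ev), decreasing = TRUE)
    data.frame(A = ai, I = Ii, re1 = re[1], re2 = re[2],
               stable = max(re) < 0)
  })
  pts <- do.call(rbind, rows)
  nonzero <- pts[pts$A > 0, , drop = FALSE]
  regime <- if (nrow(nonzero) == 0) "mono-stable"
    else if (nonzero$stable[which.max(nonzero$A)]) "bistable"
    else "excitable"
  structure(list(points = pts, regime = regime, B = B, k1 = k1, k2 = k2,
                 alpha = alpha, p = p),
            class = "fixed_point_report")
}

#' @export
print.fixed_point_report <- function(x, ...) {
  cat(sprintf("<fixed_point_report> regime: %s (B = %g, k1 = %g, k2 = %g, alpha = %s)\n",
              x$regime, x$B, x$k1, x$k2, format(x$alpha)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Stability boundary of the upper fixed point in k2
#'
#' Scans the leading Jacobian eigenvalue at the upper nonzero fixed point
#' A+ across `k2` and locates the value at which its real part changes
#' sign, by bisection. In the unsaturated limit the trace at A+ is
#' `1 - k2`, so the boundary sits at `k2 = 1` for any `B`, `k1` inside the
#' three-fixed-point regime.
#'
#' @param B pool concentration (must admit three fixed points across the
#'   scanned range).
#' @param k1 inhibitor production rate.
#' @param k2_range interval to scan.
#' @param alpha activation half-saturation.
#' @param tol bisection tolerance on k2.
#' @return List: `k2_star` (boundary), `bracket`, and `existence_boundary`
#'   (TRUE when the fixed-point pair ceases to exist inside the range, in
#'   which case `k2_star` is that existence limit, not a stability result).
#' @export
stability_boundary_k2 <- function(B, k1, k2_range = c(0.5, 2), alpha = Inf,
                                  tol = 1e-6) {
  lead_re <- function(k2) {
    fp <- fixed_points(B, k1, k2, alpha)
    nz <- fp$points[fp$points$A > 0, , drop = FALSE]
    if (nrow(nz) < 2) return(NA_real_)   # pair does not exist here
    nz$re1[which.max(nz$A)]
  }
  lo <- k2_range[1]; hi <- k2_range[2]
  flo <- lead_re(lo); fhi <- lead_re(hi)
  if (is.na(flo) || is.na(fhi))
    return(list(k2_star = NA_real_, bracket = k2_range,
                existence_boundary = TRUE))
  if (flo * fhi > 0)
    stop("leading eigenvalue does not change sign on the given k2 range")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- lead_re(mid)
    if (is.na(fm))
      return(list(k2_star = mid, bracket = c(lo, hi),
                  existence_boundary = TRUE))
    if (flo * fm <= 0) { hi <- mid } else { lo <- mid; flo <- fm }
  }
  list(k2_star = (lo + hi) / 2, bracket = c(lo, hi),
       existence_boundary = FALSE)
}

#' Sufficient condition for patch annihilation
#'
#' With inhibitor production `kappa = k1/k2 > 0`, the activated state can
#' vanish outright when no nonzero fixed point exists for any pool value
#' `0 <= b <= at`. The closed-form sufficient condition is
#' `kappa > (9/32) at^2 - 1/alpha^2`. With `exact = TRUE` the necessary and
#' sufficient condition is evaluated numerically: the fixed-point function
#' `f(a) = a b - (1 + a^2/alpha^2)(1 + kappa a^2)` (at the worst case
#' `b = at`) is maximized over `a > 0` and annihilation corresponds to
#' `max f < 0`.
#'
#' @param at total amount per unit area.
#' @param alpha activation half-saturation (`Inf` allowed).
#' @param kappa ratio `k1/k2`.
#' @param exact use the numerical necessary-and-sufficient test.
#' @return Logical: `TRUE` means any activated patch must decay.
#' @export
annihilation_condition <- function(at, alpha = Inf, kappa, exact = FALSE) {
  stopifnot(at > 0, kappa >= 0, alpha > 0)
  ia2 <- if (is.finite(alpha)) 1 / alpha^2 else 0
  if (!exact) return(kappa > (9 / 32) * at^2 - ia2)
  f <- function(a) a * at - (1 + a^2 * ia2) * (1 + kappa * a^2)
  opt <- stats::optimize(f, c(0, max(at / max(kappa + ia2, 1e-12), 4 / at, 10)),
                         maximum = TRUE)
  opt$objective < 0
}

#' Well-mixed trajectory of the patch kinetics
#'
#' Integrates the space-free system with an adaptive ODE solver; serves as
#' the brute-force oracle for the fixed-point and annihilation analysis.
#' With `conserve = TRUE` the pool is slaved to the activator,
#' `b = at - A`; otherwise `b` is held at the supplied value.
#'
#' @param A0,I0 initial state.
#' @param b pool value: total `at` when `conserve`, fixed `B` otherwise.
#' @param k1,k2,alpha,p kinetic parameters as in [fixed_points()].
#' @param Tend integration horizon (dimensionless time).
#' @param conserve slave the pool to A.
#' @param n_out number of output samples.
#' @return Data frame with columns `time`, `A`, `I`.
#' @export
simulate_wellmixed <- function(A0, I0 = 0, b, k1 = 0, k2 = 0, alpha = Inf,
                               p = 2, Tend = 100, conserve = TRUE,
                               n_out = 400) {
  stopifnot(A0 >= 0, I0 >= 0, Tend > 0)
  deriv <- function(t, y, parms) {
    A <- y[1]; I <- y[2]
    Bv <- if (conserve) max(b - A, 0) else b
    sat <- if (is.finite(alpha)) 1 + A^2 / alpha^2 else 1
    dA <- A^2 * Bv / (sat * (1 + I)) - A
    dI <- k1 * A^p - k2 * I
    list(c(dA, dI))
  }
  out <- deSolve::ode(y = c(A = A0, I = I0),
                      times = seq(0, Tend, length.out = n_out),
                      func = deriv, parms = NULL, method = "lsoda")
  as.data.frame(out)
}

#' Regime map of the decoupled kinetics
#'
#' Tabulates the fixed-point regime over a grid of total amount `at` and
#' inhibitor degradation `k2` at fixed `k1` (the pool is taken at its
#' maximal value `b = at`, the worst case for existence).
#'
#' @param at_values,k2_values grid axes.
#' @param k1 inhibitor production rate.
#' @param alpha activation half-saturation.
#' @return Data frame with `at`, `k2`, `n_fixed_points`, `regime`.
#' @export
regime_map <- function(at_values, k2_values, k1 = 0.088, alpha = Inf) {
  grid <- expand.grid(at = at_values, k2 = k2_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    fp <- fixed_points(B = grid$at[i], k1 = k1, k2 = grid$k2[i], alpha = alpha)
    data.frame(at = grid$at[i], k2 = grid$k2[i],
               n_fixed_points = nrow(fp$points), regime = fp$regime)
  })
  do.call(rbind, res)
}
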