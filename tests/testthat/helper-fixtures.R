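# Shared coarse-resolution settings used across the suite. The reference
# resolution is dx = 0.1 um; tests run mostly at dx = 0.2 um (with dt
# rescaled as dx^2) so that full simulated seconds stay cheap.

coarse_params <- function(...) {
  sim_params(dx = 0.2, ...)
}

# tweak fields of an existing sim_params without re-validating dt scaling
within_params <- function(p, ...) {
  q <- utils::modifyList(unclass(p), list(...))
  class(q) <- "sim_params"
  q
}

# a compact axisymmetric grid for operator tests (small but off-boundary
# regions are well inside)
small_grid <- function(dx = 0.2, Lr = 4, Lz = 6) {
  axisym_grid(nr = round(Lr / dx) + 1, nz = round(Lz / dx) + 1, dx = dx)
}

# brute-force oracle: does f(a) = a*b - (1 + a^2/alpha^2)(1 + kappa a^2)
# have a positive root for some 0 <= b <= at? (monotone in b, so b = at
# is the worst case); dense sign scan, independent of the package's
# root-finding path
oracle_max_f <- function(at, alpha, kappa) {
  ia2 <- if (is.finite(alpha)) 1 / alpha^2 else 0
  a <- seq(1e-4, 1000, length.out = 400000)
  max(a * at - (1 + a^2 * ia2) * (1 + kappa * a^2))
}
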