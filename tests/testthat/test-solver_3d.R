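# 3-D checks run on reduced geometries (a 4 um cell on a coarse grid):
# the solver scales linearly in node count, so these exercise every term
# at a cost compatible with a test suite.

small3 <- function(dx = 0.4, L3 = 14.4, R0 = 4, ...) {
  sim_params(dx = dx, L3 = L3, R0 = R0, ...)
}

test_that("bead indicator has the tanh profile and the right volume", {
  p <- small3()
  g <- default_cart_grid3(p)
  ctr <- rep(mean(range(g$x)), 3)
  bd <- bead_spec(Rb = 2, center = ctr)
  chi <- bead_field(g, bd, p$eps)
  # chi = 1/2 on the bead surface, ~1 at the center
  i <- which.min(abs(g$x - ctr[1]))
  expect_equal(chi[i, i, i], 1, tolerance = 1e-3)
  surf <- which.min(abs(g$x - (ctr[1] + 2)))
  expect_equal(chi[surf, i, i], 0.5, tolerance = 0.15)
  # smoothed indicator: exact continuum volume is (4/3)pi Rb^3 plus the
  # Sommerfeld correction pi^3 (eps/2)^2 Rb / 3 for the tanh tail
  vol_chi <- 4 * pi * 8 / 3 + pi^3 * (p$eps / 2)^2 * 2 / 3
  expect_equal(volume_of(chi, g), vol_chi, tolerance = 0.02)
})

test_that("engulfment fraction distinguishes outside, half, and inside", {
  p <- small3()
  g <- default_cart_grid3(p)
  ctr <- rep(mean(range(g$x)), 3)
  phi <- init_sphere_phi(g, ctr, p$R0, p$eps)
  # far outside the cell
  chi_out <- bead_field(g, bead_spec(Rb = 1, center = ctr + c(6, 0, 0)),
                        p$eps)
  expect_lt(engulfment_fraction(chi_out, phi, g), 0.05)
  expect_lt(engulfment_fraction(chi_out, phi, g, "overlap"), 0.05)
  # centered inside
  chi_in <- bead_field(g, bead_spec(Rb = 1, center = ctr), p$eps)
  expect_gt(engulfment_fraction(chi_in, phi, g), 0.95)
  expect_gt(engulfment_fraction(chi_in, phi, g, "overlap"), 0.9)
  # half-embedded in a flat interface (finer grid so the equatorial layer
  # bias is small)
  p2 <- small3(dx = 0.2, L3 = 12, R0 = 4)
  g2 <- default_cart_grid3(p2)
  ctr2 <- rep(mean(range(g2$x)), 3)
  phi_flat <- array(0, c(g2$nx, g2$ny, g2$nz))
  for (k in seq_len(g2$nz))
    phi_flat[, , k] <- (1 - tanh(2 * (g2$z[k] - ctr2[3]) / p2$eps)) / 2
  chi_half <- bead_field(g2, bead_spec(Rb = 1.2, center = ctr2), p2$eps)
  expect_equal(engulfment_fraction(chi_half, phi_flat, g2), 0.5,
               tolerance = 0.12)
})

test_that("3-D cavity detector returns enclosed volumes only", {
  p <- small3(dx = 0.2, L3 = 14)
  g <- default_cart_grid3(p)
  ctr <- rep(mean(range(g$x)), 3)
  phi <- init_sphere_phi(g, ctr, 4, p$eps)
  expect_equal(closure_detect_3d(phi, g)$volume, 0)
  # off-center cavity of radius 2 inside the cell
  hole <- init_sphere_phi(g, ctr + c(0, 0, 1), 2, p$eps)
  phi1 <- pmin(phi, 1 - hole)
  cd <- closure_detect_3d(phi1, g)
  expect_equal(cd$n_cavities, 1)
  expect_equal(cd$volume, 4 * pi * 8 / 3, tolerance = 0.05)
  # two cavities: volumes add
  hole2 <- init_sphere_phi(g, ctr - c(0, 0, 2.6), 1, p$eps)
  phi2 <- pmin(phi1, 1 - hole2)
  cd2 <- closure_detect_3d(phi2, g)
  expect_equal(cd2$n_cavities, 2)
  expect_equal(cd2$volume, 4 * pi * 8 / 3 + 4 * pi / 3, tolerance = 0.06)
})

test_that("a quiescent 3-D cell is stationary and the bead repels the membrane", {
  p <- small3(rinit = 0)
  st <- init_cell_state_3d(p, seed_patch = FALSE)
  st10 <- step_3d(st, p, n = round(5 / p$dt))
  expect_lt(abs(st10$V - p$V0) / p$V0, 0.02)
  # bead tangent to the membrane, no activator: overlap does not grow
  bd <- resolve_bead_center(bead_spec(Rb = 1.5), p, st$grid)
  chi <- bead_field(st$grid, bd, p$eps)
  ov0 <- volume_of(chi^2 * st$phi, st$grid)
  stb <- step_3d(st, p, n = round(5 / p$dt), bead = bd)
  ov1 <- volume_of(chi^2 * stb$phi, st$grid)
  expect_lt(ov1, ov0 + 0.2)
  # chi itself is static by construction (recomputed identically)
  expect_identical(chi, bead_field(st$grid, bd, p$eps))
})

test_that("drift correction keeps the centroid fixed", {
  p <- small3(rinit = 1.0, at = 2.6)
  set.seed(8)
  st <- init_cell_state_3d(p)
  st2 <- step_3d(st, p, n = round(8 / p$dt), drift = TRUE,
                 record_every = round(1 / p$dt))
  s <- attr(st2, "series")
  drift_xyz <- c(diff(range(s$centroid_x)), diff(range(s$centroid_y)),
                 diff(range(s$centroid_z)))
  expect_lt(max(drift_xyz), 0.1)
})

test_that("axisymmetric bead engulfment succeeds with adhesion at the documented point", {
  # quasi-3D bead run: F/eta = 4, at = 2.8, inhibitor on, Rb = 2 um; the
  # cup wraps the bead and seals, disconnecting its pocket from the
  # exterior within ~80 s
  p <- preset("fig5A", dx = 0.2)$params
  bd <- bead_spec(Rb = 2, Aatt = 0.8, Arep = 5.0)
  r <- run_axisym(p, seed = 2, bead = bd, t_max = 100)
  chi <- bead_field(r$state$grid, r$bead, p$eps)
  ef <- engulfment_fraction(chi, r$state$phi, r$state$grid)
  expect_gt(ef, 0.95)
  # weaker force at higher amount: the patch vanishes before uptake
  p2 <- preset("fig5A", dx = 0.2, F = 1.4, at = 2.9)$params
  r2 <- run_axisym(p2, seed = 2, bead = bead_spec(Rb = 2), t_max = 100)
  chi2 <- bead_field(r2$state$grid, r2$bead, p2$eps)
  expect_lt(engulfment_fraction(chi2, r2$state$phi, r2$state$grid), 0.5)
})
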