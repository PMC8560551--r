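test_that("force laws take their closed-form values", {
  expect_equal(protrusive_force(0, F = 2), 0)
  expect_equal(protrusive_force(1e6, F = 2), 0, tolerance = 1e-12)
  expect_equal(protrusive_force(0.05, F = 2.0, K = 0.005, Kp = 0.25, nh = 3),
               2.0 * (1000 / 1001) / (1 + 1e-6), tolerance = 1e-12)
  # competitive law: I = 0 reduces to the saturation factor; I >> Kp kills it
  A <- c(0.01, 0.05, 0.2)
  expect_equal(protrusive_force_inhibited(A, 0, F = 2),
               2 * (A / 0.005)^3 / (1 + (A / 0.005)^3), tolerance = 1e-12)
  expect_lt(max(protrusive_force_inhibited(A, I = 100, F = 2)), 1e-6)
  # A >> K with I = Kp gives F/2
  expect_equal(protrusive_force_inhibited(10, I = 0.25, F = 2), 1,
               tolerance = 1e-3)
})

test_that("a force-free sphere follows curvature flow at rate 2 eta/(tau R)", {
  p <- coarse_params(MV = 0, rinit = 0, Lr = 13, Lz = 26)
  st <- init_cell_state(p, seed_patch = FALSE)
  g <- st$grid
  R0fit <- (3 * volume_of(st$phi, g) / (4 * pi))^(1 / 3)
  st <- step_axisym(st, p, n = round(10 / p$dt))
  R1 <- (3 * volume_of(st$phi, g) / (4 * pi))^(1 / 3)
  # dR/dt = -2 eta/(tau R): R = 10, eta = 0.5, tau = 10 -> -0.01 um/s
  expect_equal((R1 - R0fit) / 10, -2 * p$eta / (p$tau * 10), tolerance = 0.1)
  # closed form R^2(t) = R^2(0) - (4 eta / tau) t
  expect_equal(R1^2, R0fit^2 - 4 * p$eta / p$tau * 10, tolerance = 0.01)
})

test_that("volume constraint holds a force-free sphere stationary", {
  p <- coarse_params(rinit = 0, Lr = 13, Lz = 26)
  st <- init_cell_state(p, seed_patch = FALSE)
  run <- step_axisym(st, p, n = round(100 / p$dt))
  s <- attr(run, "series")
  expect_lt(max(abs(s$V - p$V0) / p$V0), 0.01)
  expect_true(all(run$phi >= -0.05 & run$phi <= 1.05))
})

test_that("normal speed is consistent with the phase-field update", {
  p <- coarse_params(R0 = 5)   # V0 matches the R = 5 test sphere
  g <- axisym_grid(71, 101, p$dx)
  phi <- init_sphere_phi(g, c(0, 10), R0 = 5, eps = p$eps)
  Fp <- matrix(0, g$nr, g$nz)
  ns <- normal_speed(phi, Fp, p, g)
  # flat-ish far field: speed 0 where the gradient is cut off
  expect_equal(ns$s[g$nr - 2, 2], 0)
  # sphere speed at the interface is inward (negative) everywhere active
  act <- ns$gmag > 0.5  # well-resolved interface nodes
  expect_lt(max(ns$s[act]), 0)
  # Euler-step consistency: dphi/dt == s |grad phi| at the interface
  V <- volume_of(phi, g)
  stepped <- advance_phi(phi, Fp, within_params(p, MV = 0), n_steps = 1)
  dphi_dt <- (stepped$phi - phi) / p$dt
  ns0 <- normal_speed(phi, Fp, within_params(p, MV = 0), g, V = V)
  err <- abs(dphi_dt - ns0$s * ns0$gmag)[act]
  expect_lt(max(err) / max(abs(dphi_dt)), 0.05)
})

test_that("a banded force above 2 eta/R protrudes the interface locally", {
  p <- coarse_params(R0 = 5, MV = 0)
  g <- axisym_grid(71, 101, p$dx)
  phi <- init_sphere_phi(g, c(0, 10), R0 = 5, eps = p$eps)
  Fp <- matrix(0, g$nr, g$nz)
  band <- abs(outer(g$r, rep(1, g$nz)) - 0) < 2 &
    abs(outer(rep(1, g$nr), g$z) - 15) < 2.5
  Fp[band] <- 1.5   # well above 2 eta / R = 0.2
  res <- advance_phi(phi, Fp, p, n_steps = round(8 / p$dt))
  occ_before <- max(g$z[apply(phi >= 0.5, 2, any)])
  occ_after <- max(g$z[apply(res$phi >= 0.5, 2, any)])
  expect_gt(occ_after, occ_before + 2 * p$dx)
})

test_that("analytic force and energy estimates", {
  expect_equal(minimal_force_ratio(1.5), pi / 1.5)
  expect_equal(round(minimal_force_ratio(1.5)), 2)  # ~2.0 /um to 1 s.f.
  expect_equal(minimal_force_ratio(pi), 1)
  expect_equal(minimal_protrusion_width(0.1, 1), 2 * 0.1)
  # width 0.2 um corresponds to R = 0.1 um: F*/eta = 1/R = 10 /um
  expect_equal(1 / (minimal_protrusion_width(0.5, 5) / 2), 10)
  expect_equal(bending_surface_ratio(1.6e-3, 0.5, 1), 1.6e-3)
  expect_equal(bending_surface_ratio(2 * 0.5 * 4, 0.5, 2), 1)
  expect_lt(bending_surface_ratio(1.6e-3, 0.5, 1e6), 1e-12)
})
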