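test_that("nondimensionalization reproduces the printed mapping", {
  nd <- nondimensionalize(kA = 1, KA = 1, KI = 1, dA = 1, at_dim = 1)
  expect_equal(nd$alpha, 1)
  nd2 <- nondimensionalize(kA = 2, KA = 1, KI = 0.5, dA = 4, at_dim = 1)
  expect_equal(nd2$alpha, 1)
  expect_equal(nd2$at, 1)
  # doubling dA halves alpha and at proportionally
  base <- nondimensionalize(kA = 3, KA = 2, KI = 0.7, dA = 1, at_dim = 5,
                            k1_dim = 0.1, k2_dim = 0.2)
  dbl <- nondimensionalize(kA = 3, KA = 2, KI = 0.7, dA = 2, at_dim = 5,
                           k1_dim = 0.1, k2_dim = 0.2)
  expect_equal(dbl$alpha, base$alpha / 2)
  expect_equal(dbl$at, base$at / 2)
  expect_equal(dbl$k2, base$k2 / 2)
  expect_equal(dbl$k1, base$k1)   # k1~ = k1 KA^2/kA has no dA dependence
})

test_that("fixed points match the closed form in the unsaturated limit", {
  fp <- fixed_points(B = 2.0, k1 = 0.088, k2 = 0.54)
  kap <- 0.088 / 0.54
  a_pm <- (2 + c(-1, 1) * sqrt(4 - 4 * kap)) / (2 * kap)
  expect_equal(sort(fp$points$A), sort(c(0, a_pm)), tolerance = 1e-6)
  expect_equal(fp$points$I, kap * fp$points$A^2, tolerance = 1e-6)
  # A = 0 is always present and stable
  expect_true(fp$points$stable[fp$points$A == 0])
  # below the existence threshold only A = 0 remains
  fp0 <- fixed_points(B = 2 * sqrt(kap) * 0.99, k1 = 0.088, k2 = 0.54)
  expect_equal(nrow(fp0$points), 1)
  expect_equal(fp0$regime, "mono-stable")
  # wave-pinning limit k1 = 0: a B = 1
  fpw <- fixed_points(B = 2, k1 = 0, k2 = 0)
  expect_equal(sort(fpw$points$A), c(0, 0.5), tolerance = 1e-9)
})

test_that("fixed points agree with dense root scanning at finite alpha", {
  for (prm in list(c(B = 2.2, k1 = 0.1, k2 = 0.8, alpha = 2),
                   c(B = 3.0, k1 = 0.05, k2 = 0.5, alpha = 1),
                   c(B = 2.0, k1 = 0.088, k2 = 0.54, alpha = 50))) {
    fp <- fixed_points(prm["B"], prm["k1"], prm["k2"], prm["alpha"])
    a_pkg <- sort(fp$points$A[fp$points$A > 0])
    # oracle: sign changes of a*B - (1 + a^2/al^2)(1 + kap a^2)
    kap <- prm["k1"] / prm["k2"]
    a <- seq(1e-5, 200, length.out = 2e6)
    f <- a * prm["B"] - (1 + a^2 / prm["alpha"]^2) * (1 + kap * a^2)
    sgn <- which(diff(sign(f)) != 0)
    a_oracle <- (a[sgn] + a[sgn + 1]) / 2
    expect_equal(length(a_pkg), length(a_oracle))
    if (length(a_pkg) > 0)
      expect_equal(a_pkg, sort(a_oracle), tolerance = 1e-3)
  }
})

test_that("stability of A+ flips exactly at k2 = 1 in the unsaturated limit", {
  sb <- stability_boundary_k2(B = 2, k1 = 0.088, k2_range = c(0.5, 2))
  expect_false(sb$existence_boundary)
  expect_equal(sb$k2_star, 1, tolerance = 1e-6)
  # independent of B and k1 inside the regime
  sb2 <- stability_boundary_k2(B = 3, k1 = 0.2, k2_range = c(0.5, 2))
  expect_equal(sb2$k2_star, 1, tolerance = 1e-6)
  # direct eigenvalue checks either side of the boundary
  fp_s <- fixed_points(B = 2, k1 = 0.088, k2 = 2)
  up <- fp_s$points[which.max(fp_s$points$A), ]
  expect_true(up$stable)
  expect_equal(fp_s$regime, "bistable")
  fp_u <- fixed_points(B = 2, k1 = 0.088, k2 = 0.5)
  up_u <- fp_u$points[which.max(fp_u$points$A), ]
  expect_false(up_u$stable)
  expect_equal(fp_u$regime, "excitable")
})

test_that("annihilation condition classifies the three reference regimes", {
  # static spot persists: no inhibitor production
  expect_false(annihilation_condition(at = 2.6, alpha = 1, kappa = 0))
  # transient spot with finite lifetime: kappa = 1
  expect_true(annihilation_condition(at = 2.6, alpha = 1, kappa = 1))
  # splitting/expanding regime
  expect_false(annihilation_condition(at = 1.985, alpha = 50,
                                      kappa = 0.088 / 0.54))
  # same classifications from the exact (numerical) condition
  expect_false(annihilation_condition(2.6, 1, 0, exact = TRUE))
  expect_true(annihilation_condition(2.6, 1, 1, exact = TRUE))
  expect_false(annihilation_condition(1.985, 50, 0.088 / 0.54, exact = TRUE))
})

test_that("closed-form condition is sufficient and exact mode is equivalent to brute force", {
  ats <- seq(0.5, 4, length.out = 15)
  kaps <- c(0, 10^seq(-3, 1, length.out = 12))
  alphas <- c(1, 50, Inf)
  for (al in alphas) for (atv in ats) for (kp in kaps) {
    mx <- oracle_max_f(atv, al, kp)
    if (abs(mx) < 1e-6) next  # degenerate tangency: boundary of existence
    oracle_exists <- mx >= 0
    if (annihilation_condition(atv, al, kp))       # sufficient direction
      expect_false(oracle_exists)
    expect_equal(annihilation_condition(atv, al, kp, exact = TRUE),
                 !oracle_exists)
  }
})

test_that("well-mixed trajectories behave as the phase portrait dictates", {
  # A = 0 is invariant
  tr0 <- simulate_wellmixed(A0 = 0, b = 2.6, k1 = 1e-3, k2 = 1e-3,
                            alpha = 1, Tend = 50)
  expect_equal(max(abs(tr0$A)), 0)
  # annihilating parameters: any start decays to ~0
  for (A0 in c(0.5, 2, 10)) {
    tr <- simulate_wellmixed(A0 = A0, b = 2.6, k1 = 2e-4, k2 = 2e-4,
                             alpha = 1, Tend = 4e4, conserve = TRUE)
    expect_lt(tail(tr$A, 1), 1e-3)
  }
  # persistent parameters (kappa = 0, at above the conserved-pool
  # bistability threshold at = 2 sqrt(2)): relaxes to the upper state
  tr_p <- simulate_wellmixed(A0 = 1, b = 3.5, k1 = 0, k2 = 0, alpha = 1,
                             Tend = 200, conserve = TRUE)
  expect_gt(tail(tr_p$A, 1), 1)
  # excitable regime: perturbation above A- makes a large excursion and
  # returns toward the basal state
  fp <- fixed_points(B = 2, k1 = 0.088, k2 = 0.54)
  a_minus <- min(fp$points$A[fp$points$A > 0])
  tr_e <- simulate_wellmixed(A0 = 1.5 * a_minus, I0 = 0, b = 2,
                             k1 = 0.088, k2 = 0.54, alpha = Inf,
                             Tend = 200, conserve = FALSE)
  expect_gt(max(tr_e$A), 5 * a_minus)    # large excursion
  expect_lt(tail(tr_e$A, 1), a_minus)    # back below threshold
})

test_that("regime map labels the k2 > 1 and k2 < 1 sides correctly", {
  rm <- regime_map(at_values = c(1.5, 2.5), k2_values = c(0.5, 1.5),
                   k1 = 0.088)
  expect_equal(rm$regime[rm$at == 2.5 & rm$k2 == 1.5], "bistable")
  expect_equal(rm$regime[rm$at == 2.5 & rm$k2 == 0.5], "excitable")
  # below the existence line at < 2 sqrt(k1/k2): mono-stable
  expect_equal(rm$regime[rm$at == 1.5 & rm$k2 == 0.5][1],
               ifelse(1.5 < 2 * sqrt(0.088 / 0.5), "mono-stable",
                      "excitable"))
})
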