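test_that("matching constants glue the regions together", {
  g <- dimensionless_groups(rho = 2.5, eps = 1e-3, phi = 0.15)
  mc <- matching_constants(g)
  expect_equal(mc$c1, 1 - 2.5 * 0.15)
  expect_equal(mc$c2, 1 + 2 * 0.15 - 2 / 2.5)
  expect_identical(mc$c3, 0)
  expect_identical(mc$c4, 1)

  # c1 is both the region I long-time inhibitor level and region II's gamma(0)
  expect_equal(asym_region1(50, g)$gamma, mc$c1, tolerance = 1e-10)
  expect_equal(asym_region2(0, g)$gamma, mc$c1)
  # c2 places the region IV onset exactly at the switchover time
  expect_equal(asym_region4(switchover_tau(g), g)$beta, 0)
})

test_that("region I solves the leading-order transient system", {
  g <- groups_ref()
  r0 <- asym_region1(0, g)
  expect_equal(c(r0$beta, r0$gamma), c(g$phi, 1))

  r_inf <- asym_region1(80, g)
  expect_equal(c(r_inf$beta, r_inf$gamma), c(0, 1 - g$rho * g$phi),
               tolerance = 1e-10)

  # oracle: fine-step RK4 on the leading-order system (eps = 0 limit)
  ref <- rk4_integrate(function(t, y) c(-y[1] * y[2], -g$rho * y[1] * y[2]),
                       c(g$phi, 1), tau_max = 1, h = 1e-4)
  r1 <- asym_region1(1, g)
  expect_equal(r1$beta, ref[nrow(ref), 2], tolerance = 1e-8)
  expect_equal(r1$gamma, ref[nrow(ref), 3], tolerance = 1e-8)

  g_deg <- suppressWarnings(dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.5))
  expect_error(asym_region1(1, g_deg),
               class = "vitcclock_validation_error")  # rho*phi = 1 degenerate
})

test_that("region II satisfies the quasi-steady identity beta*gamma = eps*rho", {
  g <- groups_ref()
  tau <- seq(0, 140, by = 0.5)
  r2 <- asym_region2(tau, g)
  expect_equal(r2$beta * r2$gamma, rep(g$eps * g$rho, length(tau)))
  expect_equal(asym_region2(100, g)$gamma, 0.2)
  expect_error(asym_region2(150, g), class = "vitcclock_validation_error")
  expect_error(asym_region2(200, g), class = "vitcclock_validation_error")
})

test_that("corner solution matches regions II and IV in its tails", {
  g <- groups_ref()
  rho <- g$rho; eps <- g$eps
  tau_sw <- switchover_tau(g)

  # corner centre: gamma = sqrt(eps) * rho * sqrt(2/pi) at leading order
  r3c <- asym_region3(tau_sw, g)
  expect_equal(r3c$gamma, sqrt(eps) * rho * sqrt(2 / pi), tolerance = 1e-12)

  # taubar -> -Inf: gamma approaches the region II line at rate O(1/taubar^2)
  rel_dev <- vapply(c(-5, -10), function(taubar) {
    tau <- tau_sw + taubar / sqrt(eps)
    gII <- -rho^2 * taubar * sqrt(eps)
    abs(asym_region3(tau, g)$gamma / gII - 1)
  }, numeric(1))
  expect_lt(rel_dev[1], 0.02)
  expect_lt(rel_dev[2], rel_dev[1] / 3)

  # taubar -> +Inf: beta approaches the region IV onset line
  tau_p <- tau_sw + 3 / sqrt(eps)
  line <- rho * eps * tau_p - (1 / rho - g$phi)
  expect_lt(abs(asym_region3(tau_p, g)$beta - line), 1e-6)

  # far tails evaluate finitely (scaled-erfc form, no 0/0 or underflow)
  far <- asym_region3(c(0, 5 * tau_sw), g)
  expect_true(all(is.finite(far$beta) & is.finite(far$gamma)))
})

test_that("region IV rises to equilibrium with inhibitor flat at zero", {
  g <- groups_ref()
  tau_sw <- switchover_tau(g)
  expect_equal(asym_region4(1e7, g)$beta, 0.5, tolerance = 1e-4)
  expect_identical(asym_region4(300, g)$gamma, 0)
  expect_error(asym_region4(100, g), class = "vitcclock_validation_error")

  # numeric agreement: the leading-order error is the O(sqrt(eps))
  # switchover shift inherited through the corner, ~1e-2 here, not smaller
  traj <- simulate_clock(g, times = c(0, 300), rtol = 1e-10, atol = 1e-13)
  expect_lt(abs(asym_region4(300, g)$beta - traj$beta[2]), 0.01)
})

test_that("piecewise composite selects regions and is continuous at seams", {
  g <- groups_ref()
  comp0 <- asym_composite(0, g)
  expect_identical(as.character(comp0$region), "I")
  expect_equal(c(comp0$beta, comp0$gamma), c(g$phi, 1))
  expect_identical(as.character(asym_composite(switchover_tau(g), g)$region),
                   "III")

  tau <- seq(0, 300, by = 0.05)
  comp <- asym_composite(tau, g)
  expect_identical(levels(comp$region), c("I", "II", "III", "IV"))
  seam <- which(diff(as.integer(comp$region)) != 0)
  jumps <- pmax(abs(diff(comp$beta)[seam]), abs(diff(comp$gamma)[seam]))
  expect_lt(max(jumps), 5 * sqrt(g$eps))
})

test_that("dimensionless switchover time follows the non-uniformity formula", {
  expect_equal(switchover_tau(groups_ref()), 150)
  g0 <- dimensionless_groups(rho = 2, eps = 1e-3, phi = 0)
  expect_equal(switchover_tau(g0), 1 / (4 * 1e-3))
  g_edge <- dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.499)
  expect_lt(switchover_tau(g_edge), 1)
  expect_error(suppressWarnings(
    switchover_tau(dimensionless_groups(rho = 4, eps = 1e-3, phi = 0.3))),
    class = "vitcclock_validation_error")
})

test_that("dimensional switchover time is k1-free and homogeneous", {
  expect_equal(switchover_seconds(c0 = 1, m0 = 1, phi = 0, k0 = 1), 1)

  # bench condition: prediction lands between the two timed repeats
  t_pred <- switchover_seconds(c0 = 0.0032630, m0 = 0.0068718, phi = 0,
                               k0 = 0.57)
  expect_gt(t_pred, 116.86)
  expect_lt(t_pred, 122.34)

  # algebraic identity with the dimensionless route, any k1
  for (k1 in c(57, 570, 5700)) {
    p <- kinetic_parameters(k0 = 0.57, k1 = k1, a0 = 0.0068718, b0 = 0,
                            c0 = 0.0032630)
    g <- nondimensionalize(p)
    expect_equal(switchover_tau(g) * g$time_scale,
                 switchover_seconds(0.0032630, 0.0068718, 0, 0.57),
                 tolerance = 1e-12)
  }

  # (c0, m0) -> (lambda c0, lambda m0) scales t_sw by 1/lambda
  t1 <- switchover_seconds(0.003, 0.007, 0.1, 0.57)
  t3 <- switchover_seconds(3 * 0.003, 3 * 0.007, 0.1, 0.57)
  expect_equal(t3, t1 / 3, tolerance = 1e-12)

  expect_error(switchover_seconds(c0 = 0.001, m0 = 0.01, phi = 0.2, k0 = 1),
               class = "vitcclock_validation_error")  # c0 <= phi*m0
})
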