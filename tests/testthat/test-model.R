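test_that("dimensional mass-action rates match hand substitution", {
  p <- kinetic_parameters(k0 = 0.5, k1 = 500, a0 = 1e-3, b0 = 1e-3, c0 = 1e-3)

  expect_equal(clock_rhs_dimensional(c(0, 0, 0), p), c(0, 0, 0))

  # no inhibitor: only the slow reaction runs
  r <- clock_rhs_dimensional(c(2e-3, 1e-3, 0), p)
  expect_equal(r, c(-2 * 0.5 * (2e-3)^2, 0.5 * (2e-3)^2, 0))

  # full substitution, written out independently
  st <- c(1e-3, 1e-3, 1e-3)
  fast <- 500 * st[2] * st[3]; slow <- 0.5 * st[1]^2
  expect_equal(clock_rhs_dimensional(st, p),
               c(2 * fast - 2 * slow, -fast + slow, -fast))

  # iodine atoms conserved by the vector field itself, across random states
  set.seed(11)
  for (i in 1:25) {
    st <- stats::runif(3, 0, 1e-2)
    r <- clock_rhs_dimensional(st, p)
    expect_equal(r[1] + 2 * r[2], 0)
  }

  expect_error(clock_rhs_dimensional(c(-1e-3, 0, 0), p),
               class = "vitcclock_validation_error")
})

test_that("dimensionless rates match hand substitution and vanish at equilibrium", {
  g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
  expect_equal(clock_rhs(c(0.5, 0), g), c(0, 0))
  expect_equal(clock_rhs(c(0, 0.7), g), c(0.01 * 2, 0))
  expect_equal(clock_rhs(c(0.1, 0.5), g), c(-0.05 + 0.02 * 0.64, -0.1))
})

test_that("stiff integration agrees with a fixed-step RK4 oracle", {
  g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
  traj <- simulate_clock(g, tau_max = 30, n_out = 301L)
  ref <- rk4_integrate(rhs_oracle(2, 0.01), c(0.2, 1), 30, h = 1e-3)
  # oracle self-check: step doubling moves it by far less than the tolerance
  ref2 <- rk4_integrate(rhs_oracle(2, 0.01), c(0.2, 1), 30, h = 2e-3)
  expect_lt(max(abs(ref[nrow(ref), -1] - ref2[nrow(ref2), -1])), 1e-10)

  at <- match(round(traj$tau, 10), round(ref[, 1], 10))
  expect_false(anyNA(at))
  for (col in 2:3) {
    rel <- abs(traj[[col]] - ref[at, col]) / pmax(abs(ref[at, col]), 1e-8)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("trajectories conserve iodine atoms and deplete the inhibitor", {
  p <- kinetic_parameters(k0 = 0.57, k1 = 570, a0 = 0.004, b0 = 0.0013,
                          c0 = 0.0033)
  dtraj <- simulate_clock_dimensional(p, t_max = 600)
  expect_lt(max(abs(dtraj$a + 2 * dtraj$b - p$m0)), 1e-9 * p$m0)

  g <- dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2)
  traj <- simulate_clock(g, tau_max = 300)
  meta <- attr(traj, "meta")
  tol <- 10 * meta$atol
  expect_true(all(diff(traj$gamma) <= tol))
  expect_true(all(traj$beta >= -tol & traj$gamma >= -tol))
  expect_true(all(traj$beta <= 0.5 + tol))
})

test_that("rho*beta - gamma is conserved through the initial transient", {
  g <- groups_ref()
  tau_end <- 0.01 * switchover_tau(g)            # first 1% of the induction
  traj <- simulate_clock(g, tau_max = tau_end, n_out = 101L)
  q <- g$rho * traj$beta - traj$gamma
  expect_lt(max(abs(q - (g$rho * g$phi - 1))), 10 * g$eps)
})

test_that("trajectories hug the quasi-steady curve during induction", {
  for (eps in c(1e-2, 1e-3)) {
    g <- dimensionless_groups(rho = 2, eps = eps, phi = 0.2)
    tau_sw <- switchover_tau(g)
    traj <- simulate_clock(g, tau_max = 0.5 * tau_sw)
    mid <- traj$tau > 0.2 * tau_sw               # past the initial transient
    imbalance <- abs(traj$beta[mid] * traj$gamma[mid] -
                     g$eps * g$rho * (1 - 2 * traj$beta[mid])^2)
    expect_lt(max(imbalance), 100 * eps^2)
  }
})

test_that("quasi-steady curve evaluates pointwise and handles beta = 0", {
  g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
  expect_equal(quasi_steady_gamma(0.5, g), 0)
  expect_equal(quasi_steady_gamma(0.1, g), 0.02 * 0.64 / 0.1)
  expect_identical(quasi_steady_gamma(0, g), Inf)
  expect_error(quasi_steady_gamma(0.7, g), class = "vitcclock_validation_error")
})

test_that("numeric switchover detection lands near the asymptotic time", {
  g <- groups_ref()
  traj <- simulate_clock(g, tau_max = 300)
  tsw <- detect_switchover(traj)
  # beta starts above the corner-scale threshold and decays first: the
  # detected crossing must be the post-induction rise, not the transient
  expect_gt(g$phi, attr(tsw, "threshold"))
  expect_equal(as.numeric(tsw), 150, tolerance = 0.1)

  # halving eps doubles the induction period
  g2 <- dimensionless_groups(rho = 2, eps = 5e-4, phi = 0.2)
  tsw2 <- detect_switchover(simulate_clock(g2, tau_max = 600))
  expect_equal(as.numeric(tsw2) / as.numeric(tsw), 2, tolerance = 0.05)

  # window too short
  expect_error(detect_switchover(simulate_clock(g, tau_max = 50)),
               class = "vitcclock_numerical_error")
})

test_that("detected switchover scales as (1 - rho*phi)/(rho^2*eps)", {
  rho <- 2; phi <- 0.2
  err <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    g <- dimensionless_groups(rho = rho, eps = eps, phi = phi)
    tau_sw <- switchover_tau(g)
    tsw <- detect_switchover(simulate_clock(g, tau_max = 1.5 * tau_sw,
                                            n_out = 4001L))
    abs(as.numeric(tsw) * eps * rho^2 - (1 - rho * phi))
  }, numeric(1))
  expect_true(all(diff(err) < 0))          # converging as eps -> 0
  expect_lt(err[3] / (1 - rho * phi), 0.03)
})

test_that("equilibrium report is closed-form for randomized rho", {
  set.seed(42)
  for (rho in c(2, stats::runif(5, 0.2, 5))) {
    eq <- equilibrium_analysis(dimensionless_groups(rho = rho, eps = 1e-3,
                                                    phi = 0.1))
    expect_identical(unname(eq$state), c(0.5, 0))
    expect_identical(eq$eigenvalues, c(0, -rho / 2))
    expect_identical(unname(eq$eigenvectors[, 1]), c(1, 0))
    expect_identical(unname(eq$eigenvectors[, 2]), c(1, rho))
    expect_identical(eq$manifold_labels, c("slow", "stable"))
  }
})
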