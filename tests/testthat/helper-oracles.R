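# Independent fixed-step classical Runge-Kutta integrator, used as the
# reference oracle against the stiff solver and the closed-form region
# solutions. Deliberately hand-coded and step-doubling-checkable so it
# shares no code path with simulate_clock().
rk4_integrate <- function(f, y0, tau_max, h) {
  n_steps <- ceiling(tau_max / h)
  h <- tau_max / n_steps
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(y0) + 1L)
  out[1L, ] <- c(0, y0)
  y <- y0
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out[i + 1L, ] <- c(t, y)
  }
  out
}

# dimensionless RHS written out independently of clock_rhs()
rhs_oracle <- function(rho, eps) {
  function(t, y) c(-y[1] * y[2] + eps * rho * (1 - 2 * y[1])^2,
                   -rho * y[1] * y[2])
}

# the reference parameter point used throughout the asymptotic comparisons
groups_ref <- function() dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2)
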