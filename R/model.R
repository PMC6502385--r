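#' Mass-action right-hand side, dimensional form
#'
#' Rates of change of iodide (`a`), iodine (`b`) and ascorbic acid (`c`)
#' under the two-reaction scheme `2A -> B` (rate `k0*a^2`) and `B + C -> 2A`
#' (rate `k1*b*c`):
#' \deqn{da/dt = 2 k_1 b c - 2 k_0 a^2,\quad
#'       db/dt = -k_1 b c + k_0 a^2,\quad
#'       dc/dt = -k_1 b c.}
#' The combination `da/dt + 2 db/dt` vanishes identically: iodine atoms are
#' conserved.
#'
#' @param state Numeric length-3 vector `(a, b, c)` of concentrations in
#'   mol/l. Components slightly below zero (within `tol`) are clipped to 0;
#'   more negative values raise a validation error.
#' @param params A [kinetic_parameters()] object.
#' @param tol Negative-concentration tolerance (mol/l).
#' @return Numeric length-3 vector `(da/dt, db/dt, dc/dt)` in mol/(l s).
#' @examples
#' p <- kinetic_parameters(k0 = 0.5, k1 = 500, a0 = 1e-3, b0 = 1e-3, c0 = 1e-3)
#' clock_rhs_dimensional(c(1e-3, 1e-3, 1e-3), p)
#' @export
clock_rhs_dimensional <- function(state, params, tol = 1e-10) {
  if (!inherits(params, "clock_params"))
    stop_validation("`params` must be a clock_params object")
  if (length(state) != 3L || !is.numeric(state) || anyNA(state))
    stop_validation("`state` must be a numeric (a, b, c) triple")
  if (any(state < -tol))
    stop_validation("negative concentration beyond tolerance in state: (",
                    paste(format(state), collapse = ", "), ")")
  state <- pmax(state, 0)
  a <- state[[1]]; b <- state[[2]]; c <- state[[3]]
  slow <- params$k0 * a^2
  fast <- params$k1 * b * c
  c(2 * fast - 2 * slow, -fast + slow, -fast)
}

#' Mass-action right-hand side, dimensionless form
#'
#' The reduced two-variable system in the iodine fraction `beta = b/m0` and
#' ascorbic-acid fraction `gamma = c/c0`:
#' \deqn{d\beta/d\tau = -\beta\gamma + \epsilon\rho (1-2\beta)^2,\quad
#'       d\gamma/d\tau = -\rho \beta\gamma.}
#'
#' @param state Numeric length-2 vector `(beta, gamma)`.
#' @param groups A [dimensionless_groups()] object.
#' @return Numeric length-2 vector `(dbeta/dtau, dgamma/dtau)`.
#' @examples
#' g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
#' clock_rhs(c(0.5, 0), g)   # equilibrium: both rates vanish
#' @export
clock_rhs <- function(state, groups) {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  if (length(state) != 2L || !is.numeric(state) || anyNA(state))
    stop_validation("`state` must be a numeric (beta, gamma) pair")
  beta <- state[[1]]; gamma <- state[[2]]
  c(-beta * gamma + groups$eps * groups$rho * (1 - 2 * beta)^2,
    -groups$rho * beta * gamma)
}

# deSolve-facing versions (func/jac signatures)
.ode_func <- function(t, y, parms) {
  beta <- y[[1]]; gamma <- y[[2]]
  list(c(-beta * gamma + parms$eps * parms$rho * (1 - 2 * beta)^2,
         -parms$rho * beta * gamma))
}

.ode_jac <- function(t, y, parms) {
  beta <- y[[1]]; gamma <- y[[2]]
  matrix(c(-gamma - 4 * parms$eps * parms$rho * (1 - 2 * beta), -beta,
           -parms$rho * gamma, -parms$rho * beta),
         nrow = 2, byrow = TRUE)
}

#' Integrate the dimensionless clock system
#'
#' Solves the reduced two-variable initial-value problem with a stiff
#' solver. Only `(beta, gamma)` are integrated; in dimensional terms the
#' iodide concentration follows exactly from conservation,
#' `a = m0 (1 - 2 beta)`, so iodine-atom conservation holds by construction.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param tau_max End of the integration interval (dimensionless time).
#' @param initial Initial `(beta, gamma)`; defaults to `(phi, 1)`, i.e. the
#'   freshly mixed solution.
#' @param times Optional explicit, strictly increasing output grid starting
#'   at 0. Overrides `n_out`.
#' @param n_out Number of equally spaced output times on `[0, tau_max]`.
#' @param rtol,atol Solver tolerances. The defaults resolve `gamma` down to
#'   the corner scale `O(sqrt(eps))` with room to spare.
#' @param method deSolve integrator name (default `"lsoda"`).
#' @return A `clock_trajectory`: a data frame with columns `tau`, `beta`,
#'   `gamma` and attributes `groups`, `meta` (solver name, tolerances,
#'   success flag).
#' @examples
#' g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
#' traj <- simulate_clock(g, tau_max = 30)
#' head(as.data.frame(traj))
#' @export
simulate_clock <- function(groups, tau_max,
                           initial = c(groups$phi, 1),
                           times = NULL, n_out = 2001L,
                           rtol = 1e-8, atol = 1e-12,
                           method = "lsoda") {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  if (is.null(times)) {
    check_number(tau_max, "tau_max", lower = 0, strict = TRUE)
    times <- seq(0, tau_max, length.out = n_out)
  } else {
    if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
      stop_validation("`times` must be strictly increasing with length >= 2")
    if (times[[1]] != 0)
      stop_validation("`times` must start at 0 (the mixing instant)")
  }
  if (length(initial) != 2L || anyNA(initial))
    stop_validation("`initial` must be a numeric (beta, gamma) pair")

  out <- try(deSolve::ode(y = c(beta = initial[[1]], gamma = initial[[2]]),
                          times = times, func = .ode_func, parms = groups,
                          jacfunc = .ode_jac, jactype = "fullusr",
                          method = method, rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") ||
      !is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0)
    stop_numerical("stiff solver failed on [0, ", max(times), "]",
                   diagnostics = if (!inherits(out, "try-error"))
                     attributes(out)[c("istate", "rstate")])

  traj <- data.frame(tau = out[, "time"],
                     beta = pmax(out[, "beta"], 0),
                     gamma = pmax(out[, "gamma"], 0))
  # clip only round-off undershoot; anything worse is a solver failure
  if (any(out[, c("beta", "gamma")] < -10 * atol - rtol * 1e-2))
    stop_numerical("solver produced negative concentrations beyond tolerance")
  structure(traj,
            class = c("clock_trajectory", "data.frame"),
            groups = groups,
            meta = list(method = method, rtol = rtol, atol = atol,
                        success = TRUE))
}

#' Integrate the clock system in dimensional units
#'
#' Convenience wrapper: nondimensionalizes, integrates the reduced system,
#' and maps back to `(a, b, c)` in mol/l against time in seconds. Iodide is
#' reconstructed from conservation, `a = m0 - 2b`.
#'
#' @param params A [kinetic_parameters()] object.
#' @param t_max End time in seconds.
#' @param ... Passed on to [simulate_clock()].
#' @return A data frame with columns `t_seconds`, `a`, `b`, `c` and the
#'   same attributes as a `clock_trajectory`.
#' @export
simulate_clock_dimensional <- function(params, t_max, ...) {
  groups <- nondimensionalize(params)
  traj <- simulate_clock(groups, tau_max = t_max / groups$time_scale, ...)
  out <- data.frame(t_seconds = traj$tau * groups$time_scale,
                    a = params$m0 * (1 - 2 * traj$beta),
                    b = params$m0 * traj$beta,
                    c = params$c0 * traj$gamma)
  structure(out, groups = groups, meta = attr(traj, "meta"),
            class = c("clock_trajectory_dimensional", "data.frame"))
}

#' Numerically locate the switchover time
#'
#' Finds the first up-crossing of `beta` through a threshold after the
#' initial transient (i.e. after the minimum of `beta`), refined by the
#' solver's own root finding so the crossing is located to high precision
#' rather than read off the output grid.
#'
#' The default threshold is the leading-order corner-centre value
#' `sqrt(2*eps/pi)`: at the end of the induction period `beta` leaves the
#' `O(eps)` quasi-steady scale and passes through `O(sqrt(eps))`, and the
#' asymptotic solution at the switchover instant is exactly
#' `sqrt(eps)*sqrt(2/pi)` at leading order. Detection at this scale tracks
#' the induction-period length `(1-rho*phi)/(rho^2*eps)`; a fixed O(1)
#' threshold would instead measure the much later slow rise of iodine.
#'
#' @param traj A `clock_trajectory` from [simulate_clock()].
#' @param threshold Dimensionless `beta` level to cross; default
#'   `sqrt(2*eps/pi)`.
#' @return The crossing time `tau_sw` (dimensionless), with attribute
#'   `threshold`.
#' @seealso [switchover_tau()] for the closed-form asymptotic value.
#' @export
detect_switchover <- function(traj, threshold = NULL) {
  if (!inherits(traj, "clock_trajectory"))
    stop_validation("`traj` must come from simulate_clock()")
  groups <- attr(traj, "groups")
  meta <- attr(traj, "meta")
  if (is.null(threshold))
    threshold <- sqrt(2 * groups$eps / pi)
  check_number(threshold, "threshold", lower = 0, strict = TRUE)

  beta <- traj$beta
  i_min <- which.min(beta)
  up <- which(beta[-1] >= threshold & beta[-length(beta)] < threshold)
  up <- up[up >= i_min]
  if (length(up) == 0L)
    stop_numerical("beta never rises through ", format(threshold),
                   " within tau <= ", max(traj$tau),
                   ": simulation window too short (switchover not reached)")
  j <- up[[1]]

  # refine inside the bracketing grid cell with lsodar root finding
  root_out <- deSolve::lsodar(
    y = c(beta = beta[[j]], gamma = traj$gamma[[j]]),
    times = c(traj$tau[[j]], traj$tau[[j + 1]]),
    func = .ode_func, parms = groups,
    rootfunc = function(t, y, p) y[[1]] - threshold,
    rtol = 1e-10, atol = 1e-13)
  troot <- attr(root_out, "troot")
  tau_sw <- if (length(troot) >= 1L) troot[[1]] else {
    # crossing sits numerically on the grid point
    traj$tau[[j + 1]]
  }
  structure(tau_sw, threshold = threshold)
}

#' Equilibrium and linearization of the dimensionless system
#'
#' The system has the unique equilibrium `(beta, gamma) = (1/2, 0)`: all
#' iodine atoms converted to molecular iodine, inhibitor exhausted. The
#' linearization there has eigenvalue 0 with eigenvector `(1, 0)` (the slow
#' manifold, the `gamma = 0` axis along which the system creeps to rest)
#' and eigenvalue `-rho/2` with eigenvector `(1, rho)` (a stable direction
#' outside the physical region). Returned in closed form.
#'
#' @param groups A [dimensionless_groups()] object.
#' @return An object of class `clock_equilibrium` with fields `state`,
#'   `eigenvalues`, `eigenvectors` (columns) and `manifold_labels`.
#' @examples
#' equilibrium_analysis(dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2))
#' @export
equilibrium_analysis <- function(groups) {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  rho <- groups$rho
  structure(list(
    state = c(beta = 0.5, gamma = 0),
    eigenvalues = c(0, -rho / 2),
    eigenvectors = matrix(c(1, 0, 1, rho), nrow = 2,
                          dimnames = list(c("beta", "gamma"), NULL)),
    manifold_labels = c("slow", "stable")
  ), class = "clock_equilibrium")
}

#' @export
print.clock_equilibrium <- function(x, ...) {
  cat("Equilibrium (beta*, gamma*) = (", x$state[[1]], ",", x$state[[2]], ")\n")
  cat("  eigenvalue", format(x$eigenvalues[1]), "(", x$manifold_labels[1],
      "manifold ), eigenvector (", paste(x$eigenvectors[, 1], collapse = ", "), ")\n")
  cat("  eigenvalue", format(x$eigenvalues[2]), "(", x$manifold_labels[2],
      "manifold ), eigenvector (", paste(x$eigenvectors[, 2], collapse = ", "), ")\n")
  invisible(x)
}

#' Quasi-steady induction curve
#'
#' During the induction period the iodine balance is quasi-steady,
#' `beta*gamma = eps*rho*(1-2*beta)^2`, defining the slow curve
#' `gamma = eps*rho*(1-2*beta)^2 / beta` that trajectories hug until the
#' inhibitor is exhausted. `beta = 0` maps to `Inf` (reported as such, not
#' an error).
#'
#' @param beta Numeric vector of `beta` values in `[0, 1/2]`.
#' @param groups A [dimensionless_groups()] object.
#' @return `gamma` values of the quasi-steady curve, same length as `beta`.
#' @examples
#' g <- dimensionless_groups(rho = 2, eps = 0.01, phi = 0.2)
#' quasi_steady_gamma(c(0.1, 0.5), g)   # 0.128, 0
#' @export
quasi_steady_gamma <- function(beta, groups) {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  if (any(beta < 0 | beta > 0.5))
    stop_validation("`beta` values must lie in [0, 1/2]")
  ifelse(beta == 0, Inf, groups$eps * groups$rho * (1 - 2 * beta)^2 / beta)
}

#' Export a trajectory as delimited text
#'
#' Writes one row per sample with a single header line (`tau,beta,gamma` or
#' `t_seconds,a,b,c`), suitable for diffing and downstream plotting.
#'
#' @param traj A trajectory from [simulate_clock()] or
#'   [simulate_clock_dimensional()].
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sep = ",") {
  utils::write.table(as.data.frame(traj), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
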