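#' Matching constants of the four-region asymptotic solution
#'
#' The leading-order matched-asymptotic construction glues four regions
#' with constants fixed by matching: `c1 = 1 - rho*phi` (inhibitor level
#' entering the induction period), `c2 = 1 + 2*phi - 2/rho` (long-term
#' region), and `c3 = 0`, `c4 = 1` (corner region Riccati/erf solution).
#'
#' @param groups A [dimensionless_groups()] object with `rho*phi < 1`.
#' @return Named list with `c1`, `c2`, `c3`, `c4`.
#' @export
matching_constants <- function(groups) {
  .check_asym(groups)
  list(c1 = 1 - groups$rho * groups$phi,
       c2 = 1 + 2 * groups$phi - 2 / groups$rho,
       c3 = 0,
       c4 = 1)
}

.check_asym <- function(groups, need_lt1 = TRUE) {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  rp <- groups$rho * groups$phi
  if (rp == 1)
    stop_validation("degenerate parameters: rho*phi = 1 (region-I solution ",
                    "and matching constants are singular there)")
  if (need_lt1 && rp > 1)
    stop_validation("rho*phi = ", format(rp), " > 1: the inhibitor outlasts ",
                    "the iodine supply; no switchover/asymptotic structure")
  invisible(groups)
}

#' Region I: initial adjustment (`tau = O(1)`)
#'
#' Leading-order solution of the fast initial transient, during which a
#' fraction `rho*phi` of the inhibitor is consumed and `beta` collapses
#' towards the quasi-steady scale:
#' \deqn{\beta_0(\tau) = \frac{\phi(1-\rho\phi) e^{(\rho\phi-1)\tau}}
#'   {1 - \rho\phi\, e^{(\rho\phi-1)\tau}},\qquad
#'   \gamma_0 = \rho\beta_0 + 1 - \rho\phi.}
#' Satisfies `beta(0) = phi`, `gamma(0) = 1` exactly and tends to
#' `(0, 1 - rho*phi)` as `tau -> Inf`.
#'
#' @param tau Numeric vector of dimensionless times.
#' @param groups A [dimensionless_groups()] object (`rho*phi != 1`).
#' @return A data frame with columns `tau`, `beta`, `gamma`.
#' @export
asym_region1 <- function(tau, groups) {
  .check_asym(groups, need_lt1 = FALSE)
  rho <- groups$rho; phi <- groups$phi
  E <- exp((rho * phi - 1) * tau)
  beta <- phi * (1 - rho * phi) * E / (1 - rho * phi * E)
  data.frame(tau = tau, beta = beta, gamma = rho * beta + 1 - rho * phi)
}

#' Region II: induction period (`beta = O(eps)`, `tau = O(1/eps)`)
#'
#' Quasi-steady solution: the inhibitor decays linearly,
#' `gamma = 1 - rho*phi - rho^2*eps*tau`, while
#' `beta = eps*rho/gamma` so that `beta*gamma = eps*rho` holds exactly.
#' Valid strictly before the blow-up time `(1-rho*phi)/(rho^2*eps)`, whose
#' non-uniformity defines the switchover.
#'
#' @inheritParams asym_region1
#' @return A data frame with columns `tau`, `beta`, `gamma`.
#' @export
asym_region2 <- function(tau, groups) {
  .check_asym(groups)
  rho <- groups$rho; eps <- groups$eps; phi <- groups$phi
  gamma <- 1 - rho * phi - rho^2 * eps * tau
  if (any(gamma <= 0))
    stop_validation("tau at or beyond the region II blow-up time ",
                    format((1 - rho * phi) / (rho^2 * eps)),
                    ": outside the induction period")
  data.frame(tau = tau, beta = eps * rho / gamma, gamma = gamma)
}

#' Region III: the corner layer around the switchover
#'
#' In the corner both variables are `O(sqrt(eps))` over a time window of
#' width `O(1/sqrt(eps))` around the switchover. With the shifted inner
#' time `taubar = (eps*tau - (1/rho^2 - phi/rho))/sqrt(eps)` the Riccati
#' closed form (matching constants `c3 = 0`, `c4 = 1`) is
#' \deqn{\bar\gamma_0 = \frac{\rho\, e^{-\rho^2\bar\tau^2/2}}
#'   {\sqrt{\pi/2}\,[1 + \mathrm{erf}(\rho\bar\tau/\sqrt2)]},\qquad
#'   \bar\beta_0 = \bar\gamma_0/\rho + \rho\bar\tau,}
#' evaluated through the scaled complementary error function
#' (`erfcx`) so the `exp/erf` ratio neither underflows nor divides 0 by 0
#' far into the tails. As `taubar -> -Inf`, `gamma` matches the region II
#' line `-(rho^2*taubar)`; as `taubar -> +Inf` the transcendental term dies
#' and `beta` matches the region IV onset `rho*eps*tau - (1/rho - phi)`.
#'
#' @inheritParams asym_region1
#' @return A data frame with columns `tau`, `beta`, `gamma`.
#' @export
asym_region3 <- function(tau, groups) {
  .check_asym(groups)
  rho <- groups$rho; eps <- groups$eps; phi <- groups$phi
  taubar <- (eps * tau - (1 / rho^2 - phi / rho)) / sqrt(eps)
  z <- rho * taubar / sqrt(2)
  # gamma_bar = rho * exp(-z^2) / (sqrt(pi/2) * (1 + erf(z)))
  #           = rho / (sqrt(pi/2) * erfcx(-z))
  gb <- rho / (sqrt(pi / 2) * pracma::erfcx(-z))
  gamma <- sqrt(eps) * gb
  beta <- gamma / rho + (rho * eps * tau - (1 / rho - phi))
  data.frame(tau = tau, beta = beta, gamma = gamma)
}

#' Region IV: long-term state after the switchover
#'
#' Once the inhibitor is exhausted, `gamma` is zero beyond all algebraic
#' orders in `eps` and iodine accumulates along
#' \deqn{\beta(\tau) = \frac12 - \frac{1}{2\,(1 + 2[\phi - 1/\rho +
#'   \rho\epsilon\tau])},}
#' the solution of `dbeta/dtau = eps*rho*(1-2*beta)^2` that vanishes at the
#' switchover time (matching constant `c2 = 1 + 2*phi - 2/rho`). `beta`
#' tends to the equilibrium value 1/2 as `tau -> Inf`.
#'
#' @inheritParams asym_region1
#' @param strict If `TRUE` (default) reject `tau` before the switchover
#'   time, where the formula is outside its validity interval.
#' @return A data frame with columns `tau`, `beta`, `gamma` (`gamma`
#'   identically 0).
#' @export
asym_region4 <- function(tau, groups, strict = TRUE) {
  .check_asym(groups)
  rho <- groups$rho; eps <- groups$eps; phi <- groups$phi
  if (strict && any(eps * tau < 1 / rho^2 - phi / rho - 1e-12))
    stop_validation("tau before the switchover time: outside region IV validity")
  den <- 1 + 2 * (phi - 1 / rho + rho * eps * tau)
  data.frame(tau = tau, beta = 0.5 - 1 / (2 * den), gamma = 0)
}

#' Region boundaries used for piecewise evaluation
#'
#' Region I is used until its solution sits within `tol_I` of its
#' `tau -> Inf` limit; region III inside the corner window
#' `|eps*tau - (1/rho^2 - phi/rho)| <= 3*sqrt(eps)/rho` (three corner
#' widths); region II between; region IV after.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param tol_I Region I exhaustion tolerance (on the solution values).
#' @return Named list `tau_I`, `tau_III_lo`, `tau_III_hi`, `tau_sw`.
#' @export
region_boundaries <- function(groups, tol_I = 1e-6) {
  .check_asym(groups)
  rho <- groups$rho; eps <- groups$eps; phi <- groups$phi
  tau_sw <- switchover_tau(groups)
  half <- 3 / (rho * sqrt(eps))          # |tau - tau_sw| <= 3 sqrt(eps)/rho / eps
  # deviation from the region-I limit is max(1, rho) * beta0(tau); invert beta0
  if (phi == 0) {
    tau_I <- 0
  } else {
    target <- tol_I / max(1, rho)
    E <- target / (phi * (1 - rho * phi) + target * rho * phi)
    tau_I <- log(E) / (rho * phi - 1)
  }
  list(tau_I = tau_I,
       tau_III_lo = max(tau_sw - half, tau_I),
       tau_III_hi = tau_sw + half,
       tau_sw = tau_sw)
}

#' Piecewise composite asymptotic solution
#'
#' Evaluates the leading-order solution of whichever region each `tau`
#' falls in (see [region_boundaries()]). No additive uniform composite is
#' constructed: the approximation is presented piecewise, each region at
#' its own leading order, continuous to `O(sqrt(eps))` at the seams.
#'
#' @inheritParams asym_region1
#' @return A data frame with columns `tau`, `beta`, `gamma` and `region`
#'   (factor with levels I-IV).
#' @examples
#' g <- dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2)
#' head(asym_composite(c(0, 1, 50, 150, 250), g))
#' @export
asym_composite <- function(tau, groups) {
  .check_asym(groups)
  bnd <- region_boundaries(groups)
  region <- ifelse(tau <= min(bnd$tau_I, bnd$tau_III_lo), "I",
            ifelse(tau < bnd$tau_III_lo, "II",
            ifelse(tau <= bnd$tau_III_hi, "III", "IV")))
  out <- data.frame(tau = tau, beta = NA_real_, gamma = NA_real_,
                    region = factor(region, levels = c("I", "II", "III", "IV")))
  for (r in levels(out$region)) {
    i <- which(out$region == r)
    if (length(i) == 0L) next
    sol <- switch(r,
                  I = asym_region1(tau[i], groups),
                  II = asym_region2(tau[i], groups),
                  III = asym_region3(tau[i], groups),
                  IV = asym_region4(tau[i], groups, strict = FALSE))
    out$beta[i] <- sol$beta
    out$gamma[i] <- sol$gamma
  }
  out
}

#' Dimensionless switchover time
#'
#' The induction solution becomes non-uniform as
#' `tau -> (1 - rho*phi)/(rho^2*eps)`, equivalently
#' `eps^-1 (rho^-2 - rho^-1 phi)`: the dimensionless switchover time.
#'
#' @param groups A [dimensionless_groups()] object with `rho*phi < 1`.
#' @return The dimensionless switchover time (scalar).
#' @examples
#' switchover_tau(dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2)) # 150
#' @export
switchover_tau <- function(groups) {
  .check_asym(groups)
  if (groups$rho * groups$phi > 1)
    stop_validation("rho*phi > 1: no switchover (inhibitor outlasts substrate)")
  (1 - groups$rho * groups$phi) / (groups$rho^2 * groups$eps)
}

#' Dimensional switchover time in seconds
#'
#' The asymptotic induction-period length in dimensional variables:
#' \deqn{t_{sw} = \frac{c_0 - \phi m_0}{m_0^2 k_0}
#'             = \frac{[\mathrm{C_6H_8O_6}]_0 - [\mathrm{I_2}]_0}
#'                    {(2[\mathrm{I_2}]_0 + [\mathrm{I^-}]_0)^2 k_0}.}
#' Notably the fast rate constant `k1` drops out: only `k0` is identifiable
#' from switchover-time data.
#'
#' @param c0 Initial ascorbic-acid concentration, mol/l.
#' @param m0 Total iodine-atom concentration `a0 + 2*b0`, mol/l.
#' @param phi Initial iodine fraction `b0/m0` (dimensionless).
#' @param k0 Slow rate constant, M^-1 s^-1.
#' @return Switchover time in seconds.
#' @examples
#' switchover_seconds(c0 = 0.0032630, m0 = 0.0068718, phi = 0, k0 = 0.57)
#' @export
switchover_seconds <- function(c0, m0, phi, k0) {
  check_number(c0, "c0", lower = 0, strict = TRUE)
  check_number(m0, "m0", lower = 0, strict = TRUE)
  check_number(k0, "k0", lower = 0, strict = TRUE)
  check_number(phi, "phi")
  if (c0 <= phi * m0)
    stop_validation("c0 <= phi*m0: no induction period (inhibitor consumed ",
                    "already by the initial transient)")
  (c0 - phi * m0) / (m0^2 * k0)
}
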