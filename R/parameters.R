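#' Dimensional kinetic parameters for the clock reaction
#'
#' Bundles the two mass-action rate constants and the initial concentrations
#' of iodide (`a0`), molecular iodine (`b0`) and ascorbic acid (`c0`). The
#' total iodine-atom concentration `m0 = a0 + 2*b0` is conserved by the
#' reaction pair and is stored alongside.
#'
#' @param k0 Slow-reaction rate constant (iodide oxidation, `2A -> B`),
#'   in M^-1 s^-1.
#' @param k1 Fast-reaction rate constant (iodine inhibition by ascorbic acid,
#'   `B + C -> 2A`), in M^-1 s^-1. Must be positive.
#' @param a0,b0,c0 Initial concentrations of iodide, iodine and ascorbic
#'   acid, in mol/l. `c0` must be positive and `a0 + 2*b0` must be positive.
#'
#' @return An object of class `clock_params`: a list with fields `k0`, `k1`,
#'   `a0`, `b0`, `c0` and the derived `m0`.
#' @seealso [nondimensionalize()], [simulate_clock_dimensional()]
#' @examples
#' p <- kinetic_parameters(k0 = 0.57, k1 = 570, a0 = 0.006, b0 = 0, c0 = 0.003)
#' p$m0
#' @export
kinetic_parameters <- function(k0, k1, a0, b0, c0) {
  check_number(k0, "k0", lower = 0)
  check_number(k1, "k1", lower = 0, strict = TRUE)
  check_number(a0, "a0", lower = 0)
  check_number(b0, "b0", lower = 0)
  check_number(c0, "c0", lower = 0, strict = TRUE)
  m0 <- a0 + 2 * b0
  if (m0 <= 0)
    stop_validation("m0 = a0 + 2*b0 must be > 0: the model needs some iodine atoms")
  structure(list(k0 = k0, k1 = k1, a0 = a0, b0 = b0, c0 = c0, m0 = m0),
            class = "clock_params")
}

#' @export
print.clock_params <- function(x, ...) {
  cat("Clock reaction kinetic parameters\n")
  cat(sprintf("  k0 = %g M^-1 s^-1 (slow), k1 = %g M^-1 s^-1 (fast)\n", x$k0, x$k1))
  cat(sprintf("  a0 = %g, b0 = %g, c0 = %g mol/l  (m0 = a0 + 2 b0 = %g)\n",
              x$a0, x$b0, x$c0, x$m0))
  invisible(x)
}

#' Dimensionless groups of the clock reaction
#'
#' The reduced model depends on three dimensionless groups: the reactant
#' ratio `rho = m0/c0`, the slow/fast rate ratio `eps = k0/k1`, and the
#' initial iodine fraction `phi = b0/m0`. Time is measured in units of
#' `(k1*c0)^-1` seconds; the iodine variable `beta = b/m0` and the
#' ascorbic-acid variable `gamma = c/c0`.
#'
#' The asymptotic machinery additionally assumes `eps << 1` and
#' `rho*phi < 1` (the inhibitor must survive the initial transient); values
#' outside that regime are accepted with a warning so that plain numerical
#' simulation remains available.
#'
#' @param rho Reactant ratio `m0/c0` (> 0).
#' @param eps Rate ratio `k0/k1` (> 0).
#' @param phi Initial iodine fraction `b0/m0`, in `[0, 1/2]`.
#' @param time_scale Optional seconds per dimensionless time unit,
#'   `(k1*c0)^-1`; `NA` when working purely dimensionlessly.
#' @param conc_scale_b,conc_scale_c Optional concentration scales `m0` and
#'   `c0` in mol/l, for mapping back to dimensional units.
#'
#' @return An object of class `clock_groups`.
#' @seealso [nondimensionalize()], [dimensionalize()]
#' @examples
#' dimensionless_groups(rho = 2, eps = 1e-3, phi = 0.2)
#' @export
dimensionless_groups <- function(rho, eps, phi,
                                 time_scale = NA_real_,
                                 conc_scale_b = NA_real_,
                                 conc_scale_c = NA_real_) {
  check_number(rho, "rho", lower = 0, strict = TRUE)
  check_number(eps, "eps", lower = 0, strict = TRUE)
  check_number(phi, "phi", lower = 0)
  if (phi > 0.5)
    stop_validation("`phi` must lie in [0, 1/2]: b0 cannot exceed half of m0")
  if (eps > 0.1)
    warn_regime("eps = ", format(eps),
                " is not small; asymptotic formulas assume eps << 1")
  if (rho * phi >= 1)
    warn_regime("rho*phi = ", format(rho * phi), " >= 1: outside the ",
                "asymptotic regime (no induction period is guaranteed); ",
                "numerical simulation remains valid")
  structure(list(rho = rho, eps = eps, phi = phi,
                 time_scale = time_scale,
                 conc_scale_b = conc_scale_b,
                 conc_scale_c = conc_scale_c),
            class = "clock_groups")
}

#' @export
print.clock_groups <- function(x, ...) {
  cat("Clock reaction dimensionless groups\n")
  cat(sprintf("  rho = %g, eps = %g, phi = %g  (rho*phi = %g)\n",
              x$rho, x$eps, x$phi, x$rho * x$phi))
  if (!is.na(x$time_scale))
    cat(sprintf("  scales: %g s per tau unit, m0 = %g, c0 = %g mol/l\n",
                x$time_scale, x$conc_scale_b, x$conc_scale_c))
  invisible(x)
}

#' Nondimensionalize kinetic parameters
#'
#' Maps dimensional parameters to the groups `rho = m0/c0`, `eps = k0/k1`,
#' `phi = b0/m0`, carrying along the time scale `(k1*c0)^-1` and the
#' concentration scales `m0`, `c0` so that [dimensionalize()] is an exact
#' inverse.
#'
#' @param params A [kinetic_parameters()] object.
#' @return A [dimensionless_groups()] object with scales filled in.
#' @examples
#' p <- kinetic_parameters(k0 = 1, k1 = 1000, a0 = 0.6, b0 = 0.2, c0 = 0.5)
#' g <- nondimensionalize(p)   # rho = 2, eps = 1e-3, phi = 0.2
#' @export
nondimensionalize <- function(params) {
  if (!inherits(params, "clock_params"))
    stop_validation("`params` must be a clock_params object")
  if (params$c0 == 0) stop_validation("cannot nondimensionalize: c0 is zero")
  if (params$k1 == 0) stop_validation("cannot nondimensionalize: k1 is zero")
  dimensionless_groups(
    rho = params$m0 / params$c0,
    eps = params$k0 / params$k1,
    phi = params$b0 / params$m0,
    time_scale = 1 / (params$k1 * params$c0),
    conc_scale_b = params$m0,
    conc_scale_c = params$c0
  )
}

#' Recover dimensional parameters from dimensionless groups
#'
#' Inverts [nondimensionalize()]. Requires the scale fields to be present.
#'
#' @param groups A [dimensionless_groups()] object carrying `time_scale`,
#'   `conc_scale_b` and `conc_scale_c`.
#' @return A [kinetic_parameters()] object.
#' @export
dimensionalize <- function(groups) {
  if (!inherits(groups, "clock_groups"))
    stop_validation("`groups` must be a clock_groups object")
  if (anyNA(c(groups$time_scale, groups$conc_scale_b, groups$conc_scale_c)))
    stop_validation("groups carry no dimensional scales; build them with ",
                    "nondimensionalize() or supply the scale fields")
  c0 <- groups$conc_scale_c
  m0 <- groups$conc_scale_b
  k1 <- 1 / (groups$time_scale * c0)
  b0 <- groups$phi * m0
  kinetic_parameters(k0 = groups$eps * k1, k1 = k1,
                     a0 = m0 - 2 * b0, b0 = b0, c0 = c0)
}
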