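#' Design for a synthetic switchover-time experiment
#'
#' Describes a simulated bench campaign with the statistical structure of
#' the packaged table: a grid of `(c0, m0)` conditions, a fixed number of
#' repeats per condition, and multiplicative (log-normal) timing noise.
#' Defaults mirror the real campaign: its 9 unique conditions, 2 repeats,
#' `k0 = 0.57`, `phi = 0`, and a timing coefficient of variation of 0.08
#' (the scale of the observed repeat-pair spread).
#'
#' @param conditions Data frame with columns `c0`, `m0` (and optionally
#'   `condition_id`, `series`); default [table1_conditions()].
#' @param n_repeats Repeats per condition (>= 1).
#' @param true_k0 True slow rate constant, M^-1 s^-1.
#' @param true_phi True initial iodine fraction.
#' @param noise_cv Coefficient of variation of the timing noise (>= 0).
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return An object of class `clock_design`.
#' @export
synthetic_design <- function(conditions = table1_conditions(),
                             n_repeats = 2L, true_k0 = 0.57,
                             true_phi = 0, noise_cv = 0.08, seed = 1L) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0L ||
      !all(c("c0", "m0") %in% names(conditions)))
    stop_validation("`conditions` must be a non-empty data frame with c0, m0")
  check_number(n_repeats, "n_repeats", lower = 1)
  check_number(true_k0, "true_k0", lower = 0, strict = TRUE)
  check_number(true_phi, "true_phi")
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(seed, "seed")
  if (!"condition_id" %in% names(conditions))
    conditions$condition_id <- sprintf("c%02d", seq_len(nrow(conditions)))
  if (!"series" %in% names(conditions)) conditions$series <- NA_character_
  structure(list(conditions = conditions, n_repeats = as.integer(n_repeats),
                 true_k0 = true_k0, true_phi = true_phi,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "clock_design")
}

# evaluate f under a seed without disturbing the caller's RNG stream
.with_seed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  f()
}

#' Generate a synthetic switchover-time dataset
#'
#' Observed times are the closed-form predictions perturbed by
#' mean-preserving multiplicative log-normal noise:
#' `t_obs = t_sw * exp(sigma*Z - sigma^2/2)` with `sigma = noise_cv` and
#' `Z` standard normal. Identical seeds give identical datasets.
#'
#' @param design A [synthetic_design()].
#' @return A [switchover_dataset()] with one row per condition x repeat,
#'   plus a `t_true` column holding the noise-free times.
#' @examples
#' d <- synthetic_design(noise_cv = 0, seed = 7)
#' head(generate_switchover_dataset(d))   # noise-free: t_obs == t_true
#' @export
generate_switchover_dataset <- function(design) {
  if (!inherits(design, "clock_design"))
    stop_validation("`design` must come from synthetic_design()")
  cond <- design$conditions
  bad <- cond$c0 <= design$true_phi * cond$m0
  if (any(bad))
    stop_validation("no induction period (c0 <= phi*m0) for condition(s): ",
                    paste(cond$condition_id[bad], collapse = ", "))
  t_true <- predict_tsw(cond$c0, cond$m0, design$true_k0, design$true_phi)
  n <- nrow(cond) * design$n_repeats
  idx <- rep(seq_len(nrow(cond)), each = design$n_repeats)
  sigma <- design$noise_cv
  z <- .with_seed(design$seed, function() stats::rnorm(n))
  df <- data.frame(condition_id = cond$condition_id[idx],
                   series = cond$series[idx],
                   c0 = cond$c0[idx], m0 = cond$m0[idx],
                   repeat. = rep(seq_len(design$n_repeats), nrow(cond)),
                   t_true = t_true[idx],
                   t_obs = t_true[idx] * exp(sigma * z - sigma^2 / 2))
  # classed directly: a generated dataset may deliberately hold a single
  # condition (e.g. for calibration studies); fit_switchover() re-checks
  # identifiability on entry
  structure(df, class = c("switchover_data", "data.frame"))
}

#' Generate noisy trajectory observations
#'
#' Integrates the dimensionless system, samples it at `n_points` uniform
#' times on `[0, tau_max]`, and adds independent Gaussian noise to both
#' `beta` and `gamma`. Emulates a quantitative (e.g. absorbance-based)
#' read-out of the reaction course.
#'
#' @param groups A [dimensionless_groups()] object.
#' @param noise_sd Additive noise standard deviation (>= 0).
#' @param n_points Number of uniformly spaced samples.
#' @param seed Integer seed.
#' @param tau_max End of the observation window; defaults to twice the
#'   asymptotic switchover time.
#' @return A data frame with columns `tau`, `beta`, `gamma` (noisy) and
#'   `beta_true`, `gamma_true`.
#' @export
generate_trajectory_dataset <- function(groups, noise_sd, n_points = 200L,
                                        seed = 1L, tau_max = NULL) {
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(n_points, "n_points", lower = 2)
  if (is.null(tau_max)) tau_max <- 2 * switchover_tau(groups)
  traj <- simulate_clock(groups, tau_max = tau_max, n_out = as.integer(n_points))
  noise <- .with_seed(seed, function() stats::rnorm(2L * nrow(traj), sd = noise_sd))
  data.frame(tau = traj$tau,
             beta = traj$beta + noise[seq_len(nrow(traj))],
             gamma = traj$gamma + noise[nrow(traj) + seq_len(nrow(traj))],
             beta_true = traj$beta, gamma_true = traj$gamma)
}
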