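#' Predicted switchover time
#'
#' The closed-form induction-period length
#' `t_sw = (c0 - phi*m0) / (m0^2 * k0)` in seconds. Vectorized over the
#' concentration columns. Negative predictions (pathological `phi`) are
#' allowed: the optimizer must be free to roam.
#'
#' @param c0,m0 Initial concentrations, mol/l (`m0` counts iodine atoms).
#' @param k0 Slow rate constant, M^-1 s^-1 (> 0).
#' @param phi Initial iodine fraction (dimensionless).
#' @return Predicted switchover times, seconds.
#' @examples
#' predict_tsw(c0 = 0.003320, m0 = 0.0034962, k0 = 0.57, phi = 0)  # ~476 s
#' @export
predict_tsw <- function(c0, m0, k0, phi) {
  if (any(m0 <= 0) || k0 <= 0)
    stop_validation("`m0` and `k0` must be positive")
  (c0 - phi * m0) / (m0^2 * k0)
}

#' Assemble a switchover-time dataset
#'
#' @param df A data frame with columns `condition_id`, `c0`, `m0`, `t_obs`
#'   and optionally `series` (`"a"`/`"b"` tags). One row per timed repeat.
#' @return An object of class `switchover_data` (a data frame).
#' @export
switchover_dataset <- function(df) {
  need <- c("condition_id", "c0", "m0", "t_obs")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_validation("need a data frame with columns ",
                    paste(need, collapse = ", "))
  if (!"series" %in% names(df)) df$series <- NA_character_
  if (any(df$c0 <= 0) || any(df$m0 <= 0) || any(df$t_obs <= 0))
    stop_validation("c0, m0 and t_obs must all be positive")
  if (nrow(df) < 3L)
    stop_validation("need at least 3 records to fit two parameters")
  if (nrow(unique(df[, c("c0", "m0")])) < 2L)
    stop_validation("need at least 2 distinct (c0, m0) conditions; ",
                    "(k0, phi) are not identifiable from one condition")
  structure(as.data.frame(df), class = c("switchover_data", "data.frame"))
}

#' Read a switchover dataset from delimited text
#'
#' Expects a header line with `condition_id,c0,m0,t_obs` (and optionally
#' `series`), one row per timed repeat.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A [switchover_dataset()].
#' @export
read_switchover_dataset <- function(path, sep = ",") {
  switchover_dataset(utils::read.table(path, header = TRUE, sep = sep,
                                       stringsAsFactors = FALSE))
}

.table1_md5 <- "96fc8dcd850c2e256b9306d62b3bf672"

#' The packaged bench experiment table
#'
#' Twenty timed switchover observations (10 conditions x 2 repeats) from
#' kitchen-measure experiments: series "a" varies the vitamin C
#' concentration at fixed iodine, series "b" varies the iodine at fixed
#' vitamin C. Concentrations are the tabulated values (mol/l; `m0` counts
#' iodine atoms). One physical condition (60 ml dilution, 5 ml Lugol's)
#' appears in both series with identical repeat times; by default that
#' duplicate is dropped, leaving 9 unique conditions (18 records).
#'
#' @param dedup_shared Drop the series-"b" copy of the condition common to
#'   both series (default `TRUE`).
#' @return A [switchover_dataset()] with extra recipe columns
#'   (`vitc_dilution_ml`, `vitc_stock_conc`, `lugol_ml`, `repeat.`).
#' @export
load_table1 <- function(dedup_shared = TRUE) {
  path <- system.file("extdata", "table1_switchover.csv",
                      package = "vitcclock", mustWork = TRUE)
  if (!identical(unname(tools::md5sum(path)), .table1_md5))
    stop_validation("packaged experiment table fails its checksum: ",
                    "corrupted installation")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[names(df) == "repeat"] <- "repeat."
  if (dedup_shared)
    df <- df[df$condition_id != "b3", , drop = FALSE]
  switchover_dataset(df)
}

#' Unique experimental conditions of the packaged table
#'
#' @return A data frame with one row per distinct `(c0, m0)` condition
#'   (columns `condition_id`, `series`, `c0`, `m0`).
#' @export
table1_conditions <- function() {
  df <- as.data.frame(load_table1(dedup_shared = TRUE))
  unique(df[, c("condition_id", "series", "c0", "m0")])
}

#' Least-squares fit of (k0, phi) to switchover times
#'
#' Minimizes the unweighted sum of squared residuals (in seconds) of
#' `t_sw = (c0 - phi*m0)/(m0^2*k0)` over `(k0, phi)` with
#' Levenberg-Marquardt least squares, guarded by a multistart over
#' `k0 in {0.1, 0.5, 1, 5}` x `phi in {-0.1, 0, 0.1}` plus `init`.
#' `phi` is unconstrained (the best fit may be slightly negative); a
#' warning is emitted when the estimate leaves the physical range
#' `[0, 1/2]`.
#'
#' @param data A [switchover_dataset()].
#' @param init Starting values `c(k0, phi)`.
#' @param multistart Run the guard grid of extra starts (default `TRUE`).
#' @return An object of class `clock_fit`: list with `k0_hat`, `phi_hat`,
#'   `residuals`, `rss`, `converged`, `n_used`, plus diagnostics
#'   `gradient` (of the RSS at the optimum) and `multistart_spread`
#'   (relative spread of `k0` across starts that reached the best RSS).
#' @examples
#' fit <- fit_switchover(load_table1())
#' fit$k0_hat   # ~0.57 M^-1 s^-1
#' @export
fit_switchover <- function(data, init = c(k0 = 1, phi = 0.1),
                           multistart = TRUE) {
  if (!inherits(data, "switchover_data")) data <- switchover_dataset(data)
  if (nrow(unique(data[, c("c0", "m0")])) < 2L)
    stop_validation("(k0, phi) are not identifiable: fewer than 2 distinct conditions")

  resid_fun <- function(par)
    data$t_obs - predict_tsw(data$c0, data$m0, k0 = par[[1]], phi = par[[2]])

  # Gauss-Newton polish with the analytic Jacobian: the model is smooth and
  # near-linear around the optimum, so a few steps take the LM solution to
  # machine-precision stationarity
  polish <- function(par) {
    for (it in 1:100) {
      k0 <- par[[1]]; phi <- par[[2]]
      pred <- (data$c0 - phi * data$m0) / (data$m0^2 * k0)
      r <- data$t_obs - pred
      J <- cbind(-pred / k0, -1 / (data$m0 * k0))
      delta <- try(solve(crossprod(J), crossprod(J, r)), silent = TRUE)
      if (inherits(delta, "try-error")) break
      step <- 1
      while (k0 + step * delta[[1]] <= 0) step <- step / 2
      par <- c(k0 + step * delta[[1]], phi + step * delta[[2]])
      if (max(abs(step * delta) / pmax(abs(par), 1e-12)) < 1e-14) break
    }
    par
  }

  starts <- list(c(init[[1]], init[[2]]),
                 # method-of-moments start: per-record k0 at phi = 0
                 c(stats::median(data$c0 / (data$m0^2 * data$t_obs)), 0))
  if (multistart)
    starts <- c(starts, unlist(lapply(c(0.1, 0.5, 1, 5), function(k)
      lapply(c(-0.1, 0, 0.1), function(p) c(k, p))), recursive = FALSE))

  runs <- lapply(starts, function(s) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
      silent = TRUE)
    if (inherits(fit, "try-error") || fit$par[[1]] <= 0) NULL else fit
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L)
    stop_numerical("least-squares optimization failed from every start")

  pars <- lapply(runs, function(f) polish(f$par))
  rss <- vapply(pars, function(p) sum(resid_fun(p)^2), numeric(1))
  best <- pars[[which.min(rss)]]
  at_best <- rss <= min(rss) * (1 + 1e-8)
  k0s <- vapply(pars[at_best], function(p) p[[1]], numeric(1))
  spread <- (max(k0s) - min(k0s)) / max(abs(k0s))

  k0_hat <- best[[1]]; phi_hat <- best[[2]]
  info_best <- runs[[which.min(rss)]]$info
  if (phi_hat < -1e-8 || phi_hat > 0.5 + 1e-8)
    warn_regime("fitted phi = ", format(phi_hat),
                " lies outside the physical range [0, 1/2]")

  # gradient of the RSS via the model Jacobian at the optimum
  r <- resid_fun(c(k0_hat, phi_hat))
  dt_dk0 <- -(data$c0 - phi_hat * data$m0) / (data$m0^2 * k0_hat^2)
  dt_dphi <- -1 / (data$m0 * k0_hat)
  grad <- c(k0 = -2 * sum(r * dt_dk0), phi = -2 * sum(r * dt_dphi))

  structure(list(k0_hat = k0_hat, phi_hat = phi_hat,
                 residuals = r, rss = sum(r^2),
                 converged = info_best %in% 1:4,
                 n_used = nrow(data),
                 gradient = grad,
                 multistart_spread = spread),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("Switchover-time least-squares fit (", x$n_used, "records )\n")
  cat(sprintf("  k0 = %.4g M^-1 s^-1,  phi = %.3g\n", x$k0_hat, x$phi_hat))
  cat(sprintf("  RSS = %.6g s^2, converged: %s, multistart spread: %.2g\n",
              x$rss, x$converged, x$multistart_spread))
  invisible(x)
}
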