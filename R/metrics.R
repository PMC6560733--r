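#' Bias, standard deviation and standardized bias of log estimates
#'
#' Summarizes replicate-level log estimates against the true log effect:
#' `bias = mean(log estimates) - true_log`, the sample standard deviation
#' (n - 1 denominator), and the standardized bias `bias / sd`. Non-finite
#' replicates (non-estimable) are excluded.
#'
#' @param log_estimates Vector of replicate log estimates (may contain `NA`).
#' @param true_log True log weighted hazard ratio.
#' @return A list with `bias`, `sd`, `standardized_bias` and `n` (replicates
#'   used). `standardized_bias` is `NA` when the spread is zero.
#' @export
bias_and_sd <- function(log_estimates, true_log) {
  est <- log_estimates[is.finite(log_estimates)]
  if (length(est) < 2L) {
    stop("at least 2 estimable replicates are required", call. = FALSE)
  }
  bias <- mean(est) - true_log
  s <- stats::sd(est)
  list(bias = bias, sd = s,
       standardized_bias = if (s > 0) bias / s else NA_real_,
       n = length(est))
}

#' Root mean square error and relative efficiency of the two estimators
#'
#' The mean square error of a log estimator is `bias^2 + sd^2`; the relative
#' efficiency is `MSE(parametric) / MSE(nonparametric)`, so values above 1
#' favour the non-parametric estimator. Root-MSEs are reported.
#'
#' @param bias_parametric,sd_parametric Bias and SD of the parametric
#'   log estimator.
#' @param bias_nonparametric,sd_nonparametric Same for the non-parametric
#'   log estimator.
#' @return A list with `rmse_parametric`, `rmse_nonparametric` and
#'   `relative_efficiency` (`NA` when the non-parametric MSE is zero).
#' @export
rmse_relative_efficiency <- function(bias_parametric, sd_parametric,
                                     bias_nonparametric, sd_nonparametric) {
  mse_p <- bias_parametric^2 + sd_parametric^2
  mse_np <- bias_nonparametric^2 + sd_nonparametric^2
  list(rmse_parametric = sqrt(mse_p),
       rmse_nonparametric = sqrt(mse_np),
       relative_efficiency = if (mse_np > 0) mse_p / mse_np else NA_real_)
}

#' Confidence-interval coverage
#'
#' Percentage of replicates whose 95% normal-theory interval on the log
#' scale, `log_estimate +/- 1.959964 * se`, contains the true log effect.
#' Replicates with a missing estimate or standard error are excluded and
#' counted.
#'
#' @param log_estimates Replicate log estimates.
#' @param ses Matching permutation standard errors.
#' @param true_log True log weighted hazard ratio.
#' @return A list with `coverage` (percent, 0-100), `n` (replicates used)
#'   and `n_excluded`.
#' @export
ci_coverage <- function(log_estimates, ses, true_log) {
  if (length(log_estimates) != length(ses)) {
    stop("'log_estimates' and 'ses' must be paired", call. = FALSE)
  }
  ok <- is.finite(log_estimates) & is.finite(ses)
  if (!any(ok)) stop("no replicates with estimate and SE", call. = FALSE)
  hit <- abs(log_estimates[ok] - true_log) <= 1.959964 * ses[ok]
  list(coverage = 100 * mean(hit), n = sum(ok), n_excluded = sum(!ok))
}

#' Empirical power (or type-I error)
#'
#' Fraction of replicates in which the test rejected. Under a null scenario
#' this is the empirical type-I error. Missing flags (replicates where the
#' test could not be run) are excluded.
#'
#' @param rejections Logical vector of per-replicate rejection flags.
#' @return Proportion of rejections among non-missing replicates.
#' @export
empirical_power <- function(rejections) {
  if (length(rejections) == 0L) stop("no replicates", call. = FALSE)
  mean(rejections, na.rm = TRUE)
}
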