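#' Permutation test for the weighted all-cause hazard ratio
#'
#' Resampling test of the one-sided null \eqn{H_0: \theta^w_{CE} \ge 1}. The
#' test statistic is the observed log weighted-hazard-ratio estimate (either
#' estimator). The null distribution is rebuilt by reassigning the group
#' labels at random without replacement (group sizes preserved, times and
#' causes ride along) and recomputing the log estimate for each permutation.
#' The one-sided p-value uses the add-one convention
#' \eqn{p = (1 + \#\{\hat\theta_{perm} \le \hat\theta_{obs}\})/(B + 1)},
#' which keeps the test valid at any number of permutations. The standard
#' deviation of the permutation distribution also serves as a standard error
#' for the log estimate, giving the normal-theory interval
#' `observed +/- 1.959964 * se`.
#'
#' Permutations for which the estimate is non-estimable (zero weighted
#' cumulative hazard, non-converged Weibull fit) are dropped from the null
#' sample with a count; fewer than 10 estimable permutations refuse
#' inference. With `exact = TRUE` the Monte-Carlo sample is replaced by
#' complete enumeration of all label assignments (only feasible for small
#' samples) and the p-value is the exact proportion of assignments with a log
#' estimate at or below the observed one.
#'
#' @param data A [trial_dataset()].
#' @param weights Relevance weights, length `k`.
#' @param t Evaluation time of the estimator; defaults to `tau`.
#' @param method Estimator used for the statistic: `"nonparametric"` or
#'   `"parametric"`.
#' @param n_perm Number of Monte-Carlo permutations (ignored when
#'   `exact = TRUE`).
#' @param seed Optional integer seed for the permutation draws.
#' @param alpha One-sided significance level (default 0.025).
#' @param exact Enumerate all label assignments instead of sampling.
#' @return An object of class `whr_test` (and `whr_permutation`) with the
#'   observed log estimate as `statistic`, the permutation `p_value`,
#'   `reject` (`p_value <= alpha`), permutation `se`, normal-theory `ci_low`
#'   and `ci_high` on the log scale, the retained permutation sample
#'   `perm_log_estimates`, `n_perm` (estimable permutations) and `n_dropped`.
#' @export
permutation_test <- function(data, weights, t = NULL,
                             method = c("nonparametric", "parametric"),
                             n_perm = 1000, seed = NULL, alpha = 0.025,
                             exact = FALSE) {
  stopifnot(inherits(data, "trial_dataset"))
  method <- match.arg(method)
  .check_alpha(alpha)
  w <- weight_scheme(weights, data$k)
  if (is.null(t)) t <- data$tau
  rec <- data$records
  time <- rec$time
  cause <- rec$cause
  is_I <- rec$group == "I"
  n <- length(time)
  nI <- sum(is_I)
  if (nI == 0L || nI == n) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  est_fun <- switch(method,
    nonparametric = function(gI) .whr_np_log(time, cause, gI, w, t),
    parametric = function(gI) .whr_param_log(time, cause, gI, w, t))
  observed <- est_fun(is_I)
  if (is.na(observed)) {
    stop("observed estimate is non-estimable; permutation test undefined",
         call. = FALSE)
  }
  if (exact) {
    n_comb <- choose(n, nI)
    if (n_comb > 2e5) {
      stop("complete enumeration over ", n_comb, " assignments is not ",
           "feasible; use Monte-Carlo permutations", call. = FALSE)
    }
    assign_idx <- utils::combn(n, nI)
    perm <- apply(assign_idx, 2L, function(idx) {
      gI <- logical(n)
      gI[idx] <- TRUE
      est_fun(gI)
    })
  } else {
    if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
      stop("'n_perm' must be a positive integer", call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(n_perm), function(b) {
      gI <- logical(n)
      gI[sample.int(n, nI)] <- TRUE
      est_fun(gI)
    }, numeric(1))
  }
  n_dropped <- sum(is.na(perm))
  perm <- perm[!is.na(perm)]
  if (length(perm) < (if (exact) 2L else 10L)) {
    stop("permutation inference refused: too few estimable permutations",
         call. = FALSE)
  }
  p <- if (exact) {
    mean(perm <= observed)
  } else {
    (1 + sum(perm <= observed)) / (length(perm) + 1)
  }
  se <- stats::sd(perm)
  z975 <- 1.959964
  structure(list(statistic = observed,
                 p_value = p,
                 alpha = alpha,
                 reject = p <= alpha,
                 method = "permutation",
                 estimator = method,
                 eval_time = t,
                 n_perm = length(perm),
                 n_dropped = n_dropped,
                 exact = exact,
                 se = se,
                 ci_low = observed - z975 * se,
                 ci_high = observed + z975 * se,
                 perm_log_estimates = perm),
            class = c("whr_permutation", "whr_test"))
}
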