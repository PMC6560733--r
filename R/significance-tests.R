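#' Exact moments of the log-rank hypergeometric cell
#'
#' Expectation and variance of the number of events falling into group I when
#' `d` events are sampled without replacement at one event time from a risk
#' set of `nI + nC` subjects:
#' \eqn{E = n^I d / (n^I + n^C)} and
#' \eqn{Var = n^I n^C (n^I + n^C - d) d / ((n^I + n^C)^2 (n^I + n^C - 1))}.
#'
#' @param nI,nC At-risk counts in the two groups just before the event time.
#' @param d Number of events at that time (`0 <= d <= nI + nC`).
#' @return A list with vectors `expectation` and `variance`.
#' @export
hypergeometric_moments <- function(nI, nC, d) {
  if (any(nI < 0) || any(nC < 0)) {
    stop("at-risk counts must be non-negative", call. = FALSE)
  }
  n <- nI + nC
  if (any(n < 2)) {
    stop("risk set must contain at least 2 subjects (variance undefined)",
         call. = FALSE)
  }
  if (any(d < 0) || any(d > n)) {
    stop("'d' must lie in 0..(nI + nC)", call. = FALSE)
  }
  list(expectation = nI * d / n,
       variance = nI * nC * (n - d) * d / (n^2 * (n - 1)))
}

# Shared machinery: summed observed-minus-expected and variance terms for an
# event table; risk sets with fewer than 2 subjects carry no information and
# contribute zero.
.logrank_terms <- function(et, w = NULL) {
  n <- et$n_I + et$n_C
  ok <- n >= 2
  if (is.null(w)) {
    dI <- rowSums(et$d_I)
    d <- dI + rowSums(et$d_C)
    oe <- dI - et$n_I * d / n
    v <- et$n_I * et$n_C * (n - d) * d / (n^2 * (n - 1))
  } else {
    dpool <- et$d_I + et$d_C
    oe <- drop(et$d_I %*% w) - et$n_I / n * drop(dpool %*% w)
    v <- et$n_I * et$n_C *
      (n * drop(dpool %*% w^2) - drop(dpool^2 %*% w^2)) / (n^2 * (n - 1))
  }
  list(numerator = sum(oe[ok]), variance = sum(v[ok]))
}

.finish_logrank <- function(terms, alpha, method) {
  if (terms$variance <= 0) {
    stop("degenerate test: total log-rank variance is zero", call. = FALSE)
  }
  stat <- terms$numerator / sqrt(terms$variance)
  structure(list(statistic = stat,
                 p_value = stats::pnorm(stat),
                 alpha = alpha,
                 reject = stat <= -stats::qnorm(1 - alpha),
                 method = method),
            class = "whr_test")
}

#' Standard (one-sided) log-rank test
#'
#' The classical log-rank statistic for the composite endpoint,
#' \eqn{LR = \sum_l (d^I_l - n^I_l d_l / n_l) / \sqrt{\sum_l V_l}} with the
#' hypergeometric variances \eqn{V_l} of [hypergeometric_moments()]. The
#' statistic is asymptotically standard normal under equal all-cause hazards;
#' negative values favour the intervention and the one-sided null is rejected
#' when \eqn{LR \le -z_{1-\alpha}}.
#'
#' @param data A [trial_dataset()].
#' @param alpha One-sided significance level (default 0.025).
#' @return An object of class `whr_test` with `statistic`, `p_value`,
#'   `alpha`, `reject` and `method`.
#' @export
logrank_test <- function(data, alpha = 0.025) {
  stopifnot(inherits(data, "trial_dataset"))
  .check_alpha(alpha)
  et <- event_table(data)
  if (length(et$time) == 0L) {
    stop("no events observed; log-rank test undefined", call. = FALSE)
  }
  .finish_logrank(.logrank_terms(et), alpha, "logrank")
}

#' Weight-based log-rank test
#'
#' The modification of the log-rank test in which observed and expected event
#' counts are weighted per event *type* (not per time point): at each distinct
#' event time \eqn{t_l} the contribution is
#' \eqn{\sum_j w_j d^I_{EP_j,l} - \frac{n^I_l}{n_l} \sum_j w_j d_{EP_j,l}},
#' and the variance sums \eqn{w_j^2}-weighted hypergeometric variances,
#' \eqn{n^I_l n^C_l (n_l \sum_j w_j^2 d_{EP_j,l} - \sum_j w_j^2
#' d^2_{EP_j,l}) / (n_l^2 (n_l - 1))}. With all weights equal the statistic
#' reduces exactly to the standard log-rank statistic. The variance derivation
#' assumes that events of different types never tie at one time; with
#' continuous times this holds almost surely, and a tie in user data triggers
#' a warning while the formula is applied as stated.
#'
#' @inheritParams logrank_test
#' @param weights Relevance weights, length `k`.
#' @return An object of class `whr_test`; rejection at
#'   \eqn{LR^w \le -z_{1-\alpha}}.
#' @export
weight_based_logrank_test <- function(data, weights, alpha = 0.025) {
  stopifnot(inherits(data, "trial_dataset"))
  .check_alpha(alpha)
  w <- weight_scheme(weights, data$k)
  et <- event_table(data)
  if (length(et$time) == 0L) {
    stop("no events observed; weight-based log-rank test undefined",
         call. = FALSE)
  }
  if (data$k > 1L && any(rowSums((et$d_I + et$d_C) > 0L) > 1L)) {
    warning("events of different types tie at one event time; ",
            "the weight-based variance formula assumes no cross-type ties",
            call. = FALSE)
  }
  .finish_logrank(.logrank_terms(et, w), alpha, "weight_based_logrank")
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be a single value in (0, 1)", call. = FALSE)
  }
}

#' @export
print.whr_test <- function(x, ...) {
  lab <- switch(x$method,
                logrank = "standard log-rank test",
                weight_based_logrank = "weight-based log-rank test",
                permutation = "permutation test")
  cat(sprintf("<whr_test> %s (one-sided alpha = %g)\n", lab, x$alpha))
  cat(sprintf("  statistic: %.4f   p-value: %.4g   reject H0: %s\n",
              x$statistic, x$p_value, x$reject))
  if (!is.null(x$se)) {
    cat(sprintf("  permutation SE (log scale): %.4f   95%% CI: [%.4f, %.4f]\n",
                x$se, x$ci_low, x$ci_high))
    if (x$n_dropped > 0) {
      cat(sprintf("  (%d non-estimable permutations dropped)\n", x$n_dropped))
    }
  }
  invisible(x)
}
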