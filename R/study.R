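#' Run a Monte-Carlo simulation study
#'
#' Simulates `reps` trials from a scenario, applies both point estimators at
#' \eqn{t = \tau}, the standard and weight-based log-rank tests, and
#' (optionally) the label-permutation machinery that yields the permutation
#' test and per-replicate permutation standard errors for the confidence
#' intervals. Replicates where an estimator is non-estimable are kept in the
#' replicate table as `NA` and excluded (with counts) by the summaries.
#'
#' Reproducibility: the root `seed` deterministically spawns one child seed
#' per replicate, so any replicate can be regenerated independently, and the
#' same configuration with the same seed gives identical results. The same
#' permutation label draws are shared by both estimators within a replicate.
#'
#' @param scenario A [cause_hazard_set()] or a preset name from
#'   [list_scenarios()].
#' @param weights Relevance weights, length `k`.
#' @param tau End of the observational period (evaluation time of the
#'   estimators).
#' @param n_per_group Subjects per group (default 100).
#' @param reps Number of simulated trials (default 1000).
#' @param n_perm Permutations per replicate (default 1000).
#' @param seed Root seed.
#' @param alpha One-sided significance level (default 0.025).
#' @param permutation Which estimator(s) get the permutation machinery:
#'   `"parametric"` (the classical pairing; default), `"nonparametric"`,
#'   `"both"` or `"none"`. `"none"` skips permutations entirely (fast, but no
#'   permutation power or coverage).
#' @return An object of class `whr_study`: list with the per-replicate data
#'   frame `replicates`, the configuration, and `true_log_whr` (log of
#'   [true_whr()] at `tau`). Summarize with [study_table2()] and
#'   [study_table3()].
#' @examples
#' rep <- run_study("scenario_7", weights = c(1, 0.1), tau = 2,
#'                  reps = 20, n_perm = 50, seed = 1)
#' study_table2(rep)
#' @export
run_study <- function(scenario, weights, tau, n_per_group = 100, reps = 1000,
                      n_perm = 1000, seed = NULL, alpha = 0.025,
                      permutation = c("parametric", "nonparametric", "both",
                                      "none")) {
  label <- if (is.character(scenario)) scenario else "custom"
  set <- if (is.character(scenario)) scenario_hazards(scenario) else scenario
  stopifnot(inherits(set, "cause_hazard_set"))
  permutation <- match.arg(permutation)
  if (n_perm < 1) permutation <- "none"
  .check_alpha(alpha)
  w <- weight_scheme(weights, set$k)
  if (!is.numeric(reps) || length(reps) != 1L || reps < 1) {
    stop("'reps' must be a positive integer", call. = FALSE)
  }
  k <- set$k
  true_log <- log(true_whr(set, w, tau))
  do_np_perm <- permutation %in% c("nonparametric", "both")
  do_p_perm <- permutation %in% c("parametric", "both")

  if (!is.null(seed)) set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, reps)

  one_rep <- function(r) {
    set.seed(child[r])
    dat <- simulate_trial(set, n_per_group, tau)
    rec <- dat$records
    time <- rec$time
    cause <- rec$cause
    is_I <- rec$group == "I"
    n <- length(time)
    nI <- sum(is_I)

    ev_counts <- tabulate(cause[cause > 0L], nbins = k)
    np_log <- .whr_np_log(time, cause, is_I, w, tau)
    p_log <- .whr_param_log(time, cause, is_I, w, tau)

    wlr <- tryCatch(weight_based_logrank_test(dat, w, alpha),
                    error = function(e) NULL)
    lr <- tryCatch(logrank_test(dat, alpha), error = function(e) NULL)

    row <- c(ev_counts,
             np_log = np_log, param_log = p_log,
             wlr_stat = if (is.null(wlr)) NA_real_ else wlr$statistic,
             wlr_reject = if (is.null(wlr)) NA else as.numeric(wlr$reject),
             lr_reject = if (is.null(lr)) NA else as.numeric(lr$reject),
             np_perm_se = NA_real_, np_perm_p = NA_real_,
             param_perm_se = NA_real_, param_perm_p = NA_real_,
             np_perm_dropped = NA_real_, param_perm_dropped = NA_real_)

    if (permutation != "none") {
      np_null <- if (do_np_perm) rep(NA_real_, n_perm)
      p_null <- if (do_p_perm) rep(NA_real_, n_perm)
      for (b in seq_len(n_perm)) {
        gI <- logical(n)
        gI[sample.int(n, nI)] <- TRUE
        if (do_np_perm) np_null[b] <- .whr_np_log(time, cause, gI, w, tau)
        if (do_p_perm) p_null[b] <- .whr_param_log(time, cause, gI, w, tau)
      }
      finish <- function(null, obs) {
        kept <- null[!is.na(null)]
        if (length(kept) < 10L || is.na(obs)) {
          return(c(NA_real_, NA_real_, n_perm - length(kept)))
        }
        c(stats::sd(kept),
          (1 + sum(kept <= obs)) / (length(kept) + 1),
          n_perm - length(kept))
      }
      if (do_np_perm) {
        z <- finish(np_null, np_log)
        row["np_perm_se"] <- z[1]
        row["np_perm_p"] <- z[2]
        row["np_perm_dropped"] <- z[3]
      }
      if (do_p_perm) {
        z <- finish(p_null, p_log)
        row["param_perm_se"] <- z[1]
        row["param_perm_p"] <- z[2]
        row["param_perm_dropped"] <- z[3]
      }
    }
    row
  }

  mat <- t(vapply(seq_len(reps), one_rep, numeric(k + 11L)))
  df <- as.data.frame(mat)
  names(df)[seq_len(k)] <- paste0("events_EP", seq_len(k))
  df$rep <- seq_len(reps)

  structure(list(replicates = df,
                 scenario = label, hazards = set, weights = w, tau = tau,
                 n_per_group = n_per_group, reps = reps, n_perm = n_perm,
                 alpha = alpha, permutation = permutation,
                 true_log_whr = true_log, seed = seed),
            class = "whr_study")
}

#' @export
print.whr_study <- function(x, ...) {
  cat(sprintf(
    "<whr_study> %s: %d replicates of n = %d per group, tau = %g\n",
    x$scenario, x$reps, x$n_per_group, x$tau))
  cat("  weights:", paste(format(x$weights), collapse = ", "),
      "  ln true WHR:", sprintf("%.4f", x$true_log_whr), "\n")
  print(study_table2(x))
  invisible(x)
}

#' Effect-and-power summary of a simulation study
#'
#' One-row data frame in the layout of a simulation report: the true log
#' weighted hazard ratio, mean (SD) event counts per component, mean (SD) of
#' the two log estimators over estimable replicates, and the empirical
#' rejection rates of the permutation test (when run) and the weight-based
#' log-rank test.
#'
#' @param study A `whr_study` from [run_study()].
#' @return A one-row data frame.
#' @export
study_table2 <- function(study) {
  stopifnot(inherits(study, "whr_study"))
  df <- study$replicates
  k <- study$hazards$k
  out <- data.frame(scenario = study$scenario, tau = study$tau)
  for (j in seq_len(k)) out[[paste0("w_EP", j)]] <- study$weights[j]
  out$ln_true_whr <- study$true_log_whr
  for (j in seq_len(k)) {
    ev <- df[[paste0("events_EP", j)]]
    out[[paste0("mean_events_EP", j)]] <- mean(ev)
    out[[paste0("sd_events_EP", j)]] <- stats::sd(ev)
  }
  msd <- function(v) {
    v <- v[is.finite(v)]
    c(mean(v), stats::sd(v))
  }
  p <- msd(df$param_log)
  np <- msd(df$np_log)
  out$mean_ln_parametric <- p[1]
  out$sd_ln_parametric <- p[2]
  out$mean_ln_nonparametric <- np[1]
  out$sd_ln_nonparametric <- np[2]
  out$power_permutation <- if (study$permutation %in% c("parametric", "both")) {
    empirical_power(df$param_perm_p <= study$alpha)
  } else if (study$permutation == "nonparametric") {
    empirical_power(df$np_perm_p <= study$alpha)
  } else {
    NA_real_
  }
  out$power_weight_based <- empirical_power(df$wlr_reject > 0)
  out
}

#' Performance summary of a simulation study
#'
#' One-row data frame with, per estimator: the number of estimable
#' replicates, bias, standardized bias and root mean square error of the log
#' estimates, the relative efficiency (parametric MSE over non-parametric
#' MSE), and — when permutation standard errors were computed for that
#' estimator — the 95% confidence-interval coverage in percent.
#'
#' @inheritParams study_table2
#' @return A one-row data frame.
#' @export
study_table3 <- function(study) {
  stopifnot(inherits(study, "whr_study"))
  df <- study$replicates
  true_log <- study$true_log_whr
  bp <- bias_and_sd(df$param_log, true_log)
  bnp <- bias_and_sd(df$np_log, true_log)
  eff <- rmse_relative_efficiency(bp$bias, bp$sd, bnp$bias, bnp$sd)
  cov_of <- function(est, se) {
    if (all(!is.finite(se))) return(NA_real_)
    ci_coverage(est, se, true_log)$coverage
  }
  data.frame(scenario = study$scenario, tau = study$tau,
             n_parametric = bp$n, n_nonparametric = bnp$n,
             bias_parametric = bp$bias, bias_nonparametric = bnp$bias,
             std_bias_parametric = bp$standardized_bias,
             std_bias_nonparametric = bnp$standardized_bias,
             rmse_parametric = eff$rmse_parametric,
             rmse_nonparametric = eff$rmse_nonparametric,
             relative_efficiency = eff$relative_efficiency,
             coverage_parametric = cov_of(df$param_log, df$param_perm_se),
             coverage_nonparametric = cov_of(df$np_log, df$np_perm_se))
}
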