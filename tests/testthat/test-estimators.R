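test_that("Nelson-Aalen matches hand computation and brute force", {
  # 4 subjects: events cause 1 at t=1 (n=4) and t=4 (n=1), cause 2 at t=2,
  # censoring at t=3
  d <- td(c(1, 2, 3, 4), c(1, 2, 0, 1), rep("I", 4), k = 2, tau = 5)
  expect_equal(nelson_aalen(d, "I", 1, 4), 1.25)
  expect_equal(nelson_aalen(d, "I", 2, 4), 1 / 3)
  expect_equal(nelson_aalen(d, "I", 1, 0.5), 0)
  set.seed(9)
  for (i in 1:20) {
    dr <- random_dataset()
    for (g in c("I", "C")) {
      for (j in 1:2) {
        for (t in c(1, 2.5, 4)) {
          expect_equal(nelson_aalen(dr, g, j, t),
                       nelson_aalen_brute(dr, g, j, t))
        }
      }
    }
  }
})

test_that("per-cause estimates sum to the all-cause Nelson-Aalen", {
  set.seed(10)
  d <- simulate_trial("scenario_1", 40, tau = 1)
  et <- event_table(d)
  all_cause <- sum(rowSums(et$d_I) / et$n_I)
  expect_equal(nelson_aalen(d, "I", 1, 1) + nelson_aalen(d, "I", 2, 1),
               all_cause)
})

test_that("non-parametric estimator reduces, swaps and rescales correctly", {
  set.seed(11)
  d <- simulate_trial("scenario_2", 60, tau = 1)
  # unit weights: ratio of all-cause Nelson-Aalen estimates
  e1 <- estimate_whr(d, c(1, 1))
  na_ratio <- (nelson_aalen(d, "I", 1, 1) + nelson_aalen(d, "I", 2, 1)) /
    (nelson_aalen(d, "C", 1, 1) + nelson_aalen(d, "C", 2, 1))
  expect_equal(e1$value, na_ratio)
  # weight-scale invariance and group-swap reciprocity, both estimators
  for (m in c("nonparametric", "parametric")) {
    e <- estimate_whr(d, c(1, 0.1), method = m)
    expect_equal(estimate_whr(d, c(10, 1), method = m)$log_value, e$log_value)
    expect_equal(estimate_whr(swap_groups(d), c(1, 0.1), method = m)$log_value,
                 -e$log_value)
  }
})

test_that("zero weighted hazards give a non-estimable result", {
  d <- td(c(1, 2, 3), c(1, 0, 0), c("I", "C", "C"), k = 2, tau = 3)
  e <- estimate_whr(d, c(1, 1))
  expect_false(e$converged)
  expect_true(is.na(e$value))
  expect_match(e$reason, "zero")
})

test_that("Weibull MLE recovers parameters and the exponential closed form", {
  set.seed(12)
  n <- 20000
  t1 <- (-log(runif(n)) / 0.24)^(1 / 2)       # Weibull kappa 0.24, nu 2
  f <- fit_weibull_mle(t1, rep(1, n))
  expect_true(f$converged)
  expect_lt(abs(f$kappa - 0.24), 0.02)
  expect_lt(abs(f$nu - 2), 0.05)
  te <- -log(runif(n)) / 0.5                   # exponential, censored at 2
  tc <- pmin(te, 2)
  st <- te <= 2
  fe <- fit_weibull_mle(tc, st)
  expect_lt(abs(fe$nu - 1), 1e-2)
  # kappa tracks the exponential MLE up to the O(nu - 1) coupling
  expect_lt(abs(fe$kappa - sum(st) / sum(tc)), 5e-3)
})

test_that("Weibull fits refuse degenerate inputs", {
  expect_false(fit_weibull_mle(c(1, 2, 3), c(1, 0, 0))$converged)
  expect_false(fit_weibull_mle(rep(2, 5), rep(1, 5))$converged)
  expect_false(fit_weibull_ph(c(1, 2), c(1, 0), c("I", "C"))$converged)
})

test_that("likelihood fits agree with survreg on censored two-group data", {
  skip_if_not_installed("survival")
  set.seed(13)
  d <- simulate_trial("scenario_3", 80, tau = 2)
  rec <- d$records
  sel <- rec$group == "I"
  f <- fit_weibull_mle(rec$time[sel], rec$cause[sel] == 2)
  sr <- survival::survreg(
    survival::Surv(rec$time[sel], as.numeric(rec$cause[sel] == 2)) ~ 1,
    dist = "weibull")
  expect_equal(f$nu, 1 / sr$scale, tolerance = 1e-6)
  expect_equal(f$kappa, exp(-unname(coef(sr)[1]) / sr$scale),
               tolerance = 1e-6)
  fp <- fit_weibull_ph(rec$time, rec$cause == 1, rec$group)
  srp <- survival::survreg(
    survival::Surv(time, as.numeric(cause == 1)) ~ I(group == "I"),
    data = rec, dist = "weibull")
  expect_equal(fp$nu, 1 / srp$scale, tolerance = 1e-6)
  expect_equal(fp$kappa_C, exp(-unname(coef(srp)[1]) / srp$scale),
               tolerance = 1e-6)
  expect_equal(fp$beta, -unname(coef(srp)[2]) / srp$scale, tolerance = 1e-5)
})

test_that("parametric estimator plugs fitted hazards into the weighted ratio", {
  set.seed(14)
  d <- simulate_trial("scenario_7", 100, tau = 2)
  e <- estimate_whr(d, c(1, 0.1), method = "parametric")
  expect_true(e$converged)
  lam <- function(kap, nu, t) kap * nu * t^(nu - 1)
  comp <- e$components
  num <- sum(c(1, 0.1) * lam(comp$kappa_I, comp$nu, 2))
  den <- sum(c(1, 0.1) * lam(comp$kappa_C, comp$nu, 2))
  expect_equal(e$value, num / den)
  expect_equal(e$log_value, log(e$value))
})
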