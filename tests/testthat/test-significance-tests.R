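test_that("log-rank statistic matches a hand evaluation", {
  # I: event at t=2, censored at 3; C: event at t=1, censored at 3
  d <- td(c(2, 3, 1, 3), c(1, 0, 1, 0), c("I", "I", "C", "C"), k = 1, tau = 3)
  lt <- logrank_test(d)
  expect_equal(lt$statistic, (-0.5 + 1 / 3) / sqrt(0.25 + 2 / 9))
  expect_false(lt$reject)
  # mirror-image groups: statistic 0
  d0 <- td(c(1, 2, 1, 2), c(1, 0, 1, 0), c("I", "I", "C", "C"), k = 1,
           tau = 2)
  expect_equal(logrank_test(d0)$statistic, 0)
  # single event in I with equal risk sets: numerator +1/2, no rejection
  d1 <- td(c(1, 2, 2), c(1, 0, 0), c("I", "C", "C"), k = 1, tau = 2)
  expect_gt(logrank_test(d1)$statistic, 0)
  expect_false(logrank_test(d1, alpha = 0.2)$reject)
})

test_that("log-rank agrees with survdiff", {
  skip_if_not_installed("survival")
  set.seed(15)
  d <- simulate_trial("scenario_1", 60, tau = 1)
  rec <- d$records
  sd_fit <- survival::survdiff(
    survival::Surv(time, as.numeric(cause > 0)) ~ group, data = rec)
  expect_equal(logrank_test(d)$statistic^2, unname(sd_fit$chisq),
               tolerance = 1e-10)
})

test_that("hypergeometric moments match exhaustive enumeration", {
  expect_equal(hypergeometric_moments(2, 2, 1),
               list(expectation = 0.5, variance = 0.25))
  for (nI in 1:11) {
    for (nC in seq_len(12 - nI)) {
      for (d in 0:(nI + nC)) {
        got <- hypergeometric_moments(nI, nC, d)
        want <- hyper_moments_enum(nI, nC, d)
        expect_equal(got$expectation, want$expectation)
        expect_equal(got$variance, want$variance)
      }
    }
  }
  expect_equal(hypergeometric_moments(3, 4, 0)$variance, 0)
  expect_equal(hypergeometric_moments(3, 4, 7),
               list(expectation = 3, variance = 0))
  expect_error(hypergeometric_moments(1, 0, 1), "at least 2")
})

test_that("unit weights reduce the weight-based test to the log-rank test", {
  set.seed(16)
  for (i in 1:5) {
    d <- simulate_trial("scenario_2", 50, tau = 1)
    expect_identical(weight_based_logrank_test(d, c(1, 1))$statistic,
                     logrank_test(d)$statistic)
  }
})

test_that("weight-based statistic is weight-scale invariant", {
  set.seed(17)
  d <- simulate_trial("scenario_1", 50, tau = 1)
  s <- weight_based_logrank_test(d, c(1, 0.1))$statistic
  expect_equal(weight_based_logrank_test(d, c(5, 0.5))$statistic, s)
  expect_equal(weight_based_logrank_test(d, c(0.002, 2e-4))$statistic, s)
})

test_that("group swap negates both log-rank statistics exactly", {
  set.seed(18)
  for (i in 1:5) {
    d <- simulate_trial("scenario_4", 40, tau = 1)
    ds <- swap_groups(d)
    expect_equal(logrank_test(ds)$statistic, -logrank_test(d)$statistic)
    expect_equal(weight_based_logrank_test(ds, c(1, 0.1))$statistic,
                 -weight_based_logrank_test(d, c(1, 0.1))$statistic)
  }
})

test_that("cross-type ties warn and degenerate data error", {
  d <- td(c(1, 1, 2, 2), c(1, 2, 1, 0), c("I", "C", "C", "I"), k = 2, tau = 2)
  expect_warning(weight_based_logrank_test(d, c(1, 0.5)), "tie")
  dc <- td(c(1, 2), c(0, 0), c("I", "C"), k = 1, tau = 2)
  expect_error(logrank_test(dc), "no events")
  # every risk set exhausted by events: zero total variance
  d2 <- td(c(1, 1), c(1, 1), c("I", "C"), k = 1, tau = 2)
  expect_error(logrank_test(d2), "degenerate")
})

test_that("weight-based statistic is calibrated under an exchangeable null", {
  # identical generators in both groups; the statistic should be close to
  # standard normal
  set.seed(19)
  s <- replicate(300, {
    d <- simulate_trial("scenario_6", 60, tau = 2)
    weight_based_logrank_test(d, c(1, 0.1))$statistic
  })
  expect_lt(abs(mean(s)), 3 / sqrt(300))
  expect_lt(abs(sd(s) - 1), 0.15)
})
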