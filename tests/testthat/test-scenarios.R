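test_that("the registry holds the ten presets with their printed hazards", {
  reg <- list_scenarios()
  expect_equal(nrow(reg), 10L)
  expect_equal(reg$name, paste0("scenario_", 1:10))
  # spot-check hazard functions against the tabulated forms
  s1 <- scenario_hazards("scenario_1")
  expect_equal(hazard_value(s1$control[[2]], 1), 0.8)       # 0.8 t
  expect_equal(hazard_value(s1$intervention[[1]], 5), 0.24) # constant
  s2 <- scenario_hazards("scenario_2")
  expect_equal(hazard_value(s2$intervention[[1]], 2), 0.192 * 2^-0.2)
  expect_equal(hazard_value(s2$control[[2]], 0.5), 0.32 * 0.5^-0.2)
  s8 <- scenario_hazards("scenario_8")
  expect_equal(hazard_value(s8$intervention[[1]], 1), 0.42 * exp(0.7) - 0.42)
  expect_equal(hazard_value(s8$control[[2]], 0), 0)
  s10 <- scenario_hazards("scenario_10")
  expect_equal(hazard_value(s10$intervention[[2]], 1), 0.21 * exp(0.8))
  expect_true(attr(scenario_hazards("scenario_7"), "equal_baseline"))
  expect_false(attr(s1, "equal_baseline"))
  expect_error(scenario_hazards("scenario_99"), "unknown scenario")
})

test_that("true effects of the registry match the tabulated log ratios", {
  ln_whr <- function(nm, w, tau) log(true_whr(scenario_hazards(nm), w, tau))
  expect_equal(round(ln_whr("scenario_1", c(1, 0.1), 1), 2), -0.60)
  expect_equal(round(ln_whr("scenario_2", c(1, 0.1), 1), 2), -0.44)
  expect_equal(round(ln_whr("scenario_9", c(1, 0.1), 2), 2), -0.51)
  expect_equal(round(ln_whr("scenario_10", c(0.1, 1), 1), 2), -0.95)
  expect_identical(ln_whr("scenario_7", c(1, 0.1), 2), 0)
})

test_that("inversion sampling uses the closed-form inverse", {
  # scenario 1 control, component 1: Lambda(t) = 0.4 t, so -ln U = 0.2
  # maps to t = 0.5
  m <- scenario_hazards("scenario_1")$control[[1]]
  expect_equal(inverse_cumulative_hazard(m, 0.2), 0.5)
})

test_that("simulated trials respect censoring and determinism contracts", {
  d <- simulate_trial("scenario_1", 50, tau = 0, seed = 1)
  expect_true(all(d$records$time == 0))
  expect_true(all(d$records$cause == 0L))
  d1 <- simulate_trial("scenario_8", 30, tau = 2, seed = 99)
  d2 <- simulate_trial("scenario_8", 30, tau = 2, seed = 99)
  expect_identical(d1$records, d2$records)
  expect_true(all(d1$records$time <= 2))
  expect_equal(sum(d1$records$cause == 0), 60 - sum(d1$records$cause > 0))
})

test_that("all-cause event fraction matches the composite survival function", {
  set.seed(24)
  n <- 20000
  d <- simulate_trial("scenario_1", n, tau = 1)
  s1 <- scenario_hazards("scenario_1")
  for (g in c("I", "C")) {
    models <- if (g == "I") s1$intervention else s1$control
    p_event <- 1 - exp(-sum(vapply(models, cumulative_hazard, numeric(1), 1)))
    rec <- d$records[d$records$group == g, ]
    frac <- mean(rec$cause > 0)
    se <- sqrt(p_event * (1 - p_event) / n)
    expect_lt(abs(frac - p_event), 3 * se)
  }
})

test_that("run_study aggregates replicates reproducibly", {
  rep1 <- run_study("scenario_7", c(1, 0.1), tau = 2, n_per_group = 40,
                    reps = 8, n_perm = 40, seed = 3,
                    permutation = "both")
  rep2 <- run_study("scenario_7", c(1, 0.1), tau = 2, n_per_group = 40,
                    reps = 8, n_perm = 40, seed = 3,
                    permutation = "both")
  expect_identical(rep1$replicates, rep2$replicates)
  expect_equal(rep1$true_log_whr, 0)
  t2 <- study_table2(rep1)
  expect_equal(t2$ln_true_whr, 0)
  expect_true(t2$power_weight_based >= 0 && t2$power_weight_based <= 1)
  t3 <- study_table3(rep1)
  expect_equal(t3$rmse_nonparametric^2,
               t3$bias_nonparametric^2 +
                 (t3$bias_nonparametric / t3$std_bias_nonparametric)^2,
               tolerance = 1e-10)
  expect_true(is.finite(t3$coverage_nonparametric))
  # different seeds give different replicates
  rep3 <- run_study("scenario_7", c(1, 0.1), tau = 2, n_per_group = 40,
                    reps = 8, n_perm = 0, seed = 4, permutation = "none")
  expect_false(identical(rep1$replicates$np_log, rep3$replicates$np_log))
})
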