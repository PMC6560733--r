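test_that("severity equivalences map to relevance weights", {
  expect_equal(severity_to_weights(m = 5, r = 1), c(1, 0.2))
  expect_equal(severity_to_weights(m = 5, r = 3), c(1, 0.6))
  expect_equal(severity_to_weights(m = 1, r = 1), c(1, 1))
  # scale consistency: (m, r) and (cm, cr) give the same weights
  expect_equal(severity_to_weights(m = 10, r = 2), severity_to_weights(5, 1))
  # reference position and several components
  expect_equal(severity_to_weights(m = c(2, 4), r = c(1, 1), reference = 2),
               c(0.5, 1, 0.25))
  expect_warning(w <- severity_to_weights(m = 2, r = 3), "above 1")
  expect_equal(w, c(1, 1.5))
  expect_error(severity_to_weights(m = 0.5, r = 1), "m >= 1")
})

test_that("modified hazards scale the family parameters", {
  expect_equal(hazard_value(modified_hazard(hazard_model("constant", 0.2), 1.3), 1),
               0.26)
  expect_equal(hazard_value(modified_hazard(hazard_model("constant", 0.3), 0.6), 1),
               0.18)
  m <- hazard_model("gompertz_makeham", 0.42, 0.7, -0.42)
  mm <- modified_hazard(m, 0.5)
  ts <- c(0.2, 1, 2)
  expect_equal(hazard_value(mm, ts), 0.5 * hazard_value(m, ts))
  expect_equal(cumulative_hazard(mm, ts), 0.5 * cumulative_hazard(m, ts))
  # weight 1 is the identity
  expect_equal(modified_hazard(m, 1), m)
  # weight 0 gives a flat hazard that is not invertible
  z <- modified_hazard(hazard_model("constant", 0.2), 0)
  expect_equal(hazard_value(z, c(0, 1)), c(0, 0))
  expect_error(inverse_cumulative_hazard(z, 1), "not invertible")
})

test_that("curve tables reproduce the weighting-scheme ordering", {
  set <- const_set()
  grid <- seq(0, 3, by = 0.25)
  cur <- weight_scheme_curves(set, list(A = c(1, 0.6), B = c(1, 0.2)), grid)
  expect_setequal(unique(cur$scheme), c("unweighted", "A", "B"))
  expect_equal(nrow(cur), 3 * 2 * length(grid))
  # all curves start at 1
  expect_true(all(cur$survival[cur$time == 0] == 1))
  # down-weighting flattens: B above A above unweighted for all t > 0
  wide <- reshape(cur[cur$group == "C", ], idvar = "time",
                  timevar = "scheme", direction = "wide")
  pos <- wide$time > 0
  expect_true(all(wide$survival.B[pos] > wide$survival.A[pos]))
  expect_true(all(wide$survival.A[pos] > wide$survival.unweighted[pos]))
  # all-ones scheme coincides with the unweighted curve
  cur2 <- weight_scheme_curves(set, list(ones = c(1, 1)), grid)
  expect_equal(cur2$survival[cur2$scheme == "ones"],
               cur2$survival[cur2$scheme == "unweighted"])
})

test_that("weighted survival is monotone non-increasing in each weight", {
  set <- const_set()
  t <- 1.5
  for (j in 1:2) {
    w_lo <- c(1, 1)
    w_hi <- c(1, 1)
    w_lo[j] <- 0.3
    w_hi[j] <- 1.7
    expect_gt(weighted_survival(set, "I", w_lo, t),
              weighted_survival(set, "I", c(1, 1), t))
    expect_lt(weighted_survival(set, "I", w_hi, t),
              weighted_survival(set, "I", c(1, 1), t))
  }
})
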