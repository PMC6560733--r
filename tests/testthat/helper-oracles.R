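# Shared fixtures and independent brute-force oracles used across the suite.

# Quick dataset constructor.
td <- function(time, cause, group, k = max(1L, max(cause)), tau = max(time)) {
  trial_dataset(data.frame(time = time, cause = cause, group = group),
                k = k, tau = tau)
}

# Two constant-hazard components (0.2, 0.3) in both groups: the worked
# example of the weighting guidance.
const_set <- function() {
  cause_hazard_set(
    intervention = list(hazard_model("constant", 0.2),
                        hazard_model("constant", 0.3)),
    control = list(hazard_model("constant", 0.2),
                   hazard_model("constant", 0.3)))
}

# Brute-force Nelson-Aalen: double loop over subjects and distinct event
# times, risk sets recounted from scratch.
nelson_aalen_brute <- function(data, group, cause, t) {
  rec <- data$records[data$records$group == group, , drop = FALSE]
  ev_times <- sort(unique(data$records$time[data$records$cause > 0L]))
  total <- 0
  for (tl in ev_times[ev_times <= t]) {
    at_risk <- sum(rec$time >= tl)
    d <- sum(rec$time == tl & rec$cause == cause)
    if (d > 0) total <- total + d / at_risk
  }
  total
}

# Exact hypergeometric moments by enumeration over all possible counts in
# group I, with exact probability weights from choose().
hyper_moments_enum <- function(nI, nC, d) {
  x <- max(0, d - nC):min(nI, d)
  p <- choose(nI, x) * choose(nC, d - x) / choose(nI + nC, d)
  e <- sum(x * p)
  list(expectation = e, variance = sum((x - e)^2 * p))
}

# Random small competing-risks dataset (both groups, k causes).
random_dataset <- function(n = 12, k = 2, tau = 4) {
  time <- round(stats::runif(n, 0, tau + 1), 1)
  cause <- sample(0:k, n, replace = TRUE)
  group <- sample(c("I", "C"), n, replace = TRUE)
  group[1] <- "I"
  group[2] <- "C"
  td(time, cause, group, k = k, tau = tau)
}

# Swap the group labels of a dataset.
swap_groups <- function(data) {
  rec <- data$records
  rec$group <- ifelse(rec$group == "I", "C", "I")
  trial_dataset(rec, k = data$k, tau = data$tau)
}
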