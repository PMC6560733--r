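# One group's worth of subjects: independent latent times per component via
# inversion (T_j = Lambda_j^{-1}(-ln U_j)), observed outcome = component-wise
# minimum, administratively censored at tau.
.sim_group <- function(models, n, tau) {
  k <- length(models)
  U <- matrix(stats::runif(n * k), nrow = n, ncol = k)
  lat <- vapply(seq_len(k), function(j) {
    inverse_cumulative_hazard(models[[j]], -log(U[, j]))
  }, numeric(n))
  lat <- matrix(lat, nrow = n, ncol = k)
  cause <- max.col(-lat, ties.method = "first")
  tmin <- lat[cbind(seq_len(n), cause)]
  cens <- tmin > tau
  data.frame(time = ifelse(cens, tau, tmin),
             cause = ifelse(cens, 0L, cause))
}

#' Simulate one subject from cause-specific hazards
#'
#' Draws one latent event time per component by inversion sampling
#' (\eqn{T_j = \Lambda_j^{-1}(-\ln U_j)} with independent standard uniforms);
#' the observed outcome is the earliest latent time and its component, or an
#' administrative censoring at `tau` if no latent event occurs within the
#' observational period.
#'
#' @param models List of [hazard_model()] objects, one per component.
#' @param tau End of the observational period.
#' @return A list with `time` and `cause` (`0` = censored).
#' @export
simulate_subject <- function(models, tau) {
  stopifnot(is.list(models), length(models) >= 1L)
  row <- .sim_group(models, 1L, tau)
  list(time = row$time[1L], cause = as.integer(row$cause[1L]))
}

#' Simulate a two-group competing-risks trial
#'
#' Generates `n_per_group` subjects per group from the group-specific
#' cause-specific hazards of a [cause_hazard_set()] (or a named preset from
#' [list_scenarios()]), using latent-time inversion sampling with
#' administrative censoring at `tau`. The intervention group is drawn first,
#' then the control group, so a fixed seed reproduces the dataset exactly.
#'
#' @param hazards A `cause_hazard_set` or a scenario name.
#' @param n_per_group Subjects per group (default 100).
#' @param tau End of the observational period.
#' @param seed Optional integer seed.
#' @return A [trial_dataset()].
#' @examples
#' d <- simulate_trial("scenario_7", n_per_group = 50, tau = 2, seed = 1)
#' @export
simulate_trial <- function(hazards, n_per_group = 100, tau, seed = NULL) {
  if (is.character(hazards)) hazards <- scenario_hazards(hazards)
  stopifnot(inherits(hazards, "cause_hazard_set"))
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 1) {
    stop("'n_per_group' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  gI <- .sim_group(hazards$intervention, n_per_group, tau)
  gC <- .sim_group(hazards$control, n_per_group, tau)
  df <- rbind(cbind(gI, group = "I", stringsAsFactors = FALSE),
              cbind(gC, group = "C", stringsAsFactors = FALSE))
  trial_dataset(df, k = hazards$k, tau = tau)
}
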