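#' Cause-specific hazard sets for a two-group trial
#'
#' Bundles the cause-specific hazard models \eqn{\lambda^g_{EP_j}(t)} for the
#' intervention group (`I`) and the control group (`C`) of a two-arm trial
#' with a composite endpoint of `k` components. Both groups must define the
#' same components in the same order.
#'
#' @param intervention,control Lists of [hazard_model()] objects, one per
#'   endpoint component, in matching order.
#' @return An object of class `cause_hazard_set` with elements
#'   `intervention`, `control` and `k`.
#' @examples
#' set <- cause_hazard_set(
#'   intervention = list(hazard_model("constant", 0.05),
#'                       hazard_model("constant", 1)),
#'   control      = list(hazard_model("constant", 0.1),
#'                       hazard_model("constant", 0.5)))
#' @export
cause_hazard_set <- function(intervention, control) {
  if (!is.list(intervention) || !is.list(control)) {
    stop("'intervention' and 'control' must be lists of hazard models",
         call. = FALSE)
  }
  if (length(intervention) != length(control) || length(intervention) == 0L) {
    stop("both groups must define the same (positive) number of components",
         call. = FALSE)
  }
  ok <- vapply(c(intervention, control), inherits, logical(1), "hazard_model")
  if (!all(ok)) {
    stop("all components must be 'hazard_model' objects", call. = FALSE)
  }
  structure(list(intervention = intervention, control = control,
                 k = length(intervention)),
            class = "cause_hazard_set")
}

#' @export
print.cause_hazard_set <- function(x, ...) {
  cat(sprintf("<cause_hazard_set> %d components x 2 groups\n", x$k))
  for (g in c("intervention", "control")) {
    cat(" ", g, ":\n", sep = "")
    for (j in seq_len(x$k)) {
      cat("   EP", j, " ", sep = "")
      print(x[[g]][[j]])
    }
  }
  invisible(x)
}

.group_models <- function(set, group) {
  group <- match.arg(group, c("I", "C"))
  set[[if (group == "I") "intervention" else "control"]]
}

#' Component relevance weights
#'
#' Validates a vector of non-negative relevance weights \eqn{w_{EP_j}}, one
#' per endpoint component, with at least one strictly positive entry. Weights
#' enter all weighted quantities multiplicatively, so rescaling every weight
#' by the same positive constant leaves every hazard *ratio* unchanged.
#'
#' @param w Numeric vector of weights.
#' @param k Optional expected number of components.
#' @return The validated numeric weight vector.
#' @export
weight_scheme <- function(w, k = NULL) {
  if (!is.numeric(w) || length(w) == 0L || any(!is.finite(w))) {
    stop("weights must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (all(w == 0)) stop("at least one weight must be positive", call. = FALSE)
  if (!is.null(k) && length(w) != k) {
    stop(sprintf("expected %d weights (one per component), got %d",
                 k, length(w)), call. = FALSE)
  }
  unname(as.numeric(w))
}

#' Weighted all-cause hazard
#'
#' The weighted all-cause hazard of the composite endpoint,
#' \eqn{\lambda^w_{CE}(t) = \sum_j w_{EP_j} \lambda_{EP_j}(t)}. With all
#' weights equal to 1 this is the ordinary all-cause hazard, the sum of the
#' cause-specific hazards.
#'
#' @param set A [cause_hazard_set()].
#' @param group `"I"` (intervention) or `"C"` (control).
#' @param weights Relevance weights, see [weight_scheme()].
#' @param t Vector of evaluation times.
#' @return Weighted all-cause hazard rate(s) at `t`.
#' @examples
#' set <- cause_hazard_set(
#'   intervention = list(hazard_model("constant", 0.2),
#'                       hazard_model("constant", 0.3)),
#'   control      = list(hazard_model("constant", 0.2),
#'                       hazard_model("constant", 0.3)))
#' weighted_all_cause_hazard(set, "C", c(1, 0.6), 1)    # 0.38
#' weighted_all_cause_hazard(set, "C", c(1.3, 0.8), 1)  # 0.5
#' @export
weighted_all_cause_hazard <- function(set, group, weights, t) {
  stopifnot(inherits(set, "cause_hazard_set"))
  w <- weight_scheme(weights, set$k)
  models <- .group_models(set, group)
  out <- 0
  for (j in seq_len(set$k)) out <- out + w[j] * hazard_value(models[[j]], t)
  out
}

#' True weighted all-cause hazard ratio
#'
#' The weighted all-cause hazard ratio
#' \eqn{\theta^w_{CE}(t) = \lambda^{I,w}_{CE}(t) / \lambda^{C,w}_{CE}(t)}
#' implied by a set of cause-specific hazard functions. It is time-dependent
#' unless all components share one baseline hazard shape. Evaluated at the end
#' of follow-up \eqn{t = \tau} this is the "true" effect a simulation scenario
#' encodes.
#'
#' @inheritParams weighted_all_cause_hazard
#' @return Positive ratio(s) \eqn{\theta^w_{CE}(t)}.
#' @export
true_whr <- function(set, weights, t) {
  num <- weighted_all_cause_hazard(set, "I", weights, t)
  den <- weighted_all_cause_hazard(set, "C", weights, t)
  if (any(den <= 0)) {
    stop("weighted control hazard is zero; ratio undefined", call. = FALSE)
  }
  num / den
}

#' Integrated weighted all-cause hazard ratio
#'
#' The time-average \eqn{\Theta^w_{CE}(\tau) =
#' \frac{1}{\tau}\int_0^\tau \theta^w_{CE}(t)\,dt} of the weighted hazard
#' ratio over the observational period. When the ratio is constant in time
#' (shared baseline shape) this equals the pointwise value.
#'
#' @inheritParams weighted_all_cause_hazard
#' @param tau End of the observational period (> 0).
#' @return The integrated ratio \eqn{\Theta^w_{CE}(\tau)}.
#' @export
integrated_whr <- function(set, weights, tau) {
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau > 0)
  val <- tryCatch(
    stats::integrate(function(t) true_whr(set, weights, t), 0, tau,
                     rel.tol = 1e-9, subdivisions = 1000L)$value,
    error = function(e) {
      stop("integration of the weighted hazard ratio over [0, ", tau,
           "] failed: ", conditionMessage(e), call. = FALSE)
    })
  val / tau
}

#' Weighted composite survival function
#'
#' The event-time distribution implied by the weighted all-cause hazard,
#' \eqn{S^w_{CE}(t) = \exp(-\sum_j w_{EP_j} \Lambda_{EP_j}(t))
#' = \prod_j \exp(-w_{EP_j}\Lambda_{EP_j}(t))}. Weights below 1 flatten the
#' curve (fewer weighted events), weights above 1 steepen it.
#'
#' @inheritParams weighted_all_cause_hazard
#' @return Survival probabilities in (0, 1].
#' @export
weighted_survival <- function(set, group, weights, t) {
  stopifnot(inherits(set, "cause_hazard_set"))
  w <- weight_scheme(weights, set$k)
  models <- .group_models(set, group)
  cum <- 0
  for (j in seq_len(set$k)) {
    cum <- cum + w[j] * cumulative_hazard(models[[j]], t)
  }
  exp(-cum)
}
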