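#' Derive relevance weights from severity equivalences
#'
#' Implements the planning-stage recipe for choosing component weights: the
#' clinically most relevant event type (the reference, e.g. death) gets
#' weight 1; for every other component \eqn{EP_j} the investigator states
#' "`m[j]` events of type \eqn{EP_j} are as harmful as `r[j]` reference
#' events", which implies the weight \eqn{w_j = r_j / m_j}. Weights above 1
#' are allowed but trigger a warning, since keeping all non-reference weights
#' at or below 1 preserves comparability with the unweighted analysis.
#'
#' @param m,r Positive numeric vectors, one entry per non-reference
#'   component in endpoint order: `m[j]` events of that type are judged as
#'   harmful as `r[j]` reference events.
#' @param reference Position of the reference component among the `k =
#'   length(m) + 1` components (default 1).
#' @return A weight vector of length `length(m) + 1` with 1 at the reference
#'   position.
#' @examples
#' severity_to_weights(m = 5, r = 1)  # c(1, 0.2)
#' severity_to_weights(m = 5, r = 3)  # c(1, 0.6)
#' @export
severity_to_weights <- function(m, r, reference = 1) {
  if (!is.numeric(m) || !is.numeric(r) || length(m) != length(r) ||
      length(m) < 1L) {
    stop("'m' and 'r' must be numeric vectors of equal positive length",
         call. = FALSE)
  }
  if (any(m < 1) || any(r < 1)) {
    stop("severity equivalences require m >= 1 and r >= 1", call. = FALSE)
  }
  k <- length(m) + 1L
  if (!is.numeric(reference) || length(reference) != 1L ||
      !reference %in% seq_len(k)) {
    stop("'reference' must index one of the ", k, " components",
         call. = FALSE)
  }
  w_other <- r / m
  if (any(w_other > 1)) {
    warning("implied weight above 1; recommended practice keeps all ",
            "non-reference weights <= 1", call. = FALSE)
  }
  append(w_other, 1, after = reference - 1L)
}

#' Relevance-modified cause-specific hazard
#'
#' The weighted all-cause hazard can be read as a standard all-cause hazard
#' built from modified cause-specific hazards
#' \eqn{\tilde\lambda_{EP_j}(t) = w_{EP_j}\lambda_{EP_j}(t)}. Both supported
#' parametric families are closed under this scaling (the scale and intercept
#' parameters are multiplied by the weight), so the result is again a
#' [hazard_model()]; its cumulative hazard is the weight times the original
#' cumulative hazard.
#'
#' @param model A [hazard_model()].
#' @param weight Non-negative scalar weight.
#' @return A `hazard_model` with pointwise hazard `weight *
#'   hazard_value(model, t)`.
#' @examples
#' modified_hazard(hazard_model("constant", 0.2), 1.3)  # constant 0.26
#' @export
modified_hazard <- function(model, weight) {
  stopifnot(inherits(model, "hazard_model"))
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight < 0) {
    stop("'weight' must be a single non-negative number", call. = FALSE)
  }
  if (model$family == "custom") {
    fn <- model$fn
    return(hazard_model("custom", fn = function(t) weight * fn(t)))
  }
  hazard_model(model$family, kappa = weight * model$kappa, nu = model$nu,
               epsilon = weight * model$epsilon)
}

#' Weighted event-time-distribution curves
#'
#' Tabulates the weighted composite survival function \eqn{S^w_{CE}(t)} for
#' several candidate weighting schemes (plus the unweighted curve, weights
#' all 1) in both groups over a time grid — the data behind the side-by-side
#' curve comparison recommended when choosing weights. Down-weighting a
#' component flattens its group's curve; the tidy output plots directly with
#' any graphics system.
#'
#' @param set A [cause_hazard_set()].
#' @param schemes Named list of weight vectors (unnamed schemes are labelled
#'   `scheme_1`, `scheme_2`, ...).
#' @param times Non-empty grid of evaluation times.
#' @return A data frame with columns `scheme`, `group`, `time`, `survival`.
#' @examples
#' set <- cause_hazard_set(
#'   intervention = list(hazard_model("constant", 0.2),
#'                       hazard_model("constant", 0.3)),
#'   control      = list(hazard_model("constant", 0.25),
#'                       hazard_model("constant", 0.35)))
#' curves <- weight_scheme_curves(set,
#'   schemes = list(A = c(1, 0.6), B = c(1, 0.2)),
#'   times = seq(0, 2, by = 0.5))
#' @export
weight_scheme_curves <- function(set, schemes, times) {
  stopifnot(inherits(set, "cause_hazard_set"))
  if (!is.list(schemes) || length(schemes) == 0L) {
    stop("'schemes' must be a non-empty list of weight vectors",
         call. = FALSE)
  }
  if (!is.numeric(times) || length(times) == 0L || any(times < 0)) {
    stop("'times' must be a non-empty grid of non-negative times",
         call. = FALSE)
  }
  nm <- names(schemes)
  if (is.null(nm)) nm <- rep("", length(schemes))
  blank <- nm == ""
  nm[blank] <- paste0("scheme_", seq_along(schemes))[blank]
  all_schemes <- c(list(unweighted = rep(1, set$k)),
                   stats::setNames(schemes, nm))
  out <- do.call(rbind, lapply(names(all_schemes), function(s) {
    w <- weight_scheme(all_schemes[[s]], set$k)
    do.call(rbind, lapply(c("I", "C"), function(g) {
      data.frame(scheme = s, group = g, time = times,
                 survival = weighted_survival(set, g, w, times))
    }))
  }))
  rownames(out) <- NULL
  out
}
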