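# Benchmark scenario registry: ten two-component data-generating models
# spanning Weibull and Gompertz-Makeham cause-specific hazards, chosen so
# that the proportional-hazards and equal-baseline-hazards assumptions of the
# two estimators are met in some scenarios and violated in others.
#
# Hazards are stored as (kappa, nu[, epsilon]); e.g. "0.8t" is Weibull with
# kappa = 0.4, nu = 2 and "0.192 t^-0.2" is Weibull with nu = 0.8,
# kappa = 0.192 / 0.8 = 0.24.
.wb <- function(kappa, nu) hazard_model("weibull", kappa = kappa, nu = nu)
.gm <- function(kappa, nu, epsilon) {
  hazard_model("gompertz_makeham", kappa = kappa, nu = nu, epsilon = epsilon)
}

.scenario_registry <- function() {
  sc <- function(I1, C1, I2, C2, family, ph_components, ph_composite,
                 equal_baseline) {
    set <- cause_hazard_set(intervention = list(I1, I2),
                            control = list(C1, C2))
    attr(set, "family") <- family
    attr(set, "ph_components") <- ph_components
    attr(set, "ph_composite") <- ph_composite
    attr(set, "equal_baseline") <- equal_baseline
    set
  }
  list(
    scenario_1 = sc(.wb(0.24, 1), .wb(0.4, 1), .wb(0.12, 2), .wb(0.4, 2),
                    "weibull", TRUE, FALSE, FALSE),
    scenario_2 = sc(.wb(0.24, 0.8), .wb(0.4, 0.7), .wb(0.12, 0.7),
                    .wb(0.4, 0.8), "weibull", FALSE, FALSE, FALSE),
    scenario_3 = sc(.wb(0.12, 2), .wb(0.4, 2), .wb(0.4, 3), .wb(0.24, 3),
                    "weibull", TRUE, FALSE, FALSE),
    scenario_4 = sc(.wb(1 / 3, 0.6), .wb(3 / 7, 0.7), .wb(0.05, 2),
                    .wb(0.04, 2.5), "weibull", FALSE, FALSE, FALSE),
    scenario_5 = sc(.wb(0.5 / 0.6, 0.6), .wb(1.8, 0.5), .wb(0.25, 1),
                    .wb(0.2, 1.1), "weibull", FALSE, FALSE, FALSE),
    scenario_6 = sc(.wb(0.24, 1), .wb(0.24, 1), .wb(0.12, 2), .wb(0.12, 2),
                    "weibull", TRUE, TRUE, FALSE),
    scenario_7 = sc(.wb(0.05, 1), .wb(0.1, 1), .wb(1, 1), .wb(0.5, 1),
                    "weibull", TRUE, TRUE, TRUE),
    scenario_8 = sc(.gm(0.42, 0.7, -0.42), .gm(0.7, 0.7, -0.7),
                    .gm(0.21, 0.7, -0.21), .gm(0.7, 0.7, -0.7),
                    "gompertz_makeham", TRUE, TRUE, TRUE),
    scenario_9 = sc(.gm(0.42, 2, -0.42), .gm(0.7, 2, -0.7),
                    .gm(0.21, 0.7, -0.21), .gm(0.7, 0.7, -0.7),
                    "gompertz_makeham", TRUE, FALSE, FALSE),
    scenario_10 = sc(.gm(0.42, 0.7, 0), .gm(0.7, 0.8, 0),
                     .gm(0.21, 0.8, 0), .gm(0.7, 0.6, 0),
                     "gompertz_makeham", FALSE, FALSE, FALSE)
  )
}

#' Benchmark simulation scenarios
#'
#' `list_scenarios()` summarizes the registry of ten preset two-component
#' data-generating scenarios; `scenario_hazards(name)` returns the
#' [cause_hazard_set()] of one preset (with attributes `family`,
#' `ph_components`, `ph_composite`, `equal_baseline` describing which model
#' assumptions hold).
#'
#' @return `list_scenarios()` returns a data frame with one row per scenario;
#'   `scenario_hazards()` returns a `cause_hazard_set`.
#' @examples
#' list_scenarios()
#' scenario_hazards("scenario_7")
#' @export
list_scenarios <- function() {
  reg <- .scenario_registry()
  data.frame(
    name = names(reg),
    family = vapply(reg, attr, character(1), "family"),
    ph_components = vapply(reg, attr, logical(1), "ph_components"),
    ph_composite = vapply(reg, attr, logical(1), "ph_composite"),
    equal_baseline = vapply(reg, attr, logical(1), "equal_baseline"),
    row.names = NULL)
}

#' @rdname list_scenarios
#' @param name Scenario name, `"scenario_1"` ... `"scenario_10"`.
#' @export
scenario_hazards <- function(name) {
  reg <- .scenario_registry()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    stop("unknown scenario; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[name]]
}
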