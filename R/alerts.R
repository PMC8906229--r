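# Alert construction, identity comparison and traffic-light aggregation.

apart_alert_codes <- c(
  "WRONG_PATIENT", "WRONG_PLAN", "MU_DIFF", "STRUCTURE_DELETED",
  "VOLUME_DIFF", "TARGET_INCONSISTENT", "SMALL_SEGMENTS",
  "LOW_MU_SEGMENTS", "STRUCTURE_GAP"
)

#' Build an alert record
#'
#' @param code One of the alert codes (see [score_alerts()] for the weight
#'   scheme).
#' @param weight Non-negative severity weight.
#' @param message Human-readable description.
#' @param subject Structure or beam name the alert refers to (may be `""`).
#' @return A one-row tibble with columns code, weight, message, subject.
#' @export
new_alert <- function(code, weight, message, subject = "") {
  code <- match.arg(code, apart_alert_codes)
  if (!is.finite(weight) || weight < 0) {
    abort("alert weight must be a non-negative number", class = "apart_validation_error")
  }
  tibble(code = code, weight = as.numeric(weight), message = message, subject = subject)
}

empty_alerts <- function() {
  tibble(
    code = character(), weight = numeric(),
    message = character(), subject = character()
  )
}

.squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

#' Compare plan identities between original and adapted plan
#'
#' Patient name, patient ID and plan name are compared case-sensitively
#' after whitespace normalization. A mismatch in patient name or ID raises
#' a `WRONG_PATIENT` alert (weight 10); a plan-name mismatch raises
#' `WRONG_PLAN` (weight 10).
#'
#' @param orig,adapted [plan_identity()] objects.
#' @param config An [apart_config()].
#' @return A tibble of alerts (possibly empty).
#' @export
compare_identity <- function(orig, adapted, config = apart_config()) {
  alerts <- empty_alerts()
  if (!identical(.squish(orig$patient_name), .squish(adapted$patient_name)) ||
    !identical(.squish(orig$patient_id), .squish(adapted$patient_id))) {
    alerts <- bind_rows(alerts, new_alert(
      "WRONG_PATIENT", config$weights$WRONG_PATIENT,
      sprintf(
        "patient identity differs: '%s' [%s] vs '%s' [%s]",
        orig$patient_name, orig$patient_id,
        adapted$patient_name, adapted$patient_id
      )
    ))
  }
  if (!identical(.squish(orig$plan_name), .squish(adapted$plan_name))) {
    alerts <- bind_rows(alerts, new_alert(
      "WRONG_PLAN", config$weights$WRONG_PLAN,
      sprintf("plan name differs: '%s' vs '%s'", orig$plan_name, adapted$plan_name)
    ))
  }
  alerts
}

#' Aggregate alerts into a traffic light
#'
#' Sums the alert weights and maps the total to a verdict: 0 is green, any
#' positive total up to the orange limit (default 9) is orange, anything
#' above is red. Formula-weighted alerts (MU difference, small segments)
#' can contribute fractional weights; any positive total is made visible
#' as at least orange.
#'
#' @param alerts Alert tibble as produced by the check functions.
#' @param config An [apart_config()].
#' @return An object of class `traffic_light` with fields `value`
#'   (`"green"`, `"orange"` or `"red"`) and `total_weight`.
#' @export
score_alerts <- function(alerts, config = apart_config()) {
  if (is.null(alerts) || nrow(alerts) == 0L) {
    return(structure(list(value = "green", total_weight = 0), class = "traffic_light"))
  }
  if (any(!is.finite(alerts$weight)) || any(alerts$weight < 0)) {
    abort("alert weights must be non-negative", class = "apart_validation_error")
  }
  total <- sum(alerts$weight)
  value <- if (total == 0) {
    "green"
  } else if (total <= config$traffic_light$orange_max) {
    "orange"
  } else {
    "red"
  }
  structure(list(value = value, total_weight = total), class = "traffic_light")
}

#' @export
print.traffic_light <- function(x, ...) {
  cat(sprintf("<traffic light> %s (total weight %.3g)\n", toupper(x$value), x$total_weight))
  invisible(x)
}
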