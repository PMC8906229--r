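# Per-fraction report assembly and serialization.

#' Run all plan checks on an original/adapted pair
#'
#' Executes the full check battery in fixed order — identity, structure
#' matching and deletions, volume differences, target-chain consistency,
#' missing-slice detection, density overrides, MLC complexity and MU
#' comparison — then aggregates the weighted alerts into a traffic light.
#' Deterministic for fixed inputs and configuration.
#'
#' @param original_plan,original_rs,adapted_plan,adapted_rs Paths to the
#'   four DICOM files.
#' @param config An [apart_config()].
#' @return An object of class `apart_report`.
#' @export
run_check <- function(original_plan, original_rs, adapted_plan, adapted_rs,
                      config = apart_config()) {
  read_or_abort <- function(fn, path, what) {
    tryCatch(fn(path), error = function(e) {
      abort(
        sprintf("failed to read %s '%s': %s", what, path, conditionMessage(e)),
        class = "apart_read_error"
      )
    })
  }
  plan_or <- read_or_abort(read_plan, original_plan, "original plan")
  rs_or <- read_or_abort(read_structure_set, original_rs, "original structure set")
  plan_ad <- read_or_abort(read_plan, adapted_plan, "adapted plan")
  rs_ad <- read_or_abort(read_structure_set, adapted_rs, "adapted structure set")

  alerts <- empty_alerts()

  # 1. identity
  id_alerts <- compare_identity(plan_or$identity, plan_ad$identity, config)
  alerts <- bind_rows(alerts, id_alerts)

  # 2. structure matching / deletions
  match <- match_structures(rs_or, rs_ad)
  for (nm in match$deleted) {
    alerts <- bind_rows(alerts, new_alert(
      "STRUCTURE_DELETED", config$weights$STRUCTURE_DELETED,
      sprintf("structure '%s' is missing from the adapted structure set", nm),
      subject = nm
    ))
  }

  # 3. volume differences
  vd <- volume_diff_table(rs_or, rs_ad, match$matched, config)
  alerts <- bind_rows(alerts, vd$alerts)

  # 4. target chains
  chains <- build_chains(vd$table, config)
  chain_findings <- list()
  for (ch in chains) {
    res <- check_chain(ch, config)
    chain_findings[[length(chain_findings) + 1L]] <- res$finding
    alerts <- bind_rows(alerts, res$alerts)
  }

  # 5. gaps in adapted structures
  gap_reports <- list()
  for (s in rs_ad$structures) {
    g <- detect_gaps(s, config$thresholds$gap_factor)
    gap_reports[[length(gap_reports) + 1L]] <- g
    if (length(g$missing_z)) {
      alerts <- bind_rows(alerts, new_alert(
        "STRUCTURE_GAP", config$weights$STRUCTURE_GAP,
        sprintf(
          "'%s': missing slice(s) at z = %s mm (nominal spacing %g mm)",
          s$name, paste(format(g$missing_z), collapse = ", "), g$nominal_spacing
        ),
        subject = s$name
      ))
    }
  }

  # 6. density overrides (informational)
  overrides <- density_override_report(rs_ad, config)

  # 7. complexity + MU comparison (alerts from the adapted plan)
  cx_or <- complexity_report(plan_or, config)
  cx_ad <- complexity_report(plan_ad, config)
  alerts <- bind_rows(alerts, cx_ad$alerts)
  mu <- mu_comparison(plan_or, plan_ad, config)
  alerts <- bind_rows(alerts, mu$alerts)

  # 8. verdict
  light <- score_alerts(alerts, config)

  structure(
    list(
      files = list(
        original_plan = original_plan, original_rs = original_rs,
        adapted_plan = adapted_plan, adapted_rs = adapted_rs
      ),
      identity = list(
        original = unclass(plan_or$identity),
        adapted = unclass(plan_ad$identity)
      ),
      structure_match = match,
      volume_table = vd$table,
      chain_findings = chain_findings,
      gap_reports = gap_reports,
      density_overrides = overrides,
      complexity = list(
        original = list(beams = cx_or$beams, summary = cx_or$summary),
        adapted = list(beams = cx_ad$beams, summary = cx_ad$summary),
        mu_delta_percent = mu$mu_delta_percent,
        subsegment_change = cx_ad$summary$n_subsegments - cx_or$summary$n_subsegments
      ),
      alerts = alerts,
      light = unclass(light),
      config = unclass(config),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "apart_report"
  )
}

#' @export
print.apart_report <- function(x, ...) {
  cat(render_report(x, format = "text"), sep = "\n")
  invisible(x)
}

.report_serializable <- function(report) {
  r <- unclass(report)
  r$structure_match$matched <- as.data.frame(r$structure_match$matched)
  r$volume_table <- as.data.frame(r$volume_table)
  r$density_overrides <- as.data.frame(r$density_overrides)
  r$alerts <- as.data.frame(r$alerts)
  r$complexity$original$beams <- as.data.frame(r$complexity$original$beams)
  r$complexity$adapted$beams <- as.data.frame(r$complexity$adapted$beams)
  r
}

#' Render a report as JSON or text
#'
#' @param report An `apart_report`.
#' @param format `"json"` or `"text"`.
#' @return A character scalar (JSON) or character vector of lines (text).
#' @export
render_report <- function(report, format = c("json", "text")) {
  if (!format[1] %in% c("json", "text")) {
    abort(sprintf("unknown report format '%s'", format[1]), class = "apart_usage_error")
  }
  format <- match.arg(format)
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      .report_serializable(report),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null", pretty = TRUE
    )))
  }
  r <- report
  lines <- c(
    sprintf("TRAFFIC LIGHT: %s (total alert weight %.3g)",
      toupper(r$light$value), r$light$total_weight),
    sprintf("Patient: %s [%s]  Plan: %s",
      r$identity$adapted$patient_name, r$identity$adapted$patient_id,
      r$identity$adapted$plan_name),
    ""
  )
  if (nrow(r$alerts)) {
    lines <- c(lines, "Alerts:", sprintf(
      "  [%-19s w=%5.1f] %s", r$alerts$code, r$alerts$weight, r$alerts$message
    ), "")
  } else {
    lines <- c(lines, "Alerts: none", "")
  }
  vt <- r$volume_table
  lines <- c(lines, "Volumes [cc]:", sprintf(
    "  %-16s %8.2f -> %8.2f  (%+6.1f%%)",
    vt$name, vt$volume_original, vt$volume_adapted,
    ifelse(is.na(vt$delta_percent), NaN, vt$delta_percent)
  ), "")
  for (f in r$chain_findings) {
    lines <- c(lines, sprintf(
      "Target chain '%s': %s (sphere margin %.2f -> %.2f mm)",
      f$label, if (f$consistent) "consistent" else paste(f$reasons, collapse = "; "),
      f$sphere_margin_original, f$sphere_margin_adapted
    ))
  }
  sm <- r$complexity$adapted$summary
  lines <- c(lines, "", sprintf(
    "MU: %.1f -> %.1f (%+.1f%%), subsegments %d -> %d",
    r$complexity$original$summary$mu_total, sm$mu_total,
    r$complexity$mu_delta_percent,
    r$complexity$original$summary$n_subsegments, sm$n_subsegments
  ), sprintf(
    "Smallest segment: %.2f cm2 at %.1f MU; lowest-MU segment: %.1f MU at %.2f cm2",
    sm$min_area_segment$area_cm2, sm$min_area_segment$mu,
    sm$min_mu_segment$mu, sm$min_mu_segment$area_cm2
  ))
  bt <- r$complexity$adapted$beams
  lines <- c(lines, sprintf(
    "  beam %d: effMU %.1f (union %.1f cm2, %d segments, %.1f MU)",
    bt$beam_id, bt$eff_mu, bt$union_area_cm2, bt$n_segments, bt$sum_mu
  ))
  for (o in seq_len(nrow(r$density_overrides))) {
    lines <- c(lines, sprintf(
      "Density override: %s = %.3g (priority %d)%s",
      r$density_overrides$name[o], r$density_overrides$density[o],
      r$density_overrides$priority[o],
      if (r$density_overrides$extreme[o]) "  ** extreme value **" else ""
    ))
  }
  lines
}

#' Parse a JSON report back into an `apart_report`
#'
#' @param json JSON string produced by [render_report()].
#' @return An `apart_report` (tables restored as tibbles).
#' @export
parse_report <- function(json) {
  r <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  r$structure_match$matched <- as_tibble(r$structure_match$matched)
  r$volume_table <- as_tibble(r$volume_table)
  r$density_overrides <- as_tibble(r$density_overrides)
  r$alerts <- as_tibble(r$alerts)
  r$complexity$original$beams <- as_tibble(r$complexity$original$beams)
  r$complexity$adapted$beams <- as_tibble(r$complexity$adapted$beams)
  structure(r, class = "apart_report")
}

#' Structural validation of a rendered JSON report
#'
#' Checks the parsed report against the shipped schema's required keys and
#' types (see `system.file("schema", "report.schema.json", package =
#' "apart")` for the full schema document).
#'
#' @param json JSON string.
#' @return `TRUE` invisibly; aborts with the list of violations otherwise.
#' @export
validate_report_json <- function(json) {
  r <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  for (key in c(
    "files", "identity", "structure_match", "volume_table", "chain_findings",
    "gap_reports", "density_overrides", "complexity", "alerts", "light",
    "config", "timestamp"
  )) {
    need(key %in% names(r), sprintf("missing key '%s'", key))
  }
  need(is.character(r$light$value) && r$light$value %in% c("green", "orange", "red"),
    "light.value must be green/orange/red")
  need(is.numeric(r$light$total_weight) && r$light$total_weight >= 0,
    "light.total_weight must be a non-negative number")
  if (length(r$alerts)) {
    need(all(c("code", "weight", "message") %in% names(r$alerts)),
      "alerts must have code/weight/message columns")
    need(all(r$alerts$code %in% apart_alert_codes), "unknown alert code")
    need(all(r$alerts$weight >= 0), "negative alert weight")
  }
  for (col in c("name", "volume_original", "volume_adapted", "delta_percent")) {
    need(col %in% names(r$volume_table), sprintf("volume_table missing '%s'", col))
  }
  for (side in c("original", "adapted")) {
    need(is.numeric(r$complexity[[side]]$summary$n_segments),
      sprintf("complexity.%s.summary.n_segments missing", side))
  }
  if (length(problems)) {
    abort(paste(c("report JSON fails validation:", problems), collapse = "\n  "),
      class = "apart_validation_error"
    )
  }
  invisible(TRUE)
}
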