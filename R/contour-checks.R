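# Structure-set checks: volumes, volume differences, structure matching,
# missing-slice (gap) detection and density-override reporting.

#' Volume of a contoured structure
#'
#' Slice-prism summation: per contoured slice the net polygon area
#' (shoelace, holes subtracted by even-odd nesting) is multiplied by the
#' slice spacing; no end-cap correction is applied.
#'
#' @param s An `apart_structure`.
#' @param spacing Slice spacing in mm (> 0).
#' @return Volume in cc.
#' @export
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' s <- structure_roi("cube", 1, lapply(0:9, function(z) contour(z, sq)))
#' structure_volume(s, spacing = 1) # 1 cc
structure_volume <- function(s, spacing) {
  if (spacing <= 0) abort("spacing must be > 0", class = "apart_validation_error")
  z <- vapply(s$contours, function(ct) ct$z, numeric(1))
  groups <- split(seq_along(z), round(z, 6))
  total_mm3 <- sum(vapply(groups, function(idx) {
    slice_net_area(lapply(s$contours[idx], function(ct) ct$vertices))
  }, numeric(1))) * spacing
  if (total_mm3 <= 0) {
    warn(sprintf("structure '%s' has zero total area", s$name))
    return(0)
  }
  total_mm3 / 1000
}

#' Slice spacing of a structure inferred from its own z positions
#'
#' Mode of the consecutive z differences; ties resolved to the smallest.
#' @param s An `apart_structure`.
#' @param fallback Spacing to use when fewer than 2 distinct slices exist.
#' @return Spacing in mm.
#' @export
nominal_spacing <- function(s, fallback = 1) {
  z <- sort(unique(round(vapply(s$contours, function(ct) ct$z, numeric(1)), 6)))
  if (length(z) < 2L) return(fallback)
  d <- round(diff(z), 6)
  tab <- table(d)
  min(as.numeric(names(tab)[tab == max(tab)]))
}

#' Match structures between the original and adapted set
#'
#' Names are matched exactly but case-insensitively. Structures present
#' only in the original set are "deleted"; ones present only in the
#' adapted set are "new" (new helper structures carry no alert weight).
#'
#' @param orig,adapted `apart_structure_set` objects.
#' @return `list(matched, deleted, new, count_difference)`; `matched` is a
#'   tibble with the original and adapted names.
#' @export
match_structures <- function(orig, adapted) {
  n_or <- vapply(orig$structures, function(s) s$name, character(1))
  n_ad <- vapply(adapted$structures, function(s) s$name, character(1))
  key_or <- tolower(n_or)
  key_ad <- tolower(n_ad)
  common <- intersect(key_or, key_ad)
  matched <- tibble(
    name_original = n_or[match(common, key_or)],
    name_adapted = n_ad[match(common, key_ad)]
  )
  list(
    matched = matched,
    deleted = n_or[!key_or %in% key_ad],
    new = n_ad[!key_ad %in% key_or],
    count_difference = length(n_ad) - length(n_or)
  )
}

.find_structure <- function(ss, name) {
  for (s in ss$structures) if (tolower(s$name) == tolower(name)) return(s)
  NULL
}

#' Per-structure volume-difference table with alerts
#'
#' Computes original and adapted volumes for every matched structure and
#' raises one `VOLUME_DIFF` alert (weight 3 by default) per structure whose
#' relative volume change exceeds the threshold (default 30%). A structure
#' with zero original volume has an undefined relative change and is
#' flagged with an alert as well.
#'
#' @param orig,adapted `apart_structure_set` objects.
#' @param matched Tibble of matched names from [match_structures()].
#' @param config An [apart_config()].
#' @return `list(table, alerts)`: `table` has one row per matched structure
#'   with columns name, volume_original, volume_adapted, delta_percent,
#'   delta_cc, undefined.
#' @export
volume_diff_table <- function(orig, adapted, matched, config = apart_config()) {
  threshold <- config$thresholds$volume_diff_percent
  rows <- vector("list", nrow(matched))
  alerts <- empty_alerts()
  for (i in seq_len(nrow(matched))) {
    so <- .find_structure(orig, matched$name_original[i])
    sa <- .find_structure(adapted, matched$name_adapted[i])
    v_or <- structure_volume(so, nominal_spacing(so, orig$slice_spacing_hint %||% 1))
    v_ad <- structure_volume(sa, nominal_spacing(sa, adapted$slice_spacing_hint %||% 1))
    undefined <- v_or == 0
    delta_pct <- if (undefined) NA_real_ else 100 * (v_ad - v_or) / v_or
    rows[[i]] <- tibble(
      name = so$name, volume_original = v_or, volume_adapted = v_ad,
      delta_percent = delta_pct, delta_cc = v_ad - v_or, undefined = undefined
    )
    if (undefined) {
      alerts <- bind_rows(alerts, new_alert(
        "VOLUME_DIFF", config$weights$VOLUME_DIFF,
        sprintf("'%s': original volume is zero, relative change undefined", so$name),
        subject = so$name
      ))
    } else if (abs(delta_pct) > threshold) {
      alerts <- bind_rows(alerts, new_alert(
        "VOLUME_DIFF", config$weights$VOLUME_DIFF,
        sprintf(
          "'%s': volume change %+.1f%% exceeds %g%% (%.2f -> %.2f cc)",
          so$name, delta_pct, threshold, v_or, v_ad
        ),
        subject = so$name
      ))
    }
  }
  list(table = bind_rows(rows), alerts = alerts)
}

#' Detect missing slices in a structure
#'
#' The nominal slice spacing is the mode of consecutive z differences
#' (ties resolved to the smallest). Any consecutive difference larger than
#' `gap_factor` (default 1.5) times the nominal spacing is reported with
#' the intermediate missing z positions.
#'
#' @param s An `apart_structure`.
#' @param gap_factor Multiple of the nominal spacing above which a jump
#'   counts as a gap.
#' @return A tibble-backed report: `list(structure_name, nominal_spacing,
#'   missing_z)`.
#' @export
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' s <- structure_roi("oar", 1, lapply(c(0, 1, 3, 4), function(z) contour(z, sq)))
#' detect_gaps(s)$missing_z # 2
detect_gaps <- function(s, gap_factor = 1.5) {
  z <- sort(unique(round(vapply(s$contours, function(ct) ct$z, numeric(1)), 6)))
  if (length(z) < 2L) {
    return(list(structure_name = s$name, nominal_spacing = NA_real_, missing_z = numeric(0)))
  }
  nominal <- nominal_spacing(s)
  d <- diff(z)
  missing <- numeric(0)
  for (i in seq_along(d)) {
    if (d[i] > gap_factor * nominal) {
      k <- round(d[i] / nominal) - 1L
      if (k >= 1L) missing <- c(missing, z[i] + nominal * seq_len(k))
    }
  }
  list(structure_name = s$name, nominal_spacing = nominal, missing_z = missing)
}

#' Density-override report
#'
#' Lists every structure carrying a relative-electron-density override,
#' sorted by priority (highest first). Informational: overrides carry no
#' alert weight, but physically implausible values (zero, or outside the
#' 0-3 relative-electron-density band by default) are flagged in the table.
#'
#' @param ss An `apart_structure_set`.
#' @param config An [apart_config()].
#' @return A tibble with columns name, density, priority, extreme.
#' @export
density_override_report <- function(ss, config = apart_config()) {
  rows <- compact(map(ss$structures, function(s) {
    if (is.null(s$density_override)) return(NULL)
    tibble(
      name = s$name,
      density = s$density_override$rel_elec_density,
      priority = s$density_override$priority
    )
  }))
  if (length(rows) == 0L) {
    return(tibble(
      name = character(), density = numeric(),
      priority = integer(), extreme = logical()
    ))
  }
  bind_rows(rows) |>
    mutate(extreme = .data$density <= config$thresholds$density_min |
      .data$density > config$thresholds$density_max) |>
    arrange(desc(.data$priority))
}
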