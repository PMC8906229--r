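# MLC modulation-complexity analysis.
#
# A double-stack MLC segment is reduced to an artificial single-stack
# aperture: the field is partitioned into rows at the stack offset (half
# the leaf width for a half-leaf-shifted machine) and each row's opening
# is the intersection of the covering leaf pair of each stack ("minimum
# united opening"). All downstream quantities (segment area, subsegment
# count, per-beam union area, effective MU) are computed on these rows.

#' Combine both MLC stacks into a single-stack aperture
#'
#' The y range covered by both stacks is partitioned into rows at every
#' leaf boundary of either stack; each row is covered by exactly one leaf
#' pair per stack and its opening is
#' `[max(left_A, left_B), min(right_A, right_B)]`, open iff that interval
#' has positive length.
#'
#' @param seg An `mlc_segment`.
#' @return An `apart_aperture`: a tibble with columns y_low, y_high,
#'   x_left, x_right, open; geometry kept as an attribute.
#' @export
combine_stacks <- function(seg) {
  g <- seg$geometry
  ba <- stack_boundaries(g, "a")
  bb <- stack_boundaries(g, "b")
  lo <- max(ba[1L], bb[1L])
  hi <- min(ba[length(ba)], bb[length(bb)])
  edges <- sort(unique(round(c(ba, bb), 9)))
  edges <- edges[edges >= lo - 1e-9 & edges <= hi + 1e-9]
  y_low <- edges[-length(edges)]
  y_high <- edges[-1L]
  keep <- (y_high - y_low) > 1e-9
  y_low <- y_low[keep]; y_high <- y_high[keep]
  mid <- (y_low + y_high) / 2
  ia <- findInterval(mid, ba)
  ib <- findInterval(mid, bb)
  l <- pmax(seg$stack_a[ia, 1L], seg$stack_b[ib, 1L])
  r <- pmin(seg$stack_a[ia, 2L], seg$stack_b[ib, 2L])
  open <- r - l > 1e-9
  r[!open] <- l[!open]
  ap <- tibble(y_low = y_low, y_high = y_high, x_left = l, x_right = r, open = open)
  structure(ap, class = c("apart_aperture", class(ap)), geometry = g)
}

#' Aperture area
#' @param a An `apart_aperture`.
#' @return Open area in cm2.
#' @export
aperture_area <- function(a) {
  sum((a$x_right - a$x_left) * (a$y_high - a$y_low) * a$open) / 100
}

#' Count connected open regions (subsegments) of an aperture
#'
#' Adjacent open rows belong to the same subsegment iff their x intervals
#' overlap with positive length.
#'
#' @param a An `apart_aperture`.
#' @return Integer subsegment count.
#' @export
count_subsegments <- function(a) {
  n_comp <- 0L
  prev_open <- FALSE
  prev_l <- prev_r <- 0
  for (i in seq_len(nrow(a))) {
    if (a$open[i]) {
      connected <- prev_open &&
        (min(prev_r, a$x_right[i]) - max(prev_l, a$x_left[i]) > 1e-9)
      if (!connected) n_comp <- n_comp + 1L
      prev_l <- a$x_left[i]; prev_r <- a$x_right[i]
    }
    prev_open <- a$open[i]
  }
  n_comp
}

#' Union area of a beam's segment apertures
#'
#' Per row, the segments' open x intervals are merged and the united
#' length accumulated; rows are identical across segments of one beam
#' (same machine geometry).
#'
#' @param apertures List of `apart_aperture` objects of one beam.
#' @return Union area in cm2.
#' @export
union_area <- function(apertures) {
  if (length(apertures) == 0L) abort("union over zero apertures", class = "apart_validation_error")
  n_rows <- vapply(apertures, nrow, integer(1))
  if (length(unique(n_rows)) != 1L) {
    abort("apertures of one beam must share the same row partition",
      class = "apart_validation_error"
    )
  }
  a1 <- apertures[[1L]]
  total <- 0
  for (i in seq_len(nrow(a1))) {
    ivs <- compact(map(apertures, function(a) {
      if (a$open[i]) c(a$x_left[i], a$x_right[i]) else NULL
    }))
    if (length(ivs) == 0L) next
    m <- do.call(rbind, ivs)
    m <- m[order(m[, 1L]), , drop = FALSE]
    merged_len <- 0
    cur_l <- m[1L, 1L]; cur_r <- m[1L, 2L]
    if (nrow(m) > 1L) {
      for (k in 2L:nrow(m)) {
        if (m[k, 1L] <= cur_r) {
          cur_r <- max(cur_r, m[k, 2L])
        } else {
          merged_len <- merged_len + (cur_r - cur_l)
          cur_l <- m[k, 1L]; cur_r <- m[k, 2L]
        }
      }
    }
    merged_len <- merged_len + (cur_r - cur_l)
    total <- total + merged_len * (a1$y_high[i] - a1$y_low[i])
  }
  total / 100
}

#' Effective monitor units of a beam
#'
#' The MU-weighted sum of segment areas divided by the union area of the
#' beam's segments: an open-field-equivalent MU count. Highly modulated
#' beams (small segments inside a large union) have a low effective MU
#' relative to their physical MU.
#'
#' @param beam A beam entry of an `apart_plan` (fields `segments`, ...).
#' @return `list(eff_mu, union_area, sum_mu, n_segments)`; `eff_mu` is `NA`
#'   (with a warning) when the union area is zero.
#' @export
effective_mu <- function(beam) {
  aps <- map(beam$segments, combine_stacks)
  areas <- map_dbl(aps, aperture_area)
  mus <- map_dbl(beam$segments, "mu")
  u <- union_area(aps)
  if (u <= 0) {
    warn(sprintf("beam %s: union aperture area is zero, effective MU undefined",
      beam$name %||% "?"))
    eff <- NA_real_
  } else {
    eff <- sum(mus * areas) / u
  }
  list(eff_mu = eff, union_area = u, sum_mu = sum(mus), n_segments = length(mus))
}

#' Per-segment table of a plan
#'
#' @param plan An `apart_plan`.
#' @return Tibble with beam_id, segment, mu, area_cm2, n_subsegments.
#' @export
segment_table <- function(plan) {
  bind_rows(map(plan$beams, function(b) {
    aps <- map(b$segments, combine_stacks)
    tibble(
      beam_id = b$beam_id,
      segment = seq_along(b$segments),
      mu = map_dbl(b$segments, "mu"),
      area_cm2 = map_dbl(aps, aperture_area),
      n_subsegments = map_int(aps, count_subsegments)
    )
  }))
}

#' Small-segment and low-MU statistics with alerts
#'
#' Computes the plan fractions of segments below the area and MU limits
#' (defaults 1 cm2 and 5 MU). When more than 10% of segments are small, a
#' `SMALL_SEGMENTS` alert with formula weight `fraction% - 10` is raised;
#' when more than 5% deliver under 5 MU, a `LOW_MU_SEGMENTS` alert (weight
#' 1) is raised. The smallest-area segment (with its MU) and the
#' smallest-MU segment (with its area) are reported.
#'
#' @param plan An `apart_plan`.
#' @param config An [apart_config()].
#' @return `list(summary, segments, alerts)`.
#' @export
segment_stats <- function(plan, config = apart_config()) {
  th <- config$thresholds
  segs <- segment_table(plan)
  if (nrow(segs) == 0L) abort("plan has no segments", class = "apart_validation_error")
  frac_small <- 100 * mean(segs$area_cm2 < th$small_area_cm2)
  frac_low <- 100 * mean(segs$mu < th$low_mu)
  i_area <- which.min(segs$area_cm2)
  i_mu <- which.min(segs$mu)
  summary <- list(
    n_segments = nrow(segs),
    n_subsegments = sum(segs$n_subsegments),
    frac_small_area = frac_small,
    frac_low_mu = frac_low,
    min_area_segment = list(area_cm2 = segs$area_cm2[i_area], mu = segs$mu[i_area]),
    min_mu_segment = list(mu = segs$mu[i_mu], area_cm2 = segs$area_cm2[i_mu]),
    mu_total = plan$total_mu
  )
  alerts <- empty_alerts()
  if (frac_small > th$small_area_frac_percent) {
    alerts <- bind_rows(alerts, new_alert(
      "SMALL_SEGMENTS", frac_small - th$small_area_frac_percent,
      sprintf(
        "%.1f%% of segments are smaller than %g cm2 (limit %g%%); smallest: %.2f cm2 at %.1f MU",
        frac_small, th$small_area_cm2, th$small_area_frac_percent,
        segs$area_cm2[i_area], segs$mu[i_area]
      )
    ))
  }
  if (frac_low > th$low_mu_frac_percent) {
    alerts <- bind_rows(alerts, new_alert(
      "LOW_MU_SEGMENTS", config$weights$LOW_MU_SEGMENTS,
      sprintf(
        "%.1f%% of segments deliver less than %g MU (limit %g%%)",
        frac_low, th$low_mu, th$low_mu_frac_percent
      )
    ))
  }
  list(summary = summary, segments = segs, alerts = alerts)
}

#' Monitor-unit comparison between original and adapted plan
#'
#' @param orig,adapted `apart_plan` objects.
#' @param config An [apart_config()].
#' @return `list(mu_original, mu_adapted, mu_delta_percent, alerts)`; an
#'   `MU_DIFF` alert with formula weight `|delta%| - 10` is raised when the
#'   absolute relative MU difference exceeds the threshold (default 10%).
#' @export
mu_comparison <- function(orig, adapted, config = apart_config()) {
  if (orig$total_mu <= 0) {
    abort("original plan has zero total MU", class = "apart_validation_error")
  }
  delta <- 100 * (adapted$total_mu - orig$total_mu) / orig$total_mu
  alerts <- empty_alerts()
  th <- config$thresholds$mu_diff_percent
  if (abs(delta) > th) {
    alerts <- new_alert(
      "MU_DIFF", abs(delta) - th,
      sprintf(
        "total MU changed by %+.1f%% (%.1f -> %.1f MU, limit %g%%)",
        delta, orig$total_mu, adapted$total_mu, th
      )
    )
  }
  list(
    mu_original = orig$total_mu, mu_adapted = adapted$total_mu,
    mu_delta_percent = delta, alerts = alerts
  )
}

#' Full complexity report for one plan
#'
#' @param plan An `apart_plan`.
#' @param config An [apart_config()].
#' @return `list(beams, summary, segments, alerts)`; `beams` is a tibble
#'   with per-beam effective MU, union area and MU sum.
#' @export
complexity_report <- function(plan, config = apart_config()) {
  beams <- bind_rows(map(plan$beams, function(b) {
    e <- effective_mu(b)
    tibble(
      beam_id = b$beam_id, name = b$name, n_segments = e$n_segments,
      sum_mu = e$sum_mu, union_area_cm2 = e$union_area, eff_mu = e$eff_mu
    )
  }))
  stats <- segment_stats(plan, config)
  list(
    beams = beams, summary = stats$summary,
    segments = stats$segments, alerts = stats$alerts
  )
}
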