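# Target-chain (GTV -> CTV -> PTV) consistency checks.

#' Group target structures into GTV/CTV/PTV chains
#'
#' Names in the volume table are matched case-insensitively against the
#' configurable target pattern (a regex with two capture groups: role and
#' chain suffix). Targets sharing a suffix form one chain (GTV2 - CTV2 -
#' PTV2); a target whose suffix matches no counterpart forms a singleton
#' chain.
#'
#' @param volume_table Tibble from [volume_diff_table()].
#' @param config An [apart_config()].
#' @return List of `target_chain` objects with fields `label` and one
#'   volume-table row (or `NULL`) per role gtv/ctv/ptv.
#' @export
build_chains <- function(volume_table, config = apart_config()) {
  pattern <- config$target_patterns
  m <- regmatches(tolower(volume_table$name), regexec(pattern, tolower(volume_table$name)))
  hits <- which(vapply(m, length, integer(1)) == 3L)
  if (length(hits) == 0L) return(list())
  role <- vapply(m[hits], function(x) x[2], character(1))
  suffix <- trimws(vapply(m[hits], function(x) x[3], character(1)))
  chains <- list()
  for (sfx in unique(suffix)) {
    idx <- hits[suffix == sfx]
    ch <- structure(
      list(label = sfx, gtv = NULL, ctv = NULL, ptv = NULL),
      class = "target_chain"
    )
    for (k in seq_along(idx)) {
      r <- role[match(idx[k], hits)]
      if (is.null(ch[[r]])) ch[[r]] <- volume_table[idx[k], , drop = FALSE]
    }
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Sphere-equivalent expansion margin
#'
#' The margin between two volumes assuming both are spheres: the
#' difference of their equivalent-sphere radii, `(3 V / 4 pi)^(1/3)`.
#' May be negative when the outer volume is smaller.
#'
#' @param v_inner,v_outer Volumes in cc.
#' @return Margin in mm.
#' @export
#' @examples
#' sphere_equivalent_margin(10, 20) # ~ 3.47 mm
sphere_equivalent_margin <- function(v_inner, v_outer) {
  r <- function(v_cc) (3 * v_cc * 1000 / (4 * pi))^(1 / 3)
  r(v_outer) - r(v_inner)
}

.chain_member_ok <- function(entry) {
  !is.null(entry) && !entry$undefined && is.finite(entry$delta_percent)
}

#' Check one target chain for expansion consistency
#'
#' Raises a `TARGET_INCONSISTENT` alert (weight 2 by default) when any of:
#' (a) the PTV volume change and the GTV (or, absent a GTV, CTV) change
#' have opposite signs; (b) the relative volume changes of any two chain
#' members differ by more than the spread threshold (default 10 percentage
#' points); (c) the GTV or CTV changed (beyond the no-change tolerance,
#' default 0.5 points) while the PTV volume stayed unchanged within that
#' tolerance — the signature of a skipped or misdirected margin expansion.
#' Sphere-equivalent margins from the innermost member to the PTV are
#' reported for both plans.
#'
#' @param chain A `target_chain` from [build_chains()].
#' @param config An [apart_config()].
#' @return `list(finding, alerts)`; `finding` has the chain label, the
#'   sphere margins, `consistent` and the list of `reasons`.
#' @export
check_chain <- function(chain, config = apart_config()) {
  tol <- config$thresholds$no_change_tol_points
  spread_max <- config$thresholds$target_spread_points
  members <- compact(list(gtv = chain$gtv, ctv = chain$ctv, ptv = chain$ptv))
  usable <- members[vapply(members, .chain_member_ok, logical(1))]

  margin <- function(col) {
    inner <- chain$gtv %||% chain$ctv
    if (is.null(inner) || is.null(chain$ptv)) return(NA_real_)
    sphere_equivalent_margin(inner[[col]], chain$ptv[[col]])
  }
  finding <- list(
    label = chain$label,
    members = names(members),
    sphere_margin_original = margin("volume_original"),
    sphere_margin_adapted = margin("volume_adapted"),
    consistent = TRUE,
    reasons = character(0),
    note = ""
  )
  if (length(usable) < 2L) {
    finding$note <- if (length(members) == 1L && !is.null(chain$ptv)) {
      sprintf("chain '%s': no GTV/CTV found, consistency not checkable", chain$label)
    } else {
      sprintf("chain '%s': fewer than two members with defined volumes", chain$label)
    }
    return(list(finding = finding, alerts = empty_alerts()))
  }
  deltas <- vapply(usable, function(e) e$delta_percent, numeric(1))
  reasons <- character(0)

  # (a) opposite signs of PTV vs GTV (or CTV) change
  inner_name <- if ("gtv" %in% names(usable)) "gtv" else if ("ctv" %in% names(usable)) "ctv" else NA
  if (!is.na(inner_name) && "ptv" %in% names(usable)) {
    d_in <- deltas[[inner_name]]
    d_ptv <- deltas[["ptv"]]
    if (abs(d_in) > tol && abs(d_ptv) > tol && sign(d_in) != sign(d_ptv)) {
      reasons <- c(reasons, sprintf(
        "PTV change (%+.1f%%) and %s change (%+.1f%%) have opposite signs",
        d_ptv, toupper(inner_name), d_in
      ))
    }
  }
  # (b) spread between members
  if (length(deltas) >= 2L) {
    spread <- max(deltas) - min(deltas)
    if (spread > spread_max) {
      reasons <- c(reasons, sprintf(
        "volume changes spread %.1f points exceeds %g (%s)",
        spread, spread_max,
        paste(sprintf("%s %+.1f%%", toupper(names(deltas)), deltas), collapse = ", ")
      ))
    }
  }
  # (c) GTV/CTV changed while PTV unchanged
  if ("ptv" %in% names(usable) && abs(deltas[["ptv"]]) <= tol) {
    for (r in intersect(c("gtv", "ctv"), names(usable))) {
      if (abs(deltas[[r]]) > tol) {
        reasons <- c(reasons, sprintf(
          "%s changed by %+.1f%% while PTV volume is unchanged (margin expansion missing?)",
          toupper(r), deltas[[r]]
        ))
        break
      }
    }
  }
  finding$reasons <- reasons
  finding$consistent <- length(reasons) == 0L
  alerts <- if (length(reasons)) {
    new_alert(
      "TARGET_INCONSISTENT", config$weights$TARGET_INCONSISTENT,
      sprintf("target chain '%s': %s", chain$label, paste(reasons, collapse = "; ")),
      subject = paste0("chain:", chain$label)
    )
  } else {
    empty_alerts()
  }
  list(finding = finding, alerts = alerts)
}
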