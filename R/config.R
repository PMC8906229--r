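#' Plan-check configuration
#'
#' All thresholds and alert weights used by [run_check()] live here. The
#' defaults are the clinically used values: a 30% structure-volume
#' difference threshold, a 10-percentage-point spread limit between target
#' chain members, 1 cm2 / 5 MU small-segment limits with 10% / 5% plan
#' fractions, a 10% MU-difference threshold, and fixed alert weights
#' (wrong patient or plan 10, deleted structure 5, structure gap 5, volume
#' difference 3, target inconsistency 2, low-MU segments 1). The
#' MU-difference and small-segment alerts carry formula weights
#' (`|delta%| - 10` and `fraction% - 10`) and are not configured here.
#'
#' @param ... Named overrides, e.g. `thresholds = list(volume_diff_percent = 50)`.
#'   Nested lists are merged into the defaults.
#' @return A nested list of class `apart_config`.
#' @export
#' @examples
#' cfg <- apart_config(thresholds = list(volume_diff_percent = 50))
#' cfg$thresholds$volume_diff_percent
apart_config <- function(...) {
  defaults <- list(
    thresholds = list(
      volume_diff_percent = 30,
      target_spread_points = 10,
      no_change_tol_points = 0.5,
      mu_diff_percent = 10,
      small_area_cm2 = 1,
      small_area_frac_percent = 10,
      low_mu = 5,
      low_mu_frac_percent = 5,
      gap_factor = 1.5,
      density_min = 0,
      density_max = 3
    ),
    weights = list(
      WRONG_PATIENT = 10,
      WRONG_PLAN = 10,
      STRUCTURE_DELETED = 5,
      VOLUME_DIFF = 3,
      TARGET_INCONSISTENT = 2,
      LOW_MU_SEGMENTS = 1,
      STRUCTURE_GAP = 5
    ),
    traffic_light = list(orange_max = 9),
    # regex with two capture groups: target role, chain suffix
    target_patterns = "^(gtv|ctv|ptv)[ _-]*(.*)$"
  )
  overrides <- list(...)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_rec(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  structure(merge_rec(defaults, overrides), class = "apart_config")
}

#' Read / write a configuration file (YAML)
#'
#' @param path YAML file with any subset of the [apart_config()] keys;
#'   missing keys keep their defaults.
#' @return An `apart_config` object.
#' @export
read_apart_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(apart_config, vals)
}

#' @rdname read_apart_config
#' @param config An `apart_config` object.
#' @export
write_apart_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
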