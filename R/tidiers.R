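# Tidy accessors and plots for report objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a plan-check report
#'
#' @param x An `apart_report`.
#' @param what Which table to return: `"alerts"` (default), `"volumes"`,
#'   `"segments"` (per-beam complexity) or `"overrides"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy apart_report
#' @export
tidy.apart_report <- function(x, what = c("alerts", "volumes", "segments", "overrides"), ...) {
  what <- match.arg(what)
  switch(what,
    alerts = as_tibble(x$alerts),
    volumes = as_tibble(x$volume_table),
    segments = bind_rows(
      mutate(as_tibble(x$complexity$original$beams), plan = "original"),
      mutate(as_tibble(x$complexity$adapted$beams), plan = "adapted")
    ),
    overrides = as_tibble(x$density_overrides)
  )
}

#' One-row summary of a plan-check report
#'
#' @param x An `apart_report`.
#' @param ... Unused.
#' @return A one-row tibble: light, total weight, alert count, MU delta,
#'   structure counts.
#' @method glance apart_report
#' @export
glance.apart_report <- function(x, ...) {
  tibble(
    light = x$light$value,
    total_weight = x$light$total_weight,
    n_alerts = nrow(x$alerts),
    n_structures_matched = nrow(x$structure_match$matched),
    n_structures_deleted = length(x$structure_match$deleted),
    mu_delta_percent = x$complexity$mu_delta_percent
  )
}

#' Plot the per-structure volume changes of a report
#'
#' Bar chart of relative volume change per structure with the alert
#' threshold drawn as dashed lines.
#'
#' @param object An `apart_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apart_report
#' @export
autoplot.apart_report <- function(object, ...) {
  vt <- object$volume_table
  thr <- object$config$thresholds$volume_diff_percent
  ggplot2::ggplot(vt, ggplot2::aes(
    x = stats::reorder(.data$name, .data$delta_percent),
    y = .data$delta_percent,
    fill = abs(.data$delta_percent) > thr
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "volume change [%]",
      title = sprintf("Structure volume changes (light: %s)", object$light$value)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
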