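# ggplot2 views of the result objects.

#' Tornado plot of a one-at-a-time sensitivity analysis
#'
#' Horizontal bars from the price at the parameter's minimum-column value to
#' the price at its maximum-column value, ordered by bar width, with a
#' vertical line at the average-scenario base price.
#'
#' @param object An `oat_sensitivity` tibble from [oat_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cfg <- lumasiran_config()
#' autoplot(oat_sensitivity(cfg, "ncp"))
#' @export
autoplot.oat_sensitivity <- function(object, ...) {
  df <- dplyr::mutate(
    object,
    parameter = stats::reorder(.data$parameter, .data$width),
    lo = pmin(.data$price_at_param_min, .data$price_at_param_max),
    hi = pmax(.data$price_at_param_min, .data$price_at_param_max)
  )
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$lo, xend = .data$hi, yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$base_price),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~model, scales = "free") +
    ggplot2::labs(x = "price per patient per year (EUR)", y = NULL,
                  title = "One-at-a-time sensitivity")
}

#' Plot a tornado diagram
#'
#' Convenience wrapper around [autoplot.oat_sensitivity()].
#'
#' @param sensitivity An `oat_sensitivity` tibble.
#' @return A ggplot object.
#' @export
plot_tornado <- function(sensitivity) {
  autoplot(sensitivity)
}

#' Scenario price ranges of one model
#'
#' @param object A `scenario_set`.
#' @param ... Unused.
#' @return A ggplot object: reported price per scenario.
#' @export
autoplot.scenario_set <- function(object, ...) {
  df <- glance(object)
  df$scenario <- factor(df$scenario, levels = c("min", "avg", "max"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                   y = .data$reported_price)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "reported price (EUR per patient per year)",
                  title = paste(toupper(object$model), "price scenarios"))
}

#' Stacked price-breakdown plot
#'
#' Component contributions to the price per patient per year, per model and
#' scenario, from a bundle's breakdown table.
#'
#' @param bundle A `report_bundle` (or any tibble with `model`, `scenario`,
#'   `component`, `eur` columns).
#' @return A ggplot object.
#' @export
plot_breakdown <- function(bundle) {
  df <- if (inherits(bundle, "report_bundle")) bundle$breakdown_table else bundle
  df$scenario <- factor(df$scenario, levels = c("min", "avg", "max"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data$eur,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "EUR per patient per year",
                  title = "Price breakdown by component")
}
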