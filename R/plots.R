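#' @importFrom ggplot2 ggplot aes geom_tile geom_col geom_line geom_point
#'   geom_boxplot geom_hline labs facet_wrap scale_fill_viridis_c autoplot
#'   theme_minimal coord_flip
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a static layer or effort field on the toy grid
#'
#' @param world An `ec_world`.
#' @param layer Column of [world_layers()] to map (default `"eez"`), or
#'   supply `panel`+`year` for log10 fishing hours.
#' @param panel Optional `ec_effort_panel`.
#' @param year Year to map when a panel is given.
#' @return A ggplot.
#' @export
plot_world <- function(world, layer = "eez", panel = NULL, year = NULL) {
  px <- world$pixels
  if (!is.null(panel)) {
    year <- year %||% max(panel$year)
    d <- filter(as_tibble(panel), .data$year == !!year)
    px <- left_join(px, select(d, "pixel_id", "hours"), by = "pixel_id")
    p <- ggplot(px, aes(.data$lon, .data$lat,
                        fill = log10(.data$hours + 1))) +
      geom_tile() +
      scale_fill_viridis_c(name = "log10(hours+1)", na.value = "grey30") +
      labs(title = sprintf("Fishing effort, %d", year))
  } else {
    p <- ggplot(px, aes(.data$lon, .data$lat, fill = .data[[layer]])) +
      geom_tile() +
      labs(title = layer)
  }
  p + theme_minimal() + labs(x = "lon", y = "lat")
}

#' Plot a scenario comparison
#'
#' `type = "aggregates"`: percent change from BAU per scope and horizon.
#' `type = "distance"`: median pixel-level percent change by distance bin
#' (the spatial-dissipation view).
#'
#' @param object An `ec_scenario_result`.
#' @param type Which panel to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_scenario_result <- function(object,
                                        type = c("aggregates", "distance"),
                                        ...) {
  type <- match.arg(type)
  if (type == "aggregates") {
    ggplot(object$aggregates,
           aes(.data$scope, .data$pct_diff, fill = factor(.data$horizon))) +
      geom_col(position = "dodge") +
      geom_hline(yintercept = 0, linetype = 2) +
      labs(x = NULL, y = "% change vs BAU", fill = "horizon (y)") +
      theme_minimal()
  } else {
    d <- mutate(object$distance,
                distance_bin = factor(.data$distance_bin,
                                      levels = object$bin_levels))
    ggplot(d, aes(.data$distance_bin, .data$median_pct,
                  group = factor(.data$horizon),
                  colour = factor(.data$horizon))) +
      geom_point() + geom_line() +
      geom_hline(yintercept = 0, linetype = 2) +
      labs(x = "distance to nearest MPA (pixel widths)",
           y = "median pixel % change vs BAU", colour = "horizon (y)") +
      theme_minimal()
  }
}

#' Plot Shapley feature importance
#'
#' Mean absolute Shapley value per feature (or per group when a `group_map`
#' is supplied).
#'
#' @param object An `ec_shapley`.
#' @param group_map Optional grouping (see [default_group_map()]).
#' @param top_n Features to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_shapley <- function(object, group_map = NULL, top_n = 15, ...) {
  d <- if (is.null(group_map)) {
    head(shapley_importance(object), top_n) |>
      rename(label = "feature")
  } else {
    group_shapley(object, group_map)$summary |>
      rename(label = "group")
  }
  ggplot(d, aes(stats::reorder(.data$label, .data$mean_abs_phi),
                .data$mean_abs_phi)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "mean |Shapley value|") +
    theme_minimal()
}

#' Plot a region-stratified metric report
#'
#' @param object An `ec_metric_report`.
#' @param metrics Metric columns to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ec_metric_report <- function(object,
                                      metrics = c("roc_auc", "f_meas",
                                                  "rsq_trad", "nrmse"),
                                      ...) {
  d <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric")
  has_h <- "horizon" %in% names(d)
  p <- ggplot(d, aes(.data$scope, .data$value,
                     colour = if (has_h) factor(.data$horizon) else NULL)) +
    geom_point(size = 2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = NULL, colour = "horizon (y)") +
    theme_minimal()
  p
}

#' Overlap-versus-area curve for candidate networks
#'
#' Percent of reference fishing effort covered against percent of ocean area
#' protected, per network.
#'
#' @param overlap Output of [overlap_curve()].
#' @return A ggplot.
#' @export
plot_overlap_curve <- function(overlap) {
  ggplot(overlap, aes(.data$area_pct, .data$effort_pct, label = .data$name)) +
    geom_point() + geom_line(aes(group = 1)) +
    labs(x = "% ocean area protected", y = "% reference effort covered") +
    theme_minimal()
}
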