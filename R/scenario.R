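#' Construct a hypothetical MPA network
#'
#' Closes whole pixels (full coverage, implemented January 1 of the base
#' year) until the target share of ocean *area* is reached, under one of the
#' ranking rules: `random` (seeded random pixel ranking), `most_fished`
#' (descending reference-year fishing hours, ties by pixel id ascending),
#' `unfished` (a seeded uniform sample among zero-effort pixels), or `file`
#' (externally supplied network in the canonical CSV dialect). Because each
#' ranked rule fixes one ranking per seed, networks are nested across
#' targets.
#'
#' @param world An `ec_world`.
#' @param rule One of `"random"`, `"most_fished"`, `"unfished"`, `"file"`.
#' @param target Ocean-area fraction to close (e.g. 0.10).
#' @param effort_reference Tibble `(pixel_id, hours)` for the reference year
#'   (required for `most_fished` and `unfished`).
#' @param base_year Implementation year of the hypothetical network.
#' @param seed Seed for the random rules.
#' @param path CSV path for `rule = "file"`.
#' @return An `ec_mpa_network` with attributes `rule` and `target`.
#' @export
build_network <- function(world, rule = c("random", "most_fished", "unfished",
                                          "file"),
                          target, effort_reference = NULL, base_year,
                          seed = 1, path = NULL) {
  rule <- match.arg(rule)
  if (rule == "file") {
    net <- read_network_csv(path)
    attr(net, "rule") <- "file"
    return(net)
  }
  check_range(target, "target", 0, 1)
  px <- filter(world$pixels, !.data$is_land)
  ocean_area <- sum(px$area_m2)

  ranking <- switch(rule,
    random = {
      set.seed(child_seed(seed, "network_random"))
      sample(px$pixel_id)
    },
    most_fished = {
      if (is.null(effort_reference)) {
        ec_validation_error("`most_fished` needs `effort_reference`")
      }
      ref <- inner_join(px, as_tibble(effort_reference), by = "pixel_id")
      ref$pixel_id[order(-ref$hours, ref$pixel_id)]
    },
    unfished = {
      if (is.null(effort_reference)) {
        ec_validation_error("`unfished` needs `effort_reference`")
      }
      ref <- inner_join(px, as_tibble(effort_reference), by = "pixel_id")
      zero <- ref$pixel_id[ref$hours == 0]
      set.seed(child_seed(seed, "network_unfished"))
      sample(zero)
    }
  )
  areas <- px$area_m2[match(ranking, px$pixel_id)]
  cum_share <- cumsum(areas) / ocean_area
  if (length(ranking) == 0 || max(cum_share) < target) {
    ec_abort(sprintf(
      "target %.0f%% unreachable under rule `%s`: max achievable %.1f%%",
      100 * target, rule, 100 * max(c(0, cum_share))))
  }
  k <- which(cum_share >= target)[1]
  closed <- ranking[seq_len(k)]
  net <- mpa_network(tibble(
    mpa_id = sprintf("scn_%s_%05d", rule, closed),
    pixel_id = closed, fraction = 1,
    implementation_date = as.Date(sprintf("%d-01-01", base_year)),
    no_take = TRUE
  ))
  attr(net, "rule") <- rule
  attr(net, "target") <- target
  net
}

# features for the base year under a given in-force network, aligned to the
# model's training schema
scenario_features <- function(world, environment, panel, network, base_year,
                              schema) {
  build_feature_table(world, environment, panel, network,
                      years = base_year,
                      groups = unique(schema$features$group),
                      schema = schema)
}

predict_network <- function(models, world, environment, panel, network,
                            base_year) {
  if (inherits(models, "ec_hurdle")) models <- list(models)
  schema <- models[[1]]$schema
  for (m in models) {
    if (!identical(m$schema$hash, schema$hash)) {
      ec_abort("per-horizon models disagree on the feature schema")
    }
  }
  ft <- scenario_features(world, environment, panel, network, base_year,
                          schema)
  areas <- world$pixels$area_m2[match(ft$pixel_id, world$pixels$pixel_id)]
  purrr::map(models, function(m) {
    pred <- predict_hours(m, ft, areas)
    tibble(pixel_id = ft$pixel_id,
           horizon = m$horizon %||% NA_integer_,
           hours = pred$hours)
  }) |>
    bind_rows()
}

#' Business-as-usual predictions
#'
#' Predicts per-pixel fishing hours for every forecast horizon with features
#' computed under the baseline (pre-existing) network only — the
#' counterfactual in which no new MPAs are implemented. A pure function of
#' the baseline network: scenario specifications never enter.
#'
#' @param models A list of fitted `ec_hurdle` models (one per horizon) on a
#'   common feature schema.
#' @param world,environment,panel The toy world, environment panel and
#'   effort panel (the panel supplies the base-year lag feature).
#' @param baseline_network The in-force `ec_mpa_network` (possibly empty: MPA
#'   features then take the documented no-MPA sentinels).
#' @param base_year Feature year from which all horizons are predicted.
#' @return Tibble `(pixel_id, horizon, hours)`.
#' @export
run_bau <- function(models, world, environment, panel, baseline_network,
                    base_year) {
  predict_network(models, world, environment, panel, baseline_network,
                  base_year)
}

#' Scenario predictions under an expanded network
#'
#' Recomputes the features with the union of the baseline network and the
#' hypothetical network (implemented January 1 of the base year, so the
#' fraction-of-year is 1, years-since is 0, and the future-coverage flags are
#' all false) and predicts per-pixel hours for every horizon.
#'
#' @inheritParams run_bau
#' @param scenario_network The hypothetical `ec_mpa_network` to add.
#' @return Tibble `(pixel_id, horizon, hours)`.
#' @export
run_scenario <- function(models, world, environment, panel, baseline_network,
                         scenario_network, base_year) {
  predict_network(models, world, environment, panel,
                  network_union(baseline_network, scenario_network),
                  base_year)
}

#' Compare scenario predictions to business-as-usual
#'
#' Pixel-level, regional (inside / partial / outside the scenario's full
#' network), global and distance-binned absolute and percent differences.
#' Aggregate percent change is `100 * (sum scenario - sum BAU) / sum BAU`;
#' pixels with zero BAU prediction are excluded from pixel-level percent
#' change (their count is reported) but kept in every aggregate sum.
#'
#' @param scenario_preds,bau_preds Tibbles `(pixel_id, horizon, hours)` on
#'   identical pixel/horizon sets.
#' @param world An `ec_world`.
#' @param network The scenario's full in-force network (baseline union
#'   hypothetical), used for regions and distances.
#' @param year Year at which to rasterize the network (default: latest
#'   implementation year).
#' @param bin_breaks_pw Distance bin breaks in pixel widths away from the
#'   network (default `c(1, 2, 4)`, giving bins 0-1, 1-2, 2-4, >4).
#' @return An `ec_scenario_result`: list with `pixel`, `aggregates`,
#'   `distance` tibbles and `n_zero_bau`.
#' @export
compare_scenarios <- function(scenario_preds, bau_preds, world, network,
                              year = NULL, bin_breaks_pw = c(1, 2, 4)) {
  s <- arrange(as_tibble(scenario_preds), .data$horizon, .data$pixel_id)
  b <- arrange(as_tibble(bau_preds), .data$horizon, .data$pixel_id)
  if (!identical(s[c("pixel_id", "horizon")], b[c("pixel_id", "horizon")])) {
    ec_abort("scenario and BAU predictions cover different pixels/horizons")
  }
  rec <- as_tibble(network)
  year <- year %||% if (nrow(rec) > 0) {
    max(as.integer(format(rec$implementation_date, "%Y")))
  } else {
    max(world$config$years)
  }
  cov <- rasterize_union(network, world, year)
  region <- tibble(
    pixel_id = cov$pixel_id,
    region = dplyr::case_when(cov$coverage >= 1 - 1e-9 ~ "inside",
                              cov$coverage > 0 ~ "partial",
                              TRUE ~ "outside")
  )
  dist_m <- rep(NA_real_, nrow(cov))
  if (any(cov$coverage > 0)) {
    dist_m <- graph_distance_to_set(world, cov$pixel_id[cov$coverage > 0])
  }
  pixel_width_m <- world$config$resolution_deg * pi * EARTH_RADIUS_M / 180
  dist_pw <- dist_m / pixel_width_m
  bin_levels <- c("inside", "partial",
                  paste0(c(0, head(bin_breaks_pw, -1)), "-", bin_breaks_pw),
                  paste0(">", bin_breaks_pw[length(bin_breaks_pw)]))
  bin_of <- function(reg, pw) {
    dplyr::case_when(
      reg == "inside" ~ "inside",
      reg == "partial" ~ "partial",
      TRUE ~ {
        idx <- findInterval(pw, c(0, bin_breaks_pw), rightmost.closed = FALSE)
        lab <- c(paste0(c(0, head(bin_breaks_pw, -1)), "-", bin_breaks_pw),
                 paste0(">", bin_breaks_pw[length(bin_breaks_pw)]))
        lab[idx]
      }
    )
  }

  pixel <- s |>
    rename(hours_scenario = "hours") |>
    mutate(hours_bau = b$hours,
           abs_diff = .data$hours_scenario - .data$hours_bau,
           pct_diff = if_else(.data$hours_bau > 0,
                              100 * .data$abs_diff / .data$hours_bau,
                              NA_real_)) |>
    left_join(region, by = "pixel_id") |>
    mutate(distance_m = dist_m[match(.data$pixel_id, cov$pixel_id)],
           distance_bin = bin_of(.data$region,
                                 dist_pw[match(.data$pixel_id, cov$pixel_id)]))

  agg <- function(d, scope) {
    d |>
      group_by(.data$horizon) |>
      summarise(scope = scope,
                hours_bau = sum(.data$hours_bau),
                hours_scenario = sum(.data$hours_scenario),
                abs_diff = sum(.data$abs_diff),
                pct_diff = if_else(sum(.data$hours_bau) > 0,
                                   100 * sum(.data$abs_diff) /
                                     sum(.data$hours_bau), NA_real_),
                n = n(), .groups = "drop")
  }
  aggregates <- bind_rows(
    agg(pixel, "global"),
    purrr::map(c("inside", "partial", "outside"), function(r) {
      d <- filter(pixel, .data$region == r)
      if (nrow(d) == 0) NULL else agg(d, r)
    })
  )
  distance <- pixel |>
    group_by(.data$horizon, .data$distance_bin) |>
    summarise(n = n(),
              median_pct = median(.data$pct_diff, na.rm = TRUE),
              hours_bau = sum(.data$hours_bau),
              hours_scenario = sum(.data$hours_scenario),
              abs_diff = sum(.data$abs_diff),
              pct_diff = if_else(sum(.data$hours_bau) > 0,
                                 100 * sum(.data$abs_diff) /
                                   sum(.data$hours_bau), NA_real_),
              .groups = "drop")

  structure(list(
    pixel = pixel, aggregates = aggregates, distance = distance,
    n_zero_bau = sum(b$hours == 0), bin_levels = bin_levels,
    pixel_width_m = pixel_width_m
  ), class = "ec_scenario_result")
}

#' @export
print.ec_scenario_result <- function(x, ...) {
  cat(sprintf("<ec_scenario_result> %d pixel-horizon rows (%d zero-BAU)\n",
              nrow(x$pixel), x$n_zero_bau))
  print(x$aggregates)
  invisible(x)
}

#' Overlap of candidate networks with reference fishing effort
#'
#' For each network: the percent of ocean area closed and the percent of
#' reference-year fishing hours occurring inside the closed pixels.
#'
#' @param networks A named list of `ec_mpa_network` objects (or one network).
#' @param effort_reference Tibble `(pixel_id, hours)`; total must be > 0.
#' @param world An `ec_world`.
#' @return Tibble `(name, area_pct, effort_pct)`.
#' @export
overlap_curve <- function(networks, effort_reference, world) {
  if (inherits(networks, "ec_mpa_network")) {
    networks <- list(network = networks)
  }
  ref <- as_tibble(effort_reference)
  if (sum(ref$hours) <= 0) ec_abort("reference effort sums to zero")
  px <- filter(world$pixels, !.data$is_land)
  ocean_area <- sum(px$area_m2)
  purrr::imap(networks, function(net, nm) {
    rec <- as_tibble(net)
    yr <- if (nrow(rec) > 0) {
      max(as.integer(format(rec$implementation_date, "%Y")))
    } else {
      max(world$config$years)
    }
    cov <- rasterize_union(net, world, yr)
    closed <- cov$pixel_id[cov$coverage > 0]
    w <- cov$coverage[cov$coverage > 0]
    area_pct <- 100 * sum(px$area_m2[match(closed, px$pixel_id)] * w) /
      ocean_area
    hrs <- ref$hours[match(closed, ref$pixel_id)]
    hrs[is.na(hrs)] <- 0
    effort_pct <- 100 * sum(hrs) / sum(ref$hours)
    tibble(name = nm, area_pct = area_pct, effort_pct = effort_pct)
  }) |>
    bind_rows()
}

#' Export a scenario result as tidy CSV + aggregate JSON
#'
#' @param result An `ec_scenario_result`.
#' @param prefix Output path prefix; writes `<prefix>_pixels.csv` and
#'   `<prefix>_aggregates.json`.
#' @export
write_scenario_result <- function(result, prefix) {
  readr::write_csv(result$pixel, paste0(prefix, "_pixels.csv"))
  write_json_file(list(
    aggregates = purrr::transpose(as.list(result$aggregates)),
    distance = purrr::transpose(as.list(result$distance)),
    n_zero_bau = result$n_zero_bau
  ), paste0(prefix, "_aggregates.json"))
  invisible(prefix)
}
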