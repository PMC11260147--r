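#' Behavioral response parameters for the effort generator
#'
#' Encodes the mechanisms the generator embeds as ground truth: suppression of
#' effort inside MPAs (with imperfect compliance), a distance-decaying change
#' just outside MPA boundaries (negative = the "reduced profitability"
#' response, positive = fishing-the-line), anticipatory effort in the year
#' before implementation (the "Blue Paradox"), and all-or-nothing fleet exit
#' when an MPA covers a large share of a fleet's grounds (the fixed-cost
#' mechanism).
#'
#' @param delta_inside Effort multiplier reduction inside MPAs, in `[0, 1]`.
#' @param compliance Fraction of the inside reduction realized, in `[0, 1]`.
#' @param delta_outside Signed near-boundary change; the outside multiplier is
#'   `1 + delta_outside * exp(-d / decay_km)`.
#' @param decay_km e-folding distance of the outside response (km).
#' @param anticipation Pre-implementation effort bump for to-be-covered
#'   pixels (>= 0; 0 disables it).
#' @param p_fleet_exit Probability a fleet leaves entirely once an MPA covers
#'   more than `exit_threshold` of its grounds (area-weighted).
#' @param exit_threshold Coverage share of a fleet's grounds that triggers the
#'   exit lottery.
#' @param trend Per-year multiplicative drift of baseline effort.
#' @param sigma_log Lognormal intensity dispersion (sd of log effort).
#' @return A validated `behavior_params` list.
#' @export
behavior_params <- function(delta_inside = 0.8, compliance = 1,
                            delta_outside = -0.3, decay_km = 1100,
                            anticipation = 0, p_fleet_exit = 0,
                            exit_threshold = 0.5, trend = 1.02,
                            sigma_log = 0.7) {
  bp <- list(delta_inside = delta_inside, compliance = compliance,
             delta_outside = delta_outside, decay_km = decay_km,
             anticipation = anticipation, p_fleet_exit = p_fleet_exit,
             exit_threshold = exit_threshold, trend = trend,
             sigma_log = sigma_log)
  check_range(bp$delta_inside, "delta_inside", 0, 1)
  check_range(bp$compliance, "compliance", 0, 1)
  check_range(bp$delta_outside, "delta_outside", -1, Inf)
  check_range(bp$decay_km, "decay_km", 0, Inf, lower_strict = TRUE)
  check_range(bp$anticipation, "anticipation", 0, Inf)
  check_range(bp$p_fleet_exit, "p_fleet_exit", 0, 1)
  check_range(bp$exit_threshold, "exit_threshold", 0, 1)
  check_range(bp$trend, "trend", 0, Inf, lower_strict = TRUE)
  check_range(bp$sigma_log, "sigma_log", 0, Inf)
  structure(bp, class = "behavior_params")
}

zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# per-pixel-year MPA multiplier applied by the generator.
# froy = 1 gives the fully implemented (closed-form) multiplier.
mpa_multiplier <- function(coverage, dist_m, froy_in, froy_out, behavior) {
  m <- rep(1, length(coverage))
  covered <- coverage > 0
  m[covered] <- 1 - behavior$delta_inside * behavior$compliance *
    coverage[covered] * froy_in[covered]
  out <- !covered & is.finite(dist_m)
  m[out] <- 1 + behavior$delta_outside *
    exp(-(dist_m[out] / 1000) / behavior$decay_km) * froy_out[out]
  pmax(m, 0)
}

#' Simulate hurdle-structured fishing effort with known MPA responses
#'
#' Occurrence is Bernoulli with logistic probability driven by a pixel's
#' environment, port distance and seamount proximity; positive effort is
#' lognormal around a pixel-specific mean with a multiplicative annual trend.
#' For pixel-years after an MPA's implementation the latent intensity is
#' multiplied by `1 - delta_inside * compliance * coverage` inside, and by
#' `1 + delta_outside * exp(-d / decay_km)` outside, where `d` is the
#' land-avoiding distance to the nearest implemented MPA. In the year of
#' implementation the response is scaled by the implemented fraction of that
#' year. Anticipation multiplies effort in the year before implementation for
#' to-be-covered pixels; a zero multiplier forces occurrence to zero; fleet
#' exit (one Bernoulli draw per EEZ-anchored fleet when triggered) zeroes the
#' fleet's contribution everywhere from the trigger year on.
#'
#' @param world An `ec_world`.
#' @param environment An `ec_env_panel` from [simulate_environment()].
#' @param network An `ec_mpa_network` (implementation dates must not postdate
#'   the simulated years).
#' @param behavior A [behavior_params()].
#' @param seed Integer seed (default: derived from the world seed).
#' @return An `ec_effort_panel` tibble of pixel-year rows: `hours`,
#'   `occurrence`, and the generator's latent truth (`occurrence_prob`,
#'   `latent_log_intensity` in log(h/m^2), `applied_multiplier`, `fleet`).
#' @export
simulate_effort <- function(world, environment, network = empty_network(),
                            behavior = behavior_params(), seed = NULL) {
  stopifnot(inherits(world, "ec_world"), inherits(environment, "ec_env_panel"))
  if (!inherits(behavior, "behavior_params")) {
    behavior <- do.call(behavior_params, behavior)
  }
  years <- sort(unique(environment$year))
  rec <- as_tibble(network)
  if (nrow(rec) > 0) {
    impl_years <- as.integer(format(rec$implementation_date, "%Y"))
    if (any(impl_years > max(years))) {
      ec_validation_error(
        "network implementation dates fall after the simulated years")
    }
  }
  seed <- seed %||% child_seed(world$config$seed, "effort")
  set.seed(seed)

  px <- filter(world$pixels, !.data$is_land)
  n <- nrow(px)
  pixel_re_occ <- rnorm(n, 0, 0.8)
  pixel_re_int <- rnorm(n, 0, 0.6)
  seamount_prox <- exp(-px$dist_seamount_m / 1.5e6)
  z_port <- zscore(log(px$dist_port_m + 1e4))

  per_year_mpa <- purrr::map(years, function(y) {
    mpa_state(world, network, y)
  })
  names(per_year_mpa) <- as.character(years)

  # fleet exit bookkeeping: one lottery per fleet, drawn the first year the
  # covered share of its grounds exceeds the threshold
  fleets <- px$eez
  exited <- setNames(rep(FALSE, length(unique(fleets))), unique(fleets))
  exit_year <- setNames(rep(Inf, length(unique(fleets))), unique(fleets))
  if (behavior$p_fleet_exit > 0) {
    for (y in years) {
      st <- per_year_mpa[[as.character(y)]]
      for (fl in unique(fleets)) {
        if (is.finite(exit_year[fl])) next
        sel <- fleets == fl
        share <- sum(px$area_m2[sel] * st$coverage[sel]) / sum(px$area_m2[sel])
        if (share > behavior$exit_threshold &&
            rbinom(1, 1, behavior$p_fleet_exit) == 1) {
          exit_year[fl] <- y
        }
      }
    }
  }

  rows <- purrr::map(seq_along(years), function(i) {
    y <- years[i]
    env <- filter(environment, .data$year == y) |> arrange(.data$pixel_id)
    stopifnot(identical(env$pixel_id, px$pixel_id))
    st <- per_year_mpa[[as.character(y)]]

    m <- mpa_multiplier(st$coverage, st$dist_m, st$froy, st$froy_near, behavior)
    if (behavior$anticipation > 0) {
      newly <- !is.na(st$new_cov_year) & st$new_cov_year == y + 1 &
        st$coverage == 0
      m[newly] <- m[newly] * (1 + behavior$anticipation)
    }
    gone <- is.finite(exit_year[fleets]) & y >= exit_year[fleets]
    eta <- 0.6 + 0.8 * zscore(env$sst_mean) + 0.9 * zscore(log(env$chl_mean)) -
      0.8 * z_port + 0.9 * seamount_prox + pixel_re_occ
    p <- plogis(eta)
    p[m == 0 | gone] <- 0
    occ <- rbinom(n, 1, p)

    mu <- log(150) - log(px$area_m2) + 0.5 * zscore(log(env$chl_mean)) +
      0.25 * zscore(env$sst_mean) - 0.5 * z_port + 0.5 * seamount_prox +
      pixel_re_int + log(behavior$trend) * (y - years[1])
    latent <- ifelse(m > 0 & !gone, mu + log(pmax(m, 1e-300)), -Inf)
    eps <- rnorm(n, 0, behavior$sigma_log)
    hours <- ifelse(occ == 1, exp(latent + eps) * px$area_m2, 0)

    tibble(pixel_id = px$pixel_id, year = y, hours = hours,
           occurrence = occ, occurrence_prob = p,
           latent_log_intensity = latent,
           applied_multiplier = ifelse(gone, 0, m), fleet = fleets)
  })
  panel <- bind_rows(rows)
  class(panel) <- c("ec_effort_panel", class(tibble()))
  panel
}

# per-year MPA state: union coverage, fraction-of-year in force, and the
# land-avoiding distance to the nearest implemented MPA pixel
mpa_state <- function(world, network, year) {
  cov <- rasterize_union(network, world, year)$coverage
  act <- active_records(network, year)
  n <- length(world$ocean_ids)
  froy <- rep(0, n)
  new_cov_year <- rep(NA_integer_, n)
  rec <- as_tibble(network)
  if (nrow(rec) > 0) {
    first_year <- rec[rec$no_take, ] |>
      group_by(.data$pixel_id) |>
      summarise(fy = min(as.integer(format(.data$implementation_date, "%Y"))),
                .groups = "drop")
    idx <- match(first_year$pixel_id, world$ocean_ids)
    new_cov_year[idx] <- first_year$fy
  }
  dist_m <- rep(Inf, n)
  froy_near <- rep(0, n)
  if (nrow(act) > 0) {
    by_pix <- act |>
      group_by(.data$pixel_id) |>
      summarise(froy = max(fraction_of_year(.data$implementation_date, year)),
                .groups = "drop")
    idx <- match(by_pix$pixel_id, world$ocean_ids)
    froy[idx] <- by_pix$froy
    src <- graph_distance_to_set(world, unique(act$pixel_id),
                                 return_source = TRUE)
    dist_m <- src$distance
    froy_near <- froy[match(src$source, world$ocean_ids)]
  }
  list(coverage = cov, froy = froy, dist_m = dist_m, froy_near = froy_near,
       new_cov_year = new_cov_year)
}

#' Closed-form expected percent change in effort under a network
#'
#' The recovery oracle: the exact expectation of the multipliers
#' [simulate_effort()] applies once the network is fully implemented
#' (fraction-of-year 1, no anticipation, no fleet exit). Because the
#' multiplier shifts the lognormal location and leaves occurrence untouched
#' (for positive multipliers), the expected percent change in hours is exactly
#' `100 * (multiplier - 1)`: a pixel fully inside with
#' `delta_inside * compliance = 0.8` changes by -80%.
#'
#' @param world An `ec_world`.
#' @param behavior A [behavior_params()].
#' @param network An `ec_mpa_network`.
#' @return Tibble per ocean pixel: `region` (inside/partial/outside),
#'   `distance_m` to the nearest MPA pixel, the applied `multiplier`, and
#'   `pct_change`.
#' @export
ground_truth_effect <- function(world, behavior, network) {
  stopifnot(inherits(world, "ec_world"))
  if (!inherits(behavior, "behavior_params")) {
    behavior <- do.call(behavior_params, behavior)
  }
  rec <- as_tibble(network)
  horizon_year <- if (nrow(rec) == 0) {
    max(world$config$years)
  } else {
    max(as.integer(format(rec$implementation_date, "%Y")))
  }
  cov <- rasterize_union(network, world, horizon_year)$coverage
  n <- length(world$ocean_ids)
  dist_m <- rep(Inf, n)
  if (any(cov > 0)) {
    dist_m <- graph_distance_to_set(world, world$ocean_ids[cov > 0])
  }
  m <- mpa_multiplier(cov, dist_m, rep(1, n), rep(1, n), behavior)
  tibble(
    pixel_id = world$ocean_ids,
    region = dplyr::case_when(cov >= 1 - 1e-9 ~ "inside",
                              cov > 0 ~ "partial",
                              TRUE ~ "outside"),
    coverage = cov, distance_m = dist_m, multiplier = m,
    pct_change = 100 * (m - 1)
  )
}

#' Export an effort panel to CSV
#'
#' Long format with the latent generator columns included when present.
#' @param panel An `ec_effort_panel`.
#' @param path Output CSV path.
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(as_tibble(panel), path)
  invisible(path)
}
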