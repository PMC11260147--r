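#' Simulate environmental covariates
#'
#' Emits an environment panel with, per pixel-year, the mean and standard
#' deviation of sea surface temperature (SST), SST anomaly, chlorophyll-a and
#' wind speed — the sd fields emulate aggregation from finer source
#' resolution — plus two global annual climate indices (ENSO- and PDO-like,
#' spatially constant) and an annual fuel price (mean/sd across months).
#'
#' SST carries a latitudinal gradient plus a year-specific anomaly shared
#' across the grid through the first climate index: the anomaly field is
#' `anomaly_sd * (index_loading * index1[year] + noise)`, so with
#' `anomaly_sd = 0` SST is identical across years within each pixel, and the
#' field-mean anomaly correlates strongly with the first index by
#' construction.
#'
#' @param world An `ec_world`.
#' @param years Years to simulate (default: the world's years).
#' @param anomaly_sd Scale of all year-varying SST terms (degrees C).
#' @param index_loading Weight of the first climate index in the SST anomaly,
#'   relative to pixel-level noise (sd 0.4).
#' @param seed Integer seed (default: derived from the world seed).
#' @return Tibble, one row per ocean pixel-year, of class `ec_env_panel`;
#'   the annual climate indices are also attached as attribute
#'   `climate_indices`.
#' @export
simulate_environment <- function(world, years = NULL, anomaly_sd = 0.6,
                                 index_loading = 1, seed = NULL) {
  stopifnot(inherits(world, "ec_world"))
  years <- years %||% world$config$years
  seed <- seed %||% child_seed(world$config$seed, "environment")
  set.seed(seed)

  px <- filter(world$pixels, !.data$is_land)
  n <- nrow(px)

  index1 <- rnorm(length(years))
  index2 <- rnorm(length(years))
  fuel_mean <- 380 + cumsum(rnorm(length(years), 0, 35))
  fuel_sd <- abs(rnorm(length(years), 25, 8))
  indices <- tibble(year = years, index1 = index1, index2 = index2,
                    fuel_price_mean = fuel_mean, fuel_price_sd = fuel_sd)

  sst_base <- 28 - 0.006 * px$lat^2 + rnorm(n, 0, 0.5)
  chl_base <- pmax(0.03, 2.2 * exp(-px$dist_shore_m / 2.5e6) + rnorm(n, 0, 0.12))
  wind_base <- 6 + 3 * abs(sin(px$lat * pi / 60)) + rnorm(n, 0, 0.4)

  rows <- purrr::map(seq_along(years), function(i) {
    anom <- anomaly_sd * (index_loading * index1[i] + rnorm(n, 0, 0.4))
    tibble(
      pixel_id = px$pixel_id, year = years[i],
      sst_mean = sst_base + anom,
      sst_sd = abs(rnorm(n, 1.2, 0.3)),
      sst_anom_mean = anom,
      sst_anom_sd = abs(rnorm(n, 0.5, 0.15)),
      chl_mean = pmax(0.01, chl_base * exp(anomaly_sd * rnorm(n, 0, 0.1))),
      chl_sd = abs(rnorm(n, 0.15, 0.05)),
      wind_mean = pmax(0.5, wind_base + anomaly_sd * rnorm(n, 0, 0.3)),
      wind_sd = abs(rnorm(n, 1, 0.25)),
      enso_mean = index1[i], enso_sd = abs(rnorm(1, 0.4, 0.1)),
      pdo_mean = index2[i], pdo_sd = abs(rnorm(1, 0.4, 0.1)),
      fuel_price_mean = fuel_mean[i], fuel_price_sd = fuel_sd[i]
    )
  })
  env <- bind_rows(rows)
  attr(env, "climate_indices") <- indices
  class(env) <- c("ec_env_panel", class(tibble()))
  env
}
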