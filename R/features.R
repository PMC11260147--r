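FEATURE_GROUPS <- c("mpa", "environmental", "geographic", "governance",
                    "economic", "technological", "residual")

#' Land-avoiding distance to the nearest MPA pixel
#'
#' Zero for any pixel that contains an MPA; computed on the 8-connected ocean
#' graph with great-circle centroid edge weights, so travel through land is
#' forbidden. Ocean pixels unreachable from every MPA pixel get `Inf` with a
#' warning (the caller decides how to handle them).
#'
#' @param world An `ec_world`.
#' @param mpa_pixels Nonempty set of ocean pixel ids containing MPAs.
#' @return Tibble `(pixel_id, distance_m)` over all ocean pixels.
#' @export
mpa_distance <- function(world, mpa_pixels) {
  d <- graph_distance_to_set(world, mpa_pixels)
  tibble(pixel_id = world$ocean_ids, distance_m = d)
}

#' MPA implementation features for every ocean pixel
#'
#' Computes, for a query year, the distance to the nearest implemented MPA,
#' years since its designation (oldest MPA when several overlap the pixel;
#' 0 if designated this year), the union coverage fraction of the pixel and of
#' its first- and second-degree Moore neighborhoods (area-weighted ring
#' means, land cells counting as uncovered), the inside/partial/outside
#' region, and the implemented fraction of the query year. Before the first
#' MPA exists, distance takes the documented sentinel (twice the maximum
#' pairwise grid distance) and years-since is -1.
#'
#' @param world An `ec_world`.
#' @param network An `ec_mpa_network`.
#' @param year Query calendar year.
#' @return Tibble per ocean pixel with columns `mpa_distance_m`,
#'   `mpa_years_since`, `mpa_frac_pixel`, `mpa_frac_nb1`, `mpa_frac_nb2`,
#'   `mpa_region`, `mpa_frac_of_year`.
#' @export
mpa_pixel_features <- function(world, network, year) {
  stopifnot(inherits(world, "ec_world"))
  ocean <- world$ocean_ids
  n <- length(ocean)
  act <- active_records(network, year)
  if (nrow(act) == 0) {
    return(tibble(
      pixel_id = ocean,
      mpa_distance_m = world$no_mpa_sentinel, mpa_years_since = -1,
      mpa_frac_pixel = 0, mpa_frac_nb1 = 0, mpa_frac_nb2 = 0,
      mpa_region = "outside", mpa_frac_of_year = 0
    ))
  }
  cov <- rasterize_union(network, world, year)$coverage

  # oldest designation year per covered pixel
  first_year <- act |>
    group_by(.data$pixel_id) |>
    summarise(desig = min(as.integer(format(.data$implementation_date, "%Y"))),
              froy = max(fraction_of_year(.data$implementation_date, year)),
              .groups = "drop")
  desig <- setNames(first_year$desig, first_year$pixel_id)
  froy_pix <- rep(0, n)
  froy_pix[match(first_year$pixel_id, ocean)] <- first_year$froy

  src <- graph_distance_to_set(world, unique(act$pixel_id), return_source = TRUE)
  dist_m <- src$distance
  dist_m[cov > 0] <- 0
  nearest_pix <- src$source
  nearest_pix[cov > 0] <- ocean[cov > 0]
  years_since <- year - unname(desig[as.character(nearest_pix)])

  # ring coverage over the full grid (land = 0)
  px <- world$pixels
  cov_all <- rep(0, nrow(px))
  cov_all[ocean] <- cov
  nb_mean <- function(ring) {
    vapply(ocean, function(i) {
      nb <- ring_neighbors(px$row[i], px$col[i], ring, world$config$n_lat,
                           world$config$n_lon, world$wrap)
      if (length(nb) == 0) return(0)
      sum(cov_all[nb] * px$area_m2[nb]) / sum(px$area_m2[nb])
    }, numeric(1))
  }

  tibble(
    pixel_id = ocean,
    mpa_distance_m = dist_m,
    mpa_years_since = years_since,
    mpa_frac_pixel = cov,
    mpa_frac_nb1 = nb_mean(1L),
    mpa_frac_nb2 = nb_mean(2L),
    mpa_region = dplyr::case_when(cov >= 1 - 1e-9 ~ "inside",
                                  cov > 0 ~ "partial",
                                  TRUE ~ "outside"),
    mpa_frac_of_year = ifelse(cov > 0, froy_pix, 0)
  )
}

#' Anticipatory future-coverage flags
#'
#' Four booleans per ocean pixel: whether an MPA implemented in `year + 1` or
#' `year + 2` will fully or partially cover it. Computed from the network's
#' implementation dates only — effort data never leak in.
#'
#' @param world An `ec_world`.
#' @param network An `ec_mpa_network`.
#' @param year Query calendar year.
#' @return Tibble per ocean pixel: `mpa_lead1_full`, `mpa_lead1_partial`,
#'   `mpa_lead2_full`, `mpa_lead2_partial`.
#' @export
future_coverage_flags <- function(world, network, year) {
  stopifnot(inherits(world, "ec_world"))
  ocean <- world$ocean_ids
  rec <- as_tibble(network)
  rec <- rec[rec$no_take, , drop = FALSE]
  lead_cov <- function(lead) {
    ry <- as.integer(format(rec$implementation_date, "%Y"))
    sub <- rec[ry == year + lead, , drop = FALSE]
    cov <- rep(0, length(ocean))
    if (nrow(sub) > 0) {
      by_pix <- sub |>
        group_by(.data$pixel_id) |>
        summarise(c = interval_union_measure(.data$offset, .data$fraction),
                  .groups = "drop")
      cov[match(by_pix$pixel_id, ocean)] <- by_pix$c
    }
    cov
  }
  c1 <- lead_cov(1L); c2 <- lead_cov(2L)
  tibble(
    pixel_id = ocean,
    mpa_lead1_full = c1 >= 1 - 1e-9,
    mpa_lead1_partial = c1 > 0 & c1 < 1 - 1e-9,
    mpa_lead2_full = c2 >= 1 - 1e-9,
    mpa_lead2_partial = c2 > 0 & c2 < 1 - 1e-9
  )
}

#' Governance features per ocean pixel
#'
#' Sovereign EEZ label (labels covering less than `min_share` of the training
#' pixels collapse to `"other"`), the fraction of the pixel covered by its
#' assigned EEZ (0 on the high seas), the land-avoiding distance to the
#' nearest EEZ pixel (0 inside an EEZ), the nearest sovereign, and the
#' sovereign's region and governance-capacity categories.
#'
#' @param world An `ec_world`.
#' @param training_pixels Pixel ids defining the bucketing population
#'   (default: all ocean pixels). Must be nonempty.
#' @param min_share Collapse threshold (default 1%).
#' @return Tibble per ocean pixel with columns `eez_sovereign`,
#'   `eez_fraction`, `eez_distance_m`, `eez_nearest_sovereign`, `wb_region`,
#'   `gov_capacity`.
#' @export
assign_eez_features <- function(world, training_pixels = NULL,
                                min_share = 0.01) {
  stopifnot(inherits(world, "ec_world"))
  training_pixels <- training_pixels %||% world$ocean_ids
  if (length(training_pixels) == 0) {
    ec_validation_error("empty training set: EEZ label bucketing is undefined")
  }
  px <- filter(world$pixels, !.data$is_land)
  train <- filter(px, .data$pixel_id %in% training_pixels)
  share <- table(train$eez) / nrow(train)
  keep <- names(share)[share >= min_share | names(share) == "high_seas"]
  collapse <- function(x) if_else(x %in% keep, x, "other")

  sovereign <- collapse(px$eez)
  eez_pix <- px$pixel_id[px$eez != "high_seas"]
  if (length(eez_pix) > 0) {
    src <- graph_distance_to_set(world, eez_pix, return_source = TRUE)
    d <- src$distance
    nearest <- collapse(px$eez[match(src$source, px$pixel_id)])
    inside <- px$eez != "high_seas"
    d[inside] <- 0
    nearest[inside] <- sovereign[inside]
    unreachable <- !is.finite(d)
    d[unreachable] <- world$no_mpa_sentinel
    nearest[unreachable] <- "high_seas"
  } else {
    d <- rep(world$no_mpa_sentinel, nrow(px))
    nearest <- rep("high_seas", nrow(px))
  }
  tibble(
    pixel_id = px$pixel_id,
    eez_sovereign = sovereign,
    eez_fraction = px$eez_fraction,
    eez_distance_m = d,
    eez_nearest_sovereign = nearest,
    wb_region = px$wb_region,
    gov_capacity = px$gov_capacity
  )
}

#' Lagged log effort per pixel-year
#'
#' The residual-effects feature: `log(hours / pixel area)` at `year - lag`.
#' Zero-effort pixel-years take a documented floor — one log unit below the
#' smallest positive value in the supplied panel — so the feature is defined
#' everywhere; the accompanying flag records where the floor was used.
#'
#' @param panel An `ec_effort_panel` (or any tibble with `pixel_id`, `year`,
#'   `hours`).
#' @param world An `ec_world` (provides pixel areas).
#' @param lag Lag in years (0 = the row's own year; the lead-dataset
#'   construction then makes it a horizon-length lag of the outcome).
#' @param years Feature years to emit (default: all years with a lag year in
#'   the panel). Requesting a year whose lag year is absent is an error.
#' @param floor Optional fixed floor value (reused at prediction time from
#'   the training schema).
#' @return Tibble `(pixel_id, year, lag_log_effort, lag_is_floor)` with the
#'   floor attached as attribute `log_floor`.
#' @export
lagged_log_effort <- function(panel, world, lag = 1, years = NULL,
                              floor = NULL) {
  stopifnot(inherits(world, "ec_world"))
  panel <- as_tibble(panel)
  areas <- setNames(world$pixels$area_m2, world$pixels$pixel_id)
  pos <- panel$hours > 0
  if (is.null(floor)) {
    if (!any(pos)) ec_validation_error("panel has no positive effort; floor undefined")
    floor <- min(log(panel$hours[pos] /
                       areas[as.character(panel$pixel_id[pos])])) - 1
  }
  panel_years <- sort(unique(panel$year))
  years <- years %||% (panel_years[(panel_years - lag) %in% panel_years])
  missing <- setdiff(years - lag, panel_years)
  if (length(missing) > 0) {
    ec_abort(sprintf("panel is missing lag year(s): %s",
                     paste(sort(missing), collapse = ", ")))
  }
  src <- panel |>
    mutate(value = if_else(
      .data$hours > 0,
      log(.data$hours / unname(areas[as.character(.data$pixel_id)])),
      floor
    ), is_floor = .data$hours == 0) |>
    select("pixel_id", src_year = "year", "value", "is_floor")
  out <- tidyr::expand_grid(year = years,
                            pixel_id = sort(unique(panel$pixel_id))) |>
    mutate(src_year = .data$year - lag) |>
    inner_join(src, by = c("pixel_id", "src_year")) |>
    select("pixel_id", "year", lag_log_effort = "value",
           lag_is_floor = "is_floor") |>
    arrange(.data$year, .data$pixel_id)
  attr(out, "log_floor") <- floor
  out
}

feature_spec_table <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~name, ~group, ~type,
    "mpa_distance_m", "mpa", "numeric",
    "mpa_years_since", "mpa", "numeric",
    "mpa_frac_pixel", "mpa", "numeric",
    "mpa_frac_nb1", "mpa", "numeric",
    "mpa_frac_nb2", "mpa", "numeric",
    "mpa_region", "mpa", "categorical",
    "mpa_frac_of_year", "mpa", "numeric",
    "mpa_lead1_full", "mpa", "boolean",
    "mpa_lead1_partial", "mpa", "boolean",
    "mpa_lead2_full", "mpa", "boolean",
    "mpa_lead2_partial", "mpa", "boolean",
    "sst_mean", "environmental", "numeric",
    "sst_sd", "environmental", "numeric",
    "sst_anom_mean", "environmental", "numeric",
    "sst_anom_sd", "environmental", "numeric",
    "chl_mean", "environmental", "numeric",
    "chl_sd", "environmental", "numeric",
    "wind_mean", "environmental", "numeric",
    "wind_sd", "environmental", "numeric",
    "enso_mean", "environmental", "numeric",
    "enso_sd", "environmental", "numeric",
    "pdo_mean", "environmental", "numeric",
    "pdo_sd", "environmental", "numeric",
    "lat", "geographic", "numeric",
    "lon", "geographic", "numeric",
    "dist_shore_m", "geographic", "numeric",
    "dist_seamount_m", "geographic", "numeric",
    "depth_m", "geographic", "numeric",
    "ocean", "geographic", "categorical",
    "mesopelagic", "geographic", "categorical",
    "eez_sovereign", "governance", "categorical",
    "eez_fraction", "governance", "numeric",
    "eez_distance_m", "governance", "numeric",
    "eez_nearest_sovereign", "governance", "categorical",
    "wb_region", "governance", "categorical",
    "gov_capacity", "governance", "categorical",
    "dist_port_m", "economic", "numeric",
    "fuel_price_mean", "economic", "numeric",
    "fuel_price_sd", "economic", "numeric",
    "ais_a", "technological", "numeric",
    "ais_b", "technological", "numeric",
    "lag_log_effort", "residual", "numeric",
    "year", "residual", "numeric"
  )
}

#' Assemble the model feature table
#'
#' One row per ocean pixel-year with the full configured feature set: MPA
#' implementation (11 features), environmental (12), geographic (7),
#' governance (6), economic (3), technological (2) and residual effects (2).
#' Categorical levels are fixed when the table is first built and reused
#' verbatim at prediction time through the attached schema; the zero-effort
#' log floor and the no-MPA distance sentinel are recorded there too.
#'
#' @param world An `ec_world`.
#' @param environment An `ec_env_panel`.
#' @param panel An `ec_effort_panel` (source of the lagged-effort feature).
#' @param network An `ec_mpa_network`.
#' @param years Feature years to emit (default: all environment years present
#'   in the panel).
#' @param groups Feature groups to include (default: all).
#' @param schema A schema from a previous build, to reuse its categorical
#'   levels and log floor at prediction time.
#' @return An `ec_feature_table` tibble with id columns `pixel_id`, `year`
#'   and attribute `schema` (features, levels, floor, sentinel, hash).
#' @export
build_feature_table <- function(world, environment, panel, network,
                                years = NULL, groups = FEATURE_GROUPS,
                                schema = NULL) {
  stopifnot(inherits(world, "ec_world"))
  groups <- match.arg(groups, FEATURE_GROUPS, several.ok = TRUE)
  years <- years %||% intersect(sort(unique(environment$year)),
                                sort(unique(panel$year)))
  if (length(years) == 0) ec_validation_error("no feature years to build")

  px <- filter(world$pixels, !.data$is_land)
  gov <- assign_eez_features(world)
  lag <- lagged_log_effort(panel, world, lag = 0, years = years,
                           floor = schema$log_floor %||% NULL)

  static <- px |>
    select("pixel_id", "lat", "lon", "dist_shore_m", "dist_seamount_m",
           "depth_m", "ocean", "mesopelagic", "dist_port_m", "ais_a",
           "ais_b") |>
    left_join(gov, by = "pixel_id")

  per_year <- purrr::map(years, function(y) {
    mpa <- mpa_pixel_features(world, network, y)
    flags <- future_coverage_flags(world, network, y)
    env_y <- filter(as_tibble(environment), .data$year == y)
    static |>
      mutate(year = y) |>
      left_join(mpa, by = "pixel_id") |>
      left_join(flags, by = "pixel_id") |>
      left_join(select(env_y, -"year") |> mutate(pixel_id = env_y$pixel_id),
                by = "pixel_id")
  })
  ft <- bind_rows(per_year) |>
    left_join(select(lag, "pixel_id", "year", "lag_log_effort"),
              by = c("pixel_id", "year"))

  spec <- feature_spec_table()
  spec <- spec[spec$group %in% groups, , drop = FALSE]
  id_cols <- c("pixel_id", "year")
  ft <- ft[, unique(c(id_cols, spec$name)), drop = FALSE]

  # no missing values after assembly
  for (f in spec$name) {
    bad <- which(is.na(ft[[f]]))
    if (length(bad) > 0) {
      ec_abort(sprintf(
        "feature `%s` is undefined for %d row(s), e.g. pixel %d year %d",
        f, length(bad), ft$pixel_id[bad[1]], ft$year[bad[1]]))
    }
  }

  if (is.null(schema)) {
    cats <- spec$name[spec$type == "categorical"]
    levels <- lapply(setNames(cats, cats), function(f) {
      if (f == "mpa_region") c("inside", "partial", "outside")
      else sort(unique(c(ft[[f]], if (f == "eez_sovereign" ||
                                      f == "eez_nearest_sovereign") "other")))
    })
    schema <- list(
      features = spec, levels = levels,
      log_floor = attr(lag, "log_floor"),
      no_mpa_sentinel = world$no_mpa_sentinel,
      version = 1L
    )
    schema$hash <- rlang::hash(schema[c("features", "levels", "version")])
  } else {
    # prediction time: categorical levels must be reusable verbatim
    for (f in names(schema$levels)) {
      if (!f %in% names(ft)) next
      unseen <- setdiff(unique(ft[[f]]), schema$levels[[f]])
      if (length(unseen) > 0) {
        if ("other" %in% schema$levels[[f]]) {
          ft[[f]][ft[[f]] %in% unseen] <- "other"
        } else {
          ec_abort(sprintf("feature `%s` has level(s) unseen at training: %s",
                           f, paste(unseen, collapse = ", ")))
        }
      }
    }
  }
  structure(ft, schema = schema,
            class = c("ec_feature_table", class(tibble())))
}

#' Schema of a feature table
#' @param ft An `ec_feature_table` (or lead dataset carrying a schema).
#' @return The schema list (features, levels, log floor, sentinel, hash).
#' @export
feature_schema <- function(ft) attr(ft, "schema")

# model design frame: categoricals as factors with schema levels
schema_design <- function(data, schema) {
  out <- as.data.frame(data[, schema$features$name, drop = FALSE])
  for (f in names(schema$levels)) {
    out[[f]] <- factor(out[[f]], levels = schema$levels[[f]])
  }
  for (f in schema$features$name[schema$features$type == "boolean"]) {
    out[[f]] <- as.numeric(out[[f]])
  }
  out
}

#' Write a feature table with its JSON schema sidecar
#'
#' @param ft An `ec_feature_table`.
#' @param path CSV path; the schema is written to `<path>.schema.json`.
#' @export
write_feature_table <- function(ft, path) {
  readr::write_csv(as_tibble(ft), path)
  sc <- feature_schema(ft)
  write_json_file(list(
    features = sc$features, levels = sc$levels, log_floor = sc$log_floor,
    no_mpa_sentinel = sc$no_mpa_sentinel, version = sc$version,
    hash = sc$hash
  ), paste0(path, ".schema.json"))
  invisible(path)
}
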