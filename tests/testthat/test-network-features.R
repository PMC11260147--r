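ocean5 <- function() manual_world(matrix(FALSE, 5, 5), res = 10)

test_that("union coverage uses interval-union semantics, never a sum", {
  w <- ocean5()
  pid <- w$ocean_ids[1]
  # two MPAs each covering 60% with a known 30% joint overlap -> 0.9
  net <- mpa_network(tibble::tibble(
    mpa_id = c("a", "b"), pixel_id = pid, fraction = c(0.6, 0.6),
    offset = c(0, 0.3),
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  cov <- rasterize_union(net, w, 2020)
  expect_equal(cov$coverage[cov$pixel_id == pid], 0.9)

  # nested (default offset) records never exceed the largest fraction
  net2 <- mpa_network(tibble::tibble(
    mpa_id = c("a", "b"), pixel_id = pid, fraction = c(0.6, 0.6),
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  expect_equal(rasterize_union(net2, w, 2020)$coverage[1], 0.6)

  # implemented after the query year -> 0
  net3 <- mpa_network(tibble::tibble(
    mpa_id = "late", pixel_id = pid, fraction = 1,
    implementation_date = as.Date("2021-03-01"), no_take = TRUE))
  expect_equal(rasterize_union(net3, w, 2020)$coverage[1], 0)
  expect_equal(rasterize_union(net3, w, 2021)$coverage[1], 1)

  # single-MPA map returned unchanged
  net4 <- mpa_network(tibble::tibble(
    mpa_id = "solo", pixel_id = w$ocean_ids[1:3], fraction = c(1, 0.4, 0.7),
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  cov4 <- rasterize_union(net4, w, 2020)
  expect_equal(cov4$coverage[1:3], c(1, 0.4, 0.7))

  # unknown pixel id names the offending record
  bad <- mpa_network(tibble::tibble(
    mpa_id = "ghost", pixel_id = 999L, fraction = 1,
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  expect_error(rasterize_union(bad, w, 2020), "ghost")
})

test_that("union coverage is monotone non-decreasing in year", {
  w <- fixture_world()
  net <- fixture_history()
  yrs <- w$config$years
  covs <- sapply(yrs, function(y) rasterize_union(net, w, y)$coverage)
  expect_true(all(diff(t(covs)) >= -1e-12))
})

test_that("fraction of year follows the day-count convention, leap-aware", {
  expect_equal(fraction_of_year(as.Date("2019-01-01"), 2019), 1)
  expect_equal(fraction_of_year(as.Date("2019-07-02"), 2019), 183 / 365,
               tolerance = 1e-12)
  # leap year has 366 days
  expect_equal(fraction_of_year(as.Date("2020-12-31"), 2020), 1 / 366)
  expect_equal(fraction_of_year(as.Date("2018-05-05"), 2019), 1)
  expect_equal(fraction_of_year(as.Date("2021-01-01"), 2019), 0)
})

test_that("mpa_distance is zero at MPA pixels and haversine for neighbors", {
  w <- ocean5()
  src <- w$ocean_ids[13]  # centre
  d <- mpa_distance(w, src)
  expect_equal(d$distance_m[d$pixel_id == src], 0)
  px <- w$pixels
  nb <- d$pixel_id == 14  # open-water east neighbor, no land anywhere
  direct <- gc_distance(px$lon[13], px$lat[13], px$lon[14], px$lat[14])
  expect_equal(d$distance_m[nb], direct)
})

test_that("a land wall forces the detour the shortest-path oracle predicts", {
  land <- matrix(FALSE, 5, 5)
  land[1:4, 3] <- TRUE  # wall with a gap at the bottom row
  w <- manual_world(land, res = 10)
  src <- w$pixels$pixel_id[w$pixels$row == 1 & w$pixels$col == 1]
  d <- mpa_distance(w, src)
  oracle <- dijkstra_to_set(w, src)
  expect_equal(d$distance_m, oracle, tolerance = 1e-9)
  # the pixel across the wall is much farther than the direct line
  tgt_idx <- which(d$pixel_id ==
                     w$pixels$pixel_id[w$pixels$row == 1 & w$pixels$col == 5])
  direct <- gc_distance(-20, 20, 20, 20)
  expect_gt(d$distance_m[tgt_idx], 1.5 * direct)
})

test_that("unreachable ocean pixels get an Inf distance with a warning", {
  land <- matrix(FALSE, 5, 5)
  land[, 3] <- TRUE  # full wall
  w <- manual_world(land, res = 10)
  src <- w$pixels$pixel_id[w$pixels$row == 1 & w$pixels$col == 1]
  expect_warning(d <- mpa_distance(w, src), "unreachable")
  right <- w$pixels$col[match(d$pixel_id, w$pixels$pixel_id)] > 3
  expect_true(all(is.infinite(d$distance_m[right])))
  expect_true(all(is.finite(d$distance_m[!right])))
})

test_that("MPA pixel features cover all documented conventions", {
  w <- ocean5()
  in_pix <- w$ocean_ids[7]
  net <- mpa_network(tibble::tibble(
    mpa_id = c("old", "old", "young"),
    pixel_id = c(in_pix, 8L, 9L), fraction = c(1, 0.5, 1),
    implementation_date = as.Date(c("2016-07-02", "2016-07-02",
                                    "2018-01-01")),
    no_take = TRUE))
  f18 <- mpa_pixel_features(w, net, 2018)
  r7 <- f18[f18$pixel_id == in_pix, ]
  expect_equal(r7$mpa_distance_m, 0)
  expect_equal(r7$mpa_years_since, 2)          # oldest MPA governs
  expect_equal(r7$mpa_frac_pixel, 1)
  expect_equal(r7$mpa_region, "inside")
  expect_equal(r7$mpa_frac_of_year, 1)         # implemented in a prior year
  r8 <- f18[f18$pixel_id == 8, ]
  expect_equal(r8$mpa_region, "partial")
  r9 <- f18[f18$pixel_id == 9, ]
  expect_equal(r9$mpa_years_since, 0)          # designated this year
  expect_equal(r9$mpa_frac_of_year, 1)         # Jan 1 implementation
  out <- f18[!f18$pixel_id %in% c(7, 8, 9), ]
  expect_true(all(out$mpa_frac_of_year == 0))  # outside pixels always 0
  expect_true(all(out$mpa_region == "outside"))
  expect_true(all(out$mpa_distance_m > 0))

  # mid-year implementation year: fraction of that (leap) year
  f16 <- mpa_pixel_features(w, net, 2016)
  expect_equal(f16$mpa_frac_of_year[f16$pixel_id == in_pix], 183 / 366,
               tolerance = 1e-12)

  # region partition is exhaustive and disjoint for every year
  for (y in 2016:2019) {
    f <- mpa_pixel_features(w, net, y)
    expect_setequal(f$pixel_id, w$ocean_ids)
    expect_true(all(f$mpa_region %in% c("inside", "partial", "outside")))
  }
})

test_that("neighborhood fractions are area-weighted Moore-ring means", {
  w <- ocean5()
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = 13L, fraction = 1,
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  f <- mpa_pixel_features(w, net, 2018)
  px <- w$pixels
  # ring-1 of pixel 7 contains the covered pixel 13 among its 8 neighbors
  ring1 <- effortcast:::ring_neighbors(px$row[7], px$col[7], 1L, 5L, 5L, FALSE)
  expected <- px$area_m2[13] / sum(px$area_m2[ring1])
  expect_equal(f$mpa_frac_nb1[f$pixel_id == 7], expected, tolerance = 1e-12)
  # ring-2 of pixel 13 excludes pixel 13 itself -> 0
  expect_equal(f$mpa_frac_nb2[f$pixel_id == 13], 0)
})

test_that("before any MPA exists the documented sentinels apply", {
  w <- ocean5()
  net <- mpa_network(tibble::tibble(
    mpa_id = "future", pixel_id = 13L, fraction = 1,
    implementation_date = as.Date("2019-06-01"), no_take = TRUE))
  f <- mpa_pixel_features(w, net, 2017)
  expect_true(all(f$mpa_distance_m == w$no_mpa_sentinel))
  expect_true(all(f$mpa_years_since == -1))
  expect_true(all(f$mpa_frac_pixel == 0))
})

test_that("future-coverage flags fire on network dates only", {
  w <- ocean5()
  net <- mpa_network(tibble::tibble(
    mpa_id = c("full1", "part2"), pixel_id = c(7L, 9L), fraction = c(1, 0.4),
    implementation_date = as.Date(c("2018-03-01", "2019-08-01")),
    no_take = TRUE))
  f17 <- future_coverage_flags(w, net, 2017)
  r7 <- f17[f17$pixel_id == 7, ]
  expect_equal(unlist(r7[, -1]),
               c(mpa_lead1_full = TRUE, mpa_lead1_partial = FALSE,
                 mpa_lead2_full = FALSE, mpa_lead2_partial = FALSE))
  r9 <- f17[f17$pixel_id == 9, ]
  expect_true(r9$mpa_lead2_partial)
  expect_false(any(unlist(r9[, c("mpa_lead1_full", "mpa_lead1_partial",
                                 "mpa_lead2_full")])))
  # no future MPA -> all false
  f19 <- future_coverage_flags(w, net, 2019)
  expect_false(any(unlist(f19[, -1])))
})

test_that("EEZ features follow the assignment and bucketing rules", {
  w <- fixture_world()
  g <- assign_eez_features(w)
  px <- dplyr::filter(w$pixels, !is_land)
  hs <- g[g$eez_sovereign == "high_seas", ]
  expect_true(all(hs$eez_fraction == 0))
  expect_true(all(hs$eez_distance_m > 0 | nrow(hs) == 0))
  ins <- g[g$eez_sovereign != "high_seas", ]
  expect_true(all(ins$eez_distance_m == 0))
  expect_true(all(ins$eez_nearest_sovereign == ins$eez_sovereign))

  # a sovereign holding under 1% of the training pixels collapses to "other"
  big <- names(which.max(table(px$eez[px$eez != "high_seas"])))
  small <- setdiff(unique(px$eez), c("high_seas", big))[1]
  keep_small <- px$pixel_id[px$eez == small][1]
  train <- c(px$pixel_id[px$eez != small], keep_small)
  g2 <- assign_eez_features(w, training_pixels = train, min_share = 0.05)
  expect_true(all(g2$eez_sovereign[g2$pixel_id %in%
                                     px$pixel_id[px$eez == small]] == "other"))
  expect_error(assign_eez_features(w, training_pixels = integer(0)),
               "empty training")
})

test_that("lagged log effort floors zeros and respects log identities", {
  w <- ocean5()
  pid <- w$ocean_ids[1:3]
  area <- w$pixels$area_m2[pid]
  panel <- tibble::tibble(
    pixel_id = rep(pid, 2), year = rep(2016:2017, each = 3),
    hours = c(area[1], 2 * area[1], 0, 100, 200, 50))
  lag <- lagged_log_effort(panel, w, lag = 1)
  r <- lag[lag$year == 2017, ]
  expect_equal(r$lag_log_effort[r$pixel_id == pid[1]], 0)        # hours = area
  expect_equal(r$lag_log_effort[r$pixel_id == pid[2]], log(2))   # doubling
  floor_val <- attr(lag, "log_floor")
  expect_equal(r$lag_log_effort[r$pixel_id == pid[3]], floor_val)
  expect_true(r$lag_is_floor[r$pixel_id == pid[3]])
  expect_lt(floor_val, min(log(panel$hours[panel$hours > 0] /
                                 rep(area, 2)[panel$hours > 0])))
  expect_error(lagged_log_effort(panel, w, lag = 1, years = 2016), "2015")
})

test_that("feature table emits the documented schema deterministically", {
  ft <- fixture_features()
  sc <- feature_schema(ft)
  counts <- table(sc$features$group)
  expect_equal(as.integer(counts[c("mpa", "environmental", "geographic",
                                   "governance", "economic", "technological",
                                   "residual")]),
               c(11L, 12L, 7L, 6L, 3L, 2L, 2L))
  expect_false(anyNA(as_tibble(ft)[, sc$features$name]))

  # toggling the governance group off removes exactly its 6 features
  ft2 <- build_feature_table(fixture_world(), fixture_env(), fixture_panel(),
                             fixture_history(),
                             groups = setdiff(effortcast:::FEATURE_GROUPS,
                                              "governance"))
  expect_equal(ncol(ft) - ncol(ft2), 6)

  # rebuild with identical inputs -> identical table
  ft3 <- build_feature_table(fixture_world(), fixture_env(), fixture_panel(),
                             fixture_history())
  expect_identical(as_tibble(ft), as_tibble(ft3))
  expect_identical(feature_schema(ft)$hash, feature_schema(ft3)$hash)
})

test_that("network CSV and feature table exports round-trip", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  net <- fixture_history()
  write_network_csv(net, tmp)
  back <- read_network_csv(tmp)
  expect_equal(as_tibble(back), as_tibble(net))

  ftmp <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fixture_features(), ftmp)
  expect_true(file.exists(paste0(ftmp, ".schema.json")))
  sidecar <- jsonlite::read_json(paste0(ftmp, ".schema.json"))
  expect_equal(length(sidecar$features),
               nrow(feature_schema(fixture_features())$features))
})
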