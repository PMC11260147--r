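test_that("world config invariants are enforced with named errors", {
  expect_error(world_config(n_lat = 2, n_lon = 2), "n_lat")
  expect_error(world_config(years = c(2016, 2018, 2019, 2020)), "contiguous")
  expect_error(world_config(years = 2016:2018), "at least 4")
  expect_error(world_config(land_fraction = 0.5), "land_fraction")
  expect_error(world_config(land_fraction = -0.1), "land_fraction")
  expect_error(world_config(n_lat = 30, resolution_deg = 10), "180")
})

test_that("world generation is deterministic and geometrically exact", {
  cfg <- tiny_config()
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$pixels, w2$pixels)
  expect_identical(w1$ports, w2$ports)

  # 18 x 36 at 10 degrees: 648 pixels tiling the sphere
  wg <- generate_world(world_config(seed = 1))
  expect_equal(nrow(wg$pixels), 648)
  sphere <- 4 * pi * effortcast:::EARTH_RADIUS_M^2
  expect_equal(sum(wg$pixels$area_m2), sphere, tolerance = 1e-6)
})

test_that("every static layer is defined for every ocean pixel", {
  w <- fixture_world()
  ocean <- dplyr::filter(w$pixels, !is_land)
  for (col in c("eez", "eez_fraction", "wb_region", "gov_capacity", "depth_m",
                "ais_a", "ais_b", "ocean", "mesopelagic", "dist_shore_m",
                "dist_port_m", "dist_seamount_m")) {
    expect_false(anyNA(ocean[[col]]), label = paste("layer", col))
  }
})

test_that("land mask leaves the ocean 4-connected", {
  for (seed in c(11, 77, 300)) {
    w <- generate_world(tiny_config(seed = seed))
    edges <- effortcast:::grid_edges(w$config$n_lat, w$config$n_lon, w$wrap,
                                     connect = 4L)
    land <- w$pixels$is_land
    keep <- !land[edges[, 1]] & !land[edges[, 2]]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(edges[keep, , drop = FALSE]), w$ocean_ids),
             ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(w$ocean_ids) -
                                       igraph::vcount(g)))
    expect_equal(igraph::components(g)$no, 1)
  }
})

test_that("zero land fraction yields an all-ocean world with EEZ bands", {
  w <- generate_world(world_config(n_lat = 8, n_lon = 12,
                                   resolution_deg = 15, land_fraction = 0,
                                   n_eez = 2, seed = 3))
  expect_false(any(w$pixels$is_land))
  labs <- unique(w$pixels$eez)
  expect_true("high_seas" %in% labs)
  expect_true(any(grepl("^state_", labs)))
})

test_that("environment: anomaly scale 0 freezes SST; sd fields nonnegative", {
  w <- fixture_world()
  env0 <- simulate_environment(w, anomaly_sd = 0, seed = 9)
  per_pixel <- env0 |>
    dplyr::group_by(pixel_id) |>
    dplyr::summarise(v = stats::var(sst_mean))
  expect_true(all(per_pixel$v < 1e-20))

  env <- fixture_env()
  for (col in grep("_sd$", names(env), value = TRUE)) {
    expect_true(all(env[[col]] >= 0), label = col)
  }
})

test_that("field-mean SST anomaly tracks the first climate index", {
  w <- fixture_world()
  env <- simulate_environment(w, years = 2001:2020, seed = 4)
  idx <- attr(env, "climate_indices")
  fm <- env |>
    dplyr::group_by(year) |>
    dplyr::summarise(anom = mean(sst_anom_mean))
  expect_gt(stats::cor(fm$anom, idx$index1), 0.8)
})

test_that("effort simulation is deterministic and hurdle-structured", {
  w <- fixture_world(); env <- fixture_env(); net <- fixture_history()
  p1 <- simulate_effort(w, env, net, seed = 99)
  p2 <- simulate_effort(w, env, net, seed = 99)
  expect_identical(p1, p2)

  # hours > 0 <=> occurrence = 1
  expect_true(all((p1$hours > 0) == (p1$occurrence == 1)))
  # zero fraction matches the mean occurrence complement within 2 s.e.
  pbar <- mean(p1$occurrence_prob)
  se <- sqrt(mean(p1$occurrence_prob * (1 - p1$occurrence_prob)) /
               nrow(p1))
  expect_lt(abs(mean(p1$hours == 0) - (1 - pbar)), 2 * se + 1e-12)
})

test_that("full suppression zeroes post-implementation effort inside", {
  w <- fixture_world(); env <- fixture_env()
  target <- w$ocean_ids[5]
  net <- mpa_network(tibble::tibble(
    mpa_id = "full", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2018-01-01"), no_take = TRUE))
  bp <- behavior_params(delta_inside = 1, compliance = 1)
  panel <- simulate_effort(w, env, net, bp, seed = 2)
  post <- dplyr::filter(panel, pixel_id == target, year >= 2018)
  expect_true(all(post$hours == 0))
  expect_true(all(post$applied_multiplier == 0))
  pre <- dplyr::filter(panel, pixel_id == target, year < 2018)
  expect_true(all(pre$applied_multiplier == 1))
})

test_that("outside multiplier follows the stated exponential decay", {
  bp <- behavior_params(delta_outside = -0.5, decay_km = 1000)
  m <- effortcast:::mpa_multiplier(coverage = 0, dist_m = 1000 * 1000,
                                   froy_in = 1, froy_out = 1, behavior = bp)
  expect_equal(m, 1 - 0.5 * exp(-1), tolerance = 1e-12)
  # null outside response leaves the multiplier at exactly 1
  bp0 <- behavior_params(delta_outside = 0)
  expect_equal(effortcast:::mpa_multiplier(0, 5e5, 1, 1, bp0), 1)
})

test_that("zero outside response leaves outside effort unchanged on average", {
  w <- fixture_world(); env <- fixture_env()
  target <- w$ocean_ids[10]
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2016-01-01"), no_take = TRUE))
  bp <- behavior_params(delta_inside = 0.8, delta_outside = 0)
  with_net <- simulate_effort(w, env, net, bp, seed = 31)
  without <- simulate_effort(w, env, empty_network(), bp, seed = 31)
  out_pix <- setdiff(w$ocean_ids, target)
  a <- dplyr::filter(with_net, pixel_id %in% out_pix)$hours
  b <- dplyr::filter(without, pixel_id %in% out_pix)$hours
  # common random numbers: same seed, multiplier 1 outside => identical draws
  expect_equal(a, b)
})

test_that("expected inside effort strictly decreases in delta_inside", {
  w <- fixture_world(); env <- fixture_env()
  target <- w$ocean_ids[3:12]
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2017-01-01"), no_take = TRUE))
  means <- vapply(c(0.2, 0.5, 0.9), function(d) {
    p <- simulate_effort(w, env, net, behavior_params(delta_inside = d),
                         seed = 7)
    mean(dplyr::filter(p, pixel_id %in% target, year >= 2018)$hours)
  }, numeric(1))
  expect_gt(means[1], 0)
  expect_true(all(diff(means) < 0))
})

test_that("anticipation bumps effort the year before implementation", {
  w <- fixture_world(); env <- fixture_env()
  target <- w$ocean_ids[8]
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2019-01-01"), no_take = TRUE))
  p0 <- simulate_effort(w, env, net, behavior_params(anticipation = 0),
                        seed = 13)
  p1 <- simulate_effort(w, env, net, behavior_params(anticipation = 0.5),
                        seed = 13)
  m0 <- dplyr::filter(p0, pixel_id == target, year == 2018)$applied_multiplier
  m1 <- dplyr::filter(p1, pixel_id == target, year == 2018)$applied_multiplier
  expect_equal(m1, m0 * 1.5)
})

test_that("fleet exit zeroes a fleet once coverage crosses the threshold", {
  w <- fixture_world(); env <- fixture_env()
  px <- dplyr::filter(w$pixels, !is_land)
  fl <- names(sort(table(px$eez)))[1]
  fleet_pix <- px$pixel_id[px$eez == fl]
  net <- mpa_network(tibble::tibble(
    mpa_id = "big", pixel_id = fleet_pix, fraction = 1,
    implementation_date = as.Date("2018-01-01"), no_take = TRUE))
  bp <- behavior_params(delta_inside = 0.1, p_fleet_exit = 1,
                        exit_threshold = 0.5)
  panel <- simulate_effort(w, env, net, bp, seed = 17)
  gone <- dplyr::filter(panel, fleet == fl, year >= 2018)
  expect_true(all(gone$hours == 0))
})

test_that("network dates after the simulated years are rejected", {
  w <- fixture_world(); env <- fixture_env()
  net <- mpa_network(tibble::tibble(
    mpa_id = "late", pixel_id = w$ocean_ids[1], fraction = 1,
    implementation_date = as.Date("2030-06-01"), no_take = TRUE))
  expect_error(simulate_effort(w, env, net), "after the simulated years")
  expect_error(behavior_params(delta_inside = 1.2), "delta_inside")
  expect_error(behavior_params(decay_km = 0), "decay_km")
})

test_that("closed-form ground truth matches its trivial cases", {
  w <- fixture_world()
  target <- w$ocean_ids[1:2]
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2017-07-01"), no_take = TRUE))
  gt <- ground_truth_effect(w, behavior_params(delta_inside = 0.8,
                                               compliance = 1,
                                               delta_outside = 0), net)
  inside <- dplyr::filter(gt, pixel_id %in% target)
  expect_true(all(inside$region == "inside"))
  expect_equal(inside$pct_change, rep(-80, 2))
  outside <- dplyr::filter(gt, !pixel_id %in% target)
  expect_equal(outside$pct_change, rep(0, nrow(outside)))
})

test_that("Monte-Carlo mean effort change matches the closed form", {
  w <- fixture_world()
  env1 <- simulate_environment(w, years = 2016:2017, seed = 44)
  target <- w$ocean_ids[6:8]
  net <- mpa_network(tibble::tibble(
    mpa_id = "m", pixel_id = target, fraction = 1,
    implementation_date = as.Date("2017-01-01"), no_take = TRUE))
  bp <- behavior_params(delta_inside = 0.6, delta_outside = -0.4,
                        trend = 1)
  gt <- ground_truth_effect(w, bp, net)
  n_rep <- 120
  ratios <- purrr::map(seq_len(n_rep), function(r) {
    with_net <- simulate_effort(w, env1, net, bp, seed = 1000 + r)
    no_net <- simulate_effort(w, env1, empty_network(), bp, seed = 1000 + r)
    y1 <- dplyr::filter(with_net, year == 2017)
    y0 <- dplyr::filter(no_net, year == 2017)
    tibble::tibble(pixel_id = y1$pixel_id, with_h = y1$hours,
                   base_h = y0$hours)
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(pixel_id) |>
    dplyr::summarise(obs = 100 * (mean(with_h) / mean(base_h) - 1),
                     se_num = stats::sd(with_h) / sqrt(n_rep),
                     mean_base = mean(base_h))
  # bin by ground-truth distance and compare bin means within ~2 s.e.
  chk <- dplyr::inner_join(ratios, gt, by = "pixel_id") |>
    dplyr::mutate(bin = dplyr::case_when(
      region == "inside" ~ "inside",
      distance_m < 2.5e6 ~ "near",
      TRUE ~ "far")) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(obs = mean(obs), truth = mean(pct_change), n = dplyr::n())
  expect_true(all(abs(chk$obs - chk$truth) < 12),
              info = paste(utils::capture.output(print(chk)), collapse = "\n"))
})
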