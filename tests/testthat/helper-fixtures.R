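# shared fixtures, memoised per test run ------------------------------------

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

tiny_config <- function(seed = 11) {
  world_config(n_lat = 8, n_lon = 12, resolution_deg = 15,
               years = 2016:2021, land_fraction = 0.12, n_eez = 2,
               n_ports = 2, n_seamounts = 3, seed = seed)
}

fixture_world <- function() memo("world", generate_world(tiny_config()))

fixture_env <- function() memo("env", simulate_environment(fixture_world()))

fixture_history <- function() {
  memo("history", synthetic_mpa_history(fixture_world(), n_mpas = 5,
                                        mean_size = 3, seed = 21))
}

fixture_panel <- function() {
  memo("panel", simulate_effort(fixture_world(), fixture_env(),
                                fixture_history()))
}

fixture_features <- function() {
  memo("features", build_feature_table(fixture_world(), fixture_env(),
                                       fixture_panel(), fixture_history()))
}

fixture_lead <- function(h = 1) {
  memo(paste0("lead", h),
       make_lead_dataset(fixture_features(), fixture_panel(), h))
}

# cheap fitted hurdle (simple learners -> no tuning) for identity tests
fixture_simple_fit <- function() {
  memo("simple_fit", {
    sp <- temporal_split(fixture_lead(1))
    fit <- fit_hurdle(sp$train,
                      hurdle_spec(learner_logistic(), learner_linear(),
                                  seed = 5))
    fit
  })
}

# hand-built worlds from an explicit land matrix -----------------------------

# constructs an ec_world with the same geometry/graph conventions as
# generate_world(), but a prescribed land mask and no random layers; enough
# for distance and coverage machinery
manual_world <- function(land_mat, res = 10, years = 2016:2019) {
  n_lat <- nrow(land_mat); n_lon <- ncol(land_mat)
  n_pix <- n_lat * n_lon
  wrap <- isTRUE(abs(n_lon * res - 360) < 1e-9)
  lat_top <- n_lat * res / 2
  lon_left <- -n_lon * res / 2
  rows <- rep(seq_len(n_lat), each = n_lon)
  cols <- rep(seq_len(n_lon), times = n_lat)
  lat <- lat_top - (rows - 0.5) * res
  lon <- lon_left + (cols - 0.5) * res
  phi_top <- (lat_top - (rows - 1) * res) * pi / 180
  phi_bot <- (lat_top - rows * res) * pi / 180
  area <- effortcast:::EARTH_RADIUS_M^2 * (res * pi / 180) *
    (sin(phi_top) - sin(phi_bot))
  land <- as.vector(t(land_mat))
  ocean_ids <- which(!land)
  edges <- effortcast:::grid_edges(n_lat, n_lon, wrap, connect = 8L)
  keep <- !land[edges[, 1]] & !land[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  w <- gc_distance(lon[edges[, 1]], lat[edges[, 1]],
                   lon[edges[, 2]], lat[edges[, 2]])
  graph <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges), ocean_ids), ncol = 2), directed = FALSE)
  graph <- igraph::add_vertices(
    graph, max(0L, length(ocean_ids) - igraph::vcount(graph)))
  igraph::E(graph)$weight <- w
  pixels <- tibble::tibble(pixel_id = seq_len(n_pix), row = rows, col = cols,
                           lat = lat, lon = lon, area_m2 = area,
                           is_land = land)
  structure(list(
    config = list(n_lat = n_lat, n_lon = n_lon, resolution_deg = res,
                  years = years, seed = 1L),
    pixels = pixels, ocean_ids = ocean_ids, graph = graph, wrap = wrap,
    no_mpa_sentinel = 2 * pi * effortcast:::EARTH_RADIUS_M * 2
  ), class = "ec_world")
}

# independent shortest-path oracle: plain Dijkstra over the 8-connected
# ocean lattice with haversine edge weights, no igraph involved
dijkstra_to_set <- function(world, targets) {
  px <- world$pixels
  ocean <- world$ocean_ids
  n_lat <- world$config$n_lat; n_lon <- world$config$n_lon
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbrs <- lapply(ocean, function(i) {
    r <- px$row[i] + offs$dr; c <- px$col[i] + offs$dc
    if (world$wrap) c <- ((c - 1L) %% n_lon) + 1L
    ok <- r >= 1 & r <= n_lat & c >= 1 & c <= n_lon
    ids <- (r[ok] - 1L) * n_lon + c[ok]
    ids[ids %in% ocean]
  })
  names(nbrs) <- ocean
  dist <- setNames(rep(Inf, length(ocean)), ocean)
  dist[as.character(targets)] <- 0
  visited <- setNames(rep(FALSE, length(ocean)), ocean)
  repeat {
    u_idx <- which(!visited & is.finite(dist))
    if (length(u_idx) == 0) break
    u_idx <- u_idx[which.min(dist[u_idx])]
    u <- as.integer(names(dist)[u_idx])
    visited[u_idx] <- TRUE
    for (v in nbrs[[as.character(u)]]) {
      w <- gc_distance(px$lon[u], px$lat[u], px$lon[v], px$lat[v])
      k <- as.character(v)
      if (dist[u_idx] + w < dist[k]) dist[k] <- dist[u_idx] + w
    }
  }
  unname(dist)
}

# exhaustive-coalition Shapley oracle with background marginalization
exact_shapley <- function(f, x_row, background, features) {
  p <- length(features)
  value <- function(S) {
    hy <- background
    for (fn in features[S]) hy[[fn]] <- x_row[[fn]]
    mean(f(hy))
  }
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  vals <- vapply(subsets, value, numeric(1))
  keyed <- setNames(vals, vapply(subsets, function(s)
    paste(s, collapse = ","), character(1)))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (j %in% S) next
      s <- length(S)
      wgt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      v_with <- keyed[[paste(sort(c(S, j)), collapse = ",")]]
      phi[j] <- phi[j] + wgt * (v_with - vals[si])
    }
  }
  setNames(phi, features)
}

# random land/ocean instance for distance-oracle sweeps
random_land_instance <- function(n_lat, n_lon, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(n_lat * n_lon) < 0.3, n_lat, n_lon)
    if (sum(!m) >= 3) return(m)
  }
}
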