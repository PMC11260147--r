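#' Configure the toy ocean grid
#'
#' Defines a regular latitude/longitude lattice with a land mask and static
#' layers (EEZs, ports, seamounts, depth, AIS reception). The default is an
#' 18 x 36 grid at 10 degrees per pixel (648 pixels) covering the globe, with
#' six contiguous years — small enough that the full pipeline runs in seconds
#' while preserving the structure of a 1 x 1 degree global analysis.
#'
#' @param n_lat,n_lon Grid dimensions (rows x columns); `n_lat * n_lon >= 25`.
#' @param resolution_deg Pixel edge length in degrees.
#' @param years Contiguous calendar years to simulate; at least 4 so that the
#'   longest forecast horizon (3 years) retains a training pair.
#' @param land_fraction Target fraction of pixels that are land, in `[0, 0.5)`.
#' @param n_eez Number of coastal sovereign states (EEZ labels).
#' @param n_ports,n_seamounts Counts of port and seamount locations.
#' @param n_oceans Number of longitudinal ocean basins (categorical layer used
#'   by leave-one-ocean-out evaluation).
#' @param eez_radius EEZ band width, in pixels (Chebyshev) from each coastal
#'   anchor.
#' @param seed Master seed; every stochastic layer draws a child stream.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_lat = 18, n_lon = 36, resolution_deg = 10,
                         years = 2016:2021, land_fraction = 0.15,
                         n_eez = 3, n_ports = 4, n_seamounts = 6,
                         n_oceans = 3, eez_radius = 2, seed = 42) {
  cfg <- list(
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    resolution_deg = resolution_deg, years = as.integer(years),
    land_fraction = land_fraction, n_eez = as.integer(n_eez),
    n_ports = as.integer(n_ports), n_seamounts = as.integer(n_seamounts),
    n_oceans = as.integer(n_oceans), eez_radius = as.integer(eez_radius),
    seed = as.integer(seed)
  )
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  check_fields(cfg, c("n_lat", "n_lon", "resolution_deg", "years",
                      "land_fraction", "n_eez", "n_ports", "n_seamounts",
                      "seed"), "world_config")
  if (cfg$n_lat * cfg$n_lon < 25) {
    ec_validation_error("`n_lat * n_lon` must be at least 25")
  }
  yrs <- cfg$years
  if (length(yrs) < 4 || !all(diff(yrs) == 1)) {
    ec_validation_error("`years` must be contiguous and cover at least 4 years")
  }
  check_range(cfg$land_fraction, "land_fraction", 0, 0.5, upper_strict = TRUE)
  if (cfg$n_lat * cfg$resolution_deg > 180 + 1e-9) {
    ec_validation_error("`n_lat * resolution_deg` must not exceed 180 degrees")
  }
  if (cfg$n_lon * cfg$resolution_deg > 360 + 1e-9) {
    ec_validation_error("`n_lon * resolution_deg` must not exceed 360 degrees")
  }
  for (f in c("n_eez", "n_ports", "n_seamounts", "n_oceans")) {
    check_range(cfg[[f]], f, 1)
  }
  invisible(cfg)
}

# row/col <-> pixel id, row-major from the north-west corner
pixel_index <- function(row, col, n_lon) (row - 1L) * n_lon + col

# neighbour pixel ids at Chebyshev ring `ring`, with longitudinal wrap when the
# grid spans 360 degrees; rows beyond the poles are dropped.
ring_neighbors <- function(row, col, ring, n_lat, n_lon, wrap) {
  offs <- expand.grid(dr = -ring:ring, dc = -ring:ring)
  offs <- offs[pmax(abs(offs$dr), abs(offs$dc)) == ring, , drop = FALSE]
  r <- row + offs$dr
  c <- col + offs$dc
  if (wrap) c <- ((c - 1L) %% n_lon) + 1L
  keep <- r >= 1L & r <= n_lat & c >= 1L & c <= n_lon
  pixel_index(r[keep], c[keep], n_lon)
}

# adjacency among all grid pixels (4- or 8-connected) as an edge list
grid_edges <- function(n_lat, n_lon, wrap, connect = 8L) {
  offs <- if (connect == 8L) {
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  } else {
    list(c(0L, 1L), c(1L, 0L))
  }
  rows <- rep(seq_len(n_lat), each = n_lon)
  cols <- rep(seq_len(n_lon), times = n_lat)
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- rows + o[1]; c2 <- cols + o[2]
    if (wrap) c2 <- ((c2 - 1L) %% n_lon) + 1L
    keep <- r2 >= 1L & r2 <= n_lat & c2 >= 1L & c2 <= n_lon
    from <- c(from, pixel_index(rows[keep], cols[keep], n_lon))
    to <- c(to, pixel_index(r2[keep], c2[keep], n_lon))
  }
  cbind(from, to)
}

#' Generate the toy ocean
#'
#' Builds the grid geometry (centroids, spherical areas, land mask) and every
#' static layer: EEZ labels and fractions, World Bank-style region and
#' governance-capacity categories per sovereign, ports, seamounts, depth,
#' distance to shore, AIS reception fields, and ocean/mesopelagic categorical
#' layers. The land mask is grown from contiguous seeds and then repaired so
#' the ocean stays 4-connected (isolated ocean pockets become land).
#' Deterministic given the config seed.
#'
#' @param config A [world_config()].
#' @return An object of class `ec_world`: a list with `config`, a `pixels`
#'   tibble of all static layers, port/seamount/EEZ-anchor pixel ids, and the
#'   8-connected ocean graph used for land-avoiding distances.
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  cfg <- config
  set.seed(child_seed(cfg$seed, "world"))

  n_lat <- cfg$n_lat; n_lon <- cfg$n_lon; res <- cfg$resolution_deg
  n_pix <- n_lat * n_lon
  wrap <- isTRUE(abs(n_lon * res - 360) < 1e-9)

  lat_top <- n_lat * res / 2
  lon_left <- -n_lon * res / 2
  rows <- rep(seq_len(n_lat), each = n_lon)
  cols <- rep(seq_len(n_lon), times = n_lat)
  lat <- lat_top - (rows - 0.5) * res
  lon <- lon_left + (cols - 0.5) * res

  # spherical band areas: R^2 * dlambda * (sin(top) - sin(bottom))
  phi_top <- (lat_top - (rows - 1) * res) * pi / 180
  phi_bot <- (lat_top - rows * res) * pi / 180
  area_m2 <- EARTH_RADIUS_M^2 * (res * pi / 180) * (sin(phi_top) - sin(phi_bot))

  land <- grow_land_mask(cfg, n_lat, n_lon, wrap)
  ocean_ids <- which(!land)

  # 8-connected ocean graph with great-circle edge weights
  edges <- grid_edges(n_lat, n_lon, wrap, connect = 8L)
  keep <- !land[edges[, 1]] & !land[edges[, 2]]
  edges <- edges[keep, , drop = FALSE]
  w <- gc_distance(lon[edges[, 1]], lat[edges[, 1]],
                   lon[edges[, 2]], lat[edges[, 2]])
  graph <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges), ocean_ids), ncol = 2), directed = FALSE)
  graph <- igraph::add_vertices(graph, max(0L, length(ocean_ids) - igraph::vcount(graph)))
  igraph::E(graph)$weight <- w

  # distance to shore: direct great-circle to the nearest land centroid
  far_sentinel <- 2 * max(gc_distance(lon[1], lat[1], lon, lat))
  if (any(land)) {
    land_idx <- which(land)
    dist_shore <- vapply(ocean_ids, function(i) {
      min(gc_distance(lon[i], lat[i], lon[land_idx], lat[land_idx]))
    }, numeric(1))
  } else {
    dist_shore <- rep(far_sentinel, length(ocean_ids))
  }

  # coastal anchors: ocean pixels adjacent (Chebyshev 1) to land, else random
  coastal <- ocean_ids[vapply(ocean_ids, function(i) {
    nb <- ring_neighbors(rows[i], cols[i], 1L, n_lat, n_lon, wrap)
    any(land[nb])
  }, logical(1))]
  pool <- if (length(coastal) >= cfg$n_eez) coastal else ocean_ids
  eez_anchors <- sample(pool, cfg$n_eez)

  sovereigns <- sprintf("state_%02d", seq_len(cfg$n_eez))
  # EEZ band: ocean pixels within eez_radius (Chebyshev) of an anchor,
  # labelled by the nearest anchor (great-circle ties by anchor order)
  eez <- rep("high_seas", length(ocean_ids))
  eez_fraction <- rep(0, length(ocean_ids))
  cheb_to_anchor <- function(i, a) {
    dr <- abs(rows[i] - rows[a])
    dc <- abs(cols[i] - cols[a])
    if (wrap) dc <- pmin(dc, n_lon - dc)
    pmax(dr, dc)
  }
  cheb <- vapply(eez_anchors, function(a) cheb_to_anchor(ocean_ids, a),
                 numeric(length(ocean_ids)))
  cheb <- matrix(cheb, nrow = length(ocean_ids))
  in_band <- apply(cheb, 1, min) <= cfg$eez_radius
  nearest_anchor <- apply(cheb, 1, which.min)
  eez[in_band] <- sovereigns[nearest_anchor[in_band]]
  # pixel fraction covered by the assigned EEZ: full near the anchor, tapering
  # toward the outer ring of the band
  eez_fraction[in_band] <- pmax(0.25, 1 - 0.25 * apply(cheb, 1, min)[in_band])

  region_levels <- c("region_A", "region_B", "region_C")
  gov_levels <- c("gov_low", "gov_medium", "gov_high", "gov_no_data")
  sov_region <- setNames(region_levels[(seq_len(cfg$n_eez) - 1L) %% 3L + 1L],
                         sovereigns)
  sov_gov <- setNames(sample(gov_levels, cfg$n_eez, replace = TRUE), sovereigns)

  ports <- sample(if (length(coastal) >= cfg$n_ports) coastal else ocean_ids,
                  cfg$n_ports)
  seamounts <- sample(setdiff(ocean_ids, ports), cfg$n_seamounts)

  depth <- 5500 * (1 - exp(-dist_shore / 1.5e6)) + rnorm(length(ocean_ids), 0, 150)
  depth <- pmax(depth, 50)

  # smooth AIS reception fields (messages/day), poorer in a longitude sector
  ais_a <- 40 + 25 * sin(lon[ocean_ids] * pi / 180) +
    10 * cos(lat[ocean_ids] * pi / 90) + rnorm(length(ocean_ids), 0, 3)
  ais_b <- 12 + 8 * cos(lon[ocean_ids] * pi / 120) + rnorm(length(ocean_ids), 0, 2)
  ais_a <- pmax(ais_a, 1); ais_b <- pmax(ais_b, 0.5)

  ocean_label <- sprintf("ocean_%d", pmin(
    cfg$n_oceans, 1L + ((cols[ocean_ids] - 1L) * cfg$n_oceans) %/% n_lon))
  meso_label <- cut(lat[ocean_ids],
                    breaks = c(-91, -30, 30, 91),
                    labels = c("meso_south", "meso_tropical", "meso_north"))

  pixels <- tibble(
    pixel_id = seq_len(n_pix), row = rows, col = cols, lat = lat, lon = lon,
    area_m2 = area_m2, is_land = land
  )
  statics <- tibble(
    pixel_id = ocean_ids,
    dist_shore_m = dist_shore,
    eez = eez, eez_fraction = eez_fraction,
    wb_region = if_else(eez == "high_seas", "high_seas",
                        unname(sov_region[eez])),
    gov_capacity = if_else(eez == "high_seas", "high_seas",
                           unname(sov_gov[eez])),
    depth_m = depth, ais_a = ais_a, ais_b = ais_b,
    ocean = ocean_label, mesopelagic = as.character(meso_label)
  )
  pixels <- left_join(pixels, statics, by = "pixel_id")

  # documented "no MPA yet" sentinel: twice the largest pairwise centroid
  # distance on the ocean grid
  od <- geosphere::distm(cbind(lon[ocean_ids], lat[ocean_ids]),
                         fun = function(p1, p2)
                           geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
  no_mpa_sentinel <- 2 * max(od)

  world <- structure(list(
    config = cfg, pixels = pixels, ocean_ids = ocean_ids,
    graph = graph, wrap = wrap,
    ports = ports, seamounts = seamounts, eez_anchors = eez_anchors,
    far_sentinel = far_sentinel, no_mpa_sentinel = no_mpa_sentinel
  ), class = "ec_world")

  world$pixels$dist_port_m <- NA_real_
  world$pixels$dist_seamount_m <- NA_real_
  world$pixels$dist_port_m[ocean_ids] <-
    graph_distance_to_set(world, ports)
  world$pixels$dist_seamount_m[ocean_ids] <-
    graph_distance_to_set(world, seamounts)
  world
}

# contiguous land blobs grown from random seeds; ocean repaired to stay
# 4-connected by flooding isolated pockets
grow_land_mask <- function(cfg, n_lat, n_lon, wrap) {
  n_pix <- n_lat * n_lon
  land <- rep(FALSE, n_pix)
  n_land <- round(cfg$land_fraction * n_pix)
  if (n_land == 0) return(land)

  rows <- rep(seq_len(n_lat), each = n_lon)
  cols <- rep(seq_len(n_lon), times = n_lat)
  n_blobs <- max(1L, min(cfg$n_eez, n_land))
  seeds <- sample(n_pix, n_blobs)
  land[seeds] <- TRUE
  while (sum(land) < n_land) {
    frontier <- unique(unlist(lapply(which(land), function(i) {
      nb <- ring_neighbors(rows[i], cols[i], 1L, n_lat, n_lon, wrap)
      # 4-connected growth keeps blobs compact
      nb[abs(rows[nb] - rows[i]) + pmin(abs(cols[nb] - cols[i]),
          if (wrap) n_lon - abs(cols[nb] - cols[i]) else Inf) == 1L]
    })))
    frontier <- setdiff(frontier, which(land))
    if (length(frontier) == 0) break
    land[sample(frontier, 1L)] <- TRUE
  }

  # keep the largest 4-connected ocean component; flood the rest
  edges <- grid_edges(n_lat, n_lon, wrap, connect = 4L)
  ocean <- which(!land)
  keep <- !land[edges[, 1]] & !land[edges[, 2]]
  g <- igraph::graph_from_edgelist(
    matrix(match(as.vector(edges[keep, , drop = FALSE]), ocean), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ocean) - igraph::vcount(g)))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  land[ocean[comp$membership != main]] <- TRUE
  land
}

#' Land-avoiding distance from every ocean pixel to a target set
#'
#' Shortest-path distance on the 8-connected ocean graph with great-circle
#' centroid edge weights; travel through land is impossible by construction.
#'
#' @param world An [generate_world()] result.
#' @param target_pixels Ocean pixel ids (sources; distance 0 there).
#' @param return_source Also return which target each pixel is closest to?
#' @return Metres per ocean pixel (ordered as `world$ocean_ids`); `Inf` for
#'   ocean pixels unreachable from every target. With `return_source = TRUE`,
#'   a list with `distance` and `source` (nearest target pixel id).
#' @export
graph_distance_to_set <- function(world, target_pixels, return_source = FALSE) {
  stopifnot(inherits(world, "ec_world"))
  if (length(target_pixels) == 0) {
    ec_validation_error("`target_pixels` must be nonempty")
  }
  v <- match(target_pixels, world$ocean_ids)
  if (anyNA(v)) {
    ec_validation_error(sprintf(
      "target pixel(s) not ocean pixels: %s",
      paste(target_pixels[is.na(v)], collapse = ", ")))
  }
  d <- igraph::distances(world$graph, v = v, mode = "all")
  dist <- apply(d, 2, min)
  if (any(!is.finite(dist))) {
    rlang::warn("some ocean pixels are unreachable from every target; distance = Inf")
  }
  if (!return_source) return(dist)
  src <- target_pixels[apply(d, 2, which.min)]
  list(distance = dist, source = src)
}

#' @export
print.ec_world <- function(x, ...) {
  cat(sprintf(
    "<ec_world> %d x %d grid at %g deg (%d pixels, %d ocean, %d land)\n",
    x$config$n_lat, x$config$n_lon, x$config$resolution_deg,
    nrow(x$pixels), length(x$ocean_ids), sum(x$pixels$is_land)))
  cat(sprintf("  years %d-%d | %d EEZ, %d ports, %d seamounts | seed %d\n",
              min(x$config$years), max(x$config$years), x$config$n_eez,
              x$config$n_ports, x$config$n_seamounts, x$config$seed))
  invisible(x)
}

#' Static layers as one tibble keyed by pixel id
#'
#' @param world An `ec_world`.
#' @param ocean_only Drop land pixels?
#' @return A tibble, one row per pixel.
#' @export
world_layers <- function(world, ocean_only = TRUE) {
  px <- world$pixels
  if (ocean_only) px <- filter(px, !.data$is_land)
  px
}
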