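#' Build an MPA network from per-pixel coverage records
#'
#' The canonical toy-scale representation of an MPA network is a long table of
#' records: one row per (MPA, pixel) with the covered fraction of that pixel,
#' the implementation date, and a no-take flag. Only no-take records take part
#' in any feature computation.
#'
#' Sub-pixel geometry is summarised by an interval model: record `i` covers
#' `[offset, offset + fraction)` of the pixel, so the union of overlapping
#' MPAs is the measure of the interval union — never a sum, and never above 1.
#' With the default `offset = 0`, overlapping MPAs nest (union = max
#' fraction); explicit offsets encode known partial overlaps.
#'
#' @param records Tibble/data frame with columns `mpa_id`, `pixel_id`,
#'   `fraction`, `implementation_date` (Date or "YYYY-MM-DD"), and optionally
#'   `no_take` (default TRUE) and `offset` (default 0).
#' @return An `ec_mpa_network` tibble.
#' @export
mpa_network <- function(records) {
  rec <- as_tibble(records)
  check_fields(rec, c("mpa_id", "pixel_id", "fraction", "implementation_date"),
               "MPA records")
  if (!"no_take" %in% names(rec)) rec$no_take <- TRUE
  if (!"offset" %in% names(rec)) rec$offset <- 0
  rec$implementation_date <- as.Date(rec$implementation_date)
  rec$pixel_id <- as.integer(rec$pixel_id)
  check_range(rec$fraction, "fraction", 0, 1)
  check_range(rec$offset, "offset", 0, 1, upper_strict = TRUE)
  if (any(rec$offset + rec$fraction > 1 + 1e-9)) {
    ec_validation_error("`offset + fraction` must not exceed 1")
  }
  if (anyNA(rec$implementation_date)) {
    ec_validation_error("`implementation_date` contains unparseable dates")
  }
  structure(rec, class = c("ec_mpa_network", class(tibble())))
}

#' An empty MPA network
#' @return An `ec_mpa_network` with zero records.
#' @export
empty_network <- function() {
  mpa_network(tibble(
    mpa_id = character(0), pixel_id = integer(0), fraction = numeric(0),
    implementation_date = as.Date(character(0)), no_take = logical(0),
    offset = numeric(0)
  ))
}

#' Union of two networks
#'
#' Concatenates records; union coverage semantics (interval model) handle any
#' overlap, so `network_union(x, x)` covers exactly what `x` covers.
#'
#' @param x,y `ec_mpa_network` objects.
#' @return An `ec_mpa_network`.
#' @export
network_union <- function(x, y) {
  mpa_network(bind_rows(as_tibble(x), as_tibble(y)))
}

# active (no-take, implemented on or before `year`) records
active_records <- function(network, year) {
  rec <- as_tibble(network)
  rec[rec$no_take & as.integer(format(rec$implementation_date, "%Y")) <= year, ,
      drop = FALSE]
}

# measure of the union of intervals [offset, offset+fraction)
interval_union_measure <- function(offset, fraction) {
  if (length(offset) == 0) return(0)
  s <- offset; e <- pmin(offset + fraction, 1)
  o <- order(s)
  s <- s[o]; e <- e[o]
  total <- 0; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    } else {
      cur_e <- max(cur_e, e[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Per-pixel union coverage of all MPAs implemented by a year
#'
#' @param network An `ec_mpa_network`.
#' @param world An `ec_world` (defines the pixel universe and validates ids).
#' @param year Query calendar year; records implemented after it are ignored.
#' @return Tibble `(pixel_id, coverage)` over all ocean pixels; pixels with no
#'   overlap have coverage 0. Coverage never exceeds 1.
#' @export
rasterize_union <- function(network, world, year) {
  stopifnot(inherits(world, "ec_world"))
  rec <- as_tibble(network)
  unknown <- setdiff(rec$pixel_id, world$ocean_ids)
  if (length(unknown) > 0) {
    bad <- unique(rec$mpa_id[rec$pixel_id %in% unknown])
    ec_validation_error(sprintf(
      "MPA record(s) %s reference pixel id(s) outside the ocean grid: %s",
      paste(bad, collapse = ", "), paste(unknown, collapse = ", ")))
  }
  act <- active_records(network, year)
  cov <- tibble(pixel_id = world$ocean_ids, coverage = 0)
  if (nrow(act) > 0) {
    by_pix <- act |>
      group_by(.data$pixel_id) |>
      summarise(coverage = interval_union_measure(.data$offset, .data$fraction),
                .groups = "drop")
    cov <- cov |>
      left_join(by_pix, by = "pixel_id", suffix = c("", ".u")) |>
      mutate(coverage = dplyr::coalesce(.data$coverage.u, .data$coverage)) |>
      select("pixel_id", "coverage")
  }
  cov
}

#' Fraction of a year an implementation date was in force
#'
#' Counts the implementation day through 31 December inclusive over the year's
#' true day count (leap-aware): 1 for full-year coverage, in (0, 1) for
#' mid-year implementation, 0 before implementation.
#'
#' @param date Implementation `Date` (vectorised).
#' @param year Query calendar year (scalar).
#' @return Fractions in `[0, 1]`.
#' @export
fraction_of_year <- function(date, year) {
  date <- as.Date(date)
  impl_year <- as.integer(format(date, "%Y"))
  year_end <- as.Date(sprintf("%d-12-31", year))
  year_start <- as.Date(sprintf("%d-01-01", year))
  days_in_year <- as.integer(year_end - year_start) + 1L
  frac <- as.numeric(year_end - date + 1L) / days_in_year
  out <- ifelse(impl_year < year, 1, ifelse(impl_year > year, 0, frac))
  pmin(pmax(out, 0), 1)
}

#' Read / write the canonical network CSV
#'
#' Columns: `mpa_id, pixel_id, fraction, implementation_date, no_take[, offset]`.
#'
#' @param path CSV path.
#' @return `read_network_csv()` returns an `ec_mpa_network`.
#' @export
read_network_csv <- function(path) {
  mpa_network(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_network_csv
#' @param network An `ec_mpa_network` to write.
#' @export
write_network_csv <- function(network, path) {
  readr::write_csv(as_tibble(network), path)
  invisible(path)
}

#' Generate a synthetic MPA implementation history
#'
#' Draws contiguous no-take MPA blocks on the ocean grid with implementation
#' dates uniform within the interior simulated years (so mid-year
#' implementations, and hence partial fraction-of-year exposure, occur
#' routinely) and a few partially covered edge pixels. This is the "observed
#' history" the model trains on. The default density — 10 MPAs of about 3
#' pixels on the 537-pixel default ocean — scales the real no-take record
#' (hundreds of implemented MPAs over a ~40,000-pixel ocean) down to the toy
#' grid.
#'
#' @param world An `ec_world`.
#' @param n_mpas Number of MPAs.
#' @param mean_size Mean block size in pixels.
#' @param partial_prob Probability an edge pixel of a block is only partially
#'   covered.
#' @param seed Integer seed (default: derived from the world seed).
#' @return An `ec_mpa_network`.
#' @export
synthetic_mpa_history <- function(world, n_mpas = 10, mean_size = 3,
                                  partial_prob = 0.35, seed = NULL) {
  stopifnot(inherits(world, "ec_world"))
  seed <- seed %||% child_seed(world$config$seed, "mpa_history")
  set.seed(seed)
  yrs <- world$config$years
  # implement within the interior years so pre/post years both exist
  impl_years <- yrs[2]:yrs[length(yrs) - 1]
  px <- world$pixels
  recs <- purrr::map(seq_len(n_mpas), function(k) {
    size <- max(2L, stats::rpois(1, mean_size))
    block <- grow_ocean_block(world, size)
    frac <- rep(1, length(block))
    edge <- seq_along(block) > max(1, length(block) - 2)
    part <- edge & runif(length(block)) < partial_prob
    frac[part] <- runif(sum(part), 0.25, 0.85)
    y <- sample(impl_years, 1)
    date <- as.Date(sprintf("%d-01-01", y)) + sample(0:364, 1)
    tibble(mpa_id = sprintf("mpa_%02d", k), pixel_id = block,
           fraction = frac, implementation_date = date, no_take = TRUE)
  })
  mpa_network(bind_rows(recs))
}

# contiguous ocean block grown by 4-connected frontier expansion
grow_ocean_block <- function(world, size) {
  px <- world$pixels
  ocean <- world$ocean_ids
  n_lat <- world$config$n_lat; n_lon <- world$config$n_lon
  block <- sample(ocean, 1)
  while (length(block) < size) {
    frontier <- unique(unlist(lapply(block, function(i) {
      nb <- ring_neighbors(px$row[i], px$col[i], 1L, n_lat, n_lon, world$wrap)
      dc <- abs(px$col[nb] - px$col[i])
      if (world$wrap) dc <- pmin(dc, n_lon - dc)
      nb[nb %in% ocean & (abs(px$row[nb] - px$row[i]) + dc) == 1L]
    })))
    frontier <- setdiff(frontier, block)
    if (length(frontier) == 0) break
    block <- c(block, sample(frontier, 1))
  }
  block
}
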