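#' @importFrom rlang .data abort warn hash %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows bind_cols across n rename distinct pull
#'   if_else row_number slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats plogis qlogis rnorm runif rbinom sd var cor predict
#'   setNames glm lm binomial median quantile
#' @importFrom utils head tail
NULL

# Earth radius (m); shared by the spherical pixel areas and all great-circle
# edge weights so distances and areas are on one sphere.
EARTH_RADIUS_M <- 6371000

#' Derive a reproducible child seed
#'
#' All randomness in the package flows from one master seed. Sub-stages draw
#' their own streams through `child_seed()` so that, e.g., regenerating the
#' environment does not perturb the effort draw.
#'
#' @param seed Integer master seed.
#' @param key Character tag naming the consumer stream.
#' @return A single integer in `[0, 2^31)`.
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- rlang::hash(list(as.integer(seed), key))
  # first 7 hex digits < 2^28, always a valid R integer
  strtoi(substr(h, 1, 7), base = 16L)
}

ec_abort <- function(msg, class = "effortcast_error") {
  rlang::abort(msg, class = c(class, "effortcast_error"))
}

ec_validation_error <- function(msg) {
  ec_abort(msg, class = "effortcast_validation_error")
}

check_fields <- function(x, fields, what) {
  missing <- setdiff(fields, names(x))
  if (length(missing) > 0) {
    ec_validation_error(sprintf(
      "%s is missing required field(s): %s", what, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

check_range <- function(value, name, lower = -Inf, upper = Inf,
                        lower_strict = FALSE, upper_strict = FALSE) {
  bad <- !is.finite(value) |
    (if (lower_strict) value <= lower else value < lower) |
    (if (upper_strict) value >= upper else value > upper)
  if (any(bad)) {
    ec_validation_error(sprintf(
      "`%s` must lie in %s%s, %s%s (got %s)", name,
      if (lower_strict) "(" else "[", format(lower),
      format(upper), if (upper_strict) ")" else "]",
      paste(format(value[bad]), collapse = ", ")
    ))
  }
  invisible(value)
}

#' Great-circle distance between grid centroids
#'
#' Haversine distance on the sphere used throughout the package
#' (radius 6,371 km, matching the spherical pixel-area formula).
#'
#' @param lon1,lat1,lon2,lat2 Coordinate vectors in degrees.
#' @return Distance(s) in metres.
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

# stable JSON writer used by schema sidecars / manifests
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
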