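#' Build the per-horizon supervised dataset
#'
#' Leads the outcome by the forecast horizon: each row pairs features dated
#' `feature_year` with effort observed at `outcome_year = feature_year + t`,
#' so the row's lagged-effort feature is a t-year lag of the outcome. The
#' number of pair-years shrinks with the horizon exactly as
#' `n_years - t`.
#'
#' @param features An `ec_feature_table`.
#' @param panel An `ec_effort_panel` supplying the outcome.
#' @param horizon Forecast horizon t in years (1, 2 or 3 in the reference
#'   setup; any positive integer is accepted).
#' @return An `ec_lead_dataset` tibble: id columns `pixel_id`,
#'   `feature_year`, `outcome_year`, all features, and outcome columns
#'   `outcome_hours`, `outcome_log_hm2` (log(h/m^2), `NA` for zero effort)
#'   and `occurrence` (0/1). Carries the feature schema and `horizon`.
#' @export
make_lead_dataset <- function(features, panel, horizon) {
  stopifnot(inherits(features, "ec_feature_table"))
  horizon <- as.integer(horizon)
  check_range(horizon, "horizon", 1)
  f_years <- sort(unique(features$year))
  o_years <- sort(unique(panel$year))
  usable <- f_years[(f_years + horizon) %in% o_years]
  if (length(usable) == 0) {
    ec_abort(sprintf(
      "insufficient years for horizon %d: need feature and outcome years %d apart (have features %d-%d, outcomes %d-%d)",
      horizon, horizon, min(f_years), max(f_years), min(o_years), max(o_years)))
  }
  schema <- feature_schema(features)

  out <- as_tibble(features) |>
    filter(.data$year %in% usable) |>
    rename(feature_year = "year") |>
    mutate(outcome_year = .data$feature_year + horizon,
           year = .data$feature_year) |>
    inner_join(
      as_tibble(panel) |>
        select("pixel_id", outcome_year = "year", outcome_hours = "hours"),
      by = c("pixel_id", "outcome_year")
    )
  # area lookup for the log outcome
  out <- left_join(out, areas_tbl(panel, features),
                   by = c("pixel_id", "lat")) |>
    mutate(
      occurrence = as.integer(.data$outcome_hours > 0),
      outcome_log_hm2 = if_else(.data$outcome_hours > 0,
                                log(.data$outcome_hours / .data$.area_m2),
                                NA_real_)
    )
  structure(out, schema = schema, horizon = horizon,
            class = c("ec_lead_dataset", class(tibble())))
}

# area column for the pixels present; features tables carry no area, so this
# is resolved from the lat-band formula via the year/lat columns when a world
# is not at hand. Panels generated here always align with the feature pixels.
areas_tbl <- function(panel, features) {
  # reconstruct spherical areas from the feature table's lat column and the
  # implied resolution (uniform lat spacing)
  ft <- as_tibble(features)
  lats <- sort(unique(ft$lat))
  res <- if (length(lats) > 1) min(diff(lats)) else 10
  distinct(ft, .data$pixel_id, .data$lat) |>
    mutate(.area_m2 = EARTH_RADIUS_M^2 * (res * pi / 180) *
             (sin((.data$lat + res / 2) * pi / 180) -
                sin((.data$lat - res / 2) * pi / 180)))
}

#' Temporal train/test split
#'
#' The test partition is every row whose outcome year is the last observed
#' outcome year; training is everything earlier. Disjoint and exhaustive by
#' construction, independent of row order.
#'
#' @param dataset An `ec_lead_dataset`.
#' @return A list with `train` and `test` lead datasets.
#' @export
temporal_split <- function(dataset) {
  stopifnot(inherits(dataset, "ec_lead_dataset"))
  oy <- sort(unique(dataset$outcome_year))
  if (length(oy) < 2) {
    ec_abort("temporal split needs at least 2 distinct pair-years")
  }
  last <- max(oy)
  list(
    train = keep_lead(dataset, dataset$outcome_year < last),
    test = keep_lead(dataset, dataset$outcome_year == last)
  )
}

keep_lead <- function(dataset, idx) {
  out <- as_tibble(dataset)[idx, , drop = FALSE]
  structure(out, schema = attr(dataset, "schema"),
            horizon = attr(dataset, "horizon"),
            class = class(dataset))
}

#' Leave-one-ocean-out spatiotemporal splits
#'
#' For each ocean: the test partition is the last pair-year restricted to
#' that ocean; training is all earlier pair-years from the *other* oceans
#' only, so the held-out ocean contributes zero training rows.
#'
#' @param dataset An `ec_lead_dataset` (must carry the `ocean` feature, or
#'   supply `ocean_labels`).
#' @param ocean_labels Optional vector of ocean labels aligned with the rows.
#' @return Named list (one element per ocean) of `train`/`test` pairs.
#'   Oceans with no rows are skipped with a warning.
#' @export
spatiotemporal_splits <- function(dataset, ocean_labels = NULL) {
  stopifnot(inherits(dataset, "ec_lead_dataset"))
  labels <- ocean_labels %||% dataset$ocean
  if (is.null(labels)) ec_abort("no ocean labels available")
  oceans <- sort(unique(labels))
  if (length(oceans) < 2) ec_abort("need at least 2 oceans for leave-one-out")
  last <- max(dataset$outcome_year)
  out <- list()
  for (k in oceans) {
    test_idx <- labels == k & dataset$outcome_year == last
    train_idx <- labels != k & dataset$outcome_year < last
    if (!any(test_idx)) {
      rlang::warn(sprintf("ocean %s has no test rows; skipped", k))
      next
    }
    out[[k]] <- list(train = keep_lead(dataset, train_idx),
                     test = keep_lead(dataset, test_idx))
  }
  out
}

#' Rolling-origin time-based CV folds
#'
#' Sliding one-year folds over the training pair-years: for each candidate
#' assessment year (2nd through last), the analysis split is the preceding
#' pair-year (`scheme = "sliding"`) or all preceding pair-years
#' (`scheme = "cumulative"`). Pair-years are indexed by outcome year
#' throughout.
#'
#' @param train An `ec_lead_dataset` (the training partition).
#' @param scheme `"sliding"` (default) or `"cumulative"` analysis windows.
#' @return A `fold_plan`: list of folds, each with `analysis_years`,
#'   `assessment_year`, and row indices `analysis`/`assessment` into `train`.
#' @export
make_time_folds <- function(train, scheme = c("sliding", "cumulative")) {
  stopifnot(inherits(train, "ec_lead_dataset"))
  scheme <- match.arg(scheme)
  oy <- sort(unique(train$outcome_year))
  if (length(oy) < 2) {
    ec_abort("need at least 2 pair-years in the training data to build folds")
  }
  folds <- purrr::map(seq_along(oy)[-1], function(i) {
    analysis_years <- if (scheme == "sliding") oy[i - 1] else oy[seq_len(i - 1)]
    list(
      analysis_years = analysis_years,
      assessment_year = oy[i],
      analysis = which(train$outcome_year %in% analysis_years),
      assessment = which(train$outcome_year == oy[i])
    )
  })
  structure(list(folds = folds, scheme = scheme, pair_years = oy),
            class = "ec_fold_plan")
}

#' @export
print.ec_fold_plan <- function(x, ...) {
  cat(sprintf("<ec_fold_plan> %d fold(s), %s windows\n",
              length(x$folds), x$scheme))
  for (f in x$folds) {
    cat(sprintf("  analysis %s -> assessment %d\n",
                paste(f$analysis_years, collapse = ","), f$assessment_year))
  }
  invisible(x)
}

#' Assert the absence of temporal leakage
#'
#' Every fold must have `max(analysis years) < assessment year`, and no
#' assessment/test row may share `(pixel_id, outcome_year)` with its training
#' partition.
#'
#' @param train An `ec_lead_dataset`.
#' @param plan An `ec_fold_plan` over `train`.
#' @return `TRUE` invisibly; aborts on any violation.
#' @export
audit_leakage <- function(train, plan) {
  stopifnot(inherits(plan, "ec_fold_plan"))
  for (f in plan$folds) {
    if (max(f$analysis_years) >= f$assessment_year) {
      ec_abort(sprintf("fold with assessment year %d uses analysis years %s",
                       f$assessment_year,
                       paste(f$analysis_years, collapse = ",")))
    }
    a_keys <- paste(train$pixel_id[f$analysis], train$outcome_year[f$analysis])
    b_keys <- paste(train$pixel_id[f$assessment],
                    train$outcome_year[f$assessment])
    if (length(intersect(a_keys, b_keys)) > 0) {
      ec_abort("fold shares (pixel, outcome year) rows between partitions")
    }
  }
  invisible(TRUE)
}

#' Serialise a fold plan to JSON (years only)
#' @param plan An `ec_fold_plan`.
#' @param path Output path.
#' @export
write_fold_plan <- function(plan, path) {
  write_json_file(list(
    scheme = plan$scheme, pair_years = plan$pair_years,
    folds = lapply(plan$folds, function(f)
      list(analysis_years = f$analysis_years,
           assessment_year = f$assessment_year))
  ), path)
}
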