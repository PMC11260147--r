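#' Restrict a dataset to a subset of model features
#'
#' Produces a lead dataset (or feature table) whose schema contains only the
#' requested features — the mechanism behind the lagged-effort-only
#' robustness comparators.
#'
#' @param dataset An `ec_lead_dataset` or `ec_feature_table`.
#' @param features Feature names to keep (must exist in the schema).
#' @return The same class of object with a reduced schema.
#' @export
restrict_features <- function(dataset, features) {
  schema <- attr(dataset, "schema")
  if (is.null(schema)) ec_abort("dataset carries no feature schema")
  missing <- setdiff(features, schema$features$name)
  if (length(missing) > 0) {
    ec_abort(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  schema$features <- schema$features[schema$features$name %in% features, ,
                                     drop = FALSE]
  schema$levels <- schema$levels[intersect(names(schema$levels), features)]
  schema$hash <- rlang::hash(schema[c("features", "levels", "version")])
  drop <- setdiff(setdiff(names(dataset), features),
                  c("pixel_id", "year", "feature_year", "outcome_year",
                    "outcome_hours", "outcome_log_hm2", "occurrence",
                    ".area_m2"))
  out <- as_tibble(dataset)[, setdiff(names(dataset), drop), drop = FALSE]
  structure(out, schema = schema, horizon = attr(dataset, "horizon"),
            class = class(dataset))
}

#' Robustness comparator harness
#'
#' Runs the four benchmark specifications against the same temporal split:
#' the tree-based hurdle with all features, the tree-based hurdle with only
#' the lagged log-effort feature, and the logistic + linear hurdle with each
#' feature set (fitted without hyperparameter tuning, since those learners
#' have none). Each specification is evaluated on the held-out partition,
#' yielding directly comparable metric reports.
#'
#' @param train,test `ec_lead_dataset` partitions from [temporal_split()].
#' @param n_trees,grid_size Forest capacity for the tree specifications.
#' @param seed Seed shared across specifications.
#' @return A tibble: one metric-report row per scope and specification, with
#'   columns `spec_learner` and `spec_features`.
#' @export
robustness_comparators <- function(train, test, n_trees = 200, grid_size = 4,
                                   seed = 1) {
  lag_only <- "lag_log_effort"
  cases <- list(
    list(learner = "trees", features = "all"),
    list(learner = "trees", features = "lag_only"),
    list(learner = "simple", features = "all"),
    list(learner = "simple", features = "lag_only")
  )
  purrr::map(cases, function(cs) {
    tr <- train; te <- test
    if (cs$features == "lag_only") {
      tr <- restrict_features(tr, lag_only)
      te <- restrict_features(te, lag_only)
    }
    spec <- if (cs$learner == "trees") {
      hurdle_spec(learner_rf_class(n_trees), learner_rf_reg(n_trees),
                  grid_size = grid_size, seed = seed)
    } else {
      hurdle_spec(learner_logistic(), learner_linear(), seed = seed)
    }
    fit <- fit_hurdle(tr, spec)
    evaluate_hurdle(fit, te) |>
      mutate(spec_learner = cs$learner, spec_features = cs$features,
             .before = 1)
  }) |>
    bind_rows()
}
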