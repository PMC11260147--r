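#' Learner contracts for the two hurdle stages
#'
#' A learner is a list with `fit(x, y, params, seed)` and
#' `predict(model, x)` plus a `tunable` flag. Stage 1 learners emit the
#' class-1 probability; stage 2 learners predict log(h/m^2). The defaults are
#' random forests (500 trees); the simple-learner contract (logistic /
#' linear regression) runs through the identical pipeline, without
#' hyperparameter tuning.
#'
#' @param n_trees Number of trees for the forest learners.
#' @return A learner contract list.
#' @name learners
NULL

#' @rdname learners
#' @export
learner_rf_class <- function(n_trees = 500) {
  list(
    name = "rf_class", tunable = TRUE,
    fit = function(x, y, params, seed) {
      ranger::ranger(
        x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = n_trees, mtry = min(params$mtry %||% floor(sqrt(ncol(x))),
                                        ncol(x)),
        min.node.size = params$min_n %||% 10,
        respect.unordered.factors = "order",
        seed = seed, num.threads = 1
      )
    },
    predict = function(model, x) {
      as.numeric(predict(model, data = x, num.threads = 1)$predictions[, "1"])
    }
  )
}

#' @rdname learners
#' @export
learner_rf_reg <- function(n_trees = 500) {
  list(
    name = "rf_reg", tunable = TRUE,
    fit = function(x, y, params, seed) {
      ranger::ranger(
        x = x, y = y, num.trees = n_trees,
        mtry = min(params$mtry %||% max(1, floor(ncol(x) / 3)), ncol(x)),
        min.node.size = params$min_n %||% 5,
        respect.unordered.factors = "order",
        seed = seed, num.threads = 1
      )
    },
    predict = function(model, x) {
      as.numeric(predict(model, data = x, num.threads = 1)$predictions)
    }
  )
}

# design matrix on fixed factor levels; aliased/empty-level coefficients are
# zeroed so predictions stay finite for any schema-conforming input
glm_style_learner <- function(name, family) {
  list(
    name = name, tunable = FALSE,
    fit = function(x, y, params, seed) {
      X <- stats::model.matrix(~., data = x)
      fit <- if (is.null(family)) {
        stats::lm.fit(X, y)
      } else {
        suppressWarnings(stats::glm.fit(X, y, family = family))
      }
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      list(beta = beta, columns = colnames(X))
    },
    predict = function(model, x) {
      X <- stats::model.matrix(~., data = x)
      X <- X[, model$columns, drop = FALSE]
      eta <- drop(X %*% model$beta)
      if (is.null(family)) eta else plogis(eta)
    }
  )
}

#' @rdname learners
#' @export
learner_logistic <- function() glm_style_learner("logistic", binomial())

#' @rdname learners
#' @export
learner_linear <- function() glm_style_learner("linear", NULL)

#' Specify the hurdle model
#'
#' Bundles the two learner contracts, the hyperparameter grid (a seeded
#' maximin Latin-hypercube draw of `grid_size` points over the mtry and
#' min-node-size ranges), and the tuning protocol: stage 1 maximises
#' mean-across-folds roc_auc, the classification threshold maximises
#' mean-across-folds F1, stage 2 maximises mean-across-folds rsq_trad on
#' backtransformed level predictions with the smearing coefficient refit
#' inside each fold's analysis split.
#'
#' @param stage1,stage2 Learner contracts (see [learners]).
#' @param grid_size Number of hyperparameter combinations (default 10).
#' @param mtry_range Range of features sampled per split (default 1 to p,
#'   resolved at fit time).
#' @param min_n_range Range of minimum node sizes.
#' @param threshold_source `"cv"` (fold assessment predictions) for the
#'   F1-optimal threshold.
#' @param seed Seed governing the grid draw and all learner fits.
#' @return A `hurdle_spec` list.
#' @export
hurdle_spec <- function(stage1 = learner_rf_class(), stage2 = learner_rf_reg(),
                        grid_size = 10, mtry_range = NULL,
                        min_n_range = c(2, 40), threshold_source = "cv",
                        seed = 1) {
  structure(list(
    stage1 = stage1, stage2 = stage2, grid_size = as.integer(grid_size),
    mtry_range = mtry_range, min_n_range = min_n_range,
    threshold_source = threshold_source, seed = as.integer(seed)
  ), class = "hurdle_spec")
}

#' Hyperparameter grid for a hurdle spec
#'
#' Maximin Latin-hypercube sample over (mtry, min_n), seeded; duplicates
#' after rounding are kept (ties resolve to the first occurrence during
#' selection).
#'
#' @param spec A [hurdle_spec()].
#' @param p Number of features (resolves the default mtry range).
#' @return Tibble `(combo, mtry, min_n)`.
#' @export
hp_grid <- function(spec, p) {
  mtry_range <- spec$mtry_range %||% c(1, p)
  set.seed(child_seed(spec$seed, "grid"))
  u <- lhs::maximinLHS(spec$grid_size, 2)
  tibble(
    combo = seq_len(spec$grid_size),
    mtry = pmin(p, pmax(1, round(mtry_range[1] +
                                   u[, 1] * (mtry_range[2] - mtry_range[1])))),
    min_n = pmax(1, round(spec$min_n_range[1] +
                            u[, 2] * diff(spec$min_n_range)))
  )
}

fold_xy <- function(train, design, idx, positive_only = FALSE) {
  rows <- idx
  if (positive_only) rows <- idx[train$occurrence[idx] == 1]
  list(x = design[rows, , drop = FALSE],
       y_class = train$occurrence[rows],
       y_log = train$outcome_log_hm2[rows],
       rows = rows)
}

#' Tune the occurrence classifier
#'
#' Per-combination roc_auc computed on each fold's assessment rows and
#' averaged across folds; folds whose analysis split has a single class are
#' skipped with a warning. Ties break toward smaller complexity (smaller
#' mtry, then larger min node size), then grid order.
#'
#' @param train An `ec_lead_dataset` (training partition).
#' @param plan An `ec_fold_plan` over `train`.
#' @param spec A [hurdle_spec()].
#' @param grid Optional explicit grid (tibble with `combo`, `mtry`, `min_n`);
#'   defaults to [hp_grid()].
#' @return List: `best` (params row), `scores` (per-combo mean roc_auc).
#' @export
tune_stage1 <- function(train, plan, spec, grid = NULL) {
  schema <- attr(train, "schema")
  design <- schema_design(train, schema)
  grid <- grid %||% hp_grid(spec, ncol(design))
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    vals <- purrr::map_dbl(seq_along(plan$folds), function(fi) {
      f <- plan$folds[[fi]]
      an <- fold_xy(train, design, f$analysis)
      if (length(unique(an$y_class)) < 2) {
        rlang::warn(sprintf(
          "fold (assessment %d) skipped for stage-1 tuning: single class",
          f$assessment_year))
        return(NA_real_)
      }
      # seed keyed by the parameter values: duplicated grid rows score
      # identically and resolve to the first occurrence
      m <- spec$stage1$fit(an$x, an$y_class, params,
                           child_seed(spec$seed, paste0(
                             "s1_", params$mtry, "_", params$min_n, "_", fi)))
      as_ <- fold_xy(train, design, f$assessment)
      tryCatch(roc_auc(spec$stage1$predict(m, as_$x), as_$y_class),
               error = function(e) NA_real_)
    })
    if (all(is.na(vals))) {
      ec_abort("all folds skipped during stage-1 tuning")
    }
    mean(vals, na.rm = TRUE)
  })
  pick <- order(-scores, grid$mtry, -grid$min_n, grid$combo)[1]
  list(best = as.list(grid[pick, ]), scores = mutate(grid, roc_auc = scores))
}

#' Tune the intensity regressor
#'
#' Stage 2 trains on the positive-effort rows of each fold's analysis split;
#' its smearing coefficient is refit within the analysis split; rsq_trad is
#' computed on backtransformed level predictions (h/m^2) over the fold's
#' positive assessment rows and averaged across folds.
#'
#' @inheritParams tune_stage1
#' @return List: `best` (params row), `scores` (per-combo mean rsq_trad).
#' @export
tune_stage2 <- function(train, plan, spec, grid = NULL) {
  schema <- attr(train, "schema")
  design <- schema_design(train, schema)
  grid <- grid %||% hp_grid(spec, ncol(design))
  scores <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    vals <- purrr::map_dbl(seq_along(plan$folds), function(fi) {
      f <- plan$folds[[fi]]
      an <- fold_xy(train, design, f$analysis, positive_only = TRUE)
      as_ <- fold_xy(train, design, f$assessment, positive_only = TRUE)
      if (length(an$y_log) < 2 || length(as_$y_log) < 2 ||
          var(exp(as_$y_log)) == 0) {
        rlang::warn(sprintf(
          "fold (assessment %d) skipped for stage-2 tuning: too few positives",
          f$assessment_year))
        return(NA_real_)
      }
      m <- spec$stage2$fit(an$x, an$y_log, params,
                           child_seed(spec$seed, paste0(
                             "s2_", params$mtry, "_", params$min_n, "_", fi)))
      s_fold <- smearing_coefficient(an$y_log - spec$stage2$predict(m, an$x))
      yhat_level <- s_fold * exp(spec$stage2$predict(m, as_$x))
      rsq_trad(exp(as_$y_log), yhat_level)
    })
    if (all(is.na(vals))) {
      ec_abort("all folds skipped during stage-2 tuning")
    }
    mean(vals, na.rm = TRUE)
  })
  pick <- order(-scores, grid$mtry, -grid$min_n, grid$combo)[1]
  list(best = as.list(grid[pick, ]), scores = mutate(grid, rsq_trad = scores))
}

#' F1-optimal classification threshold
#'
#' Exhaustive scan: candidate thresholds are the midpoints of the sorted
#' unique predicted probabilities pooled across folds (padded with 0 and 1,
#' so "classify everything positive/negative" are both reachable), making
#' the scan equal to brute force by construction. The returned tau maximises
#' the mean-across-folds F1; ties resolve to the smallest tau.
#'
#' @param fold_predictions List of tibbles with columns `prob` and `label`
#'   (one element per fold; a single tibble is treated as one fold).
#' @return The threshold tau in (0, 1).
#' @export
select_threshold <- function(fold_predictions) {
  if (is.data.frame(fold_predictions)) {
    fold_predictions <- list(fold_predictions)
  }
  pooled <- sort(unique(unlist(purrr::map(fold_predictions, "prob"))))
  if (length(pooled) == 0) {
    rlang::warn("no predictions supplied; falling back to tau = 0.5")
    return(0.5)
  }
  grid <- c(0, pooled, 1)
  cands <- (head(grid, -1) + tail(grid, -1)) / 2
  cands <- unique(cands)
  mean_f1 <- purrr::map_dbl(cands, function(tau) {
    mean(purrr::map_dbl(fold_predictions, function(fp) {
      f_meas(fp$prob, fp$label, tau = tau)
    }))
  })
  if (max(mean_f1) == 0) {
    rlang::warn("no threshold yields a positive F1; falling back to tau = 0.5")
    return(0.5)
  }
  cands[which.max(mean_f1)]
}

#' Duan smearing coefficient
#'
#' Nonparametric backtransformation factor for log-modelled outcomes: the
#' mean of the exponentiated log-scale residuals from the fitting partition.
#'
#' @param log_residuals Observed log minus predicted log on the fitting
#'   partition's positive rows.
#' @return The coefficient S (> 0); 1 when all residuals are 0.
#' @export
smearing_coefficient <- function(log_residuals) {
  if (length(log_residuals) == 0) {
    ec_abort("smearing coefficient is undefined for empty residuals")
  }
  mean(exp(log_residuals))
}

#' Fit the two-stage hurdle model
#'
#' Tunes both stages on rolling-origin folds (when the learners are
#' tunable), selects the F1-optimal threshold from fold assessment
#' predictions, fits stage 1 on all training rows and stage 2 on the
#' positive-effort rows only, and computes the final smearing coefficient
#' from the full fitting partition's residuals. Deterministic given the spec
#' seed.
#'
#' @param train An `ec_lead_dataset` training partition (both classes and
#'   some positive rows required).
#' @param spec A [hurdle_spec()].
#' @param plan Optional `ec_fold_plan`; built from `train` when omitted and
#'   needed.
#' @return An `ec_hurdle` fitted model: stage-1 classifier, threshold `tau`,
#'   stage-2 regressor, smearing coefficient `smear`, the feature schema
#'   (hash-checked at prediction time), horizon, tuned parameters and CV
#'   score tables.
#' @export
fit_hurdle <- function(train, spec = hurdle_spec(), plan = NULL) {
  stopifnot(inherits(train, "ec_lead_dataset"))
  if (nrow(train) == 0) ec_abort("empty training data")
  if (length(unique(train$occurrence)) < 2) {
    ec_abort("training data must contain both classes")
  }
  if (sum(train$occurrence) == 0) ec_abort("no positive-effort rows")
  schema <- attr(train, "schema")
  design <- schema_design(train, schema)

  tunable <- isTRUE(spec$stage1$tunable) || isTRUE(spec$stage2$tunable)
  n_pair_years <- length(unique(train$outcome_year))
  if (is.null(plan) && n_pair_years >= 2) plan <- make_time_folds(train)

  params1 <- params2 <- NULL
  scores1 <- scores2 <- NULL
  if (isTRUE(spec$stage1$tunable)) {
    if (is.null(plan)) ec_abort("stage-1 tuning needs >= 2 pair-years")
    t1 <- tune_stage1(train, plan, spec)
    params1 <- t1$best; scores1 <- t1$scores
  }
  if (isTRUE(spec$stage2$tunable)) {
    if (is.null(plan)) ec_abort("stage-2 tuning needs >= 2 pair-years")
    t2 <- tune_stage2(train, plan, spec)
    params2 <- t2$best; scores2 <- t2$scores
  }

  # threshold from fold assessment predictions at the selected parameters
  if (!is.null(plan)) {
    fold_preds <- purrr::map(seq_along(plan$folds), function(fi) {
      f <- plan$folds[[fi]]
      an <- fold_xy(train, design, f$analysis)
      if (length(unique(an$y_class)) < 2) return(NULL)
      m <- spec$stage1$fit(an$x, an$y_class, params1 %||% list(),
                           child_seed(spec$seed, paste0("tau", fi)))
      as_ <- fold_xy(train, design, f$assessment)
      tibble(prob = spec$stage1$predict(m, as_$x), label = as_$y_class)
    })
    fold_preds <- purrr::compact(fold_preds)
  } else {
    rlang::warn("single pair-year: threshold selected on in-sample predictions")
    m0 <- spec$stage1$fit(design, train$occurrence, params1 %||% list(),
                          child_seed(spec$seed, "tau0"))
    fold_preds <- list(tibble(prob = spec$stage1$predict(m0, design),
                              label = train$occurrence))
  }
  tau <- select_threshold(fold_preds)

  stage1 <- spec$stage1$fit(design, train$occurrence, params1 %||% list(),
                            child_seed(spec$seed, "final_s1"))
  pos <- train$occurrence == 1
  x_pos <- design[pos, , drop = FALSE]
  y_pos <- train$outcome_log_hm2[pos]
  stage2 <- spec$stage2$fit(x_pos, y_pos, params2 %||% list(),
                            child_seed(spec$seed, "final_s2"))
  smear <- smearing_coefficient(y_pos - spec$stage2$predict(stage2, x_pos))

  structure(list(
    stage1 = stage1, stage2 = stage2, tau = tau, smear = smear,
    horizon = attr(train, "horizon"), schema = schema, spec = spec,
    params1 = params1, params2 = params2,
    cv = list(stage1 = scores1, stage2 = scores2),
    n_train = nrow(train), n_positive = sum(pos)
  ), class = "ec_hurdle")
}

#' Predict fishing hours with a fitted hurdle model
#'
#' Composes the two stages: `hours = 1{p >= tau} * S * exp(yhat_log) * area`.
#' Predictions are exactly zero wherever the class prediction is zero. The
#' feature schema hash must match the one recorded at fit time.
#'
#' @param model An `ec_hurdle`.
#' @param features An `ec_feature_table` / `ec_lead_dataset` (or plain tibble
#'   with all schema features).
#' @param pixel_areas Pixel areas (m^2), length 1 or one per row.
#' @return Tibble with `prob`, `pred_class`, `log_pred`, `hm2_pred`
#'   (S * exp(log) * class) and `hours`.
#' @export
predict_hours <- function(model, features, pixel_areas) {
  stopifnot(inherits(model, "ec_hurdle"))
  ft <- as_tibble(features)
  missing <- setdiff(model$schema$features$name, names(ft))
  if (length(missing) > 0) {
    ec_abort(sprintf("missing feature(s): %s", paste(missing, collapse = ", ")))
  }
  in_schema <- attr(features, "schema")
  if (!is.null(in_schema) && !identical(in_schema$hash, model$schema$hash)) {
    ec_abort("feature schema hash does not match the model's training schema")
  }
  design <- schema_design(ft, model$schema)
  prob <- model$spec$stage1$predict(model$stage1, design)
  pred_class <- as.integer(prob >= model$tau)
  log_pred <- model$spec$stage2$predict(model$stage2, design)
  hm2 <- pred_class * model$smear * exp(log_pred)
  tibble(prob = prob, pred_class = pred_class, log_pred = log_pred,
         hm2_pred = hm2, hours = hm2 * pixel_areas)
}

#' Evaluate a fitted hurdle on a held-out partition
#'
#' Convenience wrapper producing the region-stratified metric report from a
#' lead dataset with observed outcomes.
#'
#' @param model An `ec_hurdle`.
#' @param test An `ec_lead_dataset`.
#' @return An `ec_metric_report`.
#' @export
evaluate_hurdle <- function(model, test) {
  stopifnot(inherits(test, "ec_lead_dataset"), ".area_m2" %in% names(test))
  pred <- predict_hours(model, test, test$.area_m2)
  stratified_report(tibble(
    region = if ("mpa_region" %in% names(test)) test$mpa_region
             else "outside",
    occurrence = test$occurrence,
    prob = pred$prob, pred_class = pred$pred_class,
    y_level = test$outcome_hours / test$.area_m2,
    yhat_level = pred$hm2_pred
  ))
}

#' @export
print.ec_hurdle <- function(x, ...) {
  cat(sprintf(
    "<ec_hurdle> horizon %s | tau = %.4f | smearing S = %.4f\n",
    x$horizon %||% "?", x$tau, x$smear))
  cat(sprintf("  stage 1: %s%s | stage 2: %s%s | n = %d (%d positive)\n",
              x$spec$stage1$name,
              if (!is.null(x$params1)) sprintf(" (mtry %d, min_n %d)",
                                               x$params1$mtry, x$params1$min_n)
              else "",
              x$spec$stage2$name,
              if (!is.null(x$params2)) sprintf(" (mtry %d, min_n %d)",
                                               x$params2$mtry, x$params2$min_n)
              else "",
              x$n_train, x$n_positive))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summary of a fitted hurdle model
#'
#' One row per fitted component (stage 1, threshold, stage 2, smearing) with
#' its selected hyperparameters and cross-validated score.
#'
#' @param x An `ec_hurdle`.
#' @param ... Unused.
#' @export
tidy.ec_hurdle <- function(x, ...) {
  bind_rows(
    tibble(component = "stage1", learner = x$spec$stage1$name,
           mtry = x$params1$mtry %||% NA_integer_,
           min_n = x$params1$min_n %||% NA_integer_,
           estimate = NA_real_,
           cv_score = if (!is.null(x$cv$stage1))
             max(x$cv$stage1$roc_auc) else NA_real_,
           cv_metric = "roc_auc"),
    tibble(component = "threshold", learner = NA_character_,
           mtry = NA_integer_, min_n = NA_integer_,
           estimate = x$tau, cv_score = NA_real_, cv_metric = "f_meas"),
    tibble(component = "stage2", learner = x$spec$stage2$name,
           mtry = x$params2$mtry %||% NA_integer_,
           min_n = x$params2$min_n %||% NA_integer_,
           estimate = NA_real_,
           cv_score = if (!is.null(x$cv$stage2))
             max(x$cv$stage2$rsq_trad) else NA_real_,
           cv_metric = "rsq_trad"),
    tibble(component = "smearing", learner = NA_character_,
           mtry = NA_integer_, min_n = NA_integer_,
           estimate = x$smear, cv_score = NA_real_, cv_metric = NA_character_)
  )
}

#' One-row summary of a fitted hurdle model
#' @param x An `ec_hurdle`.
#' @param ... Unused.
#' @export
glance.ec_hurdle <- function(x, ...) {
  tibble(
    horizon = x$horizon %||% NA_integer_, n_train = x$n_train,
    n_positive = x$n_positive, tau = x$tau, smear = x$smear,
    cv_roc_auc = if (!is.null(x$cv$stage1)) max(x$cv$stage1$roc_auc)
    else NA_real_,
    cv_rsq_trad = if (!is.null(x$cv$stage2)) max(x$cv$stage2$rsq_trad)
    else NA_real_
  )
}

#' Serialise a fitted hurdle model's metadata
#'
#' Writes the JSON metadata (tau, smearing coefficient, schema hash, horizon,
#' selected hyperparameters, seed) next to the learner artifacts saved with
#' `saveRDS()`.
#'
#' @param model An `ec_hurdle`.
#' @param dir Output directory (created if needed).
#' @export
write_hurdle_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  write_json_file(list(
    tau = model$tau, smear = model$smear, horizon = model$horizon,
    schema_hash = model$schema$hash,
    params1 = model$params1, params2 = model$params2,
    seed = model$spec$seed
  ), file.path(dir, "metadata.json"))
  invisible(dir)
}
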