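#' Monte-Carlo Shapley attribution with background marginalization
#'
#' Estimates per-observation Shapley values for any prediction function by
#' permutation sampling: each sample draws a random feature ordering and a
#' random background row, and accumulates the marginal change in the
#' prediction as foreground feature values replace background values along
#' the ordering. Absent features are therefore marginalized over the
#' background sample (the Kernel-SHAP estimand). Per observation, the base
#' value plus the sum of the feature values reproduces the prediction
#' exactly (the telescoping sum is additive by construction, up to floating
#' point). Deterministic given the seed.
#'
#' For a fitted hurdle model, attribution is per stage: stage 1 on the
#' probability scale, stage 2 on the log-intensity scale (group magnitudes
#' are therefore scale-dependent across stages).
#'
#' @param object A prediction function `f(data.frame) -> numeric`, or an
#'   `ec_hurdle` (with `stage`).
#' @param foreground Feature rows to explain.
#' @param background Feature rows representing the background distribution
#'   (nonempty).
#' @param n_samples Number of (permutation, background row) samples per
#'   observation; must be at least `n_features + 2`.
#' @param seed Integer seed.
#' @param stage For `ec_hurdle` objects: `"stage1"` or `"stage2"`.
#' @param features Feature columns to attribute (default: all shared
#'   columns of foreground and background).
#' @return An `ec_shapley`: `phi` (tibble, one row per foreground
#'   observation), `base`, `pred`, the foreground rows, and the sampling
#'   parameters.
#' @export
shapley <- function(object, foreground, background, n_samples = 200,
                    seed = 1, stage = c("stage1", "stage2"),
                    features = NULL) {
  if (inherits(object, "ec_hurdle")) {
    stage <- match.arg(stage)
    model <- object
    f <- if (stage == "stage1") {
      function(x) model$spec$stage1$predict(model$stage1,
                                            schema_design(x, model$schema))
    } else {
      function(x) model$spec$stage2$predict(model$stage2,
                                            schema_design(x, model$schema))
    }
    features <- features %||% model$schema$features$name
  } else {
    stopifnot(is.function(object))
    f <- object
    features <- features %||% intersect(names(foreground), names(background))
  }
  foreground <- as_tibble(foreground)
  background <- as_tibble(background)
  if (nrow(background) == 0) ec_validation_error("background must be nonempty")
  p <- length(features)
  if (n_samples < p + 2) {
    ec_validation_error(sprintf(
      "n_samples (%d) must be at least n_features + 2 = %d", n_samples, p + 2))
  }
  set.seed(seed)
  n_f <- nrow(foreground)
  pred <- unname(f(foreground))

  phi <- matrix(0, n_f, p, dimnames = list(NULL, features))
  base <- numeric(n_f)
  other_cols <- setdiff(names(foreground), features)
  for (i in seq_len(n_f)) {
    perm_mat <- matrix(unlist(replicate(n_samples, sample.int(p),
                                        simplify = FALSE)), nrow = p)
    # balanced background draw: each background row appears (near-)equally
    # often, so background means are integrated with minimal variance
    bg_idx <- sample(rep_len(seq_len(nrow(background)), n_samples))
    # position of each feature within each chain's ordering
    pos_mat <- matrix(apply(perm_mat, 2, function(o) match(seq_len(p), o)),
                      nrow = p)
    # hybrid rows, chain-major: row j of chain c takes the first j permuted
    # features from the foreground observation, the rest from background
    row_in_chain <- rep(0:p, times = n_samples)
    chain_of <- rep(seq_len(n_samples), each = p + 1)
    hybrid <- vector("list", length(features))
    names(hybrid) <- features
    for (k in seq_len(p)) {
      fn <- features[k]
      v <- background[[fn]][bg_idx[chain_of]]
      v[row_in_chain >= pos_mat[k, chain_of]] <- foreground[[fn]][i]
      hybrid[[fn]] <- v
    }
    hy <- as_tibble(hybrid)
    for (cn in other_cols) hy[[cn]] <- foreground[[cn]][i]
    vals <- matrix(unname(f(hy)), nrow = p + 1)
    d_mat <- vals[-1, , drop = FALSE] - vals[-(p + 1), , drop = FALSE]
    sums <- rowsum(as.vector(d_mat), group = as.vector(perm_mat))
    phi[i, as.integer(rownames(sums))] <- sums[, 1] / n_samples
    base[i] <- mean(vals[1, ])
  }
  structure(list(
    phi = as_tibble(as.data.frame(phi)), base = base, pred = pred,
    foreground = foreground[, features, drop = FALSE],
    n_samples = n_samples, seed = seed, features = features
  ), class = "ec_shapley")
}

#' @export
print.ec_shapley <- function(x, ...) {
  cat(sprintf("<ec_shapley> %d observations x %d features (%d samples)\n",
              nrow(x$phi), length(x$features), x$n_samples))
  s <- sort(colMeans(abs(as.matrix(x$phi))), decreasing = TRUE)
  print(utils::head(round(s, 4), 10))
  invisible(x)
}

#' Mean absolute Shapley value per feature
#' @param result An `ec_shapley`.
#' @return Tibble `(feature, mean_abs_phi)` sorted descending.
#' @export
shapley_importance <- function(result) {
  tibble(feature = result$features,
         mean_abs_phi = unname(colMeans(abs(as.matrix(result$phi))))) |>
    arrange(dplyr::desc(.data$mean_abs_phi))
}

#' Default feature grouping for attribution
#'
#' Eight groups: previous fishing effort and year individually, plus the
#' geographic, environmental, technological, MPA-implementation, governance
#' and economic groups of the feature table.
#'
#' @param schema A feature schema.
#' @return Named list mapping group name to feature names.
#' @export
default_group_map <- function(schema) {
  ft <- schema$features
  grp <- list(
    previous_effort = "lag_log_effort",
    year = "year",
    mpa_implementation = ft$name[ft$group == "mpa"],
    environmental = ft$name[ft$group == "environmental"],
    geographic = ft$name[ft$group == "geographic"],
    governance = ft$name[ft$group == "governance"],
    economic = ft$name[ft$group == "economic"],
    technological = ft$name[ft$group == "technological"]
  )
  grp[purrr::map_int(grp, length) > 0]
}

#' Grouped Shapley values
#'
#' Exploits additivity: per observation, the group value is the sum of its
#' member features' values, so groups plus the base still reconstruct the
#' prediction. The summary is the mean absolute group value across
#' observations.
#'
#' @param result An `ec_shapley`.
#' @param group_map Named list of feature-name vectors partitioning the
#'   attributed features (unmapped features are an error).
#' @return List with `values` (per-observation tibble) and `summary`
#'   (`group`, `mean_abs_phi`).
#' @export
group_shapley <- function(result, group_map) {
  stopifnot(inherits(result, "ec_shapley"))
  mapped <- unlist(group_map, use.names = FALSE)
  unmapped <- setdiff(result$features, mapped)
  if (length(unmapped) > 0) {
    ec_abort(sprintf("feature(s) not covered by group_map: %s",
                     paste(unmapped, collapse = ", ")))
  }
  dup <- mapped[duplicated(mapped)]
  if (length(dup) > 0) {
    ec_abort(sprintf("group_map assigns feature(s) twice: %s",
                     paste(unique(dup), collapse = ", ")))
  }
  phi <- as.matrix(result$phi)
  values <- purrr::imap(group_map, function(feats, nm) {
    feats <- intersect(feats, result$features)
    rowSums(phi[, feats, drop = FALSE])
  }) |>
    as_tibble()
  list(
    values = values,
    summary = tibble(group = names(group_map),
                     mean_abs_phi = unname(purrr::map_dbl(
                       values, ~ mean(abs(.x))))) |>
      arrange(dplyr::desc(.data$mean_abs_phi))
  )
}

#' Dependence pairs for one feature
#'
#' One (feature value, Shapley value) pair per foreground observation,
#' export-ready for dependence plots.
#'
#' @param result An `ec_shapley`.
#' @param feature Feature name.
#' @return Tibble `(value, phi)`.
#' @export
dependence_table <- function(result, feature) {
  stopifnot(inherits(result, "ec_shapley"))
  if (!feature %in% result$features) {
    ec_abort(sprintf("feature `%s` not present in the Shapley result", feature))
  }
  tibble(value = result$foreground[[feature]],
         phi = result$phi[[feature]])
}

#' Write a Shapley result (long CSV + JSON summary)
#'
#' @param result An `ec_shapley`.
#' @param prefix Path prefix; writes `<prefix>_values.csv` and
#'   `<prefix>_summary.json`.
#' @param group_map Optional grouping for the summary.
#' @export
write_shapley <- function(result, prefix, group_map = NULL) {
  long <- as_tibble(result$phi) |>
    mutate(obs = row_number()) |>
    tidyr::pivot_longer(-"obs", names_to = "feature", values_to = "phi")
  readr::write_csv(long, paste0(prefix, "_values.csv"))
  summ <- list(per_feature = purrr::transpose(as.list(shapley_importance(result))))
  if (!is.null(group_map)) {
    summ$per_group <- purrr::transpose(
      as.list(group_shapley(result, group_map)$summary))
  }
  write_json_file(summ, paste0(prefix, "_summary.json"))
  invisible(prefix)
}
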