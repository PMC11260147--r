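#' ROC area under the curve
#'
#' Computed as the pairwise concordance probability — the probability that a
#' randomly chosen positive outscores a randomly chosen negative, ties
#' counted one half — via the rank formula (exactly the O(n^2) pairwise
#' count).
#'
#' @param probabilities Predicted scores.
#' @param labels 0/1 (or logical) class labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    ec_abort("roc_auc is undefined with a single class")
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

confusion_counts <- function(pred, labels) {
  labels <- as.integer(labels); pred <- as.integer(pred)
  list(tp = sum(pred == 1 & labels == 1),
       fp = sum(pred == 1 & labels == 0),
       fn = sum(pred == 0 & labels == 1),
       tn = sum(pred == 0 & labels == 0))
}

#' Precision, recall and F1 at a classification threshold
#'
#' Standard definitions: precision TP/(TP+FP), recall TP/(TP+FN), F1 their
#' harmonic mean (0 whenever TP = 0).
#'
#' @param pred Predicted 0/1 classes (or probabilities with `tau`).
#' @param labels Observed 0/1 labels.
#' @param tau Optional threshold applied to `pred` (`pred >= tau`).
#' @return Named list `precision`, `recall`, `f_meas`.
#' @export
classification_scores <- function(pred, labels, tau = NULL) {
  if (!is.null(tau)) pred <- as.integer(pred >= tau)
  cc <- confusion_counts(pred, labels)
  precision <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
  f <- if (cc$tp == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_meas = f)
}

#' @rdname classification_scores
#' @export
precision <- function(pred, labels, tau = NULL) {
  classification_scores(pred, labels, tau)$precision
}

#' @rdname classification_scores
#' @export
recall <- function(pred, labels, tau = NULL) {
  classification_scores(pred, labels, tau)$recall
}

#' @rdname classification_scores
#' @export
f_meas <- function(pred, labels, tau = NULL) {
  classification_scores(pred, labels, tau)$f_meas
}

#' Traditional (sum-of-squares) R-squared
#'
#' `1 - SSE/SST`; unbounded below, so poor predictors go negative. More
#' conservative than the squared correlation.
#'
#' @param y Observed values (needs variance and at least 2 points).
#' @param yhat Predicted values.
#' @return A value `<= 1`, possibly negative.
#' @export
rsq_trad <- function(y, yhat) {
  if (length(y) < 2 || var(y) == 0) {
    ec_abort("rsq_trad is undefined: need >= 2 observations with variance")
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Squared correlation R-squared
#' @inheritParams rsq_trad
#' @return A value in `[0, 1]`.
#' @export
rsq <- function(y, yhat) {
  if (length(y) < 2 || sd(y) == 0 || sd(yhat) == 0) return(NA_real_)
  cor(y, yhat)^2
}

#' Root-mean-square error
#' @inheritParams rsq_trad
#' @export
rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Normalised RMSE
#'
#' RMSE divided by the sample standard deviation of the observed outcome
#' (n-1 denominator); scale-invariant.
#'
#' @inheritParams rsq_trad
#' @export
nrmse <- function(y, yhat) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) ec_abort("nrmse is undefined when sd(y) = 0")
  rmse(y, yhat) / s
}

#' Region-stratified performance report
#'
#' Computes the stage-1 metrics (roc_auc, f_meas, precision, recall at the
#' model threshold) and stage-2 metrics on backtransformed level predictions
#' (rsq_trad, rsq, rmse in h/m^2, nrmse; positive-outcome rows only) for each
#' scope — global plus the mutually exclusive inside / partial / outside MPA
#' regions. Global is recomputed on all rows, never averaged over scopes.
#'
#' @param data Tibble with columns `region` (inside/partial/outside),
#'   `occurrence` (0/1 truth), `prob` (stage-1 probability), `pred_class`
#'   (0/1 at the model threshold), `y_level` (observed h/m^2) and
#'   `yhat_level` (predicted h/m^2 after smearing).
#' @param log_scale Also emit log-scale stage-2 diagnostics (`rsq_trad_log`)?
#' @return A `ec_metric_report` tibble, one row per scope; scopes with no
#'   rows are omitted with a message.
#' @export
stratified_report <- function(data, log_scale = FALSE) {
  data <- as_tibble(data)
  check_fields(data, c("region", "occurrence", "prob", "pred_class",
                       "y_level", "yhat_level"), "stratified_report data")
  scopes <- c("global", "inside", "partial", "outside")
  rows <- purrr::map(scopes, function(sc) {
    d <- if (sc == "global") data else filter(data, .data$region == sc)
    if (nrow(d) == 0) {
      message(sprintf("scope `%s` has no rows; omitted", sc))
      return(NULL)
    }
    auc <- tryCatch(roc_auc(d$prob, d$occurrence), error = function(e) NA_real_)
    cs <- classification_scores(d$pred_class, d$occurrence)
    pos <- filter(d, .data$occurrence == 1)
    s2 <- if (nrow(pos) >= 2 && var(pos$y_level) > 0) {
      list(rsq_trad = rsq_trad(pos$y_level, pos$yhat_level),
           rsq = rsq(pos$y_level, pos$yhat_level),
           rmse = rmse(pos$y_level, pos$yhat_level),
           nrmse = nrmse(pos$y_level, pos$yhat_level))
    } else {
      list(rsq_trad = NA_real_, rsq = NA_real_, rmse = NA_real_,
           nrmse = NA_real_)
    }
    out <- tibble(scope = sc, n = nrow(d), n_positive = nrow(pos),
                  roc_auc = auc, f_meas = cs$f_meas,
                  precision = cs$precision, recall = cs$recall,
                  rsq_trad = s2$rsq_trad, rsq = s2$rsq, rmse = s2$rmse,
                  nrmse = s2$nrmse)
    if (log_scale && nrow(pos) >= 2 &&
        all(c("y_log", "yhat_log") %in% names(pos)) &&
        var(pos$y_log) > 0) {
      out$rsq_trad_log <- rsq_trad(pos$y_log, pos$yhat_log)
    }
    out
  })
  out <- bind_rows(rows)
  class(out) <- c("ec_metric_report", class(out))
  out
}

#' Write a metric report to CSV or JSON
#' @param report An `ec_metric_report`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @export
write_metric_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    write_json_file(purrr::transpose(as.list(as_tibble(report))), path)
  } else {
    readr::write_csv(as_tibble(report), path)
  }
  invisible(path)
}
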