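# minimal synthetic lead dataset around an arbitrary feature -> outcome map
synthetic_lead <- function(n_per_year, years, gen, seed = 1, p = 2) {
  set.seed(seed)
  rows <- purrr::map(years, function(y) {
    x <- matrix(rnorm(n_per_year * p), n_per_year)
    colnames(x) <- paste0("x", seq_len(p))
    out <- gen(x)
    tibble::as_tibble(as.data.frame(x)) |>
      dplyr::mutate(pixel_id = dplyr::row_number(), feature_year = y - 1,
                    outcome_year = y, outcome_hours = out$hours,
                    occurrence = as.integer(out$hours > 0),
                    outcome_log_hm2 = ifelse(out$hours > 0, log(out$hours),
                                             NA_real_),
                    .area_m2 = 1)
  })
  d <- dplyr::bind_rows(rows)
  feats <- paste0("x", seq_len(p))
  schema <- list(
    features = tibble::tibble(name = feats, group = "synthetic",
                              type = "numeric"),
    levels = list(), log_floor = -30, no_mpa_sentinel = 0, version = 1L)
  schema$hash <- rlang::hash(schema[c("features", "levels", "version")])
  structure(d, schema = schema, horizon = 1L,
            class = c("ec_lead_dataset", class(tibble::tibble())))
}

test_that("the hyperparameter grid is a seeded 10-point maximin design", {
  spec <- hurdle_spec(seed = 3)
  g1 <- hp_grid(spec, p = 43)
  g2 <- hp_grid(spec, p = 43)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 10)
  expect_true(all(g1$mtry >= 1 & g1$mtry <= 43))
  expect_true(all(g1$min_n >= 2 & g1$min_n <= 40))
  g3 <- hp_grid(hurdle_spec(seed = 4), p = 43)
  expect_false(identical(g1$mtry, g3$mtry))
})

test_that("smearing coefficient is Duan's mean of exponentiated residuals", {
  expect_equal(smearing_coefficient(rep(0, 10)), 1)
  expect_equal(smearing_coefficient(c(log(2), log(0.5))), 1.25)
  set.seed(31)
  r <- rnorm(10000, 0, 0.5)
  expect_equal(smearing_coefficient(r), exp(0.125), tolerance = 0.02)
  expect_error(smearing_coefficient(numeric(0)), "empty")
})

test_that("threshold selection equals an exhaustive F1 scan", {
  # worked example: all-positive classification wins with F1 = 6/7
  fp <- tibble::tibble(prob = c(0.9, 0.8, 0.3, 0.2), label = c(1, 1, 0, 1))
  tau <- select_threshold(fp)
  expect_lt(tau, 0.2)
  expect_equal(f_meas(fp$prob, fp$label, tau = tau), 6 / 7)
  expect_equal(f_meas(fp$prob, fp$label, tau = 0.55), 0.8)

  # perfectly separated data: the midpoint of the separating gap is returned
  sep <- tibble::tibble(prob = c(0.9, 0.8, 0.2, 0.1), label = c(1, 1, 0, 0))
  expect_equal(select_threshold(sep), 0.5)

  # brute-force oracle over a dense threshold sweep, 50 random sets
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    fp <- tibble::tibble(prob = round(runif(n), 2),
                         label = rbinom(n, 1, 0.5))
    if (sum(fp$label) == 0) next
    tau <- select_threshold(fp)
    best <- max(vapply(seq(0, 1, by = 0.001), function(t)
      f_meas(fp$prob, fp$label, tau = t), numeric(1)))
    expect_equal(f_meas(fp$prob, fp$label, tau = tau), best,
                 tolerance = 1e-12)
  }

  # no achievable positive F1 -> documented fallback
  expect_warning(
    tau0 <- select_threshold(tibble::tibble(prob = c(0.4, 0.6),
                                            label = c(0, 0))),
    "falling back")
  expect_equal(tau0, 0.5)
})

test_that("stage-1 tuning averages fold AUCs and prefers simpler ties", {
  # signal requires both features: a 1-feature/huge-node combination can
  # never beat the full-signal combination
  lead <- synthetic_lead(150, 2016:2019, function(x) {
    list(hours = ifelse(x[, 1] * x[, 2] > 0,
                        exp(rnorm(nrow(x), 1, 0.1)), 0))
  }, seed = 5)
  plan <- make_time_folds(lead)
  spec <- hurdle_spec(learner_rf_class(100), learner_rf_reg(100), seed = 2)
  grid <- tibble::tibble(combo = 1:2, mtry = c(1L, 2L), min_n = c(140L, 5L))
  t1 <- tune_stage1(lead, plan, spec, grid = grid)
  expect_equal(t1$best$combo, 2)
  expect_gt(t1$scores$roc_auc[2], t1$scores$roc_auc[1])

  # duplicated combination: identical scores, first occurrence wins
  grid_dup <- tibble::tibble(combo = 1:2, mtry = c(2L, 2L),
                             min_n = c(5L, 5L))
  t2 <- tune_stage1(lead, plan, spec, grid = grid_dup)
  expect_equal(t2$scores$roc_auc[1], t2$scores$roc_auc[2])
  expect_equal(t2$best$combo, 1)

  # averaging over a single fold returns that fold's metric
  one_fold <- plan
  one_fold$folds <- plan$folds[1]
  t3 <- tune_stage1(lead, one_fold, spec, grid = grid[2, ])
  f <- plan$folds[[1]]
  design <- effortcast:::schema_design(lead, attr(lead, "schema"))
  m <- spec$stage1$fit(design[f$analysis, ], lead$occurrence[f$analysis],
                       list(mtry = 2L, min_n = 5L),
                       child_seed(spec$seed, "s1_2_5_1"))
  direct <- roc_auc(spec$stage1$predict(m, design[f$assessment, ]),
                    lead$occurrence[f$assessment])
  expect_equal(t3$scores$roc_auc, direct)
})

test_that("single-class folds are skipped with a warning", {
  lead <- synthetic_lead(40, 2016:2018, function(x) {
    list(hours = exp(rnorm(nrow(x))))  # all positive
  })
  # zeros only from 2017 on: the first fold's analysis year is single-class
  lead$outcome_hours[lead$outcome_year >= 2017 &
                       seq_len(nrow(lead)) %% 4 == 0] <- 0
  lead$occurrence <- as.integer(lead$outcome_hours > 0)
  plan <- make_time_folds(lead)
  spec <- hurdle_spec(learner_rf_class(50), learner_rf_reg(50), seed = 1)
  grid <- tibble::tibble(combo = 1L, mtry = 2L, min_n = 5L)
  # fold 2016->2017 has a single-class analysis split -> skipped
  expect_warning(tune_stage1(lead, plan, spec, grid = grid), "single class")
})

test_that("fitting composes the hurdle exactly and reproducibly", {
  lead <- synthetic_lead(120, 2016:2020, function(x) {
    p <- stats::plogis(1.2 * x[, 1])
    occ <- rbinom(nrow(x), 1, p)
    list(hours = occ * exp(0.8 * x[, 2] + rnorm(nrow(x), 0, 0.3)))
  }, seed = 9)
  sp <- temporal_split(lead)
  spec <- hurdle_spec(learner_rf_class(100), learner_rf_reg(100),
                      grid_size = 3, seed = 6)
  fit1 <- fit_hurdle(sp$train, spec)
  fit2 <- fit_hurdle(sp$train, spec)
  probe <- sp$test
  ph1 <- predict_hours(fit1, probe, probe$.area_m2)
  ph2 <- predict_hours(fit2, probe, probe$.area_m2)
  expect_identical(ph1, ph2)

  # stage-2 training rows are exactly the positive-outcome rows
  expect_equal(fit1$n_positive, sum(sp$train$outcome_hours > 0))
  expect_true(fit1$tau > 0 && fit1$tau < 1)
  expect_gt(fit1$smear, 0)

  # composition identity holds row-wise on every batch
  expect_equal(ph1$hours,
               ph1$pred_class * fit1$smear * exp(ph1$log_pred) *
                 probe$.area_m2)
  expect_true(all(ph1$hours[ph1$pred_class == 0] == 0))
  expect_true(all(ph1$hours[ph1$prob < fit1$tau] == 0))

  # doubling S doubles every positive prediction
  fit_s <- fit1; fit_s$smear <- 2 * fit1$smear
  ph_s <- predict_hours(fit_s, probe, probe$.area_m2)
  expect_equal(ph_s$hours, 2 * ph1$hours)

  # missing features are named; schema mismatch is caught
  expect_error(predict_hours(fit1, dplyr::select(probe, -"x1"), 1), "x1")
  alien <- synthetic_lead(10, 2016:2017, function(x)
    list(hours = exp(x[, 1])), p = 3)
  expect_error(predict_hours(fit1, alien, 1), "schema")

  # tidy/glance summarise the fitted components
  td <- tidy(fit1)
  expect_setequal(td$component, c("stage1", "threshold", "stage2",
                                  "smearing"))
  expect_equal(td$estimate[td$component == "smearing"], fit1$smear)
  gl <- glance(fit1)
  expect_equal(gl$tau, fit1$tau)
  expect_equal(gl$n_positive, fit1$n_positive)
})

test_that("the simple-learner contract runs the identical pipeline", {
  lead <- synthetic_lead(100, 2016:2019, function(x) {
    p <- stats::plogis(1.5 * x[, 1])
    occ <- rbinom(nrow(x), 1, p)
    list(hours = occ * exp(1 + 0.5 * x[, 2] + rnorm(nrow(x), 0, 0.2)))
  }, seed = 4)
  sp <- temporal_split(lead)
  fit <- fit_hurdle(sp$train, hurdle_spec(learner_logistic(),
                                          learner_linear(), seed = 2))
  ph <- predict_hours(fit, sp$test, 1)
  expect_true(all(is.finite(ph$hours)))
  expect_equal(ph$hours, ph$pred_class * fit$smear * exp(ph$log_pred))
  rep <- suppressMessages(evaluate_hurdle(fit, sp$test))
  expect_gt(rep$roc_auc[rep$scope == "global"], 0.7)
})

test_that("linear stage-2 recovers generator slopes within 10%", {
  n <- 5000
  set.seed(17)
  x <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
  y <- 2 + 0.7 * x$x1 - 1.3 * x$x2 + rnorm(n, 0, 0.4)
  lrn <- learner_linear()
  m <- lrn$fit(as.data.frame(x), y, list(), 1)
  expect_equal(unname(m$beta["x1"]), 0.7, tolerance = 0.10 * 0.7)
  expect_equal(unname(m$beta["x2"]), -1.3, tolerance = 0.10 * 1.3)
  expect_equal(unname(lrn$predict(m, data.frame(x1 = 0, x2 = 0))),
               unname(m$beta["(Intercept)"]))
})

test_that("the hurdle beats a zeros-included single-stage regressor", {
  # >= 30% structural zeros: composing occurrence x intensity should beat
  # one regressor trained on floored zeros, on level rsq_trad
  # strongly separable occurrence (the regime where the hurdle design pays)
  lead <- synthetic_lead(250, 2016:2020, function(x) {
    p <- stats::plogis(6 * (x[, 1] + 0.5))
    occ <- rbinom(nrow(x), 1, p)
    list(hours = occ * exp(1 + 0.9 * x[, 2] + rnorm(nrow(x), 0, 0.3)))
  }, seed = 12)
  expect_gt(mean(lead$outcome_hours == 0), 0.3)
  sp <- temporal_split(lead)
  spec <- hurdle_spec(learner_rf_class(150), learner_rf_reg(150),
                      grid_size = 3, seed = 8)
  fit <- fit_hurdle(sp$train, spec)
  ph <- predict_hours(fit, sp$test, 1)
  hurdle_rsq <- rsq_trad(sp$test$outcome_hours, ph$hours)

  floor_val <- attr(lead, "schema")$log_floor
  design <- effortcast:::schema_design(sp$train, attr(lead, "schema"))
  y_all <- ifelse(sp$train$outcome_hours > 0,
                  log(sp$train$outcome_hours), floor_val)
  single <- learner_rf_reg(150)$fit(design, y_all,
                                    list(mtry = 2, min_n = 5), 1)
  yhat_single <- exp(learner_rf_reg(150)$predict(
    single, effortcast:::schema_design(sp$test, attr(lead, "schema"))))
  single_rsq <- rsq_trad(sp$test$outcome_hours, yhat_single)
  expect_gt(hurdle_rsq, single_rsq)
})

test_that("model bundles serialise their metadata", {
  lead <- synthetic_lead(60, 2016:2018, function(x) {
    occ <- rbinom(nrow(x), 1, stats::plogis(x[, 1]))
    list(hours = occ * exp(x[, 2]))
  })
  fit <- fit_hurdle(lead, hurdle_spec(learner_logistic(), learner_linear(),
                                      seed = 1))
  dir <- withr::local_tempdir()
  write_hurdle_bundle(fit, dir)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$tau, fit$tau)
  expect_equal(meta$smear, fit$smear)
  expect_equal(meta$schema_hash, fit$schema$hash)
})
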