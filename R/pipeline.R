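#' Configuration for an end-to-end run
#'
#' Bundles every knob of the pipeline: the toy world, the behavioral
#' parameters embedded in the effort generator, the synthetic MPA history,
#' the feature groups, forecast horizons, the hurdle specification, the
#' scenario sweep and the attribution sample sizes. Fully serialisable to
#' YAML; its hash is recorded in every output.
#'
#' @param world Arguments for [world_config()].
#' @param behavior Arguments for [behavior_params()].
#' @param history Arguments for [synthetic_mpa_history()] (`n_mpas`,
#'   `mean_size`).
#' @param groups Feature groups to include.
#' @param horizons Forecast horizons to fit.
#' @param hurdle List: `learner` ("rf" or "simple"), `n_trees`, `grid_size`.
#' @param scenarios List: `enabled`, `rules`, `targets`.
#' @param shapley List: `enabled`, `n_foreground`, `n_background`,
#'   `n_samples`.
#' @param seed Master seed; every stage derives a child stream.
#' @return A `run_config` list.
#' @export
run_config <- function(world = list(), behavior = list(), history = list(),
                       groups = FEATURE_GROUPS, horizons = 1:3,
                       hurdle = list(), scenarios = list(), shapley = list(),
                       seed = 42) {
  cfg <- list(
    world = utils::modifyList(list(seed = seed), world),
    behavior = behavior,
    history = utils::modifyList(list(n_mpas = 10, mean_size = 3), history),
    groups = groups, horizons = as.integer(horizons),
    hurdle = utils::modifyList(
      list(learner = "rf", n_trees = 500, grid_size = 10,
           final_on_full = TRUE), hurdle),
    scenarios = utils::modifyList(
      list(enabled = TRUE, rules = c("random", "most_fished", "unfished"),
           targets = c(0.03, 0.05, 0.10, 0.16, 0.20, 0.30)), scenarios),
    shapley = utils::modifyList(
      list(enabled = FALSE, n_foreground = 50, n_background = 25,
           n_samples = 60), shapley),
    seed = as.integer(seed)
  )
  cfg$scenarios$targets <- sort(cfg$scenarios$targets)
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A `run_config` to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

hurdle_spec_from_config <- function(cfg, seed) {
  if (cfg$hurdle$learner == "simple") {
    hurdle_spec(stage1 = learner_logistic(), stage2 = learner_linear(),
                seed = seed)
  } else {
    hurdle_spec(stage1 = learner_rf_class(cfg$hurdle$n_trees),
                stage2 = learner_rf_reg(cfg$hurdle$n_trees),
                grid_size = cfg$hurdle$grid_size, seed = seed)
  }
}

log_stage <- function(log_path, stage, t0, extra = list()) {
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  line <- jsonlite::toJSON(c(list(stage = stage,
                                  elapsed_s = round(elapsed, 2),
                                  time = format(Sys.time(), "%FT%T")), extra),
                           auto_unbox = TRUE)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  message(sprintf("[%s] done in %.1fs", stage, elapsed))
  invisible(elapsed)
}

#' Run the full pipeline
#'
#' Sequences every stage: toy world, environment, synthetic MPA history,
#' effort simulation, feature assembly, per-horizon lead datasets with
#' temporal splits, hurdle fitting and held-out evaluation, final models on
#' the full data, the counterfactual scenario sweep, and (optionally)
#' Shapley attribution. Writes a deterministic artifact tree
#' (`world/`, `features/`, `models/`, `metrics/`, `scenarios/`, `shapley/`,
#' `manifest.json`) when `out_dir` is given, with a JSON-lines log of stage
#' timings and seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (optional; omit for an in-memory run).
#' @return Invisibly, a list with every intermediate object and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_path <- NULL
  if (!is.null(out_dir)) {
    for (d in c("", "world", "features", "models", "metrics", "scenarios",
                "shapley")) {
      dir.create(file.path(out_dir, d), showWarnings = FALSE, recursive = TRUE)
    }
    log_path <- file.path(out_dir, "run_log.jsonl")
  }
  config_hash <- rlang::hash(unclass(config))
  timings <- list()

  t0 <- Sys.time()
  wc <- do.call(world_config, config$world)
  world <- generate_world(wc)
  timings$world <- log_stage(log_path, "world", t0)

  t0 <- Sys.time()
  env <- simulate_environment(world)
  history <- do.call(synthetic_mpa_history,
                     c(list(world = world), config$history))
  behavior <- do.call(behavior_params, config$behavior)
  panel <- simulate_effort(world, env, history, behavior)
  timings$simulate <- log_stage(log_path, "simulate", t0)

  t0 <- Sys.time()
  features <- build_feature_table(world, env, panel, history,
                                  groups = config$groups)
  timings$features <- log_stage(log_path, "features", t0)

  models <- list(); final_models <- list(); metrics <- list()
  for (h in config$horizons) {
    t0 <- Sys.time()
    lead <- make_lead_dataset(features, panel, h)
    split <- temporal_split(lead)
    spec <- hurdle_spec_from_config(config,
                                    child_seed(config$seed, paste0("h", h)))
    fit <- fit_hurdle(split$train, spec)
    metrics[[as.character(h)]] <- evaluate_hurdle(fit, split$test) |>
      mutate(horizon = h)
    models[[as.character(h)]] <- fit
    final_models[[as.character(h)]] <- if (isTRUE(config$hurdle$final_on_full)) {
      fit_hurdle(lead, spec)
    } else {
      fit
    }
    timings[[paste0("fit_h", h)]] <- log_stage(
      log_path, paste0("fit_h", h), t0,
      list(tau = fit$tau, smear = fit$smear))
  }
  metric_report <- bind_rows(metrics)

  scenarios <- NULL; overlap <- NULL
  if (isTRUE(config$scenarios$enabled)) {
    t0 <- Sys.time()
    base_year <- max(world$config$years)
    effort_ref <- as_tibble(panel) |>
      filter(.data$year == base_year) |>
      select("pixel_id", "hours")
    bau <- run_bau(final_models, world, env, panel, history, base_year)
    nets <- list()
    rows <- list()
    for (rule in config$scenarios$rules) {
      for (tg in config$scenarios$targets) {
        net <- build_network(world, rule, tg, effort_ref, base_year,
                             seed = child_seed(config$seed, "scenario"))
        nm <- sprintf("%s_%02d", rule, round(100 * tg))
        nets[[nm]] <- net
        pred <- run_scenario(final_models, world, env, panel, history, net,
                             base_year)
        cmp <- compare_scenarios(pred, bau, world,
                                 network_union(history, net))
        rows[[nm]] <- cmp$aggregates |>
          mutate(rule = rule, target = tg, .before = 1)
      }
    }
    scenarios <- bind_rows(rows)
    overlap <- overlap_curve(nets, effort_ref, world)
    timings$scenarios <- log_stage(log_path, "scenarios", t0)
  }

  shap <- NULL
  if (isTRUE(config$shapley$enabled)) {
    t0 <- Sys.time()
    lead1 <- make_lead_dataset(features, panel, config$horizons[1])
    set.seed(child_seed(config$seed, "shapley_sample"))
    fg <- as_tibble(lead1)[sample.int(nrow(lead1),
                                      min(config$shapley$n_foreground,
                                          nrow(lead1))), ]
    bg <- as_tibble(lead1)[sample.int(nrow(lead1),
                                      min(config$shapley$n_background,
                                          nrow(lead1))), ]
    m1 <- final_models[[1]]
    shap <- list(
      stage1 = shapley(m1, fg, bg, n_samples = config$shapley$n_samples,
                       seed = child_seed(config$seed, "shap1"),
                       stage = "stage1"),
      stage2 = shapley(m1, fg, bg, n_samples = config$shapley$n_samples,
                       seed = child_seed(config$seed, "shap2"),
                       stage = "stage2")
    )
    timings$shapley <- log_stage(log_path, "shapley", t0)
  }

  manifest <- list(
    config_hash = config_hash, seed = config$seed,
    created = format(Sys.time(), "%FT%T"),
    horizons = config$horizons,
    timings_s = timings,
    stages = c("world", "simulate", "features", "fit", "metrics",
               if (!is.null(scenarios)) "scenarios",
               if (!is.null(shap)) "shapley")
  )

  if (!is.null(out_dir)) {
    readr::write_csv(world_layers(world), file.path(out_dir, "world",
                                                    "layers.csv"))
    write_network_csv(history, file.path(out_dir, "world", "mpa_history.csv"))
    write_panel_csv(panel, file.path(out_dir, "world", "effort_panel.csv"))
    readr::write_csv(as_tibble(env), file.path(out_dir, "world",
                                               "environment.csv"))
    write_feature_table(features, file.path(out_dir, "features",
                                            "features.csv"))
    for (h in names(final_models)) {
      write_hurdle_bundle(final_models[[h]],
                          file.path(out_dir, "models", paste0("horizon_", h)))
    }
    write_metric_report(metric_report, file.path(out_dir, "metrics",
                                                 "holdout_metrics.csv"))
    if (!is.null(scenarios)) {
      readr::write_csv(scenarios, file.path(out_dir, "scenarios",
                                            "aggregates.csv"))
      readr::write_csv(overlap, file.path(out_dir, "scenarios",
                                          "overlap.csv"))
    }
    if (!is.null(shap)) {
      write_shapley(shap$stage1, file.path(out_dir, "shapley", "stage1"),
                    default_group_map(final_models[[1]]$schema))
      write_shapley(shap$stage2, file.path(out_dir, "shapley", "stage2"),
                    default_group_map(final_models[[1]]$schema))
    }
    write_json_file(manifest, file.path(out_dir, "manifest.json"))
    write_run_config(config, file.path(out_dir, "config.yaml"))
  }

  invisible(list(
    config = config, world = world, environment = env, history = history,
    behavior = behavior, panel = panel, features = features,
    models = models, final_models = final_models, metrics = metric_report,
    scenarios = scenarios, overlap = overlap, shapley = shap,
    manifest = manifest
  ))
}
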