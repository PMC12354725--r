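#' Run the full PTML pipeline
#'
#' Orchestrates the stages end to end: validate -> impute -> features ->
#' split -> fit -> evaluate. Input is either a generated synthetic dataset
#' (when `config$simulate` is a [sim_config()]) or file paths in
#' `config$paths` (reactions, descriptors, variables). A manifest (package
#' version, seeds, config hash) is attached so any run is reproducible from
#' its configuration alone.
#'
#' @param config a list:
#'   * `simulate` — optional [sim_config()]; otherwise `paths` with
#'     `reactions`, `descriptors`, `variables`.
#'   * `scheme_id` — partition scheme (default `"PTML3"`).
#'   * `recipe` — a [feature_recipe()] (default [published_recipe()]).
#'   * `fit_population` — `"all"` or `"train"` (moving-average population).
#'   * `threshold` — binarization threshold; `NULL` uses the dataset mean,
#'     `79` reproduces the published rule.
#'   * `select` — `"all"`, `"fsw"` or `"fsw+egs"`; `forced_terms` for EGS.
#'   * `max_steps`, `enter_p` — stepwise controls.
#'   * `seed` — seed for any stochastic stage.
#'   * `out_dir` — optional directory for JSON/CSV artifacts.
#' @return a list of class `ptml_run`: `records`, `features`, `model`,
#'   `selection`, `metrics` (train/test regression metrics), `labels`,
#'   `class_threshold`, `validation` (report tibble), `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- modifyList(list(
    scheme_id = "PTML3", recipe = published_recipe("eq6"),
    fit_population = "all", threshold = NULL,
    select = "all", forced_terms = character(),
    max_steps = 10, enter_p = 0.05, seed = 1, out_dir = NULL
  ), config)

  if (!is.null(cfg$simulate)) {
    ds <- generate_dataset(cfg$simulate)
  } else {
    if (is.null(cfg$paths$reactions)) {
      abort("config needs either simulate or paths$reactions",
            class = "ptml_config_error")
    }
    for (p in unlist(cfg$paths)) {
      if (!file.exists(p)) {
        abort(paste0("missing input file: ", p), class = "ptml_config_error")
      }
    }
    ds <- read_dataset(cfg$paths$reactions,
                       descriptors = cfg$paths$descriptors,
                       variables = cfg$paths$variables)
  }
  records <- ds$records

  report <- validate_dataset(records, ds$descriptors, ds$variables)

  imp <- impute_group_mean(records, "catalyst_qty_s1")
  records <- imp$records
  variables <- if (!is.null(ds$variables)) {
    sync_catalyst_amount(ds$variables, records)
  }

  records <- stratified_split(records)

  scheme <- partition_scheme(cfg$scheme_id)
  features <- assemble_features(records, scheme = scheme, recipe = cfg$recipe,
                                fit_population = cfg$fit_population,
                                descriptors = ds$descriptors,
                                variables = variables)

  y <- records$yield_pct
  tr <- records$split_label == "t"
  selection <- switch(cfg$select,
    all = .feature_terms(features),
    fsw = forward_stepwise(features[tr, ], y[tr],
                           max_steps = cfg$max_steps, enter_p = cfg$enter_p),
    `fsw+egs` = expert_guided_selection(
      forward_stepwise(features[tr, ], y[tr],
                       max_steps = cfg$max_steps, enter_p = cfg$enter_p),
      cfg$forced_terms, recipe = cfg$recipe),
    abort(paste0("unknown select mode: ", cfg$select))
  )
  model <- fit_mlr(features[tr, ], y[tr], terms = selection)
  pred <- predict(model, features)

  thr <- cfg$threshold %||% mean(y, na.rm = TRUE)
  metrics <- list(
    train = regression_metrics(y[tr], pred[tr], threshold = thr),
    test = regression_metrics(y[!tr], pred[!tr], threshold = thr)
  )
  labels <- binarize_yield(y, threshold = thr)

  manifest <- list(
    package = "ptmlyield",
    version = as.character(utils::packageVersion("ptmlyield")),
    seed = cfg$seed,
    scheme_id = cfg$scheme_id,
    fit_population = cfg$fit_population,
    select = cfg$select,
    threshold = thr,
    n_records = nrow(records),
    n_train = sum(tr),
    config_hash = rlang::hash(cfg)
  )

  run <- structure(
    list(records = records, features = features, model = model,
         selection = selection, predictions = pred, metrics = metrics,
         labels = labels, class_threshold = thr, validation = report,
         imputation_log = imp$log, manifest = manifest),
    class = "ptml_run"
  )
  if (!is.null(cfg$out_dir)) .write_run_artifacts(run, cfg$out_dir)
  run
}

.write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_model(run$model, file.path(out_dir, "model.json"))
  readr::write_csv(run$features, file.path(out_dir, "features.csv"),
                   progress = FALSE)
  readr::write_csv(run$imputation_log, file.path(out_dir, "imputation_log.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(train = unclass(run$metrics$train), test = unclass(run$metrics$test)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.ptml_run <- function(x, ...) {
  m <- x$manifest
  cat("<ptml_run> ", m$n_records, " records (", m$n_train, " train), scheme ",
      m$scheme_id, "\n", sep = "")
  cat(sprintf("train: R %.4f  MAE %.2f%%  RMSE %.2f%%\n",
              x$metrics$train$r, x$metrics$train$mae, x$metrics$train$rmse))
  cat(sprintf("test:  R %.4f  MAE %.2f%%  RMSE %.2f%%\n",
              x$metrics$test$r, x$metrics$test$mae, x$metrics$test$rmse))
  invisible(x)
}
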