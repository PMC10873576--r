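#' Run configuration
#'
#' A run configuration ties the modules into a reproducible workflow. It is
#' an ordinary named list (conveniently read from YAML) with fields:
#'
#' * `workflow`: one of `"single"`, `"multi"`, `"design"`, `"simulate"`,
#'   `"evaluate"`.
#' * `synthetic`: a list of [synthetic_config()] arguments, *or* `dataset`:
#'   a directory written by [write_synthetic_study()] (files
#'   `train_NN.tif` / `val_NN.tif` / `test_NN.tif` with channel sidecars).
#' * `normalization`: recipe name (`"none"` for already-normalized data).
#' * `predictor`: list of [predictor_spec()] arguments.
#' * `stopping`: list with `kind` (`budget` | `cost_threshold` |
#'   `relative_improvement`) and the matching parameter.
#' * `layout`: path to a layout JSON (multi-panel only).
#' * `out_dir`: output directory; `seed`: global seed.
#'
#' The resolved configuration is serialized verbatim into the output
#' directory of every run.
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  workflows <- c("single", "multi", "design", "simulate", "evaluate")
  if (is.null(cfg$workflow) || !cfg$workflow %in% workflows) {
    abort(sprintf("config must select exactly one workflow (%s)",
                  paste(workflows, collapse = ", ")))
  }
  if (is.null(cfg$synthetic) && is.null(cfg$dataset)) {
    abort("config must provide either 'synthetic' parameters or a 'dataset' path")
  }
  if (!is.null(cfg$dataset) && !dir.exists(cfg$dataset)) {
    abort(sprintf("dataset directory not found: %s", cfg$dataset))
  }
  if (cfg$workflow == "multi") {
    if (is.null(cfg$layout)) abort("multi workflow requires a 'layout' path")
    if (is.character(cfg$layout) && !file.exists(cfg$layout)) {
      abort(sprintf("layout file not found: %s", cfg$layout))
    }
  }
  invisible(cfg)
}

resolve_stopping <- function(cfg) {
  s <- cfg$stopping %||% list(kind = "budget", budget = 3L)
  switch(s$kind,
    budget = stopping_budget(s$budget),
    cost_threshold = stopping_cost_threshold(s$threshold),
    relative_improvement = stopping_rel_improvement(s$min_improvement),
    abort(sprintf("unknown stopping kind: %s", s$kind))
  )
}

resolve_predictor <- function(cfg) {
  do.call(predictor_spec, cfg$predictor %||% list(backend = "linear"))
}

resolve_dataset <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    gen <- generate_dataset(do.call(synthetic_config, cfg$synthetic))
    gen$dataset
  } else {
    load_study(cfg$dataset)
  }
}

#' Load a study directory written by [write_synthetic_study()]
#'
#' @param dir Directory containing `train_NN.tif`, `val_NN.tif`,
#'   `test_NN.tif` images with channel-name sidecars.
#' @return A `multichannel_dataset`.
#' @export
load_study <- function(dir) {
  grab <- function(prefix) {
    files <- sort(list.files(dir, sprintf("^%s_[0-9]+\\.tif$", prefix),
                             full.names = TRUE))
    lapply(files, read_multichannel)
  }
  tr <- grab("train")
  if (!length(tr)) abort(sprintf("no training images found under %s", dir))
  multichannel_dataset(tr, grab("val"), grab("test"))
}

prepare_out_dir <- function(cfg) {
  out <- cfg$out_dir %||% file.path(tempdir(),
                                    format(Sys.time(), "panelpick_%Y%m%d%H%M%S"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  out
}

write_selection_outputs <- function(result, metrics, out) {
  write_selection_log(result, file.path(out, "selection_log.csv"))
  write_graph_json(result$graph, file.path(out, "graph.json"))
  writeLines(result$observed, file.path(out, "chosen_markers.txt"))
  jsonlite::write_json(
    list(overall_mse = metrics$overall_mse,
         per_marker = metrics$per_marker),
    file.path(out, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE
  )
  invisible(out)
}

#' Single-panel workflow: normalize, select, synthesize, evaluate
#'
#' Runs the full single-panel pipeline from a run configuration: obtain the
#' dataset (synthetic or from disk), normalize, select markers greedily,
#' predict the unobserved channels of every test image, and evaluate. The
#' output directory receives `config.yaml`, `selection_log.csv`,
#' `graph.json`, `chosen_markers.txt`, `metrics.json`, and one
#' `predicted_NN.tif` per test image.
#'
#' @param cfg A run configuration (list or YAML path).
#' @return The output directory path, invisibly; its `metrics.json` holds
#'   the evaluation.
#' @export
run_single_panel_workflow <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dataset <- resolve_dataset(cfg)
  recipe <- cfg$normalization %||% "none"
  if (recipe != "none") dataset <- normalize_dataset(dataset, recipe)
  out <- prepare_out_dir(cfg)
  result <- run_selection(dataset, resolve_predictor(cfg),
                          resolve_stopping(cfg),
                          seed = as.integer(cfg$seed %||% 1L))
  metrics <- evaluate_selection(result)
  write_selection_outputs(result, metrics, out)
  for (i in seq_along(dataset$test)) {
    pred <- predict(result$model, dataset$test[[i]])
    write_multichannel(pred, file.path(out, sprintf("predicted_%02d.tif", i)))
  }
  invisible(out)
}

#' Multi-panel workflow: per-panel selection with graph completion
#'
#' As [run_single_panel_workflow()], but markers are split across the panels
#' of the layout file, per-panel datasets are channel-masked from the source
#' dataset, selection runs on the completed graph, and multiply-predicted
#' markers are averaged. Per-panel model artifacts are written alongside the
#' usual outputs.
#'
#' @param cfg A run configuration (list or YAML path) with a `layout` entry
#'   (path to a layout JSON, or the layout list itself).
#' @return The output directory path, invisibly.
#' @export
run_multipanel_workflow <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dataset <- resolve_dataset(cfg)
  recipe <- cfg$normalization %||% "none"
  if (recipe != "none") dataset <- normalize_dataset(dataset, recipe)
  layout <- if (is.character(cfg$layout)) {
    read_layout_json(cfg$layout)
  } else if (inherits(cfg$layout, "panel_layout")) {
    cfg$layout
  } else {
    panel_layout(cfg$layout$panels, cfg$layout$capacity)
  }
  out <- prepare_out_dir(cfg)
  panel_datasets <- make_panel_datasets(dataset, layout)
  result <- run_multipanel_selection(
    panel_datasets, layout, resolve_predictor(cfg), resolve_stopping(cfg),
    seed = as.integer(cfg$seed %||% 1L),
    freeze_bounds = isTRUE(cfg$freeze_bounds)
  )
  metrics <- evaluate_selection(result, test = dataset$test)
  write_selection_outputs(result, metrics, out)
  for (p in seq_along(result$models)) {
    if (!is.null(result$models[[p]])) {
      save_predictor(result$models[[p]],
                     file.path(out, sprintf("panel_%d_model.json", p)))
    }
  }
  for (i in seq_along(dataset$test)) {
    pred <- predict_multipanel(result, dataset$test[[i]])
    write_multichannel(pred, file.path(out, sprintf("predicted_%02d.tif", i)))
  }
  invisible(out)
}
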