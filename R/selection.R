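#' Stopping criteria for the selection loop
#'
#' Exactly one of three stopping rules governs when the greedy loop halts:
#'
#' * `stopping_budget(B)` — stop once the observed set holds `B` markers
#'   (the default mode: panel sizes are fixed by imaging capacity).
#' * `stopping_cost_threshold(tau)` — stop once the *mean* node cost drops
#'   to `tau` or below.
#' * `stopping_rel_improvement(eps)` — stop once a round improves the total
#'   node cost by less than a fraction `eps` of the previous total.
#'
#' @param budget Integer number of markers to observe (`>= 1`).
#' @param threshold Nonnegative mean-node-cost threshold.
#' @param min_improvement Nonnegative relative improvement threshold.
#' @return A `stopping_criterion`.
#' @name stopping_criterion
NULL

#' @rdname stopping_criterion
#' @export
stopping_budget <- function(budget) {
  budget <- as.integer(budget)
  if (budget < 1) abort("budget must be at least 1")
  structure(list(kind = "budget", budget = budget),
            class = "stopping_criterion")
}

#' @rdname stopping_criterion
#' @export
stopping_cost_threshold <- function(threshold) {
  if (threshold < 0) abort("threshold must be nonnegative")
  structure(list(kind = "cost_threshold", threshold = threshold),
            class = "stopping_criterion")
}

#' @rdname stopping_criterion
#' @export
stopping_rel_improvement <- function(min_improvement) {
  if (min_improvement < 0) abort("min_improvement must be nonnegative")
  structure(list(kind = "relative_improvement",
                 min_improvement = min_improvement),
            class = "stopping_criterion")
}

#' Has the stopping criterion been satisfied?
#'
#' @param stop A `stopping_criterion`.
#' @param trace A selection trace tibble (see [run_selection()]) with at
#'   least one completed round for the cost-based criteria.
#' @return Logical scalar.
#' @export
stop_satisfied <- function(stop, trace) {
  if (!inherits(stop, "stopping_criterion")) {
    abort("stop must be a stopping_criterion")
  }
  if (!nrow(trace)) return(FALSE)
  last <- trace[nrow(trace), ]
  switch(stop$kind,
    budget = last$n_observed >= stop$budget,
    cost_threshold = is.finite(last$mean_cost) &&
      last$mean_cost <= stop$threshold,
    relative_improvement = {
      if (nrow(trace) < 2) return(FALSE)
      prev <- trace$total_cost[nrow(trace) - 1]
      cur <- last$total_cost
      if (!is.finite(prev) || prev <= 0) return(TRUE)
      (prev - cur) / prev < stop$min_improvement
    }
  )
}

#' Initial marker choice
#'
#' Before anything is observed node costs are undefined, so the first marker
#' is the one with minimal weighted out-degree (sum of its outgoing
#' loadings); intuitively the marker most similar, in aggregate, to all the
#' others. Ties break to the lowest marker index. Setting
#' `weighted = FALSE` uses the unweighted degree (constant on a complete
#' graph, hence always the first marker) for comparison.
#'
#' @param graph A `marker_graph` with an empty observed set.
#' @param weighted Use loadings-weighted degree (default `TRUE`).
#' @return A marker name.
#' @export
choose_initial_marker <- function(graph, weighted = TRUE) {
  if (length(graph$observed)) abort("initial marker already chosen")
  deg <- if (weighted) {
    rowSums(graph$loadings, na.rm = TRUE)
  } else {
    rep(length(graph$markers) - 1, length(graph$markers))
  }
  graph$markers[which.min(deg)] # which.min ties -> lowest index
}

#' Expected improvement of observing one more marker
#'
#' For each candidate `k` in the predicted set, computes the hypothetical
#' total node cost `psi(k)` that would result if `k` were observed, using
#' the current loadings: each predicted marker's hypothetical cost is the
#' minimum loading over in-edges from the observed set plus `k`, and `k`
#' itself (like all observed markers) costs 0. The greedy step picks the
#' candidate minimizing `psi`, ties to the lowest marker index.
#'
#' @param graph A `marker_graph` with nonempty observed and predicted sets.
#' @return A list with elements `marker` (the argmin), `psi` (its value),
#'   and `psi_all` (named vector over all candidates).
#' @export
expected_improvement <- function(graph) {
  obs <- graph$observed
  pred <- predicted_markers(graph)
  if (!length(pred)) abort("predicted set is empty; nothing to select")
  w <- graph$loadings
  psi <- vapply(pred, function(k) {
    sources <- c(obs, k)
    targets <- setdiff(pred, k)
    if (!length(targets)) return(0)
    sum(vapply(targets, function(i) min(w[sources, i]), numeric(1)))
  }, numeric(1))
  best <- which.min(psi)
  list(marker = pred[best], psi = unname(psi[best]), psi_all = psi)
}

#' Greedy predictive marker selection
#'
#' Runs the full single-panel selection loop: initialize the marker graph
#' from pairwise training-set dissimilarities; seed the observed set with
#' the minimal-weighted-degree marker; then iterate \{fit the predictor on
#' the training split for the current observed/predicted partition, measure
#' per-marker validation risks, overwrite activated edge loadings with those
#' risks, recompute node costs, add the marker with the best expected
#' improvement\} until the stopping criterion holds. A final predictor is
#' fit on the final observed set.
#'
#' @param dataset A normalized `multichannel_dataset` (>= 2 markers,
#'   nonempty validation split).
#' @param spec A [predictor_spec()].
#' @param stop A `stopping_criterion`.
#' @param seed Integer seed; every stochastic backend draws from a substream
#'   derived from it, so reruns reproduce the trace exactly.
#' @param graph Optional pre-built `marker_graph` (defaults to
#'   [init_edge_loadings()] on `dataset`).
#' @return A `selection_result`: list with `trace` (tibble: one row per
#'   round with `round`, `marker`, `psi`, `total_cost`, `mean_cost`,
#'   `n_observed`), `risks` (tibble of per-round per-marker validation
#'   risks), `observed`, `graph`, `model` (final fitted predictor), and
#'   `dataset`.
#' @export
run_selection <- function(dataset, spec, stop, seed = 1L, graph = NULL) {
  if (!is_multichannel_dataset(dataset)) {
    abort("dataset must be a multichannel_dataset")
  }
  if (!dataset_normalized(dataset)) {
    abort("dataset must be normalized before selection")
  }
  if (length(dataset$channel_names) < 2) abort("need at least 2 markers")
  if (inherits(stop, "stopping_criterion") && stop$kind == "budget" &&
      stop$budget > length(dataset$channel_names)) {
    abort("stopping budget exceeds the number of markers")
  }
  if (is.null(graph)) graph <- init_edge_loadings(dataset)

  first <- choose_initial_marker(graph)
  graph <- observe_marker(graph, first)
  nc <- node_costs(graph)
  trace <- tibble(
    round = 1L, marker = first, psi = NA_real_,
    total_cost = sum(nc$cost), mean_cost = mean(nc$cost),
    n_observed = 1L
  )
  risk_rows <- list()
  model <- NULL

  round <- 1L
  while (!stop_satisfied(stop, trace)) {
    round <- round + 1L
    if (!length(predicted_markers(graph))) break
    fit_seed <- derive_seed(seed, round)
    model <- tryCatch(
      fit_predictor(spec, dataset, graph$observed, seed = fit_seed),
      error = function(e) {
        abort(sprintf("predictor failed in round %d: %s",
                      round, conditionMessage(e)))
      }
    )
    risks <- validation_risks(model, dataset$val)
    graph <- update_edge_loadings(graph, risks)
    risk_rows[[length(risk_rows) + 1L]] <- tibble(
      round = round, marker = names(risks), risk = unname(risks)
    )
    ei <- expected_improvement(graph)
    graph <- observe_marker(graph, ei$marker)
    nc <- node_costs(graph)
    trace <- bind_rows(trace, tibble(
      round = round, marker = ei$marker, psi = ei$psi,
      total_cost = sum(nc$cost), mean_cost = mean(nc$cost),
      n_observed = length(graph$observed)
    ))
  }

  # final model on the final observed set (for prediction/evaluation)
  if (length(predicted_markers(graph))) {
    model <- fit_predictor(spec, dataset, graph$observed,
                           seed = derive_seed(seed, round + 1L))
    risks <- validation_risks(model, dataset$val)
    graph <- update_edge_loadings(graph, risks)
    risk_rows[[length(risk_rows) + 1L]] <- tibble(
      round = round + 1L, marker = names(risks), risk = unname(risks)
    )
  }

  structure(
    list(
      trace = trace,
      risks = if (length(risk_rows)) bind_rows(risk_rows) else
        tibble(round = integer(), marker = character(), risk = numeric()),
      observed = graph$observed,
      graph = graph,
      model = model,
      dataset = dataset,
      seed = seed
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d rounds, %d / %d markers observed\n",
              nrow(x$trace), length(x$observed), length(x$graph$markers)))
  cat("observed:", paste(x$observed, collapse = ", "), "\n")
  cat(sprintf("final total node cost: %.6g\n", total_node_cost(x$graph)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return One row per selection round: the marker added, its expected
#'   improvement `psi`, and the total/mean node cost after that round's
#'   loading update.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$trace

#' @rdname tidy.selection_result
#' @return `glance()`: a one-row tibble with `n_markers`, `n_observed`,
#'   `rounds`, `total_cost`, `mean_cost`.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    n_markers = length(x$graph$markers),
    n_observed = length(x$observed),
    rounds = nrow(x$trace),
    total_cost = total_node_cost(x$graph),
    mean_cost = total_node_cost(x$graph) / length(x$graph$markers)
  )
}

#' Plot the node-cost trajectory of a selection run
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot: mean node cost (the overall unpredictability being
#'   minimized) against selection round, annotated with the marker chosen at
#'   each round.
#' @method autoplot selection_result
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- object$trace
  ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$mean_cost)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$marker),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "selection round", y = "mean node cost",
                  title = "Unpredictability across marker selection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write the per-round selection log as CSV
#'
#' Columns: round, marker, psi, total and mean node cost, observed count,
#' plus one risk column per marker (validation risk in that round, NA once
#' observed or before the first fit).
#'
#' @param result A `selection_result`.
#' @param path Output CSV path.
#' @export
write_selection_log <- function(result, path) {
  wide <- result$risks |>
    mutate(marker = paste0("risk_", .data$marker)) |>
    tidyr::pivot_wider(names_from = "marker", values_from = "risk")
  log <- dplyr::left_join(result$trace, wide, by = "round")
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
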