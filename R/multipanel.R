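#' Panel layout: markers split across overlapping panels
#'
#' When the full marker set of interest exceeds what one sample can be
#' imaged with, markers are split into `m` panels bounded by the imaging
#' capacity. Panels must pairwise overlap enough that the *panel graph*
#' (panels as nodes, edges between panels with nonempty marker
#' intersection) is connected — otherwise no cross-panel loading could ever
#' be bounded.
#'
#' @param panels List of character vectors, one marker subset per panel.
#' @param capacity Maximum markers imageable in one panel.
#' @return A `panel_layout`.
#' @export
panel_layout <- function(panels, capacity = max(lengths(panels))) {
  panels <- lapply(panels, as.character)
  layout <- structure(
    list(panels = panels, capacity = as.integer(capacity),
         markers = unique(unlist(panels))),
    class = "panel_layout"
  )
  validate_panel_layout(layout)
  layout
}

#' @rdname panel_layout
#' @param layout A `panel_layout`.
#' @param markers Optional full marker set the panel union must equal.
#' @export
validate_panel_layout <- function(layout, markers = NULL) {
  panels <- layout$panels
  if (length(panels) < 1) abort("layout needs at least one panel")
  for (i in seq_along(panels)) {
    if (anyDuplicated(panels[[i]])) {
      abort(sprintf("panel %d contains duplicate markers", i))
    }
    if (length(panels[[i]]) > layout$capacity) {
      abort(sprintf("panel %d exceeds the imaging capacity (%d > %d)",
                    i, length(panels[[i]]), layout$capacity))
    }
  }
  if (!is.null(markers) && !setequal(unlist(panels), markers)) {
    abort("the union of panels must equal the full marker set")
  }
  m <- length(panels)
  if (m > 1) {
    adj <- matrix(FALSE, m, m)
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        adj[i, j] <- adj[j, i] <- length(intersect(panels[[i]], panels[[j]])) > 0
      }
    }
    reach <- rep(FALSE, m)
    frontier <- 1L
    reach[1] <- TRUE
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & !reach)
      reach[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(reach)) {
      abort(sprintf(
        "panel graph is disconnected: panel(s) %s are unreachable",
        paste(which(!reach), collapse = ", ")
      ))
    }
  }
  invisible(layout)
}

#' @export
print.panel_layout <- function(x, ...) {
  cat(sprintf("<panel_layout> %d panels, capacity %d, %d markers\n",
              length(x$panels), x$capacity, length(x$markers)))
  for (i in seq_along(x$panels)) {
    cat(sprintf("  panel %d (%d): %s\n", i, length(x$panels[[i]]),
                paste(x$panels[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' Read / write a panel layout as JSON
#'
#' Format: `{"capacity": c, "panels": [[marker, ...], ...]}`.
#'
#' @param layout A `panel_layout`.
#' @param path File path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(list(capacity = layout$capacity,
                            panels = layout$panels),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path)
  panel_layout(lapply(obj$panels, function(p) unlist(p)),
               capacity = obj$capacity)
}

#' Simulate per-panel acquisition by channel-masking a full dataset
#'
#' Each panel's dataset contains exactly that panel's channels — emulating
#' samples imaged with different panels from one fully imaged dataset.
#'
#' @param dataset A `multichannel_dataset` covering all markers.
#' @param layout A `panel_layout`.
#' @return A list of `multichannel_dataset`, one per panel.
#' @export
make_panel_datasets <- function(dataset, layout) {
  validate_panel_layout(layout, markers = dataset$channel_names)
  lapply(layout$panels, function(p) subset_dataset(dataset, p))
}

# Assemble the full marker graph from per-panel subgraphs:
#  * pair in >= 1 common panel: mean of per-panel loadings while all are
#    initial dissimilarities (the overlap-averaging rule); the minimum over
#    panels once any containing panel's edge carries a model risk (node
#    costs take the min over activated in-edges, so one stored edge per
#    ordered pair must carry the per-pair minimum);
#  * both markers observed: 0;
#  * no common panel: minimal chained triangle-inequality bound (shortest
#    path over intra-panel edges), witness recorded.
assemble_multipanel <- function(panel_graphs, layout, observed = character(),
                                frozen_cross = NULL) {
  markers <- layout$markers
  n <- length(markers)
  w <- matrix(NA_real_, n, n, dimnames = list(markers, markers))
  tg <- matrix(NA_character_, n, n, dimnames = list(markers, markers))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      mi <- markers[i]
      mj <- markers[j]
      in_p <- which(vapply(layout$panels,
                           function(p) mi %in% p && mj %in% p, logical(1)))
      if (!length(in_p)) next
      vals <- vapply(in_p, function(p) panel_graphs[[p]]$loadings[mi, mj],
                     numeric(1))
      tags <- vapply(in_p, function(p) panel_graphs[[p]]$tags[mi, mj],
                     character(1))
      if (all(tags == "initial_dissimilarity")) {
        w[i, j] <- mean(vals)
        tg[i, j] <- "initial_dissimilarity"
      } else {
        k <- which.min(vals)
        w[i, j] <- vals[k]
        tg[i, j] <- tags[k]
      }
    }
  }
  if (length(observed) > 1) {
    w[observed, observed] <- 0
    tg[observed, observed] <- "zeroed"
    diag(w) <- NA_real_
    diag(tg) <- NA_character_
  }
  cross <- is.na(w) & row(w) != col(w)
  witnesses <- list()
  if (any(cross)) {
    if (!is.null(frozen_cross)) {
      w[cross] <- frozen_cross$loadings[cross]
      tg[cross] <- "inferred_bound"
      witnesses <- frozen_cross$witnesses
    } else {
      comp <- infer_cross_panel(w, markers)
      w[cross] <- comp$w[cross]
      tg[cross] <- "inferred_bound"
      witnesses <- comp$witnesses
    }
  }
  g <- marker_graph(markers, ifelse(is.na(w) & row(w) != col(w), 0, w),
                    observed = observed, tags = tg)
  g$loadings <- w
  dimnames(g$loadings) <- list(markers, markers)
  g$witnesses <- witnesses
  g
}

# Shortest-path completion of cross-panel loadings over the directed graph
# whose edges are the available intra-panel loadings (equivalent to
# depth-first path enumeration with the min taken over path sums).
infer_cross_panel <- function(w, markers) {
  n <- length(markers)
  has_edge <- which(!is.na(w), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = markers[has_edge[, 1]], to = markers[has_edge[, 2]],
               weight = w[has_edge]),
    directed = TRUE,
    vertices = data.frame(name = markers)
  )
  dist <- igraph::distances(g, mode = "out", weights = igraph::E(g)$weight,
                            algorithm = "dijkstra")
  dist <- dist[markers, markers]
  witnesses <- list()
  out <- w
  for (i in seq_len(n)) {
    cross_j <- which(is.na(w[i, ]) & seq_len(n) != i)
    if (!length(cross_j)) next
    sp <- igraph::shortest_paths(g, from = markers[i],
                                 to = markers[cross_j], mode = "out",
                                 weights = igraph::E(g)$weight,
                                 output = "vpath")
    for (k in seq_along(cross_j)) {
      j <- cross_j[k]
      if (!is.finite(dist[i, j])) {
        abort(sprintf("no connecting path between %s and %s: panel graph disconnected",
                      markers[i], markers[j]))
      }
      out[i, j] <- dist[i, j]
      witnesses[[paste0(markers[i], "->", markers[j])]] <- list(
        from = markers[i], to = markers[j],
        path = names(sp$vpath[[k]]),
        loading = dist[i, j]
      )
    }
  }
  list(w = out, witnesses = witnesses)
}

#' Complete cross-panel edge loadings by chained triangle inequality
#'
#' For every pair of markers never imaged together, the loading is bounded
#' above by the minimum, over all panel-connecting paths through overlap
#' markers, of the summed intra-panel loadings along the path (the chained
#' triangle inequality). Implemented as single-source shortest paths over
#' the graph restricted to intra-panel edges; the witness path of each
#' inferred loading is recorded.
#'
#' @param panel_graphs List of per-panel `marker_graph`s (same order as
#'   `layout$panels`).
#' @param layout A `panel_layout`.
#' @param observed Character vector of observed markers (default none).
#' @return A completed `marker_graph` over all markers, with cross-panel
#'   edges tagged `inferred_bound` and `$witnesses` carrying their paths.
#' @export
complete_cross_panel <- function(panel_graphs, layout, observed = character()) {
  assemble_multipanel(panel_graphs, layout, observed = observed)
}

#' Initialize the multi-panel marker graph
#'
#' Per-panel subgraphs are initialized from each panel dataset's pairwise
#' training dissimilarities, then combined: overlap pairs get the average of
#' their per-panel dissimilarities, single-panel pairs their panel's value,
#' and cross-panel pairs the chained triangle-inequality bound.
#'
#' @param panel_datasets List of normalized per-panel
#'   `multichannel_dataset`s (as from [make_panel_datasets()]).
#' @param layout A `panel_layout`.
#' @return A completed `marker_graph` (see [complete_cross_panel()]).
#' @export
init_multipanel_graph <- function(panel_datasets, layout) {
  if (length(panel_datasets) != length(layout$panels)) {
    abort("one dataset per panel is required")
  }
  for (p in seq_along(layout$panels)) {
    if (!setequal(panel_datasets[[p]]$channel_names, layout$panels[[p]])) {
      abort(sprintf("panel %d dataset channels do not match its markers", p))
    }
  }
  panel_graphs <- lapply(panel_datasets, init_edge_loadings)
  complete_cross_panel(panel_graphs, layout)
}

#' Greedy selection in the multi-panel setting
#'
#' Round 0 builds the completed graph ([init_multipanel_graph()]). Each
#' round, the next marker is chosen by [expected_improvement()] on the
#' completed graph; then only the panel model(s) whose panel contains the
#' newly selected marker are retrained (both, if it is an overlap marker),
#' that panel's intra-panel edges are updated with its per-panel validation
#' risks, and the cross-panel bounds are re-derived from the current
#' intra-panel loadings (set `freeze_bounds = TRUE` to keep the Round-0
#' bounds instead).
#'
#' @param panel_datasets List of normalized per-panel datasets.
#' @param layout A `panel_layout`.
#' @param spec A [predictor_spec()].
#' @param stop A `stopping_criterion`.
#' @param seed Integer seed.
#' @param freeze_bounds Keep Round-0 cross-panel bounds (default `FALSE`:
#'   re-derive each round from the updated intra-panel loadings).
#' @return A `multipanel_result`: like a `selection_result` (trace with an
#'   extra `retrained_panels` column, per-round risks with a `panel`
#'   column), plus `panel_graphs`, `models` (one per panel), and `layout`.
#' @export
run_multipanel_selection <- function(panel_datasets, layout, spec, stop,
                                     seed = 1L, freeze_bounds = FALSE) {
  validate_panel_layout(layout)
  for (ds in panel_datasets) {
    if (!dataset_normalized(ds)) {
      abort("all panel datasets must be normalized")
    }
  }
  markers <- layout$markers
  if (inherits(stop, "stopping_criterion") && stop$kind == "budget" &&
      stop$budget > length(markers)) {
    abort("stopping budget exceeds the number of markers")
  }
  panel_graphs <- lapply(panel_datasets, init_edge_loadings)
  graph <- complete_cross_panel(panel_graphs, layout)
  frozen <- if (freeze_bounds) {
    list(loadings = graph$loadings, witnesses = graph$witnesses)
  } else {
    NULL
  }
  models <- vector("list", length(layout$panels))

  panels_of <- function(mk) {
    which(vapply(layout$panels, function(p) mk %in% p, logical(1)))
  }

  first <- choose_initial_marker(graph)
  observed <- first
  for (p in panels_of(first)) {
    panel_graphs[[p]] <- observe_marker(panel_graphs[[p]], first)
  }
  graph <- assemble_multipanel(panel_graphs, layout, observed, frozen)
  nc <- node_costs(graph)
  trace <- tibble(
    round = 1L, marker = first, psi = NA_real_,
    total_cost = sum(nc$cost), mean_cost = mean(nc$cost),
    n_observed = 1L, retrained_panels = ""
  )
  risk_rows <- list()

  round <- 1L
  last <- first
  while (!stop_satisfied(stop, trace)) {
    round <- round + 1L
    if (!length(predicted_markers(graph))) break
    retrained <- integer()
    for (p in panels_of(last)) {
      obs_p <- intersect(observed, layout$panels[[p]])
      pred_p <- setdiff(layout$panels[[p]], obs_p)
      if (!length(obs_p) || !length(pred_p)) next
      model <- tryCatch(
        fit_predictor(spec, panel_datasets[[p]], obs_p,
                      seed = derive_seed(seed, round, p)),
        error = function(e) {
          abort(sprintf("panel %d predictor failed in round %d: %s",
                        p, round, conditionMessage(e)))
        }
      )
      risks <- validation_risks(model, panel_datasets[[p]]$val)
      panel_graphs[[p]] <- update_edge_loadings(panel_graphs[[p]], risks)
      models[[p]] <- model
      retrained <- c(retrained, p)
      risk_rows[[length(risk_rows) + 1L]] <- tibble(
        round = round, panel = p, marker = names(risks),
        risk = unname(risks)
      )
    }
    graph <- assemble_multipanel(panel_graphs, layout, observed, frozen)
    ei <- expected_improvement(graph)
    observed <- c(observed, ei$marker)
    for (p in panels_of(ei$marker)) {
      panel_graphs[[p]] <- observe_marker(panel_graphs[[p]], ei$marker)
    }
    graph <- assemble_multipanel(panel_graphs, layout, observed, frozen)
    nc <- node_costs(graph)
    trace <- bind_rows(trace, tibble(
      round = round, marker = ei$marker, psi = ei$psi,
      total_cost = sum(nc$cost), mean_cost = mean(nc$cost),
      n_observed = length(observed),
      retrained_panels = paste(retrained, collapse = ";")
    ))
    last <- ei$marker
  }

  # fit final models for panels retrained by the last pick, so every panel's
  # model reflects the final partition
  for (p in panels_of(last)) {
    obs_p <- intersect(observed, layout$panels[[p]])
    pred_p <- setdiff(layout$panels[[p]], obs_p)
    if (!length(obs_p) || !length(pred_p)) {
      models[p] <- list(NULL)
      next
    }
    models[[p]] <- fit_predictor(spec, panel_datasets[[p]], obs_p,
                                 seed = derive_seed(seed, round + 1L, p))
    risks <- validation_risks(models[[p]], panel_datasets[[p]]$val)
    panel_graphs[[p]] <- update_edge_loadings(panel_graphs[[p]], risks)
    risk_rows[[length(risk_rows) + 1L]] <- tibble(
      round = round + 1L, panel = p, marker = names(risks),
      risk = unname(risks)
    )
  }
  graph <- assemble_multipanel(panel_graphs, layout, observed, frozen)

  structure(
    list(
      trace = trace,
      risks = if (length(risk_rows)) bind_rows(risk_rows) else
        tibble(round = integer(), panel = integer(), marker = character(),
               risk = numeric()),
      observed = observed,
      graph = graph,
      panel_graphs = panel_graphs,
      models = models,
      layout = layout,
      panel_datasets = panel_datasets,
      seed = seed
    ),
    class = c("multipanel_result", "selection_result")
  )
}

#' Average predictions of markers predicted by several panel models
#'
#' Markers appearing in multiple inputs receive the unweighted pixel-wise
#' mean of the predictions; single-model markers pass through unchanged.
#'
#' @param predictions List of `multichannel_image`s over the same pixel
#'   grid (channel sets may overlap).
#' @return A `multichannel_image` over the union of channels (first-seen
#'   order).
#' @export
merge_predictions <- function(predictions) {
  if (!length(predictions)) abort("no predictions to merge")
  d <- image_dim(predictions[[1]])
  for (p in predictions) {
    if (!all(image_dim(p) == d)) abort("predictions lie on different pixel grids")
  }
  all_ch <- unique(unlist(lapply(predictions, channel_names)))
  out <- array(0, c(length(all_ch), d[1], d[2]))
  cnt <- numeric(length(all_ch))
  for (p in predictions) {
    idx <- match(channel_names(p), all_ch)
    for (k in seq_along(idx)) {
      out[idx[k], , ] <- out[idx[k], , ] + p$pixels[k, , ]
      cnt[idx[k]] <- cnt[idx[k]] + 1
    }
  }
  for (k in seq_along(all_ch)) out[k, , ] <- out[k, , ] / cnt[k]
  multichannel_image(out, all_ch, predictions[[1]]$normalized)
}

#' Predict all unobserved markers of an image with the panel models
#'
#' Each panel model predicts its panel's unobserved markers from the image's
#' channels for that panel's observed markers; overlapping predictions are
#' averaged with [merge_predictions()].
#'
#' @param result A `multipanel_result`.
#' @param img A `multichannel_image` containing (at least) all observed
#'   channels.
#' @return A `multichannel_image` over all predicted markers.
#' @export
predict_multipanel <- function(result, img) {
  preds <- list()
  for (p in seq_along(result$models)) {
    model <- result$models[[p]]
    if (is.null(model)) next
    preds[[length(preds) + 1L]] <- predict(model, img)
  }
  if (!length(preds)) abort("no panel models available for prediction")
  merged <- merge_predictions(preds)
  want <- setdiff(result$graph$markers, result$observed)
  missing <- setdiff(want, channel_names(merged))
  if (length(missing)) {
    abort(sprintf("markers predicted by no panel model: %s",
                  paste(missing, collapse = ", ")))
  }
  subset_channels(merged, want)
}
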