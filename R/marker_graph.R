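#' Directed marker graph with edge loadings
#'
#' The selection method organises markers as a complete directed graph.
#' Every ordered pair `(i, j)` carries a nonnegative *loading* `w[i, j]`
#' measuring (an approximate upper bound on) the unpredictability of marker
#' `j` from marker `i`: loadings are initialized as pairwise L1 image
#' dissimilarities and later overwritten with the validation risk of the
#' fitted predictive model. Edges whose origin marker is observed are
#' *activated*; only activated edges feed node costs.
#'
#' @param markers Ordered character vector of marker identifiers.
#' @param loadings `N x N` numeric matrix of edge loadings (diagonal ignored
#'   and stored as `NA`).
#' @param observed Character vector of observed (imaged) markers.
#' @param tags Optional `N x N` character matrix of per-edge provenance tags
#'   (`initial_dissimilarity`, `model_risk`, `zeroed`, `inferred_bound`).
#' @return A `marker_graph`.
#' @export
marker_graph <- function(markers, loadings, observed = character(),
                         tags = NULL) {
  markers <- as.character(markers)
  n <- length(markers)
  if (n < 2) abort("a marker graph needs at least 2 markers")
  if (anyDuplicated(markers)) abort("marker names must be unique")
  if (!is.matrix(loadings) || any(dim(loadings) != n)) {
    abort("loadings must be an N x N matrix")
  }
  diag(loadings) <- NA_real_
  off <- loadings[row(loadings) != col(loadings)]
  if (any(!is.finite(off)) || any(off < 0)) {
    abort("all edge loadings must be finite and nonnegative")
  }
  if (!all(observed %in% markers)) abort("observed markers must be a subset")
  if (is.null(tags)) {
    tags <- matrix("initial_dissimilarity", n, n)
    diag(tags) <- NA_character_
  }
  dimnames(loadings) <- dimnames(tags) <- list(markers, markers)
  structure(
    list(markers = markers, loadings = loadings,
         observed = as.character(observed), tags = tags,
         witnesses = list()),
    class = "marker_graph"
  )
}

#' @export
print.marker_graph <- function(x, ...) {
  cat(sprintf(
    "<marker_graph> %d markers (%d observed, %d predicted)\n",
    length(x$markers), length(x$observed),
    length(x$markers) - length(x$observed)
  ))
  if (length(x$observed)) {
    cat("observed:", paste(x$observed, collapse = ", "), "\n")
    tc <- sum(node_costs(x)$cost)
    cat(sprintf("total node cost: %.6g\n", tc))
  }
  invisible(x)
}

predicted_markers <- function(graph) setdiff(graph$markers, graph$observed)

#' Pairwise L1 dissimilarity between two channel image sets
#'
#' The dissimilarity measure `xi` used everywhere: the mean absolute
#' per-pixel difference, pooled over all pixels of all supplied images (the
#' empirical expectation over the image set). This same function measures
#' validation risks, so loadings and risks are directly comparable.
#'
#' @param a,b Numeric matrices/arrays, or lists of them (one per image),
#'   holding the same marker pair's channels over the same pixel grids.
#' @return A nonnegative scalar.
#' @export
dissimilarity <- function(a, b) l1_dissimilarity(a, b)

#' Initialize edge loadings from pairwise channel dissimilarities
#'
#' Builds the complete directed graph over a dataset's markers, with both
#' directions of each pair set to the L1 dissimilarity of the two channels
#' over the training split. No marker is observed yet.
#'
#' @param dataset A normalized `multichannel_dataset` with at least 2
#'   markers.
#' @return A `marker_graph` with symmetric loadings and tag
#'   `initial_dissimilarity` on every edge.
#' @export
init_edge_loadings <- function(dataset) {
  if (!is_multichannel_dataset(dataset)) {
    abort("dataset must be a multichannel_dataset")
  }
  nm <- dataset$channel_names
  n <- length(nm)
  if (n < 2) abort("at least 2 markers are required")
  w <- matrix(0, n, n)
  chans <- lapply(seq_len(n), function(i) {
    lapply(dataset$train, function(im) im$pixels[i, , ])
  })
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      d <- l1_dissimilarity(chans[[i]], chans[[j]])
      w[i, j] <- d
      w[j, i] <- d
    }
  }
  marker_graph(nm, w)
}

#' Node costs of a marker graph
#'
#' The cost of a predicted marker is the minimum loading over its activated
#' in-edges (edges from observed markers); observed markers cost 0. The sum
#' of node costs is the selection objective: the current estimate of overall
#' unpredictability.
#'
#' @param graph A `marker_graph` with a nonempty observed set.
#' @return A tibble with columns `marker`, `observed`, `cost`; the total is
#'   `sum(.$cost)` (see [total_node_cost()]).
#' @export
node_costs <- function(graph) {
  if (!length(graph$observed)) {
    abort("node costs are undefined before any marker is observed")
  }
  obs <- graph$observed
  cost <- vapply(graph$markers, function(m) {
    if (m %in% obs) return(0)
    min(graph$loadings[obs, m])
  }, numeric(1))
  tibble(
    marker = graph$markers,
    observed = graph$markers %in% obs,
    cost = unname(cost)
  )
}

#' @rdname node_costs
#' @export
total_node_cost <- function(graph) sum(node_costs(graph)$cost)

#' Update edge loadings from predictor validation risks
#'
#' After a predictive model is (re)trained on the current observed set, each
#' predicted marker's validation risk (L1 dissimilarity of prediction vs.
#' truth on the validation split) replaces the loading of *every* activated
#' in-edge of that marker; edges between two observed markers become 0; all
#' other edges (predicted to observed, predicted to predicted) keep their
#' values — unpredictability is only meaningful from observation to
#' prediction.
#'
#' @param graph A `marker_graph` with a nonempty observed set.
#' @param risks Named numeric vector: validation risk per predicted marker
#'   (must cover exactly the predicted set).
#' @return The updated `marker_graph`.
#' @export
update_edge_loadings <- function(graph, risks) {
  obs <- graph$observed
  if (!length(obs)) abort("no observed markers; nothing to update")
  pred <- predicted_markers(graph)
  if (!setequal(names(risks), pred)) {
    extra <- setdiff(names(risks), pred)
    missing <- setdiff(pred, names(risks))
    abort(sprintf(
      "risks must cover exactly the predicted markers (missing: %s; not predicted: %s)",
      paste(missing, collapse = ",") , paste(extra, collapse = ",")
    ))
  }
  if (any(!is.finite(risks)) || any(risks < 0)) {
    abort("risks must be finite and nonnegative")
  }
  w <- graph$loadings
  tg <- graph$tags
  for (j in pred) {
    w[obs, j] <- risks[[j]]
    tg[obs, j] <- "model_risk"
  }
  if (length(obs) > 1) {
    w[obs, obs] <- 0
    tg[obs, obs] <- "zeroed"
    diag(w) <- NA_real_
    diag(tg) <- NA_character_
  }
  graph$loadings <- w
  graph$tags <- tg
  graph
}

observe_marker <- function(graph, marker) {
  if (!marker %in% graph$markers) abort(sprintf("unknown marker: %s", marker))
  if (marker %in% graph$observed) {
    abort(sprintf("marker already observed: %s", marker))
  }
  graph$observed <- c(graph$observed, marker)
  # edges among observed markers carry no unpredictability
  obs <- graph$observed
  if (length(obs) > 1) {
    graph$loadings[obs, obs] <- 0
    graph$tags[obs, obs] <- "zeroed"
    diag(graph$loadings) <- NA_real_
    diag(graph$tags) <- NA_character_
  }
  graph
}

#' Edge list of a marker graph
#'
#' @param graph A `marker_graph`.
#' @return A tibble with columns `from`, `to`, `loading`, `tag`,
#'   `activated`.
#' @export
graph_edges <- function(graph) {
  n <- length(graph$markers)
  idx <- which(row(graph$loadings) != col(graph$loadings), arr.ind = TRUE)
  tibble(
    from = graph$markers[idx[, 1]],
    to = graph$markers[idx[, 2]],
    loading = graph$loadings[idx],
    tag = graph$tags[idx],
    activated = graph$markers[idx[, 1]] %in% graph$observed
  ) |>
    arrange(.data$from, .data$to)
}

#' Serialize / restore a marker graph as JSON
#'
#' The JSON carries markers, observed set, the dense loading matrix
#' (row-major, `null` on the diagonal), per-edge tags, and witness paths of
#' inferred cross-panel edges. The round trip is lossless.
#'
#' @param graph A `marker_graph`.
#' @param path File path.
#' @return `write_graph_json()` returns `path` invisibly;
#'   `read_graph_json()` returns a `marker_graph`.
#' @export
write_graph_json <- function(graph, path) {
  obj <- list(
    markers = graph$markers,
    observed = graph$observed,
    loadings = unname(lapply(seq_len(nrow(graph$loadings)), function(i) {
      as.list(graph$loadings[i, ])
    })),
    tags = unname(lapply(seq_len(nrow(graph$tags)), function(i) {
      as.list(graph$tags[i, ])
    })),
    witnesses = graph$witnesses
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path)
  markers <- unlist(obj$markers)
  n <- length(markers)
  w <- matrix(NA_real_, n, n)
  tg <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- obj$loadings[[i]][[j]]
      if (!is.null(v)) w[i, j] <- as.numeric(v)
      t <- obj$tags[[i]][[j]]
      if (!is.null(t)) tg[i, j] <- as.character(t)
    }
  }
  w2 <- w
  w2[is.na(w2)] <- 0 # placate validator; diagonal is reset to NA inside
  g <- marker_graph(markers, w2, unlist(obj$observed) %||% character(),
                    tags = tg)
  g$loadings <- w
  dimnames(g$loadings) <- list(markers, markers)
  g$witnesses <- lapply(obj$witnesses, function(w) {
    list(from = w$from, to = w$to, path = unlist(w$path),
         loading = as.numeric(w$loading))
  })
  names(g$witnesses) <- names(obj$witnesses)
  g
}

#' Write the edge list as CSV for inspection
#'
#' @param graph A `marker_graph`.
#' @param path File path.
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(graph_edges(graph), path, row.names = FALSE)
  invisible(path)
}
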