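#' Reduce marker feature vectors to 2-D coordinates
#'
#' Principal-component projection of the centered feature vectors onto the
#' top two components, as the coordinate system in which markers are grouped
#' into candidate panels. A deterministic sign convention is applied: within
#' each component, the largest-magnitude coordinate is made positive.
#' Markers without features (NA rows) are carried through with NA
#' coordinates and assigned to panels at random later.
#'
#' @param features A data frame with a `marker` column and numeric feature
#'   columns (as from [generate_marker_features()] or a feature CSV
#'   `marker,f1,...,fd`); rows with any NA are treated as featureless.
#' @return A tibble with columns `marker`, `pc1`, `pc2`.
#' @export
reduce_features <- function(features) {
  f <- as.data.frame(features)
  if (!"marker" %in% names(f)) abort("features must have a 'marker' column")
  x <- as.matrix(f[, setdiff(names(f), "marker"), drop = FALSE])
  storage.mode(x) <- "double"
  has <- stats::complete.cases(x)
  if (sum(has) < 2) abort("at least 2 markers must have feature vectors")
  if (ncol(x) < 2) abort("feature dimension must be at least 2")
  xc <- scale(x[has, , drop = FALSE], center = TRUE, scale = FALSE)
  pc <- stats::prcomp(xc, center = FALSE, scale. = FALSE, rank. = 2)
  scores <- pc$x
  if (ncol(scores) < 2) {
    scores <- cbind(scores, matrix(0, nrow(scores), 2 - ncol(scores)))
  }
  for (k in 1:2) {
    j <- which.max(abs(scores[, k]))
    if (scores[j, k] < 0) scores[, k] <- -scores[, k]
  }
  out <- tibble(marker = f$marker, pc1 = NA_real_, pc2 = NA_real_)
  out$pc1[has] <- scores[, 1]
  out$pc2[has] <- scores[, 2]
  out
}

#' Cluster markers in the reduced coordinates
#'
#' k-means on the 2-D marker coordinates with a fixed seed. Featureless
#' markers (NA coordinates) stay unassigned (`cluster = NA`) and are placed
#' at random by [build_panels()].
#'
#' @param coords A tibble from [reduce_features()].
#' @param k Number of clusters (`1 <= k <=` number of featured markers).
#' @param seed Integer seed.
#' @return `coords` with an integer `cluster` column.
#' @export
cluster_markers <- function(coords, k, seed = 1L) {
  has <- !is.na(coords$pc1) & !is.na(coords$pc2)
  if (k < 1) abort("k must be at least 1")
  if (k > sum(has)) abort("k exceeds the number of featured markers")
  x <- as.matrix(coords[has, c("pc1", "pc2")])
  coords$cluster <- NA_integer_
  if (k == sum(has)) {
    # singleton clusters: k-means is ill-posed, assignment is forced
    coords$cluster[has] <- seq_len(k)
    return(coords)
  }
  cl <- with_rng(seed, {
    stats::kmeans(x, centers = k, nstart = 10, iter.max = 100)
  })
  coords$cluster[has] <- as.integer(cl$cluster)
  coords
}

#' Build balanced, overlapping, connected panels from marker clusters
#'
#' Panels are seeded from the clusters, rebalanced deterministically so that
#' base sizes differ by at most one (markers move, highest index first, from
#' the largest to the smallest panel), featureless markers are assigned
#' uniformly at random, and then `overlap_size` markers are shared between
#' each consecutive pair of panels (the first `overlap_size` markers of
#' panel `i + 1` are added to panel `i`), chaining the panels into a
#' connected panel graph.
#'
#' @param assignment A tibble with `marker` and `cluster` columns (from
#'   [cluster_markers()]); `NA` clusters mean featureless.
#' @param capacity Imaging capacity per panel (must be at least the balanced
#'   base size plus `overlap_size`).
#' @param overlap_size Number of shared markers between consecutive panels
#'   (`>= 1`; 0 would disconnect the panel graph).
#' @param seed Integer seed for the featureless-marker assignment.
#' @return A validated `panel_layout`.
#' @export
build_panels <- function(assignment, capacity, overlap_size = 2L, seed = 1L) {
  overlap_size <- as.integer(overlap_size)
  if (overlap_size < 1) {
    abort("overlap_size must be at least 1: empty overlaps disconnect the panel graph")
  }
  if (capacity < overlap_size + 1) {
    abort("capacity must exceed overlap_size")
  }
  ks <- sort(unique(assignment$cluster[!is.na(assignment$cluster)]))
  m <- length(ks)
  panels <- lapply(ks, function(k) assignment$marker[
    !is.na(assignment$cluster) & assignment$cluster == k
  ])
  # featureless markers: uniform random panel
  loose <- assignment$marker[is.na(assignment$cluster)]
  if (length(loose)) {
    pick <- with_rng(seed, sample.int(m, length(loose), replace = TRUE))
    for (i in seq_along(loose)) {
      panels[[pick[i]]] <- c(panels[[pick[i]]], loose[i])
    }
  }
  # deterministic rebalancing: move the highest-index marker of the largest
  # panel to the smallest until base sizes differ by <= 1
  repeat {
    sizes <- lengths(panels)
    if (max(sizes) - min(sizes) <= 1) break
    from <- which.max(sizes)
    to <- which.min(sizes)
    mover <- panels[[from]][length(panels[[from]])]
    panels[[from]] <- panels[[from]][-length(panels[[from]])]
    panels[[to]] <- c(panels[[to]], mover)
  }
  if (max(lengths(panels)) + overlap_size > capacity && m > 1) {
    abort(sprintf(
      "infeasible: balanced panel size %d plus overlap %d exceeds capacity %d",
      max(lengths(panels)), overlap_size, capacity
    ))
  }
  if (m > 1) {
    if (any(lengths(panels) < overlap_size)) {
      abort("overlap_size exceeds the smallest panel")
    }
    base <- panels
    for (i in seq_len(m - 1)) {
      panels[[i]] <- c(panels[[i]], base[[i + 1]][seq_len(overlap_size)])
    }
  }
  panel_layout(panels, capacity = capacity)
}

#' Average within-panel channel dissimilarity of a layout
#'
#' The mean, over panels, of the average pairwise L1 channel dissimilarity
#' inside each panel — the quantity feature-guided panel design tries to
#' keep low (similar markers in one panel are most predictable from each
#' other). Used to compare a designed layout against random partitions.
#'
#' @param layout A `panel_layout`.
#' @param dissim A symmetric marker dissimilarity matrix with dimnames (for
#'   example `init_edge_loadings(dataset)$loadings`).
#' @return A scalar.
#' @export
layout_dissimilarity <- function(layout, dissim) {
  per_panel <- vapply(layout$panels, function(p) {
    if (length(p) < 2) return(0)
    sub <- dissim[p, p]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  mean(per_panel)
}

#' Compare a layout against random partitions of the same shape
#'
#' Draws `n` random layouts with the same panel sizes and overlap structure
#' (marker labels permuted uniformly) and computes their within-panel
#' dissimilarities.
#'
#' @param layout A `panel_layout`.
#' @param dissim Marker dissimilarity matrix (see [layout_dissimilarity()]).
#' @param n Number of random partitions.
#' @param seed Integer seed.
#' @return A list with `observed` (the layout's dissimilarity), `random`
#'   (vector of length `n`), and `quantile` (fraction of random partitions
#'   with dissimilarity at or below the layout's).
#' @export
compare_random_partitions <- function(layout, dissim, n = 1000L, seed = 1L) {
  markers <- layout$markers
  obs <- layout_dissimilarity(layout, dissim)
  rand <- with_rng(seed, {
    vapply(seq_len(n), function(i) {
      perm <- stats::setNames(sample(markers), markers)
      shuffled <- lapply(layout$panels, function(p) unname(perm[p]))
      layout_dissimilarity(list(panels = shuffled, markers = markers), dissim)
    }, numeric(1))
  })
  list(observed = obs, random = rand,
       quantile = mean(rand <= obs))
}
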