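graph_from_w <- function(markers, edges, observed = character()) {
  n <- length(markers)
  w <- matrix(0, n, n, dimnames = list(markers, markers))
  for (e in edges) {
    w[e[[1]], e[[2]]] <- e[[3]]
    w[e[[2]], e[[1]]] <- e[[3]]
  }
  marker_graph(markers, w, observed = observed)
}

test_that("panel layouts validate capacity, union, and connectivity", {
  expect_error(panel_layout(list(c("A", "B"), c("C", "D"))),
               "disconnected")
  expect_error(panel_layout(list(c("A", "B", "C"), c("C", "D")),
                            capacity = 2), "capacity")
  lay <- panel_layout(list(c("A", "B", "C"), c("C", "D")))
  expect_equal(lay$markers, c("A", "B", "C", "D"))
  expect_error(validate_panel_layout(lay, markers = c("A", "B", "C")),
               "union")
  # layout JSON round trip
  path <- file.path(withr::local_tempdir(), "layout.json")
  write_layout_json(lay, path)
  back <- read_layout_json(path)
  expect_equal(back$panels, lay$panels)
  expect_equal(back$capacity, lay$capacity)
})

test_that("three-case initialization: averaging, single panel, triangle bound", {
  # panels {1,2,M}, {M,3}: the overlap marker M appears in both
  pA <- graph_from_w(c("m1", "m2", "M"),
                     list(list("m1", "m2", 0.6), list("m1", "M", 0.3),
                          list("m2", "M", 0.4)))
  pB <- graph_from_w(c("M", "m3"), list(list("M", "m3", 0.2)))
  lay <- panel_layout(list(c("m1", "m2", "M"), c("M", "m3")))
  g <- complete_cross_panel(list(pA, pB), lay)
  # case 2: within one panel
  expect_equal(g$loadings["m1", "m2"], 0.6)
  expect_equal(g$loadings["m1", "M"], 0.3)
  # case 3: chained triangle bound m1 -> M -> m3
  expect_equal(g$loadings["m1", "m3"], 0.5)
  expect_equal(g$tags["m1", "m3"], "inferred_bound")
  wt <- g$witnesses[["m1->m3"]]
  expect_equal(wt$path, c("m1", "M", "m3"))
  expect_equal(wt$loading, 0.5)

  # case 1: a pair inside the overlap set averages its per-panel values
  pA2 <- graph_from_w(c("m1", "Ma", "Mb"),
                      list(list("m1", "Ma", 0.5), list("m1", "Mb", 0.9),
                           list("Ma", "Mb", 0.2)))
  pB2 <- graph_from_w(c("Ma", "Mb", "m3"),
                      list(list("Ma", "Mb", 0.4), list("Ma", "m3", 0.1),
                           list("Mb", "m3", 0.6)))
  lay2 <- panel_layout(list(c("m1", "Ma", "Mb"), c("Ma", "Mb", "m3")))
  g2 <- complete_cross_panel(list(pA2, pB2), lay2)
  expect_equal(g2$loadings["Ma", "Mb"], 0.3) # (0.2 + 0.4) / 2
  # two overlap paths: min over them (0.5+0.1 vs 0.9+0.6)
  expect_equal(g2$loadings["m1", "m3"], 0.6)
  expect_equal(g2$witnesses[["m1->m3"]]$path, c("m1", "Ma", "m3"))
})

test_that("cross-panel completion equals brute-force path enumeration", {
  set.seed(31)
  for (case in 1:20) {
    m <- 2 + case %% 5 # panels
    n <- min(12, m * 2 + sample(0:3, 1))
    markers <- sprintf("x%02d", seq_len(n))
    # chained panels over a random permutation, consecutive overlap 1-2
    perm <- sample(markers)
    cuts <- sort(sample(2:(n - 1), m - 1))
    bounds <- c(0, cuts, n)
    panels <- lapply(seq_len(m), function(i) {
      lo <- bounds[i] + 1
      hi <- bounds[i + 1]
      ov <- if (i < m) perm[hi + seq_len(min(2, n - hi))] else character()
      unique(c(perm[lo:hi], ov))
    })
    if (any(lengths(panels) < 2)) next
    lay <- tryCatch(panel_layout(panels), error = function(e) NULL)
    if (is.null(lay)) next
    pgs <- lapply(panels, function(p) {
      np <- length(p)
      w <- matrix(runif(np * np), np, np)
      w <- (w + t(w)) / 2
      marker_graph(p, w)
    })
    g <- complete_cross_panel(pgs, lay)
    # oracle adjacency: NA where no shared panel, else the assembled value
    wa <- matrix(NA_real_, n, n, dimnames = list(markers, markers))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        vals <- c()
        for (p in seq_len(m)) {
          if (markers[i] %in% panels[[p]] && markers[j] %in% panels[[p]]) {
            vals <- c(vals, pgs[[p]]$loadings[markers[i], markers[j]])
          }
        }
        if (length(vals)) wa[i, j] <- mean(vals)
      }
    }
    cross <- which(is.na(wa) & row(wa) != col(wa), arr.ind = TRUE)
    for (r in seq_len(nrow(cross))) {
      i <- cross[r, 1]
      j <- cross[r, 2]
      expect_equal(
        g$loadings[markers[i], markers[j]],
        min_path_oracle(wa, i, j),
        tolerance = 1e-12
      )
    }
    # every witness path is verifiable: legs sum to the stored loading
    for (wt in g$witnesses) {
      legs <- 0
      for (s in seq_len(length(wt$path) - 1)) {
        legs <- legs + wa[wt$path[s], wt$path[s + 1]]
      }
      expect_equal(legs, wt$loading, tolerance = 1e-12)
    }
  }
})

test_that("all-zero intra loadings infer all-zero cross bounds", {
  pA <- graph_from_w(c("a", "M"), list(list("a", "M", 0)))
  pB <- graph_from_w(c("M", "b"), list(list("M", "b", 0)))
  lay <- panel_layout(list(c("a", "M"), c("M", "b")))
  g <- complete_cross_panel(list(pA, pB), lay)
  expect_equal(g$loadings["a", "b"], 0)
})

test_that("merging averages multiply-predicted markers pixel-wise", {
  mk <- function(vals, names) {
    px <- array(0, c(length(names), 2, 2))
    for (i in seq_along(names)) px[i, , ] <- vals[i]
    multichannel_image(px, names, "z")
  }
  m1 <- mk(c(1, 5), c("X", "Y"))
  m2 <- mk(c(3, 7), c("X", "Z"))
  out <- merge_predictions(list(m1, m2))
  expect_setequal(channel_names(out), c("X", "Y", "Z"))
  expect_equal(get_channel(out, "X"), matrix(2, 2, 2))
  expect_equal(get_channel(out, "Y"), matrix(5, 2, 2)) # single model: pass-through
  expect_equal(get_channel(out, "Z"), matrix(7, 2, 2))
  m3 <- mk(c(8), "X")
  out3 <- merge_predictions(list(m1, m2, m3))
  expect_equal(get_channel(out3, "X"), matrix((1 + 3 + 8) / 3, 2, 2))
  bad <- mk(c(1), "X")
  bad$pixels <- array(1, c(1, 3, 3))
  expect_error(merge_predictions(list(m1, bad)), "different pixel grids")
})

test_that("a single-panel layout reduces multi-panel selection to the single run", {
  gen <- generate_dataset(synthetic_config(noise_sd = 0.1))
  ds <- gen$dataset
  lay <- panel_layout(list(ds$channel_names))
  res_m <- run_multipanel_selection(make_panel_datasets(ds, lay), lay,
                                    predictor_spec("linear"),
                                    stopping_budget(4), seed = 5)
  res_s <- run_selection(ds, predictor_spec("linear"), stopping_budget(4),
                         seed = 5)
  expect_identical(res_m$observed, res_s$observed)
  expect_equal(res_m$trace$total_cost, res_s$trace$total_cost)
  expect_equal(res_m$trace$psi, res_s$trace$psi)
  expect_equal(res_m$trace$marker, res_s$trace$marker)
  ev_m <- evaluate_selection(res_m, test = ds$test)
  ev_s <- evaluate_selection(res_s)
  expect_equal(ev_m$overall_mse, ev_s$overall_mse, tolerance = 1e-12)
})

test_that("only panels containing the last-selected marker are retrained", {
  gen <- generate_dataset(synthetic_config(noise_sd = 0.1))
  lay <- chained_layout_12()
  res <- run_multipanel_selection(make_panel_datasets(gen$dataset, lay), lay,
                                  predictor_spec("linear"),
                                  stopping_budget(5), seed = 2)
  panels_of <- function(mk) {
    which(vapply(lay$panels, function(p) mk %in% p, logical(1)))
  }
  tr <- res$trace
  for (r in 2:nrow(tr)) {
    prev_marker <- tr$marker[r - 1]
    claimed <- as.integer(strsplit(tr$retrained_panels[r], ";")[[1]])
    eligible <- panels_of(prev_marker)
    expect_true(all(claimed %in% eligible))
    # panels of the previous pick retrain unless fully observed/unobservable
    for (p in eligible) {
      obs_p <- intersect(res$observed[seq_len(r - 1)], lay$panels[[p]])
      pred_p <- setdiff(lay$panels[[p]], obs_p)
      if (length(obs_p) && length(pred_p)) expect_true(p %in% claimed)
    }
  }
  # reruns reproduce the trace
  res2 <- run_multipanel_selection(make_panel_datasets(gen$dataset, lay), lay,
                                   predictor_spec("linear"),
                                   stopping_budget(5), seed = 2)
  expect_equal(res$trace, res2$trace)
})

test_that("multi-panel prediction covers every unobserved marker exactly once", {
  gen <- generate_dataset(synthetic_config(noise_sd = 0.1))
  lay <- chained_layout_12()
  res <- run_multipanel_selection(make_panel_datasets(gen$dataset, lay), lay,
                                  predictor_spec("linear"),
                                  stopping_budget(6), seed = 3)
  pred <- predict_multipanel(res, gen$dataset$test[[1]])
  expect_setequal(channel_names(pred),
                  setdiff(lay$markers, res$observed))
  expect_equal(anyDuplicated(channel_names(pred)), 0L)
})
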