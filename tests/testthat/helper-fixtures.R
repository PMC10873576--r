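# Fixtures and independent oracles shared across the test files.
# Oracles are deliberately naive (loops, enumeration) and never call the
# implementation paths they check.

# deterministic random image: channels x h x w
rand_image <- function(n_ch = 3, h = 8, w = 8, seed = 1,
                       names = sprintf("ch%02d", seq_len(n_ch)),
                       normalized = "none") {
  set.seed(seed)
  multichannel_image(array(rnorm(n_ch * h * w), c(n_ch, h, w)), names,
                     normalized)
}

# dataset whose channels are arbitrary functions of (row, col) noise
rand_dataset <- function(n_ch = 4, h = 8, w = 8, n_train = 2, n_val = 1,
                         n_test = 1, seed = 1, normalized = "z") {
  set.seed(seed)
  mk <- function() {
    px <- array(rnorm(n_ch * h * w), c(n_ch, h, w))
    for (i in seq_len(n_ch)) {
      ch <- px[i, , ]
      px[i, , ] <- (ch - mean(ch)) / sqrt(mean((ch - mean(ch))^2))
    }
    multichannel_image(px, sprintf("ch%02d", seq_len(n_ch)), normalized)
  }
  multichannel_dataset(replicate(n_train, mk(), simplify = FALSE),
                       replicate(n_val, mk(), simplify = FALSE),
                       replicate(n_test, mk(), simplify = FALSE))
}

# random marker graph with given observed count
rand_graph <- function(n = 6, n_obs = 2, seed = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  g <- marker_graph(sprintf("m%d", seq_len(n)), w)
  if (n_obs > 0) {
    for (m in sample(g$markers, n_obs)) {
      g <- panelpick:::observe_marker(g, m)
    }
  }
  g
}

# oracle: expected-improvement values by direct definition
psi_oracle <- function(w, markers, obs, pred) {
  vapply(pred, function(k) {
    total <- 0
    for (i in setdiff(pred, k)) {
      sources <- c(obs, k)
      total <- total + min(w[sources, i])
    }
    total
  }, numeric(1))
}

# oracle: minimum over all simple paths of summed edge weights; edges exist
# where `w` is not NA. Pure DFS enumeration.
min_path_oracle <- function(w, from, to) {
  n <- nrow(w)
  best <- Inf
  visit <- function(node, used, acc) {
    if (acc >= best) return(invisible())
    if (node == to) {
      best <<- acc
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!used[nxt] && !is.na(w[node, nxt])) {
        used[nxt] <- TRUE
        visit(nxt, used, acc + w[node, nxt])
        used[nxt] <- FALSE
      }
    }
  }
  used <- rep(FALSE, n)
  used[from] <- TRUE
  visit(from, used, 0)
  best
}

# oracle: brute-force 2-D Gaussian convolution with mirror boundary
conv_blur_oracle <- function(mat, sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k1 <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- nrow(mat)
  w <- ncol(mat)
  reflect <- function(i, n) {
    if (n == 1) return(1L)
    p <- (i - 1) %% (2 * n - 2)
    if (p < n) p + 1 else 2 * n - 1 - p
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -r:r) {
        for (dj in -r:r) {
          acc <- acc + k2[di + r + 1, dj + r + 1] *
            mat[reflect(i + di, h), reflect(j + dj, w)]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# population z-score used by oracles
zpop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# a chained multi-panel study used by several tests: 12 markers, 3 panels of
# 8 with consecutive overlaps of 6
chained_layout_12 <- function() {
  m <- sprintf("M%02d", 1:12)
  panel_layout(list(m[1:8], m[3:10], m[5:12]), capacity = 8)
}
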