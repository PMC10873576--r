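#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate arrange bind_rows bind_cols left_join
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All package randomness flows through this.
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and integer labels,
# so each round / image / split draws from its own named substream.
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(c(...)))
  m <- 2147483587 # largest prime < 2^31
  h <- 104729
  for (p in parts) {
    h <- (h * 131071 + (p %% m) + 7919) %% m
  }
  as.integer(h)
}

# Population standard deviation (divide by n), the z-score convention used
# throughout: z(x) = (x - mean(x)) / sd_pop(x).
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Shared dissimilarity xi: mean absolute per-pixel difference, pooled over all
# pixels of all images supplied. `a` and `b` are numeric vectors/arrays or
# lists of them (one element per image).
l1_dissimilarity <- function(a, b) {
  if (!is.list(a)) a <- list(a)
  if (!is.list(b)) b <- list(b)
  if (length(a) != length(b)) {
    abort("dissimilarity: the two channel sets contain different image counts")
  }
  num <- 0
  den <- 0
  for (i in seq_along(a)) {
    x <- a[[i]]
    y <- b[[i]]
    if (length(x) != length(y)) {
      abort("dissimilarity: channel shapes differ")
    }
    num <- num + sum(abs(as.numeric(x) - as.numeric(y)))
    den <- den + length(x)
  }
  num / den
}

# Linear-interpolation percentile (type 7), isolated so the convention is
# stated in one place.
percentile <- function(x, p) {
  as.numeric(stats::quantile(x, probs = p / 100, type = 7, names = FALSE))
}

#' Null-coalescing helper
#' @param x,y Values; `y` is returned when `x` is `NULL`.
#' @return `x` unless it is `NULL`, else `y`.
#' @export
#' @name op-null-default
`%||%` <- function(x, y) if (is.null(x)) y else x
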