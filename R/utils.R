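# Internal helpers: seed streams and colormaps.

# Deterministic 31-bit hash of a few small integers; used to derive
# independent per-recording RNG streams from one master seed so generated
# records do not depend on generation order. Constants are ordinary
# multiplicative-hash primes; all arithmetic stays below 2^53 so the
# double-precision modulo is exact.
hashSeed <- function(seed, ...) {
  parts <- c(as.numeric(seed), vapply(list(...), as.numeric, numeric(1)))
  h <- 104729
  for (p in parts) {
    h <- (h * 48271 + (p %% 2147483647) + 1) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Map values in [0,1] to an n x 3 RGB matrix in [0,1].
applyColormap <- function(v, colormap) {
  switch(colormap,
    gray = cbind(v, v, v),
    jet = {
      # classic jet anchors from dark blue through cyan/yellow to dark red
      anchors <- c(0, 0.125, 0.375, 0.625, 0.875, 1)
      r <- c(0, 0, 0, 1, 1, 0.5)
      g <- c(0, 0, 1, 1, 0, 0)
      b <- c(0.5, 1, 1, 0, 0, 0)
      cbind(stats::approx(anchors, r, xout = v)$y,
            stats::approx(anchors, g, xout = v)$y,
            stats::approx(anchors, b, xout = v)$y)
    },
    stop("unknown colormap: ", colormap)
  )
}

# Stratified fold assignment: deterministic given the seed, each class
# spread as evenly as possible across folds.
stratifiedFolds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  assign <- integer(length(labels))
  withSeed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < folds)
        stop(sprintf("class '%s' has fewer members (%d) than folds (%d)",
                     lv, length(idx), folds))
      idx <- sample(idx)
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}
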