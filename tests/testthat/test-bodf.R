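# Bag of Deep Features: vocabularies, histogram encoding, k selection.

test_that("vocabulary construction handles degenerate and separable cases", {
  # k = n: the centroids are the vectors themselves (as a set)
  x <- matrix(c(0, 0, 5, 5, 9, 1), 3, 2, byrow = TRUE)
  v <- buildVocabulary(x, k = 3, perClass = FALSE,
                       labels = rep("neutral", 3), seed = 1)
  expect_equal(centroids(v)[order(centroids(v)[, 1]), ],
               x[order(x[, 1]), ], ignore_attr = TRUE)
  # all-identical vectors, k = 1
  xi <- matrix(2, 10, 3)
  v1 <- buildVocabulary(xi, k = 1, perClass = FALSE,
                        labels = rep("neutral", 10), seed = 1)
  expect_equal(centroids(v1), matrix(2, 1, 3), ignore_attr = TRUE)
  # two well-separated 1-D blobs
  set.seed(16)
  blobs <- matrix(c(rnorm(50, 0), rnorm(50, 100)), ncol = 1)
  v2 <- buildVocabulary(blobs, k = 2, perClass = FALSE,
                        labels = rep("positive", 100), seed = 2)
  expect_lt(min(abs(sort(centroids(v2)[, 1]) - c(0, 100))), 0.5)
  expect_lt(max(abs(sort(centroids(v2)[, 1]) - c(0, 100))), 0.5)
  expect_error(buildVocabulary(blobs, k = 200, perClass = FALSE,
                               labels = rep("neutral", 100)), "exceeds")
})

test_that("per-class vocabularies stack one block of k centroids per class", {
  set.seed(17)
  x <- matrix(rnorm(60 * 4), 60)
  labs <- rep(emotionLevels(), each = 20)
  v <- buildVocabulary(x, k = 3, perClass = TRUE, labels = labs, seed = 5)
  expect_identical(nrow(centroids(v)), 9L)
  expect_identical(v@classLabels, rep(emotionLevels(), each = 3))
  # determinism under the seed
  v2 <- buildVocabulary(x, k = 3, perClass = TRUE, labels = labs, seed = 5)
  expect_identical(centroids(v), centroids(v2))
  expect_error(buildVocabulary(x[1:40, ], k = 3, perClass = TRUE,
                               labels = factor(labs[1:40],
                                               levels = emotionLevels())))
})

test_that("histogram encoding counts nearest centroids with stable ties", {
  v <- new("Vocabulary", centroids = rbind(0, 10), k = 2L,
           classLabels = c(NA_character_, NA_character_), perClass = FALSE,
           seed = 1L, inertia = 0)
  h <- encodeHistogram(rbind(1, 2, 9), v)
  expect_identical(histCounts(h), c(2L, 1L))
  # the midpoint ties to the lower centroid index
  expect_identical(histCounts(encodeHistogram(rbind(5), v)), c(1L, 0L))
  # encoding the centroids themselves is permutation-diagonal
  set.seed(18)
  C <- matrix(rnorm(12), 4, 3)
  v4 <- new("Vocabulary", centroids = C, k = 4L,
            classLabels = rep(NA_character_, 4), perClass = FALSE,
            seed = 1L, inertia = 0)
  expect_identical(histCounts(encodeHistogram(C, v4)), rep(1L, 4))
  expect_error(encodeHistogram(rbind(c(1, 2)), v), "dimension mismatch")
})

test_that("histogram counts are conserved and re-encoding is bit-stable", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:40, 1); q <- sample(2:6, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * q), n)
    v <- buildVocabulary(x, k = k, perClass = FALSE,
                         labels = rep("neutral", n), seed = i)
    h1 <- encodeHistogram(x, v)
    expect_identical(sum(histCounts(h1)), n)
    expect_identical(histCounts(encodeHistogram(x, v)), histCounts(h1))
  }
})

test_that("histogram length compresses the raw dimension for the paper grid", {
  for (k in c(8L, 10L, 12L, 14L))
    expect_lt(3L * k, 1000L)
  set.seed(20)
  x <- matrix(rnorm(90 * 50), 90)
  labs <- rep(emotionLevels(), each = 30)
  v <- buildVocabulary(x, k = 14, perClass = TRUE, labels = labs, seed = 3)
  h <- encodeHistogram(x, v)
  expect_identical(length(histCounts(h)), 42L)
})

test_that("selectK obeys tie-breaks, trivial cases, and error propagation", {
  set.seed(21)
  fakeFm <- FeatureMatrix(matrix(rnorm(30 * 4), 30),
                          data.frame(subject = 1L, trial = 1:30, channel = 1L,
                                     recording = sprintf("r%02d", 1:30),
                                     label = rep(emotionLevels(), each = 10)))
  res <- selectK(fakeFm, c(8L, 10L, 12L), evaluator = function(k) 0.5)
  expect_identical(res$k, 8L)
  expect_length(res$scores, 3L)
  expect_identical(selectK(fakeFm, 8L)$k, 8L)
  expect_error(selectK(fakeFm, c(8L, 10L),
                       evaluator = function(k) stop("boom")),
               "failed at k = 8")
})

test_that("selectK prefers the latent cluster count on structured data", {
  # feature vectors drawn from 10 latent clusters per class; a vocabulary
  # of matching size should beat a smaller one for most seeds
  wins <- 0L
  nSeeds <- 10L
  for (seed in seq_len(nSeeds)) {
    set.seed(seed + 300)
    rows <- list(); labs <- character(0)
    for (cls in emotionLevels()) {
      centers <- matrix(rnorm(10 * 5, sd = 6), 10)
      for (i in 1:40) {
        c0 <- centers[sample(10, 1), ]
        rows[[length(rows) + 1L]] <- c0 + rnorm(5, 0, 0.3)
        labs <- c(labs, cls)
      }
    }
    x <- do.call(rbind, rows)
    ev <- function(k) {
      v <- buildVocabulary(x, k, perClass = TRUE, labels = labs, seed = seed)
      -sum(v@inertia)  # tighter clusters score higher
    }
    res <- selectK(NULL, c(8L, 10L), evaluator = ev)
    wins <- wins + (res$k == 10L)
  }
  expect_gte(wins / nSeeds, 0.8)
})

test_that("vocabularies round-trip through HDF5 and histograms export to CSV", {
  set.seed(22)
  x <- matrix(rnorm(30 * 4), 30)
  labs <- rep(emotionLevels(), each = 10)
  v <- buildVocabulary(x, k = 2, perClass = TRUE, labels = labs, seed = 9)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  saveVocabulary(v, path)
  v2 <- readVocabulary(path)
  expect_equal(centroids(v2), centroids(v))
  expect_identical(v2@classLabels, v@classLabels)
  expect_identical(v2@k, v@k)
  h <- list(encodeHistogram(x[1:3, ], v, "recA", "negative"),
            encodeHistogram(x[4:9, ], v, "recB", "positive"))
  csv <- tempfile(fileext = ".csv")
  on.exit(unlink(csv), add = TRUE)
  exportHistograms(h, csv)
  df <- utils::read.csv(csv)
  expect_identical(nrow(df), 2L)
  expect_identical(df$recording, c("recA", "recB"))
  expect_identical(rowSums(df[, -(1:2)]), c(3, 6), ignore_attr = TRUE)
})
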