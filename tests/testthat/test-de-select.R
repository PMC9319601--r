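# Rough-set subset entropy: discretization, partitions, the entropy
# statistic and channel ranking/selection.

test_that("discretization codes columns as specified", {
  x <- cbind(f1 = rep(2.5, 10), f2 = as.numeric(1:10))
  expect_warning(dt <- discretizeFeatures(x, nBins = 5,
                                          labels = rep("neutral", 10)),
                 "constant column")
  expect_true(all(conditionAttributes(dt)[, "f1"] == 0L))
  # n distinct values with nBins = n: bijective coding
  dt2 <- discretizeFeatures(cbind(f = as.numeric(1:6)), nBins = 6,
                            labels = rep("positive", 6))
  expect_identical(conditionAttributes(dt2)[, "f"], 0:5)
  # equal-frequency occupancies on a continuous sample are balanced +- 1
  set.seed(12)
  z <- cbind(f = rnorm(101))
  dt3 <- discretizeFeatures(z, nBins = 4, labels = rep("negative", 101))
  occ <- table(conditionAttributes(dt3)[, "f"])
  expect_lte(max(occ) - min(occ), 1)
  # and match a sort-based quantile assignment
  oracle <- findInterval(rank(z[, "f"], ties.method = "first"),
                         c(1, 1 + cumsum(rep(101 / 4, 3))))
  expect_true(all(tabulate(oracle) == as.integer(occ)))
  expect_error(discretizeFeatures(z, nBins = 1, labels = rep("neutral", 101)),
               "nBins")
})

test_that("indiscernibility partitions behave by definition", {
  dt <- DecisionTable(cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L)),
                      rep(c("negative", "positive"), 2))
  pEmpty <- partitionBy(dt, character(0))
  expect_identical(pEmpty@blocks, list(1:4))
  pAll <- partitionBy(dt, c("a", "b"))
  expect_identical(pAll@blocks, list(1L, 2L, 3L, 4L))
  pA <- partitionBy(dt, "a")
  expect_identical(pA@blocks, list(1:2, 3:4))
  expect_error(partitionBy(dt, "zz"), "unknown attribute")
  # refinement: adding attributes refines the partition
  set.seed(13)
  for (i in 1:20) {
    t2 <- randomDecisionTable(8, 3)
    coarse <- partitionBy(t2, "a01")@blocks
    fine <- partitionBy(t2, c("a01", "a02"))@blocks
    for (blk in fine) {
      inCoarse <- vapply(coarse, function(cb) all(blk %in% cb), logical(1))
      expect_true(any(inCoarse))
    }
  }
})

test_that("subset entropy reproduces hand-derived values", {
  # P = C is exactly zero
  dt <- DecisionTable(cbind(a = c(0L, 1L, 2L, 2L), b = c(0L, 1L, 0L, 1L)),
                      rep(c("negative", "positive"), 2))
  expect_identical(deSubsetEntropy(dt, c("a", "b"))@value, 0)
  # C blocks {1},{2},{3,4}; P blocks {1,2},{3,4}: contributions
  # (-1,-1,0,0), E = -(1/4)(-2) = 0.5 bits
  dt2 <- DecisionTable(cbind(c1 = c(0L, 1L, 2L, 2L), p1 = c(0L, 0L, 1L, 1L)),
                       rep("neutral", 4))
  expect_equal(deSubsetEntropy(dt2, "p1")@value, 0.5)
  # C all singletons, P one block: -(1/4) * 4 * log2(1/4) = 2 bits
  dt3 <- DecisionTable(cbind(a = 0:3, z = rep(0L, 4)), rep("neutral", 4))
  expect_equal(deSubsetEntropy(dt3, "z")@value, 2)
  expect_error(deSubsetEntropy(dt3, "nope"), "subset of C")
})

test_that("fast path equals the explicit double-loop evaluation", {
  set.seed(14)
  for (i in 1:60) {
    nU <- sample(2:8, 1); nC <- sample(1:4, 1)
    tbl <- randomDecisionTable(nU, nC)
    P <- sample(colnames(conditionAttributes(tbl)),
                sample(seq_len(nC), 1))
    fast <- deSubsetEntropy(tbl, P)@value
    brute <- deSubsetEntropyBruteforce(tbl, P)@value
    expect_lt(abs(fast - brute), 1e-12)
  }
  expect_error(deSubsetEntropyBruteforce(randomDecisionTable(2, 1),
                                         "a01") -> ok, NA)
})

test_that("entropy is bounded, vanishes at P = C, and is partition-monotone", {
  set.seed(15)
  for (i in 1:60) {
    nU <- sample(2:8, 1); nC <- sample(2:4, 1)
    tbl <- randomDecisionTable(nU, nC)
    cn <- colnames(conditionAttributes(tbl))
    expect_identical(deSubsetEntropy(tbl, cn)@value, 0)
    P <- sample(cn, sample(seq_along(cn), 1))
    e <- deSubsetEntropy(tbl, P)@value
    expect_gte(e, 0)
    expect_lte(e, log2(nU) + 1e-12)
    # coarsening P can only raise the entropy
    if (length(P) > 1) {
      Psub <- P[-1]
      expect_gte(deSubsetEntropy(tbl, Psub)@value, e - 1e-12)
    }
  }
})

# build a FeatureMatrix directly in feature space (no images) for the
# cheap structural selection tests
syntheticChannelFM <- function(nRec, nCh, q = 6L, informative = integer(0),
                               seed = 1) {
  set.seed(seed)
  labels <- rep(emotionLevels(), length.out = nRec)
  rows <- list(); info <- list()
  for (r in seq_len(nRec)) {
    for (ch in seq_len(nCh)) {
      base <- rnorm(q, 0, 0.2)
      if (ch %in% informative)
        base <- base + (match(labels[r], emotionLevels()) - 2) * 2
      rows[[length(rows) + 1L]] <- base
      info[[length(info) + 1L]] <- data.frame(
        subject = 1L, trial = r, channel = ch,
        recording = sprintf("r%03d", r), label = labels[r])
    }
  }
  FeatureMatrix(do.call(rbind, rows), do.call(rbind, info))
}

test_that("identical channels tie and fall back to index order", {
  fm <- syntheticChannelFM(nRec = 12, nCh = 1, q = 6, informative = 1L)
  vals <- featureValues(fm)
  info <- unitInfo(fm)
  # clone channel 1 into channels 2 and 3
  copies <- do.call(rbind, lapply(1:3, function(ch) {
    i2 <- info; i2$channel <- ch; cbind(i2, vals)
  }))
  fm3 <- FeatureMatrix(as.matrix(copies[, -(1:5)]), copies[, 1:5])
  rk <- rankChannels(fm3)
  expect_identical(rk@channels, 1:3)
  expect_true(all(abs(diff(rankingScores(rk))) < 1e-12))
})

test_that("adding a pure-noise channel barely perturbs existing scores", {
  fm8 <- syntheticChannelFM(nRec = 18, nCh = 4, q = 6, informative = 1:2,
                            seed = 21)
  rk1 <- rankChannels(fm8)
  s1 <- rankingScores(rk1)[order(rk1@channels)]
  # augment with a fifth, pure-noise channel
  set.seed(99)
  info <- unitInfo(fm8); vals <- featureValues(fm8)
  nRec <- length(unique(info$recording))
  extraInfo <- info[info$channel == 1, ]
  extraInfo$channel <- 5L
  fm9 <- FeatureMatrix(rbind(vals, matrix(rnorm(nRec * ncol(vals), 0, 0.2),
                                          nRec)),
                       rbind(info, extraInfo))
  rk2 <- rankChannels(fm9)
  s2 <- rankingScores(rk2)[order(rk2@channels)][1:4]
  expect_lt(max(abs(s2 - s1)), 0.75)
  expect_identical(sort(order(-s2)[1:2]), sort(order(-s1)[1:2]))
})

test_that("informative channels are recovered by the ranking (small study)", {
  hits <- 0L
  for (seed in 1:3) {
    fm <- simFeatures(generateDataset(makeSeparableSpec(seed)))
    rk <- rankChannels(fm, budget = 4)
    hits <- hits + all(selectedChannels(rk) == 1:4)
  }
  expect_gte(hits, 2L)
})

test_that("selection keeps the requested channel budget in order", {
  fm <- syntheticChannelFM(nRec = 9, nCh = 62, q = 4, informative = 1:5,
                           seed = 31)
  red <- selectFeatures(fm, budget = 26)
  kept <- sort(unique(unitInfo(red)$channel))
  expect_length(kept, 26L)
  expect_identical(kept, sort(kept))
  # identity when the budget covers everything
  expect_identical(dim(selectFeatures(fm, budget = 62)), dim(fm))
  expect_error(selectFeatures(fm, budget = 63), "exceeds")
  expect_warning(rankChannels(syntheticChannelFM(6, 1, 4)), "degenerate")
})

test_that("decision tables export as headed TSV with a final decision column", {
  dt <- DecisionTable(cbind(a = c(0L, 1L), b = c(1L, 0L)),
                      c("negative", "positive"))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  exportDecisionTable(dt, path)
  df <- utils::read.delim(path)
  expect_identical(colnames(df), c("a", "b", "decision"))
  expect_identical(df$decision, c("negative", "positive"))
  expect_error(DecisionTable(cbind(decision = c(0L, 1L)), c("a", "b")),
               "disjoint")
})
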