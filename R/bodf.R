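# Bag-of-Deep-Features: per-class k-means vocabularies and
# nearest-centroid count histograms.

#' Build a k-means vocabulary
#'
#' Clusters the feature vectors with k-means (multiple random restarts, best
#' inertia kept) into k centroids per class (default) or k pooled centroids.
#' Per-class codebooks are concatenated, class by class in
#' \code{emotionLevels()} order, into one codebook of 3k rows.
#' Deterministic given the seed.
#'
#' @param matrix a \linkS4class{FeatureMatrix}, or a plain numeric matrix of
#'   vectors (rows) together with \code{labels}.
#' @param k clusters per class; the grid {8, 10, 12, 14} is the usual search
#'   range (see \code{\link{selectK}}).
#' @param perClass cluster within each class (default TRUE) or pooled.
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts (default 10).
#' @param labels class labels when \code{matrix} is bare.
#' @return A \linkS4class{Vocabulary}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 100), 50))
#' v <- buildVocabulary(x, k = 2, perClass = FALSE,
#'                      labels = rep("neutral", 100), seed = 1)
#' dim(centroids(v))
#' @export
buildVocabulary <- function(matrix, k, perClass = TRUE, seed = 1L,
                            nstart = 10L, labels = NULL) {
  if (is(matrix, "FeatureMatrix")) {
    vecs <- featureValues(matrix)
    labels <- unitInfo(matrix)$label
  } else {
    vecs <- as.matrix(matrix)
    if (is.null(labels)) stop("labels required for a bare matrix")
  }
  labels <- as.factor(labels)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  fitOne <- function(x) {
    if (nrow(x) < k)
      stop(sprintf("k (%d) exceeds the number of vectors (%d)", k, nrow(x)))
    ux <- unique(x)
    if (nrow(ux) <= k) {
      # degenerate: at most k distinct vectors; centroids are the vectors
      cent <- ux[rep_len(seq_len(nrow(ux)), k), , drop = FALSE]
      return(list(centers = cent, inertia = 0))
    }
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L)
    list(centers = km$centers, inertia = km$tot.withinss)
  }
  withSeed(seed, {
    if (perClass) {
      lev <- levels(labels)
      if (!length(lev)) stop("empty class set")
      fits <- lapply(lev, function(lv) {
        x <- vecs[labels == lv, , drop = FALSE]
        if (nrow(x) == 0L) stop("empty class: ", lv)
        fitOne(x)
      })
      cent <- do.call(rbind, lapply(fits, `[[`, "centers"))
      new("Vocabulary", centroids = unname(cent), k = k,
          classLabels = rep(lev, each = k), perClass = TRUE,
          seed = as.integer(seed),
          inertia = vapply(fits, `[[`, numeric(1), "inertia"))
    } else {
      fit <- fitOne(vecs)
      new("Vocabulary", centroids = unname(fit$centers), k = k,
          classLabels = rep(NA_character_, k), perClass = FALSE,
          seed = as.integer(seed), inertia = fit$inertia)
    }
  })
}

# index of the Euclidean-nearest centroid for each row of x;
# ties resolved to the lowest centroid index
nearestCentroid <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) - 2 * x %*% t(centers)
  apply(d2, 1, which.min)
}

#' Encode vectors as a nearest-centroid count histogram
#'
#' Each vector increments the count of its Euclidean-nearest centroid (ties
#' to the lowest centroid index); the counts always sum to the number of
#' encoded vectors.
#'
#' @param vectors numeric matrix (rows are vectors) or a single vector.
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @param recordingId,label carried into the result.
#' @return A \linkS4class{HistogramFeature}.
#' @examples
#' v <- new("Vocabulary", centroids = rbind(0, 10), k = 2L,
#'          classLabels = c(NA, NA), perClass = FALSE, seed = 1L,
#'          inertia = 0)
#' histCounts(encodeHistogram(rbind(1, 2, 9), v))  # 2, 1
#' @export
encodeHistogram <- function(vectors, vocabulary, recordingId = "r0001",
                            label = "neutral") {
  stopifnot(is(vocabulary, "Vocabulary"))
  x <- if (is.null(dim(vectors))) matrix(vectors, nrow = 1) else
    as.matrix(vectors)
  cent <- vocabulary@centroids
  if (ncol(x) != ncol(cent))
    stop(sprintf("dimension mismatch: vectors have %d dims, centroids %d",
                 ncol(x), ncol(cent)))
  idx <- nearestCentroid(x, cent)
  counts <- tabulate(idx, nbins = nrow(cent))
  new("HistogramFeature", counts = as.integer(counts),
      recordingId = as.character(recordingId), label = emotionFactor(label))
}

#' Encode every recording of a feature matrix
#'
#' Groups the units by recording and encodes each recording's channel
#' vectors against the vocabulary.
#'
#' @param matrix a \linkS4class{FeatureMatrix}.
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @return named list of \linkS4class{HistogramFeature}, one per recording.
#' @export
encodeDataset <- function(matrix, vocabulary) {
  stopifnot(is(matrix, "FeatureMatrix"))
  info <- unitInfo(matrix)
  vals <- featureValues(matrix)
  recs <- unique(info$recording)
  out <- lapply(recs, function(r) {
    sel <- info$recording == r
    encodeHistogram(vals[sel, , drop = FALSE], vocabulary,
                    recordingId = r,
                    label = as.character(info$label[sel][1]))
  })
  names(out) <- recs
  out
}

#' Histograms as a numeric matrix
#'
#' @param histograms list of \linkS4class{HistogramFeature}.
#' @return recordings x bins integer matrix with a \code{label} attribute.
#' @export
histogramMatrix <- function(histograms) {
  m <- do.call(rbind, lapply(histograms, histCounts))
  rownames(m) <- vapply(histograms, function(h) h@recordingId, character(1))
  attr(m, "label") <- emotionFactor(
    vapply(histograms, function(h) as.character(h@label), character(1)))
  m
}

#' Choose the vocabulary size over a candidate grid
#'
#' Evaluates each candidate k with the supplied evaluator and returns the
#' maximiser; ties (and constant evaluators) resolve to the smallest k. A
#' single candidate is returned without evaluation. The default evaluator is
#' cross-validated downstream accuracy of a 1-NN classifier on the encoded
#' histograms.
#'
#' @param matrix a \linkS4class{FeatureMatrix}.
#' @param candidateKs integer candidates, default {8, 10, 12, 14}.
#' @param evaluator function(k) -> numeric score; the default fits a
#'   vocabulary at k, encodes, and cross-validates.
#' @param seed RNG seed.
#' @param folds folds for the default evaluator.
#' @return list with \code{k} (best), and \code{scores} (named numeric, the
#'   full score table; empty for a single candidate).
#' @export
selectK <- function(matrix, candidateKs = c(8L, 10L, 12L, 14L),
                    evaluator = NULL, seed = 1L, folds = 3L) {
  candidateKs <- sort(unique(as.integer(candidateKs)))
  if (length(candidateKs) == 1L)
    return(list(k = candidateKs, scores = numeric(0)))
  if (is.null(evaluator)) {
    evaluator <- function(k) {
      voc <- buildVocabulary(matrix, k, seed = seed)
      hm <- histogramMatrix(encodeDataset(matrix, voc))
      lab <- attr(hm, "label")
      fold <- stratifiedFolds(lab, folds, seed)
      acc <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        pred <- class::knn(hm[tr, , drop = FALSE], hm[!tr, , drop = FALSE],
                           lab[tr], k = 1)
        mean(pred == lab[!tr])
      }, numeric(1))
      mean(acc)
    }
  }
  scores <- vapply(candidateKs, function(k) {
    tryCatch(evaluator(k),
             error = function(e) stop(sprintf("evaluator failed at k = %d: %s",
                                              k, conditionMessage(e))))
  }, numeric(1))
  names(scores) <- candidateKs
  list(k = candidateKs[which.max(scores)], scores = scores)
}

#' Serialize a vocabulary to HDF5
#'
#' @param vocabulary a \linkS4class{Vocabulary}.
#' @param path output HDF5 file (overwritten).
#' @return \code{path}, invisibly.
#' @export
saveVocabulary <- function(vocabulary, path) {
  stopifnot(is(vocabulary, "Vocabulary"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(vocabulary@centroids, path, "centroids")
  rhdf5::h5write(vocabulary@k, path, "k")
  rhdf5::h5write(vocabulary@seed, path, "seed")
  rhdf5::h5write(ifelse(is.na(vocabulary@classLabels), "",
                        vocabulary@classLabels), path, "class_labels")
  rhdf5::h5write(as.integer(vocabulary@perClass), path, "per_class")
  rhdf5::h5write(vocabulary@inertia, path, "inertia")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a vocabulary from HDF5
#'
#' @param path file written by \code{\link{saveVocabulary}}.
#' @return A \linkS4class{Vocabulary}.
#' @export
readVocabulary <- function(path) {
  cl <- as.character(rhdf5::h5read(path, "class_labels"))
  cl[cl == ""] <- NA_character_
  v <- new("Vocabulary",
           centroids = as.matrix(rhdf5::h5read(path, "centroids")),
           k = as.integer(rhdf5::h5read(path, "k")),
           classLabels = cl,
           perClass = as.logical(rhdf5::h5read(path, "per_class")),
           seed = as.integer(rhdf5::h5read(path, "seed")),
           inertia = as.numeric(rhdf5::h5read(path, "inertia")))
  rhdf5::h5closeAll()
  v
}

#' Export histograms as CSV
#'
#' One row per recording: recording id, label, then one column per
#' vocabulary bin.
#'
#' @param histograms list of \linkS4class{HistogramFeature}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportHistograms <- function(histograms, path) {
  m <- histogramMatrix(histograms)
  df <- data.frame(recording = rownames(m),
                   label = as.character(attr(m, "label")),
                   m, check.names = FALSE)
  colnames(df)[-(1:2)] <- sprintf("bin%03d", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
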