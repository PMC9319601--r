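# Classifier interpretation layer: GUI-style kernel names mapped onto
# standard learners, plus stratified cross-validated evaluation.

# Fit one classifier spec and return a predict(newdata) closure.
fitClassifier <- function(spec, x, y, seed = 1L) {
  y <- droplevels(as.factor(y))
  switch(spec@family,
    svm = {
      # cubic SVM: polynomial kernel of degree 3
      fit <- e1071::svm(x, y, kernel = "polynomial", degree = 3, coef0 = 1,
                        cost = spec@params$cost %||% 1, scale = FALSE)
      function(newx) stats::predict(fit, newx)
    },
    knn = {
      # fine KNN: single nearest neighbour; distance/vote ties are broken
      # at random inside class::knn, so predictions run under a local seed
      function(newx) withSeed(seed,
        class::knn(x, newx, y, k = spec@params$k %||% 1L))
    },
    tree = {
      # medium tree: depth-capped decision tree
      df <- data.frame(y = y, x)
      fit <- rpart::rpart(y ~ ., df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = spec@params$maxdepth %||% 20L,
                            minsplit = 5L, cp = 1e-4, xval = 0L))
      function(newx) {
        p <- stats::predict(fit, data.frame(newx), type = "class")
        factor(as.character(p), levels = levels(y))
      }
    },
    ensemble = {
      # subspace KNN: random-subspace bagging of 1-NN learners
      nLearners <- spec@params$nLearners %||% 30L
      d <- ncol(x)
      sub <- withSeed(seed, lapply(seq_len(nLearners), function(i)
        sort(sample.int(d, max(1L, floor(d / 2))))))
      function(newx) withSeed(seed, {
        votes <- vapply(sub, function(sj)
          as.character(class::knn(x[, sj, drop = FALSE],
                                  newx[, sj, drop = FALSE], y, k = 1L)),
          character(nrow(newx)))
        if (nrow(newx) == 1L) votes <- matrix(votes, nrow = 1)
        apply(votes, 1, function(v) {
          tab <- table(factor(v, levels = levels(y)))
          levels(y)[which.max(tab)]  # ties: first level
        })
      })
    })
}

specName <- function(spec) paste(spec@family, spec@variant, sep = "_")

#' The paper-grid classifier set
#'
#' Cubic SVM, fine (1-NN) KNN, medium (depth-capped) tree and
#' random-subspace KNN ensemble.
#'
#' @return list of \linkS4class{ClassifierSpec}.
#' @export
defaultClassifiers <- function() {
  list(classifierSpec("svm"), classifierSpec("knn"),
       classifierSpec("tree"), classifierSpec("ensemble"))
}

#' Cross-validated classifier evaluation on histogram features
#'
#' Stratified k-fold cross-validation: per spec, accuracy is the mean fold
#' accuracy and confusion matrices are aggregated over folds (rows = truth,
#' columns = prediction).
#'
#' @param histograms list of \linkS4class{HistogramFeature}, or a numeric
#'   matrix with a \code{label} attribute (see
#'   \code{\link{histogramMatrix}}).
#' @param specs list of \linkS4class{ClassifierSpec} (default
#'   \code{\link{defaultClassifiers}}).
#' @param folds number of folds (>= 2, default 5).
#' @param seed RNG seed for fold assignment and stochastic learners.
#' @return An \linkS4class{EvaluationReport}.
#' @export
trainEvalClassifiers <- function(histograms, specs = defaultClassifiers(),
                                 folds = 5L, seed = 1L) {
  m <- if (is.matrix(histograms)) histograms else histogramMatrix(histograms)
  lab <- attr(m, "label")
  if (nlevels(droplevels(lab)) < 2L) stop("need at least 2 classes")
  if (folds < 2L) stop("folds must be >= 2")
  fold <- stratifiedFolds(lab, folds, seed)
  nms <- vapply(specs, specName, character(1))
  lv <- levels(lab)
  conf <- stats::setNames(lapply(nms, function(i)
    matrix(0L, length(lv), length(lv), dimnames = list(truth = lv, pred = lv))),
    nms)
  accs <- matrix(NA_real_, length(specs), folds, dimnames = list(nms, NULL))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (i in seq_along(specs)) {
      pred <- fitClassifier(specs[[i]], m[tr, , drop = FALSE], lab[tr],
                            seed = seed + f)(m[!tr, , drop = FALSE])
      pred <- factor(as.character(pred), levels = lv)
      truth <- lab[!tr]
      accs[i, f] <- mean(pred == truth)
      conf[[i]] <- conf[[i]] + unclass(table(truth, pred))
    }
  }
  perClass <- lapply(conf, function(cm) {
    data.frame(class = lv,
               precision = diag(cm) / pmax(colSums(cm), 1),
               recall = diag(cm) / pmax(rowSums(cm), 1))
  })
  new("EvaluationReport", accuracies = rowMeans(accs), confusion = conf,
      perClass = perClass, chosenK = NA_real_,
      selectedChannels = list(), folds = lapply(seq_len(folds), function(f)
        list(test = rownames(m)[fold == f])),
      config = list(folds = folds), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
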