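# End-to-end orchestration: segment -> CWT -> render -> extract ->
# rank/select -> vocabulary -> histograms -> classifiers -> report.
# All data-dependent fitting (channel ranking, discretization, k-means)
# happens inside training folds only.

#' PipelineConfig: full pipeline configuration
#'
#' @slot windowLen,hop segmentation window and hop (samples).
#' @slot wavelet \linkS4class{WaveletSpec}.
#' @slot nScales,freqRange scalogram scale grid.
#' @slot imageSize,colormap,scaling rendering parameters.
#' @slot extractor \linkS4class{FeatureExtractor}.
#' @slot nBins,nComponents channel-ranking discretization parameters.
#' @slot channelBudget channels to keep (default 26); \code{NA} keeps all.
#' @slot k vocabulary size; \code{NA} triggers selection over \code{kGrid}
#'   inside each training fold.
#' @slot kGrid candidate vocabulary sizes.
#' @slot perClass per-class vocabularies (default TRUE).
#' @slot classifiers list of \linkS4class{ClassifierSpec}.
#' @slot folds cross-validation folds.
#' @slot groupBySubject keep each subject's recordings in one fold
#'   (subject-independent evaluation).
#' @slot seed master seed; every stochastic stage derives its stream from
#'   it.
#' @export
setClass("PipelineConfig",
  representation(windowLen = "integer", hop = "integer",
                 wavelet = "WaveletSpec", nScales = "integer",
                 freqRange = "numeric", imageSize = "integer",
                 colormap = "character", scaling = "character",
                 extractor = "FeatureExtractor", nBins = "integer",
                 nComponents = "integer", channelBudget = "integer",
                 k = "integer", kGrid = "integer", perClass = "logical",
                 classifiers = "list", folds = "integer",
                 groupBySubject = "logical", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- NULL
  if (object@windowLen < 2L) msg <- c(msg, "windowLen must be >= 2")
  if (object@hop < 1L) msg <- c(msg, "hop must be >= 1")
  if (object@folds < 2L) msg <- c(msg, "folds must be >= 2")
  ok <- vapply(object@classifiers, is, logical(1), class2 = "ClassifierSpec")
  if (!all(ok)) msg <- c(msg, "classifiers must be ClassifierSpec objects")
  if (is.null(msg)) TRUE else msg
})

#' @rdname PipelineConfig-class
#' @param windowLen,hop segmentation parameters (samples).
#' @param wavelet mother wavelet.
#' @param nScales,freqRange scale grid.
#' @param imageSize,colormap,scaling rendering.
#' @param extractor feature extractor.
#' @param nBins,nComponents ranking discretization.
#' @param channelBudget channels kept by selection (NA = all).
#' @param k vocabulary size (NA = select over \code{kGrid}).
#' @param kGrid candidate ks.
#' @param perClass per-class codebooks.
#' @param classifiers classifier specs.
#' @param folds CV folds.
#' @param groupBySubject subject-independent folds.
#' @param seed master seed.
#' @export
pipelineConfig <- function(windowLen = 1000L, hop = windowLen,
                           wavelet = waveletSpec(), nScales = 64L,
                           freqRange = c(1, 45), imageSize = 224L,
                           colormap = "jet", scaling = "log",
                           extractor = fallbackExtractor(),
                           nBins = 3L, nComponents = 3L,
                           channelBudget = 26L, k = 10L,
                           kGrid = c(8L, 10L, 12L, 14L), perClass = TRUE,
                           classifiers = defaultClassifiers(), folds = 5L,
                           groupBySubject = FALSE, seed = 1L) {
  new("PipelineConfig", windowLen = as.integer(windowLen),
      hop = as.integer(hop), wavelet = wavelet, nScales = as.integer(nScales),
      freqRange = freqRange, imageSize = as.integer(imageSize),
      colormap = colormap, scaling = scaling, extractor = extractor,
      nBins = as.integer(nBins), nComponents = as.integer(nComponents),
      channelBudget = as.integer(channelBudget), k = as.integer(k),
      kGrid = as.integer(kGrid), perClass = perClass,
      classifiers = classifiers, folds = as.integer(folds),
      groupBySubject = groupBySubject, seed = as.integer(seed))
}

# subset a FeatureMatrix to a set of recordings / channels
fmSubset <- function(fm, recordings = NULL, channels = NULL) {
  info <- unitInfo(fm)
  keep <- rep(TRUE, nrow(info))
  if (!is.null(recordings)) keep <- keep & info$recording %in% recordings
  if (!is.null(channels)) keep <- keep & info$channel %in% channels
  fm[, keep]
}

#' Run the full emotion-recognition pipeline
#'
#' Segments every recording, computes per-channel CWT scalogram images,
#' extracts features, and evaluates the classifier grid under stratified
#' cross-validation. Channel ranking/selection and the k-means vocabulary
#' are fitted inside each training fold only; test-fold recordings never
#' contribute vectors to a fold's k-means (the report's \code{folds} entry
#' records the vocabulary-contributing recording ids so this can be
#' audited).
#'
#' @param dataset an \linkS4class{EEGDataset}, or a file path readable by
#'   \code{\link{readDataset}}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param format container format when \code{dataset} is a path.
#' @return An \linkS4class{EvaluationReport}. Fully deterministic given the
#'   config's master seed.
#' @export
runPipeline <- function(dataset, config = pipelineConfig(), format = "hdf5") {
  stopifnot(is(config, "PipelineConfig"))
  if (is.character(dataset)) dataset <- readDataset(dataset, format)
  stopifnot(is(dataset, "EEGDataset"), length(dataset) > 0L)

  # segmentation (stage: segment); segments inherit the parent's ids, with
  # the window index folded into the trial id so each window is a distinct
  # recording unit downstream
  segs <- list()
  for (rec in as.list(dataset)) {
    pieces <- segmentSignal(rec, min(config@windowLen, ncol(rec@samples)),
                            config@hop)
    if (length(pieces) > 1L)
      pieces <- lapply(seq_along(pieces), function(j)
        initialize(pieces[[j]], trialId = pieces[[j]]@trialId * 1000L + j))
    segs <- c(segs, pieces)
  }
  segDs <- EEGDataset(segs)

  # features for every (segment, channel) unit (stage: transform/extract)
  fm <- datasetFeatures(segDs, wavelet = config@wavelet,
                        nScales = config@nScales,
                        freqRange = config@freqRange,
                        imageSize = config@imageSize,
                        colormap = config@colormap, scaling = config@scaling,
                        extractor = config@extractor)
  info <- unitInfo(fm)
  recTab <- unique(info[, c("recording", "subject", "label")])
  nCh <- length(unique(info$channel))

  lab <- emotionFactor(recTab$label)
  foldOf <- if (config@groupBySubject) {
    subj <- sort(unique(recTab$subject))
    sf <- withSeed(config@seed, sample(rep_len(seq_len(config@folds),
                                               length(subj))))
    sf[match(recTab$subject, subj)]
  } else stratifiedFolds(lab, config@folds, config@seed)

  budget <- if (is.na(config@channelBudget)) nCh
            else min(config@channelBudget, nCh)
  nms <- vapply(config@classifiers, specName, character(1))
  lv <- levels(lab)
  conf <- stats::setNames(lapply(nms, function(i)
    matrix(0L, length(lv), length(lv), dimnames = list(truth = lv, pred = lv))),
    nms)
  accs <- matrix(NA_real_, length(nms), config@folds,
                 dimnames = list(nms, NULL))
  foldInfo <- list(); selChannels <- list(); ks <- numeric(0)

  infoFm <- fm

  for (f in seq_len(config@folds)) {
    trainRecs <- recTab$recording[foldOf != f]
    testRecs <- recTab$recording[foldOf == f]
    trainFm <- fmSubset(infoFm, recordings = trainRecs)

    # channel selection fitted on the training fold only
    chans <- if (budget < nCh) {
      rk <- rankChannels(trainFm, nBins = config@nBins,
                         nComponents = config@nComponents, budget = budget)
      selectedChannels(rk)
    } else sort(unique(info$channel))
    selChannels[[f]] <- chans

    trainSel <- fmSubset(trainFm, channels = chans)
    testSel <- fmSubset(infoFm, recordings = testRecs, channels = chans)

    kf <- if (is.na(config@k)) {
      selectK(trainSel, config@kGrid, seed = hashSeed(config@seed, f, 1, 1))$k
    } else config@k
    ks <- c(ks, kf)

    voc <- buildVocabulary(trainSel, kf, perClass = config@perClass,
                           seed = hashSeed(config@seed, f, 2, 2))
    trainHm <- histogramMatrix(encodeDataset(trainSel, voc))
    testHm <- histogramMatrix(encodeDataset(testSel, voc))
    trainLab <- attr(trainHm, "label")
    testLab <- attr(testHm, "label")

    for (i in seq_along(config@classifiers)) {
      pred <- fitClassifier(config@classifiers[[i]], trainHm, trainLab,
                            seed = hashSeed(config@seed, f, 3, i))(testHm)
      pred <- factor(as.character(pred), levels = lv)
      accs[i, f] <- mean(pred == testLab)
      conf[[i]] <- conf[[i]] + unclass(table(testLab, pred))
    }
    foldInfo[[f]] <- list(train = trainRecs, test = testRecs,
                          vocabulary = unique(unitInfo(trainSel)$recording))
  }

  perClass <- lapply(conf, function(cm) {
    data.frame(class = lv,
               precision = diag(cm) / pmax(colSums(cm), 1),
               recall = diag(cm) / pmax(rowSums(cm), 1))
  })
  new("EvaluationReport", accuracies = rowMeans(accs), confusion = conf,
      perClass = perClass, chosenK = mean(ks),
      selectedChannels = selChannels, folds = foldInfo,
      config = configSnapshot(config), seed = config@seed)
}

configSnapshot <- function(config) {
  list(windowLen = config@windowLen, hop = config@hop,
       wavelet = list(family = config@wavelet@family,
                      gamma = config@wavelet@gamma,
                      beta = config@wavelet@beta,
                      omega0 = config@wavelet@omega0,
                      normalization = config@wavelet@normalization),
       nScales = config@nScales, freqRange = config@freqRange,
       imageSize = config@imageSize, colormap = config@colormap,
       scaling = config@scaling, extractor = config@extractor@name,
       nBins = config@nBins, nComponents = config@nComponents,
       channelBudget = config@channelBudget, k = config@k,
       kGrid = config@kGrid, perClass = config@perClass,
       classifiers = vapply(config@classifiers, specName, character(1)),
       folds = config@folds, groupBySubject = config@groupBySubject,
       seed = config@seed)
}

#' Write an evaluation report as JSON
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  out <- list(accuracies = as.list(report@accuracies),
              confusion = lapply(report@confusion, function(m)
                as.data.frame(as.matrix(m))),
              perClass = report@perClass,
              chosenK = report@chosenK,
              selectedChannels = report@selectedChannels,
              folds = report@folds,
              config = report@config,
              seed = report@seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the \code{\link{pipelineConfig}} arguments
#' (scalar fields only; the wavelet is given as a mapping with
#' \code{family}/\code{gamma}/\code{beta}/\code{omega0}/
#' \code{normalization}). Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("windowLen", "hop", "wavelet", "nScales", "freqRange",
             "imageSize", "colormap", "scaling", "nBins", "nComponents",
             "channelBudget", "k", "kGrid", "perClass", "folds",
             "groupBySubject", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$wavelet))
    y$wavelet <- do.call(waveletSpec, y$wavelet)
  if (!is.null(y$freqRange)) y$freqRange <- as.numeric(y$freqRange)
  if (!is.null(y$kGrid)) y$kGrid <- as.integer(y$kGrid)
  do.call(pipelineConfig, y)
}
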