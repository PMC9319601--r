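#' @import methods
#' @importFrom S4Vectors SimpleList metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Emotion class labels
#'
#' The three emotional states recognised by the pipeline, in their fixed
#' order: negative (code 0), neutral (code 1), positive (code 2).
#'
#' @return Character vector of the three labels.
#' @examples
#' emotionLevels()
#' @export
emotionLevels <- function() c("negative", "neutral", "positive")

#' Coerce to an emotion factor
#'
#' @param x character, factor or integer codes in 0..2.
#' @return Factor with levels \code{emotionLevels()}.
#' @export
emotionFactor <- function(x) {
  lv <- emotionLevels()
  if (is.numeric(x)) {
    if (any(!x %in% 0:2)) stop("emotion codes must be in 0..2")
    x <- lv[x + 1L]
  }
  x <- as.character(x)
  if (any(!x %in% lv))
    stop("invalid emotion label(s): ", paste(setdiff(unique(x), lv), collapse = ", "))
  factor(x, levels = lv)
}

# ---- ChannelMontage ---------------------------------------------------------

#' ChannelMontage: electrode layout and working subset
#'
#' Ordered 10-20-system electrode labels plus an index subset identifying the
#' working channels used downstream.
#'
#' @slot channelNames character, unique ordered electrode labels.
#' @slot selectedSubset integer, strictly increasing indices into
#'   \code{channelNames}.
#' @export
setClass("ChannelMontage",
  representation(channelNames = "character", selectedSubset = "integer"))

setValidity("ChannelMontage", function(object) {
  msg <- NULL
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channel names must be unique")
  ss <- object@selectedSubset
  if (length(ss)) {
    if (any(ss < 1L) || any(ss > length(object@channelNames)))
      msg <- c(msg, "selectedSubset indices out of range")
    if (is.unsorted(ss, strictly = TRUE))
      msg <- c(msg, "selectedSubset must be strictly increasing")
  }
  if (is.null(msg)) TRUE else msg
})

# ---- EEGRecording -----------------------------------------------------------

#' EEGRecording: one labelled multi-channel EEG window
#'
#' @slot samples numeric matrix, channels x samples, microvolts; row names are
#'   channel labels.
#' @slot samplingRate numeric, Hz.
#' @slot label factor, one of \code{emotionLevels()}.
#' @slot subjectId,trialId integer identifiers.
#' @export
setClass("EEGRecording",
  representation(samples = "matrix", samplingRate = "numeric",
                 label = "factor", subjectId = "integer",
                 trialId = "integer"))

setValidity("EEGRecording", function(object) {
  msg <- NULL
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (ncol(object@samples) < 1L) msg <- c(msg, "n_samples must be > 0")
  if (nrow(object@samples) < 1L) msg <- c(msg, "need at least one channel")
  if (!all(is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@label) != 1L || !identical(levels(object@label), emotionLevels()))
    msg <- c(msg, "label must be a length-1 factor over emotionLevels()")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EEGRecording
#'
#' @param samples channels x samples numeric matrix (row names = channels).
#' @param samplingRate sampling rate in Hz.
#' @param label emotion label (character, factor or 0..2 code).
#' @param subjectId,trialId integer identifiers.
#' @return An \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(samples, samplingRate, label,
                         subjectId = 1L, trialId = 1L) {
  new("EEGRecording", samples = samples, samplingRate = as.numeric(samplingRate),
      label = emotionFactor(label), subjectId = as.integer(subjectId),
      trialId = as.integer(trialId))
}

# ---- EEGDataset -------------------------------------------------------------

#' EEGDataset: a list of EEGRecording objects
#'
#' A \code{SimpleList} whose elements are all \linkS4class{EEGRecording}
#' objects, typically produced by \code{\link{generateDataset}} or
#' \code{\link{readDataset}}.
#' @export
setClass("EEGDataset", contains = "SimpleList",
         prototype = prototype(elementType = "EEGRecording"))

#' @rdname EEGDataset-class
#' @param ... EEGRecording objects or a single list of them.
#' @export
EEGDataset <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && !is(args[[1]], "EEGRecording"))
    args <- args[[1]]
  ok <- vapply(args, is, logical(1), class2 = "EEGRecording")
  if (!all(ok)) stop("all elements must be EEGRecording objects")
  new("EEGDataset", SimpleList(args))
}

# ---- SyntheticDatasetSpec ---------------------------------------------------

#' SyntheticDatasetSpec: parameters of the synthetic EEG generator
#'
#' Defines a SEED-style synthetic study: subjects x (3 classes x trials)
#' labelled recordings over a montage, with class-dependent band-power
#' structure on the informative channels.
#'
#' @slot nSubjects,nTrialsPerClass counts.
#' @slot montage \linkS4class{ChannelMontage}.
#' @slot samplingRate Hz.
#' @slot nSamples samples per analysis window.
#' @slot classBandGain 3 x 4 numeric matrix; rows = emotion classes in
#'   \code{emotionLevels()} order, columns = bands (delta, theta, alpha, beta);
#'   per-band amplitude multipliers, all > 0 (0 allowed to silence a band).
#' @slot informativeChannels integer indices of channels carrying the
#'   class-dependent oscillations; the rest are pure noise.
#' @slot noiseSd white-noise standard deviation (microvolts).
#' @slot baseAmplitude per-component oscillation amplitude before gains.
#' @slot nComponentsPerBand sinusoids drawn per band.
#' @slot subjectSd sd of the per-subject lognormal amplitude multiplier
#'   (0 disables the subject effect).
#' @slot seed master seed; per-recording streams are derived by hashing.
#' @export
setClass("SyntheticDatasetSpec",
  representation(nSubjects = "integer", nTrialsPerClass = "integer",
                 montage = "ChannelMontage", samplingRate = "numeric",
                 nSamples = "integer", classBandGain = "matrix",
                 informativeChannels = "integer", noiseSd = "numeric",
                 baseAmplitude = "numeric", nComponentsPerBand = "integer",
                 subjectSd = "numeric", seed = "integer"))

setValidity("SyntheticDatasetSpec", function(object) {
  msg <- NULL
  if (object@nSubjects < 1L || object@nTrialsPerClass < 1L)
    msg <- c(msg, "counts must be >= 1")
  g <- object@classBandGain
  if (!identical(dim(g), c(3L, 4L))) msg <- c(msg, "classBandGain must be 3 x 4")
  if (any(g < 0)) msg <- c(msg, "gains must be >= 0")
  nc <- length(object@montage@channelNames)
  ic <- object@informativeChannels
  if (length(ic) && (any(ic < 1L) || any(ic > nc)))
    msg <- c(msg, "informativeChannels must index the montage")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
  if (is.null(msg)) TRUE else msg
})

# ---- time-frequency types ---------------------------------------------------

#' WindowSpec: analysis window for the short-time Fourier transform
#'
#' @slot kind one of "rectangular", "hann", "gaussian".
#' @slot length window length in samples.
#' @export
setClass("WindowSpec",
  representation(kind = "character", length = "integer"))

setValidity("WindowSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("rectangular", "hann", "gaussian"))
    msg <- c(msg, "kind must be rectangular, hann or gaussian")
  if (object@length < 1L) msg <- c(msg, "length must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' @rdname WindowSpec-class
#' @param kind window type.
#' @param length window length in samples.
#' @export
windowSpec <- function(kind = c("hann", "rectangular", "gaussian"), length = 128L) {
  new("WindowSpec", kind = match.arg(kind), length = as.integer(length))
}

#' WaveletSpec: mother wavelet for the continuous wavelet transform
#'
#' Analytic mother wavelets defined in the frequency domain: the generalized
#' Morse family \eqn{\hat\psi(\omega) = a\,\omega^\beta e^{-\omega^\gamma}}
#' for \eqn{\omega > 0} (default gamma = 3, beta = 20), or the analytic
#' Morlet \eqn{\hat\psi(\omega) = 2 e^{-(\omega-\omega_0)^2/2}}.
#'
#' @slot family "morse" or "morlet".
#' @slot gamma,beta Morse shape parameters.
#' @slot omega0 Morlet centre frequency (radians).
#' @slot normalization "L1" or "L2" daughter-wavelet normalization
#'   (\eqn{1/m} vs \eqn{1/\sqrt m} prefactor).
#' @export
setClass("WaveletSpec",
  representation(family = "character", gamma = "numeric", beta = "numeric",
                 omega0 = "numeric", normalization = "character"))

setValidity("WaveletSpec", function(object) {
  msg <- NULL
  if (!object@family %in% c("morse", "morlet"))
    msg <- c(msg, "family must be morse or morlet")
  if (!object@normalization %in% c("L1", "L2"))
    msg <- c(msg, "normalization must be L1 or L2")
  if (object@family == "morse" && (object@gamma <= 0 || object@beta <= 0))
    msg <- c(msg, "morse gamma and beta must be > 0")
  if (object@family == "morlet" && object@omega0 < 4)
    msg <- c(msg, "morlet omega0 < 4 is not numerically admissible here")
  if (is.null(msg)) TRUE else msg
})

#' @rdname WaveletSpec-class
#' @param family wavelet family.
#' @param gamma,beta Morse shape parameters.
#' @param omega0 Morlet centre frequency in radians.
#' @param normalization "L1" or "L2".
#' @export
waveletSpec <- function(family = c("morse", "morlet"), gamma = 3, beta = 20,
                        omega0 = 6, normalization = c("L1", "L2")) {
  new("WaveletSpec", family = match.arg(family), gamma = gamma, beta = beta,
      omega0 = omega0, normalization = match.arg(normalization))
}

#' Scalogram: continuous wavelet transform coefficients
#'
#' @slot coefficients complex matrix, scales x times.
#' @slot scales strictly increasing positive scales (samples).
#' @slot times sample indices of the columns.
#' @slot samplingRate Hz of the source signal.
#' @slot wavelet the \linkS4class{WaveletSpec} used.
#' @slot sourceLength length i of the transformed signal.
#' @export
setClass("Scalogram",
  representation(coefficients = "matrix", scales = "numeric",
                 times = "numeric", samplingRate = "numeric",
                 wavelet = "WaveletSpec", sourceLength = "integer"))

setValidity("Scalogram", function(object) {
  msg <- NULL
  if (!is.complex(object@coefficients))
    msg <- c(msg, "coefficients must be complex")
  if (nrow(object@coefficients) != length(object@scales))
    msg <- c(msg, "nrow(coefficients) must equal length(scales)")
  if (ncol(object@coefficients) != length(object@times))
    msg <- c(msg, "ncol(coefficients) must equal length(times)")
  if (any(object@scales <= 0) || is.unsorted(object@scales, strictly = TRUE))
    msg <- c(msg, "scales must be strictly increasing and > 0")
  if (is.null(msg)) TRUE else msg
})

#' SpectrogramImage: rendered scalogram ready for a feature extractor
#'
#' @slot pixels numeric array height x width x 3, values in [0, 255].
#' @slot colormap name of the colormap used.
#' @slot scaling "linear" or "log" amplitude scaling.
#' @export
setClass("SpectrogramImage",
  representation(pixels = "array", colormap = "character", scaling = "character"))

setValidity("SpectrogramImage", function(object) {
  msg <- NULL
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be h x w x 3")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (!object@scaling %in% c("linear", "log"))
    msg <- c(msg, "scaling must be linear or log")
  if (is.null(msg)) TRUE else msg
})

# ---- features ---------------------------------------------------------------

#' FeatureExtractor: pluggable image-to-vector contract
#'
#' An extractor turns a \linkS4class{SpectrogramImage} into a fixed-length
#' numeric vector. Extractors must be deterministic and emit exactly
#' \code{outputDim} finite values for every input.
#'
#' @slot name extractor name.
#' @slot outputDim q, the constant output length.
#' @slot fun function(SpectrogramImage) -> numeric(outputDim).
#' @export
setClass("FeatureExtractor",
  representation(name = "character", outputDim = "integer", fun = "function"))

setValidity("FeatureExtractor", function(object) {
  if (object@outputDim < 1L) "outputDim must be >= 1" else TRUE
})

#' FeatureMatrix: p x q per-unit feature table
#'
#' A \code{SummarizedExperiment} holding one assay \code{"features"} with
#' q feature rows and p unit columns, where each unit is one
#' (recording, channel) pair. \code{colData} carries \code{subject},
#' \code{trial}, \code{channel}, \code{recording} and \code{label}.
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- NULL
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "must contain an assay named 'features'")
  need <- c("subject", "trial", "channel", "recording", "label")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  else if (any(is.na(SummarizedExperiment::assay(object, "features"))))
    msg <- c(msg, "feature values must not be missing")
  if (is.null(msg)) TRUE else msg
})

#' Construct a FeatureMatrix
#'
#' @param values p x q numeric matrix (units in rows, features in columns).
#' @param info data.frame with p rows: subject, trial, channel, recording,
#'   label.
#' @param featureNames optional length-q character vector.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, info, featureNames = NULL) {
  values <- as.matrix(values)
  if (nrow(info) != nrow(values)) stop("info rows must match value rows")
  if (is.null(featureNames))
    featureNames <- colnames(values)
  if (is.null(featureNames))
    featureNames <- sprintf("f%04d", seq_len(ncol(values)))
  a <- t(values)
  rownames(a) <- featureNames
  colnames(a) <- sprintf("u%04d", seq_len(ncol(a)))
  info$label <- emotionFactor(info$label)
  info <- DataFrame(info)
  rownames(info) <- colnames(a)
  se <- SummarizedExperiment(assays = list(features = a), colData = info)
  new("FeatureMatrix", se)
}

# ---- rough-set entropy types ------------------------------------------------

#' DecisionTable: discretized feature table for rough-set entropy
#'
#' Objects (universe U) in rows, discrete condition attributes C in columns,
#' plus a decision attribute D (the emotion label). The decision attribute is
#' carried for stratification; the subset-entropy formula itself only uses C.
#'
#' @slot values integer matrix |U| x |C| of discrete codes.
#' @slot decision factor of length |U|.
#' @export
setClass("DecisionTable",
  representation(values = "matrix", decision = "factor"))

setValidity("DecisionTable", function(object) {
  msg <- NULL
  if (nrow(object@values) < 1L) msg <- c(msg, "universe must be non-empty")
  if (any(is.na(object@values))) msg <- c(msg, "values must be complete")
  if (length(object@decision) != nrow(object@values))
    msg <- c(msg, "decision length must equal |U|")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "condition attributes must be named")
  if ("decision" %in% colnames(object@values))
    msg <- c(msg, "condition attributes may not be named 'decision' (C and D are disjoint)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname DecisionTable-class
#' @param values |U| x |C| matrix of discrete codes (will be coerced to
#'   integer); columns must be named.
#' @param decision decision attribute values, one per object.
#' @export
DecisionTable <- function(values, decision) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("a%03d", seq_len(ncol(values)))
  new("DecisionTable", values = values, decision = as.factor(decision))
}

#' Partition: indiscernibility partition of the universe
#'
#' @slot blocks list of integer index vectors, disjoint, covering 1..n.
#' @slot n size of the universe.
#' @export
setClass("Partition", representation(blocks = "list", n = "integer"))

setValidity("Partition", function(object) {
  idx <- sort(unlist(object@blocks))
  if (!identical(idx, seq_len(object@n)))
    "blocks must partition 1..n exactly" else TRUE
})

#' DEScore: subset-entropy value for an attribute subset
#'
#' @slot subset names of the attributes in P.
#' @slot value entropy in bits, in [0, log2 |U|].
#' @export
setClass("DEScore", representation(subset = "character", value = "numeric"))

#' ChannelRanking: per-channel subset-entropy scores and selection
#'
#' @slot channels channel indices in ranked order (best first).
#' @slot scores entropy scores, aligned with \code{channels}.
#' @slot selected indices of the channels kept.
#' @slot direction "high" or "low": whether high or low scores rank first.
#' @slot degenerate TRUE when the ranking could not discriminate (e.g. a
#'   single channel).
#' @export
setClass("ChannelRanking",
  representation(channels = "integer", scores = "numeric",
                 selected = "integer", direction = "character",
                 degenerate = "logical"))

# ---- BoDF types -------------------------------------------------------------

#' Vocabulary: k-means codebook for Bag-of-Deep-Features encoding
#'
#' @slot centroids (n_classes * k) x q matrix of cluster centres (or k x q
#'   when pooled).
#' @slot k clusters per class (or total, when pooled).
#' @slot classLabels per-centroid class label (NA when pooled).
#' @slot perClass TRUE for per-class codebooks.
#' @slot seed seed used for the k-means restarts.
#' @slot inertia total within-cluster sum of squares per class.
#' @export
setClass("Vocabulary",
  representation(centroids = "matrix", k = "integer", classLabels = "character",
                 perClass = "logical", seed = "integer", inertia = "numeric"))

setValidity("Vocabulary", function(object) {
  msg <- NULL
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (!all(is.finite(object@centroids))) msg <- c(msg, "centroids must be finite")
  if (length(object@classLabels) != nrow(object@centroids))
    msg <- c(msg, "one class label per centroid required")
  if (is.null(msg)) TRUE else msg
})

#' HistogramFeature: nearest-centroid count encoding of one recording
#'
#' @slot counts non-negative integer counts, one per vocabulary centroid;
#'   their sum equals the number of encoded raw vectors.
#' @slot recordingId source recording identifier.
#' @slot label emotion label of the source recording.
#' @export
setClass("HistogramFeature",
  representation(counts = "integer", recordingId = "character",
                 label = "factor"))

setValidity("HistogramFeature", function(object) {
  if (any(object@counts < 0L)) "counts must be non-negative" else TRUE
})

# ---- pipeline types ---------------------------------------------------------

#' ClassifierSpec: one classifier family/variant pair
#'
#' Supported pairs mirror common GUI-style names: svm/cubic (polynomial
#' kernel, degree 3), knn/fine (1 nearest neighbour), tree/medium
#' (depth-capped decision tree) and ensemble/subspace_knn (random-subspace
#' bagged 1-NN).
#'
#' @slot family one of "svm", "knn", "tree", "ensemble".
#' @slot variant kernel/variant name.
#' @slot params named list of hyperparameter overrides.
#' @export
setClass("ClassifierSpec",
  representation(family = "character", variant = "character", params = "list"))

setValidity("ClassifierSpec", function(object) {
  ok <- list(svm = "cubic", knn = "fine", tree = "medium",
             ensemble = "subspace_knn")
  f <- object@family
  if (!f %in% names(ok)) return("unknown classifier family")
  if (!object@variant %in% ok[[f]])
    return(sprintf("unsupported variant '%s' for family '%s'", object@variant, f))
  TRUE
})

#' @rdname ClassifierSpec-class
#' @param family classifier family.
#' @param variant variant name (defaults to the family's standard variant).
#' @param params named list of hyperparameter overrides.
#' @export
classifierSpec <- function(family = c("svm", "knn", "tree", "ensemble"),
                           variant = NULL, params = list()) {
  family <- match.arg(family)
  if (is.null(variant))
    variant <- c(svm = "cubic", knn = "fine", tree = "medium",
                 ensemble = "subspace_knn")[[family]]
  new("ClassifierSpec", family = family, variant = variant, params = params)
}

#' EvaluationReport: cross-validated pipeline results
#'
#' @slot accuracies named numeric, mean fold accuracy per classifier.
#' @slot confusion named list of aggregated confusion matrices
#'   (rows = truth, columns = prediction).
#' @slot perClass named list of per-class precision/recall tables.
#' @slot chosenK the vocabulary size used (per fold mean when selected).
#' @slot selectedChannels list of integer vectors, channels kept per fold.
#' @slot folds list with per-fold train/test/vocabulary recording ids.
#' @slot config named list snapshot of the configuration.
#' @slot seed master seed.
#' @export
setClass("EvaluationReport",
  representation(accuracies = "numeric", confusion = "list",
                 perClass = "list", chosenK = "numeric",
                 selectedChannels = "list", folds = "list",
                 config = "list", seed = "integer"))

setValidity("EvaluationReport", function(object) {
  a <- object@accuracies
  if (length(a) && (any(a < 0) || any(a > 1)))
    "accuracies must lie in [0, 1]" else TRUE
})
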