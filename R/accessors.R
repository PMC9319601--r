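# Accessor and show methods.

#' @rdname EEGRecording-class
#' @export
setMethod("samples", "EEGRecording", function(object) object@samples)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)

#' @rdname EEGRecording-class
#' @export
setMethod("emotionLabels", "EEGRecording", function(object) object@label)

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "EEGRecording", function(object) rownames(object@samples))

#' @rdname EEGRecording-class
#' @export
setMethod("subjectIds", "EEGRecording", function(object) object@subjectId)

#' @rdname EEGRecording-class
#' @export
setMethod("trialIds", "EEGRecording", function(object) object@trialId)

#' @rdname EEGRecording-class
#' @export
setMethod("emotionLabels", "EEGDataset", function(object)
  emotionFactor(vapply(object, function(r) as.character(r@label), character(1))))

#' @rdname EEGRecording-class
#' @export
setMethod("subjectIds", "EEGDataset", function(object)
  vapply(object, function(r) r@subjectId, integer(1)))

#' @rdname EEGRecording-class
#' @export
setMethod("trialIds", "EEGDataset", function(object)
  vapply(object, function(r) r@trialId, integer(1)))

#' @rdname EEGRecording-class
#' @export
setMethod("channelNames", "ChannelMontage", function(object) object@channelNames)

#' @rdname ChannelRanking-class
#' @param object a ChannelRanking.
#' @export
setMethod("selectedChannels", "ChannelMontage", function(object) object@selectedSubset)

#' @rdname Scalogram-class
#' @export
setMethod("waveletScales", "Scalogram", function(object) object@scales)

#' @rdname Scalogram-class
#' @export
setMethod("waveletCoefs", "Scalogram", function(object) object@coefficients)

#' @rdname Scalogram-class
#' @export
setMethod("samplingRate", "Scalogram", function(object) object@samplingRate)

#' Centre frequencies (Hz) corresponding to the scalogram's scales
#' @rdname Scalogram-class
#' @export
setMethod("scaleFrequencies", "Scalogram", function(object)
  peakFrequency(object@wavelet) * object@samplingRate / (2 * pi * object@scales))

#' @rdname Vocabulary-class
#' @param object a Vocabulary.
#' @export
setMethod("centroids", "Vocabulary", function(object) object@centroids)

#' @rdname HistogramFeature-class
#' @param object a HistogramFeature.
#' @export
setMethod("histCounts", "HistogramFeature", function(object) object@counts)

#' @rdname EvaluationReport-class
#' @param object an EvaluationReport.
#' @export
setMethod("accuracies", "EvaluationReport", function(object) object@accuracies)

#' @rdname EvaluationReport-class
#' @export
setMethod("confusionMatrices", "EvaluationReport", function(object) object@confusion)

#' @rdname ChannelRanking-class
#' @export
setMethod("selectedChannels", "ChannelRanking", function(object) object@selected)

#' @rdname ChannelRanking-class
#' @export
setMethod("rankingScores", "ChannelRanking", function(object) object@scores)

#' Per-unit feature values, p x q (units in rows)
#' @rdname FeatureMatrix-class
#' @param object a FeatureMatrix.
#' @export
setMethod("featureValues", "FeatureMatrix", function(object)
  t(SummarizedExperiment::assay(object, "features")))

#' @rdname FeatureMatrix-class
#' @export
setMethod("unitInfo", "FeatureMatrix", function(object)
  as.data.frame(SummarizedExperiment::colData(object)))

#' @rdname DecisionTable-class
#' @param object a DecisionTable.
#' @export
setMethod("conditionAttributes", "DecisionTable", function(object) object@values)

#' @rdname DecisionTable-class
#' @export
setMethod("decisionAttribute", "DecisionTable", function(object) object@decision)

# ---- show methods -----------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz\n",
              nrow(object@samples), ncol(object@samples), object@samplingRate))
  cat(sprintf("  label: %s  subject: %d  trial: %d\n",
              as.character(object@label), object@subjectId, object@trialId))
})

setMethod("show", "ChannelMontage", function(object) {
  cat(sprintf("ChannelMontage: %d channels, %d selected\n",
              length(object@channelNames), length(object@selectedSubset)))
  cat("  ", paste(utils::head(object@channelNames, 8), collapse = " "),
      if (length(object@channelNames) > 8) "..." else "", "\n")
})

setMethod("show", "Scalogram", function(object) {
  f <- range(peakFrequency(object@wavelet) * object@samplingRate /
               (2 * pi * object@scales))
  cat(sprintf("Scalogram: %d scales x %d times (%s, %s), %.2f-%.2f Hz\n",
              nrow(object@coefficients), ncol(object@coefficients),
              object@wavelet@family, object@wavelet@normalization,
              f[1], f[2]))
})

setMethod("show", "SpectrogramImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SpectrogramImage: %d x %d x 3 (%s, %s scaling)\n",
              d[1], d[2], object@colormap, object@scaling))
})

setMethod("show", "DecisionTable", function(object) {
  cat(sprintf("DecisionTable: |U| = %d, |C| = %d, decision levels: %s\n",
              nrow(object@values), ncol(object@values),
              paste(levels(object@decision), collapse = "/")))
})

setMethod("show", "DEScore", function(object) {
  cat(sprintf("DEScore: E(P|U+C) = %.6f bits over P = {%s}\n",
              object@value, paste(utils::head(object@subset, 6), collapse = ", ")))
})

setMethod("show", "ChannelRanking", function(object) {
  cat(sprintf("ChannelRanking (%s-score-first): %s\n", object@direction,
              paste(object@channels, collapse = " ")))
  cat(sprintf("  selected: %s\n", paste(object@selected, collapse = " ")))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d centroids x %d dims (k = %d%s)\n",
              nrow(object@centroids), ncol(object@centroids), object@k,
              if (object@perClass) " per class" else ", pooled"))
})

setMethod("show", "HistogramFeature", function(object) {
  cat(sprintf("HistogramFeature[%s, %s]: %d bins, %d vectors encoded\n",
              object@recordingId, as.character(object@label),
              length(object@counts), sum(object@counts)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  for (nm in names(object@accuracies))
    cat(sprintf("  %-22s accuracy %.3f\n", nm, object@accuracies[[nm]]))
  cat(sprintf("  k = %g, folds = %d, seed = %d\n", object@chosenK,
              length(object@folds), object@seed))
})

setMethod("show", "SyntheticDatasetSpec", function(object) {
  cat(sprintf(
    "SyntheticDatasetSpec: %d subjects x 3 classes x %d trials, %d ch @ %g Hz, %d samples\n",
    object@nSubjects, object@nTrialsPerClass,
    length(object@montage@channelNames), object@samplingRate, object@nSamples))
})
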