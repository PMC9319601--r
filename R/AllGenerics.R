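# Accessor generics. Slot access from user code should go through these.

#' @rdname EEGRecording-class
#' @param object,x an object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("emotionLabels", function(object) standardGeneric("emotionLabels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname EEGRecording-class
#' @export
setGeneric("trialIds", function(object) standardGeneric("trialIds"))

#' @rdname Scalogram-class
#' @export
setGeneric("waveletScales", function(object) standardGeneric("waveletScales"))

#' @rdname Scalogram-class
#' @export
setGeneric("waveletCoefs", function(object) standardGeneric("waveletCoefs"))

#' @rdname Scalogram-class
#' @export
setGeneric("scaleFrequencies", function(object) standardGeneric("scaleFrequencies"))

#' @rdname Vocabulary-class
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))

#' @rdname HistogramFeature-class
#' @export
setGeneric("histCounts", function(object) standardGeneric("histCounts"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))

#' @rdname EvaluationReport-class
#' @export
setGeneric("confusionMatrices", function(object) standardGeneric("confusionMatrices"))

#' @rdname ChannelRanking-class
#' @export
setGeneric("selectedChannels", function(object) standardGeneric("selectedChannels"))

#' @rdname ChannelRanking-class
#' @export
setGeneric("rankingScores", function(object) standardGeneric("rankingScores"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("unitInfo", function(object) standardGeneric("unitInfo"))

#' @rdname DecisionTable-class
#' @export
setGeneric("conditionAttributes", function(object) standardGeneric("conditionAttributes"))

#' @rdname DecisionTable-class
#' @export
setGeneric("decisionAttribute", function(object) standardGeneric("decisionAttribute"))
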