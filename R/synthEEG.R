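# Synthetic EEG generation with class-dependent band-power structure.

#' EEG frequency bands
#'
#' The four classical bands used throughout the pipeline: delta 1-4 Hz,
#' theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz.
#'
#' @return data.frame with columns \code{name}, \code{low}, \code{high} (Hz).
#' @examples
#' eegBands()
#' @export
eegBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             low = c(1, 4, 8, 13), high = c(4, 8, 13, 30),
             stringsAsFactors = FALSE)
}

#' Construct a band definition
#'
#' @param name band name.
#' @param low,high band edges in Hz, 0 < low < high.
#' @return one-row data.frame in the \code{\link{eegBands}} layout.
#' @export
bandDefinition <- function(name, low, high) {
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  data.frame(name = name, low = low, high = high, stringsAsFactors = FALSE)
}

#' The 62-channel extended 10-20 montage with a 26-channel working subset
#'
#' Electrode labels in the standard 62-channel extended 10-20 order used by
#' SEED-style recordings. The default working subset is a fixed 26-channel
#' scalp-covering selection (prefrontal through parietal rows); which 26
#' channels to use is a free choice and can equally be made data-driven via
#' \code{\link{rankChannels}}.
#'
#' @param subset integer indices overriding the default 26-channel subset.
#' @return A \linkS4class{ChannelMontage}.
#' @examples
#' m <- seedMontage()
#' length(channelNames(m))       # 62
#' length(selectedChannels(m))   # 26
#' @export
seedMontage <- function(subset = NULL) {
  nm <- c("FP1", "FPZ", "FP2", "AF3", "AF4",
          "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
          "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
          "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
          "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
          "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
          "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
          "CB1", "O1", "OZ", "O2", "CB2")
  if (is.null(subset))
    subset <- match(c("FP1", "FPZ", "FP2", "F7", "F3", "FZ", "F4", "F8",
                      "FT7", "FC3", "FCZ", "FC4", "FT8",
                      "T7", "C3", "CZ", "C4", "T8",
                      "TP7", "CP3", "CPZ", "CP4", "TP8",
                      "P7", "PZ", "P8"), nm)
  new("ChannelMontage", channelNames = nm, selectedSubset = as.integer(subset))
}

#' A small montage for simulation studies
#'
#' @param nChannels number of channels.
#' @param subset working-subset indices (default: all).
#' @return A \linkS4class{ChannelMontage} with labels CH01, CH02, ...
#' @export
simpleMontage <- function(nChannels, subset = seq_len(nChannels)) {
  new("ChannelMontage", channelNames = sprintf("CH%02d", seq_len(nChannels)),
      selectedSubset = as.integer(subset))
}

#' Default class-to-band amplitude gains
#'
#' Rows are the emotion classes in \code{emotionLevels()} order, columns the
#' four bands. By default the classes differ only in the beta band
#' (negative 0.6x, neutral 1x, positive 2x), reflecting the common finding
#' that higher-frequency activity discriminates affective valence; the other
#' bands are identical across classes so that separation is carried by a
#' controlled, predictable spectral signature.
#'
#' @return 3 x 4 numeric matrix with dimnames.
#' @export
defaultClassBandGain <- function() {
  g <- matrix(1, 3, 4, dimnames = list(emotionLevels(), eegBands()$name))
  g["negative", "beta"] <- 0.6
  g["positive", "beta"] <- 2.0
  g
}

#' Build a synthetic dataset specification
#'
#' Defaults emulate a SEED-style study: 15 subjects, 5 trials per class per
#' subject (15 clips), the 62-channel montage with its 26-channel working
#' subset as the informative channels, 1000-sample windows at 200 Hz.
#'
#' @param nSubjects,nTrialsPerClass study size.
#' @param montage a \linkS4class{ChannelMontage}.
#' @param samplingRate Hz.
#' @param nSamples samples per recording window.
#' @param classBandGain 3 x 4 gain matrix, see
#'   \code{\link{defaultClassBandGain}}.
#' @param informativeChannels channel indices carrying class structure
#'   (default: the montage's selected subset).
#' @param noiseSd white-noise sd in microvolts.
#' @param baseAmplitude per-sinusoid amplitude before gains (microvolts).
#' @param nComponentsPerBand sinusoids per band.
#' @param subjectSd lognormal sd of the per-subject amplitude multiplier.
#' @param seed master seed.
#' @return A \linkS4class{SyntheticDatasetSpec}.
#' @examples
#' spec <- syntheticDatasetSpec(nSubjects = 2, nTrialsPerClass = 3,
#'                              montage = simpleMontage(8))
#' spec
#' @export
syntheticDatasetSpec <- function(nSubjects = 15L, nTrialsPerClass = 5L,
                                 montage = seedMontage(),
                                 samplingRate = 200, nSamples = 1000L,
                                 classBandGain = defaultClassBandGain(),
                                 informativeChannels = selectedChannels(montage),
                                 noiseSd = 1, baseAmplitude = 5,
                                 nComponentsPerBand = 3L,
                                 subjectSd = 0.1, seed = 1L) {
  new("SyntheticDatasetSpec", nSubjects = as.integer(nSubjects),
      nTrialsPerClass = as.integer(nTrialsPerClass), montage = montage,
      samplingRate = samplingRate, nSamples = as.integer(nSamples),
      classBandGain = classBandGain,
      informativeChannels = as.integer(informativeChannels),
      noiseSd = noiseSd, baseAmplitude = baseAmplitude,
      nComponentsPerBand = as.integer(nComponentsPerBand),
      subjectSd = subjectSd, seed = as.integer(seed))
}

#' Generate one synthetic EEG recording
#'
#' Informative channels receive, per band, \code{nComponentsPerBand}
#' sinusoids at frequencies drawn uniformly within the band, with random
#' phases and amplitude \code{baseAmplitude * classBandGain[label, band]}
#' (times the per-subject multiplier); white Gaussian noise is added to all
#' channels, and non-informative channels contain noise only. The RNG stream
#' is derived by hashing (seed, subject, trial, label), so a recording is
#' bit-reproducible independently of generation order.
#'
#' @param spec a \linkS4class{SyntheticDatasetSpec}.
#' @param label emotion label.
#' @param subjectId,trialId identifiers.
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' spec <- syntheticDatasetSpec(montage = simpleMontage(4), seed = 7)
#' rec <- generateRecording(spec, "positive", 1, 1)
#' rec
#' @export
generateRecording <- function(spec, label, subjectId, trialId) {
  stopifnot(is(spec, "SyntheticDatasetSpec"))
  label <- emotionFactor(label)
  nCh <- length(spec@montage@channelNames)
  if (nCh < 1L) stop("montage has zero channels")
  n <- spec@nSamples
  t <- seq_len(n) / spec@samplingRate
  code <- as.integer(label) - 1L
  bands <- eegBands()
  gains <- spec@classBandGain[as.integer(label), ]

  subjMult <- if (spec@subjectSd > 0) {
    withSeed(hashSeed(spec@seed, subjectId, 0, 999983),
             stats::rlnorm(1, 0, spec@subjectSd))
  } else 1

  x <- withSeed(hashSeed(spec@seed, subjectId, trialId, code), {
    out <- matrix(stats::rnorm(nCh * n, 0, spec@noiseSd), nCh, n)
    for (ch in spec@informativeChannels) {
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        amp <- spec@baseAmplitude * gains[b]
        for (j in seq_len(spec@nComponentsPerBand)) {
          f <- stats::runif(1, bands$low[b], bands$high[b])
          ph <- stats::runif(1, 0, 2 * pi)
          if (amp > 0) sig <- sig + amp * sin(2 * pi * f * t + ph)
        }
      }
      out[ch, ] <- out[ch, ] + subjMult * sig
    }
    out
  })
  rownames(x) <- spec@montage@channelNames
  EEGRecording(x, spec@samplingRate, label, subjectId, trialId)
}

#' Generate a full labelled synthetic dataset
#'
#' Produces \code{nSubjects x 3 x nTrialsPerClass} recordings with balanced
#' labels, reproducible under the spec's master seed.
#'
#' @param spec a \linkS4class{SyntheticDatasetSpec}.
#' @return An \linkS4class{EEGDataset}.
#' @examples
#' spec <- syntheticDatasetSpec(nSubjects = 2, nTrialsPerClass = 3,
#'                              montage = simpleMontage(4))
#' ds <- generateDataset(spec)
#' table(emotionLabels(ds))
#' @export
generateDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticDatasetSpec"))
  recs <- list()
  for (s in seq_len(spec@nSubjects))
    for (lab in emotionLevels())
      for (tr in seq_len(spec@nTrialsPerClass))
        recs[[length(recs) + 1L]] <- generateRecording(spec, lab, s, tr)
  EEGDataset(recs)
}
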