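# Feature extraction: layer arithmetic, cross-entropy loss, the pluggable
# extractor contract, and the bundled deterministic grid-statistics
# extractor.

#' Convolution layer output size
#'
#' \eqn{Y_{out} = (Y_{in} + 2p - k)/s + 1}. Errors when the division is not
#' exact (dimension mismatch).
#'
#' @param yin input size (pixels).
#' @param k kernel size.
#' @param s stride.
#' @param p padding (>= 0).
#' @return integer output size.
#' @examples
#' convOutputSize(224, k = 34, s = 2, p = 16)  # 112
#' convOutputSize(56, k = 3, s = 1, p = 1)     # 56 (same padding)
#' @export
convOutputSize <- function(yin, k, s, p = 0L) {
  stopifnot(yin > 0, k > 0, s > 0, p >= 0)
  num <- yin + 2 * p - k
  if (num < 0) stop("kernel larger than padded input")
  if (num %% s != 0)
    stop(sprintf("dimension mismatch: (%d + 2*%d - %d) not divisible by stride %d",
                 yin, p, k, s))
  as.integer(num / s + 1)
}

#' Softmax cross-entropy loss
#'
#' \eqn{-\sum_i r_i \log \delta_i} with natural logarithm, for a one-hot
#' truth vector r and predicted class probabilities delta. Zero iff the true
#' class has probability one; a zero probability at the true class is an
#' infinite-loss condition and returns \code{Inf} with a warning.
#'
#' @param trueOnehot one-hot numeric vector.
#' @param predictedProbs probabilities in [0, 1] summing to 1 (tolerance
#'   1e-9).
#' @return non-negative numeric (possibly \code{Inf}).
#' @examples
#' crossEntropyLoss(c(1, 0, 0), c(0.5, 0.25, 0.25))  # -log(0.5)
#' @export
crossEntropyLoss <- function(trueOnehot, predictedProbs) {
  r <- trueOnehot; d <- predictedProbs
  if (length(r) != length(d)) stop("length mismatch")
  if (!all(r %in% c(0, 1)) || sum(r) != 1) stop("trueOnehot must be one-hot")
  if (any(d < 0) || any(d > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(d) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- d[which(r == 1)]
  if (p == 0) {
    warning("zero probability at the true class: infinite loss")
    return(Inf)
  }
  -log(p)
}

#' Construct a feature extractor
#'
#' @param name extractor name.
#' @param outputDim fixed output length q.
#' @param fun function mapping a \linkS4class{SpectrogramImage} to a numeric
#'   vector of length \code{outputDim}.
#' @return A \linkS4class{FeatureExtractor}.
#' @export
featureExtractor <- function(name, outputDim, fun) {
  new("FeatureExtractor", name = name, outputDim = as.integer(outputDim),
      fun = fun)
}

#' The bundled deterministic grid-statistics extractor
#'
#' A no-download stand-alone extractor over scalogram images: the image is
#' reduced to grey intensity and summarised by multi-scale grid statistics
#' --- per-cell means and standard deviations on 2x2, 4x4 and 8x8 grids,
#' magnitude-weighted 8-bin gradient-orientation histograms on the 4x4 and
#' 8x8 grids, and global intensity statistics --- zero-padded to a fixed
#' length (default q = 1000). Feature names are prefixed \code{mean_},
#' \code{sd_}, \code{grad_}, \code{glob_} and \code{pad_} so intensity
#' statistics and texture-orientation statistics can be told apart: a
#' constant brightness shift moves only the \code{mean_} and location-type
#' \code{glob_} features.
#'
#' @param outputDim target output length (default 1000).
#' @return A \linkS4class{FeatureExtractor}.
#' @examples
#' ex <- fallbackExtractor()
#' ex@name
#' @export
fallbackExtractor <- function(outputDim = 1000L) {
  outputDim <- as.integer(outputDim)
  fun <- function(image) {
    I <- (image@pixels[, , 1] + image@pixels[, , 2] + image@pixels[, , 3]) /
      (3 * 255)
    h <- nrow(I); w <- ncol(I)
    cellIndex <- function(g) {
      ri <- ceiling(seq_len(h) / (h / g))
      ci <- ceiling(seq_len(w) / (w / g))
      (ci[col(I)] - 1L) * g + ri[row(I)]
    }
    cellStats <- function(g) {
      idx <- as.vector(cellIndex(g))
      cnt <- tabulate(idx, g * g)
      mn <- rowsum(as.vector(I), idx)[, 1] / cnt
      # two-pass unbiased sd (single-pass moment differences lose precision
      # on near-constant cells)
      dev2 <- (as.vector(I) - mn[idx])^2
      sd_ <- sqrt(rowsum(dev2, idx)[, 1] / pmax(cnt - 1, 1))
      list(mean = unname(mn), sd = unname(sd_))
    }
    gx <- I[, c(2:w, w)] - I[, c(1, 1:(w - 1))]
    gy <- I[c(2:h, h), ] - I[c(1, 1:(h - 1)), ]
    mag <- sqrt(gx^2 + gy^2)
    ang <- atan2(gy, gx) %% pi  # unsigned orientation in [0, pi)
    gradHist <- function(g, nbin = 8L) {
      bin <- pmin(floor(ang / pi * nbin) + 1L, nbin)
      key <- (as.vector(cellIndex(g)) - 1L) * nbin + as.vector(bin)
      hst <- numeric(g * g * nbin)
      acc <- rowsum(as.vector(mag), key)
      hst[as.integer(rownames(acc))] <- acc[, 1]
      hst
    }
    parts <- list()
    for (g in c(2L, 4L, 8L)) {
      cs <- cellStats(g)
      parts[[paste0("mean_g", g)]] <- cs$mean
      parts[[paste0("sd_g", g)]] <- cs$sd
    }
    for (g in c(4L, 8L))
      parts[[paste0("grad_g", g)]] <- gradHist(g)
    parts[["glob"]] <- c(mean(I), stats::sd(I), stats::median(I), min(I),
                         max(I), stats::quantile(I, c(0.25, 0.75),
                                                 names = FALSE))
    v <- unlist(parts, use.names = FALSE)
    nms <- unlist(lapply(names(parts), function(p)
      sprintf("%s_%03d", p, seq_along(parts[[p]]))), use.names = FALSE)
    if (length(v) > outputDim) {
      v <- v[seq_len(outputDim)]; nms <- nms[seq_len(outputDim)]
    } else if (length(v) < outputDim) {
      npad <- outputDim - length(v)
      v <- c(v, numeric(npad))
      nms <- c(nms, sprintf("pad_%03d", seq_len(npad)))
    }
    names(v) <- nms
    v
  }
  featureExtractor("grid_stats", outputDim, fun)
}

#' Extract features from a list of scalogram images
#'
#' Applies the extractor to every image and assembles the p x q
#' \linkS4class{FeatureMatrix}, one row per (recording, channel) unit, in
#' input order. Errors if the extractor's output length drifts.
#'
#' @param images list of \linkS4class{SpectrogramImage} objects, all the
#'   same size.
#' @param extractor a \linkS4class{FeatureExtractor} (default
#'   \code{\link{fallbackExtractor}()}).
#' @param info data.frame with one row per image: \code{subject},
#'   \code{trial}, \code{channel}, \code{recording}, \code{label}. Defaults
#'   label all units identically (useful for ad-hoc extraction).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
extractFeatures <- function(images, extractor = fallbackExtractor(),
                            info = NULL) {
  if (length(images) == 0L) stop("no images supplied")
  d1 <- dim(images[[1]]@pixels)
  same <- vapply(images, function(im) identical(dim(im@pixels), d1), logical(1))
  if (!all(same)) stop("all images must have the same size")
  rows <- lapply(images, function(im) {
    v <- extractor@fun(im)
    if (length(v) != extractor@outputDim)
      stop(sprintf("extractor '%s' output length drift: got %d, expected %d",
                   extractor@name, length(v), extractor@outputDim))
    v
  })
  values <- do.call(rbind, rows)
  if (is.null(info))
    info <- data.frame(subject = 1L, trial = seq_along(images), channel = 1L,
                       recording = sprintf("r%04d", seq_along(images)),
                       label = "neutral")
  FeatureMatrix(values, info)
}

#' Scalogram-image features for a whole dataset
#'
#' Convenience wrapper running segment-free per-channel CWT, image rendering
#' and feature extraction over every recording, producing the pipeline's
#' p x q feature matrix with full unit metadata.
#'
#' @param dataset an \linkS4class{EEGDataset}.
#' @param wavelet a \linkS4class{WaveletSpec}.
#' @param nScales scales in the scalogram (default 64).
#' @param freqRange Hz range of the scale grid.
#' @param imageSize rendered image size (default 224).
#' @param colormap,scaling passed to \code{\link{renderScalogramImage}}.
#' @param extractor a \linkS4class{FeatureExtractor}.
#' @param channels channel indices to process (default: all).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
datasetFeatures <- function(dataset, wavelet = waveletSpec(), nScales = 64L,
                            freqRange = c(1, 45), imageSize = 224L,
                            colormap = "jet", scaling = "log",
                            extractor = fallbackExtractor(),
                            channels = NULL) {
  stopifnot(length(dataset) > 0L)
  fs <- dataset[[1]]@samplingRate
  scales <- defaultScales(wavelet, fs, nScales, freqRange)
  images <- list(); meta <- list()
  for (i in seq_along(dataset)) {
    rec <- dataset[[i]]
    chs <- if (is.null(channels)) seq_len(nrow(rec@samples)) else channels
    for (ch in chs) {
      sc <- cwt(rec@samples[ch, ], wavelet, scales, samplingRate = fs)
      images[[length(images) + 1L]] <-
        renderScalogramImage(sc, imageSize, colormap, scaling)
      meta[[length(meta) + 1L]] <- data.frame(
        subject = rec@subjectId, trial = rec@trialId, channel = ch,
        recording = sprintf("s%02d_t%02d_%s", rec@subjectId, rec@trialId,
                            as.character(rec@label)),
        label = as.character(rec@label))
    }
  }
  extractFeatures(images, extractor, do.call(rbind, meta))
}
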