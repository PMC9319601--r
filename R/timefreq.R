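# Time-frequency decomposition: STFT, CWT scalograms, inverse CWT,
# admissibility, band-pass decomposition, image rendering, segmentation.

#' Evaluate the mother wavelet's frequency response
#'
#' Returns \eqn{\hat\psi(\omega)} for the analytic families supported by
#' \code{\link{waveletSpec}}; identically zero for \eqn{\omega \le 0}.
#'
#' @param wavelet a \linkS4class{WaveletSpec}.
#' @param omega angular frequencies (radians per sample).
#' @return numeric vector of the same length as \code{omega}.
#' @export
waveletFourier <- function(wavelet, omega) {
  out <- numeric(length(omega))
  pos <- omega > 0
  w <- omega[pos]
  out[pos] <- switch(wavelet@family,
    morse = {
      b <- wavelet@beta; g <- wavelet@gamma
      # amplitude normalised so the peak (at (b/g)^(1/g)) has value 2
      a <- 2 * exp((b / g) * (log(g) - log(b) + 1))
      a * exp(b * log(w) - w^g)
    },
    morlet = 2 * exp(-(w - wavelet@omega0)^2 / 2))
  out
}

#' Peak (centre) angular frequency of a mother wavelet
#'
#' @param wavelet a \linkS4class{WaveletSpec}.
#' @return radians per sample at scale 1.
#' @export
peakFrequency <- function(wavelet) {
  switch(wavelet@family,
    morse = (wavelet@beta / wavelet@gamma)^(1 / wavelet@gamma),
    morlet = wavelet@omega0)
}

# Effective time-domain standard deviation of the mother wavelet envelope,
# in samples at scale 1; used to size edge padding.
waveletTimeSd <- function(wavelet) {
  switch(wavelet@family,
    morse = sqrt(wavelet@beta) / peakFrequency(wavelet),
    morlet = 1)
}

# One-sided time support radius at scale 1, beyond which the envelope is
# below ~1e-8 of its peak. The Morse envelope has heavier-than-Gaussian
# tails, hence the larger multiple of its nominal sd.
waveletSupportRadius <- function(wavelet) {
  switch(wavelet@family,
    morse = 26 * sqrt(wavelet@beta / 20),
    morlet = 7)
}

# Shared machinery for the admissibility-type integrals
#   int psi_hat(omega)^power / omega d omega   over omega > 0,
# restricted to the wavelet's effective support (outside it the response is
# below 1e-14 of the peak, so the 1/omega tail contributes negligibly; a
# truly nonzero-mean wavelet is rejected before integrating).
waveletOmegaIntegral <- function(wavelet, power) {
  f <- if (is.function(wavelet)) wavelet else
    function(w) waveletFourier(wavelet, w)
  wp <- if (is.function(wavelet)) {
    grid <- exp(seq(log(1e-3), log(1e3), length.out = 2000L))
    grid[which.max(abs(f(grid)))]
  } else peakFrequency(wavelet)
  pk <- f(wp)
  if (pk <= 0) stop("wavelet frequency response must be positive at its peak")
  if (abs(f(wp * 1e-6)) > 1e-6 * abs(pk))
    stop("non-admissible wavelet: psi_hat(0) != 0 (nonzero mean)")
  up <- wp
  while (abs(f(up)) > 1e-12 * abs(pk)) up <- up * 2
  lo <- wp
  while (lo > wp * 1e-9 && abs(f(lo / 2)) > 1e-14 * abs(pk)) lo <- lo / 2
  v <- stats::integrate(function(w) f(w)^power / w, lower = lo, upper = up,
                        rel.tol = 1e-10, subdivisions = 1000L)$value
  if (!is.finite(v) || v <= 0) stop("admissibility integral did not converge")
  v
}

#' Admissibility constant of a mother wavelet
#'
#' Numerically evaluates \eqn{C_\psi = \int \tilde{\hat\psi}(\omega) /
#' |\omega|\, d\omega} with \eqn{\tilde{\hat\psi} = \hat\psi \cdot \hat\psi}
#' (the self-dual case) by adaptive quadrature, so the constant is quadratic
#' in the wavelet amplitude. A finite positive value certifies that the
#' wavelet supports lossless analysis/reconstruction; a wavelet with
#' nonzero mean (\eqn{\hat\psi(0) \neq 0}) makes the integral diverge and is
#' rejected.
#'
#' @param wavelet a \linkS4class{WaveletSpec}, or a function
#'   \code{f(omega)} giving a frequency response directly.
#' @return positive finite numeric.
#' @examples
#' admissibilityConstant(waveletSpec("morlet"))
#' @export
admissibilityConstant <- function(wavelet) {
  if (!is.function(wavelet)) {
    key <- paste("adm", wavelet@family, wavelet@gamma, wavelet@beta,
                 wavelet@omega0, sep = "|")
    hit <- .waveletIntegralCache[[key]]
    if (!is.null(hit)) return(hit)
  }
  v <- waveletOmegaIntegral(wavelet, power = 2)
  if (!is.function(wavelet)) .waveletIntegralCache[[key]] <- v
  v
}

# Delta-synthesis constant int psi_hat(omega)/omega d omega used by the
# single-integral reconstruction in icwt().
deltaSynthesisConstant <- function(wavelet) {
  key <- paste("delta", wavelet@family, wavelet@gamma, wavelet@beta,
               wavelet@omega0, sep = "|")
  hit <- .waveletIntegralCache[[key]]
  if (!is.null(hit)) return(hit)
  v <- waveletOmegaIntegral(wavelet, power = 1)
  .waveletIntegralCache[[key]] <- v
  v
}

.waveletIntegralCache <- new.env(parent = emptyenv())

#' Default scale grid for EEG scalograms
#'
#' Logarithmically spaced scales whose centre frequencies cover
#' \code{freqRange} (default 1-45 Hz, spanning delta through beta with
#' headroom).
#'
#' @param wavelet a \linkS4class{WaveletSpec}.
#' @param samplingRate Hz.
#' @param nScales number of scales (default 64).
#' @param freqRange length-2 Hz range.
#' @return strictly increasing numeric scales in samples.
#' @export
defaultScales <- function(wavelet, samplingRate, nScales = 64L,
                          freqRange = c(1, 45)) {
  f <- exp(seq(log(freqRange[2]), log(freqRange[1]), length.out = nScales))
  sort(peakFrequency(wavelet) * samplingRate / (2 * pi * f))
}

#' Short-time Fourier transform
#'
#' Windows the signal at regular hops and Fourier-transforms each frame.
#' Rows index frequency bins, columns index window centres; the transform is
#' linear in the signal.
#'
#' @param x numeric signal.
#' @param window a \linkS4class{WindowSpec}.
#' @param hop hop size in samples (> 0).
#' @param samplingRate Hz (used only to label the frequency axis).
#' @return complex matrix with attributes \code{frequency} (Hz) and
#'   \code{time} (window-centre sample index).
#' @examples
#' x <- sin(2 * pi * 0.1 * seq_len(256))
#' S <- stft(x, windowSpec("hann", 64), hop = 16)
#' dim(S)
#' @export
stft <- function(x, window = windowSpec("hann", 128L), hop = 32L,
                 samplingRate = 1) {
  if (length(x) == 0L) stop("empty signal")
  if (hop <= 0) stop("hop must be > 0")
  L <- window@length
  if (L > length(x)) stop("window longer than signal")
  w <- switch(window@kind,
    rectangular = rep(1, L),
    hann = 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / L),
    gaussian = exp(-0.5 * ((seq_len(L) - (L + 1) / 2) / (L / 6))^2))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  out <- stats::mvfft(matrix(frames, nrow = L))
  attr(out, "frequency") <- (seq_len(L) - 1) * samplingRate / L
  attr(out, "time") <- starts + (L - 1) / 2
  out
}

#' Continuous wavelet transform
#'
#' Computes \eqn{W_x(m, n) = m^{-p} \int x(t)\,\psi^*((t - n)/m)\,dt} for
#' every scale m in \code{scales} and every shift n, with \eqn{p = 1} (L1
#' normalization) or \eqn{p = 1/2} (L2), via the Fourier-domain product
#' \eqn{X(\omega)\, m^{1-p}\hat\psi(m\omega)}. Edge effects are controlled
#' by symmetric (reflective) padding sized to the largest wavelet support,
#' trimmed after the transform.
#'
#' @param x numeric signal (a single channel).
#' @param wavelet a \linkS4class{WaveletSpec}.
#' @param scales strictly increasing positive scales in samples; default
#'   \code{\link{defaultScales}}.
#' @param samplingRate Hz, carried into the scalogram metadata.
#' @param pad logical; symmetric edge padding (default TRUE).
#' @return A \linkS4class{Scalogram} with an i-column, j-row coefficient
#'   matrix for a length-i signal and j scales.
#' @examples
#' x <- sin(2 * pi * 10 * seq_len(400) / 200)
#' sc <- cwt(x, waveletSpec("morse"), samplingRate = 200)
#' sc
#' @export
cwt <- function(x, wavelet = waveletSpec(), scales = NULL,
                samplingRate = 1, pad = TRUE) {
  if (length(x) < 2L) stop("signal too short")
  admissibilityConstant(wavelet)  # errors on non-admissible wavelets
  if (is.null(scales)) scales <- defaultScales(wavelet, samplingRate)
  if (length(scales) == 0L) stop("empty scales")
  if (any(scales <= 0)) stop("scales must be positive")
  n <- length(x)
  # symmetric (reflective) padding of up to one signal length, plus a zero
  # gap so that the circular FFT convolution has no appreciable wrap-around
  # even when the wavelet support exceeds the available reflection
  support <- ceiling(waveletSupportRadius(wavelet) * max(scales))
  padLen <- if (pad) min(n, support) else 0L
  zeroGap <- if (pad) max(0L, support - padLen) else 0L
  xp <- if (padLen > 0)
    c(rev(x[seq_len(padLen)]), x, rev(x[n - seq_len(padLen) + 1L]),
      numeric(zeroGap))
  else x
  np <- length(xp)
  X <- stats::fft(xp)
  k <- seq_len(np) - 1
  omega <- 2 * pi * ifelse(k <= np / 2, k, k - np) / np
  p <- if (wavelet@normalization == "L1") 1 else 0.5
  co <- matrix(0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    filt <- s^(1 - p) * waveletFourier(wavelet, s * omega)
    row <- stats::fft(X * filt, inverse = TRUE) / np
    co[j, ] <- row[(padLen + 1):(padLen + n)]
  }
  new("Scalogram", coefficients = co, scales = as.numeric(scales),
      times = as.numeric(seq_len(n)), samplingRate = samplingRate,
      wavelet = wavelet, sourceLength = as.integer(n))
}

#' Inverse continuous wavelet transform
#'
#' Reconstructs a real signal from an analytic-wavelet scalogram by the
#' single-integral (delta-function) formula: summing coefficients over
#' log-spaced scales with trapezoidal weights and normalising by the
#' delta-synthesis constant \eqn{C = \int \hat\psi(\omega)/\omega\,
#' d\omega} (the admissibility integral is evaluated first and must
#' converge),
#' \eqn{x(t) = (2/C_\psi)\,\mathrm{Re} \sum_j W(m_j, t)\, m_j^{p-1}\,
#' \Delta \ln m}. Linear in the coefficients; accuracy depends on the scale
#' grid covering the signal band.
#'
#' @param scalogram a \linkS4class{Scalogram}.
#' @return numeric signal of the scalogram's source length.
#' @examples
#' x <- sin(2 * pi * 10 * seq_len(1000) / 200)
#' xr <- icwt(cwt(x, samplingRate = 200))
#' sqrt(mean((x - xr)^2)) / sqrt(mean(x^2))  # small relative error
#' @export
icwt <- function(scalogram) {
  stopifnot(is(scalogram, "Scalogram"))
  wv <- scalogram@wavelet
  admissibilityConstant(wv)  # errors if the admissibility integral diverges
  C <- deltaSynthesisConstant(wv)
  s <- scalogram@scales
  ls <- log(s)
  # trapezoid weights over ln(scale)
  wgt <- if (length(s) == 1L) 1 else {
    d <- diff(ls)
    c(d[1] / 2, (d[-1] + d[-length(d)]) / 2, d[length(d)] / 2)
  }
  p <- if (wv@normalization == "L1") 1 else 0.5
  wgt <- wgt * s^(p - 1)
  (2 / C) * Re(crossprod(scalogram@coefficients, wgt))[, 1]
}

#' Band-pass decomposition into the classical EEG bands
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass of order 4
#' per band per channel.
#'
#' @param recording an \linkS4class{EEGRecording} (or a numeric matrix
#'   channels x samples together with \code{samplingRate}).
#' @param bands data.frame as returned by \code{\link{eegBands}}.
#' @param samplingRate Hz; taken from the recording when one is given.
#' @param order Butterworth order (default 4).
#' @return named list, one channels x samples matrix per band.
#' @examples
#' spec <- syntheticDatasetSpec(montage = simpleMontage(2))
#' rec <- generateRecording(spec, "neutral", 1, 1)
#' str(bandpassDecompose(rec), max.level = 1)
#' @export
bandpassDecompose <- function(recording, bands = eegBands(),
                              samplingRate = NULL, order = 4L) {
  if (is(recording, "EEGRecording")) {
    m <- recording@samples
    samplingRate <- recording@samplingRate
  } else {
    m <- as.matrix(recording)
    if (is.null(samplingRate)) stop("samplingRate required for a bare matrix")
  }
  nyq <- samplingRate / 2
  if (any(bands$high >= nyq))
    stop("band edge at or above the Nyquist frequency")
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  for (b in seq_len(nrow(bands))) {
    bt <- signal::butter(order, c(bands$low[b], bands$high[b]) / nyq,
                         type = "pass")
    out[[b]] <- t(apply(m, 1, function(ch) signal::filtfilt(bt, ch)))
    dimnames(out[[b]]) <- dimnames(m)
  }
  out
}

#' Render a scalogram as a colour image
#'
#' Maps |coefficients| through an amplitude scaling (linear, or
#' \code{log1p}-compressed) to [0, 1], applies a colormap, and bilinearly
#' resizes to the requested square size. Amplitudes are normalised by an
#' upper-quantile reference (default the 98th percentile) and clipped,
#' rather than by the raw maximum: the per-image maximum is a high-variance
#' statistic, and referencing it injects spurious image-to-image brightness
#' variation that contaminates downstream features. Deterministic.
#'
#' @param scalogram a \linkS4class{Scalogram}.
#' @param size output height/width in pixels (default 224, the standard
#'   backbone input size).
#' @param colormap "jet" (default) or "gray".
#' @param scaling "log" (default) or "linear".
#' @param refQuantile quantile of |coefficients| used as the unit-amplitude
#'   reference; 1 reproduces plain max normalization.
#' @return A \linkS4class{SpectrogramImage}.
#' @export
renderScalogramImage <- function(scalogram, size = 224L,
                                 colormap = c("jet", "gray"),
                                 scaling = c("log", "linear"),
                                 refQuantile = 0.98) {
  colormap <- match.arg(colormap)
  scaling <- match.arg(scaling)
  A <- Mod(scalogram@coefficients)
  if (nrow(A) == 0L || ncol(A) == 0L) stop("empty scalogram")
  mx <- stats::quantile(A, refQuantile, names = FALSE)
  if (mx == 0) mx <- max(A)  # degenerate sparse case: fall back to the max
  v <- if (mx == 0) array(0, dim(A)) else switch(scaling,
    linear = pmin(A / mx, 1),
    log = pmin(log1p(A) / log1p(mx), 1))
  # resize magnitude first (bilinear), then colorize
  img <- EBImage::resize(EBImage::Image(t(v)), w = size, h = size,
                         filter = "bilinear")
  vi <- pmin(pmax(t(EBImage::imageData(img)), 0), 1)
  rgb <- applyColormap(as.vector(vi), colormap)
  px <- array(rgb * 255, dim = c(dim(vi), 3L))
  new("SpectrogramImage", pixels = px, colormap = colormap, scaling = scaling)
}

#' Segment a recording into fixed-length windows
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param windowLen window length in samples (default 1000).
#' @param hop hop between window starts (default \code{windowLen}, i.e.
#'   non-overlapping).
#' @return list of \linkS4class{EEGRecording} segments carrying the parent's
#'   label and identifiers; \code{floor((n - windowLen)/hop) + 1} segments.
#' @export
segmentSignal <- function(recording, windowLen = 1000L, hop = windowLen) {
  stopifnot(is(recording, "EEGRecording"))
  if (hop <= 0) stop("hop must be > 0")
  n <- ncol(recording@samples)
  if (windowLen > n) stop("windowLen exceeds recording length")
  starts <- seq(1L, n - windowLen + 1L, by = hop)
  lapply(starts, function(s)
    EEGRecording(recording@samples[, s:(s + windowLen - 1L), drop = FALSE],
                 recording@samplingRate, recording@label,
                 recording@subjectId, recording@trialId))
}
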