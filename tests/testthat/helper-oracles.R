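# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: band powers come from a raw periodogram, wavelet
# transforms from direct time-domain quadrature with independently evaluated
# mother wavelets.

# periodogram band power: fraction helpers work on raw |fft|^2
bandPowerOracle <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sum(P[f >= lo & f < hi & f <= fs / 2])
}

# analytic Morlet mother wavelet in closed form (time domain), matching
# psi_hat(omega) = 2 exp(-(omega - omega0)^2 / 2) on omega > 0; the
# truncation correction is O(exp(-omega0^2/2)) ~ 1.5e-8 and negligible at
# the tolerances used
morletTime <- function(t, omega0 = 6) {
  sqrt(2 / pi) * exp(-t^2 / 2) * exp(1i * omega0 * t)
}

# Morse mother wavelet in time, evaluated by Gauss-Legendre quadrature of
# the inverse Fourier integral (independent of the package's FFT path)
morseTime <- function(t, gamma = 3, beta = 20, nNodes = 2000L) {
  a <- 2 * exp((beta / gamma) * (log(gamma) - log(beta) + 1))
  gl <- pracma::gaussLegendre(nNodes, 0, 6)
  psiHat <- a * exp(beta * log(gl$x) - gl$x^gamma)
  vapply(t, function(tt)
    sum(gl$w * psiHat * exp(1i * gl$x * tt)) / (2 * pi), complex(1))
}

# direct quadrature of the CWT definition on the same symmetrically padded
# signal the fast path uses (the padding is part of the transform's edge
# contract; the values themselves are computed by plain summation over the
# reflect-extended signal, with the wavelet evaluated on its full support)
cwtQuadratureOracle <- function(x, scales, family = "morlet",
                                normalization = "L1") {
  n <- length(x)
  radius <- if (family == "morse") 26 else 7
  padLen <- min(n, ceiling(radius * max(scales)))
  xp <- c(rev(x[seq_len(padLen)]), x, rev(x[n - seq_len(padLen) + 1]))
  tt <- seq_along(xp) - padLen  # original samples sit at t = 1..n
  p <- if (normalization == "L1") 1 else 0.5
  motherAt <- function(args) {
    if (family == "morlet") morletTime(args) else morseTime(args)
  }
  W <- matrix(0i, length(scales), n)
  for (j in seq_along(scales)) {
    s <- scales[j]
    # distinct args (t - b)/s for integer t - b
    offsets <- (min(tt) - n):(max(tt) - 1)
    psiVals <- motherAt(offsets / s)
    lookup <- function(d) psiVals[d - min(offsets) + 1L]
    for (b in seq_len(n))
      W[j, b] <- sum(xp * Conj(lookup(tt - b))) / s^p
  }
  W
}

# random decision table for property tests
randomDecisionTable <- function(nU, nC, nCodes = 3L) {
  vals <- matrix(sample.int(nCodes, nU * nC, replace = TRUE) - 1L, nU, nC)
  colnames(vals) <- sprintf("a%02d", seq_len(nC))
  DecisionTable(vals, sample(emotionLevels(), nU, replace = TRUE))
}

# the study-conditions generator spec used in the recovery and end-to-end
# simulations: 8 channels of which the first 4 (or all 8) are informative,
# class separation carried by a 3x beta-band gain for the positive class
separableGain <- function() {
  g <- defaultClassBandGain()
  g["positive", "beta"] <- 3
  g
}

makeSeparableSpec <- function(seed, nSubjects = 2L, nTrialsPerClass = 5L,
                              nChannels = 8L, informative = 1:4) {
  syntheticDatasetSpec(nSubjects = nSubjects,
                       nTrialsPerClass = nTrialsPerClass,
                       montage = simpleMontage(nChannels),
                       informativeChannels = informative,
                       classBandGain = separableGain(), seed = seed)
}

# compact feature settings used in simulations (documented problem sizes:
# 32 scales, 64 x 64 images keep the suite fast without changing behaviour)
simFeatures <- function(dataset) {
  datasetFeatures(dataset, nScales = 32L, imageSize = 64L)
}
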