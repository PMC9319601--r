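# Time-frequency stack: STFT, CWT vs quadrature, inverse transform,
# admissibility, band filters, rendering, segmentation.

test_that("stft is zero on zero input, linear, and localises a pure tone", {
  n <- 128L
  win <- windowSpec("rectangular", 64L)
  expect_true(all(stft(numeric(n), win, hop = 16) == 0))
  set.seed(1)
  x <- rnorm(n)
  expect_equal(stft(3.5 * x, win, hop = 16), 3.5 * stft(x, win, hop = 16))
  # pure sinusoid: per-column magnitude argmax at the nearest frequency bin,
  # cross-checked against direct summation of the windowed transform
  f0 <- 10 / 64  # cycles/sample, exactly bin 10 of a 64-point window
  x <- sin(2 * pi * f0 * seq_len(n))
  S <- stft(x, win, hop = 16)
  starts <- attr(S, "time") - (64 - 1) / 2
  for (ci in seq_along(starts)) {
    frame <- x[starts[ci]:(starts[ci] + 63)]
    direct <- vapply(0:63, function(k)
      sum(frame * exp(-2i * pi * k * (0:63) / 64)), complex(1))
    expect_equal(Mod(S[, ci]), Mod(direct), tolerance = 1e-10)
    expect_equal(which.max(Mod(S[1:32, ci])), 11L)  # bin 10 is index 11
  }
  expect_error(stft(numeric(0), win), "empty")
  expect_error(stft(x, win, hop = 0), "hop")
})

test_that("cwt is zero on zero input and linear in the signal", {
  n <- 64L
  sc0 <- cwt(numeric(n), waveletSpec("morlet"), scales = c(4, 8))
  expect_true(all(Mod(waveletCoefs(sc0)) == 0))
  set.seed(2)
  x <- rnorm(n)
  w1 <- waveletCoefs(cwt(x, waveletSpec("morlet"), scales = c(4, 8)))
  w2 <- waveletCoefs(cwt(2 * x, waveletSpec("morlet"), scales = c(4, 8)))
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
  expect_error(cwt(x, waveletSpec("morlet"), scales = numeric(0)), "empty")
  expect_error(cwt(x, waveletSpec("morlet"), scales = c(-1, 2)), "positive")
})

test_that("fast cwt matches direct quadrature of the transform definition", {
  # the daughter-wavelet construction psi((t-n)/m)/m is evaluated literally
  # in the oracle; at m = 1, n = 0 it reduces to the mother wavelet itself
  expect_equal(morletTime((5:10 - 0) / 1) / 1, morletTime(5:10))
  n <- 128L
  set.seed(3)
  x <- sin(2 * pi * 0.07 * seq_len(n)) + 0.6 * sin(2 * pi * 0.2 * seq_len(n) + 1)
  scales <- exp(seq(log(4), log(16), length.out = 6))
  for (fam in c("morlet", "morse")) {
    W <- waveletCoefs(cwt(x, waveletSpec(fam), scales))
    Wo <- cwtQuadratureOracle(x, scales, family = fam)
    expect_lt(max(Mod(W - Wo)) / max(Mod(Wo)), 1e-6)
  }
})

test_that("cwt is shift-covariant in the interior", {
  n <- 256L
  shift <- 10L
  set.seed(4)
  base <- rnorm(n + shift)
  x1 <- base[1:n]
  x2 <- base[(1 + shift):(n + shift)]  # x2[t] = x1[t + shift]
  scales <- c(4, 8, 12)
  W1 <- waveletCoefs(cwt(x1, waveletSpec("morlet"), scales))
  W2 <- waveletCoefs(cwt(x2, waveletSpec("morlet"), scales))
  # keep clear of both edges by a full wavelet support at the largest scale
  interior <- 100:(n - 100)
  dev <- Mod(W2[, interior - shift] - W1[, interior])
  expect_lt(max(dev) / max(Mod(W1)), 1e-6)
})

test_that("icwt inverts cwt on band-limited signals and is linear", {
  fs <- 200
  t <- seq_len(1000L) / fs
  u <- sin(2 * pi * 6 * t) + 0.8 * sin(2 * pi * 14 * t + 0.5) +
    0.5 * sin(2 * pi * 23 * t + 1.2)
  for (fam in c("morse", "morlet")) {
    sc <- cwt(u, waveletSpec(fam), samplingRate = fs)
    ur <- icwt(sc)
    expect_lt(sqrt(mean((u - ur)^2)) / sqrt(mean(u^2)), 0.05)
    # linearity in the coefficients and the zero case
    sc2 <- sc
    sc2@coefficients <- 2 * sc@coefficients
    expect_equal(icwt(sc2), 2 * ur, tolerance = 1e-12)
    sc0 <- sc
    sc0@coefficients[] <- 0i
    expect_true(all(icwt(sc0) == 0))
  }
})

test_that("admissibility constant is stable, quadratic in amplitude, and rejects bumps", {
  w <- waveletSpec("morlet")
  C <- admissibilityConstant(w)
  expect_true(is.finite(C) && C > 0)
  # stability: adaptive quadrature vs a fine fixed trapezoid grid
  om <- seq(1e-4, 16, length.out = 400000L)
  trap <- sum(waveletFourier(w, om)^2 / om) * diff(om[1:2])
  expect_equal(C, trap, tolerance = 1e-4)
  # doubling the amplitude scales the constant by 4
  f1 <- function(x) waveletFourier(w, x)
  f2 <- function(x) 2 * waveletFourier(w, x)
  expect_equal(admissibilityConstant(f2) / admissibilityConstant(f1), 4,
               tolerance = 1e-8)
  # a Gaussian bump (nonzero mean, no oscillation) is not admissible
  expect_error(admissibilityConstant(function(x) exp(-x^2 / 4)),
               "non-admissible")
})

test_that("band-pass decomposition isolates alpha content and is energy-consistent", {
  fs <- 200
  n <- 2000L
  x <- matrix(sin(2 * pi * 10 * seq_len(n) / fs), 1)
  rownames(x) <- "CH01"
  out <- bandpassDecompose(x, samplingRate = fs)
  pw <- vapply(out, function(m) mean(m[1, ]^2), numeric(1))
  expect_gt(pw[["alpha"]] / mean(x^2), 0.95)
  expect_lt(pw[["delta"]] / mean(x^2), 0.01)
  # zero in, zero out
  z <- bandpassDecompose(matrix(0, 1, 500), samplingRate = fs)
  expect_true(all(vapply(z, function(m) all(m == 0), logical(1))))
  # white noise: per-band power proportional to bandwidth within 20%
  set.seed(5)
  wn <- matrix(rnorm(40000L), 1)
  pw <- vapply(bandpassDecompose(wn, samplingRate = fs),
               function(m) mean(m[1, ]^2), numeric(1))
  bw <- eegBands()$high - eegBands()$low
  ratio <- (pw / sum(pw)) / (bw / sum(bw))
  expect_true(all(abs(ratio - 1) < 0.2))
  expect_error(bandpassDecompose(wn, bands = bandDefinition("hf", 50, 120),
                                 samplingRate = fs), "Nyquist")
})

test_that("scalogram rendering is deterministic and ridge-faithful", {
  # single dominant ridge at a known scale row
  co <- matrix(0.02 + 0i, 32, 32)
  jstar <- 21L
  co[jstar, ] <- 1 + 0i
  sc <- new("Scalogram", coefficients = co, scales = as.numeric(1:32),
            times = as.numeric(1:32), samplingRate = 100,
            wavelet = waveletSpec("morlet"), sourceLength = 32L)
  img <- renderScalogramImage(sc, size = 32L, colormap = "gray")
  rowMean <- rowMeans(img@pixels[, , 1])
  expect_equal(which.max(rowMean), jstar)
  img2 <- renderScalogramImage(sc, size = 32L, colormap = "gray")
  expect_identical(img@pixels, img2@pixels)
  # zero coefficients map to the colormap's minimum colour everywhere
  sc@coefficients[] <- 0i
  img0 <- renderScalogramImage(sc, size = 16L, colormap = "jet")
  expect_true(all(img0@pixels[, , 1] == 0))
  expect_true(all(img0@pixels[, , 2] == 0))
  expect_true(all(img0@pixels[, , 3] == 0.5 * 255))
  expect_error(renderScalogramImage(sc, colormap = "plasma"))
})

test_that("scalogram shape follows the 1 x i -> j x i contract", {
  x <- rnorm(300)
  sc <- cwt(x, waveletSpec("morlet"), scales = exp(seq(log(2), log(30),
                                                       length.out = 17)))
  expect_identical(dim(waveletCoefs(sc)), c(17L, 300L))
  expect_identical(sc@sourceLength, 300L)
})

test_that("segmentation counts, inherits metadata, and partitions the signal", {
  spec <- makeSeparableSpec(1, nSubjects = 1, nTrialsPerClass = 1,
                            nChannels = 2, informative = 1L)
  rec <- generateRecording(spec, "negative", 3, 4)
  expect_length(segmentSignal(rec, 1000L), 1L)
  long <- EEGRecording(cbind(samples(rec), samples(rec), samples(rec)),
                       samplingRate(rec), "negative", 3, 4)
  segs <- segmentSignal(long, 1000L, hop = 1000L)
  expect_length(segs, 3L)
  expect_true(all(vapply(segs, function(s)
    as.character(emotionLabels(s)) == "negative", logical(1))))
  expect_true(all(vapply(segs, subjectIds, integer(1)) == 3L))
  rebuilt <- do.call(cbind, lapply(segs, samples))
  expect_identical(rebuilt, samples(long))
  expect_error(segmentSignal(rec, 1000L, hop = 0), "hop")
  expect_error(segmentSignal(rec, 5000L), "exceeds")
})
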