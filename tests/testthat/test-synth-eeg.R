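# Synthetic EEG generator: determinism, band-power structure, layout.

test_that("recordings are bit-reproducible and independent of generation order", {
  spec <- makeSeparableSpec(seed = 42)
  r1 <- generateRecording(spec, "positive", 1, 2)
  r2 <- generateRecording(spec, "positive", 1, 2)
  expect_identical(samples(r1), samples(r2))
  # same recording drawn inside a full dataset equals the direct draw
  ds <- generateDataset(makeSeparableSpec(seed = 42, nSubjects = 1,
                                          nTrialsPerClass = 2))
  labs <- emotionLabels(ds)
  idx <- which(labs == "positive" & trialIds(ds) == 2 & subjectIds(ds) == 1)
  expect_identical(samples(ds[[idx]]), samples(r1))
})

test_that("noise-free single-component configuration yields a pure alpha sinusoid", {
  g <- matrix(0, 3, 4, dimnames = dimnames(defaultClassBandGain()))
  g[, "alpha"] <- 1
  spec <- syntheticDatasetSpec(nSubjects = 1, nTrialsPerClass = 1,
                               montage = simpleMontage(2, subset = 1L),
                               informativeChannels = 1L,
                               classBandGain = g, noiseSd = 0,
                               nComponentsPerBand = 1L, subjectSd = 0,
                               seed = 7)
  rec <- generateRecording(spec, "neutral", 1, 1)
  x <- samples(rec)[1, ]
  fs <- samplingRate(rec)
  # spectral mass inside the alpha band up to finite-window leakage
  expect_gt(bandPowerOracle(x, fs, 8, 13) / bandPowerOracle(x, fs, 0.1, 99),
            0.98)
  # constant amplitude envelope at the configured base amplitude
  expect_equal(max(abs(x)), spec@baseAmplitude, tolerance = 1e-2)
  # non-informative channel carries nothing at noiseSd = 0
  expect_equal(max(abs(samples(rec)[2, ])), 0)
})

test_that("class beta gains translate into ordered beta band power", {
  spec <- makeSeparableSpec(seed = 3)
  fs <- spec@samplingRate
  betaFrac <- function(lab) {
    r <- generateRecording(spec, lab, 1, 1)
    mean(vapply(spec@informativeChannels, function(ch) {
      x <- samples(r)[ch, ]
      bandPowerOracle(x, fs, 13, 30) / bandPowerOracle(x, fs, 0.1, 99)
    }, numeric(1)))
  }
  expect_gt(betaFrac("positive"), betaFrac("neutral"))
  expect_gt(betaFrac("neutral"), betaFrac("negative"))
})

test_that("beta-gain separation holds per informative channel across seeds", {
  # with gain ratio >= 2 and unit noise the beta fraction of the boosted
  # class should dominate on every informative channel
  ok <- 0L; total <- 0L
  for (seed in 1:5) {
    spec <- makeSeparableSpec(seed = seed)
    fs <- spec@samplingRate
    for (ch in spec@informativeChannels) {
      frac <- function(lab) {
        x <- samples(generateRecording(spec, lab, 1, 1))[ch, ]
        bandPowerOracle(x, fs, 13, 30) / bandPowerOracle(x, fs, 0.1, 99)
      }
      total <- total + 1L
      ok <- ok + (frac("positive") > max(frac("neutral"), frac("negative")))
    }
  }
  expect_gte(ok / total, 0.99)
})

test_that("datasets are balanced, sized and label-stable", {
  spec <- makeSeparableSpec(seed = 10, nSubjects = 2, nTrialsPerClass = 3,
                            nChannels = 4, informative = 1:2)
  ds <- generateDataset(spec)
  expect_length(ds, 18L)
  expect_true(all(table(emotionLabels(ds)) == 6L))
  ds2 <- generateDataset(spec)
  expect_identical(emotionLabels(ds), emotionLabels(ds2))
})

test_that("spec validation rejects bad configurations", {
  expect_error(syntheticDatasetSpec(nSubjects = 0), "counts")
  expect_error(syntheticDatasetSpec(noiseSd = -1), "noiseSd")
  expect_error(syntheticDatasetSpec(montage = simpleMontage(4),
                                    informativeChannels = 9L),
               "informativeChannels")
  expect_error(generateRecording(makeSeparableSpec(1), "joy", 1, 1),
               "invalid emotion")
})

test_that("datasets round-trip losslessly through the HDF5 container", {
  spec <- makeSeparableSpec(seed = 5, nSubjects = 2, nTrialsPerClass = 2,
                            nChannels = 3, informative = 1:2)
  ds <- generateDataset(spec)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  writeDataset(ds, path)
  ds2 <- readDataset(path)
  expect_length(ds2, length(ds))
  for (i in seq_along(ds)) {
    expect_equal(samples(ds2[[i]]), samples(ds[[i]]))
    expect_identical(as.character(emotionLabels(ds2[[i]])),
                     as.character(emotionLabels(ds[[i]])))
  }
  expect_identical(samplingRate(ds2[[1]]), samplingRate(ds[[1]]))
})

test_that("a 62-channel montage writes and reads its channel names in order", {
  spec <- syntheticDatasetSpec(nSubjects = 1, nTrialsPerClass = 1,
                               montage = seedMontage(), nSamples = 50L,
                               seed = 2)
  ds <- generateDataset(spec)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  writeDataset(ds, path)
  ds2 <- readDataset(path)
  expect_identical(channelNames(ds2[[1]]), channelNames(seedMontage()))
  expect_length(channelNames(ds2[[1]]), 62L)
})

test_that("writer rejects empty collections, bad formats and MAT output", {
  expect_error(writeDataset(list(), tempfile()), "empty")
  spec <- makeSeparableSpec(1, nSubjects = 1, nTrialsPerClass = 1,
                            nChannels = 2, informative = 1L)
  ds <- generateDataset(spec)
  expect_error(writeDataset(ds, tempfile(), format = "mat"), "MATLAB")
  expect_error(writeDataset(ds, tempfile(), format = "biom"))
})
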