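# Filtering, epoching, baseline correction, artifact rejection.

makeRecording <- function(data, fs = 512, channels = NULL, events = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rec <- new("ContinuousRecording", data = data, fs = fs,
             channelNames = channels)
  if (!is.null(events)) rec@events <- events
  rec
}

test_that("normalized cutoffs reproduce the reported fractions", {
  nc <- normalizedCutoffs(0.5, 70, 512)
  expect_equal(nc$lowReported, 0.0019)
  expect_equal(nc$highReported, 0.273)
  nc2 <- normalizedCutoffs(8, 12, 512)
  expect_equal(nc2$low, 0.03125)
  expect_equal(nc2$high, 0.046875)
  expect_error(normalizedCutoffs(0.5, 300, 512), "Nyquist")
  expect_error(normalizedCutoffs(12, 8, 512), "low")
})

test_that("filters attenuate 50 Hz and DC while preserving the passband", {
  fs <- 512
  t <- (0:(10 * fs - 1)) / fs
  mid <- (2 * fs):(8 * fs)  # interior, away from edge transients

  mains <- makeRecording(sin(2 * pi * 50 * t), fs)
  out <- signalData(applyFilters(mains))[1, ]
  expect_lt(sqrt(mean(out[mid]^2)), 0.05 * sqrt(mean(sin(2 * pi * 50 * t)^2)))

  dc <- makeRecording(rep(100, length(t)), fs)
  expect_lt(abs(mean(signalData(applyFilters(dc))[1, mid])), 1)

  alpha <- makeRecording(sin(2 * pi * 10 * t), fs)
  outA <- signalData(applyFilters(alpha))[1, ]
  expect_equal(sqrt(mean(outA[mid]^2)), sqrt(0.5), tolerance = 0.05)
})

test_that("filtering is linear and zero-phase", {
  fs <- 512
  set.seed(1)
  x <- rnorm(4 * fs); y <- rnorm(4 * fs)
  f <- function(v) signalData(applyFilters(makeRecording(v, fs)))[1, ]
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-5)

  # symmetric transient: latency of the absolute peak is preserved
  t <- (0:(4 * fs - 1)) / fs
  center <- 2
  pulse <- exp(-(t - center)^2 / (2 * 0.05^2)) * cos(2 * pi * 5 * (t - center))
  filtered <- f(pulse)
  expect_lte(abs(which.max(abs(filtered)) - which.max(abs(pulse))), 1)

  bad <- makeRecording(rbind(x, c(NA, x[-1])), fs)
  expect_error(applyFilters(bad), "ch2")
})

test_that("epoch extraction honors the half-open window and event bounds", {
  fs <- 512
  ev <- data.frame(onset_sample = c(5121, 10241),
                   condition = c("warm", "hot"), session = "day1")
  rec <- makeRecording(matrix(seq_len(3 * 25 * fs) + 0, nrow = 3,
                              byrow = TRUE), fs, events = ev)
  ep <- extractEpochs(rec, c(0, 3))
  expect_equal(dim(signalData(ep)), c(2, 3, 1536))
  expect_identical(epochLabels(ep), c("warm", "hot"))
  # first sample of the epoch is the event sample itself
  expect_equal(unname(signalData(ep)[1, 1, 1]), signalData(rec)[1, 5121])
  expect_equal(unname(signalData(ep)[1, 1, 1536]),
               signalData(rec)[1, 5121 + 1535])

  early <- makeRecording(matrix(0, 1, fs * 4), fs,
                         events = data.frame(onset_sample = 1,
                                             condition = "warm",
                                             session = "x"))
  expect_error(extractEpochs(early, c(-3, 0)), "event 1")
})

test_that("baseline correction subtracts the pre-stimulus mean per channel", {
  fs <- 512
  arr <- array(0, c(1, 2, 1536))
  arr[1, 1, ] <- 5; arr[1, 2, ] <- -2
  ep <- makeEpochs(arr, fs)
  baseArr <- array(0, c(1, 2, 1536))
  baseArr[1, 1, ] <- 5; baseArr[1, 2, ] <- -2
  base <- makeEpochs(baseArr, fs, window = c(-3, 0))
  corrected <- baselineCorrect(ep, base)
  expect_true(all(signalData(corrected) == 0))

  # shift invariance: adding a constant to both leaves the result unchanged
  ep2 <- makeEpochs(arr + 7, fs)
  base2 <- makeEpochs(baseArr + 7, fs, window = c(-3, 0))
  expect_equal(signalData(baselineCorrect(ep2, base2)),
               signalData(corrected))

  # arithmetic mean of the ramp 0..1535 is 767.5
  ramp <- array(rep(0:1535, each = 1), c(1, 1, 1536))
  epR <- makeEpochs(ramp, fs)
  baseR <- makeEpochs(ramp, fs, window = c(-3, 0))
  expect_equal(signalData(baselineCorrect(epR, baseR))[1, 1, ],
               (0:1535) - 767.5)

  expect_error(baselineCorrect(ep, makeEpochs(array(0, c(2, 2, 1536)), fs,
                                              window = c(-3, 0))),
               "mismatch")
})

test_that("artifact rejection applies the amplitude and EMG criteria", {
  fs <- 512
  set.seed(2)
  arr <- array(rnorm(5 * 2 * 1536, 0, 10), c(5, 2, 1536))
  arr[abs(arr) > 90] <- 0                      # keep the clean epochs clean
  raw <- arr
  arr[3, 1, 700] <- 150                        # amplitude artifact, epoch 3
  t <- (0:1535) / fs
  raw[5, 2, ] <- raw[5, 2, ] + 2000 * sin(2 * pi * 120 * t)  # 2 mV EMG burst
  ep <- makeEpochs(arr, fs)
  rawEp <- makeEpochs(raw, fs)
  rej <- rejectArtifacts(ep, rawEp)
  expect_identical(rej$log$decision,
                   c("kept", "kept", "rejected-amplitude", "kept",
                     "flagged-emg"))
  expect_equal(nEpochs(rej$epochs), 3)
  expect_identical(parentIds(rej$epochs), c(1L, 2L, 4L))

  # idempotent: rejecting the kept output changes nothing
  keptRaw <- makeEpochs(raw[c(1, 2, 4), , , drop = FALSE], fs)
  again <- rejectArtifacts(rej$epochs, keptRaw)
  expect_true(all(again$log$decision == "kept"))
  expect_identical(signalData(again$epochs), signalData(rej$epochs))
})
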