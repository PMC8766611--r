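# Synthetic-data generator: schedules, EEG sessions, ratings, skin profiles.

test_that("paradigm schedules have the study's trial counts and layout", {
  day1 <- generateParadigm(c("very_hot", "hot", "warm"), 10, seed = 1,
                           sessionId = "day1")
  day2 <- generateParadigm(c("very_cold", "cold"), 10, seed = 2,
                           sessionId = "day2")
  expect_equal(nrow(schedule(day1)), 30)
  expect_equal(nrow(schedule(day2)), 20)
  expect_equal(unname(table(schedule(day1)$condition)[c("hot", "very_hot", "warm")]),
               rep(10L, 3), ignore_attr = TRUE)
  # each trial occupies baseline + stimulation seconds
  expect_equal(diff(schedule(day1)$trial_start_s), rep(40, 29))
  expect_equal(schedule(day1)$onset_s - schedule(day1)$trial_start_s,
               rep(10, 30))

  single <- generateParadigm("warm", 1, seed = 3)
  expect_equal(nrow(schedule(single)), 1)
  expect_equal(schedule(single)$trial_start_s, 0)

  expect_error(generateParadigm(character(0), 10, seed = 1), "condition")
  expect_error(generateParadigm("warm", 0, seed = 1), ">= 1")
})

test_that("paradigm trial order is a seeded shuffle", {
  a <- generateParadigm(c("very_hot", "hot", "warm"), 10, seed = 7)
  b <- generateParadigm(c("very_hot", "hot", "warm"), 10, seed = 7)
  c <- generateParadigm(c("very_hot", "hot", "warm"), 10, seed = 8)
  expect_identical(schedule(a), schedule(b))
  expect_false(identical(schedule(a)$condition, schedule(c)$condition))
})

test_that("null generator produces an all-zero recording of the right shape", {
  p <- generateParadigm("warm", 2, seed = 1, fs = 128, nChannels = 8)
  eff <- quietEffects(peakAmplitudeUv = c(warm = 0))
  s <- generateEEGSession(p, eff, seed = 1, channelNames = smallMontage())
  expect_equal(dim(signalData(s$recording)), c(8, 2 * 40 * 128))
  expect_true(all(signalData(s$recording) == 0))
})

test_that("sessions are reproducible by seed and validate effect channels", {
  p <- generateParadigm("warm", 2, seed = 1, fs = 128, nChannels = 8)
  eff <- quietEffects(alphaAmplitudeUv = 5, pinkAmplitudeUv = 2)
  s1 <- generateEEGSession(p, eff, seed = 9, channelNames = smallMontage())
  s2 <- generateEEGSession(p, eff, seed = 9, channelNames = smallMontage())
  expect_identical(signalData(s1$recording), signalData(s2$recording))
  expect_identical(s1$trials, s2$trials)

  expect_error(
    generateEEGSession(p, eff, seed = 1,
                       channelNames = paste0("X", 1:8)),
    "Cz")
})

test_that("stimulation alpha power tracks discomfort ordering (noise-free)", {
  conds <- thermalConditions()$name
  p <- generateParadigm(conds, 3, seed = 4, nChannels = 8)
  eff <- quietEffects(alphaAmplitudeUv = 20)
  s <- generateEEGSession(p, eff, seed = 4, channelNames = smallMontage())
  ep <- extractEpochs(s$recording, c(0, 3))
  pow <- vapply(conds, function(cn) {
    idx <- which(epochLabels(ep) == cn)
    mean(trialBandPower(initialize(ep,
      data = signalData(ep)[idx, , , drop = FALSE],
      labels = epochLabels(ep)[idx],
      parentIds = parentIds(ep)[idx]), c(8, 12), "C3"))
  }, numeric(1))
  disc <- thermalConditions()$discomfort_mean[match(conds,
                                                   thermalConditions()$name)]
  # monotone agreement: alpha power strictly decreases as discomfort grows
  expect_equal(order(pow, decreasing = TRUE), order(disc))
  expect_equal(cor(pow, disc, method = "kendall"), -1)
})

test_that("ground-truth artifact table matches what rejection flags", {
  p <- generateParadigm(c("warm", "hot"), 5, seed = 5, nChannels = 8)
  eff <- quietEffects(artifactRateAmp = 0.8, artifactRateEmg = 0.8)
  s <- generateEEGSession(p, eff, seed = 5, channelNames = smallMontage())
  expect_gt(nrow(s$artifacts), 0)
  filt <- applyFilters(s$recording)
  ep <- extractEpochs(filt, c(0, 30))
  raw <- extractEpochs(s$recording, c(0, 30))
  rej <- rejectArtifacts(ep, raw)
  flagged <- sort(rej$log$epoch[rej$log$decision != "kept"])
  expect_identical(flagged, sort(unique(s$artifacts$trial)))
  # types line up where a trial has a single artifact
  one <- setdiff(s$artifacts$trial, s$artifacts$trial[duplicated(s$artifacts$trial)])
  for (tr in one) {
    want <- if (s$artifacts$type[s$artifacts$trial == tr] == "emg")
      "flagged-emg" else "rejected-amplitude"
    expect_identical(rej$log$decision[rej$log$epoch == tr], want)
  }
})

test_that("ratings follow the condition's truncated normal", {
  expect_equal(generateRatings("warm", 5, seed = 1, sd = 0), rep(2.6, 5))
  r <- generateRatings("very_hot", 100, seed = 2, mean = 9.5, sd = 1)
  expect_true(all(r <= 9))
  expect_true(all(r >= 0))
  # law of large numbers against the printed very-cold mean 6.6 +/- 0.48
  big <- generateRatings("very_cold", 10000, seed = 3)
  expect_lt(abs(mean(big) - 6.6), 0.02)
  expect_error(generateRatings("warm", 0, seed = 1), ">= 1")
  expect_identical(generateRatings("warm", 4, seed = 4, round = TRUE),
                   round(generateRatings("warm", 4, seed = 4)))
})

test_that("skin profiles relax exponentially at 250 Hz", {
  p <- generateSkinProfile(12, 3, seed = 1)
  expect_equal(ncol(skinData(p)), 750)
  expect_equal(nrow(skinData(p)), 2)
  expect_equal(p@label, "very_cold")

  flat <- generateSkinProfile(12, 1, seed = 1, tauS = 0, noiseSdC = 0)
  expect_true(all(skinData(flat) == 12))

  cool <- generateSkinProfile(12, 3, seed = 1, noiseSdC = 0)
  expect_true(all(diff(skinData(cool)[1, ]) < 0))
  expect_true(all(skinData(cool) <= 28 & skinData(cool) >= 12))
  # closed form: x(t) = obj + (amb - obj) exp(-t/tau)
  t <- (0:749) / 250
  expect_equal(skinData(cool)[1, ], 12 + 16 * exp(-t), tolerance = 1e-12)

  expect_error(generateSkinProfile(12, 0, seed = 1), "positive")
})
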