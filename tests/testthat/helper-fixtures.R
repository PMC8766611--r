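# Shared fixtures: small montages and noise-free effect specifications so
# most tests run on compact synthetic sessions.

smallMontage <- function() c("C3", "C5", "C1", "CP3", "CP5", "Cz", "O1", "Oz")

# Effects with everything switched off except what a test turns back on.
quietEffects <- function(...) {
  args <- list(...)
  base <- list(
    pinkAmplitudeUv = 0, alphaAmplitudeUv = 0,
    artifactRateAmp = 0, artifactRateEmg = 0,
    alphaChannels = smallMontage()
  )
  base[names(args)] <- args
  do.call(defaultEffectSpec, base)
}

# EpochSet wrapped around a trials x channels x samples array.
makeEpochs <- function(arr, fs, labels = rep("a", dim(arr)[1]),
                       window = c(0, dim(arr)[3] / fs),
                       channels = paste0("ch", seq_len(dim(arr)[2]))) {
  new("EpochSet", data = arr, fs = fs, labels = labels,
      parentIds = seq_len(dim(arr)[1]), window = window,
      channelNames = channels)
}

# Crops with per-class channel variance structure: each crop is white noise
# scaled per channel by the class's sd vector.
makeVarianceCrops <- function(sdA, sdB, nPerClass = 20, nSamp = 200,
                              fs = 100, seed = 1) {
  nCh <- length(sdA)
  set.seed(seed)
  arr <- array(0, c(2 * nPerClass, nCh, nSamp))
  for (i in seq_len(nPerClass)) {
    for (c in seq_len(nCh)) {
      arr[i, c, ] <- rnorm(nSamp, 0, sdA[c])
      arr[nPerClass + i, c, ] <- rnorm(nSamp, 0, sdB[c])
    }
  }
  makeEpochs(arr, fs, labels = rep(c("A", "B"), each = nPerClass))
}

# Exactly-diagonal two-channel crops: channel signals are scaled copies of
# orthogonal zero-mean sequences, so sample covariances are exact.
makeExactCrops <- function() {
  u <- c(1, -1, 1, -1); v <- c(1, 1, -1, -1)
  arr <- array(0, c(4, 2, 4))
  arr[1, 1, ] <- 2 * u; arr[1, 2, ] <- v     # class A: var ratio 4:1
  arr[2, 1, ] <- 2 * v; arr[2, 2, ] <- u
  arr[3, 1, ] <- u; arr[3, 2, ] <- 2 * v     # class B: var ratio 1:4
  arr[4, 1, ] <- v; arr[4, 2, ] <- 2 * u
  makeEpochs(arr, fs = 4, labels = c("A", "A", "B", "B"))
}
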