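# Decoding chain: sliding-window crop augmentation, common spatial patterns,
# 2-component PCA, LDA, stratified 80/20 split with 10-fold cross-validation,
# balanced accuracy.

#' Sliding-window crop augmentation
#'
#' Slices each trial into fixed-length crops at offsets 0, stride,
#' 2*stride, ... while `offset + window` fits inside the trial. The default
#' window = stride = 3 s is non-overlapping and turns each 30 s stimulation
#' trial into 10 crops (50 trials into 500). Parent-trial indices are
#' recorded so splits can be kept leakage-free.
#'
#' @param epochs an [EpochSet] (e.g. the `[0, 30)` s stimulation epochs).
#' @param windowS crop length in seconds (default 3).
#' @param strideS shift between crop starts in seconds (default 3).
#' @return an [EpochSet] of crops whose `parentIds` index the input trials.
#' @export
cropAugment <- function(epochs, windowS = 3, strideS = 3) {
  stopifnot(is(epochs, "EpochSet"))
  fs <- epochs@fs
  d <- dim(epochs@data)
  winSamp <- round(windowS * fs)
  strideSamp <- max(1L, round(strideS * fs))
  if (winSamp > d[3]) stop("crop window exceeds the trial length")
  offsets <- seq(0L, d[3] - winSamp, by = strideSamp)
  nCrops <- d[1] * length(offsets)
  arr <- array(0, dim = c(nCrops, d[2], winSamp),
               dimnames = list(NULL, epochs@channelNames, NULL))
  labels <- character(nCrops); parents <- integer(nCrops)
  k <- 0L
  for (tr in seq_len(d[1])) for (off in offsets) {
    k <- k + 1L
    arr[k, , ] <- epochs@data[tr, , (off + 1L):(off + winSamp)]
    labels[k] <- epochs@labels[tr]
    parents[k] <- epochs@parentIds[tr]
  }
  new("EpochSet", data = arr, fs = fs, labels = labels, parentIds = parents,
      window = c(0, winSamp / fs), channelNames = epochs@channelNames)
}

# Trace-normalized covariance of a channels x samples crop.
.cropCov <- function(x, shrinkage) {
  xc <- x - rowMeans(x)
  C <- tcrossprod(xc) / (ncol(x) - 1)
  C <- C / sum(diag(C))
  if (shrinkage > 0) {
    p <- nrow(C)
    C <- (1 - shrinkage) * C + shrinkage * diag(p) / p
  }
  C
}

#' Fit common spatial patterns
#'
#' Solves the simultaneous diagonalization of the two class-average
#' (trace-normalized, shrinkage-regularized) covariance matrices via
#' whitening of the composite covariance: the returned filters `W` satisfy
#' `W Ca W' = diag(lambda)` and `W Cb W' = diag(1 - lambda)`. The `nPairs`
#' filters with the largest and smallest eigenvalues (the most
#' discriminative directions for each class) are retained, ordered
#' extremes-first.
#'
#' @param crops an [EpochSet] of crops.
#' @param labels binary class labels (default the crop labels).
#' @param nPairs number of filter pairs to keep (default 2).
#' @param shrinkage trace-scaled covariance shrinkage (default 1e-4).
#' @return a [CSPModel].
#' @export
fitCSP <- function(crops, labels = epochLabels(crops), nPairs = 2,
                   shrinkage = 1e-4) {
  stopifnot(is(crops, "EpochSet"))
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("CSP requires exactly two classes")
  d <- dim(crops@data)
  if (min(table(labels)) < 2) stop("need at least 2 crops per class")
  if (2 * nPairs > d[2]) stop("nPairs too large for the channel count")

  covs <- lapply(seq_len(d[1]), function(i)
    .cropCov(crops@data[i, , ], shrinkage))
  .cspFromCovs(covs, labels, classes, nPairs, shrinkage, crops@channelNames)
}

# Core CSP solve on precomputed per-crop covariances.
.cspFromCovs <- function(covs, labels, classes, nPairs, shrinkage,
                         channelNames) {
  p <- nrow(covs[[1]])
  classCov <- function(cl) {
    idx <- which(labels == cl)
    Reduce(`+`, covs[idx]) / length(idx)
  }
  Ca <- classCov(classes[1])
  Cb <- classCov(classes[2])

  R <- Ca + Cb
  er <- eigen(R, symmetric = TRUE)
  tol <- max(er$values) * 1e-10
  if (min(er$values) < tol)
    stop("rank-deficient composite covariance; increase `shrinkage`")
  Wwhite <- diag(1 / sqrt(er$values)) %*% t(er$vectors)
  S <- Wwhite %*% Ca %*% t(Wwhite)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)           # eigenvalues descending
  Vfull <- t(es$vectors) %*% Wwhite          # rows = filters
  lambda <- pmin(pmax(es$values, 0), 1)

  n <- nrow(Vfull)
  ord <- as.vector(rbind(seq_len(nPairs), n + 1L - seq_len(nPairs)))
  patternsFull <- t(solve(Vfull))            # rows = forward-model patterns
  new("CSPModel",
      filters = Vfull[ord, , drop = FALSE],
      patterns = patternsFull[ord, , drop = FALSE],
      eigenvalues = lambda[ord],
      classPair = classes,
      shrinkage = shrinkage,
      channelNames = channelNames)
}

#' CSP log-variance features
#'
#' Projects each crop through the fitted spatial filters and returns the
#' log variance of each filtered signal (the standard CSP readout). A
#' variance floor guards against degenerate all-constant projections.
#'
#' @param model a [CSPModel].
#' @param crops an [EpochSet] with the model's channels.
#' @param varFloor lower bound applied to projected variances before the
#'   log (default 1e-12); applications are reported with a message.
#' @return numeric matrix, crops x filters.
#' @export
cspFeatures <- function(model, crops, varFloor = 1e-12) {
  stopifnot(is(model, "CSPModel"), is(crops, "EpochSet"))
  if (ncol(model@filters) != dim(crops@data)[2])
    stop("channel count does not match the CSP model")
  n <- dim(crops@data)[1]
  feats <- matrix(0, n, nrow(model@filters))
  floored <- 0L
  for (i in seq_len(n)) {
    y <- model@filters %*% crops@data[i, , ]
    v <- apply(y, 1, stats::var)
    if (any(v < varFloor)) floored <- floored + 1L
    feats[i, ] <- log(pmax(v, varFloor))
  }
  if (floored > 0)
    message("cspFeatures: variance floor applied in ", floored, " crop(s)")
  colnames(feats) <- paste0("csp", seq_len(ncol(feats)))
  feats
}

#' Principal component reduction of feature vectors
#'
#' Projects mean-centered features onto the top-k principal axes
#' (orthonormal, deterministic under the sign convention that each axis's
#' largest-magnitude loading is positive).
#'
#' @param features numeric matrix, samples x features.
#' @param k number of components (default 2).
#' @return list with `scores` (samples x k), `rotation`, `center`,
#'   `explained` (per-component proportion of variance), and `sdev`.
#' @export
reducePCA <- function(features, k = 2) {
  features <- as.matrix(features)
  if (k > ncol(features)) stop("k exceeds the feature dimension")
  if (nrow(features) < k + 1) stop("need at least k + 1 samples")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                    # fixed sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- scale(features, center = pc$center, scale = FALSE) %*% rot
  list(scores = scores, rotation = rot, center = pc$center,
       explained = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' Project new features onto a fitted PCA basis
#'
#' @param fit result of [reducePCA()].
#' @param features samples x features matrix.
#' @return samples x k score matrix.
#' @export
projectPCA <- function(fit, features) {
  scale(as.matrix(features), center = fit$center, scale = FALSE) %*% fit$rotation
}

#' Balanced accuracy from a confusion matrix
#'
#' For a 2x2 matrix (rows = truth), `(Sensitivity + Specificity) / 2` with
#' Sensitivity = TP/(TP+FN) and Specificity = TN/(TN+FP); for a k-class
#' matrix, the mean per-class recall. Symmetric under swapping class roles.
#'
#' @param confusion square count matrix, rows = true classes.
#' @return value in `[0, 1]`.
#' @examples
#' bacc(matrix(c(8, 4, 2, 6), 2))  # 0.7
#' @export
bacc <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion)) stop("confusion matrix must be square")
  totals <- rowSums(confusion)
  if (any(totals == 0)) stop("every class needs at least one instance")
  mean(diag(confusion) / totals)
}

# Stratified assignment of units to k folds (units shuffled within class).
.makeFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    if (length(idx) < k)
      stop("a class would be absent from some fold; use fewer folds")
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test masks over units; returns logical test mask.
.testMask <- function(labels, testFrac) {
  test <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nTest <- max(1L, round(testFrac * length(idx)))
    test[sample(idx, nTest)] <- TRUE
  }
  test
}

.baccFromPred <- function(truth, pred, classes) {
  conf <- table(factor(truth, classes), factor(pred, classes))
  bacc(unclass(conf))
}

#' Train and evaluate an LDA classifier on feature vectors
#'
#' Performs the stratified 80/20 split, runs stratified k-fold
#' cross-validation of an LDA classifier on the 80% training portion, fits
#' the final model on all training data, and reports per-fold validation
#' balanced accuracies plus the held-out test balanced accuracy and
#' confusion matrix. In group-aware mode (the default whenever `groups` is
#' supplied) all crops of one parent trial stay on the same side of every
#' split, so augmented crops cannot leak between train and test.
#'
#' @param features samples x features matrix.
#' @param labels binary labels.
#' @param seed integer seed for the split and folds.
#' @param groups optional parent-trial id per sample.
#' @param splitFraction training fraction (default 0.8).
#' @param folds cross-validation folds (default 10).
#' @return a [ClassifierReport].
#' @export
trainEval <- function(features, labels, seed, groups = NULL,
                      splitFraction = 0.8, folds = 10) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("trainEval expects binary labels")
  mode <- if (is.null(groups)) "crop" else "group"
  if (is.null(groups)) groups <- seq_along(labels)

  .withSeed(seed, {
    ug <- unique(groups)
    gLab <- labels[match(ug, groups)]
    testG <- .testMask(gLab, 1 - splitFraction)
    isTest <- groups %in% ug[testG]

    trG <- ug[!testG]; trGLab <- gLab[!testG]
    foldG <- .makeFolds(trGLab, folds)
    scores <- numeric(folds)
    for (f in seq_len(folds)) {
      valG <- trG[foldG == f]
      trainIdx <- which(!isTest & !(groups %in% valG))
      valIdx <- which(!isTest & (groups %in% valG))
      fit <- MASS::lda(features[trainIdx, , drop = FALSE],
                       grouping = factor(labels[trainIdx], classes))
      pred <- stats::predict(fit, features[valIdx, , drop = FALSE])$class
      scores[f] <- .baccFromPred(labels[valIdx], as.character(pred), classes)
    }
    fit <- MASS::lda(features[!isTest, , drop = FALSE],
                     grouping = factor(labels[!isTest], classes))
    pred <- stats::predict(fit, features[isTest, , drop = FALSE])$class
    conf <- unclass(table(factor(labels[isTest], classes),
                          factor(as.character(pred), classes)))
    new("ClassifierReport", confusion = conf, foldScores = scores,
        testScore = bacc(conf), seed = as.integer(seed),
        classPair = classes, mode = mode, testIndices = which(isTest))
  })
}

#' Full CSP -> PCA -> LDA decoding of a binary pair
#'
#' The end-to-end decoding chain on augmented crops: stratified 80/20
#' split (group-aware by parent trial by default), then, inside each of the
#' k validation folds, CSP and PCA are fitted on the fold's training crops
#' only (avoiding optimistic bias) and an LDA is evaluated on the held-out
#' fold; finally CSP + PCA + LDA are refitted on the whole training portion
#' and evaluated on the 20% test crops.
#'
#' @param crops an [EpochSet] of crops (see [cropAugment()]).
#' @param seed integer seed.
#' @param nPairs CSP filter pairs (default 2).
#' @param pcaComponents PCA dimensionality (default 2).
#' @param shrinkage CSP covariance shrinkage (default 1e-4).
#' @param splitFraction training fraction (default 0.8).
#' @param folds cross-validation folds (default 10).
#' @param groupAware keep all crops of a parent trial on one side of every
#'   split (default TRUE; FALSE reproduces naive per-crop stratification,
#'   which leaks parent-trial information into validation and test).
#' @param cspPerFold fit CSP/PCA inside each fold (default TRUE) or once on
#'   the whole training portion.
#' @return a [ClassifierReport].
#' @export
decodePair <- function(crops, seed, nPairs = 2, pcaComponents = 2,
                       shrinkage = 1e-4, splitFraction = 0.8, folds = 10,
                       groupAware = TRUE, cspPerFold = TRUE) {
  stopifnot(is(crops, "EpochSet"))
  labels <- crops@labels
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("decodePair expects exactly two classes")
  groups <- if (groupAware) crops@parentIds else seq_along(labels)

  subsetCrops <- function(idx)
    initialize(crops, data = crops@data[idx, , , drop = FALSE],
               labels = labels[idx], parentIds = crops@parentIds[idx])
  covs <- lapply(seq_len(dim(crops@data)[1]), function(i)
    .cropCov(crops@data[i, , ], shrinkage))
  chain <- function(trainIdx, evalIdx) {
    tr <- subsetCrops(trainIdx)
    model <- .cspFromCovs(covs[trainIdx], labels[trainIdx], classes, nPairs,
                          shrinkage, crops@channelNames)
    ftr <- cspFeatures(model, tr)
    pca <- reducePCA(ftr, k = pcaComponents)
    fit <- MASS::lda(pca$scores, grouping = factor(labels[trainIdx], classes))
    fev <- projectPCA(pca, cspFeatures(model, subsetCrops(evalIdx)))
    as.character(stats::predict(fit, fev)$class)
  }

  .withSeed(seed, {
    ug <- unique(groups)
    gLab <- labels[match(ug, groups)]
    testG <- .testMask(gLab, 1 - splitFraction)
    isTest <- groups %in% ug[testG]

    trG <- ug[!testG]; trGLab <- gLab[!testG]
    minG <- min(table(trGLab))
    if (folds > minG) {
      message("decodePair: only ", minG, " training trials in the smallest ",
              "class; using ", minG, "-fold cross-validation")
      folds <- minG
    }
    foldG <- .makeFolds(trGLab, folds)
    scores <- numeric(folds)
    trainAll <- which(!isTest)
    for (f in seq_len(folds)) {
      valG <- trG[foldG == f]
      valIdx <- which(!isTest & (groups %in% valG))
      trIdx <- setdiff(trainAll, valIdx)
      pred <- if (cspPerFold) chain(trIdx, valIdx) else NULL
      if (is.null(pred)) {
        # single CSP/PCA on the whole training portion, LDA per fold
        model <- .cspFromCovs(covs[trainAll], labels[trainAll], classes,
                              nPairs, shrinkage, crops@channelNames)
        ftr <- cspFeatures(model, subsetCrops(trainAll))
        pca <- reducePCA(ftr, k = pcaComponents)
        sc <- pca$scores
        rel <- match(trIdx, trainAll); relVal <- match(valIdx, trainAll)
        fit <- MASS::lda(sc[rel, , drop = FALSE],
                         grouping = factor(labels[trIdx], classes))
        pred <- as.character(
          stats::predict(fit, sc[relVal, , drop = FALSE])$class)
      }
      scores[f] <- .baccFromPred(labels[valIdx], pred, classes)
    }
    testIdx <- which(isTest)
    pred <- chain(trainAll, testIdx)
    conf <- unclass(table(factor(labels[testIdx], classes),
                          factor(pred, classes)))
    new("ClassifierReport", confusion = conf, foldScores = scores,
        testScore = bacc(conf), seed = as.integer(seed),
        classPair = classes,
        mode = if (groupAware) "group" else "crop",
        testIndices = testIdx)
  })
}
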