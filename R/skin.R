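# Robot-skin temperature-level classification: time-domain features per
# sensor channel, sequential forward feature selection, five classifiers,
# and the five-bin temperature classes (see conditions.R for the bins and
# the withdrawal policy).

.featureNames <- c("mav", "rms", "var", "ssi", "ssc", "wl", "wa")

# Seven time-domain features of one sensor trace.
.channelFeatures <- function(x, sscThreshold = 0.01, waThreshold = 0.01) {
  n <- length(x)
  dx <- diff(x)
  ssc <- if (n < 3) 0L else
    sum((x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n]) > sscThreshold)
  c(mav = mean(abs(x)),
    rms = sqrt(mean(x^2)),
    var = mean((x - mean(x))^2),
    ssi = sum(x^2),
    ssc = as.numeric(ssc),
    wl = sum(abs(dx)),
    wa = as.numeric(sum(abs(dx) > waThreshold)))
}

#' Time-domain features of a skin-contact window
#'
#' Computes, per sensor channel, the seven time-domain features used for
#' temperature-level classification: mean absolute value
#' `MAV = mean(|x_i|)`, root mean square, variance
#' `VAR = mean((x_i - mean(x))^2)` (divide-by-N), simple square integral
#' `SSI = sum(x_i^2)`, slope sign changes (threshold-gated), waveform
#' length `WL = sum(|x_{i+1} - x_i|)`, and Willison amplitude (count of
#' successive differences exceeding a threshold). Thresholds default to
#' 0.01 degrees C, the sensor-noise scale.
#'
#' @param x a [SkinProfile], a channels x samples matrix, or a numeric
#'   vector (treated as one channel).
#' @param sscThreshold,waThreshold thresholds for SSC and WA.
#' @return named numeric vector; with multiple channels the per-channel
#'   features are concatenated as `s<channel>_<feature>`.
#' @examples
#' extractFeatures(c(1, 2, 3))[c("s1_mav", "s1_var", "s1_wl")]  # 2, 2/3, 2
#' @export
extractFeatures <- function(x, sscThreshold = 0.01, waThreshold = 0.01) {
  if (is(x, "SkinProfile")) x <- x@data
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) < 1) stop("empty window")
  out <- numeric(0)
  for (ch in seq_len(nrow(x))) {
    f <- .channelFeatures(x[ch, ], sscThreshold, waThreshold)
    names(f) <- paste0("s", ch, "_", names(f))
    out <- c(out, f)
  }
  out
}

#' Feature table for a set of skin profiles
#'
#' Applies [extractFeatures()] to the first `windowS` seconds of each
#' profile (3 s of contact by default) and collects the results with the
#' true labels.
#'
#' @param profiles list of [SkinProfile] objects.
#' @param windowS analysis window in seconds (default 3).
#' @param ... passed to [extractFeatures()].
#' @return data.frame of features plus a `label` column.
#' @export
skinFeatureTable <- function(profiles, windowS = 3, ...) {
  rows <- lapply(profiles, function(p) {
    stopifnot(is(p, "SkinProfile"))
    nW <- min(round(windowS * p@fs), ncol(p@data))
    extractFeatures(p@data[, seq_len(nW), drop = FALSE], ...)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- vapply(profiles, function(p) p@label, character(1))
  out
}

# Mean per-class recall of an LDA under stratified CV; the selection score.
.cvScore <- function(X, y, folds = 5) {
  y <- factor(y)
  fold <- .makeFolds(as.character(y), folds)
  recalls <- matrix(NA_real_, folds, nlevels(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- MASS::lda(X[tr, , drop = FALSE], grouping = y[tr])
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])$class
    conf <- table(y[!tr], pred)
    recalls[f, ] <- diag(conf) / rowSums(conf)
  }
  mean(recalls, na.rm = TRUE)
}

#' Sequential forward feature selection
#'
#' Greedy forward selection maximizing the cross-validated mean per-class
#' recall of an LDA classifier: starting from the empty set, the feature
#' whose addition most improves the score is added until `k` features are
#' chosen. Deterministic given the seed (which fixes the CV folds).
#'
#' @param features data.frame or matrix of candidate features.
#' @param labels class labels (>= 2 classes).
#' @param k number of features to select.
#' @param seed integer seed.
#' @param folds CV folds used for scoring (default 5).
#' @return list with `selected` (feature names in selection order) and
#'   `scores` (CV score after each addition).
#' @export
selectFeatures <- function(features, labels, k, seed, folds = 5) {
  X <- as.matrix(features)
  if (k > ncol(X)) stop("k exceeds the number of features")
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  # constant columns carry no information and break LDA scoring
  usable <- colnames(X)[apply(X, 2, stats::sd) > 0]
  .withSeed(seed, {
    chosen <- character(0); scores <- numeric(0)
    repeat {
      if (length(chosen) == k) break
      cand <- setdiff(usable, chosen)
      if (!length(cand)) break
      sc <- vapply(cand, function(f)
        .cvScore(X[, c(chosen, f), drop = FALSE], labels, folds), numeric(1))
      best <- cand[which.max(sc)]
      chosen <- c(chosen, best)
      scores <- c(scores, max(sc))
    }
    list(selected = chosen, scores = scores)
  })
}

# Gaussian quadratic discriminant analysis with per-class covariance
# shrinkage toward a scaled identity (QLDA).
.qdaShrinkFit <- function(X, y, shrinkage = 1e-3) {
  y <- factor(y)
  p <- ncol(X)
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xi)
    C <- stats::cov(Xi)
    C <- (1 - shrinkage) * C + shrinkage * (sum(diag(C)) / p + 1e-12) * diag(p)
    list(mu = mu, Cinv = solve(C), logdet = determinant(C)$modulus,
         logprior = log(nrow(Xi) / nrow(X)))
  })
  structure(list(classes = classes, fits = fits), class = "qdaShrink")
}

.qdaShrinkPredict <- function(model, X) {
  X <- as.matrix(X)
  d <- vapply(model$fits, function(f) {
    xc <- sweep(X, 2, f$mu)
    -0.5 * rowSums((xc %*% f$Cinv) * xc) - 0.5 * as.numeric(f$logdet) +
      f$logprior
  }, numeric(nrow(X)))
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(X))
  model$classes[max.col(d)]
}

#' Train and evaluate a temperature-level classifier
#'
#' Builds the per-channel time-domain feature table from labelled skin
#' profiles (3 s of contact), performs a stratified 80/20 split, trains one
#' of five classifiers (KNN, SVM, NB, LDA, or QLDA - quadratic discriminant
#' analysis with per-class covariance shrinkage), and reports the 5-class
#' confusion matrix and the mean per-class recall on the test portion.
#'
#' @param profiles list of labelled [SkinProfile]s (>= 5 per class
#'   recommended) or a feature data.frame with a `label` column.
#' @param classifier one of `"QLDA"`, `"KNN"`, `"SVM"`, `"NB"`, `"LDA"`.
#' @param seed integer seed for the split.
#' @param features optional character vector restricting the feature
#'   columns (e.g. the output of [selectFeatures()]).
#' @param windowS contact window in seconds (default 3).
#' @param splitFraction training fraction (default 0.8).
#' @param knnK neighbors for KNN (default 5).
#' @param shrinkage QLDA covariance shrinkage (default 1e-3).
#' @return list with `model`, `classifier`, `features`, and `report` (a
#'   [ClassifierReport]; `balancedAccuracy()` is the mean per-class
#'   recall).
#' @export
trainTempClassifier <- function(profiles,
                                classifier = c("QLDA", "KNN", "SVM", "NB", "LDA"),
                                seed, features = NULL, windowS = 3,
                                splitFraction = 0.8, knnK = 5,
                                shrinkage = 1e-3) {
  if (is.character(classifier) && length(classifier) == 1 &&
      !classifier %in% c("QLDA", "KNN", "SVM", "NB", "LDA"))
    stop("unknown classifier '", classifier,
         "'; options are KNN, SVM, NB, LDA, QLDA")
  classifier <- match.arg(classifier)
  tab <- if (is.data.frame(profiles)) profiles else
    skinFeatureTable(profiles, windowS)
  y <- factor(tab$label)
  X <- as.matrix(tab[, setdiff(names(tab), "label"), drop = FALSE])
  if (!is.null(features)) X <- X[, features, drop = FALSE]

  .withSeed(seed, {
    isTest <- .testMask(as.character(y), 1 - splitFraction)
    Xtr <- X[!isTest, , drop = FALSE]; ytr <- droplevels(y[!isTest])
    Xte <- X[isTest, , drop = FALSE]; yte <- y[isTest]
    model <- switch(classifier,
      QLDA = .qdaShrinkFit(Xtr, ytr, shrinkage),
      LDA = MASS::lda(Xtr, grouping = ytr),
      KNN = list(X = Xtr, y = ytr, k = knnK),
      SVM = e1071::svm(Xtr, ytr),
      NB = e1071::naiveBayes(Xtr, ytr))
    pred <- switch(classifier,
      QLDA = .qdaShrinkPredict(model, Xte),
      LDA = as.character(stats::predict(model, Xte)$class),
      KNN = as.character(class::knn(model$X, Xte, model$y, k = model$k)),
      SVM = as.character(stats::predict(model, Xte)),
      NB = as.character(stats::predict(model, Xte)))
    classes <- levels(y)
    conf <- unclass(table(factor(as.character(yte), classes),
                          factor(pred, classes)))
    report <- new("ClassifierReport", confusion = conf,
                  foldScores = numeric(0), testScore = bacc(conf),
                  seed = as.integer(seed), classPair = classes,
                  mode = "profile", testIndices = which(isTest))
    list(model = model, classifier = classifier,
         features = colnames(X), report = report)
  })
}

#' Predict temperature classes for new skin profiles
#'
#' Applies a classifier trained by [trainTempClassifier()] to new contact
#' profiles (or a feature table).
#'
#' @param fit result of [trainTempClassifier()].
#' @param profiles list of [SkinProfile]s or a feature data.frame.
#' @param windowS contact window in seconds (default 3).
#' @return character vector of predicted condition labels.
#' @export
predictTemperature <- function(fit, profiles, windowS = 3) {
  tab <- if (is.data.frame(profiles)) profiles else
    skinFeatureTable(profiles, windowS)
  X <- as.matrix(tab[, setdiff(names(tab), "label"), drop = FALSE])
  X <- X[, fit$features, drop = FALSE]
  switch(fit$classifier,
    QLDA = .qdaShrinkPredict(fit$model, X),
    LDA = as.character(stats::predict(fit$model, X)$class),
    KNN = as.character(class::knn(fit$model$X, X, fit$model$y,
                                  k = fit$model$k)),
    SVM = as.character(stats::predict(fit$model, X)),
    NB = as.character(stats::predict(fit$model, X)))
}

#' Generate a labelled robot-skin dataset
#'
#' Draws `nPerClass` contact profiles per temperature class, with object
#' temperatures sampled uniformly inside each class's printed bin (or
#' drifted toward ambient by `driftC` degrees, emulating objects losing
#' their temperature over a long recording session).
#'
#' @param nPerClass profiles per class.
#' @param seed integer seed.
#' @param durationS contact duration in seconds (default 3).
#' @param driftC shift of each object temperature toward ambient, in
#'   degrees Celsius (default 0).
#' @param ... passed to [generateSkinProfile()].
#' @return list of labelled [SkinProfile]s.
#' @export
generateSkinDataset <- function(nPerClass, seed, durationS = 3, driftC = 0,
                                ...) {
  tab <- thermalConditions()
  profiles <- list()
  k <- 0L
  for (i in seq_len(nrow(tab))) for (j in seq_len(nPerClass)) {
    k <- k + 1L
    s <- .childSeed(seed, k)
    temp <- .withSeed(s, stats::runif(1, tab$temp_low_c[i], tab$temp_high_c[i]))
    if (driftC != 0) {
      ambient <- list(...)$ambientC
      if (is.null(ambient)) ambient <- 28
      temp <- temp + sign(ambient - temp) * min(driftC, abs(ambient - temp))
    }
    p <- generateSkinProfile(temp, durationS, seed = s + 1L, ...)
    p@label <- tab$name[i]   # truth is the sampled bin, even under drift
    profiles[[k]] <- p
  }
  profiles
}
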