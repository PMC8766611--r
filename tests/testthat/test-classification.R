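# Crop augmentation, CSP, PCA, LDA evaluation, balanced accuracy.

test_that("crop augmentation yields the study's crop counts", {
  fs <- 64   # counts depend only on samples, keep the fixture light
  arr <- array(rnorm(1 * 2 * 30 * fs), c(1, 2, 30 * fs))
  one <- makeEpochs(arr, fs)
  expect_equal(nEpochs(cropAugment(one, 3, 3)), 10)

  arr50 <- array(rnorm(50 * 2 * 30 * fs), c(50, 2, 30 * fs))
  fifty <- makeEpochs(arr50, fs)
  crops <- cropAugment(fifty, 3, 3)
  expect_equal(nEpochs(crops), 500)
  expect_equal(unname(table(parentIds(crops))), rep(10L, 50),
               ignore_attr = TRUE)

  # identity crop and reconstruction of the parent from its crops
  whole <- cropAugment(one, 30, 30)
  expect_equal(nEpochs(whole), 1)
  expect_equal(signalData(whole)[1, , ], arr[1, , ], ignore_attr = TRUE)
  pieces <- cropAugment(one, 3, 3)
  rebuilt <- do.call(cbind, lapply(1:10, function(k) signalData(pieces)[k, , ]))
  expect_equal(rebuilt, arr[1, , ], ignore_attr = TRUE)

  expect_error(cropAugment(one, 31, 3), "exceeds")
})

test_that("CSP solves the two-class covariance eigenproblem", {
  crops <- makeExactCrops()
  m <- fitCSP(crops, nPairs = 1, shrinkage = 0)
  # class A covariance diag(4,1), class B diag(1,4): first eigenvalue 4/5
  expect_equal(cspEigenvalues(m), c(0.8, 0.2), tolerance = 1e-12)
  f1 <- spatialFilters(m)[1, ]
  expect_equal(abs(f1[1]) / sqrt(sum(f1^2)), 1, tolerance = 1e-10)

  # identical class covariances: no discriminative direction
  same <- makeEpochs(signalData(crops)[c(1, 1, 1, 1), , , drop = FALSE],
                     fs = 4, labels = c("A", "A", "B", "B"))
  expect_equal(cspEigenvalues(fitCSP(same, nPairs = 1, shrinkage = 0)),
               c(0.5, 0.5), tolerance = 1e-12)

  # defining property: projected class covariances are diagonal
  set.seed(7)
  rand <- makeVarianceCrops(c(3, 1, 1, 2), c(1, 2, 3, 1), nPerClass = 15)
  mr <- fitCSP(rand, nPairs = 2)
  W <- spatialFilters(mr)
  for (cl in c("A", "B")) {
    idx <- which(epochLabels(rand) == cl)
    Cs <- lapply(idx, function(i) {
      C <- stats::cov(t(signalData(rand)[i, , ]))
      C <- C / sum(diag(C))
      (1 - 1e-4) * C + 1e-4 * diag(4) / 4
    })
    Cbar <- Reduce(`+`, Cs) / length(Cs)
    P <- W %*% Cbar %*% t(W)
    expect_lt(max(abs(P - diag(diag(P)))), 1e-8)
  }

  # rank deficiency without shrinkage is reported with advice
  dup <- makeEpochs(signalData(crops)[, c(1, 1), , drop = FALSE], fs = 4,
                    labels = epochLabels(crops))
  expect_error(fitCSP(dup, nPairs = 1, shrinkage = 0), "shrinkage")
})

test_that("CSP agrees with a dense generalized-eigenproblem oracle", {
  principalAngle <- function(A, B) {   # max principal angle between spans
    qa <- qr.Q(qr(t(A))); qb <- qr.Q(qr(t(B)))
    s <- svd(crossprod(qa, qb))$d
    acos(min(pmin(pmax(s, -1), 1)))
  }
  set.seed(8)
  for (nCh in c(4, 6, 8)) {
    sdA <- runif(nCh, 0.5, 3); sdB <- runif(nCh, 0.5, 3)
    crops <- makeVarianceCrops(sdA, sdB, nPerClass = 12, nSamp = 300,
                               seed = nCh)
    shr <- 1e-4
    m <- fitCSP(crops, nPairs = 1, shrinkage = shr)
    # independent route: average covariances two-pass, solve the dense
    # non-symmetric generalized eigenproblem Ca v = lambda (Ca + Cb) v
    classCov <- function(cl) {
      idx <- which(epochLabels(crops) == cl)
      Cs <- lapply(idx, function(i) {
        C <- stats::cov(t(signalData(crops)[i, , ]))
        C <- C / sum(diag(C))
        (1 - shr) * C + shr * diag(nCh) / nCh
      })
      Reduce(`+`, Cs) / length(Cs)
    }
    Ca <- classCov("A"); Cb <- classCov("B")
    eg <- eigen(solve(Ca + Cb) %*% Ca)
    ord <- order(Re(eg$values), decreasing = TRUE)
    oracle <- t(Re(eg$vectors[, c(ord[1], ord[nCh])]))
    expect_lt(principalAngle(spatialFilters(m), oracle), 1e-6)
  }
})

test_that("CSP log-variance features behave as variances", {
  set.seed(9)
  crops <- makeVarianceCrops(c(2, 1, 1), c(1, 1, 2), nPerClass = 10)
  m <- fitCSP(crops, nPairs = 1)
  f <- cspFeatures(m, crops)
  expect_equal(ncol(f), 2)  # 2 x nPairs

  scaled <- makeEpochs(3 * signalData(crops), fs = 100,
                       labels = epochLabels(crops))
  fs3 <- cspFeatures(m, scaled)
  expect_equal(fs3, f + 2 * log(3), tolerance = 1e-10)

  # consistent channel relabeling leaves features unchanged
  perm <- c(3, 1, 2)
  cropsPerm <- makeEpochs(signalData(crops)[, perm, , drop = FALSE],
                          fs = 100, labels = epochLabels(crops))
  mPerm <- new("CSPModel", filters = spatialFilters(m)[, perm],
               patterns = m@patterns[, perm],
               eigenvalues = cspEigenvalues(m), classPair = m@classPair,
               shrinkage = m@shrinkage,
               channelNames = channelLabels(m)[perm])
  expect_equal(cspFeatures(mPerm, cropsPerm), f)

  expect_error(cspFeatures(m, makeEpochs(array(0, c(1, 5, 10)), 10)),
               "channel count")
})

test_that("PCA reduction is orthonormal, deterministic and complete at k = d", {
  set.seed(10)
  X <- matrix(rnorm(400), ncol = 4) %*% diag(c(3, 2, 1, 0.5))
  full <- reducePCA(X, k = 4)
  expect_equal(sum(full$explained), 1)
  expect_equal(crossprod(full$rotation), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(apply(full$scores, 2, var)), sum(apply(X, 2, var)),
               tolerance = 1e-10)

  iso <- matrix(rnorm(4000), ncol = 2)
  expect_equal(reducePCA(iso, 2)$explained, c(0.5, 0.5), tolerance = 0.05)

  rank1 <- outer(rnorm(50), c(1, 2))
  expect_equal(reducePCA(rank1, 1)$explained[1], 1, tolerance = 1e-10)

  # fixed sign convention makes the projection deterministic
  a <- reducePCA(X, 2); b <- reducePCA(X[sample(nrow(X)), ], 2)
  expect_equal(abs(crossprod(a$rotation, b$rotation)), diag(2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(apply(a$rotation, 2, function(v) v[which.max(abs(v))]) > 0))

  expect_error(reducePCA(X, 5), "exceeds")
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(bacc(diag(c(7, 9))), 1)
  conf <- matrix(c(8, 4, 2, 6), 2)   # TP 8, FN 2, TN 6, FP 4
  expect_equal(bacc(conf), 0.7)
  expect_equal(bacc(conf[c(2, 1), c(2, 1)]), 0.7)  # class roles swapped
  expect_error(bacc(matrix(c(0, 3, 0, 4), 2)), "class")
})

test_that("trainEval reports fold and test balanced accuracies", {
  set.seed(11)
  X <- rbind(matrix(rnorm(200, 0), ncol = 2),
             matrix(rnorm(200, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 100)
  rep1 <- trainEval(X, y, seed = 1)
  expect_equal(balancedAccuracy(rep1), 1)
  expect_true(all(foldScores(rep1) == 1))
  expect_equal(sum(confusionMatrix(rep1)), 40)  # 20% of 200

  # chance level under label permutation
  set.seed(12)
  Xn <- matrix(rnorm(1000), ncol = 2)
  yn <- sample(rep(c("a", "b"), each = 250))
  repn <- trainEval(Xn, yn, seed = 2)
  expect_gte(balancedAccuracy(repn), 0.4)
  expect_lte(balancedAccuracy(repn), 0.6)

  expect_error(trainEval(X[1:12, ], y[c(1:6, 101:106)], seed = 1,
                         folds = 10),
               "fewer folds")
})

test_that("group-aware splitting keeps parent trials on one side", {
  # features memorize the parent; only leakage across the split could
  # classify random per-parent labels above chance
  set.seed(13)
  nPar <- 20
  parentLab <- rep(c("a", "b"), each = nPar / 2)
  X <- do.call(rbind, lapply(1:nPar, function(g)
    matrix(rep(rnorm(2, 10 * g), each = 10), ncol = 2) + rnorm(20, 0, 0.01)))
  y <- rep(parentLab, each = 10)
  groups <- rep(1:nPar, each = 10)
  repg <- trainEval(X, y, seed = 3, groups = groups, folds = 5)
  expect_identical(repg@mode, "group")
  expect_equal(sum(confusionMatrix(repg)), 40)  # 4 whole parents held out
  # zero parent ids appear on both sides of the split
  perParent <- table(factor(groups[repg@testIndices], levels = 1:nPar))
  expect_true(all(perParent %in% c(0L, 10L)))

  # determinism of the full decoding chain under a fixed seed
  crops <- makeVarianceCrops(c(2, 1, 1, 1), c(1, 1, 1, 2), nPerClass = 50,
                             seed = 14)
  crops@parentIds <- rep(1:20L, each = 5)
  r1 <- suppressMessages(decodePair(crops, seed = 4, folds = 5))
  r2 <- suppressMessages(decodePair(crops, seed = 4, folds = 5))
  expect_identical(confusionMatrix(r1), confusionMatrix(r2))
  expect_identical(foldScores(r1), foldScores(r2))
  expect_gte(balancedAccuracy(r1), 0.9)  # strong variance contrast
})
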