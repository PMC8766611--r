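# Robot-skin features, feature selection, temperature classes, classifiers.

test_that("time-domain features match their closed forms", {
  flat <- extractFeatures(rep(-3, 100))
  expect_equal(unname(flat[c("s1_mav", "s1_var", "s1_wl", "s1_ssc")]),
               c(3, 0, 0, 0))

  f <- extractFeatures(c(1, 2, 3))
  expect_equal(unname(f[c("s1_mav", "s1_var", "s1_wl")]), c(2, 2 / 3, 2))
  expect_equal(unname(f["s1_ssi"]), 14)

  # homogeneity and the RMS^2 = VAR + mean^2 identity on random windows
  set.seed(30)
  for (i in 1:5) {
    x <- rnorm(200, mean = runif(1, -2, 2))
    fx <- extractFeatures(x)
    f5 <- extractFeatures(5 * x)
    expect_equal(unname(f5["s1_mav"]), unname(5 * fx["s1_mav"]))
    expect_equal(unname(f5["s1_var"]), unname(25 * fx["s1_var"]))
    expect_equal(unname(fx["s1_rms"])^2,
                 unname(fx["s1_var"]) + mean(x)^2)
  }

  two <- extractFeatures(rbind(1:10, 21:30))
  expect_length(two, 14)  # 2 channels x 7 features

  expect_error(extractFeatures(numeric(0)), "empty")
})

test_that("temperatures map to the printed bins, monotonically", {
  expect_identical(tempToClass(12)$condition, "very_cold")
  expect_identical(tempToClass(12)$group, "NOX")
  expect_identical(tempToClass(28)$condition, "warm")
  expect_identical(tempToClass(28)$group, "INNO")
  expect_identical(tempToClass(43)$condition, "very_hot")

  gap <- tempToClass(15.5)
  expect_true(gap$in_gap)
  expect_true(gap$condition %in% c("very_cold", "cold"))
  expect_true(is.na(tempToClass(15.5, gap = "unresolved")$condition))
  expect_error(tempToClass(NaN), "finite")

  # monotone in the cold-to-hot ordering, and inside-bin identity
  ordering <- c("very_cold", "cold", "warm", "hot", "very_hot")
  grid <- seq(10, 44.9, by = 0.1)
  cls <- tempToClass(grid)$condition
  expect_true(all(diff(match(cls, ordering)) >= 0))
  tab <- thermalConditions()
  for (i in seq_len(nrow(tab))) {
    inside <- grid[grid > tab$temp_low_c[i] & grid < tab$temp_high_c[i]]
    expect_true(all(tempToClass(inside)$condition == tab$name[i]))
  }
})

test_that("the withdrawal policy maps intensity groups to speeds", {
  expect_identical(withdrawalPolicy("NOX"), "fast")
  expect_identical(withdrawalPolicy("MOD"), "slow")
  expect_identical(withdrawalPolicy("INNO"), "delayed")
  expect_identical(withdrawalPolicy(c("NOX", "INNO")), c("fast", "delayed"))
  expect_error(withdrawalPolicy("SOFT"), "unknown group")
})

test_that("forward selection keeps informative features and drops noise", {
  set.seed(31)
  n <- 90
  y <- rep(c("a", "b", "c"), each = n / 3)
  informative1 <- rep(c(0, 4, 8), each = n / 3) + rnorm(n, 0, 0.5)
  informative2 <- rep(c(8, 0, 4), each = n / 3) + rnorm(n, 0, 0.5)
  X <- cbind(good1 = informative1, good2 = informative2,
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  sel <- selectFeatures(X, y, k = 2, seed = 1)
  expect_setequal(sel$selected, c("good1", "good2"))

  all5 <- selectFeatures(X, y, k = 5, seed = 1)
  expect_setequal(all5$selected, colnames(X))
  expect_error(selectFeatures(X, y, k = 9, seed = 1), "exceeds")

  # determinism
  sel2 <- selectFeatures(X, y, k = 2, seed = 1)
  expect_identical(sel$selected, sel2$selected)
})

test_that("amplitude-scale features dominate selection on skin data", {
  profiles <- generateSkinDataset(10, seed = 32, noiseSdC = 0.3)
  tab <- skinFeatureTable(profiles)
  y <- tab$label
  X <- tab[, setdiff(names(tab), "label")]
  sel <- selectFeatures(X, y, k = 2, seed = 2)
  # an amplitude-scale feature is picked first (MAV, or its algebraic
  # relatives RMS = sqrt(VAR + mean^2) and SSI = N * RMS^2)
  expect_true(grepl("mav|rms|ssi", sel$selected[1]))
  # the MAV + VAR pair recovers most of the discriminative information
  set.seed(3)
  mavVar <- thermoEEG:::.cvScore(as.matrix(X[, c("s1_mav", "s1_var")]), y)
  expect_gte(mavVar, 0.85)
})

test_that("temperature classifiers separate the five bins", {
  profiles <- generateSkinDataset(10, seed = 33)
  for (cls in c("QLDA", "LDA", "KNN", "SVM", "NB")) {
    fit <- trainTempClassifier(profiles, cls, seed = 1,
                               features = c("s1_mav", "s1_var",
                                            "s2_mav", "s2_var"))
    expect_gte(balancedAccuracy(fit$report), 0.8)
  }
  # noise-free bins are perfectly separable
  clean <- generateSkinDataset(10, seed = 34, noiseSdC = 0.001)
  fitQ <- trainTempClassifier(clean, "QLDA", seed = 2,
                              features = c("s1_mav", "s1_var",
                                           "s2_mav", "s2_var"))
  expect_equal(balancedAccuracy(fitQ$report), 1)

  # determinism and error reporting
  fitA <- trainTempClassifier(profiles, "QLDA", seed = 5)
  fitB <- trainTempClassifier(profiles, "QLDA", seed = 5)
  expect_identical(confusionMatrix(fitA$report), confusionMatrix(fitB$report))
  expect_error(trainTempClassifier(profiles, "forest", seed = 1),
               "KNN, SVM, NB, LDA, QLDA")
})

test_that("permuted labels drop accuracy to the five-class chance level", {
  profiles <- generateSkinDataset(10, seed = 35)
  tab <- skinFeatureTable(profiles)
  set.seed(36)
  tab$label <- sample(tab$label)
  fit <- trainTempClassifier(tab, "QLDA", seed = 3)
  expect_gte(balancedAccuracy(fit$report), 0.0)
  expect_lte(balancedAccuracy(fit$report), 0.45)
})

test_that("objects drifting toward ambient confuse the extreme classes", {
  fit <- trainTempClassifier(generateSkinDataset(12, seed = 37), "QLDA",
                             seed = 4)
  drifted <- generateSkinDataset(12, seed = 38, driftC = 6)
  truth <- vapply(drifted, function(p) p@label, character(1))
  pred <- predictTemperature(fit, drifted)
  coldish <- truth == "very_cold"
  hotish <- truth == "very_hot"
  # drift moves the extremes toward the moderate bins
  expect_gt(mean(pred[coldish] == "cold"), 0.5)
  expect_gt(mean(pred[hotish] == "hot"), 0.5)
  # the innocuous middle class is unaffected by drift toward ambient
  warm <- truth == "warm"
  expect_gt(mean(pred[warm] == "warm"), 0.9)
})
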