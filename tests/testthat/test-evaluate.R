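test_that("AUC equals brute-force pair counting with ties at 1/2", {
  expect_equal(aucScore(c(0.9, 0.8, 0.7, 0.1), c(1, -1, 1, -1)), 0.75)
  expect_equal(aucScore(c(1, 1, 0, 0), c(1, 1, -1, -1)), 1)
  expect_equal(aucScore(rep(0.5, 10), rep(c(1, -1), 5)), 0.5)
  expect_error(aucScore(c(0.2, 0.8), c(1, 1)), "both classes")

  withr::with_seed(55, {
    for (rep in 1:30) {
      n <- sample(10:200, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
      labels <- sample(c(1, -1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(aucScore(scores, labels), bruteForceAuc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(66, {
    scores <- runif(150)
    labels <- ifelse(scores + rnorm(150, sd = 0.4) > 0.5, 1, -1)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(-1, 1))))
  expect_equal(aucScore(scores, labels), ref, tolerance = 1e-10)
})

test_that("MCC matches the closed form and its symmetries", {
  expect_equal(mcc(list(tp = 50, fp = 0, tn = 50, fn = 0)), 1)
  expect_equal(mcc(list(tp = 25, fp = 25, tn = 25, fn = 25)), 0)
  byHand <- (40 * 35 - 15 * 10) /
    sqrt((40 + 15) * (40 + 10) * (35 + 15) * (35 + 10))
  expect_equal(mcc(list(tp = 40, fn = 10, tn = 35, fp = 15)), byHand)
  # zero denominator convention
  expect_equal(mcc(list(tp = 0, fp = 0, tn = 10, fn = 5)), 0)
  # symmetric under tp<->tn, fp<->fn
  withr::with_seed(3, {
    for (rep in 1:20) {
      cc <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                             c("tp", "fp", "tn", "fn")))
      swapped <- list(tp = cc$tn, fp = cc$fn, tn = cc$tp, fn = cc$fp)
      expect_equal(mcc(cc), mcc(swapped))
    }
  })
})

test_that("precision at a threshold counts predicted positives", {
  expect_equal(precisionAt(c(0.9, 0.8, 0.7, 0.1), c(1, -1, 1, -1), 0.5), 2 / 3)
  expect_equal(as.numeric(precisionAt(c(0.9, 0.8), c(1, 1), 0.5)), 1)
  p <- precisionAt(c(0.1, 0.2), c(1, -1), 0.5)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "noPositivePredictions"))
})

test_that("ROC/PR curves are consistent with the AUC and with prevalence", {
  withr::with_seed(14, {
    for (rep in 1:15) {
      n <- sample(20:150, 1)
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
      labels <- sample(c(1, -1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      cv <- curves(scores, labels)
      expect_true(all(diff(cv$roc$fpr) >= 0))
      expect_true(all(diff(cv$pr$recall) >= 0))
      # trapezoid area under the ROC equals the Mann-Whitney AUC
      area <- sum(diff(cv$roc$fpr) *
                    (head(cv$roc$tpr, -1) + cv$roc$tpr[-1]) / 2)
      expect_equal(area, aucScore(scores, labels), tolerance = 1e-9)
    }
  })
  # perfect classifier passes through (0, 1)
  cv <- curves(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_true(any(cv$roc$fpr == 0 & cv$roc$tpr == 1))
  # all-equal scores: PR flat at prevalence
  cv2 <- curves(rep(0.5, 8), c(1, 1, -1, -1, -1, -1, -1, -1))
  expect_true(all(cv2$pr$precision == 0.25))
})

test_that("method comparison uses the paired signed-rank convention", {
  a <- seq(0.5, 0.9, length.out = 15)
  same <- compareMethods(a, a)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  # distinct positive shifts of all 15 pairs: exact signed-rank p = 2 * 2^-15
  shifted <- compareMethods(a, a + seq(0.05, 0.15, length.out = 15),
                            alpha = 0.01)
  expect_true(shifted$significant)
  expect_equal(shifted$p, 2 / 2^15, tolerance = 1e-10)
})

test_that("information gain ranks a label-identical feature at 1 bit", {
  y <- rep(c(1, -1), each = 4)
  x <- cbind(perfect = as.numeric(y == 1), constant = rep(2, 8),
             noisy = c(1, 0, 1, 1, 0, 1, 0, 0))
  rk <- informationGainRanking(x, y)
  expect_equal(rk$feature[1], "perfect")
  expect_equal(rk$gain[rk$feature == "perfect"], 1)
  expect_equal(rk$gain[rk$feature == "constant"], 0)
  # hand-computed: noisy splits 8 samples into {0:(1 pos,3 neg)},{1:(3 pos,1 neg)}
  h <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))
  handGain <- 1 - (0.5 * h(1 / 4) + 0.5 * h(3 / 4))
  expect_equal(rk$gain[rk$feature == "noisy"], handGain)
})

test_that("cross-validation partitions records and guards against leakage", {
  withr::with_seed(40, {
    d <- generateDataset(nPos = 30, nNeg = 60, lengthRange = c(80, 150),
                         seed = 17)
  })
  r <- runCV(d$dataset, "olimo", pssmProvider = pssmProviderFromSites(d$sites),
             folds = 5, cValues = c(0.125), innerFolds = 3, seed = 23)
  expect_equal(nrow(cvFolds(r)), 5L)
  expect_setequal(cvScores(r)$id, names(sequences(d$dataset)))
  expect_false(anyDuplicated(cvScores(r)$id) > 0)
  expect_true(assertNoLeakage(r))
  # the audit records PSSM inputs as training positives only, per fold
  for (a in r@meta$audit) {
    expect_gt(length(a$pssmIds), 0L)
    expect_length(intersect(a$pssmIds, a$testIds), 0L)
  }
})

test_that("a tampered audit trips the leakage guard", {
  withr::with_seed(41, {
    d <- generateDataset(nPos = 15, nNeg = 30, lengthRange = c(60, 100),
                         seed = 19)
  })
  r <- runCV(d$dataset, "oli", folds = 3, cValues = 0.25, innerFolds = 2,
             seed = 2)
  r@meta$audit[[1]]$pssmIds <- r@meta$audit[[1]]$testIds[1]
  expect_error(assertNoLeakage(r), "protocol error")
})

test_that("negative resampling partitions the pool and reports a t interval", {
  withr::with_seed(70, {
    d <- generateDataset(nPos = 20, nNeg = 120, lengthRange = c(60, 100),
                         seed = 31)
  })
  pool <- sequences(d$dataset)[datasetLabels(d$dataset) == -1]
  pos <- sequences(d$dataset)[datasetLabels(d$dataset) == 1]
  res <- negativeResamplingCI(pos, pool, drawSize = 40, draws = 3,
                              seed = 5, schema = "oli", folds = 3,
                              cValues = 0.25, innerFolds = 2)
  expect_length(res$aucs, 3L)
  expect_false(res$degenerate)
  expect_true(res$ci[1] <= res$meanAuc && res$meanAuc <= res$ci[2])
  expect_gt(diff(res$ci), 0)

  # degenerate single draw is flagged
  res1 <- suppressWarnings(negativeResamplingCI(pos, pool, drawSize = 40,
                                                draws = 1, seed = 5,
                                                schema = "oli", folds = 3,
                                                cValues = 0.25, innerFolds = 2))
  expect_true(res1$degenerate)
  expect_error(negativeResamplingCI(pos, pool, drawSize = 1000, draws = 2),
               "pool smaller")
})

test_that("cross-protein sensitivity separates disjoint planted motifs", {
  withr::with_seed(90, {
    dA <- generateDataset(nPos = 25, nNeg = 50, lengthRange = c(80, 140),
                          motif = "UGUAUAUA", protein = "A", seed = 101)
    dB <- generateDataset(nPos = 25, nNeg = 50, lengthRange = c(80, 140),
                          motif = "CCCCGGGG", protein = "B", seed = 102)
  })
  xA <- encodeFeatures(sequences(dA$dataset), "oli")
  xB <- encodeFeatures(sequences(dB$dataset), "oli")
  mA <- trainModel(xA, datasetLabels(dA$dataset), cValues = 0.25,
                   innerFolds = 3, seed = 1, protein = "A")
  mB <- trainModel(xB, datasetLabels(dB$dataset), cValues = 0.25,
                   innerFolds = 3, seed = 1, protein = "B")
  posA <- xA[datasetLabels(dA$dataset) == 1, ]
  posB <- xB[datasetLabels(dB$dataset) == 1, ]
  sens <- crossRbpSensitivity(list(A = mA, B = mB),
                              list(A = posA, B = posB))
  expect_true(all(sens >= 0 & sens <= 1))
  expect_gt(sens["A", "A"], sens["A", "B"])
  expect_gt(sens["B", "B"], sens["B", "A"])
  # resubstitution diagonal is optimistic: out-of-fold replacement lowers it
  sens2 <- crossRbpSensitivity(list(A = mA, B = mB), list(A = posA, B = posB),
                               oofSensitivity = c(A = 0.1))
  expect_equal(sens2["A", "A"], 0.1)
  expect_error(crossRbpSensitivity(list(A = mA), list(B = posB[, 1:100])),
               "contract error")
})

test_that("CvReport files are written as TSV plus summary", {
  withr::with_seed(44, {
    d <- generateDataset(nPos = 12, nNeg = 24, lengthRange = c(60, 90),
                         seed = 3)
  })
  r <- runCV(d$dataset, "oli", folds = 3, cValues = 0.25, innerFolds = 2,
             seed = 6)
  prefix <- file.path(tempdir(), "cvtest")
  paths <- writeCvReport(r, prefix)
  expect_true(all(file.exists(paths)))
  folds <- read.table(paths[1], sep = "\t", header = TRUE)
  expect_equal(nrow(folds), 3L)
})
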