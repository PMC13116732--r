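test_that("pairwise and macro AUCs match hand-computed values", {
  scores <- cbind(BA = c(0.9, 0.7, 0.8, 0.2), COPD = c(0.1, 0.3, 0.2, 0.8))
  labels <- c("BA", "BA", "COPD", "COPD")
  pw <- pairwiseOvoAuc(scores, labels)
  expect_equal(pw$auc, 0.75)  # 3 of 4 concordant pairs
  # perfectly ranked pair
  s2 <- cbind(BA = c(0.9, 0.8, 0.1), COPD = c(0.1, 0.2, 0.9))
  expect_equal(pairwiseOvoAuc(s2, c("BA", "BA", "COPD"))$auc, 1)
  # label-independent scores: 0.5 by tie convention
  s3 <- cbind(BA = rep(0.5, 6), COPD = rep(0.5, 6))
  expect_equal(pairwiseOvoAuc(s3, rep(c("BA", "COPD"), 3))$auc, 0.5)
  # macro OvO = unweighted mean of pair AUCs
  set.seed(11)
  s4 <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("BA", "CF", "COPD")))
  l4 <- sample(c("BA", "CF", "COPD"), 20, replace = TRUE)
  expect_equal(macroOvoAuc(s4, l4), mean(pairwiseOvoAuc(s4, l4)$auc))
  expect_error(macroOvoAuc(s4[l4 == "BA", , drop = FALSE], l4[l4 == "BA"]),
               ">= 2 classes")
})

test_that("AUC agrees with an independent ROC implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(40)
  pos <- rbinom(40, 1, plogis(6 * scores - 3)) == 1L
  s2 <- cbind(A = scores, B = 1 - scores)
  mine <- pairwiseOvoAuc(s2, ifelse(pos, "A", "B"))$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
  # invariance under strictly monotone transform of scores
  s3 <- cbind(A = exp(3 * scores), B = 1 - scores)
  expect_equal(pairwiseOvoAuc(s3, ifelse(pos, "A", "B"))$auc, mine)
})

test_that("Youden threshold maximizes J over all midpoints", {
  scores <- c(0.9, 0.7, 0.8, 0.2)
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  thr <- youdenThreshold(scores, pos)
  expect_equal(thr, 0.45)
  jAt <- function(t) mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
  expect_equal(jAt(thr), 0.5)
  # perfectly separated: smallest maximizer in the gap, J = 1
  thr2 <- youdenThreshold(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(thr2, 0.5)
  # identical distributions: J = 0 everywhere
  thr3 <- youdenThreshold(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  s3 <- c(1, 2, 1, 2); p3 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(mean(s3[p3] >= thr3) + mean(s3[!p3] < thr3) - 1, 0)
  # degenerate single unique score
  expect_equal(youdenThreshold(rep(0.4, 4), c(TRUE, FALSE, TRUE, FALSE)), 0.4)
  # oracle equivalence on random inputs
  set.seed(21)
  for (r in 1:20) {
    n <- sample(5:50, 1L)
    s <- round(runif(n), 2)
    p <- rbinom(n, 1, 0.5) == 1L
    if (!any(p) || all(p)) next
    t0 <- youdenThreshold(s, p)
    expect_equal(mean(s[p] >= t0) + mean(s[!p] < t0) - 1,
                 youdenBruteMaxJ(s, p), tolerance = 1e-12)
  }
})

test_that("binary metrics handle zero-denominator cells explicitly", {
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 8), 0.8, 0.9)
  pos <- c(rep(TRUE, 10), rep(FALSE, 10))
  bm <- binaryMetricsAtThreshold(scores, pos, 0.5)
  expect_equal(bm$sensitivity, 0.9)
  expect_equal(bm$specificity, 0.8)
  expect_equal(bm$ppv, 9 / 11)
  expect_equal(bm$npv, 8 / 9)
  expect_length(bm$undefined, 0L)
  # threshold -Inf: everything positive, NPV undefined
  bmAll <- binaryMetricsAtThreshold(scores, pos, -Inf)
  expect_equal(bmAll$sensitivity, 1)
  expect_equal(bmAll$specificity, 0)
  expect_true("npv" %in% bmAll$undefined)
  expect_true(is.na(bmAll$npv))
})

test_that("bootstrap CI is a percentile interval with undefined-redraw", {
  d <- data.frame(v = rep(1, 30))
  ci <- bootstrapCi(function(df) mean(df$v), d, nBoot = 50, seed = 1)
  expect_equal(ci, c(1, 1))
  set.seed(5)
  d2 <- data.frame(v = rnorm(200))
  ci2 <- bootstrapCi(function(df) mean(df$v), d2, nBoot = 300, seed = 2)
  expect_true(ci2[1L] <= mean(d2$v) && mean(d2$v) <= ci2[2L])
  # a metric that is always undefined errors out
  expect_error(bootstrapCi(function(df) NA_real_, d2, nBoot = 10, seed = 3),
               "undefined")
})

test_that("the training pipeline is leakage-free and produces probabilities", {
  ds <- generateDataset(separatedConfig(12, nFeatures = 20L))
  sp <- stratifiedSplit(ds$experiment, 0.7, seed = 12)
  tr <- splitSubset(ds$experiment, sp, "train")
  te <- splitSubset(ds$experiment, sp, "test")
  cfg <- modelConfig(nRounds = 40, maxDepth = 3, seed = 12)
  fit <- fitPipeline(tr, featureLabels(tr), cfg)
  p <- predictPipeline(fit, te)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  expect_identical(colnames(p), fit@classes)
  # perturbing test rows cannot change fitted parameters
  m <- intensityMatrix(te)
  te2 <- BreathomicsExperiment(m * 5 + 1,
                               as.data.frame(SummarizedExperiment::colData(te)))
  fit2 <- fitPipeline(tr, featureLabels(tr), cfg)
  expect_identical(fit@normalizer@center, fit2@normalizer@center)
  expect_identical(predictPipeline(fit, tr), predictPipeline(fit2, tr))
  expect_error(fitPipeline(tr, c(featureLabels(tr), "999.99"), cfg), "absent")
})

test_that("evaluation separates planted classes and is honest under the null", {
  ds <- generateDataset(separatedConfig(42, nFeatures = 30L))
  sp <- stratifiedSplit(ds$experiment, 0.7, seed = 42)
  tr <- splitSubset(ds$experiment, sp, "train")
  te <- splitSubset(ds$experiment, sp, "test")
  rep1 <- evaluateModel(tr, te, featureLabels(ds$experiment),
                        modelConfig(nRounds = 120, maxDepth = 4, seed = 42),
                        nBoot = 40, seed = 42)
  expect_gte(rep1@macroAucOvo, 0.95)
  expect_true(all(rep1@pairwise$auc >= 0.8))
  expect_true(all(rep1@pairwise$aucLo <= rep1@pairwise$auc + 1e-9))
  expect_true(all(rep1@pairwise$aucHi >= rep1@pairwise$auc - 1e-9))
  # permuted labels: chance-level discrimination
  x <- ds$experiment
  SummarizedExperiment::colData(x)$group <-
    withr::with_seed(99, sample(as.character(diagnosisGroup(x))))
  sp2 <- stratifiedSplit(x, 0.7, seed = 7)
  rep2 <- evaluateModel(splitSubset(x, sp2, "train"), splitSubset(x, sp2, "test"),
                        featureLabels(x),
                        modelConfig(nRounds = 120, maxDepth = 4, seed = 7),
                        nBoot = 10, seed = 7)
  expect_lt(abs(rep2@macroAucOvo - 0.5), 0.05)
  # report round-trips through JSON
  f <- withr::local_tempfile(fileext = ".json")
  reportToJson(rep1, f)
  back <- reportFromJson(f)
  expect_equal(back@macroAucOvo, rep1@macroAucOvo, tolerance = 1e-12)
  expect_equal(back@pairwise$auc, rep1@pairwise$auc, tolerance = 1e-12)
  expect_equal(back@testScores, rep1@testScores, tolerance = 1e-12)
  expect_identical(back@testLabels, rep1@testLabels)
  expect_error(evaluateModel(tr, tr, featureLabels(tr)), "disjoint")
})

test_that("hyperparameter tuning picks the tie-break winner deterministically", {
  ds <- generateDataset(separatedConfig(5, nFeatures = 15L))
  x <- ds$experiment[, 1:300]
  grid1 <- data.frame(maxDepth = 5L, l1 = 1, l2 = 1)
  cfg <- tuneHyperparameters(x, featureLabels(x), grid = grid1, folds = 3L,
                             repeats = 1L, seed = 9, nRounds = 20L)
  expect_equal(cfg$maxDepth, 5L)
  expect_equal(cfg$l1, 1); expect_equal(cfg$l2, 1)
  # separable data: every config is near-perfect, tie-break selects the
  # smaller depth then the larger l2
  grid2 <- expand.grid(maxDepth = c(3L, 6L), l1 = 0.1, l2 = c(0.1, 10))
  cfg2 <- tuneHyperparameters(x, featureLabels(x), grid = grid2, folds = 3L,
                              repeats = 1L, seed = 9, nRounds = 20L)
  cfg2b <- tuneHyperparameters(x, featureLabels(x), grid = grid2, folds = 3L,
                               repeats = 1L, seed = 9, nRounds = 20L)
  expect_gt(attr(cfg2, "cvAuc"), 0.95)
  expect_identical(cfg2[c("maxDepth", "l1", "l2")], cfg2b[c("maxDepth", "l1", "l2")])
  expect_error(tuneHyperparameters(x, featureLabels(x), folds = 200L, seed = 1),
               "too small")
})
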