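test_that("SMOTE balances classes by within-class interpolation", {
  set.seed(8)
  xa <- matrix(rnorm(20, 0, 1), 10, 2)
  xb <- matrix(rnorm(6, 5, 1), 3, 2)
  x <- rbind(xa, xb)
  y <- c(rep("A", 10), rep("B", 3))
  bal <- smoteBalance(x, y, seed = 4)
  expect_equal(unname(table(bal$y)["A"]), 10L)
  expect_equal(unname(table(bal$y)["B"]), 10L)
  # original rows retained
  expect_equal(bal$x[1:13, ], x, ignore_attr = TRUE)
  # each synthetic B row is a convex combination of two real B rows
  syn <- bal$x[bal$y == "B", , drop = FALSE][-(1:3), , drop = FALSE]
  onSegment <- function(s) {
    for (i in 1:3) for (j in setdiff(1:3, i)) {
      d <- xb[j, ] - xb[i, ]
      u <- if (abs(d[1L]) > 1e-12) (s[1L] - xb[i, 1L]) / d[1L] else
        (s[2L] - xb[i, 2L]) / d[2L]
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(xb[i, ] + u * d - s)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1L, onSegment)))
  # synthetic rows stay in the minority bounding box
  expect_true(all(syn[, 1L] >= min(xb[, 1L]) - 1e-9 & syn[, 1L] <= max(xb[, 1L]) + 1e-9))
  # already balanced: identity
  balEq <- smoteBalance(xa, rep(c("A", "B"), 5L), seed = 1)
  expect_identical(balEq$x, xa)
  # singleton class refused
  expect_error(smoteBalance(x[1:11, ], c(rep("A", 10), "B"), seed = 1),
               "single member")
})

test_that("stability selection aggregates gain across iterations deterministically", {
  ds <- generateDataset(plantedConfig(3, nFeatures = 25L, nSd = 3)$config)
  sp <- stratifiedSplit(ds$experiment, 0.7, seed = 3)
  tr <- splitSubset(ds$experiment, sp, "train")
  trn <- applyNormalizer(fitControlNormalizer(tr), tr)
  lc <- stabilityLearnerConfig(nrounds = 8, max_depth = 2)
  res1 <- runStabilitySelection(trn, nIter = 3, seed = 5, learnerConfig = lc)
  res2 <- runStabilitySelection(trn, nIter = 3, seed = 5, learnerConfig = lc)
  expect_identical(res1@table, res2@table)
  expect_true(all(res1@table$selectionProbability >= 0 &
                  res1@table$selectionProbability <= 1))
  expect_true(all(res1@table$meanGain >= 0))
  # covariates enter the candidate set
  expect_true(all(c("Age", "Sex", "BMI", "Smoking") %in% res1@table$feature))
  # single iteration: probabilities are 0/1 indicators of positive gain
  res3 <- runStabilitySelection(trn, nIter = 1, seed = 7, learnerConfig = lc)
  expect_true(all(res3@table$selectionProbability %in% c(0, 1)))
  expect_identical(res3@table$selectionProbability > 0, res3@table$meanGain > 0)
  expect_error(runStabilitySelection(trn, nIter = 0, seed = 1), "nIter")
})

test_that("a constant feature is never selected", {
  ds <- generateDataset(plantedConfig(4, nFeatures = 20L)$config)
  x <- ds$experiment[, 1:200]
  m <- intensityMatrix(x)
  m[, 3L] <- 1
  x <- BreathomicsExperiment(m, as.data.frame(SummarizedExperiment::colData(x)))
  xn <- applyNormalizer(fitControlNormalizer(x), x)
  res <- runStabilitySelection(xn, nIter = 3, seed = 2,
                               learnerConfig = stabilityLearnerConfig(nrounds = 8, max_depth = 2),
                               includeCovariates = FALSE)
  expect_equal(res@table$selectionProbability[3L], 0)
})

test_that("panel thresholding follows the 75th-percentile rule", {
  tab <- data.frame(feature = c("A", "B", "C", "D"),
                    selectionProbability = c(1.0, 0.8, 0.5, 0.0),
                    meanGain = c(4, 3, 2, 0))
  res <- new("StabilityResult", table = tab, nIterations = 10L,
             subsampleFraction = 0.5, seed = 1L)
  panels <- selectPanel(res, covariates = character())
  expect_equal(panels$full@thresholdValue, 0.9)
  expect_identical(panels$full@members, "A")
  # all equal nonzero probabilities: everything nonzero is kept
  tab2 <- data.frame(feature = c("A", "B", "C"),
                     selectionProbability = c(0.6, 0.6, 0.6), meanGain = 1:3)
  res2 <- new("StabilityResult", table = tab2, nIterations = 10L,
              subsampleFraction = 0.5, seed = 1L)
  expect_setequal(selectPanel(res2, covariates = character())$full@members,
                  c("A", "B", "C"))
  # covariate separation and the protected policy
  tab3 <- data.frame(feature = c("50.05", "60.05", "Age", "Sex"),
                     selectionProbability = c(1, 0.8, 1, 0),
                     meanGain = c(5, 4, 3, 0))
  res3 <- new("StabilityResult", table = tab3, nIterations = 10L,
              subsampleFraction = 0.5, seed = 1L)
  p3 <- selectPanel(res3)
  expect_true("Age" %in% p3$full@members)
  expect_false(any(c("Age", "Sex") %in% p3$vocOnly@members))
  expect_true(all(p3$vocOnly@members %in% p3$full@members))
  pProt <- selectPanel(res3, policy = "protected")
  expect_true(all(c("Age", "Sex", "BMI", "Smoking") %in% pProt$full@members))
  # all-zero probabilities refused
  tab4 <- data.frame(feature = "A", selectionProbability = 0, meanGain = 0)
  expect_error(selectPanel(new("StabilityResult", table = tab4,
                               nIterations = 1L, subsampleFraction = 0.5,
                               seed = 1L)), "zero")
})

test_that("stronger planted effects are recovered more strongly", {
  # monotone recovery: a 3-SD shift never ranks below the same feature at 1-SD
  probFor <- function(nSd, seed) {
    pc <- plantedConfig(seed, nFeatures = 25L, nSd = nSd)
    ds <- generateDataset(pc$config)
    sp <- stratifiedSplit(ds$experiment, 0.7, seed = seed)
    tr <- splitSubset(ds$experiment, sp, "train")
    trn <- applyNormalizer(fitControlNormalizer(tr), tr)
    res <- runStabilitySelection(trn, nIter = 10, seed = seed,
                                 learnerConfig = stabilityLearnerConfig(nrounds = 6, max_depth = 2),
                                 includeCovariates = FALSE)
    mean(res@table$meanGain[match(pc$planted, res@table$feature)])
  }
  gains <- vapply(1:5, function(s) c(probFor(0.5, s), probFor(3, s)), numeric(2L))
  expect_gt(mean(gains[2L, ]), mean(gains[1L, ]))
})
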