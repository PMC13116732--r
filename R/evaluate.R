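# Multiclass model training with leakage-free in-fold preprocessing, and
# one-vs-one evaluation: pairwise AUCs, Youden-thresholded binary metrics,
# and bootstrap confidence intervals.

#' Fitted training pipeline (scaler -> SMOTE -> boosted trees)
#'
#' @slot normalizer Control-referenced scaler fitted on the training data
#'   of the fit call only.
#' @slot booster Fitted xgboost handle.
#' @slot classes Class labels in model order.
#' @slot features Panel feature labels in model column order.
#' @slot config Model configuration list.
#' @export
setClass("FittedPipeline",
  representation(normalizer = "ControlNormalizer", booster = "ANY",
                 classes = "character", features = "character",
                 config = "list")
)

#' Multiclass model configuration
#'
#' Defaults follow the tuned-model setup: 800 boosting rounds with tree
#' depth and L1/L2 penalties drawn from the tuning grid (see
#' [defaultTuningGrid()]).  The learning rate is an implementation default.
#'
#' @param nRounds Boosting rounds (default 800).
#' @param maxDepth Maximum tree depth (grid values 7 or 12).
#' @param l1 L1 regularization weight (reg_alpha; grid 0.1, 1, 10).
#' @param l2 L2 regularization weight (reg_lambda; grid 0.1, 1, 10).
#' @param eta Learning rate (default 0.1).
#' @param seed Integer seed for the booster.
#' @return Named list of class settings.
#' @export
modelConfig <- function(nRounds = 800L, maxDepth = 7L, l1 = 0.1, l2 = 0.1,
                        eta = 0.1, seed = 1L) {
  list(nRounds = as.integer(nRounds), maxDepth = as.integer(maxDepth),
       l1 = l1, l2 = l2, eta = eta, seed = as.integer(seed))
}

#' Hyperparameter tuning grid
#'
#' The exhaustive 2 x 3 x 3 grid over maximum depth and the two
#' regularization penalties.
#'
#' @return data.frame with columns `maxDepth`, `l1`, `l2`.
#' @export
defaultTuningGrid <- function() {
  expand.grid(maxDepth = c(7L, 12L), l1 = c(0.1, 1, 10), l2 = c(0.1, 1, 10),
              KEEP.OUT.ATTRS = FALSE)
}

# Panel feature matrix: VOC intensities plus encoded covariates, restricted
# to the panel in panel order.
.panelMatrix <- function(x, features) {
  m <- cbind(intensityMatrix(x), encodeCovariates(covariateTable(x)))
  miss <- setdiff(features, colnames(m))
  if (length(miss)) {
    stop("panel feature(s) absent from table: ", paste(head(miss, 5L), collapse = ", "))
  }
  m[, features, drop = FALSE]
}

#' Fit the training pipeline on a (fold-)training table
#'
#' On fit the pipeline (1) fits the control-referenced scaler on the given
#' training rows only, (2) SMOTE-balances the scaled training rows only,
#' and (3) fits the multiclass gradient-boosted model.  Rows outside the
#' fit call (e.g. validation folds or the test set) never influence the
#' scaler or the oversampling.
#'
#' @param x Raw-intensity training [BreathomicsExperiment-class].
#' @param panel A [FeaturePanel-class] (or character vector of features).
#' @param config A [modelConfig()] list.
#' @param controlLabel Reference class for the scaler.
#' @return A [FittedPipeline-class].
#' @export
fitPipeline <- function(x, panel, config = modelConfig(),
                        controlLabel = "Control") {
  features <- if (is(panel, "FeaturePanel")) panelMembers(panel) else panel
  if (!length(features)) stop("panel must be nonempty")
  normalizer <- fitControlNormalizer(x, controlLabel = controlLabel)
  xn <- applyNormalizer(normalizer, x)
  feat <- .panelMatrix(xn, features)
  y <- as.character(diagnosisGroup(x))
  bal <- smoteBalance(feat, y, seed = config$seed)
  classes <- .GROUPS[.GROUPS %in% unique(bal$y)]
  lab <- match(bal$y, classes) - 1L
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 max_depth = config$maxDepth, eta = config$eta,
                 alpha = config$l1, lambda = config$l2,
                 nthread = 1L, tree_method = "hist",
                 seed = config$seed)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(bal$x, label = lab, nthread = 1L),
    nrounds = config$nRounds, verbose = 0L
  )
  new("FittedPipeline", normalizer = normalizer, booster = booster,
      classes = classes, features = features, config = config)
}

#' Predict class probabilities from a fitted pipeline
#'
#' Applies the stored scaler, then the model.  Probability rows sum to 1.
#'
#' @param fit A [FittedPipeline-class].
#' @param x A raw-intensity [BreathomicsExperiment-class].
#' @return Numeric matrix, samples x classes, with class column names.
#' @export
predictPipeline <- function(fit, x) {
  stopifnot(is(fit, "FittedPipeline"))
  xn <- applyNormalizer(fit@normalizer, x)
  feat <- .panelMatrix(xn, fit@features)
  p <- predict(fit@booster, xgboost::xgb.DMatrix(feat, nthread = 1L))
  if (!is.matrix(p)) p <- matrix(p, nrow = nrow(feat), byrow = TRUE)
  dimnames(p) <- list(rownames(feat), fit@classes)
  p
}

# Mann-Whitney AUC with tie correction (mid-ranks; ties count 1/2).
.aucRank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pairwise one-vs-one AUCs
#'
#' For each unordered class pair (i, j) the samples of the two classes are
#' retained and scored with the normalized score p_i / (p_i + p_j), making
#' the pair AUC invariant to probability mass on the remaining classes.
#' The AUC is the Mann-Whitney statistic with tie correction.
#'
#' @param scores Class-probability matrix (samples x classes, named
#'   columns).
#' @param labels Class label vector.
#' @return data.frame with columns `classA`, `classB`, `auc` (positive
#'   class = `classA`, the earlier label in canonical group order).
#' @export
pairwiseOvoAuc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)[colnames(scores) %in% unique(labels)]
  if (length(classes) < 2L) stop("need >= 2 classes present")
  pairs <- utils::combn(classes, 2L)
  out <- data.frame(classA = pairs[1L, ], classB = pairs[2L, ],
                    auc = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    sel <- labels %in% c(a, b)
    s <- .pairScore(scores[sel, , drop = FALSE], a, b)
    out$auc[k] <- .aucRank(s, labels[sel] == a)
  }
  out
}

# Normalized pair score p_a / (p_a + p_b); both-zero rows get 0.5.
.pairScore <- function(scores, a, b) {
  tot <- scores[, a] + scores[, b]
  s <- ifelse(tot > 0, scores[, a] / tot, 0.5)
  unname(s)
}

#' Macro-averaged one-vs-one AUC
#'
#' Unweighted mean of [pairwiseOvoAuc()] over all unordered class pairs.
#'
#' @inheritParams pairwiseOvoAuc
#' @return Single numeric AUC.
#' @export
macroOvoAuc <- function(scores, labels) {
  mean(pairwiseOvoAuc(scores, labels)$auc)
}

#' Macro-averaged one-vs-rest AUC
#'
#' Mean over classes of AUC(class vs rest) using the class's own
#' probability as score.
#'
#' @inheritParams pairwiseOvoAuc
#' @return Single numeric AUC.
#' @export
macroOvrAuc <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- colnames(scores)[colnames(scores) %in% unique(labels)]
  if (length(classes) < 2L) stop("need >= 2 classes present")
  mean(vapply(classes, function(cl) .aucRank(scores[, cl], labels == cl),
              numeric(1L)))
}

#' Youden-index optimal threshold
#'
#' Maximizes J(t) = sensitivity(t) + specificity(t) - 1 over the midpoints
#' of sorted unique scores plus -Inf/+Inf sentinels (score >= t predicts
#' positive).  Ties are broken toward the smallest threshold.  A degenerate
#' single unique score returns that score (J = 0).
#'
#' @param scores Numeric score vector.
#' @param positive Logical vector, TRUE for the positive class.
#' @return The threshold t*.
#' @export
youdenThreshold <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), any(positive), any(!positive))
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- c(-Inf, (u[-length(u)] + u[-1L]) / 2, Inf)
  j <- vapply(cand, function(t) {
    mean(scores[positive] >= t) + mean(scores[!positive] < t) - 1
  }, numeric(1L))
  cand[which(j >= max(j) - 1e-12)[1L]]
}

#' Binary diagnostic metrics at a fixed threshold
#'
#' Computes sensitivity, specificity, PPV and NPV from the 2x2 confusion
#' table with `score >= threshold` predicting positive.  Metrics whose
#' denominator is zero are returned as `NA` and named in the `undefined`
#' element rather than coerced to 0.
#'
#' @param scores Numeric score vector.
#' @param positive Logical vector, TRUE for the positive class.
#' @param threshold Decision threshold (finite or -Inf/+Inf sentinel).
#' @return List with `sensitivity`, `specificity`, `ppv`, `npv` and
#'   `undefined` (character vector of undefined metric names).
#' @export
binaryMetricsAtThreshold <- function(scores, positive, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & positive); fn <- sum(!pred & positive)
  tn <- sum(!pred & !positive); fp <- sum(pred & !positive)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
              ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn))
  out$undefined <- names(out)[vapply(out[1:4], is.na, TRUE)]
  out
}

#' Nonparametric bootstrap percentile confidence interval
#'
#' Resamples the rows of `data` with replacement and recomputes
#' `metricFn`; resamples on which the metric is undefined (returns `NA`,
#' e.g. because a needed class is absent) are redrawn, up to ten times the
#' requested number of replicates in total.
#'
#' @param metricFn Function taking a resampled data.frame, returning a
#'   single numeric or `NA` when undefined.
#' @param data data.frame of test instances.
#' @param nBoot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Numeric length-2 vector (lower, upper percentile).
#' @export
bootstrapCi <- function(metricFn, data, nBoot = 1000L, seed, conf = 0.95) {
  nBoot <- as.integer(nBoot)
  stopifnot(nBoot >= 2L)
  n <- nrow(data)
  .withSeed(seed, {
    vals <- numeric(0L)
    attempts <- 0L
    maxAttempts <- 10L * nBoot
    while (length(vals) < nBoot && attempts < maxAttempts) {
      attempts <- attempts + 1L
      v <- metricFn(data[sample.int(n, n, replace = TRUE), , drop = FALSE])
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (attempts > 0 && (attempts - length(vals)) / attempts > 0.9) {
      stop("metric undefined on > 90% of attempted bootstrap resamples")
    }
    alpha <- (1 - conf) / 2
    .pctl(vals, c(alpha, 1 - alpha))
  })
}

#' Train on the training set and evaluate on the test set
#'
#' Fits the pipeline on the training table, derives per-pair Youden
#' thresholds from the (refit-on-full-training) training scores, and
#' evaluates macro OvO/OvR AUC, all pairwise AUCs and thresholded
#' sensitivity/specificity/PPV/NPV on the test table, attaching bootstrap
#' percentile confidence intervals throughout.
#'
#' @param train,test Disjoint raw-intensity
#'   [BreathomicsExperiment-class] tables.
#' @param panel A [FeaturePanel-class] or character vector.
#' @param config A [modelConfig()] list.
#' @param nBoot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param controlLabel Reference class for the in-pipeline scaler.
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(train, test, panel, config = modelConfig(),
                          nBoot = 1000L, seed = 1L, controlLabel = "Control") {
  if (length(intersect(sampleIds(train), sampleIds(test)))) {
    stop("train and test sets must be disjoint")
  }
  fit <- fitPipeline(train, panel, config, controlLabel)
  trainScores <- predictPipeline(fit, train)
  testScores <- predictPipeline(fit, test)
  trainLab <- as.character(diagnosisGroup(train))
  testLab <- as.character(diagnosisGroup(test))

  pw <- pairwiseOvoAuc(testScores, testLab)
  pw$aucLo <- pw$aucHi <- NA_real_
  for (m in c("threshold", "sensitivity", "specificity", "ppv", "npv")) pw[[m]] <- NA_real_
  for (m in c("sensitivityLo", "sensitivityHi", "specificityLo", "specificityHi",
              "ppvLo", "ppvHi", "npvLo", "npvHi")) pw[[m]] <- NA_real_

  for (k in seq_len(nrow(pw))) {
    a <- pw$classA[k]; b <- pw$classB[k]
    selTr <- trainLab %in% c(a, b)
    thr <- youdenThreshold(.pairScore(trainScores[selTr, , drop = FALSE], a, b),
                           trainLab[selTr] == a)
    pw$threshold[k] <- thr
    selTe <- testLab %in% c(a, b)
    sTe <- .pairScore(testScores[selTe, , drop = FALSE], a, b)
    posTe <- testLab[selTe] == a
    bm <- binaryMetricsAtThreshold(sTe, posTe, thr)
    pw$sensitivity[k] <- bm$sensitivity; pw$specificity[k] <- bm$specificity
    pw$ppv[k] <- bm$ppv; pw$npv[k] <- bm$npv

    pairDf <- data.frame(s = sTe, pos = posTe)
    ciSeed <- .deriveSeed(seed, paste0("pair-", a, "-", b))
    ci <- bootstrapCi(function(d) .aucRank(d$s, d$pos), pairDf, nBoot, ciSeed)
    pw$aucLo[k] <- ci[1L]; pw$aucHi[k] <- ci[2L]
    for (m in c("sensitivity", "specificity", "ppv", "npv")) {
      fn <- function(d) binaryMetricsAtThreshold(d$s, d$pos, thr)[[m]]
      ciM <- tryCatch(bootstrapCi(fn, pairDf, nBoot,
                                  .deriveSeed(ciSeed, m)),
                      error = function(e) c(NA_real_, NA_real_))
      pw[[paste0(m, "Lo")]][k] <- ciM[1L]
      pw[[paste0(m, "Hi")]][k] <- ciM[2L]
    }
  }

  testDf <- data.frame(label = testLab, as.data.frame(testScores, check.names = FALSE))
  scoreCols <- colnames(testScores)
  macroFn <- function(metric) function(d) {
    sc <- as.matrix(d[, scoreCols, drop = FALSE])
    tryCatch(metric(sc, d$label), error = function(e) NA_real_)
  }
  ciOvo <- bootstrapCi(macroFn(macroOvoAuc), testDf, nBoot, .deriveSeed(seed, "macro-ovo"))
  ciOvr <- bootstrapCi(macroFn(macroOvrAuc), testDf, nBoot, .deriveSeed(seed, "macro-ovr"))

  new("EvaluationReport",
      macroAucOvo = macroOvoAuc(testScores, testLab),
      macroAucOvr = macroOvrAuc(testScores, testLab),
      macroCi = list(ovo = ciOvo, ovr = ciOvr),
      pairwise = pw, testScores = testScores, testLabels = testLab,
      nBoot = as.integer(nBoot), seed = as.integer(seed))
}

#' Tune hyperparameters by repeated stratified cross-validation
#'
#' Exhaustive search over the tuning grid; every candidate is scored by
#' mean cross-validated macro OvO AUC under repeated stratified k-fold
#' cross-validation, with the pipeline (scaler -> SMOTE -> model) refitted
#' inside every training fold.  Ties are broken toward the smaller depth,
#' then the larger L2 penalty (stronger regularization).
#'
#' @param train Raw-intensity training [BreathomicsExperiment-class].
#' @param panel A [FeaturePanel-class] or character vector.
#' @param grid data.frame of candidates, see [defaultTuningGrid()].
#' @param folds,repeats Cross-validation folds (default 10) and repeats
#'   (default 3).
#' @param seed Integer seed.
#' @param nRounds,eta Fixed learner settings shared by all candidates.
#' @param controlLabel Reference class for the in-fold scaler.
#' @return The winning [modelConfig()] list, with the achieved mean CV AUC
#'   attached as attribute `cvAuc`.
#' @export
tuneHyperparameters <- function(train, panel, grid = defaultTuningGrid(),
                                folds = 10L, repeats = 3L, seed = 1L,
                                nRounds = 800L, eta = 0.1,
                                controlLabel = "Control") {
  y <- as.character(diagnosisGroup(train))
  counts <- table(y)
  if (any(counts < folds)) {
    stop("class too small for stratified ", folds, "-fold CV: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  }
  foldSets <- lapply(seq_len(repeats), function(r) {
    .withSeed(.deriveSeed(seed, paste0("cvfold-", r)), .stratifiedFolds(y, folds))
  })
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- modelConfig(nRounds = nRounds, maxDepth = grid$maxDepth[g],
                       l1 = grid$l1[g], l2 = grid$l2[g], eta = eta,
                       seed = .deriveSeed(seed, paste0("cfg-", g)))
    aucs <- c()
    for (r in seq_len(repeats)) {
      foldId <- foldSets[[r]]
      for (f in seq_len(folds)) {
        trIdx <- which(foldId != f)
        teIdx <- which(foldId == f)
        fit <- fitPipeline(train[, trIdx], panel, cfg, controlLabel)
        sc <- predictPipeline(fit, train[, teIdx])
        aucs <- c(aucs, tryCatch(macroOvoAuc(sc, y[teIdx]),
                                 error = function(e) NA_real_))
      }
    }
    score[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- order(-score, grid$maxDepth, -grid$l2)[1L]
  out <- modelConfig(nRounds = nRounds, maxDepth = grid$maxDepth[best],
                     l1 = grid$l1[best], l2 = grid$l2[best], eta = eta,
                     seed = as.integer(seed))
  attr(out, "cvAuc") <- score[best]
  out
}

# Stratified fold ids: within each class, shuffled round-robin assignment.
.stratifiedFolds <- function(y, folds) {
  foldId <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldId[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldId
}

#' Serialize an evaluation report to JSON
#'
#' @param report An [EvaluationReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
reportToJson <- function(report, path) {
  obj <- list(
    macroAucOvo = report@macroAucOvo, macroAucOvr = report@macroAucOvr,
    macroCi = report@macroCi, pairwise = report@pairwise,
    testScores = as.data.frame(report@testScores, check.names = FALSE),
    testSampleIds = rownames(report@testScores),
    testLabels = report@testLabels,
    nBoot = report@nBoot, seed = report@seed
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Deserialize an evaluation report from JSON
#'
#' @param path Path written by [reportToJson()].
#' @return An [EvaluationReport-class].
#' @export
reportFromJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scores <- as.matrix(obj$testScores)
  rownames(scores) <- obj$testSampleIds
  pw <- as.data.frame(obj$pairwise, stringsAsFactors = FALSE)
  new("EvaluationReport",
      macroAucOvo = obj$macroAucOvo, macroAucOvr = obj$macroAucOvr,
      macroCi = list(ovo = as.numeric(obj$macroCi$ovo),
                     ovr = as.numeric(obj$macroCi$ovr)),
      pairwise = pw, testScores = scores,
      testLabels = as.character(obj$testLabels),
      nBoot = as.integer(obj$nBoot), seed = as.integer(obj$seed))
}
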