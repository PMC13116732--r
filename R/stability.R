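# Ensemble stability selection: repeated stratified subsampling, SMOTE
# class balancing, boosted-tree gain importance, aggregation, and
# percentile-threshold panel construction.

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Upsamples every minority class to the majority-class count.  Each
#' synthetic observation is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`,
#' where `x` is a real minority row and `x_nn` one of its `k` nearest
#' same-class neighbors (Euclidean distance); `k` is reduced to class size
#' minus one for very small classes.  Original rows are always retained.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class label vector of length `nrow(x)`; every class needs >= 2
#'   members.
#' @param seed Integer seed.
#' @param k Number of neighbors (default 5).
#' @return List with the balanced matrix `x` and labels `y`; already
#'   balanced input is returned unchanged.
#' @export
smoteBalance <- function(x, y, seed, k = 5L) {
  x <- as.matrix(x)
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("class with a single member cannot be oversampled: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  nMaj <- max(counts)
  if (all(counts == nMaj)) return(list(x = x, y = y))
  .withSeed(seed, {
    synthX <- list(); synthY <- list()
    for (cl in names(counts)[counts < nMaj]) {
      idx <- which(y == cl)
      xc <- x[idx, , drop = FALSE]
      nc <- length(idx)
      kc <- min(k, nc - 1L)
      d <- as.matrix(dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1L, function(r) order(r)[seq_len(kc)]))
      nSyn <- nMaj - nc
      base <- rep_len(seq_len(nc), nSyn)[sample.int(nSyn)]
      pick <- nn[cbind(base, sample.int(kc, nSyn, replace = TRUE))]
      u <- runif(nSyn)
      s <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      rownames(s) <- sprintf("syn_%s_%d", cl, seq_len(nSyn))
      synthX[[cl]] <- s
      synthY[[cl]] <- rep(cl, nSyn)
    }
    list(x = rbind(x, do.call(rbind, synthX)),
         y = c(y, unlist(synthY, use.names = FALSE)))
  })
}

# Stratified subsample without replacement: per class, ceil-free
# largest-remainder counts at the requested fraction, minimum 2 per class.
.stratifiedSubsample <- function(y, fraction) {
  counts <- table(y)
  take <- pmax(2L, .largestRemainder(as.integer(counts), fraction))
  idx <- unlist(lapply(seq_along(counts), function(i) {
    cl <- names(counts)[i]
    sample(which(y == cl), take[i])
  }), use.names = FALSE)
  sort(idx)
}

# One boosted-tree fit returning per-feature gain importance (0 for
# features never used in a split).
.xgbGain <- function(x, y, learnerConfig, seed) {
  classes <- sort(unique(y))
  lab <- match(y, classes) - 1L
  params <- list(
    objective = if (length(classes) > 2L) "multi:softprob" else "binary:logistic",
    max_depth = learnerConfig$max_depth,
    eta = learnerConfig$eta,
    nthread = 1L,
    tree_method = "hist",
    seed = as.integer(seed)
  )
  if (length(classes) > 2L) params$num_class <- length(classes)
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = lab, nthread = 1L),
    nrounds = learnerConfig$nrounds, verbose = 0L
  )
  # feature names passed explicitly: avoids the booster's native
  # string-info query, which proved unstable over many repeated fits
  imp <- xgboost::xgb.importance(model = booster, feature_names = colnames(x))
  gain <- setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  gain
}

#' Default inner learner configuration for stability selection
#'
#' A fixed, modest gradient-boosting configuration; the ranking is driven
#' by aggregation over iterations, not by tuning the inner learner.
#'
#' @param nrounds,max_depth,eta Boosting rounds, tree depth, learning rate.
#' @return Named list.
#' @export
stabilityLearnerConfig <- function(nrounds = 200L, max_depth = 6L, eta = 0.3) {
  list(nrounds = as.integer(nrounds), max_depth = as.integer(max_depth), eta = eta)
}

#' Run ensemble stability selection
#'
#' Per iteration: draw a stratified subsample without replacement
#' (`subsampleFraction` of the training observations), balance classes with
#' SMOTE, fit a multiclass gradient-boosted tree ensemble, and record each
#' feature's gain importance.  Aggregated over iterations this yields the
#' selection probability (fraction of iterations with strictly positive
#' gain) and the mean gain per feature.  Candidate features are the VOC
#' intensities plus, optionally, the encoded clinical covariates (Age,
#' Sex, BMI, Smoking).
#'
#' @param x Normalized training [BreathomicsExperiment-class].
#' @param nIter Number of iterations (default 500).
#' @param subsampleFraction Fraction of training observations per iteration
#'   (default 0.5).
#' @param seed Integer seed; iteration seeds are derived as seed + index.
#' @param learnerConfig Inner learner settings, see
#'   [stabilityLearnerConfig()].
#' @param includeCovariates Add encoded clinical covariates to the
#'   candidate set (default TRUE).
#' @return A [StabilityResult-class].
#' @export
runStabilitySelection <- function(x, nIter = 500L, subsampleFraction = 0.5,
                                  seed, learnerConfig = stabilityLearnerConfig(),
                                  includeCovariates = TRUE) {
  stopifnot(is(x, "BreathomicsExperiment"))
  nIter <- as.integer(nIter)
  if (nIter < 1L) stop("nIter must be >= 1")
  feat <- intensityMatrix(x)
  if (includeCovariates) feat <- cbind(feat, encodeCovariates(covariateTable(x)))
  y <- as.character(diagnosisGroup(x))
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("subsample would leave a class with < 2 members: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  p <- ncol(feat)
  posCount <- setNames(numeric(p), colnames(feat))
  gainSum <- setNames(numeric(p), colnames(feat))
  for (it in seq_len(nIter)) {
    itSeed <- as.integer(seed) + it
    idx <- .withSeed(itSeed, .stratifiedSubsample(y, subsampleFraction))
    bal <- smoteBalance(feat[idx, , drop = FALSE], y[idx], seed = itSeed)
    gain <- .xgbGain(bal$x, bal$y, learnerConfig, seed = itSeed)
    posCount <- posCount + (gain > 0)
    gainSum <- gainSum + gain
  }
  tab <- data.frame(feature = colnames(feat),
                    selectionProbability = posCount / nIter,
                    meanGain = gainSum / nIter,
                    stringsAsFactors = FALSE, row.names = NULL)
  new("StabilityResult", table = tab, nIterations = nIter,
      subsampleFraction = subsampleFraction, seed = as.integer(seed))
}

#' Build the feature panels from a stability result
#'
#' The threshold is the 75th percentile (linear interpolation) of the
#' selection probabilities restricted to features with nonzero stability.
#' The full panel keeps every feature (VOC or covariate) at or above the
#' threshold; the VOC-only panel is the full panel minus covariates.
#' Under `policy = "protected"` the clinical covariates are additionally
#' force-appended to the full panel regardless of their probability.
#' Panel order: descending probability, then descending mean gain, then
#' ascending m/z label.
#'
#' @param result A [StabilityResult-class].
#' @param percentile Threshold percentile (default 75).
#' @param covariates Labels treated as clinical covariates.
#' @param policy `"none"` (default) or `"protected"`.
#' @return Named list with [FeaturePanel-class] elements `full` and
#'   `vocOnly`.
#' @export
selectPanel <- function(result, percentile = 75,
                        covariates = c("Age", "Sex", "BMI", "Smoking"),
                        policy = c("none", "protected")) {
  stopifnot(is(result, "StabilityResult"))
  policy <- match.arg(policy)
  tab <- result@table
  nz <- tab$selectionProbability[tab$selectionProbability > 0]
  if (!length(nz)) stop("all selection probabilities are zero")
  threshold <- .pctl(nz, percentile / 100)
  keep <- tab[tab$selectionProbability >= threshold, , drop = FALSE]
  ord <- order(-keep$selectionProbability, -keep$meanGain,
               suppressWarnings(as.numeric(keep$feature)), keep$feature)
  members <- keep$feature[ord]
  if (policy == "protected") {
    members <- c(members, setdiff(covariates, members))
  }
  full <- new("FeaturePanel", panelType = "full", members = members,
              thresholdValue = threshold,
              protectedCovariates = policy == "protected")
  vocMembers <- setdiff(members, covariates)
  if (!length(vocMembers)) stop("VOC-only panel is empty")
  vocOnly <- new("FeaturePanel", panelType = "voc_only", members = vocMembers,
                 thresholdValue = threshold, protectedCovariates = FALSE)
  list(full = full, vocOnly = vocOnly)
}

#' Members of a feature panel
#'
#' @param panel A [FeaturePanel-class].
#' @return Character vector of feature labels in panel order.
#' @export
panelMembers <- function(panel) {
  stopifnot(is(panel, "FeaturePanel"))
  panel@members
}
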