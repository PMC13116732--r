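#' Stratified participant-level train/test split
#'
#' Partitions participants into a training and a test set while preserving
#' the diagnosis-class proportions.  The total training size is fixed at
#' `floor(trainFraction * N)`; per-class training counts are allocated by
#' the largest-remainder rule so every class share matches the global
#' fraction to within one participant.
#'
#' @param x A [BreathomicsExperiment-class].
#' @param trainFraction Training proportion (default 0.70).
#' @param seed Integer seed; determines which participants land in which
#'   subset.
#' @return A [SplitAssignment-class].
#' @export
stratifiedSplit <- function(x, trainFraction = 0.70, seed) {
  stopifnot(is(x, "BreathomicsExperiment"),
            trainFraction > 0, trainFraction < 1)
  g <- as.character(diagnosisGroup(x))
  ids <- sampleIds(x)
  sizes <- table(g)
  if (any(sizes < 2L)) {
    stop("every class needs >= 2 participants; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  counts <- .largestRemainder(as.integer(sizes), trainFraction)
  names(counts) <- names(sizes)
  trainIds <- .withSeed(seed, {
    unlist(lapply(names(sizes), function(cl) {
      clIds <- ids[g == cl]
      sample(clIds, counts[[cl]])
    }), use.names = FALSE)
  })
  new("SplitAssignment",
      trainIds = trainIds, testIds = setdiff(ids, trainIds),
      trainFraction = trainFraction, seed = as.integer(seed))
}

# Largest-remainder allocation of floor(fraction * sum(n)) among classes.
# Remainder ties are broken toward the larger fractional part, then the
# earlier class in table order (deterministic).
.largestRemainder <- function(n, fraction) {
  total <- floor(fraction * sum(n))
  quota <- fraction * n
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0L) {
    ord <- order(-(quota - base), seq_along(n))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1L
  }
  as.integer(base)
}

#' Subset an experiment by a split
#'
#' @param x A [BreathomicsExperiment-class].
#' @param split A [SplitAssignment-class].
#' @param which `"train"` or `"test"`.
#' @return The corresponding [BreathomicsExperiment-class] subset.
#' @export
splitSubset <- function(x, split, which = c("train", "test")) {
  which <- match.arg(which)
  ids <- if (which == "train") split@trainIds else split@testIds
  x[, ids]
}

#' Fit the control-referenced robust normalizer
#'
#' For every feature, the center is the median and the scale the
#' interquartile range (75th minus 25th percentile, linear-interpolation
#' percentiles) computed over the *training-set control samples only*.
#' Patient rows and test rows never influence the parameters.  Features
#' with zero IQR receive scale 1 so that near-constant features survive
#' scaling unharmed.
#'
#' @param x A [BreathomicsExperiment-class] (raw intensities).
#' @param split Optional [SplitAssignment-class]; when given, only training
#'   samples are considered.
#' @param controlLabel Reference class label (default `"Control"`).
#' @return A [ControlNormalizer-class].
#' @export
fitControlNormalizer <- function(x, split = NULL, controlLabel = "Control") {
  stopifnot(is(x, "BreathomicsExperiment"))
  if (!is.null(split)) x <- splitSubset(x, split, "train")
  ctrl <- diagnosisGroup(x) == controlLabel
  if (sum(ctrl) < 2L) {
    stop("training subset contains fewer than 2 '", controlLabel, "' samples")
  }
  m <- intensityMatrix(x)[ctrl, , drop = FALSE]
  center <- apply(m, 2L, median)
  scale <- apply(m, 2L, .iqr)
  scale[scale == 0] <- 1
  new("ControlNormalizer", center = center, scale = scale,
      controlLabel = controlLabel, nControls = sum(ctrl))
}

#' Apply a fitted control normalizer
#'
#' Each intensity x becomes (x - center) / scale with the control-referenced
#' parameters, applied identically to every sample (patients and controls,
#' training and test alike).
#'
#' @param params A [ControlNormalizer-class].
#' @param x A [BreathomicsExperiment-class] whose features are all covered
#'   by `params`.
#' @return Normalized [BreathomicsExperiment-class].
#' @export
applyNormalizer <- function(params, x) {
  stopifnot(is(params, "ControlNormalizer"), is(x, "BreathomicsExperiment"))
  feats <- featureLabels(x)
  miss <- setdiff(feats, names(params@center))
  if (length(miss)) {
    stop("features missing from normalizer params: ",
         paste(head(miss, 5L), collapse = ", "))
  }
  m <- intensityMatrix(x)
  norm <- sweep(sweep(m, 2L, params@center[feats], "-"),
                2L, params@scale[feats], "/")
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- t(norm)
  out
}
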