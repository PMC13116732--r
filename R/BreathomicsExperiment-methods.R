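#' Construct a BreathomicsExperiment
#'
#' @param intensities Numeric matrix, samples x m/z features; column names
#'   are m/z labels parseable as positive decimals, row names are unique
#'   participant identifiers.  Values are ion intensities (counts per
#'   second, arbitrary scale).
#' @param sampleData data.frame with one row per sample and columns
#'   `group`, `age`, `sex`, `bmi`, `smoking` (see
#'   [BreathomicsExperiment-class]).
#' @param metadata Optional list stored in the object metadata.
#' @return A [BreathomicsExperiment-class] object.
#' @examples
#' m <- matrix(runif(20, 1, 2), 4, 5,
#'             dimnames = list(paste0("s", 1:4), c("42.00", "59.05", "95.05", "118.07", "159.07")))
#' sd <- data.frame(group = c("Control", "Control", "CF", "BA"),
#'                  age = c(30, 40, 25, 50), sex = c("male", "female", "male", "female"),
#'                  bmi = c(24, 25, 19, 28), smoking = c("never", "former", "never", "never"),
#'                  row.names = rownames(m))
#' be <- BreathomicsExperiment(m, sd)
#' be
#' @export
BreathomicsExperiment <- function(intensities, sampleData, metadata = list()) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities))) {
    stop("intensities must have sample identifiers as row names")
  }
  if (is.null(colnames(intensities))) {
    stop("intensities must have m/z labels as column names")
  }
  mz <- suppressWarnings(as.numeric(colnames(intensities)))
  if (anyNA(mz) || any(mz <= 0)) {
    bad <- colnames(intensities)[is.na(mz) | mz <= 0]
    stop("m/z labels must be parseable as positive decimals: ",
         paste(head(bad, 3L), collapse = ", "))
  }
  sampleData <- as.data.frame(sampleData)
  if (!identical(rownames(sampleData), rownames(intensities))) {
    sampleData <- sampleData[rownames(intensities), , drop = FALSE]
  }
  se <- SummarizedExperiment(
    assays = list(intensity = t(intensities)),
    rowData = DataFrame(mz = mz, row.names = colnames(intensities)),
    colData = DataFrame(sampleData),
    metadata = metadata
  )
  new("BreathomicsExperiment", se)
}

#' @name BreathomicsExperiment-accessors
#' @title Accessors for BreathomicsExperiment
#' @description `intensityMatrix` returns the samples x features intensity
#'   matrix; `diagnosisGroup` the per-sample diagnosis factor;
#'   `covariateTable` the clinical covariates; `mzValues` the numeric m/z of
#'   each feature; `sampleIds` the participant identifiers;
#'   `featureLabels` the m/z labels.
#' @param x A [BreathomicsExperiment-class].
#' @return See description; matrix, factor, data.frame or character vector.
NULL

#' @rdname BreathomicsExperiment-accessors
#' @export
intensityMatrix <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  t(assay(x, "intensity"))
}

#' @rdname BreathomicsExperiment-accessors
#' @export
diagnosisGroup <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  factor(as.character(colData(x)$group), levels = .GROUPS)
}

#' @rdname BreathomicsExperiment-accessors
#' @export
covariateTable <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  as.data.frame(colData(x)[, c("age", "sex", "bmi", "smoking"), drop = FALSE])
}

#' @rdname BreathomicsExperiment-accessors
#' @export
mzValues <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  setNames(rowData(x)$mz, rownames(x))
}

#' @rdname BreathomicsExperiment-accessors
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  colnames(x)
}

#' @rdname BreathomicsExperiment-accessors
#' @export
featureLabels <- function(x) {
  stopifnot(is(x, "BreathomicsExperiment"))
  rownames(x)
}

setMethod("show", "BreathomicsExperiment", function(object) {
  cat("BreathomicsExperiment with", ncol(object), "participants and",
      nrow(object), "m/z features\n")
  tab <- table(factor(as.character(colData(object)$group), levels = .GROUPS))
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  mz <- rowData(object)$mz
  cat(sprintf("m/z range: [%.2f, %.2f]\n", min(mz), max(mz)))
})

setMethod("show", "SplitAssignment", function(object) {
  cat(sprintf("SplitAssignment: %d train / %d test (fraction %.2f, seed %d)\n",
              length(object@trainIds), length(object@testIds),
              object@trainFraction, object@seed))
})

setMethod("show", "ControlNormalizer", function(object) {
  cat(sprintf("ControlNormalizer (%s, n = %d): %d features\n",
              object@controlLabel, object@nControls, length(object@center)))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf("StabilityResult: %d features, %d iterations (subsample %.2f)\n",
              nrow(object@table), object@nIterations, object@subsampleFraction))
  top <- head(object@table[order(-object@table$selectionProbability,
                                 -object@table$meanGain), ], 5L)
  cat("top features:", paste(sprintf("%s (%.2f)", top$feature,
                                     top$selectionProbability), collapse = ", "), "\n")
})

setMethod("show", "FeaturePanel", function(object) {
  cat(sprintf("FeaturePanel [%s]: %d members (threshold %.3f)\n",
              object@panelType, length(object@members), object@thresholdValue))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: macro OvO AUC %.3f (95%% CI %.3f-%.3f), OvR %.3f\n",
              object@macroAucOvo, object@macroCi$ovo[1L], object@macroCi$ovo[2L],
              object@macroAucOvr))
  cat(sprintf("%d class pairs, %d bootstrap replicates\n",
              nrow(object@pairwise), object@nBoot))
})

setMethod("show", "SignedCorrelationMatrix", function(object) {
  cat(sprintf("SignedCorrelationMatrix: %d nodes, median of %d subsamples of size %d\n",
              nrow(object@matrix), object@nBoot, object@subsampleSize))
})

setMethod("show", "VOCNetwork", function(object) {
  cat(sprintf("VOCNetwork: %d nodes, %d edges (%d negative)\n",
              length(object@nodes), nrow(object@edges),
              sum(object@edges$sign < 0)))
})

setMethod("show", "CentralityProfile", function(object) {
  cat(sprintf("CentralityProfile: %d nodes (Katz alpha %.4f, lambda_max %.4f)\n",
              nrow(object@table), object@alpha, object@lambdaMax))
})

setMethod("show", "DeviationReport", function(object) {
  cat(sprintf("DeviationReport vs %s: %d deviations, %d flagged strong\n",
              object@controlLabel, nrow(object@deviations),
              sum(object@deviations$strong)))
})

setMethod("show", "CliqueResult", function(object) {
  if (object@empty) {
    cat(sprintf("CliqueResult [%s]: empty (no edge at threshold %.3f)\n",
                object@group, object@rThreshold))
  } else {
    cat(sprintf("CliqueResult [%s]: %d nodes, total weight %.3f (threshold %.3f)\n",
                object@group, length(object@members), object@weight,
                object@rThreshold))
  }
})
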