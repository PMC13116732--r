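#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' BreathomicsExperiment: participant-level breath VOC profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' one breath profile per participant.  The single assay `"intensity"` is an
#' m/z-feature x sample matrix of ion intensities (counts per second,
#' arbitrary scale; non-negative on the raw scale, any sign after
#' normalization).  `rowData` carries the numeric m/z value of each feature;
#' `colData` carries the diagnosis `group` (one of BA, COPD, CF, LAM,
#' Control) and the clinical covariates `age` (years), `sex`
#' (male/female), `bmi` (kg/m^2) and `smoking` (never/former/current).
#'
#' Each participant contributes exactly one sample, so sample and participant
#' identifiers coincide and must be unique.
#'
#' @export
setClass("BreathomicsExperiment", contains = "SummarizedExperiment")

setValidity("BreathomicsExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'intensity' is required")
  }
  cd <- colData(object)
  need <- c("group", "age", "sex", "bmi", "smoking")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) {
    msg <- c(msg, paste0("missing colData columns: ", paste(miss, collapse = ", ")))
  }
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- c(msg, paste0("sample_id must be unique",
                         if (length(dup)) paste0(" (duplicated: ",
                                                 paste(head(dup, 3L), collapse = ", "), ")")))
  }
  if ("group" %in% colnames(cd)) {
    g <- as.character(cd$group)
    bad <- setdiff(unique(g), .GROUPS)
    if (length(bad)) {
      msg <- c(msg, paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
    }
  }
  rd <- rowData(object)
  if (!"mz" %in% colnames(rd)) {
    msg <- c(msg, "rowData column 'mz' is required")
  } else {
    mz <- rd$mz
    if (!is.numeric(mz) || anyNA(mz) || any(mz <= 0)) {
      msg <- c(msg, "m/z labels must be parseable as positive decimals")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Group specification for the synthetic cohort generator
#'
#' Describes one diagnosis group: its size, covariate distribution
#' parameters, multiplicative intensity shifts of informative features
#' relative to the control marginals, and the latent feature-feature
#' correlation matrix of the Gaussian copula.
#'
#' @slot label Diagnosis label, one of BA, COPD, CF, LAM, Control.
#' @slot n Integer participant count (>= 2).
#' @slot ageMean,ageSd Age distribution parameters in years (truncated to
#'   18-89 at sampling time).
#' @slot bmiMean,bmiSd BMI distribution parameters in kg/m^2.
#' @slot maleProp Proportion of male participants in [0, 1].
#' @slot smokingProps Named numeric of length 3 (never, former, current)
#'   summing to 1.
#' @slot informativeShifts Named numeric: m/z label -> multiplicative shift
#'   of the marginal mean versus control.
#' @slot correlationMatrix Positive-definite latent correlation matrix with
#'   one row/column per generated feature.
#' @export
setClass("GroupSpec",
  representation(
    label = "character", n = "integer",
    ageMean = "numeric", ageSd = "numeric",
    bmiMean = "numeric", bmiSd = "numeric",
    maleProp = "numeric", smokingProps = "numeric",
    informativeShifts = "numeric", correlationMatrix = "matrix"
  )
)

setValidity("GroupSpec", function(object) {
  msg <- character()
  if (!object@label %in% .GROUPS) msg <- c(msg, "unknown group label")
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (object@maleProp < 0 || object@maleProp > 1) msg <- c(msg, "maleProp must be in [0, 1]")
  sp <- object@smokingProps
  if (length(sp) != 3L || any(sp < 0) || abs(sum(sp) - 1) > 1e-8) {
    msg <- c(msg, "smokingProps must be 3 non-negative values summing to 1")
  }
  R <- object@correlationMatrix
  if (nrow(R) != ncol(R)) msg <- c(msg, "correlationMatrix must be square")
  else {
    if (max(abs(R - t(R))) > 1e-10) msg <- c(msg, "correlationMatrix must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-10) msg <- c(msg, "correlationMatrix must have unit diagonal")
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) msg <- c(msg, sprintf("correlationMatrix smallest eigenvalue %.3e is not > 0", ev))
  }
  if (length(msg)) msg else TRUE
})

#' Full configuration of the synthetic cohort generator
#'
#' @slot groups List of [GroupSpec-class] objects, one per diagnosis group.
#' @slot baseline data.frame with columns `feature`, `mz`, `mean`, `sd`:
#'   the control-group marginal targets (original intensity scale) for every
#'   generated feature.
#' @slot mzRange Numeric length-2 range of generated m/z values.
#' @slot noiseSd Log-scale standard deviation of per-observation noise.
#' @slot seed Integer seed; fully determines the output.
#' @export
setClass("GeneratorConfig",
  representation(
    groups = "list", baseline = "data.frame",
    mzRange = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (!all(vapply(object@groups, is, TRUE, "GroupSpec"))) {
    msg <- c(msg, "groups must be a list of GroupSpec objects")
  }
  b <- object@baseline
  if (!all(c("feature", "mz", "mean", "sd") %in% names(b))) {
    msg <- c(msg, "baseline needs columns feature, mz, mean, sd")
  } else {
    if (anyDuplicated(b$feature)) msg <- c(msg, "m/z feature labels must be unique")
    if (any(b$mean <= 0) || any(b$sd < 0)) msg <- c(msg, "baseline means must be > 0, sds >= 0")
    for (g in object@groups) {
      if (is(g, "GroupSpec")) {
        if (nrow(g@correlationMatrix) != nrow(b)) {
          msg <- c(msg, sprintf("correlation matrix of %s has dimension %d, expected %d",
                                g@label, nrow(g@correlationMatrix), nrow(b)))
        }
        unknown <- setdiff(names(g@informativeShifts), b$feature)
        if (length(unknown)) {
          msg <- c(msg, paste0("shift features absent from baseline: ",
                               paste(unknown, collapse = ", ")))
        }
      }
    }
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Participant-level train/test split
#'
#' @slot trainIds,testIds Disjoint character vectors of sample identifiers
#'   whose union is the full sample set.
#' @slot trainFraction Target train proportion.
#' @slot seed Integer seed used for the within-class draw.
#' @export
setClass("SplitAssignment",
  representation(trainIds = "character", testIds = "character",
                 trainFraction = "numeric", seed = "integer")
)

setValidity("SplitAssignment", function(object) {
  if (length(intersect(object@trainIds, object@testIds)) > 0L) {
    "trainIds and testIds must be disjoint"
  } else TRUE
})

#' Control-referenced robust normalizer parameters
#'
#' Per-feature center (median) and scale (interquartile range) estimated on
#' the training-set control samples only.
#'
#' @slot center,scale Named numeric vectors, one entry per retained feature.
#' @slot controlLabel Label of the reference class.
#' @slot nControls Number of control samples the parameters were fitted on.
#' @export
setClass("ControlNormalizer",
  representation(center = "numeric", scale = "numeric",
                 controlLabel = "character", nControls = "integer")
)

setValidity("ControlNormalizer", function(object) {
  msg <- character()
  if (!identical(names(object@center), names(object@scale))) {
    msg <- c(msg, "center and scale must cover the same features")
  }
  if (any(object@scale < 0)) msg <- c(msg, "scale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of ensemble stability selection
#'
#' @slot table data.frame with columns `feature`, `selectionProbability`
#'   (fraction of iterations with strictly positive gain, in [0, 1]) and
#'   `meanGain` (gain importance averaged over all iterations).
#' @slot nIterations,subsampleFraction,seed Run parameters.
#' @export
setClass("StabilityResult",
  representation(table = "data.frame", nIterations = "integer",
                 subsampleFraction = "numeric", seed = "integer")
)

setValidity("StabilityResult", function(object) {
  p <- object@table$selectionProbability
  if (any(p < 0 | p > 1)) "selection probabilities must lie in [0, 1]" else TRUE
})

#' A selected feature panel
#'
#' @slot panelType `"full"` (VOCs plus clinical covariates) or `"voc_only"`.
#' @slot members Ordered feature labels (descending selection probability,
#'   then descending mean gain, then ascending m/z label).
#' @slot thresholdValue Selection-probability threshold that defined the panel.
#' @slot protectedCovariates Whether covariates were force-retained.
#' @export
setClass("FeaturePanel",
  representation(panelType = "character", members = "character",
                 thresholdValue = "numeric", protectedCovariates = "logical")
)

setValidity("FeaturePanel", function(object) {
  msg <- character()
  if (!object@panelType %in% c("full", "voc_only")) msg <- c(msg, "invalid panelType")
  if (length(object@members) == 0L) msg <- c(msg, "panel must be nonempty")
  if (object@panelType == "voc_only" &&
      any(object@members %in% .COVARIATE_FEATURES)) {
    msg <- c(msg, "voc_only panel must not contain covariates")
  }
  if (length(msg)) msg else TRUE
})

#' Multiclass evaluation report
#'
#' @slot macroAucOvo,macroAucOvr Macro-averaged one-vs-one / one-vs-rest AUC
#'   on the test set.
#' @slot macroCi Named list with elements `ovo` and `ovr`, each a length-2
#'   numeric (2.5th and 97.5th bootstrap percentiles).
#' @slot pairwise data.frame, one row per unordered class pair: `classA`,
#'   `classB`, `auc`, `aucLo`, `aucHi`, `threshold` (Youden, from training
#'   scores), `sensitivity`, `specificity`, `ppv`, `npv` and their CI bounds
#'   (NA where a zero-denominator cell makes the point estimate undefined).
#' @slot testScores Matrix of test-set class probabilities (samples x classes).
#' @slot testLabels Character vector of test-set diagnosis labels.
#' @slot nBoot,seed Bootstrap parameters.
#' @export
setClass("EvaluationReport",
  representation(macroAucOvo = "numeric", macroAucOvr = "numeric",
                 macroCi = "list", pairwise = "data.frame",
                 testScores = "matrix", testLabels = "character",
                 nBoot = "integer", seed = "integer")
)

#' Bootstrap-aggregated signed distance-correlation matrix
#'
#' @slot matrix Symmetric numeric matrix of median signed distance
#'   correlations in [-1, 1]; the diagonal is unused and set to 0.
#' @slot nBoot Number of subsamples aggregated.
#' @slot subsampleSize Observations per subsample (max(2, floor(n / 3))).
#' @slot seed Integer seed.
#' @export
setClass("SignedCorrelationMatrix",
  representation(matrix = "matrix", nBoot = "integer",
                 subsampleSize = "integer", seed = "integer")
)

setValidity("SignedCorrelationMatrix", function(object) {
  m <- object@matrix
  msg <- character()
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(m) > 1 + 1e-12)) msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Weighted signed VOC association network
#'
#' @slot nodes Character vector of m/z node labels (isolated nodes retained).
#' @slot edges data.frame with columns `from`, `to`, `weight` (absolute
#'   signed correlation, > epsilon) and `sign` (+1 or -1).
#' @slot epsilon Edge-inclusion cutoff (strict).
#' @export
setClass("VOCNetwork",
  representation(nodes = "character", edges = "data.frame", epsilon = "numeric")
)

setValidity("VOCNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$weight <= object@epsilon)) msg <- c(msg, "edge weights must exceed epsilon")
    if (!all(c(e$from, e$to) %in% object@nodes)) msg <- c(msg, "edge endpoints must be nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Node centrality profile of a VOC network
#'
#' @slot table data.frame with one row per node: raw `weightedDegree`,
#'   `betweenness`, `eigenvector`, `katz` plus min-max normalized variants
#'   (suffix `Norm`, each in [0, 1]).
#' @slot alpha Katz attenuation used (0.9 / largest eigenvalue).
#' @slot lambdaMax Largest eigenvalue of the absolute-weight adjacency.
#' @export
setClass("CentralityProfile",
  representation(table = "data.frame", alpha = "numeric", lambdaMax = "numeric")
)

#' Centrality deviation report versus the control network
#'
#' @slot deviations data.frame: `group`, `metric`, `node`, `delta`
#'   (normalized disease minus normalized control) and `strong` flag.
#' @slot thresholds data.frame: per metric, `lower` (5th percentile) and
#'   `upper` (95th percentile) of the pooled signed deviation distribution.
#' @slot controlLabel Reference group label.
#' @export
setClass("DeviationReport",
  representation(deviations = "data.frame", thresholds = "data.frame",
                 controlLabel = "character")
)

#' Maximal weighted clique result
#'
#' @slot members Node labels of the maximum-total-weight clique (sorted).
#' @slot weight Sum of all pairwise edge weights inside the clique.
#' @slot rThreshold Edge-inclusion correlation threshold used.
#' @slot group Optional diagnosis label the network belonged to.
#' @slot empty TRUE when no edge survived the threshold.
#' @export
setClass("CliqueResult",
  representation(members = "character", weight = "numeric",
                 rThreshold = "numeric", group = "character", empty = "logical")
)
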