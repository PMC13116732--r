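# Per-VOC nonparametric group comparisons: global Kruskal-Wallis, post hoc
# pairwise Mann-Whitney with Holm-Bonferroni correction (within one VOC),
# and group summary tables on both normalized and original scales.

#' Kruskal-Wallis H-test across groups
#'
#' Pooled mid-ranks with tie correction; p-value from the chi-square
#' distribution with (k - 1) degrees of freedom.  All-identical values
#' return H = 0, p = 1.
#'
#' @param valuesByGroup Named list of numeric vectors, one per group.
#' @return Named numeric with elements `H` and `p`.
#' @export
kruskalWallis <- function(valuesByGroup) {
  stopifnot(length(valuesByGroup) >= 2L, all(lengths(valuesByGroup) >= 1L))
  v <- unlist(valuesByGroup, use.names = FALSE)
  if (length(unique(v)) == 1L) return(c(H = 0, p = 1))
  g <- factor(rep(names(valuesByGroup), lengths(valuesByGroup)))
  kt <- stats::kruskal.test(v, g)
  c(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Pairwise two-sided Mann-Whitney U tests
#'
#' One two-sided p-value per unordered group pair: exact enumeration when
#' both sides have at most 8 observations and no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param valuesByGroup Named list of numeric vectors (>= 1 value each).
#' @return data.frame with columns `groupA`, `groupB`, `p`.
#' @export
pairwiseMannWhitney <- function(valuesByGroup) {
  stopifnot(length(valuesByGroup) >= 2L)
  if (any(lengths(valuesByGroup) == 0L)) stop("empty group")
  pairs <- utils::combn(names(valuesByGroup), 2L)
  p <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- valuesByGroup[[pairs[1L, k]]]
    b <- valuesByGroup[[pairs[2L, k]]]
    exact <- length(a) <= 8L && length(b) <= 8L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)
    )
    min(1, unname(wt$p.value))
  }, numeric(1L))
  data.frame(groupA = pairs[1L, ], groupB = pairs[2L, ], p = p,
             stringsAsFactors = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order; each adjusted value
#'   dominates its raw value and is capped at 1.
#' @export
holmBonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Group summary statistics per feature
#'
#' Mean, SD, median and IQR of each requested feature within each
#' diagnosis group, on the scale of the supplied table.
#'
#' @param x A [BreathomicsExperiment-class].
#' @param features Feature labels to summarize (default all).
#' @return data.frame with one row per feature x group.
#' @export
summarizeGroups <- function(x, features = featureLabels(x)) {
  stopifnot(is(x, "BreathomicsExperiment"))
  miss <- setdiff(features, featureLabels(x))
  if (length(miss)) stop("features not present: ", paste(head(miss, 5L), collapse = ", "))
  m <- intensityMatrix(x)[, features, drop = FALSE]
  g <- as.character(diagnosisGroup(x))
  groups <- .GROUPS[.GROUPS %in% unique(g)]
  out <- do.call(rbind, lapply(features, function(f) {
    do.call(rbind, lapply(groups, function(cl) {
      v <- m[g == cl, f]
      data.frame(feature = f, group = cl, n = length(v),
                 mean = mean(v), sd = sd(v),
                 median = median(v), iqr = .iqr(v),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Univariate result container
#'
#' @slot global data.frame per feature: `feature`, `H`, `p`.
#' @slot pairwise data.frame per feature x pair (present only for features
#'   whose global test rejected at 0.05): `feature`, `groupA`, `groupB`,
#'   `pRaw`, `pHolm` (Holm correction within one feature's pair family).
#' @slot summariesNormalized,summariesOriginal Group summary tables on the
#'   normalized and (when supplied) original intensity scales.
#' @export
setClass("UnivariateResult",
  representation(global = "data.frame", pairwise = "data.frame",
                 summariesNormalized = "data.frame",
                 summariesOriginal = "data.frame")
)

setMethod("show", "UnivariateResult", function(object) {
  cat(sprintf("UnivariateResult: %d features, %d with global p < 0.05\n",
              nrow(object@global), sum(object@global$p < 0.05)))
})

#' Univariate group comparisons over a feature panel
#'
#' For each feature the global Kruskal-Wallis test is applied first; upon
#' rejection (p < 0.05) all pairwise Mann-Whitney tests are performed and
#' Holm-Bonferroni corrected within that feature's pair family.  Tests run
#' on the normalized data; summaries are additionally reported on the
#' original scale when the raw table is supplied.
#'
#' @param xNorm Normalized [BreathomicsExperiment-class].
#' @param features Feature labels to test (e.g. a VOC panel).
#' @param xRaw Optional raw-intensity table for original-scale summaries.
#' @param alpha Global gate level (default 0.05).
#' @return An [UnivariateResult-class].
#' @export
univariateStats <- function(xNorm, features, xRaw = NULL, alpha = 0.05) {
  stopifnot(is(xNorm, "BreathomicsExperiment"))
  m <- intensityMatrix(xNorm)
  miss <- setdiff(features, colnames(m))
  if (length(miss)) stop("features not present: ", paste(head(miss, 5L), collapse = ", "))
  g <- as.character(diagnosisGroup(xNorm))
  groups <- .GROUPS[.GROUPS %in% unique(g)]
  globalRows <- list(); pairRows <- list()
  for (f in features) {
    byGroup <- lapply(setNames(groups, groups), function(cl) m[g == cl, f])
    kw <- kruskalWallis(byGroup)
    globalRows[[f]] <- data.frame(feature = f, H = kw[["H"]], p = kw[["p"]],
                                  stringsAsFactors = FALSE)
    if (kw[["p"]] < alpha) {
      pw <- pairwiseMannWhitney(byGroup)
      pw <- data.frame(feature = f, groupA = pw$groupA, groupB = pw$groupB,
                       pRaw = pw$p, pHolm = holmBonferroni(pw$p),
                       stringsAsFactors = FALSE)
      pairRows[[f]] <- pw
    }
  }
  empty <- data.frame(feature = character(), groupA = character(),
                      groupB = character(), pRaw = numeric(), pHolm = numeric(),
                      stringsAsFactors = FALSE)
  new("UnivariateResult",
      global = do.call(rbind, c(globalRows, list(make.row.names = FALSE))),
      pairwise = if (length(pairRows)) {
        do.call(rbind, c(pairRows, list(make.row.names = FALSE)))
      } else empty,
      summariesNormalized = summarizeGroups(xNorm, features),
      summariesOriginal = if (!is.null(xRaw)) summarizeGroups(xRaw, features)
                          else data.frame())
}
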