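#' Read a breath feature table from CSV or TSV
#'
#' Expects a header with columns `sample_id`, `group`, `age`, `sex`, `bmi`,
#' `smoking` followed by one column per m/z feature.  The delimiter (comma
#' or tab) is sniffed from the first line.
#'
#' @param path Path to a delimited text file.
#' @return A [BreathomicsExperiment-class].
#' @export
readFeatureTable <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "age", "sex", "bmi", "smoking")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicated sample_id: ", paste(head(dup, 5L), collapse = ", "))
  }
  bad <- setdiff(unique(df$group), .GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  featCols <- setdiff(names(df), required)
  if (!length(featCols)) stop("no m/z feature columns found")
  feats <- df[, featCols, drop = FALSE]
  nonNum <- featCols[!vapply(feats, is.numeric, TRUE)]
  if (length(nonNum)) {
    stop("non-numeric intensity column(s): ", paste(head(nonNum, 5L), collapse = ", "))
  }
  m <- as.matrix(feats)
  rownames(m) <- df$sample_id
  BreathomicsExperiment(
    m,
    data.frame(group = df$group, age = as.numeric(df$age), sex = df$sex,
               bmi = as.numeric(df$bmi), smoking = df$smoking,
               row.names = df$sample_id)
  )
}

#' Write a breath feature table to CSV or TSV
#'
#' Column order is `sample_id`, `group`, `age`, `sex`, `bmi`, `smoking`,
#' then the m/z features.  Values are written at full double precision so
#' that write-then-read round-trips to at least 12 significant digits.
#'
#' @param x A [BreathomicsExperiment-class].
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @param digits Optional number of decimal places for intensities (default
#'   full precision).
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(x, path, digits = NULL) {
  stopifnot(is(x, "BreathomicsExperiment"))
  m <- intensityMatrix(x)
  if (!is.null(digits)) m <- round(m, digits)
  cov <- covariateTable(x)
  df <- data.frame(sample_id = sampleIds(x),
                   group = as.character(diagnosisGroup(x)),
                   age = cov$age, sex = cov$sex, bmi = cov$bmi,
                   smoking = cov$smoking, check.names = FALSE)
  df <- cbind(df, as.data.frame(m, check.names = FALSE))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils write.table
NULL

#' Filter m/z features by mass cutoff and exclusion list
#'
#' Removes features whose m/z lies strictly below `minMz` (the boundary
#' value is retained) and features named on an exclusion list, e.g.
#' instrument calibration ions.  Covariates and sample annotation are
#' untouched.  The operation is idempotent.
#'
#' @param x A [BreathomicsExperiment-class].
#' @param minMz Minimum retained m/z (default 42).
#' @param exclude Character vector of feature labels to drop; entries not
#'   present trigger a warning, not an error.
#' @return Filtered [BreathomicsExperiment-class].
#' @export
filterFeatures <- function(x, minMz = 42, exclude = character()) {
  stopifnot(is(x, "BreathomicsExperiment"))
  absent <- setdiff(exclude, featureLabels(x))
  if (length(absent)) {
    warning("exclusion list entries not present: ", paste(absent, collapse = ", "))
  }
  keep <- mzValues(x) >= minMz & !(featureLabels(x) %in% exclude)
  if (!any(keep)) stop("no features remain after filtering")
  x[keep, ]
}
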