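#' @import methods
#' @importFrom stats quantile median rnorm runif qnorm pnorm qlnorm sd
#'   kruskal.test wilcox.test p.adjust setNames cor dist var predict
#' @importFrom utils read.csv write.csv head
NULL

# Diagnosis labels recognised throughout the package; order fixes the class
# order used by the multiclass model and all pairwise reports.
.GROUPS <- c("BA", "COPD", "CF", "LAM", "Control")

# Names under which clinical covariates enter models alongside m/z features.
.COVARIATE_FEATURES <- c("Age", "Sex", "BMI", "Smoking")

.SMOKING_LEVELS <- c("never", "former", "current")
.SEX_LEVELS <- c("male", "female")

#' Evaluate an expression under a local RNG seed
#'
#' All stochastic operations in the package route their `seed` argument
#' through this helper so the caller's RNG state is never disturbed.
#' @noRd
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# One percentile convention everywhere: linear interpolation between order
# statistics (quantile type 7).
.pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

.iqr <- function(x) {
  q <- .pctl(x, c(0.25, 0.75))
  q[2L] - q[1L]
}

#' Encode clinical covariates numerically for tree models
#'
#' Sex becomes a male indicator (male = 1, female = 0) and smoking status is
#' encoded ordinally (never = 0, former = 1, current = 2); age and BMI pass
#' through unchanged.
#'
#' @param covariates data.frame with columns `age`, `sex`, `bmi`, `smoking`.
#' @return Numeric matrix with columns `Age`, `Sex`, `BMI`, `Smoking`.
#' @export
encodeCovariates <- function(covariates) {
  stopifnot(all(c("age", "sex", "bmi", "smoking") %in% names(covariates)))
  sex <- as.character(covariates$sex)
  smoking <- as.character(covariates$smoking)
  if (!all(sex %in% .SEX_LEVELS)) {
    stop("sex must be one of: ", paste(.SEX_LEVELS, collapse = ", "))
  }
  if (!all(smoking %in% .SMOKING_LEVELS)) {
    stop("smoking must be one of: ", paste(.SMOKING_LEVELS, collapse = ", "))
  }
  m <- cbind(
    Age = as.numeric(covariates$age),
    Sex = as.numeric(sex == "male"),
    BMI = as.numeric(covariates$bmi),
    Smoking = as.numeric(match(smoking, .SMOKING_LEVELS) - 1L)
  )
  rownames(m) <- rownames(covariates)
  m
}

# Stable per-stage seed derivation: root seed plus a small offset from the
# stage name, kept inside the 32-bit integer range.
.deriveSeed <- function(seed, stage) {
  off <- sum(utf8ToInt(stage)) %% 10000L
  as.integer((as.integer(seed) + off) %% .Machine$integer.max)
}
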