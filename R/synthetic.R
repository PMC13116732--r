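# Synthetic breath-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: five
# diagnosis groups with realistic covariate distributions, ~123 exact-mass
# features in m/z [42, 685] with lognormal marginals, group-specific
# multiplicative intensity shifts for a core set of informative ions, and
# group-specific latent correlation structure (hub remodeling) imposed
# through a Gaussian copula.

# The 29-member VOC panel around which the generator's correlation
# structure is organised, at two-decimal m/z labels.
.PANEL_FEATURES <- c(
  "45.99", "47.04", "55.04", "58.95", "71.06", "71.08", "73.07", "77.06",
  "79.05", "83.09", "85.07", "85.10", "95.05", "95.08", "96.06", "97.09",
  "97.10", "103.08", "105.94", "107.96", "109.07", "109.10", "118.07",
  "119.96", "149.10", "159.07", "181.01", "235.21", "329.84"
)

# Network hubs of the healthy-control association structure and the
# secondary high-degree nodes.
.HUB_FEATURES <- c("85.07", "85.10", "97.09", "97.10", "71.06", "71.08")
.SECONDARY_HUBS <- c("119.96", "107.96")

# Per-group mean +/- SD targets (original intensity scale, counts per
# second) for the 13 core informative ions; control column doubles as the
# baseline marginal for every group's non-shifted features.
.CORE_TARGETS <- local({
  tab <- rbind(
    c(71.06,  0.211, 0.503, 0.360, 0.617, 0.125, 0.299, 0.058, 0.049, 0.077, 0.092),
    c(73.07,  0.069, 0.070, 0.166, 0.549, 0.043, 0.051, 0.049, 0.019, 0.045, 0.021),
    c(79.05,  0.022, 0.023, 0.038, 0.031, 0.013, 0.008, 0.019, 0.028, 0.014, 0.011),
    c(83.09,  0.046, 0.113, 0.049, 0.044, 0.033, 0.214, 0.034, 0.089, 0.043, 0.199),
    c(85.07,  0.056, 0.051, 0.054, 0.037, 0.016, 0.005, 0.023, 0.016, 0.028, 0.028),
    c(95.05,  0.187, 0.144, 0.141, 0.137, 0.050, 0.086, 0.284, 0.175, 0.213, 0.130),
    c(97.09,  0.025, 0.022, 0.037, 0.034, 0.013, 0.019, 0.020, 0.028, 0.017, 0.024),
    c(109.07, 0.032, 0.022, 0.034, 0.023, 0.014, 0.005, 0.031, 0.028, 0.029, 0.052),
    c(118.07, 0.037, 0.044, 0.023, 0.036, 0.005, 0.009, 0.060, 0.051, 0.041, 0.040),
    c(149.10, 0.017, 0.067, 0.011, 0.010, 0.014, 0.008, 0.018, 0.018, 0.025, 0.113),
    c(159.07, 0.032, 0.173, 0.060, 0.284, 0.005, 0.002, 0.112, 0.389, 0.066, 0.340),
    c(181.01, 0.008, 0.017, 0.006, 0.006, 0.009, 0.007, 0.006, 0.008, 0.020, 0.082),
    c(235.21, 0.006, 0.005, 0.006, 0.005, 0.012, 0.027, 0.011, 0.008, 0.015, 0.056)
  )
  df <- data.frame(
    feature = sprintf("%.2f", tab[, 1L]),
    baMean = tab[, 2L], baSd = tab[, 3L],
    copdMean = tab[, 4L], copdSd = tab[, 5L],
    cfMean = tab[, 6L], cfSd = tab[, 7L],
    lamMean = tab[, 8L], lamSd = tab[, 9L],
    controlMean = tab[, 10L], controlSd = tab[, 11L],
    stringsAsFactors = FALSE
  )
  df
})

#' Control-group marginal targets for the default generator
#'
#' The 13 core informative ions carry their published-scale control means
#' and SDs; the remaining panel ions and the filler features get plausible
#' positive, right-skewed marginals (coefficient of variation around 1).
#'
#' @param nFeatures Total feature count (default 123; must be >= 29).
#' @return data.frame with columns `feature`, `mz`, `mean`, `sd`.
#' @export
defaultBaseline <- function(nFeatures = 123L) {
  nFeatures <- as.integer(nFeatures)
  if (nFeatures < 10L) stop("nFeatures must be at least 10")
  # for reduced feature counts keep the core informative ions (and hence
  # the hub structure) before the remaining panel ions
  ordered <- unique(c(.CORE_TARGETS$feature, .HUB_FEATURES, .SECONDARY_HUBS,
                      .PANEL_FEATURES))
  keep <- ordered[seq_len(min(nFeatures, length(ordered)))]
  panel <- data.frame(feature = keep, mz = as.numeric(keep),
                      stringsAsFactors = FALSE)
  core <- .CORE_TARGETS
  panel$mean <- core$controlMean[match(panel$feature, core$feature)]
  panel$sd <- core$controlSd[match(panel$feature, core$feature)]
  # non-core panel ions: deterministic plausible marginals, CV = 1
  open <- is.na(panel$mean)
  nOpen <- sum(open)
  panel$mean[open] <- round(exp(seq(log(0.01), log(0.25), length.out = nOpen)), 4L)
  panel$sd[open] <- panel$mean[open]
  nFill <- nFeatures - nrow(panel)
  if (nFill > 0L) {
    # filler m/z on a deterministic grid over [42, 685], avoiding collisions
    # with panel labels; low-level background ions, CV = 0.8
    mzFill <- round(seq(42.5, 684.5, length.out = nFill) + 0.013, 2L)
    lab <- sprintf("%.2f", mzFill)
    clash <- lab %in% panel$feature
    mzFill[clash] <- mzFill[clash] + 0.1
    lab <- sprintf("%.2f", mzFill)
    fillMean <- round(exp(seq(log(0.005), log(0.1), length.out = nFill)), 5L)
    fill <- data.frame(feature = lab, mz = mzFill, mean = fillMean,
                       sd = 0.8 * fillMean, stringsAsFactors = FALSE)
    panel <- rbind(panel, fill)
  }
  panel[order(panel$mz), , drop = FALSE]
}

# Latent correlation matrix for one group over the given feature labels.
# Healthy controls carry a hub block (85.07/85.10/97.09/97.10/71.06/71.08);
# disease groups rewire it: new hubs emerge (CF 159.07, COPD 149.10/235.21,
# BA 235.21, LAM 149.10) while all diseases except LAM lose 71.xx
# connectivity.
.groupCorrelation <- function(label, features) {
  p <- length(features)
  R <- diag(p)
  dimnames(R) <- list(features, features)
  panel <- intersect(features, .PANEL_FEATURES)
  base <- if (label == "LAM") 0.30 else 0.15
  R[panel, panel] <- base
  hubs <- intersect(features, .HUB_FEATURES)
  sec <- intersect(features, .SECONDARY_HUBS)
  R[hubs, panel] <- 0.45; R[panel, hubs] <- 0.45
  R[hubs, hubs] <- 0.75
  R[sec, panel] <- 0.35; R[panel, sec] <- 0.35
  R[sec, c(hubs, sec)] <- 0.60; R[c(hubs, sec), sec] <- 0.60
  boost <- function(R, node, r) {
    if (node %in% features) {
      R[node, panel] <- r; R[panel, node] <- r
    }
    R
  }
  damp71 <- function(R) {
    n71 <- intersect(features, c("71.06", "71.08"))
    R[n71, panel] <- 0.05; R[panel, n71] <- 0.05
    if (length(n71) == 2L) { R["71.06", "71.08"] <- 0.30; R["71.08", "71.06"] <- 0.30 }
    R
  }
  if (label == "BA") {
    R <- boost(R, "235.21", 0.55)
    R <- damp71(R)
  } else if (label == "COPD") {
    R <- boost(R, "149.10", 0.60)
    R <- boost(R, "235.21", 0.60)
    R <- boost(R, "181.01", 0.50)
    R <- damp71(R)
  } else if (label == "CF") {
    R <- boost(R, "159.07", 0.70)
    R <- boost(R, "96.06", 0.50)
    R <- boost(R, "119.96", 0.05)
    R <- damp71(R)
  } else if (label == "LAM") {
    R <- boost(R, "149.10", 0.65)
    R <- boost(R, "103.08", 0.50)
  }
  diag(R) <- 1
  R <- (R + t(R)) / 2
  nearestPositiveDefinite(R)
}

#' Default group specifications of the synthetic cohort
#'
#' Returns the five diagnosis-group specifications the generator emulates:
#' sizes (BA 160, COPD 128, CF 102, LAM 51, Control 402; 843 in total),
#' covariate distributions (age, BMI, sex and smoking mix per group; LAM
#' all female, CF all never-smokers), multiplicative intensity shifts of
#' the 13 core informative ions relative to control (e.g. phenol m/z 95.05
#' and indole m/z 118.07 depressed in CF, m/z 71.06 elevated in COPD), and
#' the group-specific latent correlation structure with control hubs at
#' m/z 85.07, 85.10, 97.09, 97.10, 71.06 and 71.08.
#'
#' @param baseline Marginal target table, as from [defaultBaseline()].
#' @return Named list of five [GroupSpec-class] objects.
#' @export
defaultGroupSpecs <- function(baseline = defaultBaseline()) {
  core <- .CORE_TARGETS
  features <- baseline$feature
  shiftsFor <- function(meanCol) {
    s <- setNames(core[[meanCol]] / core$controlMean, core$feature)
    s[names(s) %in% features]
  }
  mk <- function(label, n, male, ageM, ageS, bmiM, bmiS, smoking, shifts) {
    new("GroupSpec", label = label, n = as.integer(n),
        ageMean = ageM, ageSd = ageS, bmiMean = bmiM, bmiSd = bmiS,
        maleProp = male,
        smokingProps = setNames(smoking / sum(smoking), .SMOKING_LEVELS),
        informativeShifts = shifts,
        correlationMatrix = .groupCorrelation(label, features))
  }
  list(
    BA = mk("BA", 160L, 56 / 160, 58.4, 17.1, 29.3, 8.5,
            c(85, 54, 21), shiftsFor("baMean")),
    COPD = mk("COPD", 128L, 111 / 128, 66.6, 10.3, 25.9, 5.8,
              c(25, 43, 60), shiftsFor("copdMean")),
    CF = mk("CF", 102L, 54 / 102, 25.6, 7.8, 19.8, 3.6,
            c(102, 0, 0), shiftsFor("cfMean")),
    LAM = mk("LAM", 51L, 0, 48.7, 10.9, 24.7, 5.1,
             c(50, 0, 1), shiftsFor("lamMean")),
    Control = mk("Control", 402L, 154 / 402, 39.1, 14.0, 25.0, 5.2,
                 c(281, 107, 14), setNames(numeric(0), character(0)))
  )
}

#' Default generator configuration
#'
#' @param seed Integer seed that fully determines the generated cohort.
#' @param nFeatures Total feature count (default 123).
#' @param noiseSd Log-scale per-observation noise SD (default 0.1).
#' @return A [GeneratorConfig-class].
#' @export
defaultGeneratorConfig <- function(seed = 1L, nFeatures = 123L, noiseSd = 0.1) {
  baseline <- defaultBaseline(nFeatures)
  new("GeneratorConfig", groups = defaultGroupSpecs(baseline),
      baseline = baseline, mzRange = c(42, 685),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Nearest positive-definite correlation matrix
#'
#' Projects a symmetric matrix onto the set of valid correlation matrices
#' (symmetric, unit diagonal, smallest eigenvalue >= `tol`).  Already-valid
#' input is returned unchanged, making the operation idempotent.
#'
#' @param m Symmetric square numeric matrix.
#' @param tol Minimum acceptable smallest eigenvalue (default 1e-8).
#' @return A positive-definite correlation matrix of the same dimension.
#' @export
nearestPositiveDefinite <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  if (max(abs(m - t(m))) > 1e-8) stop("input must be symmetric")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= tol && max(abs(diag(m) - 1)) < 1e-12) {
    return(m)
  }
  fixed <- as.matrix(Matrix::nearPD(m, corr = TRUE, eig.tol = 1e-10,
                                    conv.tol = 1e-13, maxit = 500L)$mat)
  fixed <- (fixed + t(fixed)) / 2
  # nearPD guarantees PSD; shrink toward the identity until the smallest
  # eigenvalue clears tol
  lam <- min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values)
  while (lam < tol) {
    w <- max(tol - lam, tol) * 1.1
    fixed <- (1 - w) * fixed + w * diag(nrow(fixed))
    lam <- min(eigen(fixed, symmetric = TRUE, only.values = TRUE)$values)
  }
  diag(fixed) <- 1
  dimnames(fixed) <- dimnames(m)
  fixed
}

#' Sample the clinical covariate block of one group
#'
#' Age and BMI are drawn from truncated normal distributions (age clipped
#' to 18-89 years, BMI to 13-60 kg/m^2) by inverse-CDF sampling; sex and
#' smoking status are drawn categorically from the group proportions.
#'
#' @param spec A [GroupSpec-class].
#' @param seed Integer seed; identical seeds give identical blocks.
#' @return data.frame with columns `age`, `sex`, `bmi`, `smoking`.
#' @export
sampleCovariates <- function(spec, seed) {
  stopifnot(is(spec, "GroupSpec"))
  validObject(spec)
  n <- spec@n
  .withSeed(seed, {
    rtrunc <- function(n, mean, sd, lo, hi) {
      pLo <- pnorm(lo, mean, sd)
      pHi <- pnorm(hi, mean, sd)
      qnorm(runif(n, pLo, pHi), mean, sd)
    }
    data.frame(
      age = rtrunc(n, spec@ageMean, spec@ageSd, 18, 89),
      sex = sample(.SEX_LEVELS, n, replace = TRUE,
                   prob = c(spec@maleProp, 1 - spec@maleProp)),
      bmi = rtrunc(n, spec@bmiMean, spec@bmiSd, 13, 60),
      smoking = sample(.SMOKING_LEVELS, n, replace = TRUE,
                       prob = spec@smokingProps),
      stringsAsFactors = FALSE
    )
  })
}

#' Sample the VOC intensity block of one group
#'
#' Draws a latent multivariate normal with the group's correlation matrix
#' (Gaussian copula), maps each marginal to a lognormal whose mean matches
#' the control target times the group's informative shift (SD scales
#' proportionally), and multiplies in log-scale observation noise.  All
#' intensities are strictly positive.
#'
#' @param spec A [GroupSpec-class].
#' @param baseline Marginal target table (`feature`, `mean`, `sd`), one row
#'   per feature; must match the dimension of the spec's correlation matrix.
#' @param seed Integer seed.
#' @param noiseSd Log-scale noise SD (default 0.1).
#' @return Numeric matrix, `spec@n` x `nrow(baseline)`.
#' @export
sampleVocMatrix <- function(spec, baseline, seed, noiseSd = 0.1) {
  stopifnot(is(spec, "GroupSpec"))
  p <- nrow(baseline)
  R <- spec@correlationMatrix
  if (nrow(R) != p) {
    stop("correlation matrix dimension ", nrow(R), " != feature count ", p)
  }
  lam <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (lam <= 0) {
    stop(sprintf("correlation matrix is not positive definite (smallest eigenvalue %.3e)",
                 lam))
  }
  shift <- rep(1, p)
  idx <- match(names(spec@informativeShifts), baseline$feature)
  shift[idx[!is.na(idx)]] <- spec@informativeShifts[!is.na(idx)]
  mTarget <- baseline$mean * shift
  cv <- baseline$sd / baseline$mean
  sigma2 <- log(1 + cv^2)
  mu <- log(mTarget) - sigma2 / 2
  .withSeed(seed, {
    Z <- matrix(rnorm(spec@n * p), spec@n, p) %*% chol(R)
    U <- pnorm(Z)
    X <- vapply(seq_len(p), function(j) qlnorm(U[, j], mu[j], sqrt(sigma2[j])),
                numeric(spec@n))
    X <- matrix(X, nrow = spec@n)
    if (noiseSd > 0) X <- X * exp(matrix(rnorm(spec@n * p, 0, noiseSd), spec@n, p))
    colnames(X) <- baseline$feature
    X
  })
}

#' Generate a complete synthetic breath cohort
#'
#' Concatenates all group blocks (843 participants under the default
#' configuration), shuffles the row order deterministically, and returns
#' the experiment together with the generating ground truth.
#'
#' @param config A [GeneratorConfig-class], e.g. [defaultGeneratorConfig()].
#' @return List with elements `experiment`
#'   ([BreathomicsExperiment-class]), `informative` (character vector of
#'   m/z labels with a planted shift in at least one group) and
#'   `correlations` (per-group latent correlation matrices).  The same
#'   ground truth is stored in `metadata(experiment)$groundTruth`.
#' @examples
#' cfg <- defaultGeneratorConfig(seed = 7, nFeatures = 40)
#' ds <- generateDataset(cfg)
#' ds$experiment
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  baseline <- config@baseline
  blocks <- lapply(config@groups, function(spec) {
    cov <- sampleCovariates(spec, .deriveSeed(config@seed, paste0("cov-", spec@label)))
    voc <- sampleVocMatrix(spec, baseline,
                           .deriveSeed(config@seed, paste0("voc-", spec@label)),
                           noiseSd = config@noiseSd)
    rownames(voc) <- sprintf("%s_%04d", spec@label, seq_len(spec@n))
    rownames(cov) <- rownames(voc)
    list(voc = voc, cov = cov, group = rep(spec@label, spec@n))
  })
  voc <- do.call(rbind, lapply(blocks, `[[`, "voc"))
  cov <- do.call(rbind, lapply(blocks, `[[`, "cov"))
  group <- unlist(lapply(blocks, `[[`, "group"), use.names = FALSE)
  ord <- .withSeed(.deriveSeed(config@seed, "shuffle"), sample(nrow(voc)))
  voc <- voc[ord, , drop = FALSE]
  cov <- cov[ord, , drop = FALSE]
  group <- group[ord]
  informative <- sort(unique(unlist(lapply(config@groups, function(s) {
    names(s@informativeShifts)[abs(s@informativeShifts - 1) > 1e-12]
  }))))
  correlations <- lapply(config@groups, slot, "correlationMatrix")
  gt <- list(informative = informative, correlations = correlations,
             seed = config@seed, noiseSd = config@noiseSd)
  exp <- BreathomicsExperiment(
    voc,
    data.frame(group = group, age = cov$age, sex = cov$sex, bmi = cov$bmi,
               smoking = cov$smoking, row.names = rownames(voc)),
    metadata = list(groundTruth = gt)
  )
  list(experiment = exp, informative = informative, correlations = correlations)
}
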