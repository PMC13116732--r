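test_that("default group specs reproduce the cohort composition", {
  specs <- defaultGroupSpecs(defaultBaseline(40))
  sizes <- vapply(specs, slot, integer(1L), "n")
  expect_equal(unname(sizes[c("BA", "COPD", "CF", "LAM", "Control")]),
               c(160L, 128L, 102L, 51L, 402L))
  expect_equal(sum(sizes), 843L)
  expect_identical(specs$LAM@maleProp, 0)
  expect_equal(unname(specs$CF@smokingProps["never"]), 1)
  # CF phenol-like ion depressed relative to control on the original scale
  expect_equal(unname(specs$CF@informativeShifts["95.05"]) * 0.213, 0.050,
               tolerance = 1e-6)
})

test_that("covariate sampling respects group constraints and seeds", {
  specs <- defaultGroupSpecs(defaultBaseline(35))
  lam <- sampleCovariates(specs$LAM, seed = 3)
  expect_true(all(lam$sex == "female"))
  cf <- sampleCovariates(specs$CF, seed = 3)
  expect_true(all(cf$smoking == "never"))
  expect_true(all(cf$age >= 18 & cf$age <= 89))
  expect_identical(sampleCovariates(specs$BA, seed = 9),
                   sampleCovariates(specs$BA, seed = 9))
  bad <- specs$BA
  bad@smokingProps <- c(never = 0.5, former = 0.2, current = 0.2)
  expect_error(sampleCovariates(bad, seed = 1), "summing to 1")
})

test_that("VOC sampling matches configured marginals and correlations", {
  base <- defaultBaseline(30)
  specs <- strippedSpecs(defaultGroupSpecs(base))
  ctrl <- specs$Control
  # marginal fidelity: noise-free control means within 3 SE of targets
  m <- sampleVocMatrix(ctrl, base, seed = 11, noiseSd = 0)
  expect_true(all(m > 0))
  core <- c("95.05", "118.07", "71.06", "85.07")
  for (f in core) {
    i <- match(f, base$feature)
    se <- base$sd[i] / sqrt(ctrl@n)
    expect_lt(abs(mean(m[, f]) - base$mean[i]), 3 * se)
  }
  # planted latent correlation 0.9 -> strong observed association
  b2 <- data.frame(feature = c("60.05", "61.05"), mz = c(60.05, 61.05),
                   mean = c(0.1, 0.1), sd = c(0.05, 0.05))
  g2 <- new("GroupSpec", label = "Control", n = 400L,
            ageMean = 40, ageSd = 10, bmiMean = 25, bmiSd = 4,
            maleProp = 0.5,
            smokingProps = setNames(c(1, 0, 0), c("never", "former", "current")),
            informativeShifts = setNames(numeric(0), character(0)),
            correlationMatrix = matrix(c(1, 0.9, 0.9, 1), 2))
  m2 <- sampleVocMatrix(g2, b2, seed = 21, noiseSd = 0)
  expect_gt(cor(m2[, 1L], m2[, 2L]), 0.7)
  # independence under the identity copula: near-zero distance correlation
  g0 <- g2; g0@correlationMatrix <- diag(2)
  m0 <- sampleVocMatrix(g0, b2, seed = 22, noiseSd = 0)
  expect_lt(distanceCorrelation(m0[, 1L], m0[, 2L]), 0.15)
  # non-positive-definite matrix is rejected, naming the eigenvalue
  gBad <- g2
  gBad@correlationMatrix <- matrix(c(1, 1, 1, 1), 2)
  expect_error(sampleVocMatrix(gBad, b2, seed = 1), "eigenvalue")
})

test_that("latent correlation recovery improves with sample size", {
  base <- defaultBaseline(29)
  specs <- strippedSpecs(defaultGroupSpecs(base))
  ctrl <- specs$Control
  R <- ctrl@correlationMatrix
  frob <- function(n, seed) {
    ctrl@n <- as.integer(n)
    m <- sampleVocMatrix(ctrl, base, seed = seed, noiseSd = 0)
    z <- apply(m, 2L, function(v) qnorm((rank(v) - 0.5) / length(v)))
    sqrt(sum((cor(z) - R)^2))
  }
  expect_lt(frob(400, 5), frob(100, 5))
})

test_that("nearest positive-definite projection is valid and idempotent", {
  expect_identical(nearestPositiveDefinite(diag(3)), diag(3))
  m <- matrix(c(1, 1.2, 1.2, 1), 2)
  fixed <- nearestPositiveDefinite(m)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 1e-8 - 1e-12))
  expect_lt(abs(fixed[1, 2]), 1.2)
  expect_equal(diag(fixed), c(1, 1))
  # random symmetric input
  set.seed(4)
  r <- matrix(runif(36, -1, 1), 6); r <- (r + t(r)) / 2; diag(r) <- 1
  f2 <- nearestPositiveDefinite(r)
  expect_true(all(eigen(f2, symmetric = TRUE, only.values = TRUE)$values >= 1e-8 - 1e-12))
  expect_identical(nearestPositiveDefinite(f2), f2)
  expect_error(nearestPositiveDefinite(matrix(1, 2, 3)), "square")
})

test_that("generated datasets are deterministic with correct shape", {
  cfg <- defaultGeneratorConfig(seed = 31, nFeatures = 35)
  ds1 <- generateDataset(cfg)
  ds2 <- generateDataset(cfg)
  expect_identical(intensityMatrix(ds1$experiment), intensityMatrix(ds2$experiment))
  expect_identical(as.character(diagnosisGroup(ds1$experiment)),
                   as.character(diagnosisGroup(ds2$experiment)))
  expect_equal(ncol(ds1$experiment), 843L)
  expect_equal(nrow(ds1$experiment), 35L)
  expect_true(all(ds1$informative %in% featureLabels(ds1$experiment)))
  expect_true(all(intensityMatrix(ds1$experiment) > 0))
  expect_false(anyNA(intensityMatrix(ds1$experiment)))
  # CF group mean of the phenol-like ion lies below control
  m <- intensityMatrix(ds1$experiment)
  g <- as.character(diagnosisGroup(ds1$experiment))
  expect_lt(mean(m[g == "CF", "95.05"]), mean(m[g == "Control", "95.05"]))
})
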