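test_that("Kendall sign captures monotone direction with ties", {
  x <- c(1, 2, 3, 4)
  expect_equal(kendallSign(x, x), 1)
  expect_equal(kendallSign(x, -x), -1)
  expect_equal(kendallSign(x, c(1, 3, 2, 4)), 1)  # 5 concordant, 1 discordant
  expect_equal(kendallSign(x, rep(2, 4)), 0)
  expect_equal(kendallSign(c(1, 2, 3, 4), c(1, 4, 2, 3)), 1)
})

test_that("distance correlation matches the brute-force double-centering oracle", {
  expect_equal(distanceCorrelation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(distanceCorrelation(1:10, rep(3, 10)), 0)
  x <- c(1, 2, 3, 10); y <- c(2, 1, 4, 9)
  expect_equal(distanceCorrelation(x, y), dcorBrute(x, y), tolerance = 1e-12)
  set.seed(31)
  for (r in 1:10) {
    n <- sample(5:50, 1L)
    a <- rnorm(n); b <- 0.5 * a^2 + rnorm(n, sd = 0.3)
    expect_equal(distanceCorrelation(a, b), dcorBrute(a, b), tolerance = 1e-12)
  }
})

test_that("signed distance correlation combines magnitude and direction", {
  x <- 1:12
  expect_equal(signedDistanceCorrelation(x, x), 1)
  expect_equal(signedDistanceCorrelation(x, -x), -1)
  set.seed(7)
  a <- rnorm(30); b <- rnorm(30)
  s <- signedDistanceCorrelation(a, b)
  expect_equal(abs(s), distanceCorrelation(a, b))
  expect_equal(s, signedDistanceCorrelation(b, a))
  expect_true(abs(s) <= 1)
})

test_that("bootstrap association matrices are symmetric and seeded", {
  set.seed(13)
  n <- 120
  z <- rnorm(n)
  block <- cbind(a = z + rnorm(n, sd = 0.1), b = -z + rnorm(n, sd = 0.1),
                 c = rnorm(n))
  scm <- bootstrapAssociationMatrix(block, nBoot = 60, seed = 4)
  m <- scm@matrix
  expect_identical(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), colnames(block)))
  expect_gt(m["a", "b"] * -1, 0.8)           # near-linear negative pair
  expect_lt(abs(m["a", "c"]), 0.4)           # independent pair stays small
  expect_equal(scm@subsampleSize, 40L)
  scm2 <- bootstrapAssociationMatrix(block, nBoot = 60, seed = 4)
  expect_identical(scm@matrix, scm2@matrix)
  # column order only relabels the result
  scm3 <- bootstrapAssociationMatrix(block[, c(2, 1, 3)], nBoot = 60, seed = 4)
  expect_equal(scm3@matrix["a", "b"], scm@matrix["a", "b"], tolerance = 0.15)
  expect_error(bootstrapAssociationMatrix(block[1:2, ], nBoot = 5, seed = 1),
               ">= 3")
})

test_that("network construction applies the strict epsilon rule", {
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  net0 <- buildNetwork(m)
  expect_equal(nrow(net0@edges), 0L)
  expect_identical(net0@nodes, letters[1:3])
  m["a", "b"] <- m["b", "a"] <- 0.4
  m["a", "c"] <- m["c", "a"] <- 1e-6   # exactly epsilon: excluded
  net <- buildNetwork(m, epsilon = 1e-6)
  expect_equal(nrow(net@edges), 1L)
  expect_equal(net@edges$weight, 0.4)
  m["b", "c"] <- m["c", "b"] <- -0.3
  net2 <- buildNetwork(m)
  expect_equal(sort(net2@edges$sign), c(-1, 1))
  expect_true(all(net2@edges$weight > 0))
})

test_that("centralities match small-graph oracles", {
  # path a-b-c: all betweenness mass on b
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- m["b", "a"] <- 0.8
  m["b", "c"] <- m["c", "b"] <- 0.5
  prof <- computeCentralities(buildNetwork(m))
  tab <- prof@table
  expect_equal(tab$betweenness[tab$node == "b"], 1)
  expect_equal(tab$betweenness[tab$node != "b"], c(0, 0))
  expect_equal(tab$weightedDegree, c(0.8, 1.3, 0.5))
  # Katz on the unit-weight 3-path: dense linear solve oracle
  mu <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  mu["a", "b"] <- mu["b", "a"] <- 1
  mu["b", "c"] <- mu["c", "b"] <- 1
  profU <- computeCentralities(buildNetwork(mu))
  alpha <- 0.9 / sqrt(2)
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  katzOracle <- solve(diag(3) - alpha * A, rep(1, 3))
  expect_equal(profU@table$katz, as.vector(katzOracle), tolerance = 1e-10)
  expect_equal(profU@alpha * profU@lambdaMax, 0.9, tolerance = 1e-10)
  # Katz residual invariant
  expect_lt(max(abs((diag(3) - alpha * A) %*% profU@table$katz - 1)), 1e-8)
  # complete equal-weight graph: full symmetry across nodes
  mc <- matrix(0.6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(mc) <- 0
  profC <- computeCentralities(buildNetwork(mc))
  for (col in c("weightedDegree", "betweenness", "eigenvector", "katz")) {
    expect_equal(max(profC@table[[col]]) - min(profC@table[[col]]), 0,
                 tolerance = 1e-9)
  }
  # min-max normalization spans [0, 1] for non-constant metrics
  expect_equal(range(prof@table$weightedDegreeNorm), c(0, 1))
  expect_true(all(prof@table$katzNorm >= 0 & prof@table$katzNorm <= 1))
  # edgeless network: all-zero centralities
  prof0 <- computeCentralities(buildNetwork(matrix(0, 2, 2,
    dimnames = list(c("x", "y"), c("x", "y")))))
  expect_true(all(prof0@table[, -1L] == 0))
})

test_that("weighted betweenness matches brute-force path enumeration", {
  set.seed(17)
  for (r in 1:5) {
    p <- sample(5:8, 1L)
    m <- matrix(0, p, p, dimnames = list(letters[1:p], letters[1:p]))
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < 0.5) m[i, j] <- m[j, i] <- runif(1, 0.1, 1)
    }
    net <- buildNetwork(m)
    if (nrow(net@edges) == 0L) next
    prof <- computeCentralities(net)
    oracle <- betweennessBrute(net)
    expect_equal(setNames(prof@table$betweenness, prof@table$node),
                 oracle, tolerance = 1e-9)
  }
})

test_that("deviation report flags strong remodeling against adaptive thresholds", {
  mkProfile <- function(vals) {
    tab <- data.frame(node = names(vals), weightedDegree = unname(vals),
                      betweenness = 0, eigenvector = 0, katz = 0)
    rng <- max(vals) - min(vals)
    tab$weightedDegreeNorm <- if (rng == 0) 0 else (unname(vals) - min(vals)) / rng
    tab$betweennessNorm <- tab$eigenvectorNorm <- tab$katzNorm <- 0
    new("CentralityProfile", table = tab, alpha = 0.5, lambdaMax = 1)
  }
  ctrl <- mkProfile(c(a = 1, b = 2, c = 3, d = 4))
  # control vs itself: identically zero, nothing flagged
  devSelf <- deviationReport(list(Control = ctrl, CF = ctrl))
  expect_true(all(devSelf@deviations$delta == 0))
  expect_false(any(devSelf@deviations$strong))
  # a genuine rewiring is flagged with the correct sign
  dis <- mkProfile(c(a = 4, b = 2, c = 3, d = 1))
  dev <- deviationReport(list(Control = ctrl, CF = dis))
  wd <- dev@deviations[dev@deviations$metric == "weightedDegree", ]
  expect_equal(wd$delta[wd$node == "a"], 1)
  expect_equal(wd$delta[wd$node == "d"], -1)
  expect_true(wd$strong[wd$node == "a"])
  expect_true(wd$strong[wd$node == "d"])
  thr <- dev@thresholds[dev@thresholds$metric == "weightedDegree", ]
  expect_lt(thr$lower, 0); expect_gt(thr$upper, 0)
  expect_error(deviationReport(list(Control = ctrl,
                                    CF = mkProfile(c(x = 1, y = 2, z = 3, w = 4)))),
               "node sets differ")
})

test_that("Cohen's d converts to the equivalent correlation", {
  expect_equal(cohensDToR(0), 0)
  expect_equal(round(cohensDToR(0.5), 4), 0.2425)
  d <- seq(0, 50, by = 0.5)
  r <- cohensDToR(d)
  expect_true(all(diff(r) > 0))
  expect_true(all(r < 1))
  expect_gt(cohensDToR(1000), 0.999)
})

test_that("maximal weighted clique agrees with exhaustive search", {
  # triangle above threshold
  m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m[upper.tri(m)] <- 0.5; m <- m + t(m)
  cl <- maxWeightedClique(buildNetwork(m), 0.24)
  expect_identical(cl@members, c("a", "b", "c"))
  expect_equal(cl@weight, 1.5)
  expect_false(cl@empty)
  # threshold above the maximum weight: empty flagged clique
  clEmpty <- maxWeightedClique(buildNetwork(m), 0.9)
  expect_true(clEmpty@empty)
  expect_equal(clEmpty@weight, 0)
  expect_length(clEmpty@members, 0L)
  # random graphs vs the brute-force subset oracle
  set.seed(23)
  for (r in 1:6) {
    p <- sample(6:10, 1L)
    mm <- matrix(0, p, p, dimnames = list(letters[1:p], letters[1:p]))
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      if (runif(1) < 0.6) mm[i, j] <- mm[j, i] <- round(runif(1, 0.05, 1), 3)
    }
    net <- buildNetwork(mm)
    thr <- runif(1, 0, 0.4)
    mine <- maxWeightedClique(net, thr)
    oracle <- cliqueBrute(net, thr)
    if (is.null(oracle$members) || length(oracle$members) == 0L) {
      expect_true(mine@empty)
    } else {
      expect_identical(mine@members, oracle$members)
      expect_equal(mine@weight, oracle$weight, tolerance = 1e-12)
    }
  }
})
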