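# Shared fixtures (built in code) and independent brute-force oracles.

# Tiny hand-built experiment: 3 groups, deterministic values.
tinyExperiment <- function(nPerGroup = 4L, nFeatures = 5L, seed = 1L) {
  withr::with_seed(seed, {
    groups <- rep(c("Control", "CF", "BA"), each = nPerGroup)
    n <- length(groups)
    m <- matrix(rlnorm(n * nFeatures, meanlog = -2, sdlog = 0.5), n, nFeatures)
    dimnames(m) <- list(sprintf("s%02d", seq_len(n)),
                        sprintf("%.2f", seq(50, 50 + nFeatures - 1) + 0.05))
    BreathomicsExperiment(m, data.frame(
      group = groups,
      age = round(runif(n, 20, 80)), sex = sample(c("male", "female"), n, TRUE),
      bmi = round(runif(n, 18, 35), 1),
      smoking = sample(c("never", "former", "current"), n, TRUE),
      row.names = rownames(m)))
  })
}

# Generator config with all default shifts removed.
strippedSpecs <- function(specs) {
  for (nm in names(specs)) {
    specs[[nm]]@informativeShifts <- setNames(numeric(0), character(0))
  }
  specs
}

# Multiplicative shift placing a group's mean nSd control-SDs above control.
shiftBySd <- function(baseline, features, nSd) {
  i <- match(features, baseline$feature)
  setNames(1 + nSd * baseline$sd[i] / baseline$mean[i], features)
}

# 5 planted informative VOCs among nFeatures - 5 nulls, default group sizes.
plantedConfig <- function(seed, nFeatures = 55L, nSd = 1.5) {
  base <- defaultBaseline(nFeatures)
  specs <- strippedSpecs(defaultGroupSpecs(base))
  planted <- base$feature[round(seq(10, nFeatures - 5, length.out = 5))]
  specs$BA@informativeShifts <- shiftBySd(base, planted[c(1L, 5L)], nSd)
  specs$COPD@informativeShifts <- shiftBySd(base, planted[2L], nSd)
  specs$CF@informativeShifts <- shiftBySd(base, planted[3L], nSd)
  specs$LAM@informativeShifts <- shiftBySd(base, planted[4L], nSd)
  cfg <- new("GeneratorConfig", groups = specs, baseline = base,
             mzRange = c(42, 685), noiseSd = 0.1, seed = as.integer(seed))
  list(config = cfg, planted = planted)
}

# Strongly separated 5-class cohort: each disease group has its own
# signature features shifted nSd control-SDs.
separatedConfig <- function(seed, nFeatures = 30L, nSd = 4) {
  base <- defaultBaseline(nFeatures)
  specs <- strippedSpecs(defaultGroupSpecs(base))
  nSig <- min(20L, nFeatures - 2L)
  sig <- split(base$feature[seq_len(nSig)], rep(1:4, length.out = nSig))
  specs$BA@informativeShifts <- shiftBySd(base, sig[[1L]], nSd)
  specs$COPD@informativeShifts <- shiftBySd(base, sig[[2L]], nSd)
  specs$CF@informativeShifts <- shiftBySd(base, sig[[3L]], nSd)
  specs$LAM@informativeShifts <- shiftBySd(base, sig[[4L]], nSd)
  new("GeneratorConfig", groups = specs, baseline = base,
      mzRange = c(42, 685), noiseSd = 0.1, seed = as.integer(seed))
}

# ---- independent oracles (kept naive on purpose) -------------------------

# Distance correlation by explicit double-centering loops.
dcorBrute <- function(x, y) {
  n <- length(x)
  a <- abs(outer(x, x, "-")); b <- abs(outer(y, y, "-"))
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- a[i, j] - mean(a[i, ]) - mean(a[, j]) + mean(a)
    B[i, j] <- b[i, j] - mean(b[i, ]) - mean(b[, j]) + mean(b)
  }
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2; dvy <- sum(B * B) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvx * dvy))
}

# Maximum-total-weight clique by exhaustive subset enumeration (<= 12 nodes),
# with the same tie rules as the implementation.
cliqueBrute <- function(net, rThreshold) {
  e <- net@edges[net@edges$weight >= rThreshold, , drop = FALSE]
  if (nrow(e) == 0L) return(list(members = character(), weight = 0))
  nodes <- sort(unique(c(e$from, e$to)))
  p <- length(nodes)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  A[cbind(e$from, e$to)] <- e$weight
  A[cbind(e$to, e$from)] <- e$weight
  best <- NULL
  for (mask in seq_len(2^p - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
    if (length(idx) < 2L) next
    sub <- A[idx, idx, drop = FALSE]
    if (any(sub[upper.tri(sub)] == 0)) next
    w <- sum(sub) / 2
    members <- nodes[idx]
    if (is.null(best) || w > best$weight + 1e-12 ||
        (abs(w - best$weight) <= 1e-12 &&
         (length(members) > length(best$members) ||
          (length(members) == length(best$members) &&
           paste(members, collapse = "|") < paste(best$members, collapse = "|"))))) {
      best <- list(members = members, weight = w)
    }
  }
  best
}

# Pair-normalized weighted betweenness by exhaustive simple-path
# enumeration (<= 8 nodes); edge length 1 / weight.
betweennessBrute <- function(net) {
  nodes <- net@nodes
  p <- length(nodes)
  L <- matrix(Inf, p, p, dimnames = list(nodes, nodes))
  e <- net@edges
  L[cbind(e$from, e$to)] <- 1 / e$weight
  L[cbind(e$to, e$from)] <- 1 / e$weight
  allPaths <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1L]] <<- list(path = path, len = len); return() }
      for (nxt in nodes[is.finite(L[last, ]) & !(nodes %in% path)]) {
        walk(c(path, nxt), len + L[last, nxt])
      }
    }
    walk(s, 0)
    out
  }
  btw <- setNames(numeric(p), nodes)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    paths <- allPaths(nodes[i], nodes[j])
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1L), "len")
    short <- paths[lens <= min(lens) + 1e-9]
    for (v in setdiff(nodes, c(nodes[i], nodes[j]))) {
      through <- sum(vapply(short, function(pp) v %in% pp$path, TRUE))
      btw[v] <- btw[v] + through / length(short)
    }
  }
  btw / ((p - 1) * (p - 2) / 2)
}

# Youden J by dense threshold scan (all observed scores and midpoints).
youdenBruteMaxJ <- function(scores, positive) {
  u <- sort(unique(scores))
  cand <- unique(c(-Inf, u, (u[-length(u)] + u[-1L]) / 2, Inf))
  max(vapply(cand, function(t) {
    mean(scores[positive] >= t) + mean(scores[!positive] < t) - 1
  }, numeric(1L)))
}
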