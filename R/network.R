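# Weighted signed VOC networks: construction, centralities, deviation from
# the control network with adaptive thresholds, and maximal weighted
# cliques.

#' Build a VOC network from a signed association matrix
#'
#' Nodes are the matrix labels; an edge (i, j) is included iff the
#' absolute signed correlation strictly exceeds `epsilon`.  Edge weight is
#' the absolute value, the sign is retained.  Isolated nodes are kept.
#'
#' @param m A [SignedCorrelationMatrix-class] or symmetric numeric matrix.
#' @param epsilon Strict inclusion cutoff (default 1e-6).
#' @return A [VOCNetwork-class].
#' @export
buildNetwork <- function(m, epsilon = 1e-6) {
  if (is(m, "SignedCorrelationMatrix")) m <- m@matrix
  stopifnot(nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-10) stop("matrix must be symmetric")
  nodes <- colnames(m)
  if (is.null(nodes)) nodes <- as.character(seq_len(ncol(m)))
  idx <- which(upper.tri(m) & abs(m) > epsilon, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = abs(m[idx]), sign = sign(m[idx]),
                      stringsAsFactors = FALSE)
  new("VOCNetwork", nodes = nodes, edges = edges, epsilon = epsilon)
}

# igraph view of a VOCNetwork (absolute weights as the 'weight' attribute).
.asIgraph <- function(net) {
  igraph::graph_from_data_frame(net@edges[, c("from", "to", "weight")],
                                directed = FALSE,
                                vertices = data.frame(name = net@nodes))
}

# Absolute-weight adjacency matrix in node order.
.adjacency <- function(net) {
  p <- length(net@nodes)
  A <- matrix(0, p, p, dimnames = list(net@nodes, net@nodes))
  e <- net@edges
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  A
}

# Power iteration for the leading eigenvector of a symmetric non-negative
# matrix; returns the unit vector and the Rayleigh quotient on A.  A
# positive diagonal shift keeps the dominant eigenvalue strictly separated
# on bipartite graphs (where the spectrum is symmetric about 0) without
# changing the eigenvectors.
.powerIteration <- function(A, tol = 1e-10, maxIter = 1e4L) {
  p <- nrow(A)
  shift <- max(rowSums(A)) / 2 + 1
  B <- A + diag(shift, p)
  x <- rep(1 / sqrt(p), p)
  for (it in seq_len(maxIter)) {
    y <- B %*% x
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(list(vector = rep(0, p), value = 0, iterations = it))
    y <- as.vector(y) / ny
    if (max(abs(y - x)) < tol) {
      return(list(vector = y, value = as.vector(t(y) %*% A %*% y), iterations = it))
    }
    x <- y
  }
  stop("power iteration did not converge within ", maxIter, " iterations")
}

#' Compute weighted node centralities
#'
#' Four centralities per node: weighted degree (sum of incident absolute
#' weights), weighted betweenness (proportion of shortest paths through
#' the node, edge length = 1 / |w| so stronger associations are shorter;
#' the complement length 1 - |w| is available via `lengthTransform`),
#' eigenvector centrality of the absolute-weight adjacency (power
#' iteration, tolerance 1e-10), and Katz centrality with attenuation
#' alpha = 0.9 / lambda_max, obtained by solving (I - alpha A) x = 1.
#' Each metric is additionally min-max normalized across nodes to [0, 1]
#' (a constant metric normalizes to all zeros).  An edgeless network has
#' all centralities 0.
#'
#' @param net A [VOCNetwork-class].
#' @param lengthTransform `"reciprocal"` (default) or `"complement"` edge
#'   length for betweenness.
#' @return A [CentralityProfile-class].
#' @export
computeCentralities <- function(net, lengthTransform = c("reciprocal", "complement")) {
  stopifnot(is(net, "VOCNetwork"), length(net@nodes) > 0L)
  lengthTransform <- match.arg(lengthTransform)
  p <- length(net@nodes)
  if (nrow(net@edges) == 0L) {
    zero <- setNames(rep(0, p), net@nodes)
    tab <- data.frame(node = net@nodes, weightedDegree = 0, betweenness = 0,
                      eigenvector = 0, katz = 0, weightedDegreeNorm = 0,
                      betweennessNorm = 0, eigenvectorNorm = 0, katzNorm = 0,
                      stringsAsFactors = FALSE)
    return(new("CentralityProfile", table = tab, alpha = 0, lambdaMax = 0))
  }
  g <- .asIgraph(net)
  wd <- igraph::strength(g, weights = igraph::E(g)$weight)
  len <- if (lengthTransform == "reciprocal") 1 / igraph::E(g)$weight
         else 1 - igraph::E(g)$weight
  btw <- igraph::betweenness(g, weights = len, normalized = TRUE)
  A <- .adjacency(net)
  pi <- .powerIteration(A)
  eig <- abs(pi$vector)
  lambdaMax <- max(pi$value, max(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
  alpha <- 0.9 / lambdaMax
  katz <- as.vector(solve(diag(p) - alpha * A, rep(1, p)))
  minmax <- function(v) {
    r <- max(v) - min(v)
    if (r == 0) rep(0, length(v)) else (v - min(v)) / r
  }
  ord <- net@nodes
  tab <- data.frame(node = ord,
                    weightedDegree = unname(wd[ord]),
                    betweenness = unname(btw[ord]),
                    eigenvector = eig, katz = katz,
                    stringsAsFactors = FALSE)
  tab$weightedDegreeNorm <- minmax(tab$weightedDegree)
  tab$betweennessNorm <- minmax(tab$betweenness)
  tab$eigenvectorNorm <- minmax(tab$eigenvector)
  tab$katzNorm <- minmax(tab$katz)
  new("CentralityProfile", table = tab, alpha = alpha, lambdaMax = lambdaMax)
}

.METRICS <- c(weightedDegree = "weightedDegreeNorm",
              betweenness = "betweennessNorm",
              eigenvector = "eigenvectorNorm",
              katz = "katzNorm")

#' Centrality deviations from the control network with adaptive thresholds
#'
#' For every disease group, metric and node, the deviation is the min-max
#' normalized centrality in the disease network minus the corresponding
#' normalized value in the control network.  Per metric, the signed
#' deviations of all nodes in all non-control groups are pooled and the
#' 5th/95th percentiles of that distribution define the adaptive lower and
#' upper thresholds; nodes are flagged strong iff their deviation falls
#' strictly outside the thresholds.  A control-vs-control comparison is
#' identically zero and never flagged.
#'
#' @param profiles Named list of [CentralityProfile-class] objects with
#'   identical node sets, including the control group.
#' @param controlLabel Name of the control entry (default `"Control"`).
#' @param percentiles Length-2 percentile pair (default c(5, 95)).
#' @return A [DeviationReport-class].
#' @export
deviationReport <- function(profiles, controlLabel = "Control",
                            percentiles = c(5, 95)) {
  stopifnot(controlLabel %in% names(profiles))
  nodes <- profiles[[controlLabel]]@table$node
  for (nm in names(profiles)) {
    if (!identical(sort(profiles[[nm]]@table$node), sort(nodes))) {
      stop("node sets differ between groups: ", nm)
    }
  }
  ctrl <- profiles[[controlLabel]]@table
  diseases <- setdiff(names(profiles), controlLabel)
  rows <- list()
  for (grp in diseases) {
    dtab <- profiles[[grp]]@table
    dtab <- dtab[match(nodes, dtab$node), ]
    for (metric in names(.METRICS)) {
      col <- .METRICS[[metric]]
      rows[[paste(grp, metric)]] <- data.frame(
        group = grp, metric = metric, node = nodes,
        delta = dtab[[col]] - ctrl[[col]],
        stringsAsFactors = FALSE)
    }
  }
  dev <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  thresholds <- do.call(rbind, lapply(names(.METRICS), function(metric) {
    pooled <- dev$delta[dev$metric == metric]
    q <- .pctl(pooled, percentiles / 100)
    data.frame(metric = metric, lower = q[1L], upper = q[2L],
               stringsAsFactors = FALSE)
  }))
  dev$strong <- FALSE
  for (k in seq_len(nrow(thresholds))) {
    sel <- dev$metric == thresholds$metric[k]
    dev$strong[sel] <- dev$delta[sel] < thresholds$lower[k] |
      dev$delta[sel] > thresholds$upper[k]
  }
  new("DeviationReport", deviations = dev, thresholds = thresholds,
      controlLabel = controlLabel)
}

#' Convert Cohen's d to an equivalent correlation coefficient
#'
#' Equal-group-size point-biserial conversion r = d / sqrt(d^2 + 4);
#' monotone in d with r -> 1 as d grows.
#'
#' @param d Standardized mean difference, d >= 0.
#' @return Correlation r in [0, 1).
#' @export
cohensDToR <- function(d) {
  stopifnot(all(d >= 0))
  d / sqrt(d^2 + 4)
}

#' Maximal weighted clique at a correlation threshold
#'
#' Keeps edges with weight >= `rThreshold` (absolute weights; direction is
#' irrelevant for clustering), enumerates all maximal cliques
#' (Bron-Kerbosch with pivoting) and returns the clique with the maximum
#' total edge weight.  Ties go to the larger clique, then the
#' lexicographically smallest node set.  If no edge survives, an empty
#' flagged clique of weight 0 is returned.
#'
#' @param net A [VOCNetwork-class].
#' @param rThreshold Edge-inclusion threshold >= 0, typically
#'   [cohensDToR()] of a moderate effect size (d = 0.5).
#' @param group Optional diagnosis label recorded in the result.
#' @return A [CliqueResult-class].
#' @export
maxWeightedClique <- function(net, rThreshold, group = NA_character_) {
  stopifnot(is(net, "VOCNetwork"), rThreshold >= 0)
  e <- net@edges[net@edges$weight >= rThreshold, , drop = FALSE]
  if (nrow(e) == 0L) {
    return(new("CliqueResult", members = character(), weight = 0,
               rThreshold = rThreshold, group = as.character(group),
               empty = TRUE))
  }
  sub <- new("VOCNetwork", nodes = sort(unique(c(e$from, e$to))),
             edges = e, epsilon = net@epsilon)
  g <- .asIgraph(sub)
  A <- .adjacency(sub)
  cliques <- igraph::max_cliques(g, min = 2L)
  best <- NULL
  for (cl in cliques) {
    members <- sort(igraph::V(g)$name[cl])
    w <- sum(A[members, members]) / 2
    if (is.null(best) ||
        w > best$weight + 1e-12 ||
        (abs(w - best$weight) <= 1e-12 &&
         (length(members) > length(best$members) ||
          (length(members) == length(best$members) &&
           paste(members, collapse = "|") < paste(best$members, collapse = "|"))))) {
      best <- list(members = members, weight = w)
    }
  }
  new("CliqueResult", members = best$members, weight = best$weight,
      rThreshold = rThreshold, group = as.character(group), empty = FALSE)
}

#' Export a network as a signed edge list
#'
#' @param net A [VOCNetwork-class].
#' @param path Output CSV path (`node_i`, `node_j`, `weight`, `sign`).
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "VOCNetwork"))
  e <- net@edges
  write.csv(data.frame(node_i = e$from, node_j = e$to,
                       weight = e$weight, sign = e$sign),
            path, row.names = FALSE)
  invisible(path)
}

#' @importFrom utils write.csv
NULL
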