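#' Binarize the node-partner correlation structure
#'
#' Computes Pearson correlations between every candidate gene (node) and every
#' background feature (partner) on the analysis scale, then thresholds the
#' absolute correlations into a binary incidence matrix `M`, where each
#' partner column that links several nodes acts as a hyperedge joining them.
#' The default rule sets the threshold at `mean(|r|) + k * sd(|r|)` over all
#' node-partner pairs (k = 1), a standard hypernetwork convention; an absolute
#' threshold or an upper-quantile rule can be chosen instead. Constant
#' features get correlation 0 with a warning.
#'
#' @param expr [OmicsMatrix-class] or matrix, features x samples.
#' @param nodes character vector of node feature IDs (must be features of
#'   `expr`).
#' @param partners partner feature IDs; default all features except the nodes.
#' @param rule `"mean_sd"`, `"absolute"` or `"quantile"`.
#' @param k SD multiplier for `"mean_sd"`.
#' @param threshold absolute |r| cut-off for `"absolute"`.
#' @param quantile upper quantile of |r| for `"quantile"`.
#' @param scale analysis scale (see [detectDifferential()]).
#' @return binary integer matrix, nodes x partners, with the applied cut-off
#'   in attribute `"threshold"`. Entries are 1 where |r| strictly exceeds it.
#' @export
binarizeCorrelations <- function(expr, nodes, partners = NULL,
                                 rule = c("mean_sd", "absolute", "quantile"),
                                 k = 1, threshold = NULL, quantile = 0.95,
                                 scale = "auto") {
  rule <- match.arg(rule)
  v <- analysisScale(expr, scale)
  if (!all(nodes %in% rownames(v)))
    stop("some nodes are not features of 'expr'")
  if (is.null(partners)) partners <- setdiff(rownames(v), nodes)
  if (!all(partners %in% rownames(v)))
    stop("some partners are not features of 'expr'")
  r <- suppressWarnings(
    stats::cor(t(v[nodes, , drop = FALSE]), t(v[partners, , drop = FALSE])))
  if (anyNA(r)) {
    warning("constant feature(s): their correlations are set to 0")
    r[is.na(r)] <- 0
  }
  a <- abs(r)
  thr <- switch(rule,
                mean_sd = mean(a) + k * stats::sd(a),
                absolute = threshold,
                quantile = stats::quantile(a, quantile, names = FALSE))
  if (is.null(thr)) stop("rule 'absolute' needs 'threshold'")
  M <- matrix(as.integer(a > thr), nrow(a), ncol(a), dimnames = dimnames(a))
  attr(M, "threshold") <- thr
  M
}

#' Shared-partner adjacency of a hypergraph
#'
#' `A[i, k]` counts the partners j with `M[i, j] = M[k, j] = 1`, i.e. how many
#' hyperedges join nodes i and k. Computed exactly in integer arithmetic as
#' `M %*% t(M)` with the diagonal zeroed (so self-counts never dominate
#' centrality).
#'
#' @param M binary incidence matrix (nodes x partners).
#' @return symmetric integer matrix, zero diagonal.
#' @examples
#' M <- rbind(a = c(1, 1, 0, 0), b = c(0, 1, 1, 0), c = c(1, 1, 1, 0))
#' hypergraphAdjacency(M)
#' @export
hypergraphAdjacency <- function(M) {
  M <- as.matrix(M)
  if (length(M) && !all(M %in% c(0, 1)))
    stop("'M' must be binary")
  storage.mode(M) <- "integer"
  A <- tcrossprod(M)
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  A
}

#' Extract the central cluster of a hypergraph
#'
#' Hierarchically clusters the rows of the shared-partner adjacency (Ward
#' linkage on Euclidean distances), picks the number of clusters k in
#' `kRange` by the largest average silhouette width, and declares central the
#' cluster with the highest median within-cluster adjacency — the node subset
#' sharing the most correlated partners. Ties go to the larger cluster, then
#' to the cluster containing the lexicographically smallest node. An all-zero
#' adjacency yields a single cluster flagged as having no structure; a single
#' node is its own central cluster.
#'
#' @param A adjacency matrix from [hypergraphAdjacency()] (or a
#'   [Hypergraph-class], whose slots are then filled in).
#' @param kRange candidate cluster counts (default 2..6, bounded by n - 1).
#' @param linkage hclust method (default `"ward.D2"`).
#' @return a list with `centralCluster`, `clusterLabels`, `noStructure` — or,
#'   when called on a [Hypergraph-class], the updated object.
#' @export
extractCentralCluster <- function(A, kRange = 2:6, linkage = "ward.D2") {
  if (is(A, "Hypergraph")) {
    res <- extractCentralCluster(A@adjacency, kRange, linkage)
    A@clusterLabels <- res$clusterLabels
    A@centralCluster <- res$centralCluster
    A@noStructure <- res$noStructure
    return(A)
  }
  n <- nrow(A)
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0L)
    return(list(centralCluster = character(), clusterLabels = integer(),
                noStructure = TRUE))
  if (n == 1L)
    return(list(centralCluster = ids,
                clusterLabels = stats::setNames(1L, ids),
                noStructure = all(A == 0)))
  if (all(A == 0)) {
    warning("all-zero adjacency: no structure; returning a single cluster")
    return(list(centralCluster = ids,
                clusterLabels = stats::setNames(rep(1L, n), ids),
                noStructure = TRUE))
  }
  d <- stats::dist(A)
  hc <- stats::hclust(d, method = linkage)
  kRange <- kRange[kRange >= 2 & kRange <= n - 1]
  if (!length(kRange)) kRange <- 2L
  sil <- vapply(kRange, function(k) {
    lab <- stats::cutree(hc, k)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  labels <- stats::cutree(hc, kRange[which.max(sil)])
  names(labels) <- ids

  medianWithin <- function(members) {
    if (length(members) < 2L) return(0)
    sub <- A[members, members, drop = FALSE]
    stats::median(sub[upper.tri(sub)])
  }
  byCluster <- split(ids, labels)
  score <- vapply(byCluster, medianWithin, numeric(1))
  size <- lengths(byCluster)
  first <- vapply(byCluster, function(m) min(m), character(1))
  ord <- order(-score, -size, first)
  central <- byCluster[[ord[1]]]
  list(centralCluster = central, clusterLabels = labels, noStructure = FALSE)
}

#' Build a hypergraph over a candidate gene set
#'
#' Convenience constructor running [binarizeCorrelations()],
#' [hypergraphAdjacency()] and [extractCentralCluster()] in sequence.
#'
#' @inheritParams binarizeCorrelations
#' @inheritParams extractCentralCluster
#' @param ... passed to [binarizeCorrelations()].
#' @return a [Hypergraph-class].
#' @export
buildHypergraph <- function(expr, nodes, partners = NULL, kRange = 2:6,
                            linkage = "ward.D2", ...) {
  M <- binarizeCorrelations(expr, nodes, partners, ...)
  A <- hypergraphAdjacency(M)
  res <- extractCentralCluster(A, kRange, linkage)
  thr <- attr(M, "threshold")
  attr(M, "threshold") <- NULL
  new("Hypergraph",
      nodeIds = rownames(M), partnerIds = colnames(M),
      incidence = M, adjacency = A,
      clusterLabels = res$clusterLabels,
      centralCluster = res$centralCluster,
      threshold = thr, noStructure = res$noStructure)
}

#' @rdname Hypergraph-class
#' @export
setMethod("nodeIds", "Hypergraph", function(x) x@nodeIds)
#' @rdname Hypergraph-class
#' @export
setMethod("partnerIds", "Hypergraph", function(x) x@partnerIds)
#' @rdname Hypergraph-class
#' @export
setMethod("incidenceMatrix", "Hypergraph", function(x) x@incidence)
#' @rdname Hypergraph-class
#' @export
setMethod("adjacencyMatrix", "Hypergraph", function(x) x@adjacency)
#' @rdname Hypergraph-class
#' @export
setMethod("clusterLabels", "Hypergraph", function(x) x@clusterLabels)
#' @rdname Hypergraph-class
#' @export
setMethod("centralCluster", "Hypergraph", function(x) x@centralCluster)

setMethod("show", "Hypergraph", function(object) {
  cat(sprintf("Hypergraph: %d nodes x %d partners (|r| > %.4f)\n",
              length(object@nodeIds), length(object@partnerIds),
              object@threshold))
  k <- length(unique(object@clusterLabels))
  cat(sprintf("%d cluster(s); central cluster: %d gene(s)%s\n", k,
              length(object@centralCluster),
              if (object@noStructure) " [no structure]" else ""))
})

#' Jaccard index of two sets
#'
#' @param a,b vectors treated as sets.
#' @return |intersection| / |union| (1 when both are empty).
#' @export
jaccardIndex <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}
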