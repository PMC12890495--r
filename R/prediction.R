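#' Random-forest configuration
#'
#' @param nTrees number of trees (default 1000, the size used throughout the
#'   analysis).
#' @param mtry variables tried per split; default `floor(sqrt(p))`.
#' @param minLeaf minimum terminal-node size.
#' @param seed RNG seed, recorded in every report.
#' @param importanceMode `"impurity"` (mean decrease in Gini) or
#'   `"permutation"` (mean decrease in accuracy).
#' @param stratified use a stratified bootstrap (equal draws per class) to
#'   counter class imbalance; default plain bootstrap.
#' @return list of class `RFConfig`.
#' @export
rfConfig <- function(nTrees = 1000L, mtry = NULL, minLeaf = 1L, seed = 1L,
                     importanceMode = c("impurity", "permutation"),
                     stratified = FALSE) {
  importanceMode <- match.arg(importanceMode)
  if (nTrees < 1L) stop("'nTrees' must be >= 1")
  structure(list(nTrees = as.integer(nTrees), mtry = mtry,
                 minLeaf = as.integer(minLeaf), seed = as.integer(seed),
                 importanceMode = importanceMode, stratified = stratified),
            class = "RFConfig")
}

# Fit a forest and return it plus per-sample positive-class OOB votes.
fitForest <- function(X, y, cfg, needImportance = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("'y' must have exactly two classes")
  if (any(table(y) < 2L)) stop("both classes need at least 2 samples")
  if (anyNA(X)) stop("missing values in 'X'; impute before training")
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(ncol(X)))) else cfg$mtry
  args <- list(x = X, y = y, ntree = cfg$nTrees, mtry = mtry,
               nodesize = cfg$minLeaf,
               importance = needImportance &&
                 cfg$importanceMode == "permutation",
               keep.forest = FALSE)
  if (isTRUE(cfg$stratified)) {
    nmin <- min(table(y))
    args$strata <- y
    args$sampsize <- c(nmin, nmin)
  }
  rf <- do.call(randomForest::randomForest, args)
  pos <- levels(y)[2]
  votes <- rf$votes[, pos]
  names(votes) <- rownames(X)
  imp <- if (cfg$importanceMode == "permutation")
    rf$importance[, "MeanDecreaseAccuracy"]
  else rf$importance[, "MeanDecreaseGini"]
  list(rf = rf, votes = votes, importance = imp, positive = pos, y = y)
}

#' Train a random forest and report out-of-bag performance
#'
#' Each tree is grown on a bootstrap sample; the samples a tree never saw
#' (out-of-bag) vote on it, giving every subject an internal test prediction.
#' The per-sample positive-class OOB vote fraction yields the confusion matrix
#' at the 0.5 vote threshold, the OOB error rate, and a ROC curve with
#' trapezoidal AUC over all vote thresholds.
#'
#' @param X samples x features numeric matrix (no missing values).
#' @param y binary labels (factor/logical/0-1); the second level is positive.
#' @param cfg an [rfConfig()].
#' @return an [RFReport-class].
#' @export
trainRFOOB <- function(X, y, cfg = rfConfig()) {
  set.seed(cfg$seed)
  fit <- fitForest(X, y, cfg)
  votes <- fit$votes
  y <- fit$y
  ok <- !is.na(votes)
  if (any(!ok)) {
    warning(sum(!ok), " sample(s) had no OOB trees; excluded from metrics")
    votes <- votes[ok]; y <- y[ok]
  }
  pred <- factor(ifelse(votes > 0.5, levels(y)[2], levels(y)[1]),
                 levels = levels(y))
  cm <- table(truth = y, prediction = pred)
  cm <- matrix(as.integer(cm), 2, 2, dimnames = dimnames(cm))
  roc <- oobRocAuc(votes, y == levels(y)[2])
  new("RFReport",
      oobConfusion = cm,
      oobErrorRate = (cm[1, 2] + cm[2, 1]) / sum(cm),
      roc = roc$roc, auc = roc$auc,
      importance = fit$importance,
      oobVotes = votes,
      positiveClass = fit$positive,
      config = unclass(cfg))
}

#' ROC curve and AUC from out-of-bag votes
#'
#' Sweeps every distinct score as a threshold (score at or above the
#' threshold predicts positive), records (FPR, TPR) points, and integrates by
#' the trapezoidal rule. Tied scores contribute half-credit, so the AUC equals
#' the normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores in \[0, 1\] (e.g. OOB vote fractions).
#' @param y binary truth (logical or coercible; `TRUE`/second level positive).
#' @return list with `auc` and `roc` (data.frame `fpr`, `tpr`, ordered from
#'   (0,0) to (1,1)).
#' @examples
#' oobRocAuc(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))$auc  # 0.75
#' @export
oobRocAuc <- function(scores, y) {
  if (is.factor(y)) y <- y == levels(y)[2]
  y <- as.logical(y)
  if (length(scores) != length(y)) stop("'scores' and 'y' lengths differ")
  nPos <- sum(y); nNeg <- sum(!y)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC undefined: only one class present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y) / nPos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !y) / nNeg, numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Boruta all-relevant feature selection
#'
#' In each iteration every feature is duplicated as a "shadow" whose values
#' are independently permuted across samples (re-permuted every iteration), a
#' forest is fitted on the augmented matrix, and every real feature whose
#' importance exceeds the maximum shadow importance scores a hit. After
#' `nIterations`, a two-sided binomial test of the hit count against p = 0.5
#' classifies each feature: significantly more hits than half confirms it,
#' significantly fewer rejects it, anything else stays tentative.
#'
#' @param X samples x features matrix.
#' @param y binary labels.
#' @param cfg an [rfConfig()]; the default uses 300 trees per iteration.
#' @param nIterations shadow iterations (at least 10; default 100).
#' @param alpha two-sided significance level (default 0.05).
#' @return a [BorutaResult-class].
#' @export
borutaSelect <- function(X, y, cfg = rfConfig(nTrees = 300L),
                         nIterations = 100L, alpha = 0.05) {
  if (nIterations < 10L)
    stop("'nIterations' must be at least 10 (binomial test underpowered)")
  X <- as.matrix(X)
  p <- ncol(X)
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("f", seq_len(p))
  set.seed(cfg$seed)
  hits <- stats::setNames(integer(p), feats)
  for (it in seq_len(nIterations)) {
    shadow <- apply(X, 2, sample)
    colnames(shadow) <- paste0("shadow_", feats)
    fit <- fitForest(cbind(X, shadow), y, cfg)
    imp <- fit$importance
    maxShadow <- max(imp[colnames(shadow)])
    hits <- hits + (imp[feats] > maxShadow)
  }
  pHigh <- stats::pbinom(hits - 1L, nIterations, 0.5, lower.tail = FALSE)
  pLow <- stats::pbinom(hits, nIterations, 0.5)
  status <- ifelse(pHigh < alpha / 2, "confirmed",
                   ifelse(pLow < alpha / 2, "rejected", "tentative"))
  new("BorutaResult",
      status = factor(stats::setNames(status, feats),
                      levels = c("confirmed", "tentative", "rejected")),
      hitCounts = hits,
      nIterations = as.integer(nIterations),
      alpha = alpha)
}

#' Evaluate a trained gene set in an external cohort
#'
#' Mirrors the validation design: the gene set selected in the discovery
#' cohort is intersected with the validation cohort's features, a fresh
#' forest is fitted on the validation data restricted to those genes, and the
#' out-of-bag metrics serve as the test surface (no tree weights transfer).
#'
#' @param geneSet character vector of feature names selected in discovery.
#' @param XNew validation samples x features matrix.
#' @param yNew validation binary labels.
#' @param cfg an [rfConfig()].
#' @return an [RFReport-class]; the intersected gene set and its size are in
#'   attributes `"geneSet"` and `"nIntersected"`.
#' @export
predictExternal <- function(geneSet, XNew, yNew, cfg = rfConfig()) {
  XNew <- as.matrix(XNew)
  present <- intersect(geneSet, colnames(XNew))
  if (!length(present))
    stop("no genes of the trained set are present in the validation matrix")
  message(length(present), " of ", length(geneSet),
          " trained genes present in the validation cohort")
  report <- trainRFOOB(XNew[, present, drop = FALSE], yNew, cfg)
  attr(report, "geneSet") <- present
  attr(report, "nIntersected") <- length(present)
  report
}

#' @rdname RFReport-class
#' @export
setMethod("oobConfusion", "RFReport", function(x) x@oobConfusion)
#' @rdname RFReport-class
#' @export
setMethod("oobErrorRate", "RFReport", function(x) x@oobErrorRate)
#' @rdname RFReport-class
#' @export
setMethod("oobVotes", "RFReport", function(x) x@oobVotes)
#' @rdname RFReport-class
#' @export
setMethod("rocPoints", "RFReport", function(x) x@roc)
#' @rdname RFReport-class
#' @export
setMethod("oobAUC", "RFReport", function(x) x@auc)
#' @rdname RFReport-class
#' @export
setMethod("featureImportance", "RFReport", function(x) x@importance)

setMethod("show", "RFReport", function(object) {
  cat(sprintf("RFReport: OOB AUC %.3f, OOB error rate %.1f%% (positive: %s)\n",
              object@auc, 100 * object@oobErrorRate, object@positiveClass))
  print(object@oobConfusion)
})

#' @rdname BorutaResult-class
#' @export
setMethod("borutaStatus", "BorutaResult", function(x) x@status)
#' @rdname BorutaResult-class
#' @export
setMethod("hitCounts", "BorutaResult", function(x) x@hitCounts)

setMethod("show", "BorutaResult", function(object) {
  tab <- table(object@status)
  cat(sprintf("BorutaResult (%d iterations, alpha = %g): %d confirmed, %d tentative, %d rejected\n",
              object@nIterations, object@alpha,
              tab["confirmed"], tab["tentative"], tab["rejected"]))
})
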