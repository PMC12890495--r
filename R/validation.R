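#' Unsupervised k-means clustering of a transcriptome
#'
#' Lloyd's algorithm on samples in feature space, best of `nInit` random
#' initializations by total within-cluster sum of squares. Features are
#' z-scored per gene by default (configurable; zero-variance features are
#' dropped).
#'
#' @param expr [OmicsMatrix-class] or matrix (features x samples).
#' @param k number of clusters (default 2).
#' @param nInit random starts (default 25).
#' @param seed RNG seed.
#' @param standardize z-score each feature before clustering.
#' @param scale analysis scale (see [detectDifferential()]).
#' @return list with `labels` (named integer vector) and the
#'   [stats::kmeans()] fit.
#' @export
kmeansClusters <- function(expr, k = 2L, nInit = 25L, seed = 1L,
                           standardize = TRUE, scale = "auto") {
  X <- t(analysisScale(expr, scale))
  if (k > nrow(X))
    stop("k (", k, ") exceeds the number of samples (", nrow(X), ")")
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  set.seed(seed)
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, nrow(X)), rownames(X))
    return(list(labels = labels, fit = NULL))
  }
  fit <- stats::kmeans(X, centers = k, nstart = nInit,
                       algorithm = "Lloyd", iter.max = 100L)
  list(labels = stats::setNames(fit$cluster, rownames(X)), fit = fit)
}

#' Two-group phenotype contrasts
#'
#' For each marker, picks a two-sided Student's t test when Shapiro-Wilk finds
#' both groups compatible with normality (at 0.05), otherwise a Mann-Whitney U
#' test; either test can be forced. Markers absent from the table or with
#' fewer than 2 observations in a group are skipped with a warning.
#'
#' @param labels two-level grouping, one per row of `pheno`.
#' @param pheno data.frame of markers.
#' @param markers character vector of column names to contrast.
#' @param testPolicy `"auto"`, `"t"`, or `"mann-whitney"`.
#' @return data.frame with per-group summaries (mean, sd, median, range, n),
#'   `test_used`, `p_value` and `direction` (sign of group 2 minus group 1
#'   difference in medians).
#' @export
contrastGroups <- function(labels, pheno, markers,
                           testPolicy = c("auto", "t", "mann-whitney")) {
  testPolicy <- match.arg(testPolicy)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("'labels' must define two groups")
  res <- lapply(markers, function(m) {
    if (!m %in% names(pheno)) {
      warning("marker '", m, "' absent; skipped")
      return(NULL)
    }
    x <- pheno[[m]]
    g1 <- x[labels == levels(labels)[1]]; g1 <- g1[!is.na(g1)]
    g2 <- x[labels == levels(labels)[2]]; g2 <- g2[!is.na(g2)]
    if (length(g1) < 2L || length(g2) < 2L) {
      warning("marker '", m, "' has a group with < 2 observations; skipped")
      return(NULL)
    }
    test <- testPolicy
    if (test == "auto") {
      normal <- vapply(list(g1, g2), function(g) {
        if (length(g) < 3L || stats::sd(g) == 0) return(FALSE)
        stats::shapiro.test(g[seq_len(min(length(g), 5000L))])$p.value > 0.05
      }, logical(1))
      test <- if (all(normal)) "t" else "mann-whitney"
    }
    p <- if (test == "t")
      stats::t.test(g1, g2)$p.value
    else
      suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE))$p.value
    data.frame(marker = m,
               n1 = length(g1), mean1 = mean(g1), sd1 = stats::sd(g1),
               median1 = stats::median(g1), min1 = min(g1), max1 = max(g1),
               n2 = length(g2), mean2 = mean(g2), sd2 = stats::sd(g2),
               median2 = stats::median(g2), min2 = min(g2), max2 = max(g2),
               test_used = test, p_value = p,
               direction = sign(stats::median(g2) - stats::median(g1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Kendall's tau-b association
#'
#' Tie-corrected tau-b with a two-sided p-value from the normal approximation
#' with tie-corrected variance (exact enumeration when n <= 10 and there are
#' no ties, as provided by [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, n >= 3 complete pairs.
#' @return list with `tau`, `p_value`, `n`.
#' @examples
#' kendallTau(1:4, c(1, 3, 2, 4))$tau  # 2/3
#' @export
kendallTau <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("tau is undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "kendall",
                    exact = n <= 10 &&
                      !anyDuplicated(x) && !anyDuplicated(y)))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Partial Kendall correlation controlling for one covariate
#'
#' \deqn{\tau_{xy\cdot z} = \frac{\tau_{xy} - \tau_{xz}\tau_{yz}}
#'   {\sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}}}
#'
#' The p-value uses the same normal approximation as the marginal tau (an
#' approximation; documented in the methods vignette).
#'
#' @param x,y,z numeric vectors; complete triples only, n >= 4.
#' @return list with `tau` (partial), `marginal_tau`, `p_value`, `n`.
#' @export
partialKendallTau <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete triples")
  txy <- stats::cor(x, y, method = "kendall")
  txz <- stats::cor(x, z, method = "kendall")
  tyz <- stats::cor(y, z, method = "kendall")
  if (abs(txz) >= 1 || abs(tyz) >= 1)
    stop("partial tau undefined: a control correlation is +/-1")
  pt <- (txy - txz * tyz) / sqrt((1 - txz^2) * (1 - tyz^2))
  sigma <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  list(tau = pt, marginal_tau = txy,
       p_value = 2 * stats::pnorm(-abs(pt) / sigma), n = n)
}

#' Extreme-quartile phenotype contrasts
#'
#' Applies [contrastGroups()] to the subjects in the lowest (Q1) and highest
#' (Q4) quartile of a trajectory statistic, across a marker panel.
#'
#' @param quartiles factor of `Q1`..`Q4` labels (e.g. from
#'   [assignQuartiles()]), one per row of `pheno`.
#' @param pheno data.frame of markers.
#' @param markers columns to contrast.
#' @param testPolicy passed to [contrastGroups()].
#' @return data.frame as in [contrastGroups()] (group 1 = Q1, group 2 = Q4).
#' @export
quartileContrast <- function(quartiles, pheno, markers,
                             testPolicy = "auto") {
  inQ <- quartiles %in% c("Q1", "Q4")
  q <- factor(as.character(quartiles[inQ]), levels = c("Q1", "Q4"))
  if (!any(q == "Q1") || !any(q == "Q4"))
    stop("an extreme quartile is empty")
  contrastGroups(q, pheno[inQ, , drop = FALSE], markers, testPolicy)
}
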