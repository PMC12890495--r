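#' Differential methylation / expression between two groups
#'
#' Per-feature two-group testing with an empirical-Bayes moderated t statistic
#' (limma's variance shrinkage), Benjamini-Hochberg adjusted q-values and a
#' significance flag at the configured FDR. Methylation is tested on M-values
#' (`log2(beta/(1-beta))`) with the effect reported as the delta-beta (group
#' difference of mean beta); expression counts are tested on `log2(cpm + 1)`
#' with the effect as the log2 fold change of group means. A plain Welch t
#' test is available by `method = "welch"`.
#'
#' @param x an [OmicsMatrix-class] or numeric matrix (features x samples).
#' @param labels two-level factor (or coercible), one entry per sample. The
#'   reported effect is level 2 minus level 1.
#' @param scale analysis scale; `"auto"` picks from the omics type.
#' @param fdr q-value threshold for the `significant` flag.
#' @param method `"moderated"` (limma) or `"welch"`.
#' @return data.frame with `feature_id`, `effect`, `statistic`, `p_value`,
#'   `q_value`, `significant`.
#' @export
detectDifferential <- function(x, labels,
                               scale = c("auto", "M-value", "log2cpm",
                                         "identity"),
                               fdr = 0.05,
                               method = c("moderated", "welch")) {
  method <- match.arg(method)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop("'labels' must define exactly two groups")
  if (any(table(labels) < 2L))
    stop("both groups need at least 2 samples")
  v <- analysisScale(x, scale)
  if (ncol(v) != length(labels))
    stop("'labels' must have one entry per sample")
  g2 <- labels == levels(labels)[2]

  if (method == "moderated") {
    design <- stats::model.matrix(~labels)
    fit <- limma::eBayes(limma::lmFit(v, design))
    stat <- fit$t[, 2]
    p <- fit$p.value[, 2]
  } else {
    m1 <- rowMeans(v[, !g2, drop = FALSE]); m2 <- rowMeans(v[, g2, drop = FALSE])
    v1 <- apply(v[, !g2, drop = FALSE], 1, stats::var)
    v2 <- apply(v[, g2, drop = FALSE], 1, stats::var)
    n1 <- sum(!g2); n2 <- sum(g2)
    se <- sqrt(v1 / n1 + v2 / n2)
    stat <- (m2 - m1) / se
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  }

  # effect on the reporting scale: delta-beta for methylation, else the
  # analysis-scale group mean difference (log2FC for expression)
  isMeth <- is(x, "OmicsMatrix") && omicsType(x) == "methylation"
  eff <- if (isMeth) {
    b <- omicsValues(x)
    rowMeans(b[, g2, drop = FALSE]) - rowMeans(b[, !g2, drop = FALSE])
  } else {
    rowMeans(v[, g2, drop = FALSE]) - rowMeans(v[, !g2, drop = FALSE])
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(v),
             effect = unname(eff),
             statistic = unname(stat),
             p_value = unname(p),
             q_value = unname(q),
             significant = unname(q < fdr),
             stringsAsFactors = FALSE)
}

#' Call differentially methylated regions (>= 7 DMPs)
#'
#' Groups significant DMPs into genomic regions and keeps only regions
#' containing at least `minDMPs` (default 7) member DMPs. With a supplied
#' region map (a `GRanges` or a data.frame with `chrom`, `start`, `end`), DMPs
#' are assigned to regions by overlap; otherwise regions are formed
#' agglomeratively by merging DMPs separated by at most `maxGap` bp (default
#' 1000). Coordinates are 0-based half-open in the annotation and reported the
#' same way.
#'
#' @param dmps data.frame from [detectDifferential()]; only rows with
#'   `significant == TRUE` are used.
#' @param annotation data.frame with rownames (or column `feature_id`)
#'   matching the DMP IDs and columns `chrom`, `start`, `end`.
#' @param regionMap optional region map (see above).
#' @param minDMPs minimum members per region.
#' @param maxGap merge gap for the agglomerative fallback, bp.
#' @return a [GenomicRanges::GRanges] with metadata columns `n_dmps` and
#'   `member_dmp_ids` (a CharacterList). Significant DMPs lacking coordinates
#'   are dropped with a warning.
#' @export
callDMRs <- function(dmps, annotation, regionMap = NULL, minDMPs = 7L,
                     maxGap = 1000L) {
  sig <- dmps$feature_id[dmps$significant]
  if (!length(sig))
    return(GenomicRanges::GRanges(n_dmps = integer(),
                                  member_dmp_ids = IRanges::CharacterList()))
  if (!is.null(annotation$feature_id))
    rownames(annotation) <- annotation$feature_id
  have <- sig %in% rownames(annotation) &
    !is.na(annotation[sig, "chrom"]) & !is.na(annotation[sig, "start"])
  if (any(!have)) {
    warning(sum(!have), " significant DMP(s) lack coordinates; excluded")
    sig <- sig[have]
  }
  if (!length(sig))
    return(GenomicRanges::GRanges(n_dmps = integer(),
                                  member_dmp_ids = IRanges::CharacterList()))
  ann <- annotation[sig, , drop = FALSE]
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(start = ann$start + 1L,
                                                end = ann$end))
  names(gr) <- sig

  if (is.null(regionMap)) {
    regions <- GenomicRanges::reduce(gr, min.gapwidth = maxGap + 1L)
    hit <- GenomicRanges::findOverlaps(gr, regions)
  } else {
    if (is.data.frame(regionMap))
      regionMap <- GenomicRanges::GRanges(
        regionMap$chrom,
        IRanges::IRanges(start = regionMap$start + 1L, end = regionMap$end))
    regions <- regionMap
    hit <- GenomicRanges::findOverlaps(gr, regions)
  }
  members <- split(names(gr)[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit))
  counts <- lengths(members)
  keep <- as.integer(names(members)[counts >= minDMPs])
  if (!length(keep))
    return(GenomicRanges::GRanges(n_dmps = integer(),
                                  member_dmp_ids = IRanges::CharacterList()))
  out <- regions[keep]
  S4Vectors::mcols(out)$n_dmps <-
    unname(counts[as.character(keep)])
  S4Vectors::mcols(out)$member_dmp_ids <-
    IRanges::CharacterList(unname(members[as.character(keep)]))
  out
}

#' Correlate CpG methylation with gene expression
#'
#' Pearson correlation for each candidate CpG-gene pair over the samples the
#' two matrices share, with a t-distribution p-value and BH q-values across
#' all pairs. Methylation enters on the M-value scale and expression as
#' `log2(cpm + 1)` by default, both configurable.
#'
#' @param meth,expr [OmicsMatrix-class] objects (or matrices).
#' @param pairs data.frame with columns `cpg_id`, `gene_id`; typically all
#'   combinations of significant DMPs and significant DEGs.
#' @param methScale,exprScale passed to the internal scale transform.
#' @param q FDR threshold for the `retained` flag.
#' @return data.frame with `cpg_id`, `gene_id`, `r`, `p_value`, `q_value`,
#'   `retained`, plus attribute `"n_samples"`.
#' @export
correlateCpgGene <- function(meth, expr, pairs,
                             methScale = "M-value", exprScale = "auto",
                             q = 0.05) {
  mv <- analysisScale(meth, methScale)
  ev <- analysisScale(expr, exprScale)
  shared <- intersect(colnames(mv), colnames(ev))
  if (length(shared) < 3L)
    stop("need at least 3 shared samples (have ", length(shared), ")")
  mv <- mv[, shared, drop = FALSE]
  ev <- ev[, shared, drop = FALSE]
  bad <- !(pairs$cpg_id %in% rownames(mv)) | !(pairs$gene_id %in% rownames(ev))
  if (any(bad)) {
    warning(sum(bad), " pair(s) reference unknown features; dropped")
    pairs <- pairs[!bad, , drop = FALSE]
  }
  n <- length(shared)
  r <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(mv[pairs$cpg_id[i], ], ev[pairs$gene_id[i], ]), numeric(1))
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-tt, n - 2)
  p[abs(r) >= 1] <- 0
  qv <- stats::p.adjust(p, method = "BH")
  out <- data.frame(cpg_id = pairs$cpg_id, gene_id = pairs$gene_id,
                    r = r, p_value = p, q_value = qv, retained = qv < q,
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  out
}

#' PLSDA group-separation gate
#'
#' Partial least squares discriminant analysis as an initial gate: the
#' feature matrix is autoscaled, PLS components are extracted by NIPALS
#' against a one-hot class response, and the separation statistic is the
#' Euclidean distance between class centroids in score space. Significance
#' comes from a label-permutation null:
#' `p = (1 + #{perm >= observed}) / (nPermutations + 1)`.
#'
#' @param x [OmicsMatrix-class] or matrix (features x samples).
#' @param labels two-level grouping, one per sample.
#' @param nComponents number of PLS components (default 2).
#' @param nPermutations permutation count for the null (default 1000).
#' @param seed RNG seed (permutations only; the fit is deterministic).
#' @param scale analysis scale, as in [detectDifferential()].
#' @return list with `scores` (samples x components), `statistic`, `p_value`,
#'   `permStatistics`.
#' @export
plsdaGate <- function(x, labels, nComponents = 2L, nPermutations = 1000L,
                      seed = 1L, scale = "auto") {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("'labels' must define two groups")
  if (any(table(labels) < 2L)) stop("both groups need at least 2 samples")
  X <- t(analysisScale(x, scale))                     # samples x features
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("constant matrix: no variance to decompose")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X)
  Y1 <- stats::model.matrix(~ 0 + labels)

  separation <- function(Ymat) {
    Tm <- nipalsPLS(X, scale(Ymat, scale = FALSE), nComponents)
    c1 <- colMeans(Tm[Ymat[, 1] == 1, , drop = FALSE])
    c2 <- colMeans(Tm[Ymat[, 2] == 1, , drop = FALSE])
    sqrt(sum((c1 - c2)^2))
  }
  obs <- separation(Y1)
  set.seed(seed)
  perm <- vapply(seq_len(nPermutations), function(i)
    separation(Y1[sample(nrow(Y1)), , drop = FALSE]), numeric(1))
  scores <- nipalsPLS(X, scale(Y1, scale = FALSE), nComponents)
  rownames(scores) <- rownames(X)
  list(scores = scores, statistic = obs,
       p_value = (1 + sum(perm >= obs)) / (nPermutations + 1),
       permStatistics = perm)
}

# NIPALS PLS2: X (n x p, centered/scaled), Y (n x q, centered). Returns the
# n x ncomp score matrix. Power iterations on the dominant singular pair of
# X'Y, with deflation of both blocks.
nipalsPLS <- function(X, Y, ncomp, tol = 1e-10, maxit = 500L) {
  n <- nrow(X)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (sum(u^2) < 1e-24) break      # response block exhausted
    tOld <- rep(Inf, n)
    for (it in seq_len(maxit)) {
      w <- crossprod(X, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-150) break
      w <- w / wn
      tt <- X %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% q / sum(q^2)
      if (sum((tt - tOld)^2) / max(sum(tt^2), .Machine$double.eps) < tol)
        break
      tOld <- tt
    }
    p <- crossprod(X, tt) / sum(tt^2)
    X <- X - tcrossprod(tt, p)
    Y <- Y - tcrossprod(tt, q)
    Tm[, a] <- tt
  }
  Tm
}
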