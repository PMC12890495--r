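#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Feature-by-sample omics container
#'
#' An `OmicsMatrix` is a thin specialisation of
#' [SummarizedExperiment::SummarizedExperiment] holding one assay of features
#' (rows) by samples (columns), plus per-feature annotation in `rowData()`:
#' genomic coordinates (`chrom`, `start`, `end`, 0-based half-open) for
#' methylation arrays, or a `gene_symbol` for expression matrices. The
#' `omicsType` slot records what the values are, which downstream operations
#' use to pick the analysis scale:
#'
#' * `"methylation"` — beta values in \[0, 1\]; tested on M-values
#'   `log2(beta/(1-beta))`.
#' * `"expression"` — non-negative counts; tested on `log2(cpm + 1)`.
#' * `"expression_cpm"` — counts-per-million (each column sums to 1e6).
#' * `"generic"` — used as-is.
#'
#' @slot omicsType character scalar, one of the types above.
#' @seealso [OmicsMatrix()] for construction, [computeCPM()],
#'   [detectDifferential()].
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
         contains = "SummarizedExperiment",
         representation(omicsType = "character"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@omicsType) != 1L ||
      !object@omicsType %in% c("methylation", "expression", "expression_cpm",
                               "generic"))
    msg <- c(msg, "omicsType must be one of 'methylation', 'expression', 'expression_cpm', 'generic'")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample IDs")
  if (length(SummarizedExperiment::assays(object)) >= 1L && ncol(object) > 0L) {
    v <- SummarizedExperiment::assay(object, 1L)
    if (identical(object@omicsType, "methylation") &&
        (min(v, na.rm = TRUE) < 0 || max(v, na.rm = TRUE) > 1))
      msg <- c(msg, "methylation beta values must lie in [0, 1]")
    if (object@omicsType %in% c("expression", "expression_cpm") &&
        min(v, na.rm = TRUE) < 0)
      msg <- c(msg, "expression values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Shared-correlation hypergraph over a candidate gene set
#'
#' Nodes are candidate genes; partners are background features. The incidence
#' matrix M has `M[i, j] = 1` when |r| between node i and partner j exceeds the
#' binarization rule, so a partner correlated with several nodes acts as one
#' hyperedge joining them all. The adjacency `A = M %*% t(M)` with zeroed
#' diagonal counts, for every node pair, how many partners they share; the
#' central cluster is the group of nodes sharing the most correlated partners.
#'
#' @slot nodeIds,partnerIds character vectors naming nodes / partners.
#' @slot incidence binary integer matrix, nodes x partners.
#' @slot adjacency integer matrix of shared-partner counts, zero diagonal.
#' @slot clusterLabels integer vector of cluster memberships, named by node.
#' @slot centralCluster character vector, the member set of the central cluster.
#' @slot threshold numeric, the |r| cut-off actually applied.
#' @slot noStructure logical, `TRUE` when the adjacency was all-zero and the
#'   single-cluster fallback was used.
#' @seealso [buildHypergraph()], [hypergraphAdjacency()],
#'   [extractCentralCluster()]
#' @exportClass Hypergraph
setClass("Hypergraph",
         representation(nodeIds = "character",
                        partnerIds = "character",
                        incidence = "matrix",
                        adjacency = "matrix",
                        clusterLabels = "integer",
                        centralCluster = "character",
                        threshold = "numeric",
                        noStructure = "logical"))

setValidity("Hypergraph", function(object) {
  msg <- character()
  M <- object@incidence
  A <- object@adjacency
  if (nrow(M) != length(object@nodeIds))
    msg <- c(msg, "incidence rows must match nodeIds")
  if (ncol(M) != length(object@partnerIds))
    msg <- c(msg, "incidence columns must match partnerIds")
  if (length(M) && !all(M %in% c(0, 1)))
    msg <- c(msg, "incidence must be binary")
  if (nrow(A) != ncol(A) || nrow(A) != length(object@nodeIds))
    msg <- c(msg, "adjacency must be square, nodes x nodes")
  if (length(A)) {
    if (!isTRUE(all.equal(A, t(A))))
      msg <- c(msg, "adjacency must be symmetric")
    if (any(A < 0) || any(A != round(A)))
      msg <- c(msg, "adjacency entries must be non-negative integers")
    if (any(diag(A) != 0))
      msg <- c(msg, "adjacency diagonal must be zero")
  }
  if (length(object@centralCluster) &&
      !all(object@centralCluster %in% object@nodeIds))
    msg <- c(msg, "centralCluster must be a subset of nodeIds")
  if (length(msg)) msg else TRUE
})

#' Out-of-bag random-forest report
#'
#' Collects everything the OOB evaluation of a forest produces: per-sample OOB
#' vote fractions for the positive class, the 2x2 confusion matrix at the 0.5
#' vote threshold, the OOB error rate, the ROC curve traced over vote
#' thresholds with its trapezoidal AUC, and per-feature importances.
#'
#' @slot oobConfusion 2x2 integer matrix (truth x prediction).
#' @slot oobErrorRate misclassified / total, from the confusion matrix.
#' @slot roc data.frame with columns `fpr`, `tpr` (monotone non-decreasing).
#' @slot auc trapezoidal area under `roc`, in \[0, 1\].
#' @slot importance named numeric per-feature score.
#' @slot oobVotes named numeric, per-sample positive-class OOB vote fraction.
#' @slot positiveClass character, the level treated as positive.
#' @slot config the [rfConfig()] list used (records the seed).
#' @seealso [trainRFOOB()], [oobRocAuc()], [predictExternal()]
#' @exportClass RFReport
setClass("RFReport",
         representation(oobConfusion = "matrix",
                        oobErrorRate = "numeric",
                        roc = "data.frame",
                        auc = "numeric",
                        importance = "numeric",
                        oobVotes = "numeric",
                        positiveClass = "character",
                        config = "list"))

setValidity("RFReport", function(object) {
  msg <- character()
  cm <- object@oobConfusion
  if (!all(dim(cm) == c(2L, 2L)))
    msg <- c(msg, "oobConfusion must be 2x2")
  else {
    err <- (cm[1, 2] + cm[2, 1]) / sum(cm)
    if (abs(err - object@oobErrorRate) > 1e-12)
      msg <- c(msg, "oobErrorRate must equal misclassified/total from oobConfusion")
  }
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (nrow(object@roc)) {
    if (is.unsorted(object@roc$fpr) || is.unsorted(object@roc$tpr))
      msg <- c(msg, "roc points must be monotone non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Boruta all-relevant feature-selection result
#'
#' Each iteration appends freshly permuted shadow copies of every feature,
#' refits a random forest, and scores a "hit" for every real feature whose
#' importance beats the best shadow. A two-sided binomial test on the hit
#' counts against p = 0.5 splits features into confirmed / rejected, the
#' remainder staying tentative.
#'
#' @slot status named factor with levels confirmed, tentative, rejected.
#' @slot hitCounts named integer vector of hits per feature.
#' @slot nIterations number of shadow iterations run.
#' @slot alpha two-sided significance level of the binomial test.
#' @seealso [borutaSelect()]
#' @exportClass BorutaResult
setClass("BorutaResult",
         representation(status = "factor",
                        hitCounts = "integer",
                        nIterations = "integer",
                        alpha = "numeric"))

setValidity("BorutaResult", function(object) {
  msg <- character()
  if (!identical(levels(object@status),
                 c("confirmed", "tentative", "rejected")))
    msg <- c(msg, "status levels must be confirmed, tentative, rejected")
  if (length(object@status) != length(object@hitCounts))
    msg <- c(msg, "status and hitCounts must cover the same features")
  if (anyNA(object@status))
    msg <- c(msg, "every feature must receive a status")
  if (length(msg)) msg else TRUE
})

#' A simulated two-omics cohort with planted signal
#'
#' Bundles the four tables the analysis consumes — per-subject growth records,
#' cardiometabolic phenotypes, a methylation [OmicsMatrix] (beta values) and an
#' expression [OmicsMatrix] (counts) — together with the ground truth of the
#' simulation (per-subject group labels, per-feature planted-signal flags) and
#' the generating [simulationConfig()].
#'
#' @slot growth data.frame, one row per subject (see [simulateCohort()]).
#' @slot phenotype data.frame of cardiometabolic markers at the visit age.
#' @slot methylation,expression [OmicsMatrix] objects sharing subject IDs.
#' @slot truth list with elements `subjects`, `cpgs`, `genes`.
#' @slot config the generating configuration.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
         representation(growth = "data.frame",
                        phenotype = "data.frame",
                        methylation = "OmicsMatrix",
                        expression = "OmicsMatrix",
                        truth = "list",
                        config = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@growth$subject_id
  if (nrow(object@phenotype) &&
      !identical(sort(ids), sort(object@phenotype$subject_id)))
    msg <- c(msg, "growth and phenotype must share subject IDs")
  for (what in c("methylation", "expression")) {
    om <- slot(object, what)
    if (ncol(om) && !identical(sort(ids), sort(colnames(om))))
      msg <- c(msg, paste(what, "samples must match growth subject IDs"))
  }
  if (length(ids) &&
      (is.null(object@truth$subjects) ||
       !identical(sort(ids), sort(object@truth$subjects$subject_id))))
    msg <- c(msg, "truth must cover every subject")
  if (length(msg)) msg else TRUE
})
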