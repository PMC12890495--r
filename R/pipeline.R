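#' Run the discovery pipeline on a cohort
#'
#' Chains the full analysis: NHLBI phenotyping and growth classification
#' define the unhealthy CU-SGA group versus the rest of the cohort; a PLSDA
#' permutation gate checks for overall omic separation; differential
#' methylation points (and >= `minDMPs` regions) and differentially expressed
#' genes are called; significant DMP x DEG pairs are correlated and the genes
#' of the retained edges seed a shared-correlation hypergraph whose central
#' cluster is the candidate gene signature; finally an out-of-bag random
#' forest and a Boruta selection loop quantify how well that signature
#' separates the groups.
#'
#' @param cohort a [SyntheticCohort-class] (or any object with the same
#'   accessors).
#' @param thresholds [nhlbiThresholds()] for the phenotype call.
#' @param fdr FDR threshold used for DMPs, DEGs and correlation edges.
#' @param minDMPs minimum DMPs per differentially methylated region.
#' @param plsdaPermutations permutations for the gate (0 skips it).
#' @param rfCfg [rfConfig()] for the final forest.
#' @param borutaIterations Boruta iterations (0 skips Boruta).
#' @param borutaCfg [rfConfig()] for the Boruta refits.
#' @param seed seed for the PLSDA permutations.
#' @return list with elements `calls`, `classes`, `labels`, `plsda`, `dmps`,
#'   `degs`, `dmrs`, `edges`, `candidateGenes`, `hypergraph`, `rf`,
#'   `boruta`.
#' @export
runPipeline <- function(cohort,
                        thresholds = nhlbiThresholds(),
                        fdr = 0.05, minDMPs = 7L,
                        plsdaPermutations = 199L,
                        rfCfg = rfConfig(),
                        borutaIterations = 50L,
                        borutaCfg = rfConfig(nTrees = 300L),
                        seed = 1L) {
  growth <- growthTable(cohort)
  pheno <- phenotypeTable(cohort)
  meth <- methylationMatrix(cohort)
  expr <- expressionMatrix(cohort)

  calls <- callPrehypertension(pheno, thresholds)
  birth <- classifyBirthSize(growth$birthweight_percentile)
  post <- classifyPostnatal(birth, growth$height_percentile_age7)
  flagged <- calls$prehypertensive[match(growth$subject_id,
                                         calls$subject_id)]
  labels <- factor(ifelse(!is.na(flagged) & flagged & post == "CU-SGA",
                          "unhealthy-CU-SGA", "rest"),
                   levels = c("rest", "unhealthy-CU-SGA"))
  names(labels) <- growth$subject_id

  empty <- list(plsda = NULL, dmps = NULL, degs = NULL, dmrs = NULL,
                edges = NULL, candidateGenes = character(),
                hypergraph = NULL, rf = NULL, boruta = NULL)
  if (nlevels(droplevels(labels)) < 2L || min(table(labels)) < 2L) {
    message("fewer than 2 subjects per group; omic stages skipped")
    return(c(list(calls = calls,
                  classes = data.frame(subject_id = growth$subject_id,
                                       birth_class = birth,
                                       postnatal_class = post,
                                       stringsAsFactors = FALSE),
                  labels = labels), empty))
  }

  plsda <- NULL
  if (plsdaPermutations > 0)
    plsda <- plsdaGate(expr, labels, nPermutations = plsdaPermutations,
                       seed = seed)

  ord <- match(sampleIds(meth), growth$subject_id)
  dmps <- detectDifferential(meth, labels[ord], fdr = fdr)
  degs <- detectDifferential(expr, labels[ord], fdr = fdr)
  dmrs <- callDMRs(dmps, featureAnnotation(meth), minDMPs = minDMPs)

  sigCpgs <- dmps$feature_id[dmps$significant]
  sigGenes <- degs$feature_id[degs$significant]
  edges <- NULL
  candidates <- character()
  if (length(sigCpgs) && length(sigGenes)) {
    pairs <- expand.grid(cpg_id = sigCpgs, gene_id = sigGenes,
                         stringsAsFactors = FALSE)
    edges <- correlateCpgGene(meth, expr, pairs, q = fdr)
    candidates <- sort(unique(edges$gene_id[edges$retained]))
  }

  hg <- NULL; rf <- NULL; boruta <- NULL
  if (length(candidates) >= 2L) {
    hg <- buildHypergraph(expr, nodes = candidates)
    sig <- centralCluster(hg)
    if (length(sig) >= 1L && nlevels(droplevels(labels)) == 2L) {
      X <- t(analysisScale(expr)[sig, , drop = FALSE])
      rf <- trainRFOOB(X, labels[ord], rfCfg)
      if (borutaIterations > 0)
        boruta <- borutaSelect(X, labels[ord], borutaCfg,
                               nIterations = borutaIterations)
    }
  } else if (length(candidates) < 2L) {
    message("fewer than 2 candidate genes; hypergraph and prediction skipped")
  }

  list(calls = calls,
       classes = data.frame(subject_id = growth$subject_id,
                            birth_class = birth, postnatal_class = post,
                            stringsAsFactors = FALSE),
       labels = labels, plsda = plsda,
       dmps = dmps, degs = degs, dmrs = dmrs, edges = edges,
       candidateGenes = candidates, hypergraph = hg,
       rf = rf, boruta = boruta)
}
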