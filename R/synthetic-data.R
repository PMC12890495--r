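#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort with ~10%
#' SGA and ~10% LGA births, a catch-up subgroup of the SGA children of whom a
#' configurable fraction (~25%, mirroring the reported relative frequency)
#' develops the prehypertensive phenotype, region-clustered differential
#' methylation, correlated CpG-gene pairs, and one coordinated multi-gene
#' expression cluster driven by a shared latent factor.
#'
#' The latent structure is parametrized by target correlations rather than raw
#' loadings: `cpgGeneCorr` is the target Pearson r between a planted CpG
#' (M-value scale) and its paired gene (log2 cpm scale), `clusterCorr` the
#' target pairwise r within the coordinated gene cluster, and `partnerCorr`
#' the target r between a cluster gene and each of the `nFactorPartners`
#' background genes that respond weakly to the same factor (these partners are
#' what makes the cluster detectable as a shared-correlation hypergraph
#' block). The variance budget on the gene side must leave room for sampling
#' noise; each gene's pair fraction is capped at `0.90 - clusterCorr`,
#' reducing the CpG-pair correlation of cluster genes when both targets are
#' high.
#'
#' @param nSubjects cohort size (0 gives an empty cohort).
#' @param fracSGA,fracLGA birth-size stratum probabilities (defaults 0.10).
#' @param fracCUgivenSGA probability an SGA child catches up by age 7.
#' @param fracCDgivenLGA probability an LGA child catches down.
#' @param fracUnhealthyGivenCUSGA fraction of CU-SGA children planted as
#'   prehypertensive (default 0.25).
#' @param nCpgs,nGenes feature counts.
#' @param nPlantedDmps,dmpsPerRegion planted differentially methylated CpGs,
#'   laid out in regions of `dmpsPerRegion` consecutive CpGs.
#' @param nPlantedDegs planted differentially expressed genes; the first
#'   `clusterSize` of them form the coordinated cluster.
#' @param clusterSize coordinated cluster size (default 42).
#' @param effectSizeMeth delta-beta separating the unhealthy subgroup.
#' @param effectSizeExpr log2 fold change separating the unhealthy subgroup.
#' @param cpgGeneCorr,clusterCorr,partnerCorr target correlations (above).
#' @param nFactorPartners background genes weakly loaded on the cluster
#'   factor.
#' @param sbpShift mmHg added to the unhealthy subgroup's systolic pressure.
#' @param visitAge age (years) of the phenotype visit.
#' @param dispersion negative-binomial gene dispersion.
#' @param libSdLog log-sd of the log-normal library sizes (0.3 ~ CV 30%).
#' @param seed integer RNG seed; identical configs give bit-identical
#'   cohorts.
#' @return list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSubjects,
                             fracSGA = 0.10, fracLGA = 0.10,
                             fracCUgivenSGA = 0.85, fracCDgivenLGA = 0.5,
                             fracUnhealthyGivenCUSGA = 0.25,
                             nCpgs = 5000L, nGenes = 2000L,
                             nPlantedDmps = 70L, dmpsPerRegion = 7L,
                             nPlantedDegs = 54L, clusterSize = 42L,
                             effectSizeMeth = 0.35, effectSizeExpr = 2.2,
                             cpgGeneCorr = 0.45, clusterCorr = 0.4,
                             partnerCorr = 0.25, nFactorPartners = 150L,
                             sbpShift = 30, visitAge = 17,
                             dispersion = 0.1, libSdLog = 0.3,
                             seed = 1L) {
  props <- c(fracSGA = fracSGA, fracLGA = fracLGA,
             fracCUgivenSGA = fracCUgivenSGA,
             fracCDgivenLGA = fracCDgivenLGA,
             fracUnhealthyGivenCUSGA = fracUnhealthyGivenCUSGA)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  if (fracSGA + fracLGA > 1) stop("fracSGA + fracLGA must not exceed 1")
  if (nSubjects < 0) stop("nSubjects must be non-negative")
  counts <- c(nCpgs = nCpgs, nGenes = nGenes)
  if (any(counts <= 0)) stop("feature counts must be positive")
  if (nPlantedDmps > nCpgs || nPlantedDegs > nGenes)
    stop("planted feature counts must not exceed totals")
  if (clusterSize > nPlantedDegs)
    stop("clusterSize must not exceed nPlantedDegs")
  if (nFactorPartners > nGenes - nPlantedDegs)
    stop("nFactorPartners exceeds the number of background genes")
  if (abs(cpgGeneCorr) >= 1) stop("cpgGeneCorr must lie in (-1, 1)")
  if (clusterCorr < 0 || clusterCorr >= 1)
    stop("clusterCorr must lie in [0, 1)")
  if (clusterSize >= 2 && nFactorPartners > 0 && clusterCorr > 0 &&
      partnerCorr^2 / clusterCorr > 0.95)
    stop("partnerCorr too high for the chosen clusterCorr ",
         "(partner variance fraction would exceed 0.95)")
  structure(list(nSubjects = as.integer(nSubjects), fracSGA = fracSGA,
                 fracLGA = fracLGA, fracCUgivenSGA = fracCUgivenSGA,
                 fracCDgivenLGA = fracCDgivenLGA,
                 fracUnhealthyGivenCUSGA = fracUnhealthyGivenCUSGA,
                 nCpgs = as.integer(nCpgs), nGenes = as.integer(nGenes),
                 nPlantedDmps = as.integer(nPlantedDmps),
                 dmpsPerRegion = as.integer(dmpsPerRegion),
                 nPlantedDegs = as.integer(nPlantedDegs),
                 clusterSize = as.integer(clusterSize),
                 effectSizeMeth = effectSizeMeth,
                 effectSizeExpr = effectSizeExpr,
                 cpgGeneCorr = cpgGeneCorr, clusterCorr = clusterCorr,
                 partnerCorr = partnerCorr,
                 nFactorPartners = as.integer(nFactorPartners),
                 sbpShift = sbpShift, visitAge = visitAge,
                 dispersion = dispersion, libSdLog = libSdLog,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a full synthetic cohort
#'
#' Draws growth records and cardiometabolic phenotypes, then fills in the
#' methylation and expression matrices via [simulateOmicsSignal()]. Birth
#' strata are drawn with the configured probabilities and the birthweight
#' percentile uniform within each stratum's band (below 10 / 10-90 / above
#' 90), so at the default 10%/10% the percentile is uniform on (0, 100).
#' SGA children catch up with probability `fracCUgivenSGA` (their age-7
#' height percentile is drawn above 10); a fraction
#' `fracUnhealthyGivenCUSGA` of the catch-up SGA children is planted as
#' unhealthy and receives `sbpShift` on SBP plus the planted omics effects.
#'
#' @param config a [simulationConfig()].
#' @return a [SyntheticCohort-class].
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$nSubjects
  if (n == 0L) return(emptyCohort(config))
  set.seed(config$seed)
  ids <- sprintf("S%04d", seq_len(n))

  stratum <- sample(c("SGA", "LGA", "AGA"), n, replace = TRUE,
                    prob = c(config$fracSGA, config$fracLGA,
                             1 - config$fracSGA - config$fracLGA))
  if (config$fracSGA > 0 && !any(stratum == "SGA"))
    stop("infeasible draw: the SGA stratum is empty at n = ", n)
  if (config$fracLGA > 0 && !any(stratum == "LGA"))
    stop("infeasible draw: the LGA stratum is empty at n = ", n)
  bwPct <- numeric(n)
  bwPct[stratum == "SGA"] <- stats::runif(sum(stratum == "SGA"), 0.2, 10)
  bwPct[stratum == "AGA"] <- stats::runif(sum(stratum == "AGA"), 10, 90)
  bwPct[stratum == "LGA"] <- stats::runif(sum(stratum == "LGA"), 90, 99.8)

  cu <- rep(FALSE, n)
  isSGA <- stratum == "SGA"; isLGA <- stratum == "LGA"
  cu[isSGA] <- stats::runif(sum(isSGA)) < config$fracCUgivenSGA
  cd <- rep(FALSE, n)
  cd[isLGA] <- stats::runif(sum(isLGA)) < config$fracCDgivenLGA
  if (config$fracCUgivenSGA > 0 && !any(cu))
    stop("infeasible draw: the CU-SGA stratum is empty at n = ", n)
  heightPct <- stats::runif(n, 0.5, 99.5)
  heightPct[isSGA & cu] <- stats::runif(sum(isSGA & cu), 10.5, 95)
  heightPct[isSGA & !cu] <- stats::runif(sum(isSGA & !cu), 0.5, 9.5)
  heightPct[isLGA & cd] <- stats::runif(sum(isLGA & cd), 5, 89.5)
  heightPct[isLGA & !cd] <- stats::runif(sum(isLGA & !cd), 90.5, 99.5)

  cusga <- isSGA & cu
  unhealthy <- rep(FALSE, n)
  unhealthy[cusga] <- stats::runif(sum(cusga)) <
    config$fracUnhealthyGivenCUSGA
  if (config$fracUnhealthyGivenCUSGA > 0 && any(cusga) && !any(unhealthy))
    stop("infeasible draw: the unhealthy CU-SGA stratum is empty at n = ", n)

  ga <- pmin(pmax(round(stats::rnorm(n, 40, 1.3)), 37), 42)
  bwSds <- stats::qnorm(bwPct / 100)
  birthweight <- round(3500 + 450 * bwSds + 150 * (ga - 40))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  efw23 <- pmin(pmax(bwPct + stats::rnorm(n, 0, 15), 0.5), 99.5)
  daysBetween <- (ga - 23) * 7
  cwSds <- 0.4 * bwSds + 0.8 * cusga + stats::rnorm(n, 0, 0.9)

  growth <- data.frame(subject_id = ids, sex = sex,
                       gestational_age = ga, birthweight = birthweight,
                       birthweight_percentile = bwPct,
                       birthweight_sds = bwSds,
                       efw23_percentile = efw23,
                       days_between = daysBetween,
                       height_percentile_age7 = heightPct,
                       child_weight_sds = cwSds,
                       visit_age = config$visitAge,
                       stringsAsFactors = FALSE)

  bmiSds <- 0.4 * cwSds + stats::rnorm(n, 0, 0.9)
  phenotype <- data.frame(
    subject_id = ids, age = config$visitAge, sex = sex,
    sbp = 102 + 2.5 * cwSds + config$sbpShift * unhealthy +
      stats::rnorm(n, 0, 6),
    dbp = 62 + 1.0 * cwSds + stats::rnorm(n, 0, 6),
    hdl = pmax(1.35 + stats::rnorm(n, 0, 0.11), 0.3),
    ldl = pmax(2.5 + stats::rnorm(n, 0, 0.30), 0.5),
    bmi_sds = bmiSds,
    fat_pct = 22 + 2 * bmiSds + stats::rnorm(n, 0, 4),
    insulin = exp(stats::rnorm(n, log(8), 0.4)),
    stringsAsFactors = FALSE)

  birthClass <- as.character(classifyBirthSize(bwPct))
  postClass <- as.character(classifyPostnatal(classifyBirthSize(bwPct),
                                              heightPct))
  truthSubjects <- data.frame(subject_id = ids,
                              birth_class = birthClass,
                              postnatal_class = postClass,
                              cu_sga = cusga,
                              unhealthy = unhealthy,
                              stringsAsFactors = FALSE)

  cohort <- new("SyntheticCohort", growth = growth, phenotype = phenotype,
                methylation = emptyOmics(config$nCpgs, "cg", "methylation"),
                expression = emptyOmics(config$nGenes, "GENE", "expression"),
                truth = list(subjects = truthSubjects),
                config = unclass(config))
  simulateOmicsSignal(cohort, config)
}

#' Fill in the omics matrices of a cohort
#'
#' Plants `nPlantedDmps` differentially methylated CpGs in regions of
#' `dmpsPerRegion` consecutive CpGs, pairs each of the first `nPlantedDegs`
#' planted CpGs with one planted gene through a shared standard-normal latent
#' factor calibrated to the target correlation, drives the first
#' `clusterSize` planted genes with one common cluster factor (plus weak
#' loadings on `nFactorPartners` background genes), and shifts all planted
#' features in the unhealthy subgroup by the configured effect sizes.
#' Methylation noise is logit-normal around group-specific means, clipped to
#' \[0.01, 0.99\]; expression counts are negative binomial with log-normal
#' library sizes.
#'
#' @param cohort a [SyntheticCohort-class] with growth and phenotype filled.
#' @param config the generating [simulationConfig()].
#' @return the cohort with `methylation` and `expression` populated and the
#'   feature truth tables added.
#' @export
simulateOmicsSignal <- function(cohort, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (abs(config$cpgGeneCorr) >= 1) stop("cpgGeneCorr must lie in (-1, 1)")
  n <- nrow(cohort@growth)
  if (n == 0L) return(cohort)
  set.seed(config$seed + 1000003L)
  ids <- cohort@growth$subject_id
  unhealthy <- cohort@truth$subjects$unhealthy

  nCpgs <- config$nCpgs; nGenes <- config$nGenes
  nP <- config$nPlantedDmps; nD <- config$nPlantedDegs
  nPairs <- min(nP, nD)
  nClu <- config$clusterSize

  cpgIds <- sprintf("cg%05d", seq_len(nCpgs))
  geneIds <- sprintf("GENE%04d", seq_len(nGenes))

  ## latent factors
  r <- config$cpgGeneCorr
  fCpg <- max(0.6, min(r^2 / 0.9, 0.95))
  fGene <- if (r == 0) 0 else r^2 / fCpg
  pairFactor <- matrix(stats::rnorm(nPairs * n), nPairs, n)
  clusterFactor <- stats::rnorm(n)

  ## ---- methylation ----
  s1 <- 0.35
  baseBeta <- numeric(nCpgs)
  planted <- seq_len(nP)
  baseBeta[planted] <- stats::runif(nP, 0.40, 0.60)
  bg <- setdiff(seq_len(nCpgs), planted)
  bimodal <- stats::runif(length(bg)) < 0.5
  baseBeta[bg[bimodal]] <- stats::rbeta(sum(bimodal), 8, 2)
  baseBeta[bg[!bimodal]] <- stats::rbeta(sum(!bimodal), 2, 8)
  baseBeta <- pmin(pmax(baseBeta, 0.02), 0.98)

  effSign <- integer(nCpgs)
  effSign[planted] <- rep_len(c(1L, -1L), nP)
  targetBeta <- pmin(pmax(baseBeta + effSign * config$effectSizeMeth,
                          0.02), 0.98)
  logitShift <- stats::qlogis(targetBeta) - stats::qlogis(baseBeta)

  aCpg <- numeric(nCpgs)
  if (nPairs > 0 && r != 0)
    aCpg[seq_len(nPairs)] <- sign(r) * s1 * sqrt(fCpg / (1 - fCpg))

  logit <- matrix(stats::qlogis(baseBeta), nCpgs, n) +
    matrix(stats::rnorm(nCpgs * n, 0, s1), nCpgs, n)
  if (nPairs > 0)
    logit[seq_len(nPairs), ] <- logit[seq_len(nPairs), ] +
      aCpg[seq_len(nPairs)] * pairFactor
  logit[, unhealthy] <- logit[, unhealthy] +
    matrix(logitShift, nCpgs, sum(unhealthy))
  beta <- pmin(pmax(stats::plogis(logit), 0.01), 0.99)
  dimnames(beta) <- list(cpgIds, ids)

  ## CpG coordinates: planted regions of consecutive CpGs (200 bp apart),
  ## background CpGs 3 kb apart so stray significant singletons never merge
  nRegions <- ceiling(nP / config$dmpsPerRegion)
  regionId <- rep(NA_integer_, nCpgs)
  regionId[planted] <- rep(seq_len(nRegions),
                           each = config$dmpsPerRegion)[seq_len(nP)]
  withinRegion <- stats::ave(seq_len(nP), regionId[planted],
                             FUN = seq_along)
  start <- integer(nCpgs)
  start[planted] <- regionId[planted] * 1000000L +
    (withinRegion - 1L) * 200L
  start[bg] <- 50000000L + (seq_along(bg) - 1L) * 3000L
  cpgAnn <- data.frame(chrom = "chr1", start = start, end = start + 2L,
                       row.names = cpgIds)

  ## ---- expression ----
  disp <- config$dispersion
  m <- pmin(pmax(stats::rnorm(nGenes, 5, 1.8), 0), 11)
  plantedG <- seq_len(nD)
  inCluster <- seq_len(nGenes) %in% seq_len(nClu)
  partnerIdx <- if (config$nFactorPartners > 0)
    nD + seq_len(config$nFactorPartners) else integer()
  m[plantedG] <- stats::runif(nD, 5, 6.5)
  m[partnerIdx] <- stats::runif(length(partnerIdx), 6, 8)

  meanLib <- 5e6
  vhat <- (1 / (2^m * meanLib / 1e6) + disp) / log(2)^2

  fPairG <- numeric(nGenes)
  fClu <- numeric(nGenes)
  if (nPairs > 0) fPairG[seq_len(nPairs)] <- fGene
  fClu[inCluster] <- config$clusterCorr
  fClu[partnerIdx] <- if (config$clusterCorr > 0)
    config$partnerCorr^2 / config$clusterCorr else 0
  # cap so every gene keeps >= 10% sampling-noise share; without this the
  # latent variances explode and the biggest genes dominate the libraries
  fPairG <- pmin(fPairG, 0.90 - fClu)
  fNoise <- 1 - fPairG - fClu
  Tvar <- vhat / fNoise
  bGene <- sqrt(fPairG * Tvar)
  lClu <- sqrt(fClu * Tvar)

  # signed loadings keep the factor library-neutral (an up/down regulon), so
  # cpm normalization does not absorb part of the planted correlation
  loadSign <- integer(nGenes)
  loadSign[inCluster] <- rep_len(c(1L, -1L), nClu)
  loadSign[partnerIdx] <- rep_len(c(1L, -1L), length(partnerIdx))
  geneSign <- integer(nGenes)
  geneSign[plantedG] <- rep_len(c(1L, -1L), nD)
  geneSign[inCluster] <- loadSign[inCluster]   # DE direction follows loading

  lm2 <- matrix(m, nGenes, n)
  if (nPairs > 0)
    lm2[seq_len(nPairs), ] <- lm2[seq_len(nPairs), ] +
      bGene[seq_len(nPairs)] * pairFactor
  driven <- c(which(inCluster), partnerIdx)
  lm2[driven, ] <- lm2[driven, ] +
    outer(loadSign[driven] * lClu[driven], clusterFactor)
  lm2[plantedG, unhealthy] <- lm2[plantedG, unhealthy] +
    geneSign[plantedG] * config$effectSizeExpr

  libs <- stats::rlnorm(n, log(meanLib), config$libSdLog)
  mu <- 2^lm2 * matrix(libs / 1e6, nGenes, n, byrow = TRUE)
  counts <- matrix(stats::rnbinom(nGenes * n, mu = mu, size = 1 / disp),
                   nGenes, n, dimnames = list(geneIds, ids))

  geneAnn <- data.frame(gene_symbol = geneIds, row.names = geneIds)

  truth <- cohort@truth
  truth$cpgs <- data.frame(
    cpg_id = cpgIds,
    planted_dmp = seq_len(nCpgs) %in% planted,
    region_id = regionId,
    pair_gene = c(geneIds[seq_len(nPairs)],
                  rep(NA_character_, nCpgs - nPairs)),
    effect_sign = effSign,
    stringsAsFactors = FALSE)
  truth$genes <- data.frame(
    gene_id = geneIds,
    planted_deg = seq_len(nGenes) %in% plantedG,
    in_cluster = inCluster,
    factor_partner = seq_len(nGenes) %in% partnerIdx,
    pair_cpg = c(cpgIds[seq_len(nPairs)],
                 rep(NA_character_, nGenes - nPairs)),
    effect_sign = geneSign,
    stringsAsFactors = FALSE)

  methylation <- OmicsMatrix(beta, annotation = cpgAnn,
                             type = "methylation")
  expression <- OmicsMatrix(counts, annotation = geneAnn,
                            type = "expression")
  new("SyntheticCohort", growth = cohort@growth,
      phenotype = cohort@phenotype,
      methylation = methylation, expression = expression,
      truth = truth, config = unclass(config))
}

emptyOmics <- function(nFeatures, prefix, type) {
  ids <- sprintf(paste0(prefix, "%05d"), seq_len(nFeatures))
  v <- matrix(numeric(), nFeatures, 0,
              dimnames = list(ids, character()))
  OmicsMatrix(v, type = type)
}

emptyCohort <- function(config) {
  emptyGrowth <- data.frame(subject_id = character(),
                            stringsAsFactors = FALSE)
  new("SyntheticCohort",
      growth = emptyGrowth,
      phenotype = data.frame(subject_id = character(),
                             stringsAsFactors = FALSE),
      methylation = emptyOmics(config$nCpgs, "cg", "methylation"),
      expression = emptyOmics(config$nGenes, "GENE", "expression"),
      truth = list(subjects = data.frame(subject_id = character(),
                                         stringsAsFactors = FALSE),
                   cpgs = data.frame(), genes = data.frame()),
      config = unclass(config))
}

#' @rdname SyntheticCohort-class
#' @export
setMethod("growthTable", "SyntheticCohort", function(x) x@growth)
#' @rdname SyntheticCohort-class
#' @export
setMethod("phenotypeTable", "SyntheticCohort", function(x) x@phenotype)
#' @rdname SyntheticCohort-class
#' @export
setMethod("methylationMatrix", "SyntheticCohort", function(x) x@methylation)
#' @rdname SyntheticCohort-class
#' @export
setMethod("expressionMatrix", "SyntheticCohort", function(x) x@expression)
#' @rdname SyntheticCohort-class
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
  n <- nrow(object@growth)
  cat(sprintf("SyntheticCohort: %d subjects, %d CpGs, %d genes\n", n,
              nrow(object@methylation), nrow(object@expression)))
  if (n) {
    t <- object@truth$subjects
    cat(sprintf("  CU-SGA: %d (unhealthy: %d)\n", sum(t$cu_sga),
                sum(t$unhealthy)))
  }
})

#' Write a cohort to plain-text files
#'
#' Writes `growth.csv`, `phenotype.csv`, `methylation.tsv` (CpG x sample),
#' `cpg_annotation.bed` (0-based half-open), `expression.tsv` (gene x
#' sample), `truth.json` and `config.yaml` into a directory.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort@growth, file.path(dir, "growth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort@phenotype, file.path(dir, "phenotype.csv"),
                   row.names = FALSE)
  writeTsv <- function(om, path, idCol) {
    v <- omicsValues(om)
    tab <- data.frame(id = rownames(v), v, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(tab)[1] <- idCol
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeTsv(cohort@methylation, file.path(dir, "methylation.tsv"), "cpg_id")
  writeTsv(cohort@expression, file.path(dir, "expression.tsv"), "gene_id")
  ann <- featureAnnotation(cohort@methylation)
  if (nrow(ann) && all(c("chrom", "start", "end") %in% names(ann)))
    utils::write.table(
      data.frame(ann$chrom, ann$start, ann$end, rownames(ann)),
      file.path(dir, "cpg_annotation.bed"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  yaml::write_yaml(cohort@config, file.path(dir, "config.yaml"))
  invisible(dir)
}
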