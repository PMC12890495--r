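smallConfig <- function(...) {
  simulationConfig(nSubjects = 200, nCpgs = 300, nGenes = 250,
                   nPlantedDmps = 21, dmpsPerRegion = 7, nPlantedDegs = 12,
                   clusterSize = 8, nFactorPartners = 30, seed = 1, ...)
}

test_that("the generator is reproducible and respects value ranges", {
  cfg <- smallConfig()
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(omicsValues(methylationMatrix(a)),
                   omicsValues(methylationMatrix(b)))
  expect_identical(omicsValues(expressionMatrix(a)),
                   omicsValues(expressionMatrix(b)))
  expect_identical(growthTable(a), growthTable(b))

  betas <- omicsValues(methylationMatrix(a))
  expect_true(all(betas >= 0 & betas <= 1))
  counts <- omicsValues(expressionMatrix(a))
  expect_true(all(counts >= 0 & counts == round(counts)))
  # truth covers every subject and every feature
  tr <- cohortTruth(a)
  expect_setequal(tr$subjects$subject_id, growthTable(a)$subject_id)
  expect_setequal(tr$cpgs$cpg_id, featureIds(methylationMatrix(a)))
  expect_setequal(tr$genes$gene_id, featureIds(expressionMatrix(a)))
})

test_that("an empty cohort is empty but well-formed", {
  co <- simulateCohort(simulationConfig(nSubjects = 0))
  expect_equal(nrow(growthTable(co)), 0)
  expect_equal(ncol(methylationMatrix(co)), 0)
  expect_equal(nrow(cohortTruth(co)$subjects), 0)
})

test_that("birth strata appear at their configured frequencies", {
  co <- simulateCohort(simulationConfig(nSubjects = 5000, nCpgs = 10,
                                        nGenes = 10, nPlantedDmps = 0,
                                        nPlantedDegs = 0, clusterSize = 0,
                                        nFactorPartners = 0, seed = 1))
  tr <- cohortTruth(co)$subjects
  # 99% binomial interval at n = 5000, p = 0.10
  expect_gt(mean(tr$birth_class == "SGA"), 0.08)
  expect_lt(mean(tr$birth_class == "SGA"), 0.12)
  expect_gt(mean(tr$birth_class == "LGA"), 0.08)
  expect_lt(mean(tr$birth_class == "LGA"), 0.12)
  # percentile uniform at default strata: mean ~50
  expect_equal(mean(growthTable(co)$birthweight_percentile), 50,
               tolerance = 2)
})

test_that("unhealthy prevalence among catch-up SGA converges to its target", {
  co <- simulateCohort(simulationConfig(nSubjects = 10000, nCpgs = 10,
                                        nGenes = 10, nPlantedDmps = 0,
                                        nPlantedDegs = 0, clusterSize = 0,
                                        nFactorPartners = 0, seed = 2))
  tr <- cohortTruth(co)$subjects
  nCU <- sum(tr$cu_sga)
  k <- sum(tr$unhealthy)
  # 99% binomial bounds given the realized CU-SGA count
  expect_gte(k, qbinom(0.005, nCU, 0.25))
  expect_lte(k, qbinom(0.995, nCU, 0.25))
})

test_that("invalid configurations are rejected with clear errors", {
  expect_error(simulationConfig(100, fracSGA = 0.7, fracLGA = 0.7), "exceed")
  expect_error(simulationConfig(100, fracSGA = -0.1), "proportions")
  expect_error(simulationConfig(100, nPlantedDmps = 1e6), "totals")
  expect_error(simulationConfig(100, cpgGeneCorr = 1.2), "cpgGeneCorr")
  expect_error(simulationConfig(100, clusterSize = 99, nPlantedDegs = 12),
               "clusterSize")
})

test_that("infeasible strata raise errors naming the stratum", {
  expect_error(simulateCohort(simulationConfig(nSubjects = 3, seed = 1,
                                               nCpgs = 10, nGenes = 10,
                                               nPlantedDmps = 2,
                                               nPlantedDegs = 2,
                                               clusterSize = 2,
                                               nFactorPartners = 2)),
               "stratum")
})

test_that("planted CpG-gene pairs hit the target correlation", {
  # Fisher-z 99% interval around r = 0.9 at n = 500 is about [0.876, 0.921];
  # the generator is checked against the slightly wider stated band
  co <- simulateCohort(simulationConfig(
    nSubjects = 500, nCpgs = 500, nGenes = 400, nPlantedDmps = 14,
    nPlantedDegs = 10, clusterSize = 4, nFactorPartners = 30,
    cpgGeneCorr = 0.9, effectSizeMeth = 0, effectSizeExpr = 0,
    sbpShift = 0, seed = 7))
  g <- cohortTruth(co)$genes
  mv <- log2(omicsValues(methylationMatrix(co)) /
               (1 - omicsValues(methylationMatrix(co))))
  ev <- log2(omicsValues(computeCPM(expressionMatrix(co))) + 1)
  nc <- g[g$planted_deg & !g$in_cluster, ]
  rs <- vapply(seq_len(nrow(nc)), function(i)
    cor(mv[nc$pair_cpg[i], ], ev[nc$gene_id[i], ]), numeric(1))
  expect_true(all(rs > 0.85 & rs < 0.94))
})

test_that("the coordinated cluster out-correlates the background", {
  co <- simulateCohort(simulationConfig(nSubjects = 400, nCpgs = 200,
                                        nGenes = 400, nPlantedDmps = 14,
                                        nPlantedDegs = 12, clusterSize = 10,
                                        nFactorPartners = 40, seed = 3))
  g <- cohortTruth(co)$genes
  ev <- log2(omicsValues(computeCPM(expressionMatrix(co))) + 1)
  cl <- g$gene_id[g$in_cluster]
  bg <- g$gene_id[!g$planted_deg & !g$factor_partner][1:60]
  C <- abs(cor(t(ev[cl, ])))
  B <- abs(cor(t(ev[bg, ])))
  expect_gt(mean(C[upper.tri(C)]), mean(B[upper.tri(B)]) + 0.2)
})

test_that("zero effect sizes leave group differences at noise level", {
  co <- simulateCohort(simulationConfig(nSubjects = 500, nCpgs = 300,
                                        nGenes = 250, nPlantedDmps = 21,
                                        nPlantedDegs = 12, clusterSize = 8,
                                        nFactorPartners = 30, seed = 1,
                                        effectSizeMeth = 0,
                                        effectSizeExpr = 0, sbpShift = 0))
  tr <- cohortTruth(co)
  expect_true(any(tr$subjects$unhealthy))   # truth flags still present
  y <- tr$subjects$unhealthy
  mv <- omicsValues(methylationMatrix(co))
  p <- apply(mv[tr$cpgs$planted_dmp, ], 1, function(v)
    t.test(v[y], v[!y])$p.value)
  # planted features behave as null: p-values not concentrated near zero
  expect_gt(min(p) * length(p), 0.001)  # no Bonferroni-significant feature
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("cohorts round-trip through the plain-text writers", {
  co <- simulateCohort(smallConfig())
  dir <- tempfile()
  writeCohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("growth.csv", "phenotype.csv", "methylation.tsv", "expression.tsv",
      "cpg_annotation.bed", "truth.json", "config.yaml")))))
  g2 <- readGrowthTable(file.path(dir, "growth.csv"))
  expect_equal(g2$subject_id, growthTable(co)$subject_id)
  om <- readOmicsMatrix(file.path(dir, "methylation.tsv"),
                        file.path(dir, "cpg_annotation.bed"),
                        type = "methylation")
  expect_equal(omicsValues(om), omicsValues(methylationMatrix(co)),
               tolerance = 1e-12)
  expect_equal(featureAnnotation(om)$start,
               featureAnnotation(methylationMatrix(co))$start)
  unlink(dir, recursive = TRUE)
})
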