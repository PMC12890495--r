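test_that("cpm normalization conserves library mass", {
  m <- matrix(c(1, 3, 6), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(unname(omicsValues(computeCPM(m))[, 1]), c(1e5, 3e5, 6e5))

  single <- matrix(c(5, 17, 400), 1, 3,
                   dimnames = list("g1", paste0("s", 1:3)))
  expect_true(all(omicsValues(computeCPM(single)) == 1e6))

  set.seed(4)
  counts <- matrix(rpois(600, 40), 30, 20,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  cpm <- omicsValues(computeCPM(counts))
  expect_equal(colSums(cpm), rep(1e6, 20), tolerance = 1e-6,
               ignore_attr = TRUE)

  bad <- counts; bad[, 3] <- 0
  expect_error(computeCPM(bad), "s3")
})

test_that("differential testing is calibrated under the null", {
  set.seed(11)
  m <- matrix(rnorm(10000 * 40), 10000, 40,
              dimnames = list(paste0("f", 1:10000), paste0("s", 1:40)))
  res <- detectDifferential(m, rep(c("a", "b"), each = 20))
  frac <- mean(res$p_value < 0.05)
  # 99% binomial bounds around 0.05 at 10,000 features
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 10000))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 10000))
  expect_equal(sum(res$significant), 0)
})

test_that("planted methylation differences are recovered with high recall", {
  set.seed(12)
  nf <- 2000; n <- 200
  base <- runif(nf, 0.3, 0.7)
  logit <- matrix(qlogis(base), nf, n) + matrix(rnorm(nf * n, 0, 0.5), nf, n)
  planted <- 1:100
  grp <- rep(c("a", "b"), each = 100)
  shift <- qlogis(base[planted] + 0.2) - qlogis(base[planted])
  logit[planted, grp == "b"] <- logit[planted, grp == "b"] + shift
  beta <- plogis(logit)
  dimnames(beta) <- list(paste0("cg", 1:nf), paste0("s", 1:n))
  om <- OmicsMatrix(beta, type = "methylation")
  res <- detectDifferential(om, grp)
  expect_gt(mean(res$significant[planted]), 0.9)
  # delta-beta effect reported on the beta scale, positive for the shift up;
  # subject-level logit noise attenuates the mean slightly below the planted
  # 0.2 (Jensen), so allow a 10% band
  expect_equal(mean(res$effect[planted]), 0.2, tolerance = 0.1)
  expect_true(all(res$effect[planted] > 0))
  expect_lt(mean(res$significant[-planted]), 0.02)
})

test_that("zero within-group variance still yields a finite statistic", {
  m <- rbind(f1 = c(1, 1, 2, 2), f2 = c(0.3, 0.31, 0.29, 0.3))
  colnames(m) <- paste0("s", 1:4)
  res <- detectDifferential(m, c("a", "a", "b", "b"))
  expect_true(all(is.finite(res$statistic)))
  expect_true(res$significant[1])
})

test_that("statistics flip sign under label swap, p-values unchanged", {
  set.seed(13)
  m <- matrix(rnorm(500 * 20), 500, 20,
              dimnames = list(paste0("f", 1:500), paste0("s", 1:20)))
  g <- rep(c("a", "b"), each = 10)
  r1 <- detectDifferential(m, g)
  r2 <- detectDifferential(m, factor(g, levels = c("b", "a")))
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  # and sample order does not matter
  perm <- sample(20)
  r3 <- detectDifferential(m[, perm], g[perm])
  expect_equal(r1$statistic, r3$statistic, tolerance = 1e-12)
})

test_that("Welch-t mode agrees with per-feature t.test", {
  set.seed(14)
  m <- matrix(rnorm(50 * 16), 50, 16,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:16)))
  g <- rep(c("a", "b"), each = 8)
  res <- detectDifferential(m, g, method = "welch")
  ora <- apply(m, 1, function(v) t.test(v[g == "b"], v[g == "a"])$p.value)
  expect_equal(res$p_value, unname(ora), tolerance = 1e-12)
})

test_that("BH adjustment equals brute-force step-up", {
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bruteForceBH(p), tolerance = 1e-12)
  }
  # and the q-values reported by detectDifferential follow BH
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(paste0("f", 1:100), paste0("s", 1:8)))
  res <- detectDifferential(m, rep(c("a", "b"), each = 4))
  expect_equal(res$q_value, bruteForceBH(res$p_value), tolerance = 1e-12)
})

makeDmps <- function(ids, sig = TRUE) {
  data.frame(feature_id = ids, effect = 0.2, statistic = 5,
             p_value = 1e-6, q_value = 1e-5, significant = sig,
             stringsAsFactors = FALSE)
}

test_that("DMR calling enforces the 7-DMP region minimum", {
  ann <- data.frame(chrom = "chr1", start = seq(0, by = 100, length.out = 13),
                    end = seq(2, by = 100, length.out = 13),
                    row.names = paste0("cg", 1:13))
  # 7 consecutive significant CpGs -> one region
  r <- callDMRs(makeDmps(paste0("cg", 1:7)), ann)
  expect_equal(length(r), 1)
  expect_equal(r$n_dmps, 7)
  expect_setequal(unlist(r$member_dmp_ids), paste0("cg", 1:7))
  # 6 -> none
  expect_equal(length(callDMRs(makeDmps(paste0("cg", 1:6)), ann)), 0)
})

test_that("planted regions are found among scattered singleton DMPs", {
  pos <- c(seq(0, by = 200, length.out = 7),          # region 1
           seq(1e6, by = 200, length.out = 8),        # region 2
           seq(5e7, by = 5e4, length.out = 5))        # scattered singletons
  ann <- data.frame(chrom = "chr1", start = pos, end = pos + 2,
                    row.names = paste0("cg", seq_along(pos)))
  r <- callDMRs(makeDmps(rownames(ann)), ann)
  expect_equal(length(r), 2)
  expect_equal(sort(r$n_dmps), c(7, 8))
  # regions are disjoint
  expect_equal(length(GenomicRanges::reduce(r)), 2)
  # a region map overrides the gap rule
  map <- data.frame(chrom = "chr1", start = 0, end = 2e6)
  r2 <- callDMRs(makeDmps(rownames(ann)), ann, regionMap = map)
  expect_equal(length(r2), 1)
  expect_equal(r2$n_dmps, 15)
})

test_that("missing coordinates exclude DMPs with a warning", {
  ann <- data.frame(chrom = "chr1", start = seq(0, 600, by = 100),
                    end = seq(2, 602, by = 100),
                    row.names = paste0("cg", 1:7))
  dmps <- makeDmps(paste0("cg", 1:8))   # cg8 has no coordinates
  expect_warning(r <- callDMRs(dmps, ann), "excluded")
  expect_equal(r$n_dmps, 7)
})

test_that("CpG-gene correlation recovers planted and null pairs", {
  set.seed(16)
  n <- 500
  z <- rnorm(n)
  meth <- matrix(plogis(0.8 * z + rnorm(n, 0, 0.4)), 1, n,
                 dimnames = list("cgA", paste0("s", 1:n)))
  meth <- rbind(meth, cgB = plogis(rnorm(n)))
  expr <- rbind(gA = 2^(6 + 0.9 * z + rnorm(n, 0, 0.4)),
                gB = 2^(6 + rnorm(n)))
  colnames(expr) <- paste0("s", 1:n)
  pairs <- expand.grid(cpg_id = c("cgA", "cgB"), gene_id = c("gA", "gB"),
                       stringsAsFactors = FALSE)
  edges <- correlateCpgGene(OmicsMatrix(meth, type = "methylation"),
                            OmicsMatrix(expr, type = "generic"), pairs,
                            exprScale = "identity")
  planted <- edges[edges$cpg_id == "cgA" & edges$gene_id == "gA", ]
  expect_gt(planted$r, 0.5); expect_true(planted$retained)
  nullp <- edges[edges$cpg_id == "cgB" & edges$gene_id == "gB", ]
  expect_lt(abs(nullp$r), 0.15)
  # perfect linear dependence
  m2 <- matrix(seq(0.1, 0.9, length.out = 10), 1, 10,
               dimnames = list("cg1", paste0("s", 1:10)))
  e2 <- matrix(seq(1, 20, length.out = 10), 1, 10,
               dimnames = list("g1", paste0("s", 1:10)))
  ed <- correlateCpgGene(m2, e2, data.frame(cpg_id = "cg1", gene_id = "g1"),
                         methScale = "identity", exprScale = "identity")
  expect_equal(ed$r, 1)
  expect_equal(ed$p_value, 0)
  expect_error(correlateCpgGene(m2[, 1:2, drop = FALSE], e2,
                                data.frame(cpg_id = "cg1", gene_id = "g1")),
               "shared samples")
})

test_that("PLSDA separates planted classes and stays null-calibrated", {
  set.seed(17)
  n <- 40; p <- 60
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  g <- rep(c("a", "b"), each = n / 2)
  X[1:10, g == "b"] <- X[1:10, g == "b"] + 3
  res <- plsdaGate(X, g, nPermutations = 199, seed = 1, scale = "identity")
  expect_equal(res$p_value, 1 / 200)
  expect_equal(dim(res$scores), c(n, 2))
  # determinism
  res2 <- plsdaGate(X, g, nPermutations = 199, seed = 1, scale = "identity")
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$scores, res2$scores)
  # labels permuted against the structure: non-significant in the typical run
  gp <- sample(g)
  resNull <- plsdaGate(X, gp, nPermutations = 199, seed = 2,
                       scale = "identity")
  expect_gt(resNull$p_value, 0.05)
  # constant matrix errors
  expect_error(plsdaGate(matrix(1, 5, 6, dimnames = list(paste0("f", 1:5),
                                                         paste0("s", 1:6))),
                         rep(c("a", "b"), 3), scale = "identity"),
               "constant")
})

test_that("NIPALS first component matches the dominant singular pair of X'Y", {
  set.seed(18)
  X <- scale(matrix(rnorm(30 * 12), 30, 12))
  Y <- scale(stats::model.matrix(~ 0 + factor(rep(c("a", "b"), each = 15))),
             scale = FALSE)
  Tm <- hypergrowth:::nipalsPLS(X, Y, 1)
  sv <- svd(crossprod(X, Y))
  tRef <- drop(X %*% sv$u[, 1])
  expect_equal(abs(cor(Tm[, 1], tRef)), 1, tolerance = 1e-8)
})
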