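test_that("k-means separates well-separated blobs perfectly", {
  set.seed(41)
  n <- 60
  expr <- cbind(matrix(rnorm(50 * n / 2), 50, n / 2),
                matrix(rnorm(50 * n / 2, 4), 50, n / 2))
  dimnames(expr) <- list(paste0("g", 1:50), paste0("s", 1:n))
  truth <- rep(1:2, each = n / 2)
  km <- kmeansClusters(expr, k = 2, seed = 1, scale = "identity")
  expect_equal(mclust::adjustedRandIndex(km$labels, truth), 1)
  # determinism given the seed
  km2 <- kmeansClusters(expr, k = 2, seed = 1, scale = "identity")
  expect_identical(km$labels, km2$labels)
  # k = 1 puts everyone together; k > n errors
  expect_equal(unique(kmeansClusters(expr, k = 1, scale = "identity")$labels),
               1L)
  expect_error(kmeansClusters(expr, k = n + 1, scale = "identity"),
               "exceeds")
})

test_that("the k-means objective never increases across Lloyd iterations", {
  set.seed(42)
  X <- matrix(rnorm(200 * 5), 200, 5)
  wss <- vapply(1:6, function(it) {
    set.seed(7)
    suppressWarnings(
      kmeans(X, centers = 3, algorithm = "Lloyd", iter.max = it,
             nstart = 1)$tot.withinss)
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-8))
})

test_that("group contrasts choose tests sensibly and detect shifts", {
  set.seed(43)
  n <- 40
  pheno <- data.frame(normalish = rnorm(n),
                      skewed = rexp(n),
                      shifted = c(rnorm(n / 2), rnorm(n / 2, 2)))
  labels <- rep(c("a", "b"), each = n / 2)
  res <- contrastGroups(labels, pheno, c("normalish", "skewed", "shifted"))
  expect_equal(res$test_used[res$marker == "normalish"], "t")
  expect_equal(res$test_used[res$marker == "skewed"], "mann-whitney")
  expect_lt(res$p_value[res$marker == "shifted"], 0.01)
  resMW <- contrastGroups(labels, pheno, "shifted",
                          testPolicy = "mann-whitney")
  expect_lt(resMW$p_value, 0.01)
  # degenerate group sizes are skipped with a warning
  expect_warning(
    none <- contrastGroups(rep(c("a", "b"), c(1, n - 1)), pheno, "normalish"),
    "skipped")
  expect_null(none)
  expect_warning(contrastGroups(labels, pheno, "absent"), "absent")
})

test_that("null contrasts are calibrated", {
  set.seed(44)
  x <- rnorm(40)
  p <- vapply(1:400, function(i) {
    g <- sample(rep(c("a", "b"), each = 20))
    contrastGroups(g, data.frame(m = x), "m", testPolicy = "t")$p_value
  }, numeric(1))
  frac <- mean(p < 0.05)
  expect_gt(frac, 0.05 - 2.576 * sqrt(0.05 * 0.95 / 400))
  expect_lt(frac, 0.05 + 2.576 * sqrt(0.05 * 0.95 / 400))
})

test_that("Kendall tau-b matches brute-force pair counting", {
  expect_equal(kendallTau(1:4, c(1, 3, 2, 4))$tau, 2 / 3, tolerance = 1e-12)
  expect_equal(kendallTau(1:10, (1:10)^3)$tau, 1)
  expect_error(kendallTau(rep(1, 5), 1:5), "constant")
  set.seed(45)
  for (i in 1:500) {
    n <- sample(4:200, 1)
    x <- sample(round(rnorm(n), sample(0:2, 1)))
    y <- round(0.5 * x + rnorm(n), sample(0:2, 1))
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendallTau(x, y)$tau, bruteForceTauB(x, y),
                 tolerance = 1e-12)
  }
})

test_that("independent pairs keep tau near zero", {
  set.seed(46)
  taus <- vapply(1:50, function(i)
    kendallTau(rnorm(500), rnorm(500))$tau, numeric(1))
  # sd(tau) at n = 500 is about 0.03; 0.12 is a 4-sigma envelope
  expect_true(all(abs(taus) < 0.12))
  expect_lt(abs(mean(taus)), 0.02)
})

test_that("partial Kendall tau follows its closed form and symmetries", {
  set.seed(47)
  # tau_xz = tau_yz = 0 exactly reduces to the marginal
  x <- c(1, 2, 3, 4); y <- c(1, 3, 4, 2); z <- c(2, 4, 1, 3)
  expect_equal(cor(x, z, method = "kendall"), 0)
  expect_equal(cor(y, z, method = "kendall"), 0)
  expect_equal(partialKendallTau(x, y, z)$tau, kendallTau(x, y)$tau)
  # symmetric in x <-> y
  a <- rnorm(80); b <- 0.5 * a + rnorm(80); cvar <- rnorm(80)
  expect_equal(partialKendallTau(a, b, cvar)$tau,
               partialKendallTau(b, a, cvar)$tau)
  # z independent of both: partial ~ marginal
  n <- 500
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
  pk <- partialKendallTau(x, y, z)
  expect_lt(abs(pk$tau - pk$marginal_tau), 0.05)
  # confounding: x and y driven by z only -> partialling out z strongly
  # attenuates the association (the rank-based partial does not vanish
  # exactly for Gaussian mediation, but must shrink it substantially)
  z <- rnorm(n)
  x <- z + rnorm(n, 0, 0.3); y <- 2 * z + rnorm(n, 0, 0.3)
  pk2 <- partialKendallTau(x, y, z)
  expect_lt(abs(pk2$tau), 0.5 * abs(pk2$marginal_tau))
  expect_lt(abs(pk2$tau), 0.35)
  expect_error(partialKendallTau(1:10, rnorm(10), 1:10), "undefined")
})

test_that("extreme-quartile contrasts pick up a planted gradient", {
  set.seed(48)
  n <- 200
  traj <- rnorm(n)
  q <- assignQuartiles(traj)
  pheno <- data.frame(sbp = 104 + 3 * traj + rnorm(n, 0, 5),
                      hdl = 1.3 + rnorm(n, 0, 0.2))
  res <- quartileContrast(q, pheno, c("sbp", "hdl"))
  expect_lt(res$p_value[res$marker == "sbp"], 0.05)
  expect_equal(res$direction[res$marker == "sbp"], 1)  # higher in Q4
  expect_gt(res$p_value[res$marker == "hdl"], 0.05)
  expect_error(quartileContrast(factor(rep("Q2", 10),
                                       levels = paste0("Q", 1:4)),
                                pheno[1:10, ], "sbp"),
               "empty")
})
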