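test_that("PCNM of a regular transect yields orthogonal sinusoid-like axes", {
  coords <- cbind(x = seq(0, 90, by = 10), y = 0)
  ax <- pcnmAxes(coords)
  sc <- axisScores(ax)
  expect_gte(ncol(sc), 3)
  ## orthogonality
  g <- crossprod(sc)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  ## eigenvalues strictly decreasing; sign changes grow with axis order
  expect_true(all(diff(axisEigenvalues(ax)) < 1e-12))
  expect_equal(countSignChanges(sc[, 1]) + 1, countSignChanges(sc[, 2]))
  expect_lt(countSignChanges(sc[, 1]), countSignChanges(sc[, 3]))
})

test_that("degenerate coordinate sets are rejected", {
  expect_error(pcnmAxes(cbind(c(0, 1), c(0, 0))), ">= 3 points")
  expect_error(pcnmAxes(matrix(1, 5, 2)), "identical")
})

test_that("PCA reproduces variance structure and reconstructs its input", {
  x <- rnorm(30)
  two <- cbind(a = x, b = 2 * x + 3)   # perfectly correlated pair
  ax <- pcaAxes(two)
  expect_equal(axisEigenvalues(ax)[1] / sum(axisEigenvalues(ax)), 1,
               tolerance = 1e-12)
  set.seed(61)
  X <- matrix(rnorm(100), 20, 5)
  ax2 <- pcaAxes(X)
  Z <- scale(X)
  rec <- axisScores(ax2) %*% t(axisLoadings(ax2))
  expect_equal(rec, Z, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(axisEigenvalues(ax2)), 5, tolerance = 1e-10)
  expect_error(pcaAxes(cbind(X, const = 1)), "zero-variance")
  X[3, 2] <- NA
  expect_error(pcaAxes(X), "missing")
})

test_that("PCA loadings recover a planted two-block correlation structure", {
  set.seed(67)
  n <- 200
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, 0, 0.2), f1 + rnorm(n, 0, 0.2),
             f2 + rnorm(n, 0, 0.2), f2 + rnorm(n, 0, 0.2))
  ax <- pcaAxes(X)
  ld <- abs(axisLoadings(ax)[, 1:2])
  ## first two components separate the blocks: within-block loadings move
  ## together on one of PC1/PC2
  blockOf <- apply(ld, 1, which.max)
  expect_equal(blockOf[1], blockOf[2])
  expect_equal(blockOf[3], blockOf[4])
  expect_false(blockOf[1] == blockOf[3])
})

test_that("PCoA of Euclidean distances reproduces the configuration", {
  set.seed(71)
  pts <- matrix(rnorm(40), 20, 2)
  ax <- pcoaAxes(dist(pts))
  rec <- axisScores(ax)[, 1:2]
  pr <- vegan::procrustes(pts, rec)
  expect_lt(sum(pr$residuals^2), 1e-8)
  ## zero matrix: all eigenvalues numerically zero
  z <- pcoaAxes(as.dist(matrix(0, 4, 4)))
  expect_true(all(abs(axisEigenvalues(z)) < 1e-10))
})

test_that("PCoA reports negative eigenvalues of semimetric dissimilarities", {
  set.seed(73)
  m <- matrix(rpois(120, 5), 12, 10)
  ax <- pcoaAxes(vegan::vegdist(m, "bray"))
  expect_true(any(axisEigenvalues(ax) < 0))
  expect_true(all(is.finite(axisScores(ax))))
})

test_that("a betaNTI matrix is shifted to non-negative before ordination", {
  ds <- randomDataset(nTaxa = 15, nSamples = 6, seed = 79)
  bn <- betaNti(ds, nNull = 99, seed = 1)
  ax <- pcoaAxes(bn)
  expect_true(all(is.finite(axisScores(ax))))
  expect_gte(attr(axisScores(ax), "shift"), 0)
})

test_that("dbRDA on Euclidean distances equals classical RDA", {
  set.seed(83)
  Y <- matrix(rnorm(80), 20, 4)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  mc <- vegan::capscale(dist(Y) ~ a + b, data = X)
  mr <- vegan::rda(Y ~ a + b, data = X)
  fC <- (mc$CCA$tot.chi / mc$CCA$qrank) / (mc$CA$tot.chi / (20 - mc$CCA$qrank - 1))
  fR <- (mr$CCA$tot.chi / mr$CCA$qrank) / (mr$CA$tot.chi / (20 - mr$CCA$qrank - 1))
  expect_equal(fC, fR, tolerance = 1e-8)
  expect_equal(vegan::RsquareAdj(mc)$adj.r.squared,
               vegan::RsquareAdj(mr)$adj.r.squared, tolerance = 1e-8)
})

test_that("forward selection finds a planted linear signal first", {
  set.seed(89)
  n <- 30
  axes <- matrix(rnorm(n * 4), n, 4,
                 dimnames = list(NULL, paste0("PC", 1:4)))
  ## response driven by axis 2 (tiny second dimension keeps the
  ## dissimilarity full rank, which constrained ordination requires)
  resp <- dist(cbind(axes[, 2], 0.02 * rnorm(n)))
  sel <- dbrdaForward(as.matrix(resp), axes, alpha = 0.05, nPerm = 199,
                      seed = 17)
  expect_equal(sel$axis[1], "PC2")
  expect_equal(sel$p[1], 1 / 200)  # permutation floor
  ## cumulative adjusted R2 never decreases over selection steps
  expect_true(all(diff(sel$adj_r2_cum) >= -1e-12))
})

test_that("forward selection is deterministic given the seed", {
  set.seed(97)
  axes <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  resp <- as.matrix(dist(axes[, 1] + rnorm(25, 0, 0.5)))
  s1 <- dbrdaForward(resp, axes, nPerm = 99, seed = 4)
  s2 <- dbrdaForward(resp, axes, nPerm = 99, seed = 4)
  expect_identical(s1$axis, s2$axis)
  expect_identical(s1$p, s2$p)
})

test_that("Spearman screen handles monotone pairs and Bonferroni adjustment", {
  x <- sort(rnorm(25))
  b <- cbind(up = exp(x), down = -x^3)
  res <- correlateAxes(matrix(x, dimnames = list(NULL, "ax1")), b, family = 10)
  expect_equal(res$rho[res$variable == "up"], 1)
  expect_equal(res$rho[res$variable == "down"], -1)
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$p_adj <= 1))
  expect_error(correlateAxes(matrix(x), cbind(k = rep(1, 25))), "constant")
})

test_that("the driver wrapper recovers a planted environmental signal", {
  sim <- simulateMetacommunity(reducedConfig("env_filtering", seed = 311))
  bn <- betaNti(sim$dataset, nNull = 199, seed = 1)
  da <- driverAnalysis(bn, sim$dataset, alpha = 0.05, nPerm = 199, seed = 7)
  expect_s4_class(da$pcnm, "AxisSet")
  expect_s4_class(da$pca, "AxisSet")
  ## the site-level environmental gradient must be detected
  expect_gt(nrow(da$selection), 0)
  expect_true(all(c("axis", "adj_r2_cum", "df", "aic", "F", "p") %in%
                    names(da$selection)))
  expect_true(all(da$interpretation$interpretation %in%
                    c("ENV measured", "ENV unmeasured (spatially structured)")))
  expect_true(nrow(da$axisCorrelations) > 0)
})
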