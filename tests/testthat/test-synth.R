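test_that("simulation is bit-identical under a fixed seed", {
  cfg <- reducedConfig("env_filtering", seed = 77)
  a <- simulateMetacommunity(cfg)
  b <- simulateMetacommunity(cfg)
  expect_identical(otuCounts(a$dataset), otuCounts(b$dataset))
  expect_identical(sampleData(a$dataset), sampleData(b$dataset))
  expect_identical(otuTree(a$dataset)$edge.length,
                   otuTree(b$dataset)$edge.length)
  expect_identical(a$truth$env, b$truth$env)
  c <- simulateMetacommunity(reducedConfig("env_filtering", seed = 78))
  expect_false(identical(otuCounts(a$dataset), otuCounts(c$dataset)))
})

test_that("the default configuration mirrors the emulated study design", {
  cfg <- synthConfig(seed = 5)
  expect_equal(cfg$sites * cfg$plotsPerSite * cfg$hosts * cfg$replicates, 96)
  sim <- simulateMetacommunity(synthConfig(seed = 5, readsPerSample = 2000))
  expect_equal(nrow(otuCounts(sim$dataset)), 92)   # 96 - 4 dropout
  expect_lte(ncol(otuCounts(sim$dataset)), 449)
  expect_equal(length(otuTree(sim$dataset)$tip.label),
               ncol(otuCounts(sim$dataset)))
  smp <- sampleData(sim$dataset)
  expect_equal(length(unique(smp$site)), 2)
  expect_equal(length(unique(smp$plot)), 8)
  expect_equal(length(unique(smp$host)), 3)
  expect_true(all(c("x", "y", "pH", "OM", "GM", "season") %in% names(smp)))
})

test_that("simulated trees have the requested tips and positive lengths", {
  cfg <- reducedConfig("neutral_drift", seed = 9)
  tr <- simulateTree(cfg)
  expect_equal(length(tr$tip.label), 60)
  expect_true(all(tr$edge.length >= 0))
  expect_error(simulateTree(synthConfig(birth = 0.5, death = 0.5)),
               "birth > death")
})

test_that("Brownian niches have the closed-form tip variance and signal", {
  set.seed(15)
  tr <- ape::rphylo(30, 1, 0)   # ultrametric: equal root-to-tip depth
  depth <- max(ape::node.depth.edgelength(tr))
  rate <- 0.7
  reps <- vapply(1:500, function(i) evolveNiche(tr, rate),
                 numeric(30))
  tipVar <- mean(apply(reps, 1, var))
  expect_equal(tipVar, rate * depth, tolerance = 0.1 * rate * depth)
  ## zero rate: all optima collapse to the root value
  expect_true(all(evolveNiche(tr, 0) == 0))
  ## phylogenetic signal: closest relatives more similar than random pairs
  d <- ape::cophenetic.phylo(tr)
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  sqNn <- mean(vapply(1:500, function(i) {
    mean((reps[, i] - reps[nn, i])^2)
  }, numeric(1)))
  sqRnd <- mean(vapply(1:500, function(i) {
    mean((reps[, i] - reps[sample(30), i])^2)
  }, numeric(1)))
  expect_lt(sqNn, sqRnd)
})

test_that("an infinite dispersal length removes distance decay", {
  sim <- simulateMetacommunity(reducedConfig("dispersal_limitation",
                                             seed = 21, lambda = 1e12))
  ds <- sim$dataset
  cnt <- otuCounts(ds)
  bc <- as.matrix(vegan::vegdist(cnt, "bray"))
  smp <- sampleData(ds)
  cross <- outer(smp$site, smp$site, "!=")
  ut <- upper.tri(bc)
  expect_lt(abs(mean(bc[ut & cross]) - mean(bc[ut & !cross])), 0.02)
})

test_that("an infinitely wide niche filter reduces to neutral sampling", {
  wide <- simulateMetacommunity(reducedConfig("env_filtering", seed = 23,
                                              filterStrength = 1e6))
  neutral <- simulateMetacommunity(reducedConfig("neutral_drift", seed = 23,
                                                 driftGenerations = 0))
  mbc <- function(s) {
    m <- as.matrix(vegan::vegdist(otuCounts(s$dataset), "bray"))
    mean(m[upper.tri(m)])
  }
  expect_lt(abs(mbc(wide) - mbc(neutral)), 0.02)
})

test_that("doubling sequencing depth barely moves mean Bray-Curtis", {
  a <- simulateMetacommunity(reducedConfig("env_filtering", seed = 25,
                                           readsPerSample = 1000))
  b <- simulateMetacommunity(reducedConfig("env_filtering", seed = 25,
                                           readsPerSample = 2000))
  mbc <- function(s) {
    m <- as.matrix(vegan::vegdist(otuCounts(s$dataset), "bray"))
    mean(m[upper.tri(m)])
  }
  expect_lt(abs(mbc(a) - mbc(b)), 0.05)
  ## the latent structure is untouched: same environments, same niches
  expect_identical(a$truth$env, b$truth$env)
  expect_identical(a$truth$niche, b$truth$niche)
})

test_that("soil covariates carry the planted environmental gradient", {
  sim <- simulateMetacommunity(reducedConfig("env_filtering", seed = 27))
  smp <- sampleData(sim$dataset)
  expect_gt(cor(smp$pH, sim$truth$env), 0.8)
  expect_gt(cor(log(smp$OM), sim$truth$env), 0.8)
})

test_that("datasets round-trip through the on-disk directory layout", {
  sim <- simulateMetacommunity(reducedConfig("neutral_drift", seed = 29))
  dir <- withr::local_tempdir()
  writeDataset(sim$dataset, dir, truth = sim$truth)
  expect_true(all(file.exists(file.path(dir,
    c("otu_table.tsv", "tree.nwk", "metadata.csv", "truth.json")))))
  back <- readDataset(dir)
  ## tip order may differ after the Newick round trip; content must not
  ord <- otuNames(sim$dataset)
  expect_identical(otuCounts(back)[, ord], otuCounts(sim$dataset))
  expect_identical(sampleData(back)$sample_id, sampleNames(sim$dataset))
  expect_equal(phyloDistances(back)[ord, ord], phyloDistances(sim$dataset),
               tolerance = 1e-6)
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(tr$scenario, "neutral_drift")
})

test_that("degenerate filter configurations are refused", {
  expect_error(reducedConfig("env_filtering", seed = 1, filterStrength = 0),
               "degenerate")
  expect_error(synthConfig(replicates = 1), "replicates")
})
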