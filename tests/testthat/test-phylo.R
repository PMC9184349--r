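test_that("cophenetic distances are path sums on the tree", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- phyloDistances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  ## star tree: all pairs at twice the branch length
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  ds <- phyloDistances(star)
  expect_true(all(ds[upper.tri(ds)] == 6))
})

test_that("cophenetic distances agree with a naive path-walking oracle", {
  set.seed(20)
  tr <- ape::rtree(20)
  d <- phyloDistances(tr)
  o <- pathDistOracle(tr)
  expect_equal(d[rownames(o), colnames(o)], o, tolerance = 1e-10)
})

test_that("weighted MNTD matches the exhaustive nearest-neighbour scan", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  d <- phyloDistances(tr)
  expect_equal(mntdWeighted(c(A = 0.5, B = 0.5), d), 2)
  expect_true(is.na(mntdWeighted(c(A = 1, B = 0), d)))
  set.seed(31)
  for (rep in 1:20) {
    tr <- ape::rcoal(10)
    d <- phyloDistances(tr)
    f <- rexp(10) * rbinom(10, 1, 0.7)
    if (sum(f > 0) < 2) next
    names(f) <- rownames(d)
    expect_equal(mntdWeighted(f, d), mntdOracle(f, d), tolerance = 1e-12)
  }
})

test_that("betaMNTD is symmetric, zero on identical communities, and matches brute force", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  d <- phyloDistances(tr)
  expect_equal(betaMntd(c(1, 0), c(0, 1), d), 2)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    tr <- ape::rcoal(n)
    d <- phyloDistances(tr)
    fk <- rexp(n) * rbinom(n, 1, 0.8)
    fl <- rexp(n) * rbinom(n, 1, 0.8)
    if (sum(fk > 0) == 0 || sum(fl > 0) == 0) next
    expect_equal(betaMntd(fk, fl, d), bmntdOracle(fk, fl, d), tolerance = 1e-12)
    expect_equal(betaMntd(fk, fl, d), betaMntd(fl, fk, d), tolerance = 1e-15)
    expect_equal(betaMntd(fk, fk, d), 0)
  }
  expect_error(betaMntd(c(0, 0), c(1, 0), d), "empty")
})

test_that("observed MNTD and betaMNTD agree with picante", {
  skip_if_not_installed("picante")
  ds <- randomDataset(nTaxa = 15, nSamples = 6, seed = 23)
  comm <- otuCounts(ds)
  d <- phyloDistances(ds)
  ses <- picante::ses.mntd(comm, d, null.model = "taxa.labels", runs = 2,
                           abundance.weighted = TRUE)
  mine <- ntiScores(ds, nNull = 2, seed = 1)
  expect_equal(mine$mntd_obs, ses$mntd.obs, tolerance = 1e-10)
  cdn <- as.matrix(picante::comdistnt(comm, d, abundance.weighted = TRUE))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(betaMntd(comm[i, ], comm[j, ], d), cdn[i, j],
                 tolerance = 1e-10)
  }
})

test_that("NTI null matches picante's taxa-labels z-score within Monte-Carlo error", {
  skip_if_not_installed("picante")
  ds <- randomDataset(nTaxa = 12, nSamples = 5, seed = 29)
  comm <- otuCounts(ds)
  d <- phyloDistances(ds)
  set.seed(99)
  ses <- picante::ses.mntd(comm, d, null.model = "taxa.labels", runs = 999,
                           abundance.weighted = TRUE)
  mine <- ntiScores(ds, nNull = 999, seed = 7)
  ## NTI = -z; independent permutation streams, so compare loosely
  expect_equal(mine$nti, -ses$mntd.obs.z, tolerance = 0.25)
})

test_that("a community holding every pool taxon has a degenerate null", {
  tr <- ape::rcoal(6)
  tr$tip.label <- paste0("t", 1:6)
  cnt <- rbind(s1 = rep(5L, 6), s2 = c(9L, 3L, 0L, 0L, 1L, 0L))
  colnames(cnt) <- tr$tip.label
  smp <- data.frame(sample_id = c("s1", "s2"), site = "A", plot = "A1",
                    host = "h")
  ds <- assemblyDataset(cnt, tr, smp)
  nt <- ntiScores(ds, nNull = 99, seed = 1)
  expect_false(nt$valid[1])   # MNTD invariant under label shuffles
  expect_true(is.na(nt$nti[1]))
  expect_true(nt$valid[2])
})

test_that("sister-taxa communities are phylogenetically clustered (NTI > 0)", {
  ## two close sisters amid distant taxa: observed MNTD far below null mean
  tr <- ape::read.tree(text = "(((A:0.1,B:0.1):4.9,(C:2,D:2):3):5,(E:4,F:4):6);")
  cnt <- rbind(s1 = c(10L, 10L, 0L, 0L, 0L, 0L),
               s2 = c(0L, 0L, 7L, 0L, 6L, 0L))
  colnames(cnt) <- c("A", "B", "C", "D", "E", "F")
  smp <- data.frame(sample_id = c("s1", "s2"), site = "A", plot = "A1",
                    host = "h")
  ds <- assemblyDataset(cnt, tr, smp)
  nt <- ntiScores(ds, nNull = 999, seed = 3)
  expect_gt(nt$nti[1], 0)
})

test_that("identical communities give a degenerate betaMNTD null (flagged)", {
  ## taxa shared by both communities contribute distance 0 under every
  ## label permutation, so equal supports make betaMNTD identically zero
  ## and the null sd degenerate: the pair must be flagged, not scored
  ds <- randomDataset(nTaxa = 20, nSamples = 6, seed = 37)
  cnt <- otuCounts(ds)
  cnt["s02", ] <- cnt["s01", ]  # duplicated pair
  ds2 <- suppressMessages(assemblyDataset(cnt, otuTree(ds), sampleData(ds)))
  expect_message(bn <- betaNti(ds2, nNull = 199, seed = 11), "degenerate")
  expect_true(is.na(turnoverValues(bn)["s01", "s02"]))
  expect_false(bn@valid["s01", "s02"])
})

test_that("an observation at the null lower bound gives strongly negative betaNTI", {
  ## s2 = s1 minus taxon B, whose nearest retained relative A sits at the
  ## smallest tip-tip distance in the tree: the observed betaMNTD is the
  ## minimum attainable under any label shuffle
  tr <- ape::read.tree(text = "(((A:0.1,B:0.1):4.9,(C:2,D:2):3):5,(E:4,F:4):6);")
  cnt <- rbind(s1 = c(8L, 4L, 5L, 0L, 6L, 0L),
               s2 = c(8L, 0L, 5L, 0L, 6L, 0L),
               s3 = c(0L, 0L, 3L, 7L, 2L, 9L))
  colnames(cnt) <- c("A", "B", "C", "D", "E", "F")
  smp <- data.frame(sample_id = rownames(cnt), site = "A", plot = "A1",
                    host = "h")
  ds <- assemblyDataset(cnt, tr, smp)
  bn <- betaNti(ds, nNull = 999, seed = 13)
  expect_lt(turnoverValues(bn)["s1", "s2"], -1)
})

test_that("betaNTI is bit-identical under identical inputs and seed", {
  ds <- randomDataset(nTaxa = 15, nSamples = 6, seed = 41)
  a <- betaNti(ds, nNull = 99, seed = 5)
  b <- betaNti(ds, nNull = 99, seed = 5)
  expect_identical(turnoverValues(a), turnoverValues(b))
  c <- betaNti(ds, nNull = 99, seed = 6)
  expect_false(identical(turnoverValues(a), turnoverValues(c)))
})

test_that("null permutations preserve abundances: betaNTI matrix is symmetric with invalid diagonal", {
  ds <- randomDataset(nTaxa = 15, nSamples = 6, seed = 43)
  bn <- betaNti(ds, nNull = 99, seed = 5)
  v <- bn@values
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_false(any(diag(bn@valid)))
  lng <- turnoverLong(bn)
  expect_equal(nrow(lng), choose(6, 2))
})
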