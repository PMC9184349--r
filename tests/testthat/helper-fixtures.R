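## Fixtures built in code: no data files.

## random dataset with a random coalescent tree and uniform random counts;
## minimal but valid nested design metadata
randomDataset <- function(nTaxa = 20, nSamples = 8, reads = 200, seed = 1,
                          sites = 2) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    tr <- ape::rcoal(nTaxa)
    tr$tip.label <- sprintf("t%02d", seq_len(nTaxa))
    cnt <- t(vapply(seq_len(nSamples), function(i) {
      p <- rexp(nTaxa)
      as.integer(rmultinom(1, reads, p))
    }, integer(nTaxa)))
    dimnames(cnt) <- list(sprintf("s%02d", seq_len(nSamples)), tr$tip.label)
    site <- rep(sprintf("site%d", seq_len(sites)), length.out = nSamples)
    smp <- data.frame(
      sample_id = rownames(cnt),
      site = site,
      plot = paste0(site, "_p", rep(1:2, length.out = nSamples)),
      host = rep(c("hostA", "hostB"), length.out = nSamples),
      season = "spring",
      x = runif(nSamples, 0, 100), y = runif(nSamples, 0, 100),
      pH = rnorm(nSamples, 7, 0.3), OM = rlnorm(nSamples, 2, 0.3),
      GM = rnorm(nSamples, 20, 3),
      stringsAsFactors = FALSE
    )
    suppressMessages(assemblyDataset(cnt, tr, smp))
  })
}

## the reduced study-shaped configuration used throughout the test suite:
## 2 sites x 2 plots x 3 hosts x 2 replicates = 24 samples, 60 OTUs
reducedConfig <- function(scenario, seed, readsPerSample = 1000, ...) {
  synthConfig(nTaxa = 60, sites = 2, plotsPerSite = 2, hosts = 3,
              replicates = 2, dropout = 0, readsPerSample = readsPerSample,
              scenario = scenario, seed = seed, ...)
}

## tree with two deeply separated clades (within-clade depth `within`,
## clades joined at depth `split`)
twoCladeTree <- function(nA = 10, nB = 10, within = 1, split = 10) {
  mk <- function(n, pre) {
    tr <- ape::rcoal(n)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * within
    tr$tip.label <- paste0(pre, seq_len(n))
    sub(";$", "", ape::write.tree(tr))
  }
  txt <- paste0("(", mk(nA, "a"), ":", split - within, ",",
                mk(nB, "b"), ":", split - within, ");")
  ape::read.tree(text = txt)
}
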