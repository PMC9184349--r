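## Synthetic-data generator: dated birth-death phylogeny, Brownian niche
## evolution, nested sampling design (sites > plots > hosts > replicates)
## with hierarchical coordinates, latent environmental gradient with
## derived soil covariates, and OTU read counts produced under known
## assembly regimes. Gives every pipeline stage a ground-truth surface.

#' Synthetic-scenario configuration
#'
#' Defaults mirror the emulated field study: 2 sites x 4 plots x 3 host
#' species x 4 replicates (96 samples, 4 dropped at random to give 92),
#' 449 OTUs on a birth-death phylogeny, and roughly 70,000 reads per
#' sample. Site centres are ~100 km apart, plots spread within ~2 km of
#' their site centre, samples within ~30 m of their plot centre, so PCNM
#' axes separate the design scales by construction.
#'
#' Scenario knobs (units):
#' * `filterStrength`: niche breadth sigma of the Gaussian environmental
#'   filter, on the latent-environment scale (default 1; the planted
#'   site-to-site environmental contrast is `2 * envContrast` = 4, i.e.
#'   strong filtering).
#' * `nicheRate`: Brownian variance per unit time for niche evolution
#'   (default 1); tip optima are rescaled to the environment scale while
#'   keeping their phylogenetic correlation, so conservatism is governed
#'   by tree shape, not by the raw rate.
#' * `migration`: mixing proportion toward the regional mean community
#'   (default 0.9, i.e. strong homogenizing dispersal when that scenario
#'   is chosen).
#' * `lambda`: distance-decay length of the colonization kernel in
#'   coordinate units (default 2000 m: between the within-plot scale,
#'   tens of metres, and the between-plot scale, kilometres, so decay is
#'   planted between plots and between sites but is negligible within a
#'   plot).
#' * `driftGenerations`, `driftPopSize`: length and population size of the
#'   multinomial resampling chain in the neutral scenario (defaults 15 and
#'   1000).
#'
#' @param nTaxa number of OTUs (tree tips).
#' @param birth,death birth-death rates per time unit (`birth > death >= 0`).
#' @param sites,plotsPerSite,hosts,replicates nested design dimensions.
#' @param dropout samples removed at random after simulation (study had
#'   96 - 4 = 92).
#' @param scenario one of `neutral_drift`, `env_filtering`,
#'   `dispersal_limitation`, `homogenizing_dispersal`, `mixed`.
#' @param filterStrength,nicheRate,migration,lambda scenario knobs, above.
#' @param envContrast half-range of the site-level latent environment.
#' @param driftGenerations,driftPopSize neutral drift-chain controls.
#' @param readsPerSample sequencing depth per sample.
#' @param seed integer seed making the whole dataset reproducible.
#' @return a `SynthConfig` (validated list).
#' @export
synthConfig <- function(nTaxa = 449, birth = 1, death = 0.5,
                        sites = 2, plotsPerSite = 4, hosts = 3,
                        replicates = 4, dropout = 4,
                        scenario = c("neutral_drift", "env_filtering",
                                     "dispersal_limitation",
                                     "homogenizing_dispersal", "mixed"),
                        filterStrength = 1, nicheRate = 1, migration = 0.9,
                        lambda = 2000, envContrast = 2,
                        driftGenerations = 15, driftPopSize = 1000,
                        readsPerSample = 70000, seed = NULL) {
  scenario <- match.arg(scenario)
  cfg <- list(nTaxa = nTaxa, birth = birth, death = death, sites = sites,
              plotsPerSite = plotsPerSite, hosts = hosts,
              replicates = replicates, dropout = dropout,
              scenario = scenario, filterStrength = filterStrength,
              nicheRate = nicheRate, migration = migration, lambda = lambda,
              envContrast = envContrast,
              driftGenerations = driftGenerations,
              driftPopSize = driftPopSize,
              readsPerSample = readsPerSample, seed = seed)
  with(cfg, {
    stopifnot(nTaxa >= 3, birth > death, death >= 0, sites >= 1,
              plotsPerSite >= 1, hosts >= 1, replicates >= 2,
              dropout >= 0, filterStrength >= 0, nicheRate >= 0,
              migration >= 0, migration <= 1, lambda > 0,
              readsPerSample >= 1, driftGenerations >= 0, driftPopSize >= 2)
  })
  if (cfg$scenario == "env_filtering" && cfg$filterStrength == 0 &&
      cfg$sites > 1)
    stop("filterStrength = 0 with a heterogeneous environment is degenerate")
  structure(cfg, class = "SynthConfig")
}

#' Simulate a dated birth-death phylogeny
#'
#' Birth-death tree conditioned on the configured number of extant tips
#' (via `ape::rphylo`), branch lengths in time units.
#'
#' @param cfg a [synthConfig()] (or any list with `nTaxa`, `birth`,
#'   `death`).
#' @param seed optional seed (defaults to `cfg$seed`).
#' @return an `ape::phylo` with `cfg$nTaxa` tips labelled `otu0001`, ...
#' @export
simulateTree <- function(cfg, seed = cfg$seed) {
  stopifnot(cfg$birth > cfg$death, cfg$death >= 0)
  tr <- withSeed(seed, ape::rphylo(cfg$nTaxa, cfg$birth, cfg$death))
  tr$tip.label <- sprintf("otu%04d", seq_len(cfg$nTaxa))
  tr
}

#' Evolve niche optima along a phylogeny
#'
#' Brownian motion with variance `rate` per unit time from a root value of
#' 0, so related taxa receive similar optima (the phylogenetic
#' conservatism the turnover framework assumes) and tip variance is
#' approximately `rate` times the root-to-tip depth.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @param rate Brownian variance per unit time (>= 0).
#' @param seed optional seed.
#' @return named numeric vector of tip niche optima.
#' @export
evolveNiche <- function(tree, rate, seed = NULL) {
  stopifnot(rate >= 0)
  withSeed(seed, ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate),
                                 root.value = 0))
}

buildDesign <- function(cfg) {
  grid <- expand.grid(rep = seq_len(cfg$replicates),
                      host = sprintf("host%d", seq_len(cfg$hosts)),
                      plot = seq_len(cfg$plotsPerSite),
                      site = sprintf("site%s", LETTERS[seq_len(cfg$sites)]),
                      stringsAsFactors = FALSE)
  grid$plot <- paste0(sub("site", "", grid$site), grid$plot)
  grid$sample_id <- sprintf("s%03d", seq_len(nrow(grid)))
  grid$season <- ifelse(grid$rep %% 2 == 1, "spring", "autumn")
  grid
}

#' Simulate a metacommunity under a known assembly regime
#'
#' Builds the full synthetic dataset: tree, Brownian niche optima, nested
#' design with hierarchical coordinates, a site-level latent environmental
#' gradient with derived soil covariates (pH, OM, GM = deterministic
#' functions of the latent environment plus Gaussian noise), per-taxon
#' home locations, and per-sample expected relative abundances under the
#' configured scenario:
#' * `env_filtering`: expected abundance of taxon i in sample s is
#'   proportional to `base_i * exp(-(env_s - niche_i)^2 / (2 sigma^2))`;
#' * `dispersal_limitation`: proportional to
#'   `base_i * exp(-dist(s, home_i) / lambda)`;
#' * `homogenizing_dispersal`: `(1 - m) * local + m * regional mean`,
#'   local being the dispersal kernel weights;
#' * `neutral_drift`: multinomial resampling chains from the regional base
#'   abundances, no selection term;
#' * `mixed`: filter times kernel.
#'
#' Reads are then drawn multinomially at the configured depth (all
#' expected abundances are fixed before any read is drawn, so changing
#' only the depth leaves the latent structure untouched), `dropout`
#' samples are removed at random, and the aligned [AssemblyDataset] is
#' returned with the ground truth recorded before sequencing noise.
#'
#' @param cfg a [synthConfig()].
#' @param seed optional seed overriding `cfg$seed`; drives every random
#'   stage.
#' @return list with `dataset` (an [AssemblyDataset]) and `truth` (list:
#'   `scenario`, per-sample `env`, standardized `niche` optima, `homes`,
#'   `baseAbundance`, `expectedDominant` process).
#' @export
simulateMetacommunity <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "SynthConfig") || is.list(cfg))
  withSeed(seed, {
    tree <- ape::rphylo(cfg$nTaxa, cfg$birth, cfg$death)
    tree$tip.label <- sprintf("otu%04d", seq_len(cfg$nTaxa))
    nicheRaw <- ape::rTraitCont(tree, model = "BM",
                                sigma = sqrt(cfg$nicheRate), root.value = 0)
    ## rescale optima onto the environment scale, keeping the phylogenetic
    ## correlation structure (conservatism) intact
    niche <- if (sd(nicheRaw) > 0)
      (nicheRaw - mean(nicheRaw)) / sd(nicheRaw) * cfg$envContrast
    else nicheRaw

    des <- buildDesign(cfg)
    n <- nrow(des)
    siteIds <- unique(des$site)
    siteCenter <- cbind(x = (seq_along(siteIds) - 1) * 1e5, y = 0)
    rownames(siteCenter) <- siteIds
    plotIds <- unique(des$plot)
    plotCenter <- siteCenter[unique(des[, c("site", "plot")])$site, , drop = FALSE] +
      matrix(runif(2 * length(plotIds), -2000, 2000), ncol = 2)
    rownames(plotCenter) <- plotIds
    xy <- plotCenter[des$plot, , drop = FALSE] +
      matrix(runif(2 * n, -30, 30), ncol = 2)
    des$x <- xy[, 1]
    des$y <- xy[, 2]

    envSite <- setNames(seq(-1, 1, length.out = max(cfg$sites, 2))[seq_len(cfg$sites)] *
                          cfg$envContrast, siteIds)
    envPlot <- setNames(envSite[unique(des[, c("site", "plot")])$site] +
                          rnorm(length(plotIds), 0, 0.2), plotIds)
    env <- envPlot[des$plot] + rnorm(n, 0, 0.1)
    names(env) <- des$sample_id

    des$pH <- 7 + 0.4 * env + rnorm(n, 0, 0.15)
    des$OM <- exp(2.3 + 0.35 * env + rnorm(n, 0, 0.25))
    des$GM <- pmax(2, 20 + 4 * env + rnorm(n, 0, 2))

    base <- rlnorm(cfg$nTaxa, 0, 1)
    homes <- cbind(x = runif(cfg$nTaxa, min(des$x), max(des$x)),
                   y = runif(cfg$nTaxa, min(des$y), max(des$y)))
    rownames(homes) <- tree$tip.label

    kernel <- function(s) {
      dh <- sqrt((homes[, 1] - des$x[s])^2 + (homes[, 2] - des$y[s])^2)
      exp(-dh / cfg$lambda)
    }
    filterW <- function(s) {
      if (cfg$filterStrength == 0) return(rep(1, cfg$nTaxa))
      exp(-(env[s] - niche)^2 / (2 * cfg$filterStrength^2))
    }
    driftChain <- function(p) {
      for (g in seq_len(cfg$driftGenerations)) {
        p <- as.vector(rmultinom(1L, cfg$driftPopSize, p)) / cfg$driftPopSize
      }
      p
    }

    ## all expected abundances computed before any read is drawn
    P <- matrix(0, n, cfg$nTaxa, dimnames = list(des$sample_id, tree$tip.label))
    if (cfg$scenario == "homogenizing_dispersal") {
      localW <- t(vapply(seq_len(n), function(s) {
        w <- base * kernel(s)
        w / sum(w)
      }, numeric(cfg$nTaxa)))
      regional <- colMeans(localW)
      P <- (1 - cfg$migration) * localW +
        matrix(regional, n, cfg$nTaxa, byrow = TRUE) * cfg$migration
    } else {
      for (s in seq_len(n)) {
        w <- switch(cfg$scenario,
          neutral_drift = driftChain(base / sum(base)),
          env_filtering = base * filterW(s),
          dispersal_limitation = base * kernel(s),
          mixed = base * filterW(s) * kernel(s)
        )
        if (sum(w) <= 0)
          stop("degenerate expected abundances (all-zero) in sample ",
               des$sample_id[s], "; widen filterStrength or lambda")
        P[s, ] <- w / sum(w)
      }
    }

    counts <- matrix(0L, n, cfg$nTaxa,
                     dimnames = list(des$sample_id, tree$tip.label))
    for (s in seq_len(n)) {
      counts[s, ] <- as.integer(rmultinom(1L, cfg$readsPerSample, P[s, ]))
    }

    keepSamples <- seq_len(n)
    if (cfg$dropout > 0) {
      keepSamples <- sort(sample.int(n, n - cfg$dropout))
    }
    counts <- counts[keepSamples, , drop = FALSE]
    des <- des[keepSamples, , drop = FALSE]

    ds <- suppressMessages(assemblyDataset(counts, tree, des))
    truth <- list(
      scenario = cfg$scenario,
      env = env[keepSamples],
      niche = niche,
      homes = homes,
      baseAbundance = setNames(base, tree$tip.label),
      expectedDominant = switch(cfg$scenario,
        neutral_drift = "drift",
        env_filtering = "selection",
        dispersal_limitation = "dispersal_limitation",
        homogenizing_dispersal = "homogenizing_dispersal",
        mixed = "mixed")
    )
    list(dataset = ds, truth = truth)
  })
}

#' Write / read a simulated dataset directory
#'
#' `writeDataset` writes `otu_table.tsv` (canonical TSV dialect),
#' `tree.nwk`, `metadata.csv` and, when a truth list is supplied,
#' `truth.json`. `readDataset` reads the three core files back into an
#' aligned [AssemblyDataset].
#'
#' @param ds an [AssemblyDataset].
#' @param dir directory (created if absent).
#' @param truth optional ground-truth list to serialize as JSON.
#' @return `writeDataset`: `dir`, invisibly; `readDataset`: an
#'   [AssemblyDataset].
#' @export
writeDataset <- function(ds, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeOtuTable(otuCounts(ds), file.path(dir, "otu_table.tsv"))
  ape::write.tree(otuTree(ds), file.path(dir, "tree.nwk"))
  write.table(sampleData(ds), file.path(dir, "metadata.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    tr <- truth
    tr$homes <- NULL  # matrices serialize poorly; coordinates live in metadata
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname writeDataset
#' @param dropUnknownOtus passed to [assemblyDataset()].
#' @export
readDataset <- function(dir, dropUnknownOtus = FALSE) {
  assemblyDataset(
    readOtuTable(file.path(dir, "otu_table.tsv")),
    readTree(file.path(dir, "tree.nwk")),
    readSampleData(file.path(dir, "metadata.csv")),
    dropUnknownOtus = dropUnknownOtus
  )
}
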