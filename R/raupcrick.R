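## Raup-Crick null model on Bray-Curtis dissimilarity (RCbray).
##
## Null communities are assembled probabilistically from the sample pool in
## the Stegen-style two-stage recipe: species identities are drawn without
## replacement with probability proportional to pool occupancy, then the
## remaining individuals are assigned with probability proportional to
## pool-wide relative abundance, so every null community preserves the
## richness and the total count of its real counterpart. Restricting the
## pool restricts both stages, which is what scales the null to a habitat
## unit.

#' Bray-Curtis dissimilarity between two communities
#'
#' \eqn{BC = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, in \[0, 1\];
#' 0 for identical vectors, 1 for disjoint supports. Bray-Curtis is a
#' semimetric (no triangle inequality).
#'
#' @param x,y count or relative-abundance vectors over the same taxa, each
#'   with positive total.
#' @return dissimilarity in \[0, 1\].
#' @export
brayCurtis <- function(x, y) {
  if (sum(x) <= 0 || sum(y) <= 0) stop("empty community in brayCurtis")
  sum(abs(x - y)) / sum(x + y)
}

#' Draw one Raup-Crick null community
#'
#' Assembles a null community from the pool: `richness` species drawn
#' without replacement with probability proportional to `occupancy`
#' (uniform if `occupancyWeighting = FALSE`), each receiving one
#' individual; the remaining `total - richness` individuals are assigned
#' multinomially with probability proportional to `abundance` over the
#' drawn species (uniform if `abundanceFill = FALSE`).
#'
#' @param richness number of species in the null community.
#' @param total total count of the null community (>= richness).
#' @param occupancy per-species occupancy (number of pool samples occupied).
#' @param abundance per-species pooled counts (or relative abundances).
#' @param occupancyWeighting,abundanceFill stage weighting flags.
#' @return integer count vector over all pool species.
#' @export
rcNullCommunity <- function(richness, total, occupancy, abundance,
                            occupancyWeighting = TRUE, abundanceFill = TRUE) {
  S <- length(occupancy)
  stopifnot(richness >= 1L, richness <= S, total >= richness)
  sp <- sample.int(S, richness, replace = FALSE,
                   prob = if (occupancyWeighting) occupancy else NULL)
  x <- integer(S)
  x[sp] <- 1L
  extra <- total - richness
  if (extra > 0L) {
    pr <- if (abundanceFill) abundance[sp] else rep.int(1, richness)
    if (richness == 1L) {
      x[sp] <- as.integer(total)
    } else {
      x[sp] <- x[sp] + as.integer(rmultinom(1L, extra, pr))
    }
  }
  x
}

#' Pairwise Raup-Crick Bray-Curtis (RCbray) turnover
#'
#' For every pair of pool samples, the observed Bray-Curtis dissimilarity
#' (on counts, matching the null communities' count scale; set
#' `relAbund = TRUE` for a relative-abundance variant) is located within a
#' null distribution of `nNull` Bray-Curtis values between freshly
#' assembled null-community pairs (see [rcNullCommunity()]), each
#' preserving its counterpart's richness and total. The score is the
#' rescaled mid-P statistic
#' \deqn{RC_{bray} = 2\,[(\#\{BC_{null} < BC_{obs}\} +
#'       0.5\,\#\{BC_{null} = BC_{obs}\}) / n_{null} - 0.5] \in [-1, 1].}
#' RCbray > 0.95 flags turnover beyond chance (dispersal limitation when
#' selection is excluded), RCbray < -0.95 turnover below chance
#' (homogenizing dispersal). Ties count 0.5 (mid-P convention).
#'
#' Pairs are visited in a fixed order under one seeded stream, so results
#' are bit-identical for identical inputs and seed.
#'
#' @inheritParams betaNti
#' @param occupancyWeighting species draw proportional to pool occupancy.
#' @param abundanceFill individual filling proportional to pooled relative
#'   abundance.
#' @param relAbund compare observed communities on relative abundances
#'   instead of counts (non-default).
#' @return a [TurnoverMatrix] with `metric = "RCbray"`.
#' @export
rcBray <- function(ds, pool = sampleNames(ds), nNull = 999, seed = NULL,
                   occupancyWeighting = TRUE, abundanceFill = TRUE,
                   relAbund = FALSE, poolId = "region") {
  if (length(pool) < 2L) stop("rcBray needs a pool of >= 2 samples")
  if (nNull < 1) stop("nNull must be >= 1")
  cnt <- otuCounts(ds)
  bad <- setdiff(pool, rownames(cnt))
  if (length(bad)) stop("pool sample(s) not in dataset: ",
                        paste(bad, collapse = ", "))
  cnt <- cnt[pool, , drop = FALSE]
  keep <- colSums(cnt) > 0
  cnt <- cnt[, keep, drop = FALSE]
  occ <- colSums(cnt > 0)
  ab <- colSums(cnt)
  rich <- rowSums(cnt > 0)
  tot <- rowSums(cnt)
  stopifnot(all(rich <= ncol(cnt)))
  n <- length(pool)
  ij <- pairIndices(n)
  rc <- matrix(0, n, n)
  bcVec <- function(x, y) if (relAbund) brayCurtis(x / sum(x), y / sum(y)) else brayCurtis(x, y)
  withSeed(seed, {
    for (r in seq_len(nrow(ij))) {
      k <- ij[r, 1]; l <- ij[r, 2]
      obsBC <- bcVec(cnt[k, ], cnt[l, ])
      less <- 0
      ties <- 0
      for (b in seq_len(nNull)) {
        nk <- rcNullCommunity(rich[k], tot[k], occ, ab,
                              occupancyWeighting, abundanceFill)
        nl <- rcNullCommunity(rich[l], tot[l], occ, ab,
                              occupancyWeighting, abundanceFill)
        nb <- bcVec(nk, nl)
        if (nb < obsBC) less <- less + 1
        else if (nb == obsBC) ties <- ties + 1
      }
      rc[k, l] <- rc[l, k] <- 2 * ((less + 0.5 * ties) / nNull - 0.5)
    }
  })
  valid <- matrix(TRUE, n, n)
  diag(valid) <- FALSE
  dimnames(rc) <- dimnames(valid) <- list(pool, pool)
  new("TurnoverMatrix", values = rc, valid = valid, metric = "RCbray",
      poolId = poolId, nNull = as.integer(nNull),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      provenance = list(occupancyWeighting = occupancyWeighting,
                        abundanceFill = abundanceFill,
                        relAbund = relAbund,
                        totals = "observed per-sample totals preserved"))
}
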