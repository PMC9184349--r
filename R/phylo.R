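## Phylogenetic turnover null models: abundance-weighted MNTD / NTI and
## betaMNTD / betaNTI with taxa-shuffle (taxa-labels) permutation nulls.
##
## The null randomizes the identity of the taxa on the distance matrix
## (rows and columns permuted jointly) while every community keeps its
## abundance vector, so only the phylogenetic placement of abundance is
## randomized. The shuffled label set is restricted to the taxa occurring
## in the chosen sample pool: restricting the pool is what scales the
## inference to region / site / plot / host (shuffling taxa absent from a
## unit would leak regional phylogenetic structure into its local null).

#' @rdname phyloDistances
#' @export
setMethod("phyloDistances", "ANY", function(x) {
  if (!inherits(x, "phylo")) stop("need an AssemblyDataset or an ape phylo")
  ape::cophenetic.phylo(x)
})

#' Abundance-weighted mean nearest taxon distance (MNTD)
#'
#' For one community: the mean, weighted by relative abundance, of each
#' taxon's phylogenetic distance to its nearest co-occurring relative,
#' \eqn{\sum_i f_i \min_{j \ne i, f_j > 0} d(i,j)}. Units are the tree's
#' time units. Undefined (NA) for communities with fewer than two taxa.
#'
#' @param f relative-abundance vector named by (or aligned with) the rows
#'   of `d`; only strictly positive entries count as present.
#' @param d symmetric cophenetic distance matrix.
#' @return weighted MNTD, or `NA_real_` if fewer than 2 taxa are present.
#' @export
mntdWeighted <- function(f, d) {
  idx <- which(f > 0)
  if (length(idx) < 2L) return(NA_real_)
  sub <- d[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  nn <- rowMins(sub)
  fr <- f[idx] / sum(f[idx])
  sum(fr * nn)
}

#' Abundance-weighted between-community MNTD (betaMNTD)
#'
#' The between-assemblage analogue of MNTD: for each taxon of one
#' community, its distance to the nearest taxon of the other community
#' (zero for shared taxa), abundance-weighted and averaged over both
#' directions,
#' \deqn{0.5\,[\sum_i f_{i,k} \min_{j \in l} d(i,j) +
#'       \sum_j f_{j,l} \min_{i \in k} d(j,i)].}
#' Symmetric in its arguments and zero for identical communities.
#'
#' @param fk,fl relative-abundance (or count) vectors over the same taxa
#'   as `d`.
#' @param d symmetric cophenetic distance matrix.
#' @return betaMNTD in time units.
#' @export
betaMntd <- function(fk, fl, d) {
  ik <- which(fk > 0)
  il <- which(fl > 0)
  if (!length(ik) || !length(il)) stop("empty community in betaMntd")
  frk <- fk[ik] / sum(fk[ik])
  frl <- fl[il] / sum(fl[il])
  nnk <- rowMins(d[ik, il, drop = FALSE])
  nnl <- rowMins(d[il, ik, drop = FALSE])
  0.5 * (sum(frk * nnk) + sum(frl * nnl))
}

## betaMNTD for all sample pairs at once.
## Frel: taxa x samples relative abundances; d: taxa x taxa distances;
## supports: list of taxon index vectors per sample.
## M[i, l] = min_{j in support(l)} d(i, j); A = Frel' M gives the directed
## sums, and the symmetrized 0.5 (A + A') is the betaMNTD matrix (shared
## taxa hit d(i,i) = 0 automatically).
bmntdMatrix <- function(Frel, d, supports) {
  n <- length(supports)
  M <- matrix(0, nrow(Frel), n)
  for (l in seq_len(n)) {
    M[, l] <- rowMins(d[, supports[[l]], drop = FALSE])
  }
  A <- crossprod(Frel, M)
  0.5 * (A + t(A))
}

poolSlice <- function(ds, pool, weighted) {
  cnt <- otuCounts(ds)
  bad <- setdiff(pool, rownames(cnt))
  if (length(bad)) stop("pool sample(s) not in dataset: ",
                        paste(bad, collapse = ", "))
  cnt <- cnt[pool, , drop = FALSE]
  keep <- colSums(cnt) > 0
  cnt <- cnt[, keep, drop = FALSE]
  if (!weighted) cnt <- (cnt > 0) * 1L
  list(
    counts = cnt,
    d = phyloDistances(ds)[keep, keep, drop = FALSE],
    Frel = t(relAbundanceMatrix(cnt)),
    supports = lapply(seq_len(nrow(cnt)), function(i) which(cnt[i, ] > 0))
  )
}

#' Nearest taxon index (NTI) with a taxa-labels null
#'
#' Per-sample abundance-weighted MNTD compared against a null obtained by
#' permuting the taxon labels of the distance matrix uniformly at random
#' (`nNull` permutations over the taxa present in `pool`). The index is the
#' negated z-score, \eqn{NTI = -(MNTD_{obs} - \bar{MNTD}_{null}) / sd_{null}},
#' so phylogenetic clustering (observed below the null mean) gives NTI > 0.
#' The null standard deviation uses denominator `nNull - 1`.
#'
#' Samples with fewer than two taxa, and samples whose MNTD is invariant
#' under label shuffles (e.g. a community containing every pool taxon),
#' are flagged invalid.
#'
#' @param ds an [AssemblyDataset].
#' @param pool sample ids defining the null pool (default: all samples);
#'   the shuffled label set is the union of taxa occurring in the pool.
#' @param nNull number of null permutations (>= 1).
#' @param seed integer seed for reproducibility (optional).
#' @param weighted abundance-weighted (default) or presence/absence.
#' @return data.frame with one row per pool sample: `sample_id`,
#'   `mntd_obs`, `null_mean`, `null_sd`, `nti`, `n_taxa`, `valid`,
#'   `n_null`, `seed`.
#' @export
ntiScores <- function(ds, pool = sampleNames(ds), nNull = 999, seed = NULL,
                      weighted = TRUE) {
  if (nNull < 1) stop("nNull must be >= 1")
  ps <- poolSlice(ds, pool, weighted)
  S <- nrow(ps$Frel)
  n <- length(pool)
  fmat <- t(ps$Frel)  # samples x taxa relative abundances
  obs <- vapply(seq_len(n), function(i) mntdWeighted(fmat[i, ], ps$d),
                numeric(1))
  nullSum <- numeric(n)
  nullSq <- numeric(n)
  withSeed(seed, {
    for (b in seq_len(nNull)) {
      p <- sample.int(S)
      dp <- ps$d[p, p, drop = FALSE]
      nb <- vapply(seq_len(n), function(i) mntdWeighted(fmat[i, ], dp),
                   numeric(1))
      nullSum <- nullSum + nb
      nullSq <- nullSq + nb * nb
    }
  })
  nm <- nullSum / nNull
  nv <- if (nNull > 1) pmax(0, (nullSq - nNull * nm^2) / (nNull - 1)) else rep(NA_real_, n)
  nsd <- sqrt(nv)
  valid <- !is.na(obs) & !is.na(nsd) & nsd > 1e-12
  nti <- ifelse(valid, -(obs - nm) / nsd, NA_real_)
  data.frame(
    sample_id = pool,
    mntd_obs = obs,
    null_mean = ifelse(is.na(obs), NA_real_, nm),
    null_sd = ifelse(is.na(obs), NA_real_, nsd),
    nti = nti,
    n_taxa = vapply(seq_len(n), function(i) sum(fmat[i, ] > 0), integer(1)),
    valid = valid,
    n_null = nNull,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    stringsAsFactors = FALSE
  )
}

#' Pairwise betaNTI with a taxa-shuffle null
#'
#' For every pair of samples in `pool`, the observed [betaMntd()] is
#' compared to `nNull` values obtained by jointly permuting the taxon
#' labels of the cophenetic distance matrix (taxa present in the pool
#' only):
#' \deqn{\beta NTI = (\beta MNTD_{obs} - \bar{\beta MNTD}_{null}) / sd_{null},}
#' with the null sd using denominator `nNull - 1`. |betaNTI| > 2 is the
#' conventional signature of selection; the sign separates heterogeneous
#' (> 2) from homogeneous (< -2) selection.
#'
#' One permutation stream serves the whole matrix: permutations are drawn
#' in a fixed order independent of the pair, so results are bit-identical
#' for identical `(dataset, pool, nNull, seed)`. Pairs with a degenerate
#' null (sd = 0) are flagged invalid.
#'
#' @inheritParams ntiScores
#' @param poolId label stored as null-pool provenance.
#' @return a [TurnoverMatrix] with `metric = "bNTI"` over the pool samples.
#' @export
betaNti <- function(ds, pool = sampleNames(ds), nNull = 999, seed = NULL,
                    weighted = TRUE, poolId = "region") {
  if (length(pool) < 2L) stop("betaNti needs a pool of >= 2 samples")
  if (nNull < 1) stop("nNull must be >= 1")
  ps <- poolSlice(ds, pool, weighted)
  S <- nrow(ps$Frel)
  n <- length(pool)
  obs <- bmntdMatrix(ps$Frel, ps$d, ps$supports)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  withSeed(seed, {
    for (b in seq_len(nNull)) {
      p <- sample.int(S)
      nb <- bmntdMatrix(ps$Frel, ps$d[p, p, drop = FALSE], ps$supports)
      sum1 <- sum1 + nb
      sum2 <- sum2 + nb * nb
    }
  })
  nm <- sum1 / nNull
  nv <- if (nNull > 1) (sum2 - nNull * nm^2) / (nNull - 1) else matrix(NA_real_, n, n)
  nv[nv < 0] <- 0  # guard tiny negative round-off
  nsd <- sqrt(nv)
  valid <- is.finite(nsd) & nsd > 1e-12
  diag(valid) <- FALSE
  z <- matrix(NA_real_, n, n)
  z[valid] <- (obs[valid] - nm[valid]) / nsd[valid]
  z[!valid] <- 0
  dimnames(z) <- dimnames(valid) <- list(pool, pool)
  nInvalid <- sum(valid[upper.tri(valid)] == FALSE)
  if (nInvalid > 0)
    message(poolId, ": ", nInvalid, " pair(s) with degenerate betaMNTD null flagged invalid")
  new("TurnoverMatrix", values = z, valid = valid, metric = "bNTI",
      poolId = poolId, nNull = as.integer(nNull),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      provenance = list(weighted = weighted, null = "taxa-shuffle"))
}
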