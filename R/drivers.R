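## Environmental / spatial driver analysis of turnover: PCNM spatial
## decomposition, PCA of standardized predictors, PCoA of turnover
## matrices, distance-based RDA with permutation forward selection, and
## Spearman/Bonferroni correlation screens.

#' Principal coordinates of neighbour matrices (PCNM / Moran eigenvectors)
#'
#' Decomposes sample coordinates into multi-scale spatial predictors: the
#' Euclidean distance matrix is truncated at the longest edge of its
#' minimum spanning tree, distances beyond the threshold are replaced by
#' four times the threshold, and principal coordinates of the truncated
#' matrix with positive eigenvalues are retained (Borcard-Legendre
#' construction, via `vegan::pcnm`). On a regular transect the axes are
#' discretized sinusoids of decreasing period.
#'
#' @param coords numeric matrix/data.frame of projected sample coordinates
#'   (>= 3 non-collocated points).
#' @return an [AxisSet] of kind `"PCNM"`; scores are mutually orthogonal.
#' @export
pcnmAxes <- function(coords) {
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  dd <- dist(coords)
  if (max(dd) == 0) stop("all points identical: no spatial structure")
  if (nrow(coords) < 3L) stop("need >= 3 points for PCNM")
  pc <- vegan::pcnm(dd)
  ## vegan returns eigenvectors for positive eigenvalues only
  sc <- as.matrix(pc$vectors)
  if (ncol(sc) == 0) stop("no positive-eigenvalue PCNM axis")
  rownames(sc) <- rownames(coords)
  new("AxisSet", kind = "PCNM", scores = sc,
      eig = pc$values[seq_len(ncol(sc))], loadings = matrix(0, 0, 0))
}

#' Principal component analysis of standardized predictors
#'
#' Variables are z-scored (zero-variance variables are an error), then
#' decomposed into orthonormal loadings; component variances sum to the
#' number of variables.
#'
#' @param predictors numeric matrix/data.frame of predictor variables,
#'   no missing values.
#' @return an [AxisSet] of kind `"PCA"` with scores, component variances
#'   (`axisEigenvalues`) and loadings.
#' @export
pcaAxes <- function(predictors) {
  X <- as.matrix(predictors)
  if (any(is.na(X))) stop("missing values in predictors; refusing to impute")
  if (ncol(X) < 2L) stop("need >= 2 variables for PCA")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) stop("zero-variance predictor(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  pr <- prcomp(X, center = TRUE, scale. = TRUE)
  new("AxisSet", kind = "PCA", scores = pr$x,
      eig = pr$sdev^2, loadings = pr$rotation)
}

## Coerce a turnover matrix / dist / matrix into a dist; betaNTI can be
## negative and is not a distance, so it is shifted by its minimum to
## non-negative values first (shift recorded as an attribute).
turnoverToDist <- function(x) {
  m <- if (is(x, "TurnoverMatrix")) x@values else as.matrix(x)
  if (is(x, "TurnoverMatrix")) {
    bad <- !x@valid
    diag(bad) <- FALSE
    if (any(bad)) {
      ## degenerate-null pairs carry no deviation signal; enter at z = 0
      message("treating ", sum(bad) / 2,
              " invalid pair(s) as zero deviation for ordination")
      m[bad] <- 0
    }
  }
  shift <- 0
  mn <- min(m[upper.tri(m)], na.rm = TRUE)
  if (mn < 0) {
    shift <- -mn
    m <- m + shift
  }
  diag(m) <- 0
  d <- as.dist(m)
  attr(d, "shift") <- shift
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of the squared dissimilarities followed by
#' eigendecomposition; axes with positive eigenvalues are retained, and
#' negative eigenvalues (Bray-Curtis and betaNTI are not Euclidean) are
#' reported, not corrected. A [TurnoverMatrix] response is shifted to
#' non-negative values first (betaNTI is a z-score, not a distance); the
#' shift is recorded in `attr(axisScores(.), "shift")`.
#'
#' @param d a symmetric matrix, `dist`, or [TurnoverMatrix].
#' @return an [AxisSet] of kind `"PCoA"`; `axisEigenvalues` carries all
#'   eigenvalues including negative ones.
#' @export
pcoaAxes <- function(d) {
  dd <- if (inherits(d, "dist")) d else turnoverToDist(d)
  n <- attr(dd, "Size")
  ## cmdscale warns when asked for more axes than positive eigenvalues;
  ## expected for semimetric input, so silenced here
  mds <- suppressWarnings(cmdscale(dd, k = n - 1L, eig = TRUE))
  eig <- mds$eig
  npos <- min(sum(eig > 1e-8 * max(abs(eig), 1e-300)), ncol(mds$points))
  sc <- mds$points[, seq_len(npos), drop = FALSE]
  if (npos > 0) colnames(sc) <- paste0("PCoA", seq_len(npos))
  attr(sc, "shift") <- attr(dd, "shift")
  new("AxisSet", kind = "PCoA", scores = sc,
      eig = sort(eig, decreasing = TRUE), loadings = matrix(0, 0, 0))
}

#' Distance-based RDA with permutation forward selection
#'
#' Constrained ordination of a dissimilarity response on candidate
#' predictor axes (`vegan::capscale`), with forward selection: at each
#' step the candidate with the smallest permutation p-value of the partial
#' pseudo-F enters, and selection stops when no candidate reaches
#' `alpha` or when the cumulative adjusted R-squared would exceed the
#' full-model adjusted R-squared (the double stopping criterion;
#' disable the ceiling with `adjR2Ceiling = FALSE`). An AIC-like
#' criterion is reported for each step but never used to stop.
#'
#' A [TurnoverMatrix] response (betaNTI) is shifted to non-negative values
#' before ordination, see [pcoaAxes()].
#'
#' @param response a `dist`, symmetric matrix or [TurnoverMatrix].
#' @param axes an [AxisSet] (typically PCA axes) or a numeric matrix of
#'   candidate predictors, rows aligned with the response.
#' @param alpha permutation p-value threshold to enter (default 0.05).
#' @param nPerm permutations per test (default 999); must resolve `alpha`
#'   (i.e. `1/(nPerm+1) <= alpha`).
#' @param seed integer seed for the permutation stream.
#' @param adjR2Ceiling stop when cumulative adjusted R2 would exceed the
#'   full model's (default TRUE).
#' @return data.frame (selection table): one row per selected axis with
#'   `axis`, `adj_r2_cum`, `df`, `aic`, `F`, `p`, plus attributes
#'   `full_adj_r2` and `model` (the final capscale fit). Zero rows if
#'   nothing is selected.
#' @export
dbrdaForward <- function(response, axes, alpha = 0.05, nPerm = 999,
                         seed = NULL, adjR2Ceiling = TRUE) {
  if (1 / (nPerm + 1) > alpha)
    stop("nPerm too small to resolve alpha = ", alpha)
  d <- if (inherits(response, "dist")) response else turnoverToDist(response)
  X <- as.data.frame(if (is(axes, "AxisSet")) axisScores(axes) else axes)
  if (attr(d, "Size") != nrow(X)) stop("response and predictors not aligned")
  full <- vegan::capscale(d ~ ., data = X)
  fullR2 <- vegan::RsquareAdj(full)$adj.r.squared
  candidates <- names(X)
  chosen <- character(0)
  rows <- list()
  withSeed(seed, {
    repeat {
      remaining <- setdiff(candidates, chosen)
      if (!length(remaining)) break
      pvals <- numeric(length(remaining))
      fvals <- numeric(length(remaining))
      for (i in seq_along(remaining)) {
        fm <- stats::reformulate(c(chosen, remaining[i]), response = "d")
        m1 <- vegan::capscale(fm, data = X)
        an <- vegan::anova.cca(m1, permutations = nPerm, by = "margin")
        j <- match(remaining[i], rownames(an))
        pvals[i] <- an[j, "Pr(>F)"]
        fvals[i] <- an[j, "F"]
      }
      best <- which.min(pvals)
      if (pvals[best] > alpha) break
      trial <- c(chosen, remaining[best])
      mTrial <- vegan::capscale(stats::reformulate(trial, response = "d"), data = X)
      r2 <- vegan::RsquareAdj(mTrial)$adj.r.squared
      chosen <- trial
      rows[[length(rows) + 1L]] <- data.frame(
        axis = remaining[best],
        adj_r2_cum = r2,
        df = nrow(X) - length(chosen) - 1L,
        aic = stats::extractAIC(mTrial)[2L],
        F = fvals[best],
        p = pvals[best],
        stringsAsFactors = FALSE
      )
      ## double stopping rule: once the cumulative adjusted R2 exceeds the
      ## full model's, no further candidate may enter (the alpha-significant
      ## step that crossed the ceiling is kept)
      if (adjR2Ceiling && !is.na(fullR2) && !is.na(r2) && r2 > fullR2) break
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(axis = character(0), adj_r2_cum = numeric(0), df = integer(0),
               aic = numeric(0), F = numeric(0), p = numeric(0))
  attr(out, "full_adj_r2") <- fullR2
  if (length(chosen))
    attr(out, "model") <- vegan::capscale(stats::reformulate(chosen, response = "d"),
                                          data = X)
  out
}

#' Spearman correlations with Bonferroni adjustment
#'
#' Correlates each ordination axis with each variable (or taxon relative
#' abundance): Spearman rho, raw p (asymptotic, ties allowed), and
#' Bonferroni-adjusted p = min(1, p * family). By default the family size
#' is the number of tests performed in the call.
#'
#' @param a an [AxisSet] or score matrix (samples x axes).
#' @param b numeric matrix/data.frame of variables, rows aligned with `a`.
#' @param family Bonferroni family size (default: number of tests).
#' @return data.frame with `axis`, `variable`, `rho`, `p`, `p_adj`.
#' @export
correlateAxes <- function(a, b, family = NULL) {
  A <- if (is(a, "AxisSet")) axisScores(a) else as.matrix(a)
  B <- as.matrix(b)
  if (nrow(A) != nrow(B)) stop("rows of axes and variables not aligned")
  if (is.null(colnames(A))) colnames(A) <- paste0("axis", seq_len(ncol(A)))
  if (is.null(colnames(B))) colnames(B) <- paste0("var", seq_len(ncol(B)))
  const <- apply(B, 2, function(v) sd(v) == 0)
  if (any(const)) stop("constant column(s): ",
                       paste(colnames(B)[const], collapse = ", "))
  grid <- expand.grid(axis = colnames(A), variable = colnames(B),
                      stringsAsFactors = FALSE)
  family <- family %||% nrow(grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- suppressWarnings(cor.test(A[, grid$axis[i]], B[, grid$variable[i]],
                                    method = "spearman", exact = FALSE))
    data.frame(axis = grid$axis[i], variable = grid$variable[i],
               rho = unname(ct$estimate), p = ct$p.value,
               p_adj = min(1, ct$p.value * family),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full driver analysis of a turnover matrix
#'
#' Convenience wrapper reproducing the standard driver workflow: PCNM of
#' sample coordinates, PCA of the standardized predictor block (soil
#' covariates + PCNM axes + optional host-phylogeny PCoA axes), forward
#' dbRDA selection of PCA axes against the turnover response, and a
#' Spearman/Bonferroni screen of turnover PCoA axes against the selected
#' PCA axes. The host-plant phylogeny enters as the first two PCoA axes
#' of its distance matrix.
#'
#' Interpretation aid: for each selected PCA axis the report lists the
#' dominant loading block (`soil` / `host` = measured environment,
#' `spatial` = spatially structured unmeasured environment); a loading
#' report, not a causal claim.
#'
#' @param tm a [TurnoverMatrix] (betaNTI or RCbray).
#' @param ds the [AssemblyDataset] the matrix came from.
#' @param hostPhyloDist optional square host-species phylogenetic distance
#'   matrix (dimnames = host levels).
#' @param alpha,nPerm,seed forward-selection controls, see
#'   [dbrdaForward()].
#' @return list with `pcnm`, `pca` ([AxisSet]s), `selection` (data.frame),
#'   `axisCorrelations` (data.frame; empty if nothing selected) and
#'   `interpretation` (data.frame of dominant loading blocks).
#' @export
driverAnalysis <- function(tm, ds, hostPhyloDist = NULL, alpha = 0.05,
                           nPerm = 999, seed = NULL) {
  smp <- sampleData(ds)
  need <- c("x", "y", "pH", "OM", "GM")
  miss <- setdiff(need, names(smp))
  if (length(miss)) stop("driver analysis needs metadata column(s): ",
                         paste(miss, collapse = ", "))
  soil <- as.matrix(smp[, c("pH", "OM", "GM")])
  if (any(is.na(soil))) stop("missing soil covariates; refusing to impute")
  pcnm <- pcnmAxes(as.matrix(smp[, c("x", "y")]))
  block <- cbind(soil, axisScores(pcnm))
  blockKind <- c(rep("soil", 3L), rep("spatial", ncol(axisScores(pcnm))))
  if (!is.null(hostPhyloDist)) {
    hp <- cmdscale(as.dist(as.matrix(hostPhyloDist)), k = 2L)
    hostAxes <- hp[match(as.character(smp$host), rownames(as.matrix(hostPhyloDist))), ,
                   drop = FALSE]
    colnames(hostAxes) <- c("hostPCo1", "hostPCo2")
    block <- cbind(block, hostAxes)
    blockKind <- c(blockKind, "host", "host")
  }
  pca <- pcaAxes(block)
  sel <- dbrdaForward(tm, pca, alpha = alpha, nPerm = nPerm, seed = seed)
  interp <- NULL
  corrs <- data.frame()
  if (nrow(sel)) {
    ld <- axisLoadings(pca)
    interp <- do.call(rbind, lapply(sel$axis, function(ax) {
      w <- abs(ld[, ax])
      byKind <- tapply(w, blockKind, max)
      data.frame(axis = ax,
                 dominant_block = names(byKind)[which.max(byKind)],
                 interpretation = if (names(byKind)[which.max(byKind)] == "spatial")
                   "ENV unmeasured (spatially structured)" else "ENV measured",
                 stringsAsFactors = FALSE)
    }))
    pco <- pcoaAxes(tm)
    corrs <- correlateAxes(pco, axisScores(pca)[, sel$axis, drop = FALSE])
  }
  list(pcnm = pcnm, pca = pca, selection = sel,
       axisCorrelations = corrs, interpretation = interp)
}
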