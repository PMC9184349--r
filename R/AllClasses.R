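#' @include AllGenerics.R
NULL

#' Aligned community dataset: OTU counts, dated phylogeny, sample design
#'
#' The central container of the package, holding a samples-by-OTUs integer
#' count matrix, a dated phylogeny over exactly the same OTUs, and a
#' sample-data frame describing the nested sampling design
#' (site / plot-in-site / host plant), coordinates and soil covariates.
#' All three components are mutually aligned at construction
#' (see [assemblyDataset()]) and the cophenetic distance matrix is cached.
#'
#' Invariants enforced by the validity method:
#' * count matrix is non-negative integer with unique sample and OTU ids;
#' * every sample has total count > 0 and every OTU occurs in >= 1 sample;
#' * tree tips, count columns and cached distances name the same OTU set,
#'   in identical order;
#' * `sampleData` rows match count rows in identical order;
#' * each plot belongs to exactly one site (nested design);
#' * coordinates, when present, are finite.
#'
#' @slot counts integer matrix, samples x OTUs.
#' @slot tree an `ape::phylo` with branch lengths in time units.
#' @slot samples data.frame with at least `sample_id`, `site`, `plot`,
#'   `host`; optionally `season`, `x`, `y`, `pH`, `OM`, `GM`.
#' @slot phyDist cached cophenetic distance matrix (OTUs x OTUs).
#'
#' @param x an `AssemblyDataset`.
#' @return `otuCounts`: the count matrix; `sampleData`: the sample frame;
#'   `otuTree`: the phylogeny; `sampleNames`/`otuNames`: character vectors;
#'   `relAbundance`: row-stochastic matrix of within-sample relative
#'   abundances.
#' @aliases otuCounts sampleData otuTree sampleNames otuNames relAbundance
#' @seealso [assemblyDataset()], [betaNti()], [rcBray()], [partitionByScale()]
#' @export
setClass("AssemblyDataset",
  representation(
    counts  = "matrix",
    tree    = "ANY",
    samples = "data.frame",
    phyDist = "matrix"
  )
)

setValidity("AssemblyDataset", function(object) {
  cnt <- object@counts
  tr <- object@tree
  smp <- object@samples
  msg <- character(0)
  if (!inherits(tr, "phylo")) msg <- c(msg, "tree must be an ape 'phylo' object")
  if (!is.numeric(cnt)) msg <- c(msg, "counts must be numeric")
  if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
    return("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(cnt))) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(colnames(cnt))) msg <- c(msg, "duplicate OTU ids")
  if (any(cnt < 0) || any(cnt != round(cnt)))
    msg <- c(msg, "counts must be non-negative integers")
  if (any(rowSums(cnt) <= 0)) msg <- c(msg, "every sample must have total count > 0")
  if (any(colSums(cnt) <= 0)) msg <- c(msg, "every OTU must occur in at least one sample")
  if (inherits(tr, "phylo")) {
    if (is.null(tr$edge.length)) msg <- c(msg, "tree must have branch lengths")
    if (!identical(colnames(cnt), tr$tip.label))
      msg <- c(msg, "count columns and tree tips must name the same OTUs in the same order")
  }
  if (!identical(rownames(cnt), as.character(smp$sample_id)))
    msg <- c(msg, "sample rows of counts and sampleData must match in order")
  if (!all(c("site", "plot", "host") %in% names(smp)))
    msg <- c(msg, "sampleData needs columns site, plot, host")
  if (all(c("site", "plot") %in% names(smp))) {
    nsite <- tapply(as.character(smp$site), as.character(smp$plot),
                    function(s) length(unique(s)))
    if (any(nsite > 1))
      msg <- c(msg, paste0("plot(s) assigned to more than one site: ",
                           paste(names(nsite)[nsite > 1], collapse = ", ")))
  }
  for (cc in c("x", "y")) {
    if (cc %in% names(smp) && any(!is.finite(smp[[cc]])))
      msg <- c(msg, paste0("non-finite coordinate in column ", cc))
  }
  if (!identical(dimnames(object@phyDist), list(colnames(cnt), colnames(cnt))))
    msg <- c(msg, "cached phylogenetic distances out of sync with counts")
  if (length(msg)) msg else TRUE
})

#' Pairwise turnover null-model results
#'
#' Symmetric matrix of pairwise turnover scores (betaNTI z-scores or
#' Raup-Crick Bray-Curtis values) with full null-model provenance: which
#' metric, which sample pool the null communities were drawn from, how many
#' null replicates, and the RNG seed. Entries whose null distribution was
#' degenerate (zero standard deviation) are flagged invalid, as is the
#' diagonal.
#'
#' @slot values symmetric numeric matrix of scores (pool samples only).
#' @slot valid logical matrix; `FALSE` on the diagonal and for degenerate
#'   pairs.
#' @slot metric `"bNTI"` or `"RCbray"`.
#' @slot poolId label of the null pool (e.g. `"region"`, `"siteA:p2"`).
#' @slot nNull number of null replicates.
#' @slot seed integer seed used (NA if unseeded).
#' @slot provenance named list of extra settings (weighting flags etc.).
#'
#' @param x a `TurnoverMatrix`.
#' @return `turnoverValues`: the score matrix with invalid entries set `NA`;
#'   `turnoverLong`: long-format data.frame (`sample_a`, `sample_b`,
#'   `pool_id`, `metric`, `value`, `valid`), one row per unordered pair.
#' @aliases turnoverValues turnoverLong
#' @export
setClass("TurnoverMatrix",
  representation(
    values     = "matrix",
    valid      = "matrix",
    metric     = "character",
    poolId     = "character",
    nNull      = "integer",
    seed       = "integer",
    provenance = "list"
  )
)

setValidity("TurnoverMatrix", function(object) {
  v <- object@values
  ok <- object@valid
  msg <- character(0)
  if (!identical(dim(v), dim(ok))) msg <- c(msg, "values/valid dimension mismatch")
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must carry identical sample dimnames")
  if (!object@metric %in% c("bNTI", "RCbray")) msg <- c(msg, "unknown metric")
  if (nrow(v) > 0) {
    if (any(diag(ok))) msg <- c(msg, "diagonal must be flagged invalid")
    both <- ok & t(ok)
    if (any(abs(v[both] - t(v)[both]) > 1e-12)) msg <- c(msg, "values must be symmetric")
    if (any(!is.finite(v[ok & upper.tri(v)])))
      msg <- c(msg, "valid entries must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Ordination axes (PCNM, PCA or PCoA)
#'
#' Container for sample scores from one of the ordinations used by the
#' driver analysis: Moran-eigenvector spatial axes (PCNM), principal
#' components of standardized predictors (PCA), or principal coordinates of
#' a dissimilarity matrix (PCoA). Axes are ordered by decreasing
#' eigenvalue / explained variance.
#'
#' @slot kind `"PCNM"`, `"PCA"` or `"PCoA"`.
#' @slot scores samples x axes score matrix.
#' @slot eig eigenvalues (PCNM/PCoA: all, including any negative ones,
#'   which are reported, not corrected; PCA: component variances).
#' @slot loadings variable loadings (PCA only; empty matrix otherwise).
#'
#' @param x an `AxisSet`.
#' @return `axisScores`: score matrix; `axisEigenvalues`: numeric vector;
#'   `axisLoadings`: loading matrix.
#' @aliases axisScores axisEigenvalues axisLoadings
#' @export
setClass("AxisSet",
  representation(
    kind     = "character",
    scores   = "matrix",
    eig      = "numeric",
    loadings = "matrix"
  )
)

setValidity("AxisSet", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("PCNM", "PCA", "PCoA")) msg <- c(msg, "unknown axis kind")
  ne <- length(object@eig)
  if (ne > 1 && any(diff(object@eig) > 1e-8))
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  if (length(msg)) msg else TRUE
})

#' Assembly-process partition across habitat scales
#'
#' Result of [partitionByScale()]: every within-unit community pair at every
#' requested habitat scale, its betaNTI and Raup-Crick Bray-Curtis values
#' computed with the scale-restricted null pool, the assigned assembly
#' process, and the per-scale process counts and percentages.
#'
#' @slot pairs data.frame, one row per (scale, unit, pair): `level`, `unit`,
#'   `sample_a`, `sample_b`, `bnti`, `rcbray`, `process`.
#' @slot byScale data.frame of per-scale counts and percentages per process
#'   (the five exclusive labels plus the `selection` aggregate).
#' @slot params provenance list (levels, nNull, seed, weighting).
#'
#' @param x an `AssemblyPartition`.
#' @return `assemblyPairs`: the per-pair data.frame; `processTable`: the
#'   per-scale summary data.frame.
#' @aliases assemblyPairs processTable
#' @seealso [classifyPairs()], [chiSquareAcrossScales()]
#' @export
setClass("AssemblyPartition",
  representation(
    pairs   = "data.frame",
    byScale = "data.frame",
    params  = "list"
  )
)

## ---- accessors ----

#' @rdname AssemblyDataset-class
#' @export
setMethod("otuCounts", "AssemblyDataset", function(x) x@counts)

#' @rdname AssemblyDataset-class
#' @export
setMethod("sampleData", "AssemblyDataset", function(x) x@samples)

#' @rdname AssemblyDataset-class
#' @export
setMethod("otuTree", "AssemblyDataset", function(x) x@tree)

#' @rdname AssemblyDataset-class
#' @export
setMethod("sampleNames", "AssemblyDataset", function(x) rownames(x@counts))

#' @rdname AssemblyDataset-class
#' @export
setMethod("otuNames", "AssemblyDataset", function(x) colnames(x@counts))

#' @rdname phyloDistances
#' @export
setMethod("phyloDistances", "AssemblyDataset", function(x) x@phyDist)

#' @rdname AssemblyDataset-class
#' @export
setMethod("relAbundance", "AssemblyDataset", function(x) {
  relAbundanceMatrix(x@counts)
})

#' @rdname TurnoverMatrix-class
#' @export
setMethod("turnoverValues", "TurnoverMatrix", function(x) {
  v <- x@values
  v[!x@valid] <- NA_real_
  v
})

#' @rdname TurnoverMatrix-class
#' @export
setMethod("turnoverLong", "TurnoverMatrix", function(x) {
  ids <- rownames(x@values)
  ij <- pairIndices(length(ids))
  data.frame(
    sample_a = ids[ij[, 1]],
    sample_b = ids[ij[, 2]],
    pool_id = x@poolId,
    metric = x@metric,
    value = x@values[ij],
    valid = x@valid[ij],
    stringsAsFactors = FALSE
  )
})

#' @rdname AxisSet-class
#' @export
setMethod("axisScores", "AxisSet", function(x) x@scores)

#' @rdname AxisSet-class
#' @export
setMethod("axisEigenvalues", "AxisSet", function(x) x@eig)

#' @rdname AxisSet-class
#' @export
setMethod("axisLoadings", "AxisSet", function(x) x@loadings)

#' @rdname AssemblyPartition-class
#' @export
setMethod("assemblyPairs", "AssemblyPartition", function(x) x@pairs)

#' @rdname AssemblyPartition-class
#' @export
setMethod("processTable", "AssemblyPartition", function(x) x@byScale)

## ---- show ----

setMethod("show", "AssemblyDataset", function(object) {
  cnt <- object@counts
  smp <- object@samples
  cat("AssemblyDataset:", nrow(cnt), "samples x", ncol(cnt), "OTUs\n")
  cat("  total reads:", sum(cnt), "\n")
  cat("  design: ", length(unique(smp$site)), " site(s), ",
      length(unique(paste(smp$site, smp$plot))), " plot(s), ",
      length(unique(smp$host)), " host(s)\n", sep = "")
  covs <- intersect(c("pH", "OM", "GM", "x", "y"), names(smp))
  if (length(covs)) cat("  covariates:", paste(covs, collapse = ", "), "\n")
  cat("  tree depth (time units):",
      format(max(ape::node.depth.edgelength(object@tree)), digits = 4), "\n")
})

setMethod("show", "TurnoverMatrix", function(object) {
  n <- nrow(object@values)
  cat("TurnoverMatrix [", object@metric, "]: ", n, " samples, pool '",
      object@poolId, "', ", object@nNull, " nulls, seed ",
      object@seed, "\n", sep = "")
  ut <- upper.tri(object@values)
  ok <- object@valid & ut
  if (any(ok)) {
    cat("  valid pairs:", sum(ok), "/", sum(ut), "  range:",
        paste(format(range(object@values[ok]), digits = 4), collapse = " .. "),
        "\n")
  }
})

setMethod("show", "AxisSet", function(object) {
  cat("AxisSet [", object@kind, "]: ", nrow(object@scores), " samples x ",
      ncol(object@scores), " axes\n", sep = "")
})

setMethod("show", "AssemblyPartition", function(object) {
  cat("AssemblyPartition:", nrow(object@pairs), "pairs over levels",
      paste(object@params$levels, collapse = ", "), "\n")
  print(object@byScale, row.names = FALSE)
})
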