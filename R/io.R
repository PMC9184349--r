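## I/O and alignment for the three core inputs: OTU table (TSV/CSV),
## dated phylogeny (Newick) and sample metadata (CSV).

sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an OTU count table
#'
#' Reads a tab- or comma-separated table of integer read counts with sample
#' and OTU identifiers in the header row/column. The orientation flag
#' accommodates the transposed convention (OTUs as rows) common in ecology;
#' output is always normalized to samples x OTUs.
#'
#' All-zero OTU columns are dropped with a message (they carry no
#' information for any metric); an all-zero sample is an error.
#'
#' @param path path to the table.
#' @param orientation `"samples"` if samples are rows (default) or
#'   `"otus"` if OTUs are rows.
#' @return integer matrix, samples x OTUs, with dimnames.
#' @export
readOtuTable <- function(path, orientation = c("samples", "otus")) {
  orientation <- match.arg(orientation)
  sep <- sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) == 0L) stop("empty OTU table: ", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in OTU table: ", path)
  if (orientation == "otus") m <- t(m)
  validateCounts(m)
}

validateCounts <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(m))) stop("duplicate OTU ids in OTU table")
  if (any(!is.finite(m)) || any(m < 0)) stop("negative or non-finite counts")
  if (any(m != round(m))) stop("non-integer counts in OTU table")
  zs <- rowSums(m) == 0
  if (any(zs)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(m)[zs], collapse = ", "))
  }
  zo <- colSums(m) == 0
  if (any(zo)) {
    message("dropping ", sum(zo), " OTU(s) with zero total count")
    m <- m[, !zo, drop = FALSE]
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU count table
#'
#' Canonical dialect: TSV, samples as rows, OTU ids in the header, sample
#' ids in the first column headed `sample_id`. `readOtuTable()` of the
#' written file reproduces the matrix exactly.
#'
#' @param counts samples x OTUs integer matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dated phylogeny from Newick
#'
#' @param path Newick file; every edge must carry a branch length
#'   (time units).
#' @return an `ape::phylo` with whitespace/quote-stripped tip labels.
#' @export
readTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree has missing branch lengths: ", path)
  if (any(tr$edge.length < 0)) stop("negative branch lengths in tree")
  tr$tip.label <- trimws(gsub("^['\"]|['\"]$", "", tr$tip.label))
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Read sample metadata
#'
#' CSV with one row per sample. Required columns: `sample_id`, `site`,
#' `plot`, `host`. Recognised optional columns: `season`, `x`, `y`
#' (projected coordinates), `pH`, `OM` (% mass), `GM` (% mass). Missing
#' covariate cells stay `NA`; the driver analysis refuses incomplete
#' covariates rather than imputing.
#'
#' @param path CSV path.
#' @return data.frame of sample metadata.
#' @export
readSampleData <- function(path) {
  df <- read.table(path, header = TRUE, sep = sniffSep(path),
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "site", "plot", "host")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Assemble and align a community dataset
#'
#' Aligns an OTU count matrix, a dated phylogeny and sample metadata into a
#' validated [AssemblyDataset]: sample order is harmonized to the count
#' matrix, the tree is pruned to the OTUs present, count columns are
#' reordered to the tree's tip order, and cophenetic distances are cached.
#' OTUs absent from the tree are an error naming the offenders unless
#' `dropUnknownOtus = TRUE`, in which case they are dropped with a message.
#' Alignment is idempotent.
#'
#' @param counts samples x OTUs integer matrix (see [readOtuTable()]).
#' @param tree `ape::phylo` over (a superset of) the table's OTUs.
#' @param samples metadata data.frame (see [readSampleData()]).
#' @param dropUnknownOtus drop table OTUs missing from the tree instead of
#'   erroring.
#' @return an [AssemblyDataset].
#' @export
assemblyDataset <- function(counts, tree, samples, dropUnknownOtus = FALSE) {
  counts <- validateCounts(as.matrix(counts))
  miss <- setdiff(rownames(counts), samples$sample_id)
  if (length(miss)) stop("sample(s) present in OTU table but not metadata: ",
                         paste(miss, collapse = ", "))
  samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL

  unknown <- setdiff(colnames(counts), tree$tip.label)
  if (length(unknown)) {
    if (!dropUnknownOtus)
      stop("OTU(s) absent from the tree: ", paste(unknown, collapse = ", "),
           " (set dropUnknownOtus = TRUE to drop them)")
    message("dropping ", length(unknown), " OTU(s) absent from the tree")
    counts <- counts[, setdiff(colnames(counts), unknown), drop = FALSE]
    counts <- validateCounts(counts)
  }
  tree <- ape::keep.tip(tree, colnames(counts))
  counts <- counts[, tree$tip.label, drop = FALSE]
  pd <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]

  new("AssemblyDataset", counts = counts, tree = tree,
      samples = samples, phyDist = pd)
}

#' Within-sample relative abundances
#'
#' Divides each sample's counts by its total; rows sum to 1 within 1e-12.
#' Computed on demand and never stored in files, so no precision drift.
#'
#' @param counts samples x OTUs matrix with positive row totals.
#' @return row-stochastic numeric matrix.
#' @export
relAbundanceMatrix <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("zero-total sample in relative abundance")
  counts / tot
}

#' Habitat-scale unit membership
#'
#' Maps every sample to its unit at a habitat scale of the nested design:
#' `region` (one unit), `site`, `plot` (site:plot) or `host`
#' (site:plot:host). Units at finer levels nest within coarser ones by
#' construction.
#'
#' @param x an [AssemblyDataset] or a sample-data frame.
#' @param level one of `"region"`, `"site"`, `"plot"`, `"host"`.
#' @return character vector of unit ids, one per sample.
#' @export
scaleUnits <- function(x, level = c("region", "site", "plot", "host")) {
  level <- match.arg(level)
  smp <- if (is(x, "AssemblyDataset")) sampleData(x) else x
  switch(level,
    region = rep("region", nrow(smp)),
    site   = as.character(smp$site),
    plot   = paste(smp$site, smp$plot, sep = ":"),
    host   = paste(smp$site, smp$plot, smp$host, sep = ":")
  )
}

#' Write a turnover matrix as long-format CSV
#'
#' One row per unordered sample pair: `sample_a`, `sample_b`, `pool_id`,
#' `metric`, `value`, `valid`.
#'
#' @param x a [TurnoverMatrix] (or a data.frame already in long format).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTurnover <- function(x, path) {
  df <- if (is(x, "TurnoverMatrix")) turnoverLong(x) else x
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
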