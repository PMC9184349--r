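#' @rdname AssemblyDataset-class
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname AssemblyDataset-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname AssemblyDataset-class
#' @export
setGeneric("otuTree", function(x) standardGeneric("otuTree"))

#' @rdname AssemblyDataset-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname AssemblyDataset-class
#' @export
setGeneric("otuNames", function(x) standardGeneric("otuNames"))

#' Cophenetic (patristic) distances between OTUs
#'
#' Pairwise path-length distances on the dated phylogeny: the sum of branch
#' lengths along the path connecting two tips, in the tree's time units.
#' For an [AssemblyDataset] the matrix is computed once at construction and
#' cached.
#'
#' @param x an `AssemblyDataset` or an `ape::phylo` tree.
#' @return symmetric numeric matrix with zero diagonal, dimnames = OTU ids.
#' @export
setGeneric("phyloDistances", function(x) standardGeneric("phyloDistances"))

#' @rdname AssemblyDataset-class
#' @export
setGeneric("relAbundance", function(x) standardGeneric("relAbundance"))

#' @rdname TurnoverMatrix-class
#' @export
setGeneric("turnoverValues", function(x) standardGeneric("turnoverValues"))

#' @rdname TurnoverMatrix-class
#' @export
setGeneric("turnoverLong", function(x) standardGeneric("turnoverLong"))

#' @rdname AxisSet-class
#' @export
setGeneric("axisScores", function(x) standardGeneric("axisScores"))

#' @rdname AxisSet-class
#' @export
setGeneric("axisEigenvalues", function(x) standardGeneric("axisEigenvalues"))

#' @rdname AxisSet-class
#' @export
setGeneric("axisLoadings", function(x) standardGeneric("axisLoadings"))

#' @rdname AssemblyPartition-class
#' @export
setGeneric("assemblyPairs", function(x) standardGeneric("assemblyPairs"))

#' @rdname AssemblyPartition-class
#' @export
setGeneric("processTable", function(x) standardGeneric("processTable"))
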