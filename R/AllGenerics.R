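#' @rdname SampleMatrix-class
#' @param x,object a SampleMatrix.
#' @export
setGeneric("armNames", function(x) standardGeneric("armNames"))

#' @rdname SampleMatrix-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname SampleMatrix-class
#' @param arm arm name.
#' @export
setGeneric("armBases", function(x, arm) standardGeneric("armBases"))

#' @rdname SampleMatrix-class
#' @param group one of \code{"lab"}, \code{"wild"}, \code{"outgroup"}.
#' @export
setGeneric("groupSamples", function(x, group) standardGeneric("groupSamples"))

#' @rdname SyntheticDataset-class
#' @param x,object a SyntheticDataset.
#' @export
setGeneric("sampleMatrix", function(x) standardGeneric("sampleMatrix"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("refSequences", function(x) standardGeneric("refSequences"))

#' @rdname SyntheticDataset-class
#' @export
setGeneric("preferredCodons", function(x) standardGeneric("preferredCodons"))

#' @rdname SampleMatrix-class
#' @export
setMethod("armNames", "SampleMatrix", function(x) names(x@arms))

#' @rdname SampleMatrix-class
#' @export
setMethod("sampleInfo", "SampleMatrix", function(x) x@sampleInfo)

#' @rdname SampleMatrix-class
#' @export
setMethod("armBases", "SampleMatrix", function(x, arm) {
  if (!arm %in% names(x@arms)) stop("unknown arm: ", arm)
  x@arms[[arm]]
})

#' @rdname SampleMatrix-class
#' @export
setMethod("groupSamples", "SampleMatrix", function(x, group) {
  x@sampleInfo$sample_id[x@sampleInfo$group == group]
})

#' @rdname SampleMatrix-class
#' @export
setMethod("show", "SampleMatrix", function(object) {
  si <- object@sampleInfo
  cat("SampleMatrix with", nrow(si), "samples (",
      sum(si$group == "lab"), "lab,", sum(si$group == "wild"), "wild,",
      sum(si$group == "outgroup"), "outgroup )\n")
  for (arm in names(object@arms))
    cat("  arm", arm, ":", nrow(object@arms[[arm]]), "bp\n")
})

#' @rdname GeneModelSet-class
#' @param x,object a GeneModelSet.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GeneModelSet-class
#' @export
setGeneric("geneFeatures", function(x) standardGeneric("geneFeatures"))

#' @rdname GeneModelSet-class
#' @export
setMethod("genes", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneFeatures", "GeneModelSet", function(x) x@features)

#' @rdname GeneModelSet-class
#' @export
setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet with", length(object@genes), "genes,",
      sum(object@genes$neuro), "flagged neurogenetic\n")
})

#' @rdname SyntheticDataset-class
#' @export
setMethod("sampleMatrix", "SyntheticDataset", function(x) x@sampleMatrix)

#' @rdname SyntheticDataset-class
#' @export
setMethod("geneModels", "SyntheticDataset", function(x) x@geneModels)

#' @rdname SyntheticDataset-class
#' @export
setMethod("simTruth", "SyntheticDataset", function(x) x@truth)

#' @rdname SyntheticDataset-class
#' @export
setMethod("refSequences", "SyntheticDataset", function(x) x@reference)

#' @rdname SyntheticDataset-class
#' @export
setMethod("preferredCodons", "SyntheticDataset", function(x) x@preferredCodons)

#' @rdname SyntheticDataset-class
#' @export
setMethod("show", "SyntheticDataset", function(object) {
  show(object@sampleMatrix)
  show(object@geneModels)
  cat("truth:", nrow(object@truth$selected), "selected loci,",
      nrow(object@truth$polymorphic), "polymorphic sites\n")
})
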