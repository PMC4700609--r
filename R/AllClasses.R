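#' @import methods
#' @importFrom stats rbinom rexp rpois runif sd setNames quantile median
#'   chisq.test p.adjust phyper wilcox.test kruskal.test binom.test
#' @importFrom utils read.delim write.table head
NULL

VALID_GROUPS <- c("lab", "wild", "outgroup")
BASES <- c("A", "C", "G", "T")

#' SampleMatrix: aligned per-sample bases at genomic coordinates
#'
#' Holds one character matrix per chromosome arm (positions x samples,
#' alphabet A/C/G/T/N, coordinates 1-based inclusive) together with a sample
#' table assigning each sample to the \code{lab}, \code{wild} or
#' \code{outgroup} group. All samples cover identical coordinate ranges per
#' arm; uncalled bases are \code{N}. Exactly one outgroup sample is required
#' so that every site can be polarised.
#'
#' @slot arms named list of character matrices, one per arm; rows are
#'   positions, columns are sample ids.
#' @slot sampleInfo data.frame with columns \code{sample_id} and
#'   \code{group}.
#' @export
setClass("SampleMatrix", representation(
  arms = "list",
  sampleInfo = "data.frame"
))

setValidity("SampleMatrix", function(object) {
  msgs <- character()
  si <- object@sampleInfo
  if (!all(c("sample_id", "group") %in% names(si)))
    msgs <- c(msgs, "sampleInfo must have columns sample_id, group")
  else {
    if (anyDuplicated(si$sample_id))
      msgs <- c(msgs, "duplicated sample ids")
    if (!all(si$group %in% VALID_GROUPS))
      msgs <- c(msgs, "groups must be lab, wild or outgroup")
    if (nrow(si) > 0L && sum(si$group == "outgroup") != 1L)
      msgs <- c(msgs, "exactly one outgroup sample is required")
    for (arm in names(object@arms)) {
      m <- object@arms[[arm]]
      if (!is.matrix(m) || !is.character(m))
        msgs <- c(msgs, sprintf("arm '%s' is not a character matrix", arm))
      else if (!identical(colnames(m), si$sample_id))
        msgs <- c(msgs, sprintf("arm '%s' columns do not match sampleInfo", arm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SampleMatrix
#'
#' @param arms named list of character matrices (positions x samples).
#' @param sampleInfo data.frame with columns \code{sample_id}, \code{group}.
#' @return A [SampleMatrix-class] object.
#' @export
SampleMatrix <- function(arms, sampleInfo) {
  arms <- lapply(arms, function(m) {
    m[!(m %in% BASES)] <- "N"
    m
  })
  new("SampleMatrix", arms = arms,
      sampleInfo = as.data.frame(sampleInfo, stringsAsFactors = FALSE))
}

#' GeneModelSet: gene models with CDS phase on synthetic or real arms
#'
#' Each gene is represented by a single (longest) transcript whose features
#' (exon, CDS, five_prime_UTR, three_prime_UTR) are stored as a
#' \code{GRanges}. CDS total length per gene must be divisible by three.
#'
#' @slot genes \code{GRanges} of gene spans; metadata columns
#'   \code{gene_id}, \code{neuro} (logical), \code{gene_length}.
#' @slot features \code{GRanges} of gene sub-features; metadata columns
#'   \code{type}, \code{gene_id}, \code{phase} (CDS only, else NA).
#' @export
setClass("GeneModelSet", representation(
  genes = "GRanges",
  features = "GRanges"
))

setValidity("GeneModelSet", function(object) {
  msgs <- character()
  feats <- object@features
  if (length(feats)) {
    cds <- feats[feats$type == "CDS"]
    if (length(cds)) {
      tot <- tapply(BiocGenerics::width(cds), cds$gene_id, sum)
      bad <- names(tot)[tot %% 3L != 0L]
      if (length(bad))
        msgs <- c(msgs, paste("CDS length not divisible by 3 for gene(s):",
                              paste(bad, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticDataset: a complete simulated lab-domestication study
#'
#' Bundles the simulated [SampleMatrix-class], gene models, the ancestral
#' reference sequences, the preferred-codon table and a truth record
#' (selected loci, segregating sites, de novo mutations) so that downstream
#' inference can be validated against known ground truth.
#'
#' @slot sampleMatrix the simulated base matrix.
#' @slot geneModels gene models on the simulated arms.
#' @slot reference named list of ancestral reference sequences (character
#'   vectors of single bases) per arm.
#' @slot preferredCodons data.frame (codon, amino_acid, preferred).
#' @slot truth list with elements \code{selected}, \code{polymorphic},
#'   \code{pool_sites}, \code{de_novo}.
#' @slot config the [simulationConfig()] list used.
#' @export
setClass("SyntheticDataset", representation(
  sampleMatrix = "SampleMatrix",
  geneModels = "GeneModelSet",
  reference = "list",
  preferredCodons = "data.frame",
  truth = "list",
  config = "list"
))

setValidity("SyntheticDataset", function(object) {
  msgs <- character()
  tp <- object@truth$polymorphic
  if (!is.null(tp) && nrow(tp)) {
    sm <- object@sampleMatrix
    for (arm in unique(tp$arm)) {
      m <- sm@arms[[arm]]
      pos <- tp$pos[tp$arm == arm]
      poly <- vapply(pos, function(p) {
        b <- m[p, ]
        length(unique(b[b != "N"])) >= 2L
      }, logical(1))
      if (!all(poly))
        msgs <- c(msgs, sprintf("truth positions on %s not polymorphic", arm))
    }
  }
  if (length(msgs)) msgs else TRUE
})
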