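## Gene-model context and coding-change scoring for polarised SNPs:
## region labels (5'UTR / CDS / intron / 3'UTR / intergenic), codon
## position C1-C3 read in frame on the coding strand, replacement vs
## silent status, Grantham distance for replacements and preferred-codon
## shift class (P2P/P2N/N2P/N2N) for silent changes.

REGIONS <- c("five_prime_utr", "exon_cds", "intron", "three_prime_utr",
             "intergenic")

typeToRegion <- c(CDS = "exon_cds", five_prime_UTR = "five_prime_utr",
                  three_prime_UTR = "three_prime_utr")

#' Annotate the genic region of positions
#'
#' Positions inside a gene but outside its exonic features are introns;
#' positions outside all genes are intergenic. When genes overlap, a
#' position is assigned to the gene giving the highest-priority feature
#' (CDS over UTR over intron); remaining ties go to the gene with the
#' smaller span.
#'
#' @param arm arm label (recycled).
#' @param position positions (bp, 1-based).
#' @param models a [GeneModelSet-class].
#' @return data.frame with columns \code{arm}, \code{pos}, \code{region},
#'   \code{gene_id} (NA when intergenic).
#' @export
annotateRegion <- function(arm, position, models) {
  known <- GenomeInfoDb::seqlevels(genes(models))
  bad <- setdiff(unique(arm), known)
  if (length(bad))
    stop("unknown arm(s): ", paste(bad, collapse = ", "))
  q <- GenomicRanges::GRanges(arm, IRanges::IRanges(position, position))
  g <- genes(models)
  f <- geneFeatures(models)

  res <- data.frame(arm = as.character(arm), pos = position,
                    region = "intergenic", gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  hitsG <- GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE)
  if (!length(hitsG)) return(res)
  hitsF <- GenomicRanges::findOverlaps(q, f, ignore.strand = TRUE)
  prio <- c(exon_cds = 1L, five_prime_utr = 2L, three_prime_utr = 2L,
            intron = 3L)

  ## candidate (query, gene, region) rows: feature overlaps plus intronic
  ## fallbacks from gene-span overlaps
  cand <- rbind(
    data.frame(qi = S4Vectors::queryHits(hitsF),
               gene = f$gene_id[S4Vectors::subjectHits(hitsF)],
               region = unname(
                 typeToRegion[f$type[S4Vectors::subjectHits(hitsF)]]),
               stringsAsFactors = FALSE),
    data.frame(qi = S4Vectors::queryHits(hitsG),
               gene = g$gene_id[S4Vectors::subjectHits(hitsG)],
               region = "intron", stringsAsFactors = FALSE))
  cand <- cand[!is.na(cand$region), ]
  cand$prio <- prio[cand$region]
  cand$span <- BiocGenerics::width(g)[match(cand$gene, g$gene_id)]
  ## intronic fallback only applies where the same gene has no feature hit
  cand <- cand[order(cand$qi, cand$prio, cand$span), ]
  dupGene <- duplicated(cand[, c("qi", "gene")])
  cand <- cand[!dupGene, ]
  best <- cand[!duplicated(cand$qi), ]
  res$region[best$qi] <- best$region
  res$gene_id[best$qi] <- best$gene
  res
}

## ordered CDS segments (transcription order) and cumulative offsets
cdsSegments <- function(models, gene_id) {
  f <- geneFeatures(models)
  cds <- f[f$gene_id == gene_id & f$type == "CDS"]
  if (!length(cds)) stop("gene has no CDS: ", gene_id)
  strand <- as.character(BiocGenerics::strand(cds))[1L]
  o <- order(BiocGenerics::start(cds),
             decreasing = (strand == "-"))
  cds <- cds[o]
  w <- BiocGenerics::width(cds)
  list(start = BiocGenerics::start(cds), end = BiocGenerics::end(cds),
       strand = strand, width = w, offset = c(0L, cumsum(w))[seq_along(w)])
}

## genomic position -> CDS coordinate (1-based, transcription order)
cdsCoord <- function(seg, pos) {
  for (i in seq_along(seg$width)) {
    if (pos >= seg$start[i] && pos <= seg$end[i]) {
      return(seg$offset[i] +
               if (seg$strand == "+") pos - seg$start[i] + 1L
               else seg$end[i] - pos + 1L)
    }
  }
  NA_integer_
}

## CDS coordinate -> genomic position
cdsToGenomic <- function(seg, coord) {
  i <- findInterval(coord - 1L, cumsum(c(0L, seg$width)),
                    rightmost.closed = FALSE)
  within <- coord - seg$offset[i]
  if (seg$strand == "+") seg$start[i] + within - 1L
  else seg$end[i] - within + 1L
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Codon context of a coding position
#'
#' Computes the codon position (C1/C2/C3) and the reference codon read
#' 5'->3' on the coding strand (reverse-complemented for minus-strand
#' genes), honouring splicing across CDS segments.
#'
#' @param arm arm label.
#' @param position genomic position annotated as CDS.
#' @param models a [GeneModelSet-class].
#' @param reference named list of reference base vectors per arm (as in
#'   [refSequences()]), or a \code{Biostrings::DNAStringSet}.
#' @param gene_id the gene to use (required when genes overlap).
#' @return list with \code{codon_position} ("C1"/"C2"/"C3"),
#'   \code{ref_codon}, \code{frame_offset} (0-based within codon) and
#'   \code{codon_genomic} (genomic positions of the codon bases in
#'   transcription order).
#' @export
codonContext <- function(arm, position, models, reference,
                         gene_id = NULL) {
  if (is.null(gene_id)) {
    ann <- annotateRegion(arm, position, models)
    if (ann$region != "exon_cds")
      stop("position ", position, " is not in a CDS")
    gene_id <- ann$gene_id
  }
  refArm <- referenceBases(reference, arm)
  seg <- cdsSegments(models, gene_id)
  coord <- cdsCoord(seg, position)
  if (is.na(coord)) stop("position not inside CDS of ", gene_id)
  off <- (coord - 1L) %% 3L
  codonStart <- coord - off
  gpos <- vapply(codonStart + 0:2, function(cc) cdsToGenomic(seg, cc),
                 numeric(1))
  bases <- refArm[gpos]
  if (seg$strand == "-") bases <- unname(COMPLEMENT[bases])
  list(codon_position = paste0("C", off + 1L),
       ref_codon = paste(bases, collapse = ""),
       frame_offset = off,
       codon_genomic = gpos)
}

referenceBases <- function(reference, arm) {
  if (methods::is(reference, "DNAStringSet"))
    strsplit(toupper(as.character(reference[[arm]])), "")[[1L]]
  else reference[[arm]]
}

#' Score a coding substitution
#'
#' Classifies a single-base codon change as replacement or silent,
#' attaches the Grantham distance for replacements and the preferred-codon
#' shift class (P2P/P2N/N2P/N2N) for silent changes. Substitutions that
#' create or destroy a stop codon are replacements without a Grantham
#' score and are flagged.
#'
#' @param ref_codon ancestral codon (coding strand, 5'->3').
#' @param derived_base derived base on the coding strand.
#' @param codon_position "C1", "C2" or "C3" (or 1:3).
#' @param preferred_table data.frame (codon, preferred) as from
#'   [defaultPreferredCodons()].
#' @param grantham_matrix matrix from [granthamMatrix()].
#' @return list with \code{substitution_type}, \code{grantham},
#'   \code{codon_shift}, \code{stop_involved}, \code{derived_codon}.
#' @export
scoreSubstitution <- function(ref_codon, derived_base, codon_position,
                              preferred_table = defaultPreferredCodons(),
                              grantham_matrix = granthamMatrix()) {
  off <- if (is.character(codon_position))
    as.integer(sub("^C", "", codon_position)) else as.integer(codon_position)
  stopifnot(off %in% 1:3)
  if (grepl("N", ref_codon) || derived_base == "N")
    stop("codon containing N cannot be scored")
  der_codon <- ref_codon
  substr(der_codon, off, off) <- derived_base
  if (der_codon == ref_codon)
    stop("identical codons: not a substitution")
  gc <- Biostrings::GENETIC_CODE
  aa1 <- unname(gc[ref_codon])
  aa2 <- unname(gc[der_codon])
  stopInv <- aa1 == "*" || aa2 == "*"
  if (aa1 == aa2) {
    pref <- setNames(preferred_table$preferred, preferred_table$codon)
    shift <- paste0(ifelse(pref[ref_codon] == 1, "P", "N"), "2",
                    ifelse(pref[der_codon] == 1, "P", "N"))
    list(substitution_type = "silent", grantham = NA_real_,
         codon_shift = unname(shift), stop_involved = FALSE,
         derived_codon = der_codon)
  } else {
    g <- if (stopInv) NA_real_ else grantham_matrix[aa1, aa2]
    list(substitution_type = "replacement", grantham = g,
         codon_shift = NA_character_, stop_involved = stopInv,
         derived_codon = der_codon)
  }
}

#' Annotate a classified SNP table against gene models
#'
#' Joins region labels and, for CDS SNPs, codon context and substitution
#' scores onto the SNP table. The focal position's base in the reference
#' codon is set to the ancestral allele before scoring, so the scored
#' change is ancestral codon -> derived codon. SNPs whose codon contains
#' an uncalled base are skipped with a count.
#'
#' @param snps classified SNP table (needs arm, pos, anc, der).
#' @param models a [GeneModelSet-class].
#' @param reference per-arm reference bases (list or DNAStringSet).
#' @param preferred_table,grantham_matrix scoring tables.
#' @return the input joined with columns \code{region}, \code{gene_id},
#'   \code{codon_position}, \code{ref_codon}, \code{derived_codon},
#'   \code{substitution_type}, \code{grantham}, \code{codon_shift}.
#' @export
annotateSnps <- function(snps, models, reference,
                         preferred_table = defaultPreferredCodons(),
                         grantham_matrix = granthamMatrix()) {
  ann <- annotateRegion(snps$arm, snps$pos, models)
  snps$region <- ann$region
  snps$gene_id <- ann$gene_id
  snps$codon_position <- NA_character_
  snps$ref_codon <- NA_character_
  snps$derived_codon <- NA_character_
  snps$substitution_type <- NA_character_
  snps$grantham <- NA_real_
  snps$codon_shift <- NA_character_
  skipped <- 0L
  cdsIdx <- which(snps$region == "exon_cds")
  for (i in cdsIdx) {
    ctx <- codonContext(snps$arm[i], snps$pos[i], models, reference,
                        gene_id = snps$gene_id[i])
    strand <- cdsSegments(models, snps$gene_id[i])$strand
    anc <- if (strand == "-") COMPLEMENT[[snps$anc[i]]] else snps$anc[i]
    der <- if (strand == "-") COMPLEMENT[[snps$der[i]]] else snps$der[i]
    off <- ctx$frame_offset + 1L
    codon <- ctx$ref_codon
    substr(codon, off, off) <- anc
    if (grepl("N", codon) || der == "N") { skipped <- skipped + 1L; next }
    sc <- scoreSubstitution(codon, der, off, preferred_table,
                            grantham_matrix)
    snps$codon_position[i] <- ctx$codon_position
    snps$ref_codon[i] <- codon
    snps$derived_codon[i] <- sc$derived_codon
    snps$substitution_type[i] <- sc$substitution_type
    snps$grantham[i] <- sc$grantham
    snps$codon_shift[i] <- sc$codon_shift
  }
  attr(snps, "skipped_codons") <- skipped
  snps
}
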