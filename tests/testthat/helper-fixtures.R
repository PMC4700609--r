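## shared fixtures: tiny hand-built sample matrices and gene models

## a SampleMatrix from a list of per-sample base strings (single arm)
toyMatrix <- function(seqs, groups, arm = "2L") {
  ids <- names(seqs)
  m <- vapply(seqs, function(s) strsplit(s, "")[[1L]],
              character(nchar(seqs[[1L]])))
  m <- matrix(m, ncol = length(seqs), dimnames = list(NULL, ids))
  SampleMatrix(setNames(list(m), arm),
               data.frame(sample_id = ids, group = groups,
                          stringsAsFactors = FALSE))
}

## repeat a base n times
bp <- function(base, n) strrep(base, n)

## a deterministic two-gene model set on a 600 bp arm with a spliced
## plus-strand gene and a spliced minus-strand gene; reference designed so
## codons are known by construction
toyGeneFixture <- function() {
  arm <- "2L"
  ## plus-strand gene: 5'UTR 101..110, CDS 111..118 + 131..140 (18 bp),
  ## 3'UTR 141..150 (intron 119..130)
  ## minus-strand gene: genomic 3'UTR 301..310, CDS 311..318 + 331..340,
  ## 5'UTR 341..350 (transcribed right to left)
  gdf <- data.frame(
    gene_id = c("gP", "gM"), start = c(101L, 301L), end = c(150L, 350L),
    strand = c("+", "-"), neuro = c(FALSE, TRUE),
    gene_length = c(50L, 50L))
  fdf <- data.frame(
    start = c(101L, 111L, 131L, 141L, 301L, 311L, 331L, 341L),
    end = c(110L, 118L, 140L, 150L, 310L, 318L, 340L, 350L),
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR",
             "three_prime_UTR", "CDS", "CDS", "five_prime_UTR"),
    gene_id = c("gP", "gP", "gP", "gP", "gM", "gM", "gM", "gM"),
    strand = c("+", "+", "+", "+", "-", "-", "-", "-"),
    phase = c(NA, 0L, 1L, NA, NA, 2L, 0L, NA))
  g <- GenomicRanges::GRanges(arm, IRanges::IRanges(gdf$start, gdf$end),
                              strand = gdf$strand, gene_id = gdf$gene_id,
                              neuro = gdf$neuro,
                              gene_length = gdf$gene_length)
  f <- GenomicRanges::GRanges(arm, IRanges::IRanges(fdf$start, fdf$end),
                              strand = fdf$strand, type = fdf$type,
                              gene_id = fdf$gene_id, phase = fdf$phase)
  GenomeInfoDb::seqlengths(g) <- 600L
  GenomeInfoDb::seqlengths(f) <- 600L
  models <- new("GeneModelSet", genes = g, features = f)

  ref <- rep("A", 600)
  ## plus CDS (18 bp, transcription order = genomic):
  ## ATG GCT TAC | first exon 111..118 = ATGGCTTA, second 131..140
  plusCds <- strsplit("ATGGCTTACCTGAAATTT", "")[[1L]]
  ref[111:118] <- plusCds[1:8]
  ref[131:140] <- plusCds[9:18]
  ## minus CDS read 5'->3' on the coding strand: ATGTGTCCCGGGTTTTAA is
  ## 18 bp laid right-to-left from genomic 340 down; genomic bases are the
  ## complement in reverse order. Transcription order segments: first CDS
  ## segment 331..340 (10 bp), then 311..318 (8 bp).
  minusCds <- strsplit("ATGTGTCCCGGGTTTAGC", "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref[340:331] <- comp[minusCds[1:10]]
  ref[318:311] <- comp[minusCds[11:18]]
  list(models = models, ref = setNames(list(ref), arm),
       plus_cds = paste(plusCds, collapse = ""),
       minus_cds = paste(minusCds, collapse = ""))
}

## random CDS of n codons without internal stops (for neutral-simulator
## tests); deterministic given seed
randomCds <- function(nCodons, seed) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  set.seed(seed)
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}
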