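## Readers and writers for the package's on-disk study layout:
## per-sample FASTA (one record per arm), a sample->group map TSV, GFF3
## gene models, preferred-codon and truth TSVs, and a manifest.

#' Write a synthetic dataset to disk as a reusable fixture
#'
#' Emits one FASTA per sample (records named by arm), the reference FASTA,
#' a group map TSV, gene models as GFF3, the preferred-codon table, truth
#' TSVs, a YAML echo of the simulation configuration and a manifest. The
#' layout round-trips losslessly through [readSampleMatrix()].
#'
#' @param dataset a [SyntheticDataset-class].
#' @param directory output directory (created if needed).
#' @return data.frame manifest (columns \code{file}, \code{role}),
#'   invisibly written as \code{manifest.tsv}.
#' @export
writeFixture <- function(dataset, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory)
  sm <- sampleMatrix(dataset)
  si <- sampleInfo(sm)
  arms <- armNames(sm)
  manifest <- list()
  addRow <- function(file, role)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, role = role, stringsAsFactors = FALSE)

  for (j in seq_len(nrow(si))) {
    id <- si$sample_id[j]
    seqs <- Biostrings::DNAStringSet(vapply(
      arms, function(a) paste(sm@arms[[a]][, id], collapse = ""),
      character(1)))
    names(seqs) <- arms
    f <- file.path(directory, paste0(id, ".fasta"))
    Biostrings::writeXStringSet(seqs, f)
    addRow(basename(f), "sample_fasta")
  }
  if (length(dataset@reference)) {
    refs <- Biostrings::DNAStringSet(vapply(
      dataset@reference, paste, character(1), collapse = ""))
    f <- file.path(directory, "reference.fasta")
    Biostrings::writeXStringSet(refs, f)
    addRow(basename(f), "reference_fasta")
  }
  f <- file.path(directory, "groups.tsv")
  write.table(si, f, sep = "\t", quote = FALSE, row.names = FALSE)
  addRow(basename(f), "group_map")

  f <- file.path(directory, "genes.gff3")
  exportGeneModels(geneModels(dataset), f)
  addRow(basename(f), "gene_models")

  f <- file.path(directory, "preferred_codons.tsv")
  write.table(preferredCodons(dataset), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  addRow(basename(f), "preferred_codons")

  truth <- simTruth(dataset)
  for (nm in names(truth)) {
    f <- file.path(directory, paste0("truth_", nm, ".tsv"))
    write.table(truth[[nm]], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    addRow(basename(f), paste0("truth_", nm))
  }
  if (length(dataset@config)) {
    f <- file.path(directory, "config.yaml")
    cfgOut <- dataset@config
    cfgOut$selected_loci <- if (is.null(cfgOut$selected_loci)) list()
                            else as.list(cfgOut$selected_loci)
    yaml::write_yaml(cfgOut, f)
    addRow(basename(f), "config_echo")
  }
  man <- do.call(rbind, manifest)
  write.table(man, file.path(directory, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man
}

#' Read grouped sample sequences into a SampleMatrix
#'
#' Accepts either a named vector of per-sample FASTA paths (names are
#' sample ids; each file holds one record per arm) or a fixture directory
#' written by [writeFixture()] (sample set and groups taken from
#' \code{groups.tsv}). Bases outside A/C/G/T (including lowercase input,
#' which is uppercased first) become \code{N}.
#'
#' @param path fixture directory, or named character vector of FASTA paths.
#' @param groups data.frame (\code{sample_id}, \code{group}) or path to a
#'   TSV with those columns; optional when \code{path} is a fixture
#'   directory.
#' @return A [SampleMatrix-class].
#' @export
readSampleMatrix <- function(path, groups = NULL) {
  if (length(path) == 1L && dir.exists(path)) {
    if (is.null(groups)) groups <- file.path(path, "groups.tsv")
    gr <- if (is.character(groups)) read.delim(groups) else groups
    files <- file.path(path, paste0(gr$sample_id, ".fasta"))
    names(files) <- gr$sample_id
  } else {
    files <- path
    if (is.null(names(files)) || any(names(files) == ""))
      stop("FASTA paths must be named by sample id")
    if (is.null(groups)) stop("a sample group map is required")
    gr <- if (is.character(groups)) read.delim(groups) else groups
  }
  miss <- setdiff(names(files), gr$sample_id)
  if (length(miss))
    stop("missing group assignment for sample(s): ",
         paste(miss, collapse = ", "))
  gr <- gr[match(names(files), gr$sample_id), ]

  perSample <- lapply(names(files), function(id) {
    s <- Biostrings::readDNAStringSet(files[[id]])
    names(s) <- sub("\\s.*$", "", names(s))
    s
  })
  names(perSample) <- names(files)
  armsRef <- names(perSample[[1L]])
  lens <- Biostrings::width(perSample[[1L]])
  for (id in names(perSample)) {
    s <- perSample[[id]]
    if (!identical(sort(names(s)), sort(armsRef)))
      stop("sample ", id, " does not cover arms ",
           paste(armsRef, collapse = ","))
    for (a in armsRef)
      if (Biostrings::width(s[a]) != lens[match(a, armsRef)])
        stop("length mismatch for sample ", id, " on arm ", a)
  }
  arms <- lapply(armsRef, function(a) {
    m <- vapply(names(perSample), function(id)
      strsplit(toupper(as.character(perSample[[id]][[a]])), "")[[1L]],
      character(lens[match(a, armsRef)]))
    m <- matrix(m, ncol = length(perSample),
                dimnames = list(NULL, names(perSample)))
    m
  })
  names(arms) <- armsRef
  SampleMatrix(arms, data.frame(sample_id = names(files),
                                group = gr$group,
                                stringsAsFactors = FALSE))
}

#' Read a multi-sample VCF into a SampleMatrix
#'
#' Invariant positions are supplied by the reference FASTA; SNP records
#' overwrite the reference base per sample. Haploid calls and homozygous
#' diploid genotypes are accepted; heterozygous genotypes are set to
#' \code{N} with a warning (lab strains are expected to be isogenic).
#'
#' @param vcf path to a VCFv4 file.
#' @param reference path to the reference FASTA (records named by arm).
#' @param groups data.frame or TSV path mapping \code{sample_id} to
#'   \code{group}; must also assign a group to the reference-derived
#'   outgroup if one is included as a sample.
#' @return A [SampleMatrix-class].
#' @export
readSampleMatrixVcf <- function(vcf, reference, groups) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  refSet <- Biostrings::readDNAStringSet(reference)
  names(refSet) <- sub("\\s.*$", "", names(refSet))
  gt <- vcfR::extract.gt(v)
  fix <- vcfR::getFIX(v)
  samples <- colnames(gt)
  gr <- if (is.character(groups)) read.delim(groups) else groups
  miss <- setdiff(samples, gr$sample_id)
  if (length(miss))
    stop("missing group assignment for sample(s): ",
         paste(miss, collapse = ", "))
  arms <- lapply(names(refSet), function(a) {
    base <- strsplit(toupper(as.character(refSet[[a]])), "")[[1L]]
    matrix(base, length(base), length(samples),
           dimnames = list(NULL, samples))
  })
  names(arms) <- names(refSet)
  nHet <- 0L
  for (i in seq_len(nrow(gt))) {
    a <- fix[i, "CHROM"]
    if (!a %in% names(arms)) stop("VCF record on unknown arm: ", a)
    p <- as.integer(fix[i, "POS"])
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",")[[1L]])
    if (any(nchar(alleles) != 1L)) next  # SNPs only
    for (j in seq_along(samples)) {
      g <- gt[i, j]
      if (is.na(g)) { arms[[a]][p, j] <- "N"; next }
      al <- strsplit(g, "[/|]")[[1L]]
      if (length(unique(al)) > 1L) {
        arms[[a]][p, j] <- "N"
        nHet <- nHet + 1L
      } else {
        arms[[a]][p, j] <- alleles[as.integer(al[1L]) + 1L]
      }
    }
  }
  if (nHet > 0L)
    warning(nHet, " heterozygous genotype(s) set to N")
  gr <- gr[match(samples, gr$sample_id), ]
  SampleMatrix(arms, data.frame(sample_id = samples, group = gr$group,
                                stringsAsFactors = FALSE))
}

#' Export gene models as GFF3
#'
#' Writes gene, mRNA, exon, CDS and UTR features (1-based inclusive, CDS
#' phase included) for one transcript per gene.
#'
#' @param models a [GeneModelSet-class].
#' @param path output GFF3 path.
#' @export
exportGeneModels <- function(models, path) {
  g <- genes(models)
  f <- geneFeatures(models)
  rows <- list()
  if (length(g)) {
    gid <- g$gene_id
    tid <- paste0(gid, ".t1")
    grGene <- g
    S4Vectors::mcols(grGene) <- S4Vectors::DataFrame(
      type = "gene", ID = gid, Parent = NA_character_,
      neuro = as.integer(g$neuro), phase = NA_integer_)
    grRna <- g
    S4Vectors::mcols(grRna) <- S4Vectors::DataFrame(
      type = "mRNA", ID = tid, Parent = gid,
      neuro = NA_integer_, phase = NA_integer_)
    ## exons = merged UTR/CDS segments per gene
    exList <- lapply(seq_along(gid), function(i) {
      fi <- f[f$gene_id == gid[i]]
      ex <- GenomicRanges::reduce(fi, ignore.strand = TRUE)
      BiocGenerics::strand(ex) <- as.character(BiocGenerics::strand(g))[i]
      S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
        type = "exon", ID = NA_character_, Parent = tid[i],
        neuro = NA_integer_, phase = NA_integer_)
      ex
    })
    grEx <- do.call(c, exList)
    grF <- f
    S4Vectors::mcols(grF) <- S4Vectors::DataFrame(
      type = f$type, ID = NA_character_,
      Parent = paste0(f$gene_id, ".t1"),
      neuro = NA_integer_, phase = f$phase)
    all <- c(grGene, grRna, grEx, grF)
  } else {
    all <- GenomicRanges::GRanges()
  }
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Import gene models from a GFF3 written by [exportGeneModels()]
#'
#' @param path GFF3 path.
#' @return A [GeneModelSet-class].
#' @export
importGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr))
    return(new("GeneModelSet",
               genes = GenomicRanges::GRanges(
                 gene_id = character(), neuro = logical(),
                 gene_length = integer()),
               features = GenomicRanges::GRanges(
                 type = character(), gene_id = character(),
                 phase = integer())))
  isGene <- gr$type == "gene"
  g <- gr[isGene]
  neuro <- if (!is.null(g$neuro)) as.logical(as.integer(g$neuro))
           else rep(FALSE, length(g))
  gOut <- GenomicRanges::granges(g)
  S4Vectors::mcols(gOut) <- S4Vectors::DataFrame(
    gene_id = as.character(g$ID), neuro = neuro,
    gene_length = BiocGenerics::width(g))
  keep <- gr$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR")
  f <- gr[keep]
  parent <- vapply(f$Parent, function(x)
    if (length(x)) x[[1L]] else NA_character_, character(1))
  fOut <- GenomicRanges::granges(f)
  phase <- if (!is.null(f$phase)) as.integer(f$phase)
           else rep(NA_integer_, length(f))
  S4Vectors::mcols(fOut) <- S4Vectors::DataFrame(
    type = as.character(f$type),
    gene_id = sub("\\.t1$", "", parent),
    phase = phase)
  new("GeneModelSet", genes = gOut, features = fOut)
}
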