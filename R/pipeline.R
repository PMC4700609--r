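## End-to-end orchestration: simulate (or read) -> filter -> classify ->
## annotate -> constraint envelope -> diversity/haplotypes -> enrichment
## and trees, with all tabular outputs written to an output directory.

#' Pipeline configuration
#'
#' Either \code{simulate} (a [simulationConfig()]) or \code{input_dir} (a
#' fixture directory readable by [readSampleMatrix()]) must be supplied.
#' Thresholds default to the analysis constants: Z-FST 2.5, Z-hap 2.5,
#' 1000 neutral and baseline replicates, 50 kb theta windows, 100 kb Dxy
#' windows, 1000 bootstrap replicates.
#'
#' @param simulate a [simulationConfig()], or NULL.
#' @param input_dir fixture directory, or NULL.
#' @param filter a [filterConfig()].
#' @param z_fst,z_hap outlier thresholds.
#' @param neutral_reps,baseline_reps,bootstrap_reps replicate counts.
#' @param theta_window,dxy_window window sizes (bp).
#' @param out_dir output directory.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(simulate = NULL, input_dir = NULL,
                           filter = filterConfig(),
                           z_fst = 2.5, z_hap = 2.5,
                           neutral_reps = 1000L, baseline_reps = 1000L,
                           bootstrap_reps = 1000L,
                           theta_window = 50000L, dxy_window = 100000L,
                           out_dir = tempfile("labSweeps_run_"),
                           seed = 1L) {
  if (is.null(simulate) && is.null(input_dir))
    stop("either a simulation config or an input directory is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  stopifnot(z_fst > 0, z_hap > 0, neutral_reps > 0, baseline_reps > 0,
            bootstrap_reps >= 0, theta_window > 0, dxy_window > 0)
  structure(list(simulate = simulate, input_dir = input_dir,
                 filter = filter, z_fst = z_fst, z_hap = z_hap,
                 neutral_reps = as.integer(neutral_reps),
                 baseline_reps = as.integer(baseline_reps),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 theta_window = as.integer(theta_window),
                 dxy_window = as.integer(dxy_window),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipelineConfig")
}

stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + stage * 9973) %% 2147483647)
}

writeTsv <- function(x, dir, name) {
  f <- file.path(dir, name)
  write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

#' Run the full analysis pipeline
#'
#' Executes every stage on simulated or on-disk data and writes TSV/BED/
#' newick outputs plus a run log with per-stage exclusion counts. Returns
#' a manifest of outputs and the in-memory results. Stage errors halt the
#' run with the stage name attached.
#'
#' @param config a [pipelineConfig()].
#' @return list with elements \code{manifest} (files by stage),
#'   \code{results} (per-stage objects) and \code{summary}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(config$out_dir, "run.log")
  logLine <- function(...) cat(..., "\n", file = log, append = TRUE)
  manifest <- list()
  res <- list()
  stage <- function(name, expr) {
    logLine("[stage]", name)
    tryCatch(expr, error = function(e) {
      logLine("[error]", name, conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cat("", file = log)

  ds <- NULL
  stage("input", {
    if (!is.null(config$simulate)) {
      ds <- simulateDataset(config$simulate)
      sm <- sampleMatrix(ds)
      models <- geneModels(ds)
      reference <- refSequences(ds)
      pref <- preferredCodons(ds)
    } else {
      sm <- readSampleMatrix(config$input_dir)
      gff <- file.path(config$input_dir, "genes.gff3")
      models <- if (file.exists(gff)) importGeneModels(gff) else NULL
      refF <- file.path(config$input_dir, "reference.fasta")
      reference <- if (file.exists(refF))
        Biostrings::readDNAStringSet(refF) else NULL
      prefF <- file.path(config$input_dir, "preferred_codons.tsv")
      pref <- if (file.exists(prefF)) read.delim(prefF)
              else defaultPreferredCodons()
    }
    res$matrix <- sm
    res$models <- models
    res$reference <- reference
    res$preferred <- pref
  })

  stage("filter", {
    flt <- filterSites(res$matrix, config$filter)
    logLine("eligible sites:", flt$eligible_sites)
    for (nm in names(flt$exclusions))
      logLine("excluded", nm, ":", flt$exclusions[[nm]])
    res$filtered <- flt
    manifest$sites <- writeTsv(flt$sites, config$out_dir,
                                "polarized_sites.tsv")
  })

  stage("classify", {
    snps <- classifyLabSpecific(res$filtered$sites)
    snps <- zClassifyFst(snps, config$z_fst)
    res$snps <- snps
    overlap <- sum(snps$lab_specific & snps$fst_class != "none")
    logLine("lab-specific:", sum(snps$lab_specific),
            "| fst_lab>wild:", sum(snps$fst_class == "fst_lab_gt_wild"),
            "| fst_wild>lab:", sum(snps$fst_class == "fst_wild_gt_lab"),
            "| overlap:", overlap)
    res$class_overlap <- overlap
    manifest$snps <- writeTsv(
      snps[, setdiff(names(snps), "lab_carriers")],
      config$out_dir, "classified_snps.tsv")
  })

  stage("annotate", {
    if (is.null(res$models) || is.null(res$reference)) {
      logLine("no gene models/reference; annotation skipped")
      res$annotated <- NULL
    } else {
      ann <- annotateSnps(res$snps, res$models, res$reference,
                          res$preferred)
      res$annotated <- ann
      logLine("CDS SNPs:", sum(ann$region == "exon_cds"),
              "| skipped codons:", attr(ann, "skipped_codons"))
      manifest$annotation <- writeTsv(
        ann[, setdiff(names(ann), "lab_carriers")],
        config$out_dir, "snp_annotation.tsv")
    }
  })

  stage("constraint", {
    if (is.null(res$annotated)) {
      res$constraint <- NULL
    } else {
      ann <- res$annotated
      labAnn <- ann[ann$lab_specific & !is.na(ann$substitution_type), ]
      nCds <- nrow(labAnn)
      if (nCds >= 1L) {
        cdsSeqs <- extractCdsSequences(res$models, res$reference)
        env <- simulateNeutral(cdsSeqs, nCds, res$preferred,
                               granthamMatrix(),
                               reps = config$neutral_reps,
                               seed = stageSeed(config$seed, 3L))
        labSum <- summarizeBins(labAnn)
        ## wild reference: derived SNPs absent from lab, binned by wild
        ## frequency fifths
        wildAnn <- ann[!is.na(ann$substitution_type) & ann$lab_der == 0L &
                         ann$wild_der > 0L, ]
        wildAnn$freq_class <- labFreqClass(wildAnn$wild_der,
                                           wildAnn$wild_called)
        wildAnn$wild_carriers <- wildCarriersColumn(res$matrix, wildAnn)
        wildSum <- summarizeBins(wildAnn, carriers_col = "wild_carriers")
        cmp <- compareBins(labSum, wildSum, env)
        res$constraint <- list(lab = labSum, wild = wildSum,
                                envelope = env, comparison = cmp)
        manifest$constraint <- writeTsv(
          cmp, config$out_dir, "constraint_comparison.tsv")
        manifest$bins <- writeTsv(
          labSum[, !vapply(labSum, is.list, logical(1))],
          config$out_dir, "lab_bins.tsv")
      } else {
        logLine("no lab-specific CDS SNPs; constraint stage skipped")
        res$constraint <- NULL
      }
    }
  })

  stage("diversity", {
    theta <- list(
      wild = wattersonWindows(res$matrix, "wild", config$theta_window),
      lab = wattersonWindows(res$matrix, "lab", config$theta_window))
    dxy <- dxyWindows(res$matrix, "wild", "outgroup", config$dxy_window)
    res$theta <- theta
    res$dxy <- dxy
    manifest$theta_wild <- writeTsv(theta$wild, config$out_dir,
                                     "theta_wild.tsv")
    manifest$theta_lab <- writeTsv(theta$lab, config$out_dir,
                                    "theta_lab.tsv")
    manifest$dxy <- writeTsv(dxy, config$out_dir, "dxy.tsv")
  })

  stage("haplotypes", {
    snps <- res$snps
    focal <- snps[snps$snp_class != "none", , drop = FALSE]
    if (nrow(focal) >= 2L) {
      blocks <- extendHaplotypes(res$matrix, focal)
      ho <- haplotypeOutliers(blocks, config$z_hap)
      res$haplotypes <- ho
      bed <- data.frame(arm = ho$blocks$arm,
                        start = ho$blocks$start - 1L,
                        end = ho$blocks$end,
                        focal_pos = ho$blocks$focal_pos,
                        snp_class = ho$blocks$snp_class,
                        freq_class = ho$blocks$freq_class,
                        length = ho$blocks$length,
                        z_hap = ho$blocks$z_hap)
      manifest$blocks <- writeTsv(bed, config$out_dir,
                                   "haplotype_blocks.bed")
      labPoly <- snps[snps$lab_der >= 1L & snps$lab_der < snps$lab_called, ]
      if (nrow(labPoly) >= 10L) {
        res$baseline <- randomSiteBaseline(
          res$matrix, labPoly, n_sites = min(50L, nrow(labPoly)),
          reps = config$baseline_reps,
          seed = stageSeed(config$seed, 5L))
      }
      logLine("blocks:", nrow(ho$blocks), "| outliers:",
              nrow(ho$outliers))
    } else {
      logLine("fewer than 2 focal SNPs; haplotype stage skipped")
      res$haplotypes <- NULL
    }
  })

  stage("enrichment_trees", {
    snps <- res$snps
    sel <- snps[snps$snp_class != "none", , drop = FALSE]
    armsLen <- vapply(armNames(res$matrix),
                      function(a) nrow(armBases(res$matrix, a)),
                      numeric(1))
    if (nrow(sel) > 0L && length(armsLen) > 1L) {
      res$arm_enrichment <- categoryEnrichment(
        sel$arm, armsLen / sum(armsLen))
      manifest$arm_enrichment <- writeTsv(
        res$arm_enrichment, config$out_dir, "arm_enrichment.tsv")
    }
    if (!is.null(res$models) && !is.null(res$haplotypes)) {
      out <- res$haplotypes$outliers
      g <- genes(res$models)
      if (nrow(out) > 0L && length(g) > 0L) {
        outGr <- GenomicRanges::GRanges(
          out$arm, IRanges::IRanges(out$start, out$end))
        hits <- GenomicRanges::findOverlaps(outGr, g,
                                            ignore.strand = TRUE)
        hitGenes <- unique(g$gene_id[S4Vectors::subjectHits(hits)])
        if (length(hitGenes)) {
          sets <- list(neurogenetic = g$gene_id[g$neuro],
                       other = g$gene_id[!g$neuro])
          lens <- setNames(g$gene_length, g$gene_id)
          res$gene_set_enrichment <- list(
            unnormalized = geneSetEnrichment(hitGenes, sets,
                                             g$gene_id),
            normalized = geneSetEnrichment(hitGenes, sets, g$gene_id,
                                           lens, TRUE))
          manifest$gene_sets <- writeTsv(
            res$gene_set_enrichment$unnormalized, config$out_dir,
            "gene_set_enrichment.tsv")
        }
      }
    }
    shared <- res$snps[res$snps$lab_der > 0L & res$snps$wild_der > 0L, ]
    if (nrow(shared) >= 3L && config$bootstrap_reps > 0L) {
      si <- sampleInfo(res$matrix)
      keep <- si$sample_id[si$group != "outgroup"]
      snpMat <- snpBaseMatrix(res$matrix, shared, keep)
      if (ncol(snpMat) >= 3L) {
        tree <- njTree(snpMat, config$bootstrap_reps,
                       seed = stageSeed(config$seed, 7L))
        res$tree <- tree
        manifest$tree <- file.path(config$out_dir, "nj_tree.nwk")
        writeTreeNewick(tree, manifest$tree)
      }
    }
  })

  summary <- list(
    eligible_sites = res$filtered$eligible_sites,
    n_snps = nrow(res$snps),
    n_lab_specific = sum(res$snps$lab_specific),
    n_fst_lab_gt_wild = sum(res$snps$fst_class == "fst_lab_gt_wild"),
    n_fst_wild_gt_lab = sum(res$snps$fst_class == "fst_wild_gt_lab"),
    class_overlap = res$class_overlap,
    mean_theta_wild = mean(res$theta$wild$theta_per_bp, na.rm = TRUE),
    mean_theta_lab = mean(res$theta$lab$theta_per_bp, na.rm = TRUE),
    mean_dxy = mean(res$dxy$dxy, na.rm = TRUE),
    n_blocks = if (!is.null(res$haplotypes))
      nrow(res$haplotypes$blocks) else 0L,
    n_outlier_blocks = if (!is.null(res$haplotypes))
      nrow(res$haplotypes$outliers) else 0L)
  writeTsv(data.frame(metric = names(summary),
                      value = unlist(lapply(summary, format))),
           config$out_dir, "summary.tsv")
  logLine("[done]")
  list(manifest = manifest, results = res, summary = summary)
}

## extract spliced CDS sequences (coding strand) for all genes
extractCdsSequences <- function(models, reference) {
  g <- genes(models)
  vapply(g$gene_id, function(gid) {
    seg <- cdsSegments(models, gid)
    arm <- as.character(GenomeInfoDb::seqnames(
      g[g$gene_id == gid]))[1L]
    refArm <- referenceBases(reference, arm)
    parts <- lapply(seq_along(seg$width), function(i) {
      b <- refArm[seg$start[i]:seg$end[i]]
      if (seg$strand == "-") rev(unname(COMPLEMENT[b])) else b
    })
    paste(unlist(parts), collapse = "")
  }, character(1))
}

## comma-separated wild carrier ids per SNP row
wildCarriersColumn <- function(matrix, snps) {
  si <- sampleInfo(matrix)
  wildIds <- si$sample_id[si$group == "wild"]
  out <- character(nrow(snps))
  for (arm in unique(snps$arm)) {
    rows <- which(snps$arm == arm)
    m <- armBases(matrix, arm)
    for (i in rows) {
      b <- m[snps$pos[i], wildIds]
      out[i] <- paste(wildIds[b == snps$der[i]], collapse = ",")
    }
  }
  out
}

## samples x sites base matrix at SNP positions
snpBaseMatrix <- function(matrix, snps, sample_ids) {
  cols <- list()
  for (arm in unique(snps$arm)) {
    m <- armBases(matrix, arm)
    pos <- snps$pos[snps$arm == arm]
    cols[[arm]] <- t(m[pos, sample_ids, drop = FALSE])
  }
  do.call(cbind, cols)
}
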