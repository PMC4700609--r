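## Extended haplotype blocks around focal SNPs among inbred lab strains.
## From a focal SNP, the block extends left and right while all
## derived-allele carriers with called bases agree and at most one carrier
## is missing per site; it stops (exclusive) at the first violating site
## or the arm edge. Unusually long blocks (Z-hap above threshold over the
## pooled block-length distribution) flag candidate selective sweeps.

## per-site congruence vector for a carrier set: TRUE where called carrier
## bases agree and missing carriers <= maxMissing
carrierOkVector <- function(m, carrierIds, maxMissing) {
  sub <- m[, carrierIds, drop = FALSE]
  nMiss <- rowSums(sub == "N")
  agree <- rep(TRUE, nrow(sub))
  if (ncol(sub) > 1L) {
    cnt <- vapply(BASES, function(b) rowSums(sub == b), numeric(nrow(sub)))
    agree <- rowSums(cnt > 0) <= 1L
  }
  agree & nMiss <= maxMissing
}

## single-carrier congruence: carrier called and agreeing with the
## majority base of the remaining strains (uncalled consensus tolerated)
singleCarrierOkVector <- function(m, carrier) {
  others <- setdiff(colnames(m), carrier)
  sub <- m[, others, drop = FALSE]
  cnt <- vapply(BASES, function(b) rowSums(sub == b), numeric(nrow(sub)))
  cons <- BASES[max.col(cnt, ties.method = "first")]
  cons[rowSums(cnt) == 0] <- "N"
  cb <- m[, carrier]
  cb != "N" & (cons == "N" | cb == cons)
}

## run of TRUE around index i: c(start, end) positions (inclusive)
runAround <- function(ok, i) {
  bad <- which(!ok)
  lo <- bad[bad < i]
  hi <- bad[bad > i]
  c(if (length(lo)) max(lo) + 1L else 1L,
    if (length(hi)) min(hi) - 1L else length(ok))
}

#' Extend the shared haplotype around one focal SNP
#'
#' @param lab_matrix character matrix (positions x lab strains) for one
#'   arm.
#' @param focal_pos focal SNP position.
#' @param carriers strain ids carrying the derived allele. With a single
#'   carrier the block is measured as the carrier's homozygosity run
#'   against the consensus of the remaining strains (experimental; shared
#'   haplotype length is undefined for one carrier).
#' @param max_missing_per_site carriers allowed to be missing per site
#'   (default 1).
#' @return list with \code{start}, \code{end}, \code{length}.
#' @export
extendHaplotype <- function(lab_matrix, focal_pos, carriers,
                            max_missing_per_site = 1L) {
  if (!length(carriers)) stop("focal SNP has no lab carriers")
  if (length(carriers) >= 2L) {
    ok <- carrierOkVector(lab_matrix, carriers, max_missing_per_site)
  } else {
    ## single carrier: congruence with the consensus of the other strains
    ok <- singleCarrierOkVector(lab_matrix, carriers)
  }
  ok[focal_pos] <- TRUE  # the focal site itself anchors the block
  span <- runAround(ok, focal_pos)
  list(start = span[1L], end = span[2L],
       length = span[2L] - span[1L] + 1L)
}

#' Extended haplotype blocks for a classified SNP table
#'
#' Computes one block per focal SNP (rows of \code{snps}) on its arm.
#' Carrier sets are taken from \code{lab_carriers}; single-carrier SNPs
#' use the experimental consensus-run measure and are flagged.
#'
#' @param matrix a [SampleMatrix-class].
#' @param snps classified SNP table (arm, pos, lab_carriers, freq_class,
#'   snp_class).
#' @param max_missing_per_site carriers allowed missing per site.
#' @param congruence \code{"carriers"} evaluates agreement over
#'   derived-allele carriers only (non-carriers vary freely);
#'   \code{"all"} requires congruence across every lab strain.
#' @return data.frame of blocks: arm, focal_pos, start, end, length,
#'   n_carriers, single_carrier, freq_class, snp_class.
#' @export
extendHaplotypes <- function(matrix, snps, max_missing_per_site = 1L,
                             congruence = c("carriers", "all")) {
  congruence <- match.arg(congruence)
  si <- sampleInfo(matrix)
  labIds <- si$sample_id[si$group == "lab"]
  out <- vector("list", nrow(snps))
  for (arm in unique(snps$arm)) {
    m <- armBases(matrix, arm)[, labIds, drop = FALSE]
    rows <- which(snps$arm == arm)
    ## memoise congruence vectors per carrier set
    cache <- new.env(parent = emptyenv())
    for (i in rows) {
      carriers <- strsplit(snps$lab_carriers[i], ",")[[1L]]
      carriers <- carriers[carriers != ""]
      if (!length(carriers)) next
      evalSet <- if (congruence == "all") labIds else carriers
      key <- paste(sort(evalSet), collapse = "|")
      ok <- cache[[key]]
      if (is.null(ok)) {
        ok <- if (length(evalSet) >= 2L)
          carrierOkVector(m, evalSet, max_missing_per_site)
        else singleCarrierOkVector(m, evalSet)
        cache[[key]] <- ok
      }
      ok2 <- ok
      ok2[snps$pos[i]] <- TRUE
      span <- runAround(ok2, snps$pos[i])
      blk <- list(start = span[1L], end = span[2L],
                  length = span[2L] - span[1L] + 1L)
      out[[i]] <- data.frame(
        arm = arm, focal_pos = snps$pos[i], start = blk$start,
        end = blk$end, length = blk$length,
        n_carriers = length(carriers),
        single_carrier = length(carriers) == 1L,
        freq_class = snps$freq_class[i],
        snp_class = if ("snp_class" %in% names(snps)) snps$snp_class[i]
                    else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(blocks))
    blocks <- data.frame(arm = character(), focal_pos = integer(),
                         start = integer(), end = integer(),
                         length = integer(), n_carriers = integer(),
                         single_carrier = logical(),
                         freq_class = numeric(), snp_class = character())
  rownames(blocks) <- NULL
  blocks
}

#' Z-hap outlier calling and per-class length summary
#'
#' Z-scores block lengths against the pooled block-length distribution
#' (population-form SD), returns blocks with \code{z_hap} and an outlier
#' flag, a per-frequency-class length summary, and the Wilcoxon rank-sum
#' comparison of the fixed-class (>= 0.8) lengths against all other
#' classes.
#'
#' @param blocks data.frame from [extendHaplotypes()].
#' @param z_threshold Z-hap cutoff (default 2.5).
#' @return list with \code{blocks} (plus \code{z_hap}, \code{outlier}),
#'   \code{outliers}, \code{class_summary}, \code{p_high_vs_rest}.
#' @export
haplotypeOutliers <- function(blocks, z_threshold = 2.5) {
  if (nrow(blocks) < 2L) stop("need at least 2 blocks")
  mu <- mean(blocks$length)
  sig <- sqrt(mean((blocks$length - mu)^2))
  if (sig == 0) stop("degenerate block-length distribution (sd = 0)")
  blocks$z_hap <- (blocks$length - mu) / sig
  blocks$outlier <- blocks$z_hap > z_threshold
  cls <- sort(unique(blocks$freq_class))
  classSummary <- do.call(rbind, lapply(cls, function(cl) {
    l <- blocks$length[blocks$freq_class == cl]
    data.frame(freq_class = cl, n = length(l), mean_length = mean(l),
               median_length = median(l), max_length = max(l))
  }))
  hi <- blocks$length[blocks$freq_class >= 0.8]
  lo <- blocks$length[blocks$freq_class < 0.8]
  pHi <- if (length(hi) && length(lo))
    suppressWarnings(wilcox.test(hi, lo)$p.value) else NA_real_
  list(blocks = blocks, outliers = blocks[blocks$outlier, , drop = FALSE],
       class_summary = classSummary, p_high_vs_rest = pHi)
}

#' Random-site haplotype-length baseline
#'
#' Samples \code{n_sites} lab-polymorphic focal sites uniformly per
#' replicate and records the mean haplotype length, giving a null
#' distribution against which an observed class mean is compared (reported
#' as the number of baseline SEs separating them).
#'
#' @param matrix a [SampleMatrix-class].
#' @param snps classified SNP table restricted to lab-polymorphic focal
#'   candidates (needs arm, pos, lab_carriers, freq_class).
#' @param n_sites sites per replicate.
#' @param reps replicate count (default 1000).
#' @param seed RNG seed.
#' @param observed_mean optional observed class mean length to compare.
#' @param max_missing_per_site carriers allowed missing per site.
#' @return list with \code{replicate_means}, \code{baseline_mean},
#'   \code{baseline_se}, and (when \code{observed_mean} is given)
#'   \code{se_separation}.
#' @export
randomSiteBaseline <- function(matrix, snps, n_sites, reps = 1000L,
                               seed = 1L, observed_mean = NULL,
                               max_missing_per_site = 1L) {
  usable <- snps[!is.na(snps$lab_carriers) & snps$lab_carriers != "", ,
                 drop = FALSE]
  if (n_sites > nrow(usable))
    stop("n_sites exceeds the ", nrow(usable), " available focal sites")
  ## block lengths are deterministic per site: compute once, resample
  blocks <- extendHaplotypes(matrix, usable, max_missing_per_site)
  key <- paste(usable$arm, usable$pos)
  bkey <- paste(blocks$arm, blocks$focal_pos)
  lens <- blocks$length[match(key, bkey)]
  lens <- lens[!is.na(lens)]
  means <- withSeed(seed, vapply(seq_len(reps), function(r)
    mean(lens[sample.int(length(lens), n_sites)]), numeric(1)))
  bm <- mean(means)
  bse <- sd(means) / sqrt(1)  # SE of a single replicate set = SD of means
  out <- list(replicate_means = means, baseline_mean = bm,
              baseline_se = bse)
  if (!is.null(observed_mean))
    out$se_separation <- if (bse > 0) (observed_mean - bm) / bse else
      ifelse(observed_mean == bm, 0, Inf)
  out
}
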