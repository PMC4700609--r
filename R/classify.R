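## Classification of polarised SNPs: lab-specific status, lab frequency
## class (fifths of the five-strain site frequency spectrum), Hudson's FST
## with a genome-wide Z-transformation, and the subsampling Sign test that
## asks whether lab strains carry more private variation than a random
## wild subset of the same size.

#' Map lab derived-allele frequencies to fifths
#'
#' With five strains the lab site-frequency spectrum is divided into fifths
#' (0.2, 0.4, 0.6, 0.8, 1.0). Fixed sites reached with missing data (4/4)
#' map to the fixed class 1.0.
#'
#' @param lab_der derived-allele counts among lab strains.
#' @param lab_called called lab strains per site.
#' @return numeric vector of frequency classes; NA where no lab copy of the
#'   derived allele is called.
#' @export
labFreqClass <- function(lab_der, lab_called) {
  f <- ifelse(lab_called > 0, lab_der / lab_called, NA_real_)
  cls <- ceiling(f * 5 - 1e-9) / 5
  cls[lab_der == 0L] <- NA_real_
  cls[lab_der == lab_called & lab_called > 0L] <- 1
  cls
}

#' Classify lab-specific SNPs
#'
#' A SNP is lab-specific when the derived allele is carried by at least one
#' lab strain and by no wild sample. Adds \code{lab_specific} and
#' \code{freq_class} columns to the polarised site table.
#'
#' @param sites data.frame as returned in \code{filterSites()$sites}.
#' @return the input with columns \code{lab_specific}, \code{freq_class}.
#' @export
classifyLabSpecific <- function(sites) {
  sites$lab_specific <- sites$wild_der == 0L & sites$lab_der >= 1L
  sites$freq_class <- labFreqClass(sites$lab_der, sites$lab_called)
  sites
}

#' Hudson's FST estimator for one diallelic site
#'
#' Ratio form
#' \deqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#'                     {p_1(1-p_2) + p_2(1-p_1)}}
#' Vectorised over sites. Undefined (NA) when both populations are fixed
#' for the same state (denominator zero). Negative values are retained.
#'
#' @param p1,p2 derived-allele frequencies in each population.
#' @param n1,n2 called sample sizes (each at least 2).
#' @return numeric vector of FST values (NA where undefined).
#' @export
hudsonFst <- function(p1, n1, p2, n2) {
  if (any(n1 < 2) || any(n2 < 2))
    stop("sample sizes below 2: within-population variance correction undefined")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("frequencies must lie in [0, 1]")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den == 0, NA_real_, num / den)
}

#' Z-transform FST and assign highly differentiated classes
#'
#' Computes FST per SNP (lab vs wild), Z-transforms over all SNPs with
#' defined FST using the population (n) form of the standard deviation, and
#' labels SNPs with Z above the threshold as \code{fst_lab_gt_wild} or
#' \code{fst_wild_gt_lab} according to which group carries the derived
#' allele at higher frequency. Lab-specific status is kept alongside, so
#' the overlap of the two labellings is reportable.
#'
#' @param records classified site table (from [classifyLabSpecific()]).
#' @param z_threshold Z-score cutoff for the highly differentiated class.
#' @return the input with columns \code{fst}, \code{z_fst},
#'   \code{fst_class} and a consolidated \code{snp_class}.
#' @export
zClassifyFst <- function(records, z_threshold = 2.5) {
  p1 <- records$lab_der / records$lab_called
  p2 <- records$wild_der / records$wild_called
  records$fst <- hudsonFst(p1, records$lab_called, p2, records$wild_called)
  def <- !is.na(records$fst)
  if (sum(def) < 2L) stop("need at least 2 records with defined FST")
  mu <- mean(records$fst[def])
  sig <- sqrt(mean((records$fst[def] - mu)^2))
  if (sig == 0) stop("degenerate FST distribution (sd = 0)")
  records$z_fst <- (records$fst - mu) / sig
  records$fst_class <- "none"
  hi <- def & records$z_fst > z_threshold
  records$fst_class[hi & p1 > p2] <- "fst_lab_gt_wild"
  records$fst_class[hi & p2 > p1] <- "fst_wild_gt_lab"
  records$snp_class <- ifelse(records$lab_specific, "lab_specific",
                              records$fst_class)
  records
}

#' Subsampling specificity Sign test
#'
#' Do the lab strains carry more subset-private derived alleles than a
#' random wild subset of the same size would? Each replicate draws \code{k}
#' wild genomes without replacement, counts derived alleles present in the
#' subset but absent from the remaining wild genomes (under the same
#' coverage rules used for lab-specific calls), and compares the count to
#' \code{observed_specific}. The two-sided Sign test is applied to the
#' per-replicate comparisons.
#'
#' @param matrix a [SampleMatrix-class].
#' @param observed_specific observed lab-specific SNP count to compare
#'   against.
#' @param k subset size (default 5).
#' @param reps replicate count (default 1000).
#' @param seed RNG seed.
#' @param config a [filterConfig()] supplying the coverage fractions.
#' @return list with \code{observed_specific_count},
#'   \code{replicate_counts}, \code{p_value}.
#' @export
subsampleSpecificityTest <- function(matrix, observed_specific, k = 5L,
                                     reps = 1000L, seed = 1L,
                                     config = filterConfig()) {
  si <- sampleInfo(matrix)
  wildIds <- si$sample_id[si$group == "wild"]
  if (k >= length(wildIds))
    stop("subset size k must be smaller than the wild sample count")
  ## subset-private alleles are by construction singletons or near-
  ## singletons of the wild panel, so the error-guard singleton exclusion
  ## must be lifted here or it would erase the very signal being counted
  config$exclude_wild_singletons <- FALSE
  polar <- filterSites(matrix, config)$sites
  if (!nrow(polar)) stop("no polarised sites available")

  ## per-arm derived-allele indicator over wild samples at polarised sites
  derInd <- list(); calledInd <- list()
  for (arm in unique(polar$arm)) {
    m <- armBases(matrix, arm)
    p <- polar[polar$arm == arm, ]
    sub <- m[p$pos, wildIds, drop = FALSE]
    derInd[[arm]] <- sub == p$der
    calledInd[[arm]] <- sub != "N"
  }
  D <- do.call(rbind, derInd)
  C <- do.call(rbind, calledInd)
  minSub <- ceiling(config$min_lab_fraction * k)
  minRest <- ceiling(config$min_wild_fraction * (length(wildIds) - k))

  counts <- withSeed(seed, vapply(seq_len(reps), function(r) {
    idx <- sample.int(length(wildIds), k)
    inSub <- seq_along(wildIds) %in% idx
    subDer <- rowSums(D[, inSub, drop = FALSE])
    restDer <- rowSums(D[, !inSub, drop = FALSE])
    subCall <- rowSums(C[, inSub, drop = FALSE])
    restCall <- rowSums(C[, !inSub, drop = FALSE])
    sum(subDer > 0 & restDer == 0 & subCall >= minSub &
          restCall >= minRest)
  }, numeric(1)))

  nBelow <- sum(counts < observed_specific)
  nAbove <- sum(counts > observed_specific)
  n <- nBelow + nAbove
  p <- if (n == 0) 1 else binom.test(nBelow, n, 0.5)$p.value
  list(observed_specific_count = observed_specific,
       replicate_counts = counts, p_value = p)
}
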