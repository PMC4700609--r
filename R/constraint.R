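## Selective-constraint statistics per lab frequency class and the neutral
## codon-mutation envelope. Four parameters are tracked per bin: mean
## Grantham score per replacement SNP, mean replacement/silent ratio per
## individual, the C1/(C2+C3) codon-position ratio, and the per-individual
## proportions of N2P and P2N silent shifts. The neutral null draws n
## mutations uniformly over concatenated CDS with equal probability of
## changing any codon position to any other base.

FREQ_BINS <- c(0.2, 0.4, 0.6, 0.8, 1.0)

#' Summarise constraint parameters per frequency class
#'
#' Restricts the annotation table to CDS SNPs and computes, per frequency
#' bin: mean Grantham over replacement SNPs; replacement/silent ratio per
#' individual (each carrier's replacement and silent derived-allele counts
#' in the bin) averaged over individuals with defined ratios; the pooled
#' C1/(C2+C3) count ratio; and per-individual proportions of N2P and P2N
#' among silent changes, averaged. Individuals with zero silent SNPs in a
#' bin contribute no R/S value (missing, not zero).
#'
#' @param annotations annotated SNP table with \code{freq_class},
#'   \code{substitution_type}, \code{grantham}, \code{codon_position},
#'   \code{codon_shift} and a \code{carriers} column (comma-separated
#'   sample ids; pass \code{lab_carriers} for the lab group).
#' @param carriers_col name of the carrier column.
#' @return data.frame with one row per frequency bin: \code{freq_class},
#'   \code{mean_grantham}, \code{rs_ratio}, \code{c1_ratio}, \code{n2p},
#'   \code{p2n}, \code{n_snps}, plus list-columns of the per-individual
#'   values used by [compareBins()].
#' @export
summarizeBins <- function(annotations, carriers_col = "lab_carriers") {
  cds <- annotations[!is.na(annotations$substitution_type), , drop = FALSE]
  carr <- strsplit(ifelse(is.na(cds[[carriers_col]]), "",
                          cds[[carriers_col]]), ",")
  out <- lapply(FREQ_BINS, function(b) {
    inBin <- !is.na(cds$freq_class) & abs(cds$freq_class - b) < 1e-9
    d <- cds[inBin, , drop = FALSE]
    cb <- carr[inBin]
    reps <- d$substitution_type == "replacement"
    inds <- unique(unlist(cb))
    perInd <- lapply(inds, function(id) {
      has <- vapply(cb, function(x) id %in% x, logical(1))
      nR <- sum(has & reps)
      nS <- sum(has & !reps)
      sil <- d$codon_shift[has & !reps]
      list(rs = if (nS > 0) nR / nS else NA_real_,
           n2p = if (nS > 0) mean(sil == "N2P") else NA_real_,
           p2n = if (nS > 0) mean(sil == "P2N") else NA_real_)
    })
    rsInd <- vapply(perInd, `[[`, numeric(1), "rs")
    n2pInd <- vapply(perInd, `[[`, numeric(1), "n2p")
    p2nInd <- vapply(perInd, `[[`, numeric(1), "p2n")
    nC1 <- sum(d$codon_position == "C1", na.rm = TRUE)
    nC23 <- sum(d$codon_position %in% c("C2", "C3"))
    gvals <- d$grantham[reps & !is.na(d$grantham)]
    data.frame(
      freq_class = b,
      mean_grantham = if (length(gvals)) mean(gvals) else NA_real_,
      rs_ratio = if (any(!is.na(rsInd))) mean(rsInd, na.rm = TRUE)
                 else NA_real_,
      c1_ratio = if (nC23 > 0) nC1 / nC23 else NA_real_,
      n2p = if (any(!is.na(n2pInd))) mean(n2pInd, na.rm = TRUE)
            else NA_real_,
      p2n = if (any(!is.na(p2nInd))) mean(p2nInd, na.rm = TRUE)
            else NA_real_,
      n_snps = nrow(d),
      grantham_values = I(list(gvals)),
      rs_values = I(list(rsInd[!is.na(rsInd)])),
      n2p_values = I(list(n2pInd[!is.na(n2pInd)])),
      p2n_values = I(list(p2nInd[!is.na(p2nInd)])))
  })
  do.call(rbind, out)
}

## precompute the outcome of every possible single-base change of a CDS
## set: one row per (position, alternative base)
enumerateCdsOutcomes <- function(cds_sequences, preferred_table,
                                 grantham_matrix) {
  seqs <- if (methods::is(cds_sequences, "DNAStringSet"))
    as.character(cds_sequences) else unlist(cds_sequences)
  concat <- paste(toupper(seqs), collapse = "")
  L <- nchar(concat)
  if (L == 0L) stop("total CDS length is zero")
  if (L %% 3L != 0L) stop("concatenated CDS length not divisible by 3")
  bases <- strsplit(concat, "")[[1L]]
  gc <- Biostrings::GENETIC_CODE
  pref <- setNames(preferred_table$preferred, preferred_table$codon)

  pos <- rep(seq_len(L), each = 3L)
  refB <- bases[pos]
  altIdx <- unlist(lapply(refB[seq(1, length(pos), by = 3L)],
                          function(b) setdiff(BASES, b)))
  off <- (pos - 1L) %% 3L + 1L
  codonStart <- pos - off + 1L
  refCodon <- paste0(bases[codonStart], bases[codonStart + 1L],
                     bases[codonStart + 2L])
  derCodon <- refCodon
  for (k in 1:3) {
    sel <- off == k
    tmp <- derCodon[sel]
    substr(tmp, k, k) <- altIdx[sel]
    derCodon[sel] <- tmp
  }
  aa1 <- unname(gc[refCodon])
  aa2 <- unname(gc[derCodon])
  silent <- aa1 == aa2
  stopInv <- aa1 == "*" | aa2 == "*"
  gsc <- rep(NA_real_, length(pos))
  repl <- !silent & !stopInv
  gsc[repl] <- grantham_matrix[cbind(aa1[repl], aa2[repl])]
  shift <- rep(NA_character_, length(pos))
  shift[silent] <- paste0(ifelse(pref[refCodon[silent]] == 1, "P", "N"),
                          "2",
                          ifelse(pref[derCodon[silent]] == 1, "P", "N"))
  data.frame(pos = pos, alt = altIdx, codon_pos = off,
             silent = silent, stop_involved = stopInv, grantham = gsc,
             shift = shift, stringsAsFactors = FALSE)
}

neutralParams <- function(o) {
  nRep <- sum(!o$silent)
  nSil <- sum(o$silent)
  g <- o$grantham[!o$silent & !is.na(o$grantham)]
  c(mean_grantham = if (length(g)) mean(g) else NA_real_,
    rs_ratio = if (nSil > 0) nRep / nSil else NA_real_,
    c1_ratio = {
      n1 <- sum(o$codon_pos == 1L)
      n23 <- sum(o$codon_pos != 1L)
      if (n23 > 0) n1 / n23 else NA_real_
    },
    n2p = if (nSil > 0) mean(o$shift[o$silent] == "N2P") else NA_real_,
    p2n = if (nSil > 0) mean(o$shift[o$silent] == "P2N") else NA_real_)
}

#' Neutral codon-mutation simulation envelope
#'
#' Per replicate, draws \code{n_mutations} distinct positions uniformly
#' over the concatenated CDS and mutates each to one of the other three
#' bases with probability 1/3, then scores the changes and computes the
#' four constraint parameters (pooled across mutations; simulated
#' mutations carry no strain assignment). The envelope is the mean and SD
#' of each parameter across replicates.
#'
#' @param cds_sequences character vector or \code{DNAStringSet} of coding
#'   sequences (concatenated length divisible by 3).
#' @param n_mutations mutations per replicate.
#' @param preferred_table,grantham_matrix scoring tables.
#' @param reps replicate count (default 1000).
#' @param seed RNG seed.
#' @return list with \code{mean}, \code{sd} (named vectors over the four
#'   parameters), \code{replicates} (reps x 5 matrix), \code{n_mutations},
#'   \code{reps}, \code{seed}.
#' @export
simulateNeutral <- function(cds_sequences, n_mutations,
                            preferred_table = defaultPreferredCodons(),
                            grantham_matrix = granthamMatrix(),
                            reps = 1000L, seed = 1L) {
  stopifnot(n_mutations >= 1L)
  outcomes <- enumerateCdsOutcomes(cds_sequences, preferred_table,
                                   grantham_matrix)
  L <- max(outcomes$pos)
  if (n_mutations > L)
    stop("n_mutations exceeds total CDS length (", L, " bp)")
  repMat <- withSeed(seed, {
    t(vapply(seq_len(reps), function(r) {
      p <- sample.int(L, n_mutations)           # without replacement
      a <- sample.int(3L, n_mutations, replace = TRUE)
      neutralParams(outcomes[(p - 1L) * 3L + a, ])
    }, numeric(5)))
  })
  list(mean = colMeans(repMat), sd = apply(repMat, 2L, sd),
       replicates = repMat, n_mutations = n_mutations, reps = reps,
       seed = seed)
}

#' Exact neutral expectation by exhaustive enumeration
#'
#' Evaluates the four constraint parameters over all possible single-base
#' changes of the CDS set, equally weighted -- the infinite-replicate limit
#' of [simulateNeutral()].
#'
#' @inheritParams simulateNeutral
#' @return named vector of the four parameters.
#' @export
enumerateNeutralExpectation <- function(cds_sequences,
                                        preferred_table =
                                          defaultPreferredCodons(),
                                        grantham_matrix =
                                          granthamMatrix()) {
  neutralParams(enumerateCdsOutcomes(cds_sequences, preferred_table,
                                     grantham_matrix))
}

#' Compare per-bin constraint estimates to wild and neutral references
#'
#' Runs two-sided Wilcoxon rank-sum tests per frequency bin and parameter:
#' lab per-SNP/per-individual values against the neutral replicate
#' distribution, and lab against wild values. Bins without data are
#' flagged and skipped. Significance flags follow the 0.05 and 0.001
#' levels.
#'
#' @param lab_summary,wild_summary outputs of [summarizeBins()].
#' @param envelope output of [simulateNeutral()].
#' @return data.frame with one row per (bin, parameter): observed values,
#'   neutral mean/SD, p-values and significance flags.
#' @export
compareBins <- function(lab_summary, wild_summary, envelope) {
  params <- c("mean_grantham", "rs_ratio", "c1_ratio", "n2p", "p2n")
  valueCols <- c(mean_grantham = "grantham_values", rs_ratio = "rs_values",
                 c1_ratio = NA, n2p = "n2p_values", p2n = "p2n_values")
  rows <- list()
  for (i in seq_len(nrow(lab_summary))) {
    for (p in params) {
      labVals <- if (is.na(valueCols[[p]]))
        lab_summary[[p]][i] else lab_summary[[valueCols[[p]]]][[i]]
      labVals <- labVals[!is.na(labVals)]
      wildVals <- if (is.na(valueCols[[p]]))
        wild_summary[[p]][i] else wild_summary[[valueCols[[p]]]][[i]]
      wildVals <- wildVals[!is.na(wildVals)]
      neut <- envelope$replicates[, p]
      neut <- neut[!is.na(neut)]
      pNeut <- if (length(labVals) && length(neut))
        suppressWarnings(wilcox.test(labVals, neut)$p.value) else NA_real_
      pWild <- if (length(labVals) && length(wildVals))
        suppressWarnings(wilcox.test(labVals, wildVals)$p.value)
        else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        freq_class = lab_summary$freq_class[i], parameter = p,
        lab_value = lab_summary[[p]][i],
        wild_value = wild_summary[[p]][i],
        neutral_mean = envelope$mean[[p]], neutral_sd = envelope$sd[[p]],
        p_vs_neutral = pNeut, p_vs_wild = pWild,
        flag_neutral = significanceFlag(pNeut),
        flag_wild = significanceFlag(pWild),
        skipped = length(labVals) == 0L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

significanceFlag <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.05) "**" else ""
}
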