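## Coverage filtering, diallelic restriction and outgroup polarisation.
## A site survives iff it is called in >= 75% of lab strains and >= 75% of
## wild samples (ceilings), carries at most two alleles among called
## ingroup bases, and the outgroup base matches one of them; the
## non-outgroup allele is the derived state. Wild-only singletons are
## dropped by default to guard against sequencing error.

#' Filtering configuration
#'
#' @param min_lab_fraction minimum fraction of lab strains with a called
#'   base (ceiling applied; 0.75 of five strains means at least four).
#' @param min_wild_fraction minimum called fraction of wild samples.
#' @param max_alleles maximum distinct alleles among called ingroup bases.
#' @param exclude_wild_singletons drop sites whose derived allele occurs
#'   exactly once in the wild and never in the lab.
#' @param require_outgroup error when the matrix lacks an outgroup sample.
#' @return validated list of class \code{filterConfig}.
#' @export
filterConfig <- function(min_lab_fraction = 0.75,
                         min_wild_fraction = 0.75,
                         max_alleles = 2L,
                         exclude_wild_singletons = TRUE,
                         require_outgroup = TRUE) {
  stopifnot(min_lab_fraction > 0, min_lab_fraction <= 1,
            min_wild_fraction > 0, min_wild_fraction <= 1,
            max_alleles >= 2L)
  structure(list(min_lab_fraction = min_lab_fraction,
                 min_wild_fraction = min_wild_fraction,
                 max_alleles = as.integer(max_alleles),
                 exclude_wild_singletons = exclude_wild_singletons,
                 require_outgroup = require_outgroup),
            class = "filterConfig")
}

## per-group base counts for one arm matrix: list of 4 count vectors + called
baseCounts <- function(m, idx) {
  sub <- m[, idx, drop = FALSE]
  counts <- lapply(BASES, function(b) rowSums(sub == b))
  names(counts) <- BASES
  counts$called <- rowSums(sub != "N")
  counts
}

#' Filter and polarise sites
#'
#' Applies the coverage, diallelic and outgroup-polarisation rules to every
#' position of every arm and returns the table of polarised SNPs, the
#' eligible-site denominator (sites passing coverage/diallelic/outgroup
#' rules, whether or not they are polymorphic) and per-rule exclusion
#' counts. Monoallelic sites matching the outgroup are eligible but emit no
#' record; sites where both ingroup alleles differ from the outgroup are
#' unpolarizable and dropped. The output is independent of sample order.
#'
#' @param matrix a [SampleMatrix-class].
#' @param config a [filterConfig()].
#' @return list with elements \code{sites} (data.frame: arm, pos, anc, der,
#'   lab_der, lab_called, wild_der, wild_called, lab_carriers),
#'   \code{eligible_sites}, \code{exclusions}.
#' @export
filterSites <- function(matrix, config = filterConfig()) {
  stopifnot(is(matrix, "SampleMatrix"))
  si <- sampleInfo(matrix)
  labIds <- si$sample_id[si$group == "lab"]
  wildIds <- si$sample_id[si$group == "wild"]
  ogId <- si$sample_id[si$group == "outgroup"]
  if (length(ogId) != 1L) {
    if (config$require_outgroup)
      stop("matrix has no outgroup sample; polarisation impossible")
    stop("filterSites requires exactly one outgroup sample")
  }
  minLab <- ceiling(config$min_lab_fraction * length(labIds))
  minWild <- ceiling(config$min_wild_fraction * length(wildIds))

  excl <- c(low_coverage = 0L, too_many_alleles = 0L,
            outgroup_missing = 0L, unpolarizable = 0L,
            wild_singleton = 0L)
  eligible <- 0L
  out <- list()
  for (arm in armNames(matrix)) {
    m <- armBases(matrix, arm)
    lab <- baseCounts(m, labIds)
    wild <- baseCounts(m, wildIds)
    og <- m[, ogId]

    covOK <- lab$called >= minLab & wild$called >= minWild
    excl["low_coverage"] <- excl["low_coverage"] + sum(!covOK)

    tot <- vapply(BASES, function(b) lab[[b]] + wild[[b]],
                  numeric(nrow(m)))
    nAlleles <- rowSums(tot > 0)
    allelesOK <- nAlleles <= config$max_alleles
    excl["too_many_alleles"] <-
      excl["too_many_alleles"] + sum(covOK & !allelesOK)

    ogOK <- og != "N"
    excl["outgroup_missing"] <-
      excl["outgroup_missing"] + sum(covOK & allelesOK & !ogOK)

    ## outgroup allele must be observed among ingroup alleles
    ogCount <- tot[cbind(seq_len(nrow(m)),
                         match(og, BASES, nomatch = 1L))]
    ogCount[!ogOK] <- 0
    ogSeen <- ogCount > 0
    pass <- covOK & allelesOK & ogOK
    excl["unpolarizable"] <- excl["unpolarizable"] + sum(pass & !ogSeen)
    elig <- pass & ogSeen
    eligible <- eligible + sum(elig)

    poly <- elig & nAlleles == 2L
    idx <- which(poly)
    if (!length(idx)) next
    ## derived = the non-outgroup allele
    der <- character(length(idx))
    for (b in BASES) {
      hit <- tot[idx, b] > 0 & og[idx] != b
      der[hit] <- b
    }
    derCol <- match(der, BASES)
    labDer <- vapply(seq_along(idx), function(i)
      lab[[der[i]]][idx[i]], numeric(1))
    wildDer <- vapply(seq_along(idx), function(i)
      wild[[der[i]]][idx[i]], numeric(1))

    keep <- rep(TRUE, length(idx))
    if (config$exclude_wild_singletons) {
      singleton <- wildDer == 1 & labDer == 0
      excl["wild_singleton"] <- excl["wild_singleton"] + sum(singleton)
      keep <- !singleton
    }
    idx2 <- idx[keep]
    if (!length(idx2)) next
    carriers <- vapply(seq_along(idx2), function(i) {
      r <- m[idx2[i], labIds]
      paste(labIds[r == der[keep][i]], collapse = ",")
    }, character(1))
    out[[arm]] <- data.frame(
      arm = arm, pos = idx2,
      anc = og[idx2], der = der[keep],
      lab_der = as.integer(labDer[keep]),
      lab_called = as.integer(lab$called[idx2]),
      wild_der = as.integer(wildDer[keep]),
      wild_called = as.integer(wild$called[idx2]),
      lab_carriers = carriers,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(arm = character(), pos = integer(), anc = character(),
               der = character(), lab_der = integer(),
               lab_called = integer(), wild_der = integer(),
               wild_called = integer(), lab_carriers = character(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  list(sites = sites, eligible_sites = eligible, exclusions = excl)
}
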