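## Category and gene-set enrichment with Benjamini-Hochberg correction,
## optional gene-length normalisation of the background, and the back-of-
## the-envelope expectation for de novo mutation counts.

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' preserved. Thin validated wrapper around \code{p.adjust}.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bhCorrect <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Category enrichment of classified SNPs
#'
#' Per category, the expected count is the total times the background
#' proportion; a one-degree chi-squared test (no continuity correction by
#' default) compares the in/out split to the background split, and BH
#' correction is applied across categories.
#'
#' @param categories character vector: the category of each SNP.
#' @param background named numeric vector of background proportions
#'   (summing to 1) covering every observed category.
#' @param yates apply Yates continuity correction (for small counts).
#' @return data.frame: category_id, observed, expected, fold, chi2, p,
#'   p_bh.
#' @export
categoryEnrichment <- function(categories, background, yates = FALSE) {
  if (abs(sum(background) - 1) > 1e-6)
    stop("background proportions must sum to 1")
  obsT <- table(categories)
  missing <- setdiff(names(obsT), names(background))
  if (length(missing))
    stop("category absent from background: ",
         paste(missing, collapse = ", "))
  total <- length(categories)
  rows <- lapply(names(background), function(cat) {
    obs <- if (cat %in% names(obsT)) as.integer(obsT[[cat]]) else 0L
    p0 <- background[[cat]]
    expd <- total * p0
    tst <- suppressWarnings(
      chisq.test(c(obs, total - obs), p = c(p0, 1 - p0),
                 correct = yates))
    chi2 <- unname(tst$statistic)
    if (yates && obs != expd) {
      ## chisq.test ignores `correct` for goodness-of-fit; apply by hand
      chi2 <- (abs(obs - expd) - 0.5)^2 / expd +
        (abs((total - obs) - (total - expd)) - 0.5)^2 / (total - expd)
    }
    data.frame(category_id = cat, observed = obs, expected = expd,
               fold = if (expd > 0) obs / expd else NA_real_,
               chi2 = chi2,
               p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bhCorrect(out$p)
  out
}

#' Gene-set enrichment with optional gene-length normalisation
#'
#' Unnormalised mode tests the hit overlap of each set against the
#' hypergeometric null (genes sampled uniformly from the universe).
#' Normalised mode weights the background expectation by each set's share
#' of total gene length -- so sets of disproportionately long genes are no
#' longer called enriched merely for presenting a larger mutational
#' target -- and tests the observed hit count against that length-weighted
#' proportion with a one-degree chi-squared test. BH correction is applied
#' across sets.
#'
#' @param hit_genes character vector of hit gene ids (subset of universe).
#' @param gene_sets named list: set id -> gene id vector.
#' @param universe character vector of all gene ids.
#' @param gene_lengths named numeric vector (bp per gene); required when
#'   \code{normalize_by_length}.
#' @param normalize_by_length logical.
#' @return data.frame: category_id, observed, expected, fold, p, p_bh.
#' @export
geneSetEnrichment <- function(hit_genes, gene_sets, universe,
                              gene_lengths = NULL,
                              normalize_by_length = FALSE) {
  if (!all(hit_genes %in% universe))
    stop("hit genes must be a subset of the universe")
  nHit <- length(unique(hit_genes))
  hit <- unique(hit_genes)
  N <- length(unique(universe))
  if (normalize_by_length) {
    if (is.null(gene_lengths))
      stop("gene_lengths required when normalize_by_length is set")
    noLen <- setdiff(universe, names(gene_lengths))
    if (length(noLen))
      stop("gene(s) without length: ", paste(head(noLen, 5L),
                                             collapse = ", "))
    totLen <- sum(gene_lengths[universe])
  }
  rows <- lapply(names(gene_sets), function(sid) {
    set <- intersect(gene_sets[[sid]], universe)
    k <- length(intersect(hit, set))
    if (normalize_by_length) {
      p0 <- sum(gene_lengths[set]) / totLen
      expd <- nHit * p0
      tst <- suppressWarnings(
        chisq.test(c(k, nHit - k), p = c(p0, 1 - p0)))
      p <- tst$p.value
    } else {
      expd <- nHit * length(set) / N
      ## upper-tail hypergeometric: P(X >= k)
      p <- phyper(k - 1L, length(set), N - length(set), nHit,
                  lower.tail = FALSE)
    }
    data.frame(category_id = sid, observed = k, expected = expd,
               fold = if (expd > 0) k / expd else NA_real_, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bhCorrect(out$p)
  out
}

#' Expected count of de novo lab-specific SNPs
#'
#' The product of the per-generation mutation rate, callable genome size,
#' generations per year, years in culture and number of strains: the
#' back-of-the-envelope upper bound on how many strain-private SNPs
#' mutation alone can supply.
#'
#' @param mu mutations/bp/generation.
#' @param genome_bp callable genome size in bp.
#' @param generations_per_year generations per year in culture.
#' @param years years since strain establishment.
#' @param n_strains number of strains.
#' @return expected SNP count.
#' @examples
#' expectedDeNovoSnps(3.5e-9, 1.2e8, 20, 75, 5)  # ~3150
#' @export
expectedDeNovoSnps <- function(mu, genome_bp, generations_per_year, years,
                               n_strains) {
  args <- c(mu, genome_bp, generations_per_year, years, n_strains)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all inputs must be positive")
  mu * genome_bp * generations_per_year * years * n_strains
}
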