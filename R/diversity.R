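## Watterson's theta in non-overlapping windows and Dxy between groups.

#' Watterson's theta in non-overlapping windows
#'
#' Per window: S counts diallelic sites among the group's samples at
#' positions where at least \code{min_called_fraction} of the group is
#' called; the effective sample size n is the rounded mean number of
#' called samples at eligible sites; theta per bp is
#' \eqn{S / (a_n L_{eff})} with \eqn{a_n = \sum_{i=1}^{n-1} 1/i} and
#' \eqn{L_{eff}} the eligible bp in the window. Windows without eligible
#' sites report NA.
#'
#' @param matrix a [SampleMatrix-class].
#' @param group group label ("lab" or "wild").
#' @param window window size in bp (default 50 kb).
#' @param min_called_fraction call-rate rule for site eligibility.
#' @return data.frame: arm, start, end, segregating_sites, mean_called,
#'   eligible_bp, theta_per_bp.
#' @export
wattersonWindows <- function(matrix, group, window = 50000L,
                             min_called_fraction = 0.75) {
  si <- sampleInfo(matrix)
  ids <- si$sample_id[si$group == group]
  if (length(ids) < 2L) stop("group '", group, "' has fewer than 2 samples")
  out <- list()
  for (arm in armNames(matrix)) {
    m <- armBases(matrix, arm)[, ids, drop = FALSE]
    called <- rowSums(m != "N")
    counts <- vapply(BASES, function(b) rowSums(m == b), numeric(nrow(m)))
    nAll <- rowSums(counts > 0)
    elig <- called >= ceiling(min_called_fraction * length(ids))
    seg <- elig & nAll == 2L
    L <- nrow(m)
    starts <- seq(1L, L, by = window)
    for (s in starts) {
      e <- min(s + window - 1L, L)
      idx <- s:e
      eligW <- elig[idx]
      Leff <- sum(eligW)
      if (Leff == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          arm = arm, start = s, end = e, segregating_sites = NA_integer_,
          mean_called = NA_real_, eligible_bp = 0L,
          theta_per_bp = NA_real_)
        next
      }
      S <- sum(seg[idx])
      n <- round(mean(called[idx][eligW]))
      an <- sum(1 / seq_len(max(n - 1L, 1L)))
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, start = s, end = e, segregating_sites = S,
        mean_called = n, eligible_bp = Leff,
        theta_per_bp = S / (an * Leff))
    }
  }
  do.call(rbind, out)
}

#' Dxy between two groups in non-overlapping windows
#'
#' Per eligible site (both groups have at least one called base), the mean
#' over between-group sample pairs of the per-site difference indicator,
#' averaged over eligible sites in the window:
#' per site \eqn{1 - \sum_b f_A(b) f_B(b)} with \eqn{f} the within-group
#' base frequencies among called samples.
#'
#' @param matrix a [SampleMatrix-class].
#' @param group_a,group_b group labels.
#' @param window window size in bp (default 100 kb).
#' @return data.frame: arm, start, end, eligible_bp, dxy.
#' @export
dxyWindows <- function(matrix, group_a, group_b, window = 100000L) {
  si <- sampleInfo(matrix)
  idsA <- si$sample_id[si$group == group_a]
  idsB <- si$sample_id[si$group == group_b]
  if (!length(idsA) || !length(idsB)) stop("both groups must be non-empty")
  out <- list()
  for (arm in armNames(matrix)) {
    mA <- armBases(matrix, arm)[, idsA, drop = FALSE]
    mB <- armBases(matrix, arm)[, idsB, drop = FALSE]
    cntA <- vapply(BASES, function(b) rowSums(mA == b), numeric(nrow(mA)))
    cntB <- vapply(BASES, function(b) rowSums(mB == b), numeric(nrow(mB)))
    calledA <- rowSums(cntA)
    calledB <- rowSums(cntB)
    elig <- calledA > 0 & calledB > 0
    d <- rep(NA_real_, nrow(mA))
    fa <- cntA[elig, , drop = FALSE] / calledA[elig]
    fb <- cntB[elig, , drop = FALSE] / calledB[elig]
    d[elig] <- 1 - rowSums(fa * fb)
    L <- nrow(mA)
    starts <- seq(1L, L, by = window)
    for (s in starts) {
      e <- min(s + window - 1L, L)
      idx <- s:e
      Leff <- sum(elig[idx])
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, start = s, end = e, eligible_bp = Leff,
        dxy = if (Leff > 0L) mean(d[idx], na.rm = TRUE) else NA_real_)
    }
  }
  do.call(rbind, out)
}
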