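## Neighbor-joining trees on p-distances with site-resampling bootstrap.

#' Pairwise p-distance matrix with pairwise deletion
#'
#' Mismatch proportion over sites called (non-N) in both samples of each
#' pair.
#'
#' @param snp_matrix character matrix, samples x sites (alphabet
#'   A/C/G/T/N).
#' @return symmetric numeric matrix of distances.
#' @export
pDistance <- function(snp_matrix) {
  n <- nrow(snp_matrix)
  called <- snp_matrix != "N"
  joint <- tcrossprod(called * 1)
  match <- matrix(0, n, n)
  for (b in BASES) {
    ind <- (snp_matrix == b) * 1
    match <- match + tcrossprod(ind)
  }
  if (any(joint[upper.tri(joint)] == 0))
    stop("sample pair with zero jointly-called sites")
  d <- 1 - match / joint
  diag(d) <- 0
  dimnames(d) <- list(rownames(snp_matrix), rownames(snp_matrix))
  d
}

#' Neighbor-joining tree with site-resampling bootstrap
#'
#' Builds the NJ tree from p-distances and bootstraps by resampling site
#' columns with replacement; node labels carry the percentage of
#' replicates containing each internal bipartition.
#'
#' @param snp_matrix character matrix, samples x diallelic sites.
#' @param bootstrap_reps bootstrap replicates (default 1000; 0 disables).
#' @param seed RNG seed for the bootstrap.
#' @return an \code{ape::phylo} tree with bootstrap percentages in
#'   \code{node.label} (root unlabeled).
#' @export
njTree <- function(snp_matrix, bootstrap_reps = 1000L, seed = 1L) {
  if (nrow(snp_matrix) < 3L) stop("need at least 3 samples")
  if (any(rowSums(snp_matrix != "N") == 0L))
    stop("sample with no called sites")
  tree <- ape::nj(pDistance(snp_matrix))
  if (bootstrap_reps > 0L) {
    boots <- withSeed(seed, lapply(seq_len(bootstrap_reps), function(r) {
      idx <- sample.int(ncol(snp_matrix), ncol(snp_matrix),
                        replace = TRUE)
      ape::nj(pDistance(snp_matrix[, idx, drop = FALSE]))
    }))
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    tree$node.label <- round(100 * counts / bootstrap_reps, 1)
    tree$node.label[1L] <- NA  # root bipartition is not meaningful
  }
  tree
}

#' Bootstrap support for the monophyly of a sample set
#'
#' Convenience check used to ask, e.g., whether the lab strains form a
#' clade: the percentage of bootstrap replicates in which \code{tips}
#' forms a bipartition of the unrooted tree.
#'
#' @param snp_matrix samples x sites character matrix.
#' @param tips sample names whose monophyly is assessed.
#' @param bootstrap_reps replicates.
#' @param seed RNG seed.
#' @return list with \code{support} (percent), \code{in_tree} (logical:
#'   clade present in the point-estimate tree).
#' @export
cladeSupport <- function(snp_matrix, tips, bootstrap_reps = 100L,
                         seed = 1L) {
  stopifnot(all(tips %in% rownames(snp_matrix)))
  isClade <- function(tr) {
    ## unrooted bipartition check: tips (or their complement) form a clade
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    want <- sort(match(tips, labs))
    other <- sort(setdiff(seq_along(labs), want))
    any(vapply(parts, function(p)
      identical(sort(p), want) || identical(sort(p), other), logical(1)))
  }
  tree <- ape::nj(pDistance(snp_matrix))
  hits <- withSeed(seed, vapply(seq_len(bootstrap_reps), function(r) {
    idx <- sample.int(ncol(snp_matrix), ncol(snp_matrix), replace = TRUE)
    isClade(ape::nj(pDistance(snp_matrix[, idx, drop = FALSE])))
  }, logical(1)))
  list(support = 100 * mean(hits), in_tree = isClade(tree))
}

#' Write a tree to newick
#'
#' @param tree an \code{ape::phylo}.
#' @param path output file.
#' @export
writeTreeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
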