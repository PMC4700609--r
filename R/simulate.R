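## Forward-in-time generator for a synthetic lab-domestication study:
## an ancestral pool with a neutral site-frequency spectrum, a small shared
## laboratory founding stock evolving under drift (and optional selection)
## during a short domestication phase, five strains inbred to fixation, a
## wild panel sampled from the same pool, and a diverged outgroup.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulateDataset()]. Defaults
#' describe a compact but structurally faithful study: five nearly
#' homozygous lab strains descended from one small founding stock, a wild
#' panel of 205 genomes drawn from the same ancestral pool, and an outgroup
#' diverged by 5\% -- with per-arm lengths scaled to tens of kilobases so a
#' full study simulates in seconds.
#'
#' @param genome_length bp per chromosome arm.
#' @param arm_names arm labels.
#' @param n_wild number of wild genomes sampled.
#' @param n_lab number of lab strains.
#' @param ancestral_theta per-bp pairwise diversity of the ancestral pool.
#' @param outgroup_divergence substitutions/bp separating outgroup from the
#'   ancestor.
#' @param inbreeding_generations generations of within-strain inbreeding
#'   after strains separate from the stock.
#' @param domestication_generations generations the shared founding stock
#'   evolves (drift + selection) before strains are established.
#' @param founder_count_per_strain founding individuals per strain (each
#'   contributes two haplotypes).
#' @param lab_stock_size haplotypes in the shared founding stock.
#' @param selected_loci data.frame with columns \code{arm}, \code{pos},
#'   \code{s} (selection coefficient), or NULL.
#' @param selected_init_freq initial pool frequency of each selected derived
#'   allele.
#' @param sweep_span mean one-sided extent (bp) of the shared founder
#'   haplotype flanking a selected allele.
#' @param recomb_rate per-bp per-generation crossover rate.
#' @param missing_rate_lab,missing_rate_wild i.i.d. per-site per-sample
#'   probability of an uncalled base (\code{N}).
#' @param de_novo_rate per-bp per-generation strain-private mutation rate
#'   (rescaled upward so compact arms accrue realistic per-genome counts).
#' @param pool_size ancestral pool haplotype count; default
#'   \code{2 * n_wild + 20}.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(genome_length = 50000L,
                             arm_names = c("2L", "2R", "3L", "3R", "X"),
                             n_wild = 205L,
                             n_lab = 5L,
                             ancestral_theta = 0.005,
                             outgroup_divergence = 0.05,
                             inbreeding_generations = 150L,
                             domestication_generations = 0L,
                             founder_count_per_strain = 4L,
                             lab_stock_size = 40L,
                             selected_loci = NULL,
                             selected_init_freq = 0.25,
                             sweep_span = 15000,
                             recomb_rate = 1e-8,
                             missing_rate_lab = 0.001,
                             missing_rate_wild = 0.02,
                             de_novo_rate = 3.5e-9,
                             pool_size = NULL,
                             seed = 1L) {
  if (is.null(pool_size)) pool_size <- 2L * as.integer(n_wild) + 20L
  cfg <- list(genome_length = as.integer(genome_length),
              arm_names = as.character(arm_names),
              n_wild = as.integer(n_wild), n_lab = as.integer(n_lab),
              ancestral_theta = ancestral_theta,
              outgroup_divergence = outgroup_divergence,
              inbreeding_generations = as.integer(inbreeding_generations),
              domestication_generations = as.integer(domestication_generations),
              founder_count_per_strain = as.integer(founder_count_per_strain),
              lab_stock_size = as.integer(lab_stock_size),
              selected_loci = selected_loci,
              selected_init_freq = selected_init_freq,
              sweep_span = sweep_span,
              recomb_rate = recomb_rate,
              missing_rate_lab = missing_rate_lab,
              missing_rate_wild = missing_rate_wild,
              de_novo_rate = de_novo_rate,
              pool_size = as.integer(pool_size),
              seed = as.integer(seed))
  rates <- c(cfg$ancestral_theta, cfg$outgroup_divergence,
             cfg$missing_rate_lab, cfg$missing_rate_wild,
             cfg$selected_init_freq)
  if (any(rates < 0) || any(c(cfg$outgroup_divergence, cfg$missing_rate_lab,
                              cfg$missing_rate_wild,
                              cfg$selected_init_freq) > 1))
    stop("rates and probabilities must lie in [0, 1]")
  counts <- c(cfg$genome_length, cfg$n_wild, cfg$n_lab,
              cfg$founder_count_per_strain, cfg$lab_stock_size,
              cfg$pool_size)
  if (any(counts <= 0L))
    stop("lengths and counts must be positive integers")
  if (cfg$inbreeding_generations < 0L || cfg$domestication_generations < 0L)
    stop("generation counts must be non-negative")
  if (cfg$pool_size <= cfg$n_wild)
    stop("pool_size must exceed n_wild")
  if (anyDuplicated(cfg$arm_names))
    stop("duplicated arm names")
  if (!is.null(cfg$selected_loci)) {
    sl <- cfg$selected_loci
    if (!all(c("arm", "pos", "s") %in% names(sl)))
      stop("selected_loci needs columns arm, pos, s")
    if (!all(sl$arm %in% cfg$arm_names))
      stop("selected loci on undeclared arms: ",
           paste(setdiff(sl$arm, cfg$arm_names), collapse = ", "))
    if (any(sl$pos < 1L | sl$pos > cfg$genome_length))
      stop("selected loci positions fall outside declared arm lengths")
    if (any(sl$s < 0)) stop("selection coefficients must be non-negative")
  }
  class(cfg) <- "simulationConfig"
  cfg
}

## run expr with a private RNG stream seeded by `seed`
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## one Wright-Fisher generation over a haplotype matrix (sites x N logical),
## with crossover and fitness-biased acceptance at selected site rows
wfGeneration <- function(H, sitePos, L, recomb, selRows, selS) {
  N <- ncol(H)
  wmax <- if (length(selRows)) prod(1 + selS) else 1
  out <- H
  for (j in seq_len(N)) {
    repeat {
      p <- sample.int(N, 2L, replace = TRUE)
      child <- H[, p[1L]]
      k <- rpois(1L, recomb * L)
      if (k > 0L) {
        bp <- sort(runif(k, 1, L))
        seg <- findInterval(sitePos, bp) %% 2L == 1L
        child[seg] <- H[seg, p[2L]]
      }
      if (!length(selRows)) break
      w <- prod(1 + selS * child[selRows])
      if (runif(1) <= w / wmax) break
    }
    out[, j] <- child
  }
  out
}

simulateArm <- function(arm, cfg) {
  L <- cfg$genome_length
  P <- cfg$pool_size
  ref <- sample(BASES, L, replace = TRUE)

  aP <- sum(1 / seq_len(P - 1L))
  pSeg <- min(1, cfg$ancestral_theta * aP)
  S <- rbinom(1L, L, pSeg)
  pos <- sort(sample.int(L, S))
  G <- matrix(FALSE, S, P)
  if (S > 0L) {
    cnt <- sample.int(P - 1L, S, replace = TRUE, prob = 1 / seq_len(P - 1L))
    for (s in seq_len(S)) G[s, sample.int(P, cnt[s])] <- TRUE
  }
  derived <- vapply(pos, function(p) sample(setdiff(BASES, ref[p]), 1L),
                    character(1))

  ## plant selected alleles on a clean (ancestral-background) haplotype:
  ## carriers share an unbroken flanking span copied from the ancestral
  ## state, emulating a young allele on a single common background
  sel <- cfg$selected_loci
  sel <- if (is.null(sel)) sel else sel[sel$arm == arm, , drop = FALSE]
  selRows <- integer(0)
  selS <- numeric(0)
  selCarriers <- list()
  if (!is.null(sel) && nrow(sel)) {
    for (i in seq_len(nrow(sel))) {
      p0 <- as.integer(sel$pos[i])
      row <- match(p0, pos)
      if (is.na(row)) {
        ins <- findInterval(p0, pos)
        pos <- append(pos, p0, after = ins)
        derived <- append(derived, sample(setdiff(BASES, ref[p0]), 1L),
                          after = ins)
        G <- rbind(G[seq_len(ins), , drop = FALSE],
                   rep(FALSE, P),
                   G[seq(ins + 1L, length.out = nrow(G) - ins), ,
                     drop = FALSE])
        row <- ins + 1L
        selRows[selRows > ins] <- selRows[selRows > ins] + 1L
      }
      carriers <- sample.int(P, max(1L, round(cfg$selected_init_freq * P)))
      for (cc in carriers) {
        d <- cfg$sweep_span * runif(2L, 0.8, 1.2)
        win <- pos >= p0 - d[1L] & pos <= p0 + d[2L]
        G[win, cc] <- FALSE
      }
      selRows <- c(selRows, row)
      selS <- c(selS, sel$s[i])
      selCarriers[[length(selCarriers) + 1L]] <- carriers
    }
    ## set carrier states after all spans are painted, so overlapping
    ## sweep spans cannot erase one another's selected alleles
    for (i in seq_along(selRows)) {
      G[selRows[i], ] <- FALSE
      G[selRows[i], selCarriers[[i]]] <- TRUE
    }
  }
  S <- length(pos)

  ## wild panel: haplotypes drawn without replacement from the pool
  widx <- sample.int(P, cfg$n_wild)
  wildH <- G[, widx, drop = FALSE]

  ## shared lab founding stock sampled from the pool; an optional
  ## domestication phase lets the stock drift (and respond to selection)
  ## as one population before strains are split off
  stockN <- min(cfg$lab_stock_size, P)
  sidx <- sample.int(P, stockN)
  stock <- G[, sidx, drop = FALSE]
  for (g in seq_len(cfg$domestication_generations))
    stock <- wfGeneration(stock, pos, L, cfg$recomb_rate, selRows, selS)

  ## per-strain inbreeding from a handful of stock founders down to one
  ## fixed haplotype (isofemale-line style), then strain-private
  ## mutations. Founder sets are disjoint across strains when the stock is
  ## large enough, so strains are related through the shared pool rather
  ## than through literal founder reuse. When selection is simulated, each
  ## strain's founder set is conditioned to capture the selected standing
  ## variants (the loci under study are those whose alleles the founders
  ## actually carried).
  Hs <- 2L * cfg$founder_count_per_strain
  founderSets <- if (stockN >= cfg$n_lab * Hs) {
    split(sample.int(stockN, cfg$n_lab * Hs),
          rep(seq_len(cfg$n_lab), each = Hs))
  } else {
    lapply(seq_len(cfg$n_lab), function(k)
      sample.int(stockN, min(Hs, stockN)))
  }
  if (length(selRows)) {
    minCarry <- min(max(2L, ceiling(0.4 * Hs)), Hs)
    for (r in selRows) {
      ## pool carriers not already present in the stock are available to
      ## swap in for non-carrier founder columns, one strain at a time
      availPool <- setdiff(which(G[r, ]), sidx)
      for (k in seq_len(cfg$n_lab)) {
        cols <- founderSets[[k]]
        need <- minCarry - sum(stock[r, cols])
        if (need <= 0L || !length(availPool)) next
        replCols <- cols[!stock[r, cols]]
        nTake <- min(need, length(availPool), length(replCols))
        if (nTake < 1L) next
        take <- availPool[seq_len(nTake)]
        availPool <- availPool[-seq_len(nTake)]
        stock[, replCols[seq_len(nTake)]] <- G[, take, drop = FALSE]
        sidx[replCols[seq_len(nTake)]] <- take
      }
    }
  }
  deNovo <- list()
  labHaps <- matrix(FALSE, S, cfg$n_lab)
  labNew <- vector("list", cfg$n_lab)
  for (k in seq_len(cfg$n_lab)) {
    Fm <- stock[, founderSets[[k]], drop = FALSE]
    for (g in seq_len(cfg$inbreeding_generations)) {
      if (S > 0L && all(Fm == Fm[, 1L])) break
      if (S == 0L) break
      Fm <- wfGeneration(Fm, pos, L, cfg$recomb_rate, selRows, selS)
    }
    labHaps[, k] <- Fm[, 1L]
    nMut <- rpois(1L, cfg$de_novo_rate * L * cfg$inbreeding_generations)
    newPos <- setdiff(sample.int(L, min(nMut, L)), pos)
    labNew[[k]] <- data.frame(
      pos = newPos,
      base = vapply(newPos, function(p) sample(setdiff(BASES, ref[p]), 1L),
                    character(1)),
      stringsAsFactors = FALSE)
  }

  ## outgroup: ancestor plus divergence
  og <- ref
  nD <- rbinom(1L, L, cfg$outgroup_divergence)
  if (nD > 0L) {
    ## selected loci stay polarizable: outgroup divergence is placed away
    ## from them (a locus with a misinferred ancestral state would not
    ## enter a curated sweep scan)
    dpos <- sample.int(L, min(nD + length(selRows), L))
    dpos <- setdiff(dpos, pos[selRows])[seq_len(min(nD, L))]
    dpos <- dpos[!is.na(dpos)]
    og[dpos] <- vapply(dpos, function(p) sample(setdiff(BASES, ref[p]), 1L),
                       character(1))
  }

  labIds <- paste0("lab_", seq_len(cfg$n_lab))
  wildIds <- paste0("wild_", seq_len(cfg$n_wild))
  ids <- c(labIds, wildIds, "outgroup")
  m <- matrix(ref, L, length(ids), dimnames = list(NULL, ids))
  for (k in seq_len(cfg$n_lab)) {
    hit <- which(labHaps[, k])
    m[pos[hit], k] <- derived[hit]
    dn <- labNew[[k]]
    if (nrow(dn)) m[dn$pos, k] <- dn$base
  }
  for (j in seq_len(cfg$n_wild)) {
    hit <- which(wildH[, j])
    m[pos[hit], cfg$n_lab + j] <- derived[hit]
  }
  m[, "outgroup"] <- og

  ## i.i.d. missing data
  if (cfg$missing_rate_lab > 0 && cfg$n_lab > 0L) {
    mask <- matrix(runif(L * cfg$n_lab) < cfg$missing_rate_lab, L)
    m[, seq_len(cfg$n_lab)][mask] <- "N"
  }
  if (cfg$missing_rate_wild > 0 && cfg$n_wild > 0L) {
    mask <- matrix(runif(L * cfg$n_wild) < cfg$missing_rate_wild, L)
    m[, cfg$n_lab + seq_len(cfg$n_wild)][mask] <- "N"
  }

  dn <- do.call(rbind, lapply(seq_along(labNew), function(k)
    if (nrow(labNew[[k]])) cbind(strain = labIds[k], labNew[[k]])))
  list(matrix = m, ref = ref, pos = pos,
       de_novo = dn, sel_rows = selRows)
}

#' Simulate a complete synthetic study
#'
#' Runs the forward simulation described in [simulationConfig()] for every
#' arm and assembles the result into a [SyntheticDataset-class]: the base
#' matrix of lab strains, wild panel and outgroup; gene models; ancestral
#' reference; the packaged preferred-codon table; and a truth record of
#' selected loci, realized polymorphic positions and strain-private
#' mutations. Lab strain sequences are fully inbred single haplotypes, so
#' within-strain heterozygosity is zero by construction.
#'
#' @param config a [simulationConfig()].
#' @param gene_density mean genes per bp used when generating gene models
#'   (default one gene per 8 kb).
#' @param neuro_fraction fraction of genes flagged neurogenetic.
#' @return A [SyntheticDataset-class].
#' @examples
#' cfg <- simulationConfig(genome_length = 5000, arm_names = "2L",
#'                         n_wild = 20, pool_size = 60, seed = 42)
#' ds <- simulateDataset(cfg)
#' ds
#' @export
simulateDataset <- function(config, gene_density = 1 / 8000,
                            neuro_fraction = 0.1) {
  stopifnot(inherits(config, "simulationConfig"))
  withSeed(config$seed, {
    armRes <- lapply(config$arm_names, simulateArm, cfg = config)
    names(armRes) <- config$arm_names

    si <- data.frame(
      sample_id = colnames(armRes[[1L]]$matrix),
      group = c(rep("lab", config$n_lab), rep("wild", config$n_wild),
                "outgroup"),
      stringsAsFactors = FALSE)
    sm <- SampleMatrix(lapply(armRes, `[[`, "matrix"), si)

    nG <- max(0L, round(gene_density * config$genome_length))
    gmods <- lapply(seq_along(config$arm_names), function(i)
      generateGeneModels(config$genome_length, nG, neuro_fraction,
                         seed = config$seed + 7919L * i,
                         arm = config$arm_names[i]))
    gm <- combineGeneModels(gmods)

    poly <- do.call(rbind, lapply(config$arm_names, function(a) {
      r <- armRes[[a]]
      cand <- sort(unique(c(r$pos, r$de_novo$pos)))
      if (!length(cand)) return(NULL)
      ing <- r$matrix[cand, si$group != "outgroup", drop = FALSE]
      keep <- apply(ing, 1L, function(b) {
        b <- b[b != "N"]
        length(unique(b)) >= 2L
      })
      if (!any(keep)) NULL
      else data.frame(arm = a, pos = cand[keep], stringsAsFactors = FALSE)
    }))
    if (is.null(poly))
      poly <- data.frame(arm = character(), pos = integer())

    selTruth <- config$selected_loci
    if (is.null(selTruth))
      selTruth <- data.frame(arm = character(), pos = integer(),
                             s = numeric())
    deNovo <- do.call(rbind, lapply(config$arm_names, function(a) {
      d <- armRes[[a]]$de_novo
      if (is.null(d) || !nrow(d)) NULL else cbind(arm = a, d)
    }))
    if (is.null(deNovo))
      deNovo <- data.frame(arm = character(), strain = character(),
                           pos = integer(), base = character())
    poolSites <- do.call(rbind, lapply(config$arm_names, function(a)
      if (length(armRes[[a]]$pos))
        data.frame(arm = a, pos = armRes[[a]]$pos, stringsAsFactors = FALSE)))
    if (is.null(poolSites))
      poolSites <- data.frame(arm = character(), pos = integer())

    new("SyntheticDataset",
        sampleMatrix = sm,
        geneModels = gm,
        reference = lapply(armRes, `[[`, "ref"),
        preferredCodons = defaultPreferredCodons(),
        truth = list(selected = selTruth, polymorphic = poly,
                     pool_sites = poolSites, de_novo = deNovo),
        config = unclass(config))
  })
}

#' Generate random gene models on one arm
#'
#' Places non-overlapping genes with 5'UTR / multi-exon CDS / 3'UTR
#' structure and random strand. A \code{neuro_fraction} share of genes is
#' flagged neurogenetic and drawn from a longer coding-length distribution,
#' emulating the disproportionate genomic footprint of neurogenetic genes.
#'
#' @param genome_length arm length in bp.
#' @param n_genes number of genes to place.
#' @param neuro_fraction per-gene probability of the neurogenetic flag.
#' @param seed RNG seed.
#' @param arm arm label used as seqname.
#' @return A [GeneModelSet-class].
#' @export
generateGeneModels <- function(genome_length, n_genes, neuro_fraction,
                               seed = 1L, arm = "2L") {
  stopifnot(genome_length > 0, n_genes >= 0, neuro_fraction >= 0,
            neuro_fraction <= 1)
  withSeed(seed, {
    if (n_genes == 0L)
      return(emptyGeneModelSet(arm, genome_length))
    neuro <- runif(n_genes) < neuro_fraction
    plans <- lapply(seq_len(n_genes), function(i) {
      nCodons <- if (neuro[i]) sample(250:900, 1L) else sample(60:300, 1L)
      cdsBp <- 3L * nCodons
      nEx <- sample.int(4L, 1L)
      ## exons cut at nucleotide granularity so splice sites fall inside
      ## codons and CDS phases are non-trivial
      cuts <- if (nEx > 1L)
        sort(sample(seq_len(cdsBp - 1L), nEx - 1L)) else integer(0)
      exBp <- diff(c(0L, cuts, cdsBp))
      introns <- if (nEx > 1L) sample(60:200, nEx - 1L, replace = TRUE)
                 else integer(0)
      list(u5 = sample(30:150, 1L), u3 = sample(50:250, 1L),
           cds = exBp, introns = introns,
           strand = sample(c("+", "-"), 1L), neuro = neuro[i])
    })
    spans <- vapply(plans, function(p)
      p$u5 + p$u3 + sum(p$cds) + sum(p$introns), numeric(1))
    slack <- genome_length - sum(spans) - (n_genes + 1L)
    if (slack < 0)
      stop("cannot place ", n_genes,
           " non-overlapping genes in ", genome_length, " bp")
    gaps <- 1L + as.vector(stats::rmultinom(1L, slack, rep(1, n_genes + 1L)))
    feat <- list()
    gene <- list()
    cur <- 0L
    for (i in seq_len(n_genes)) {
      cur <- cur + gaps[i]
      p <- plans[[i]]
      gid <- sprintf("%s_g%03d", arm, i)
      start <- cur + 1L
      ## genomic-order segment layout; transcription order depends on strand
      segLens <- if (p$strand == "+") {
        c(p$u5, as.vector(rbind(p$cds, c(p$introns, NA)))[
            seq_len(2L * length(p$cds) - 1L)], p$u3)
      } else {
        c(p$u3, as.vector(rbind(rev(p$cds), c(rev(p$introns), NA)))[
            seq_len(2L * length(p$cds) - 1L)], p$u5)
      }
      segTypes <- if (p$strand == "+") {
        c("five_prime_UTR",
          rep(c("CDS", "intron"), length.out = 2L * length(p$cds) - 1L),
          "three_prime_UTR")
      } else {
        c("three_prime_UTR",
          rep(c("CDS", "intron"), length.out = 2L * length(p$cds) - 1L),
          "five_prime_UTR")
      }
      ends <- cur + cumsum(segLens)
      starts <- c(cur + 1L, head(ends, -1L) + 1L)
      gspan <- c(start, ends[length(ends)])
      keep <- segTypes != "intron"
      df <- data.frame(start = starts[keep], end = ends[keep],
                       type = segTypes[keep], stringsAsFactors = FALSE)
      ## CDS phase in transcription order
      cdsIdx <- which(df$type == "CDS")
      if (p$strand == "-") cdsIdx <- rev(cdsIdx)
      clen <- df$end[cdsIdx] - df$start[cdsIdx] + 1L
      phase <- c(0L, (3L - cumsum(clen)[-length(clen)] %% 3L) %% 3L)
      df$phase <- NA_integer_
      df$phase[cdsIdx] <- phase
      df$gene_id <- gid
      df$strand <- p$strand
      feat[[i]] <- df
      gene[[i]] <- data.frame(gene_id = gid, start = gspan[1L],
                              end = gspan[2L], strand = p$strand,
                              neuro = p$neuro,
                              gene_length = gspan[2L] - gspan[1L] + 1L,
                              stringsAsFactors = FALSE)
      cur <- ends[length(ends)]
    }
    gdf <- do.call(rbind, gene)
    fdf <- do.call(rbind, feat)
    gr <- GenomicRanges::GRanges(
      arm, IRanges::IRanges(gdf$start, gdf$end), strand = gdf$strand,
      gene_id = gdf$gene_id, neuro = gdf$neuro,
      gene_length = gdf$gene_length)
    fr <- GenomicRanges::GRanges(
      arm, IRanges::IRanges(fdf$start, fdf$end), strand = fdf$strand,
      type = fdf$type, gene_id = fdf$gene_id, phase = fdf$phase)
    GenomeInfoDb::seqlengths(gr) <- genome_length
    GenomeInfoDb::seqlengths(fr) <- genome_length
    new("GeneModelSet", genes = gr, features = fr)
  })
}

emptyGeneModelSet <- function(arm, genome_length) {
  gr <- GenomicRanges::GRanges(
    seqnames = factor(character(), levels = arm),
    IRanges::IRanges(), strand = character(),
    gene_id = character(), neuro = logical(), gene_length = integer())
  fr <- GenomicRanges::GRanges(
    seqnames = factor(character(), levels = arm),
    IRanges::IRanges(), strand = character(),
    type = character(), gene_id = character(), phase = integer())
  GenomeInfoDb::seqlengths(gr) <- genome_length
  GenomeInfoDb::seqlengths(fr) <- genome_length
  new("GeneModelSet", genes = gr, features = fr)
}

combineGeneModels <- function(models) {
  suppressWarnings(new("GeneModelSet",
      genes = do.call(c, lapply(models, genes)),
      features = do.call(c, lapply(models, geneFeatures))))
}

#' Default preferred-codon table
#'
#' Loads the packaged synthetic default table: one preferred codon per
#' amino acid with a C/G-ending bias typical of Drosophila codon usage.
#' Replace with a user TSV (columns \code{codon}, \code{preferred}) to use
#' an empirically derived classification.
#'
#' @return data.frame with columns \code{codon}, \code{amino_acid},
#'   \code{preferred}.
#' @export
defaultPreferredCodons <- function() {
  f <- system.file("extdata", "preferred_codons_synthetic_default.tsv",
                   package = "labSweeps", mustWork = TRUE)
  read.delim(f, stringsAsFactors = FALSE)
}

#' Packaged Grantham (1974) amino-acid distance matrix
#'
#' @return 20x20 symmetric numeric matrix indexed by one-letter amino-acid
#'   codes; diagonal zero.
#' @export
granthamMatrix <- function() {
  f <- system.file("extdata", "grantham1974.tsv",
                   package = "labSweeps", mustWork = TRUE)
  d <- read.delim(f, check.names = FALSE)
  m <- as.matrix(d[, -1L])
  storage.mode(m) <- "double"
  rownames(m) <- d$aa
  m
}
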