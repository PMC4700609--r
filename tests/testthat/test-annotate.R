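## gene-model context and codon-level scoring against hand-built fixtures

test_that("region labels follow CDS/UTR/intron/intergenic priority", {
  fx <- toyGeneFixture()
  ann <- annotateRegion(rep("2L", 6), c(50L, 105L, 115L, 125L, 145L, 500L),
                        fx$models)
  expect_identical(ann$region,
                   c("intergenic", "five_prime_utr", "exon_cds", "intron",
                     "three_prime_utr", "intergenic"))
  expect_identical(ann$gene_id[3L], "gP")
  expect_true(is.na(ann$gene_id[1L]))
  expect_error(annotateRegion("9R", 10L, fx$models), "unknown arm")
})

test_that("region labels partition every position of a generated arm", {
  gm <- generateGeneModels(20000L, 6L, 0.2, seed = 5L)
  ann <- annotateRegion(rep("2L", 20000L), 1:20000, gm)
  counts <- table(ann$region)
  expect_identical(sum(counts), 20000L)
  ## every label class observed with this layout
  expect_true(all(c("exon_cds", "intron", "intergenic") %in% names(counts)))
})

test_that("overlapping genes resolve by CDS priority then smaller span", {
  fx <- toyGeneFixture()
  g <- genes(fx$models)
  f <- geneFeatures(fx$models)
  ## add a wide gene overlapping gP whose CDS misses position 115
  g2 <- GenomicRanges::GRanges("2L", IRanges::IRanges(90L, 400L),
                               strand = "+", gene_id = "gWide",
                               neuro = FALSE, gene_length = 311L)
  f2 <- GenomicRanges::GRanges("2L", IRanges::IRanges(200L, 259L),
                               strand = "+", type = "CDS",
                               gene_id = "gWide", phase = 0L)
  models <- new("GeneModelSet", genes = suppressWarnings(c(g, g2)),
                features = suppressWarnings(c(f, f2)))
  ann <- annotateRegion(rep("2L", 3), c(115L, 230L, 160L), models)
  ## 115: CDS of gP beats intron of gWide; 230: CDS of gWide;
  ## 160: intron of gWide only (outside gP)
  expect_identical(ann$gene_id, c("gP", "gWide", "gWide"))
  expect_identical(ann$region, c("exon_cds", "exon_cds", "intron"))
})

test_that("codon context honours frame, splicing and strand", {
  fx <- toyGeneFixture()
  ## plus strand: CDS = ATG GCT TAC CTG AAA TTT over 111..118 + 131..140
  c1 <- codonContext("2L", 111L, fx$models, fx$ref)
  expect_identical(c1$codon_position, "C1")
  expect_identical(c1$ref_codon, "ATG")
  cLast <- codonContext("2L", 140L, fx$models, fx$ref)
  expect_identical(cLast$codon_position, "C3")
  expect_identical(cLast$ref_codon, "TTT")
  ## codon 3 (TAC) spans the splice: bases 117,118 | 131
  cSplice <- codonContext("2L", 131L, fx$models, fx$ref)
  expect_identical(cSplice$ref_codon, "TAC")
  expect_identical(cSplice$codon_position, "C3")
  expect_identical(cSplice$codon_genomic, c(117, 118, 131))

  ## minus strand: CDS = ATG TGT CCC GGG TTT AGC, first base at genomic 340
  m1 <- codonContext("2L", 340L, fx$models, fx$ref)
  expect_identical(m1$codon_position, "C1")
  expect_identical(m1$ref_codon, "ATG")
  mLast <- codonContext("2L", 311L, fx$models, fx$ref)
  expect_identical(mLast$codon_position, "C3")
  expect_identical(mLast$ref_codon, "AGC")
  ## spliced codon GGG sits across 331 | 318,317
  mSplice <- codonContext("2L", 318L, fx$models, fx$ref)
  expect_identical(mSplice$ref_codon, "GGG")

  ## extracted CDS sequences match the designed coding sequences
  cds <- labSweeps:::extractCdsSequences(fx$models, fx$ref)
  expect_identical(unname(cds["gP"]), fx$plus_cds)
  expect_identical(unname(cds["gM"]), fx$minus_cds)
})

test_that("substitution scoring distinguishes silent, replacement and stops", {
  s1 <- scoreSubstitution("CTG", "A", 3)     # Leu -> Leu
  expect_identical(s1$substitution_type, "silent")
  expect_identical(s1$codon_shift, "P2N")    # CTG preferred, CTA not
  expect_true(is.na(s1$grantham))

  s2 <- scoreSubstitution("ATT", "G", 3)     # Ile -> Met
  expect_identical(s2$substitution_type, "replacement")
  expect_identical(unname(s2$grantham), 10)
  expect_true(is.na(s2$codon_shift))

  s3 <- scoreSubstitution("TAC", "A", 3)     # Tyr -> stop
  expect_identical(s3$substitution_type, "replacement")
  expect_true(is.na(s3$grantham))
  expect_true(s3$stop_involved)

  expect_error(scoreSubstitution("GAT", "T", 3), "identical")
  expect_error(scoreSubstitution("ANT", "G", 3), "N")
})

test_that("all 576 single-base codon changes agree with a translation oracle", {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  pref <- defaultPreferredCodons()
  gm <- granthamMatrix()
  nC2rep <- 0L; nC2 <- 0L
  for (cod in codons) {
    for (k in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(cod, k, k))) {
        der <- cod; substr(der, k, k) <- alt
        sc <- scoreSubstitution(cod, alt, k, pref, gm)
        silent <- gc[[cod]] == gc[[der]]
        expect_identical(sc$substitution_type,
                         if (silent) "silent" else "replacement")
        expect_identical(sc$derived_codon, der)
        if (!silent && gc[[cod]] != "*" && gc[[der]] != "*")
          expect_identical(unname(sc$grantham),
                           gm[gc[[cod]], gc[[der]]])
        if (k == 2L) {
          nC2 <- nC2 + 1L
          nC2rep <- nC2rep + !silent
        }
      }
    }
  }
  ## second-position changes are almost always replacements (the serine
  ## family provides the only silent exceptions under the standard code)
  expect_gt(nC2rep / nC2, 0.97)
})

test_that("the Grantham matrix is symmetric with a zero diagonal", {
  gm <- granthamMatrix()
  expect_identical(dim(gm), c(20L, 20L))
  expect_true(isSymmetric(gm))
  expect_true(all(diag(gm) == 0))
})

test_that("annotateSnps scores ancestral-to-derived codon changes", {
  fx <- toyGeneFixture()
  ## SNP at 112 (C2 of ATG): anc T, der C => ACG (Thr): replacement
  ## SNP at 140 (C3 of TTT): anc T, der C => TTC (Phe): silent N2P
  ## SNP at 125: intron; SNP at 50: intergenic
  snps <- data.frame(arm = "2L", pos = c(112L, 140L, 125L, 50L),
                     anc = c("T", "T", "A", "A"),
                     der = c("C", "C", "G", "G"),
                     stringsAsFactors = FALSE)
  ann <- annotateSnps(snps, fx$models, fx$ref)
  expect_identical(ann$region,
                   c("exon_cds", "exon_cds", "intron", "intergenic"))
  expect_identical(ann$substitution_type[1:2], c("replacement", "silent"))
  expect_identical(ann$codon_position[1:2], c("C2", "C3"))
  expect_identical(unname(ann$grantham[1]),
                   granthamMatrix()["M", "T"])
  expect_identical(ann$codon_shift[2], "N2P")
  ## minus-strand SNP: genomic 339 is C2 of ATG (coding T); genomic base
  ## complement: anc A, der G on genomic = C on coding: ATG -> ACG
  snpsM <- data.frame(arm = "2L", pos = 339L, anc = "A", der = "G",
                      stringsAsFactors = FALSE)
  annM <- annotateSnps(snpsM, fx$models, fx$ref)
  expect_identical(annM$ref_codon, "ATG")
  expect_identical(annM$derived_codon, "ACG")
  expect_identical(annM$substitution_type, "replacement")
})
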