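test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulationConfig(genome_length = 4000L, arm_names = c("2L", "X"),
                          n_wild = 10L, pool_size = 40L, seed = 11L)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  for (a in c("2L", "X"))
    expect_identical(armBases(sampleMatrix(d1), a),
                     armBases(sampleMatrix(d2), a))
  expect_identical(simTruth(d1), simTruth(d2))
  expect_identical(refSequences(d1), refSequences(d2))
})

test_that("the no-mutation limit yields identical samples and no polymorphism", {
  cfg <- simulationConfig(genome_length = 2000L, arm_names = "2L",
                          n_wild = 6L, pool_size = 20L,
                          ancestral_theta = 0, outgroup_divergence = 0,
                          missing_rate_lab = 0, missing_rate_wild = 0,
                          seed = 2L)
  ds <- simulateDataset(cfg)
  m <- armBases(sampleMatrix(ds), "2L")
  expect_true(all(m == m[, 1L]))
  expect_identical(nrow(simTruth(ds)$polymorphic), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(missing_rate_lab = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(genome_length = 0), "positive")
  expect_error(simulationConfig(n_wild = 50, pool_size = 40),
               "pool_size")
  expect_error(
    simulationConfig(selected_loci = data.frame(arm = "4", pos = 10,
                                                s = 0.5)),
    "undeclared arms")
  expect_error(
    simulationConfig(genome_length = 1000L, arm_names = "2L",
                     selected_loci = data.frame(arm = "2L", pos = 2000L,
                                                s = 0.5)),
    "outside declared arm lengths")
})

test_that("wild pairwise diversity matches the configured theta", {
  ## replicate-simulation oracle: mean pairwise diversity across seeds
  ## should recover ancestral_theta within 3 Monte-Carlo SE
  theta <- 0.005
  pis <- vapply(1:10, function(s) {
    cfg <- simulationConfig(genome_length = 30000L, arm_names = "2L",
                            n_wild = 20L, pool_size = 60L,
                            ancestral_theta = theta,
                            missing_rate_wild = 0, seed = 100L + s)
    ds <- simulateDataset(cfg)
    m <- armBases(sampleMatrix(ds), "2L")
    w <- m[, groupSamples(sampleMatrix(ds), "wild")]
    pairs <- combn(ncol(w), 2L)
    mean(vapply(seq_len(ncol(pairs)), function(i)
      mean(w[, pairs[1L, i]] != w[, pairs[2L, i]]), numeric(1)))
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 3 * se + 1e-12)
})

test_that("truth positions are polymorphic and the dataset validates", {
  cfg <- simulationConfig(genome_length = 6000L, arm_names = "2L",
                          n_wild = 12L, pool_size = 40L, seed = 7L)
  ds <- simulateDataset(cfg)
  expect_true(validObject(ds))
  tp <- simTruth(ds)$polymorphic
  expect_gt(nrow(tp), 0L)
  m <- armBases(sampleMatrix(ds), "2L")
  ing <- m[, sampleInfo(sampleMatrix(ds))$group != "outgroup"]
  poly <- vapply(tp$pos, function(p) {
    b <- ing[p, ]; b <- b[b != "N"]; length(unique(b)) >= 2L
  }, logical(1))
  expect_true(all(poly))
})

test_that("lab theta drops below wild theta under drift-dominated founding", {
  cfg <- simulationConfig(genome_length = 50000L, arm_names = "2L",
                          n_wild = 25L, pool_size = 80L,
                          lab_stock_size = 8L, founder_count_per_strain = 4L,
                          domestication_generations = 30L, seed = 5L)
  ds <- simulateDataset(cfg)
  thL <- wattersonWindows(sampleMatrix(ds), "lab", 50000L)
  thW <- wattersonWindows(sampleMatrix(ds), "wild", 50000L)
  expect_lt(mean(thL$theta_per_bp, na.rm = TRUE),
            mean(thW$theta_per_bp, na.rm = TRUE))
})

test_that("gene model generation honours counts, flags and structure", {
  expect_identical(length(genes(generateGeneModels(5000L, 0L, 0.5))), 0L)
  gmAll <- generateGeneModels(100000L, 20L, 1.0, seed = 2L)
  expect_true(all(genes(gmAll)$neuro))

  gm <- generateGeneModels(300000L, 100L, 0.1, seed = 7L)
  nNeuro <- sum(genes(gm)$neuro)
  expect_gte(nNeuro, qbinom(0.005, 100L, 0.1))
  expect_lte(nNeuro, qbinom(0.995, 100L, 0.1))
  expect_true(validObject(gm))

  ## genes must not overlap, CDS lengths divisible by 3, phases consistent
  g <- genes(gm)
  o <- order(BiocGenerics::start(g))
  expect_true(all(BiocGenerics::start(g)[o][-1L] >
                    BiocGenerics::end(g)[o][-length(g)]))
  f <- geneFeatures(gm)
  cds <- f[f$type == "CDS"]
  for (gid in unique(cds$gene_id)) {
    ci <- cds[cds$gene_id == gid]
    strand <- as.character(BiocGenerics::strand(ci))[1L]
    oo <- order(BiocGenerics::start(ci), decreasing = strand == "-")
    w <- BiocGenerics::width(ci)[oo]
    expect_identical(sum(w) %% 3L, 0L)
    expect_identical(ci$phase[oo],
                     c(0L, (3L - cumsum(w)[-length(w)] %% 3L) %% 3L))
  }

  ## neurogenetic genes come from a longer length distribution
  gmBig <- generateGeneModels(500000L, 120L, 0.3, seed = 9L)
  gb <- genes(gmBig)
  expect_gt(mean(gb$gene_length[gb$neuro]),
            mean(gb$gene_length[!gb$neuro]))
})

test_that("gene placement fails cleanly when the genome is too small", {
  expect_error(generateGeneModels(2000L, 50L, 0, seed = 1L),
               "cannot place")
})

test_that("fixtures round-trip through the readers", {
  cfg <- simulationConfig(genome_length = 4000L, arm_names = c("2L", "X"),
                          n_wild = 6L, pool_size = 24L, seed = 9L)
  ds <- simulateDataset(cfg)
  dir <- withr::local_tempdir()
  man <- writeFixture(ds, dir)
  expect_identical(sum(man$role == "sample_fasta"),
                   nrow(sampleInfo(sampleMatrix(ds))))
  back <- readSampleMatrix(dir)
  for (a in c("2L", "X"))
    expect_identical(armBases(back, a), armBases(sampleMatrix(ds), a))
  ## per-sample FASTAs carry one record per arm
  one <- Biostrings::readDNAStringSet(file.path(dir, "lab_1.fasta"))
  expect_identical(sort(names(one)), sort(c("2L", "X")))
})

test_that("an empty dataset writes a valid empty fixture", {
  sm <- SampleMatrix(list(), data.frame(sample_id = character(),
                                        group = character()))
  ds <- new("SyntheticDataset", sampleMatrix = sm,
            geneModels = generateGeneModels(1000L, 0L, 0),
            reference = list(), preferredCodons = defaultPreferredCodons(),
            truth = list(selected = data.frame(),
                         polymorphic = data.frame(arm = character(),
                                                  pos = integer())),
            config = list())
  dir <- withr::local_tempdir()
  man <- writeFixture(ds, dir)
  expect_identical(sum(man$role == "sample_fasta"), 0L)
  expect_identical(length(genes(importGeneModels(
    file.path(dir, "genes.gff3")))), 0L)
})
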