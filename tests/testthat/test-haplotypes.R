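## extended haplotype blocks, Z-hap outliers and the random-site baseline

## lab matrix with a planted shared haplotype: 5 strains, identical inside
## [focal - span, focal + span], discordant at the first site beyond each
## edge, random-ish agreement elsewhere
plantedLab <- function(L = 5000L, focal = 2500L, span = 1000L) {
  m <- matrix("A", L, 5L, dimnames = list(NULL, paste0("lab_", 1:5)))
  m[focal - span - 1L, 1L] <- "T"   # discordance just left of the span
  m[focal + span + 1L, 2L] <- "G"   # and just right
  m[focal, ] <- "C"                 # the shared derived allele
  m
}

test_that("blocks stop at the first discordant site on each side", {
  m <- plantedLab()
  blk <- extendHaplotype(m, 2500L, paste0("lab_", 1:5))
  expect_identical(blk$start, 1500L)
  expect_identical(blk$end, 3500L)
  expect_identical(blk$length, 2001L)

  ## immediate discordance on both sides -> minimal block of length 1
  m2 <- matrix("A", 11, 3, dimnames = list(NULL, paste0("lab_", 1:3)))
  m2[5, 1] <- "T"; m2[7, 2] <- "G"; m2[6, ] <- "C"
  blk2 <- extendHaplotype(m2, 6L, paste0("lab_", 1:3))
  expect_identical(blk2$length, 1L)
})

test_that("one missing strain per site is tolerated, two are not", {
  m <- plantedLab()
  m[2000:3000, 3L] <- "N"             # one strain uncalled across the span
  blk <- extendHaplotype(m, 2500L, paste0("lab_", 1:5))
  expect_identical(blk$length, 2001L)
  m[2600, 4L] <- "N"                  # a second missing strain at one site
  blk2 <- extendHaplotype(m, 2500L, paste0("lab_", 1:5))
  expect_identical(blk2$end, 2599L)
})

test_that("raising the missing allowance never shortens a block", {
  cfg <- simulationConfig(genome_length = 5000L, arm_names = "2L",
                          n_wild = 10L, pool_size = 40L,
                          missing_rate_lab = 0.05, seed = 17L)
  sm <- sampleMatrix(simulateDataset(cfg))
  snps <- classifyLabSpecific(filterSites(sm)$sites)
  snps <- snps[snps$lab_der >= 2L, ]
  for (mm in 0:1) {
    b0 <- extendHaplotypes(sm, snps, max_missing_per_site = mm)
    b1 <- extendHaplotypes(sm, snps, max_missing_per_site = mm + 1L)
    shared <- intersect(paste(b0$arm, b0$focal_pos),
                        paste(b1$arm, b1$focal_pos))
    k0 <- match(shared, paste(b0$arm, b0$focal_pos))
    k1 <- match(shared, paste(b1$arm, b1$focal_pos))
    expect_true(all(b1$length[k1] >= b0$length[k0]))
  }
})

test_that("extendHaplotypes matches a brute-force scan and contains the focal", {
  cfg <- simulationConfig(genome_length = 4000L, arm_names = "2L",
                          n_wild = 10L, pool_size = 40L,
                          missing_rate_lab = 0.02, seed = 19L)
  sm <- sampleMatrix(simulateDataset(cfg))
  snps <- classifyLabSpecific(filterSites(sm)$sites)
  snps$snp_class <- "x"
  snps <- snps[snps$lab_der >= 2L & snps$lab_der < snps$lab_called, ]
  blocks <- extendHaplotypes(sm, snps)
  m <- armBases(sm, "2L")[, paste0("lab_", 1:5)]
  for (i in seq_len(nrow(blocks))) {
    carriers <- strsplit(snps$lab_carriers[i], ",")[[1L]]
    p <- blocks$focal_pos[i]
    ## naive outward walk
    okAt <- function(q) {
      b <- m[q, carriers]
      called <- b[b != "N"]
      length(unique(called)) <= 1L && sum(b == "N") <= 1L
    }
    lo <- p; while (lo > 1L && okAt(lo - 1L)) lo <- lo - 1L
    hi <- p; while (hi < nrow(m) && okAt(hi + 1L)) hi <- hi + 1L
    expect_identical(blocks$start[i], lo)
    expect_identical(blocks$end[i], hi)
    expect_true(blocks$start[i] <= p && p <= blocks$end[i])
  }
})

test_that("all-strain congruence is at least as strict as carriers-only", {
  cfg <- simulationConfig(genome_length = 4000L, arm_names = "2L",
                          n_wild = 10L, pool_size = 40L, seed = 23L)
  sm <- sampleMatrix(simulateDataset(cfg))
  snps <- classifyLabSpecific(filterSites(sm)$sites)
  snps <- snps[snps$lab_der >= 2L, ]
  bc <- extendHaplotypes(sm, snps, congruence = "carriers")
  ba <- extendHaplotypes(sm, snps, congruence = "all")
  shared <- intersect(paste(bc$focal_pos), paste(ba$focal_pos))
  expect_true(all(ba$length[match(shared, paste(ba$focal_pos))] <=
                    bc$length[match(shared, paste(bc$focal_pos))]))
})

test_that("Z-hap outliers follow the hand computation", {
  blocks <- data.frame(arm = "2L", focal_pos = 1:10, start = 1L, end = 1L,
                       length = c(rep(100L, 9), 1100L),
                       n_carriers = 5L, single_carrier = FALSE,
                       freq_class = c(rep(0.4, 5), rep(1, 5)),
                       snp_class = "lab_specific")
  ho <- haplotypeOutliers(blocks)
  ## mu = 200, population sd = 300, z(1100) = 3
  expect_equal(ho$blocks$z_hap[10L], 3)
  expect_identical(nrow(ho$outliers), 1L)
  expect_identical(ho$outliers$focal_pos, 10L)
  expect_true(all(c("freq_class", "mean_length") %in%
                    names(ho$class_summary)))
  expect_true(is.finite(ho$p_high_vs_rest))
  expect_error(haplotypeOutliers(blocks[blocks$length == 100L, ]),
               "degenerate")
  expect_error(haplotypeOutliers(blocks[1L, , drop = FALSE]), "at least 2")
})

test_that("neutral data show no haplotype-length trend across frequency classes", {
  ## multi-carrier classes only: the single-carrier measure is a
  ## different (consensus-run) statistic and is flagged experimental
  quiet <- 0L
  nSeeds <- 8L
  for (s in seq_len(nSeeds)) {
    cfg <- simulationConfig(genome_length = 60000L, arm_names = "2L",
                            n_wild = 30L, pool_size = 100L,
                            seed = 1500L + s)
    sm <- sampleMatrix(simulateDataset(cfg))
    snps <- zClassifyFst(classifyLabSpecific(filterSites(sm)$sites))
    focal <- snps[snps$snp_class != "none", ]
    blocks <- extendHaplotypes(sm, focal)
    mb <- blocks[blocks$n_carriers >= 2L, ]
    if (length(unique(mb$freq_class)) < 2L) next
    p <- kruskal.test(mb$length, factor(mb$freq_class))$p.value
    quiet <- quiet + (p > 0.01)
  }
  expect_gte(quiet, nSeeds - 1L)
})

test_that("the random-site baseline is deterministic and handles degeneracy", {
  ## degenerate matrix: every candidate block has length 1
  pat <- c("A", "C", "G", "T")
  m <- matrix("A", 200, 5, dimnames = list(NULL, paste0("lab_", 1:5)))
  m[, 1] <- pat[(seq_len(200) - 1L) %% 4L + 1L]
  m[, 2] <- pat[seq_len(200) %% 4L + 1L]   # disagrees with lab_1 everywhere
  sm <- SampleMatrix(
    list(`2L` = cbind(m, out = rep("A", 200))),
    data.frame(sample_id = c(paste0("lab_", 1:5), "out"),
               group = c(rep("lab", 5), "outgroup")))
  snps <- data.frame(arm = "2L", pos = seq(10L, 150L, by = 10L),
                     lab_carriers = "lab_1,lab_2", freq_class = 0.4)
  base <- randomSiteBaseline(sm, snps, n_sites = 5L, reps = 30L, seed = 4L)
  expect_equal(base$baseline_mean, 1)
  expect_equal(base$baseline_se, 0)
  base2 <- randomSiteBaseline(sm, snps, n_sites = 5L, reps = 30L,
                              seed = 4L)
  expect_identical(base$replicate_means, base2$replicate_means)
  expect_error(randomSiteBaseline(sm, snps, n_sites = 100L, reps = 5L),
               "exceeds")
})
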