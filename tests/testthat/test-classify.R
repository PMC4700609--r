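## lab-specific calls, frequency fifths, Hudson FST and its Z-transform

test_that("lab-specific classification and frequency fifths follow the rules", {
  sites <- data.frame(
    lab_der = c(3L, 4L, 2L, 0L, 1L),
    lab_called = c(5L, 4L, 5L, 5L, 5L),
    wild_der = c(0L, 0L, 1L, 3L, 0L),
    wild_called = c(200L, 388L, 200L, 200L, 200L))
  out <- classifyLabSpecific(sites)
  expect_identical(out$lab_specific, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  ## 3/5 -> 0.6; 4/4 (one strain missing) -> fixed class 1.0; 1/5 -> 0.2
  expect_identical(out$freq_class, c(0.6, 1.0, 0.4, NA, 0.2))
})

test_that("every lab-polymorphic record falls in exactly one fifth", {
  grid <- expand.grid(der = 0:5, called = 3:5)
  grid <- grid[grid$der <= grid$called, ]
  cls <- labFreqClass(grid$der, grid$called)
  ok <- grid$der == 0L
  expect_true(all(is.na(cls[ok])))
  expect_true(all(cls[!ok] %in% c(0.2, 0.4, 0.6, 0.8, 1.0)))
})

test_that("hudsonFst reproduces hand computations", {
  expect_equal(hudsonFst(1, 5, 0, 205), 1)
  expect_equal(hudsonFst(0.5, 10, 0.5, 10),
               (0 - 0.25 / 9 - 0.25 / 9) / 0.5)
  expect_equal(hudsonFst(0.8, 5, 0.2, 205),
               (0.36 - 0.16 / 4 - 0.16 / 204) / 0.68,
               tolerance = 1e-12)
  expect_equal(round(hudsonFst(0.8, 5, 0.2, 205), 5), 0.46943)
})

test_that("hudsonFst is symmetric, bounded by 1 and flags degeneracy", {
  withr::with_seed(42, {
    p1 <- runif(500); p2 <- runif(500)
    n1 <- sample(2:300, 500, TRUE); n2 <- sample(2:300, 500, TRUE)
  })
  a <- hudsonFst(p1, n1, p2, n2)
  b <- hudsonFst(p2, n2, p1, n1)
  expect_equal(a, b, tolerance = 1e-12)
  expect_true(all(a <= 1 + 1e-12, na.rm = TRUE))
  expect_identical(hudsonFst(0, 5, 0, 10), NA_real_)
  expect_identical(hudsonFst(1, 5, 1, 10), NA_real_)
  expect_equal(hudsonFst(c(1, 0), c(5, 5), c(0, 1), c(10, 10)), c(1, 1))
  expect_error(hudsonFst(0.5, 1, 0.5, 10), "sample sizes")
})

test_that("the FST Z-transform matches the population-form hand computation", {
  ## nine records with identical moderate FST plus one fixed difference:
  ## fst = {0.4444... x9, 1}, mu = 0.5, population sd = 1/6, z = 3 for
  ## the fixed difference (hand computation)
  recs <- data.frame(
    lab_der = c(rep(0L, 9), 5L), lab_called = 5L,
    wild_der = c(rep(5L, 9), 0L), wild_called = 10L,
    lab_specific = FALSE, freq_class = NA_real_)
  out <- zClassifyFst(recs, z_threshold = 2.5)
  fst9 <- (0.25 - 0.25 / 9) / 0.5
  expect_equal(out$fst, c(rep(fst9, 9), 1), tolerance = 1e-12)
  mu <- (9 * fst9 + 1) / 10
  sig <- sqrt((9 * (fst9 - mu)^2 + (1 - mu)^2) / 10)
  expect_equal(out$z_fst[10], (1 - mu) / sig)
  expect_gt(out$z_fst[10], 2.5)
  expect_equal(mean(out$z_fst), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(out$z_fst^2)), 1, tolerance = 1e-9)
  expect_identical(out$fst_class, c(rep("none", 9), "fst_lab_gt_wild"))
})

test_that("Fst* direction follows the higher derived frequency", {
  recs <- data.frame(
    lab_der = c(rep(2L, 20), 0L), lab_called = 5L,
    wild_der = c(rep(4L, 20), 19L), wild_called = 20L,
    lab_specific = FALSE, freq_class = NA_real_)
  out <- zClassifyFst(recs)
  last <- nrow(recs)
  expect_gt(out$z_fst[last], 2.5)
  expect_identical(out$fst_class[last], "fst_wild_gt_lab")
})

test_that("degenerate FST distributions are rejected", {
  recs <- data.frame(lab_der = rep(5L, 4), lab_called = 5L,
                     wild_der = 0L, wild_called = 10L,
                     lab_specific = TRUE, freq_class = 1)
  expect_error(zClassifyFst(recs), "degenerate")
})

test_that("z-classification is invariant to record order", {
  cfg <- simulationConfig(genome_length = 5000L, arm_names = "2L",
                          n_wild = 10L, pool_size = 40L, seed = 8L)
  sm <- sampleMatrix(simulateDataset(cfg))
  recs <- classifyLabSpecific(filterSites(sm)$sites)
  o1 <- zClassifyFst(recs)
  perm <- withr::with_seed(2, sample(nrow(recs)))
  o2 <- zClassifyFst(recs[perm, ])
  o2 <- o2[order(o2$pos), ]
  o1 <- o1[order(o1$pos), ]
  expect_equal(o1$z_fst, o2$z_fst)
  expect_identical(o1$snp_class, o2$snp_class)
})

test_that("subsampling Sign test behaves at its extremes and under the null", {
  cfg <- simulationConfig(genome_length = 10000L, arm_names = "2L",
                          n_wild = 24L, pool_size = 60L, seed = 12L)
  sm <- sampleMatrix(simulateDataset(cfg))
  res <- subsampleSpecificityTest(sm, observed_specific = 10000L,
                                  k = 5L, reps = 40L, seed = 1L)
  expect_identical(length(res$replicate_counts), 40L)
  expect_true(all(res$replicate_counts < 10000L))
  expect_equal(res$p_value, binom.test(40, 40, 0.5)$p.value)

  med <- median(res$replicate_counts)
  resMed <- subsampleSpecificityTest(sm, observed_specific = med,
                                     k = 5L, reps = 40L, seed = 1L)
  expect_gt(resMed$p_value, 0.05)
  expect_error(subsampleSpecificityTest(sm, 1L, k = 24L, reps = 5L),
               "smaller")
})

test_that("a lab that is just a random wild subset is not called enriched", {
  hits <- 0L
  nSeeds <- 6L
  for (s in seq_len(nSeeds)) {
    ## simulate a pure wild panel and relabel five random genomes as
    ## "lab": the lab private-SNP count is then exactly a subset-private
    ## count and the Sign test should stay quiet
    cfg <- simulationConfig(genome_length = 12000L, arm_names = "2L",
                            n_wild = 65L, n_lab = 5L, pool_size = 150L,
                            missing_rate_lab = 0.02, seed = 300L + s)
    sm <- sampleMatrix(simulateDataset(cfg))
    si <- sampleInfo(sm)
    wildIds <- si$sample_id[si$group == "wild"]
    relabel <- withr::with_seed(s, sample(wildIds, 5L))
    keep <- c(wildIds, "outgroup")        # drop the simulated lab strains
    groups <- ifelse(keep %in% relabel, "lab",
                     ifelse(keep == "outgroup", "outgroup", "wild"))
    sm2 <- SampleMatrix(list(`2L` = armBases(sm, "2L")[, keep]),
                        data.frame(sample_id = keep, group = groups))
    obs <- sum(classifyLabSpecific(filterSites(
      sm2, filterConfig(exclude_wild_singletons = FALSE))$sites)$lab_specific)
    res <- subsampleSpecificityTest(sm2, observed_specific = obs,
                                    k = 5L, reps = 60L, seed = s)
    ## under the null the relabeled "lab" count is exchangeable with the
    ## replicate counts, so it must not sit in the upper tail
    hits <- hits + (obs <= quantile(res$replicate_counts, 0.95))
  }
  expect_gte(hits, nSeeds - 1L)
})
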