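test_that("truth generation is seeded, labeled, and gap-respecting", {
  cfg <- simulation_config(seed = 11, chrom_lengths = c(chr1 = 1e7),
                           n_shared = 600, n_specific_a = 250,
                           n_specific_b = 150, min_gap = 500)
  t1 <- simulate_region_truth(cfg)
  t2 <- simulate_region_truth(cfg)
  expect_identical(t1$regions, t2$regions)
  expect_equal(as.integer(table(t1$regions$label)[c("shared", "specific_a", "specific_b")]),
               c(600L, 250L, 150L))
  # exhaustive pairwise gap scan (regions are sorted per chromosome)
  r <- t1$regions[order(t1$regions$chrom, t1$regions$start), ]
  for (ch in unique(r$chrom)) {
    b <- r[r$chrom == ch, ]
    if (nrow(b) > 1) {
      expect_true(all(b$start[-1] - b$end[-nrow(b)] >= 500))
    }
  }
  expect_true(all(r$start >= 0 & r$end <= 1e7))

  empty <- simulate_region_truth(simulation_config(
    seed = 1, n_shared = 0, n_specific_a = 0, n_specific_b = 0))
  expect_equal(nrow(empty$regions), 0L)
})

test_that("an overfull genome raises a capacity error", {
  cfg <- simulation_config(seed = 1, chrom_lengths = c(chr1 = 20000L),
                           n_shared = 50, n_specific_a = 0, n_specific_b = 0,
                           region_length_range = c(500L, 2000L),
                           min_gap = 1000L)
  expect_error(simulate_region_truth(cfg), "genome too small")
})

test_that("noiseless replicates reproduce the truth; p_detect 0 empties them", {
  cfg <- simulation_config(seed = 19, p_detect = 1, boundary_jitter_sd = 0,
                           fp_rate = 0)
  truth <- simulate_region_truth(cfg)
  reps <- simulate_replicates(truth)
  a_truth <- truth$regions[truth$regions$label %in% c("shared", "specific_a"),
                           c("chrom", "start", "end")]
  for (s in reps$samples_a) expect_same_intervals(s$intervals, a_truth)
  b_truth <- truth$regions[truth$regions$label %in% c("shared", "specific_b"),
                           c("chrom", "start", "end")]
  for (s in reps$samples_b) expect_same_intervals(s$intervals, b_truth)

  cfg0 <- simulation_config(seed = 19, p_detect = 0, fp_rate = 0)
  reps0 <- simulate_replicates(simulate_region_truth(cfg0))
  expect_true(all(vapply(reps0$samples_a, n_regions, integer(1)) == 0L))
})

test_that("replicate generation is a pure function of the config", {
  cfg <- simulation_config(seed = 23)
  truth <- simulate_region_truth(cfg)
  r1 <- simulate_replicates(truth)
  r2 <- simulate_replicates(truth)
  expect_identical(lapply(r1$samples_a, `[[`, "intervals"),
                   lapply(r2$samples_a, `[[`, "intervals"))
})

test_that("detection counts follow the binomial expectation", {
  # 1000 eligible regions at p = 0.8 across 20 replicate draws
  cfg <- simulation_config(seed = 29, chrom_lengths = c(chr1 = 2e7),
                           n_shared = 1000, n_specific_a = 0,
                           n_specific_b = 0, n_replicates_a = 20,
                           p_detect = 0.8, boundary_jitter_sd = 0,
                           fp_rate = 0, min_gap = 500)
  reps <- simulate_replicates(simulate_region_truth(cfg))
  counts <- vapply(reps$samples_a, n_regions, integer(1))
  se <- sqrt(1000 * 0.8 * 0.2)
  expect_lt(abs(mean(counts) - 800), 3 * se / sqrt(length(counts)))
  expect_true(all(abs(counts - 800) < 5 * se))
})

test_that("false positives land off-truth and jitter keeps intervals valid", {
  cfg <- simulation_config(seed = 31, p_detect = 0.5, boundary_jitter_sd = 150,
                           fp_rate = 40)
  truth <- simulate_region_truth(cfg)
  reps <- simulate_replicates(truth)
  for (s in c(reps$samples_a, reps$samples_b)) {
    expect_true(all(s$intervals$start < s$intervals$end))
    expect_true(all(s$intervals$start >= 0))
  }
  # with jitter off, any replicate region not matching truth is a false
  # positive and must not touch a truth region
  cfg2 <- simulation_config(seed = 37, p_detect = 0.5, boundary_jitter_sd = 0,
                            fp_rate = 40)
  truth2 <- simulate_region_truth(cfg2)
  reps2 <- simulate_replicates(truth2)
  for (s in reps2$samples_a) {
    key <- paste(truth2$regions$chrom, truth2$regions$start)
    fps <- s$intervals[!paste(s$intervals$chrom, s$intervals$start) %in% key, ]
    if (nrow(fps) > 0) {
      expect_equal(nrow(intersect_bases(fps, truth2$regions)), 0L)
    }
  }
})

test_that("emitted BED files round-trip through read_bed", {
  cfg <- simulation_config(seed = 41)
  reps <- simulate_replicates(simulate_region_truth(cfg))
  s <- reps$samples_b[[1]]
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(s, p)
  expect_equal(read_bed(p)$intervals, s$intervals)
})

test_that("expression simulation plants what it reports", {
  s0 <- simulate_expression(n_probes = 100, n_up = 0, n_down = 0, seed = 1)
  expect_equal(nrow(s0$truth), 0L)
  expect_identical(simulate_expression(n_probes = 500, seed = 2, n_up = 26,
                                       n_down = 12)$matrix,
                   simulate_expression(n_probes = 500, seed = 2, n_up = 26,
                                       n_down = 12)$matrix)
  expect_error(simulate_expression(n_probes = 10, n_up = 8, n_down = 8),
               "exceeds")

  # planted probes carry the configured offset within noise propagation
  sim <- simulate_expression(n_probes = 3000, n_up = 100, n_down = 100,
                             log2fc = 3, noise_sd = 0.25, n_per_group = 6,
                             seed = 43)
  lg <- log2(sim$matrix)
  a <- sim$groups == "A"
  diff <- rowMeans(lg[sim$truth$probe[sim$truth$direction == "up"], a]) -
    rowMeans(lg[sim$truth$probe[sim$truth$direction == "up"], !a])
  se_probe <- 0.25 * sqrt(2 / 6)
  expect_lt(abs(mean(diff) - 3), 4 * se_probe / sqrt(100))
  expect_true(all(sim$matrix > 0))
})

test_that("methylation simulation respects means, sd 0, and the seed", {
  exact <- simulate_methylation(c(A = 35, B = 70), n_clones = 2, n_cpgs = 3,
                                sd = 0, seed = 47)
  expect_true(all(exact$methylation_pct[exact$group == "A"] == 35))
  expect_true(all(exact$methylation_pct[exact$group == "B"] == 70))
  expect_identical(simulate_methylation(c(A = 35, B = 70), seed = 5),
                   simulate_methylation(c(A = 35, B = 70), seed = 5))
  expect_error(simulate_methylation(c(A = 120)), "\\[0, 100\\]")
  clipped <- simulate_methylation(c(A = 1), n_clones = 5, n_cpgs = 10,
                                  sd = 30, seed = 53)
  expect_true(all(clipped$methylation_pct >= 0 &
                    clipped$methylation_pct <= 100))
})
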