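test_that("percentile-shift normalization aligns the chosen percentile", {
  set.seed(51)
  mat <- matrix(2^rnorm(500, 8, 2), 100, 5,
                dimnames = list(NULL, paste0("s", 1:5)))
  norm <- percentile_shift_normalize(mat)
  q75 <- apply(norm, 2, quantile, probs = 0.75, names = FALSE)
  expect_lt(max(q75) - min(q75), 1e-9)

  # rescaling a sample by x8 is removed entirely: the duplicate equals the
  # original after normalization
  mat2 <- cbind(mat, s6 = mat[, 1] * 8)
  norm2 <- percentile_shift_normalize(mat2)
  expect_equal(unname(norm2[, "s6"]), unname(norm2[, "s1"]))

  # already-aligned samples are shifted by a common constant only
  same <- cbind(a = mat[, 1], b = mat[, 1] * 2)
  ns <- percentile_shift_normalize(same)
  expect_equal(diff(range((ns[, "a"] - log2(same[, "a"])))), 0)

  expect_error(percentile_shift_normalize(mat - 10), "positive")
})

test_that("normalization matches hand arithmetic on a tiny matrix", {
  mat <- matrix(c(1, 2, 4, 8, 16,
                  2, 4, 8, 16, 32), 5, 2,
                dimnames = list(NULL, c("a", "b")))
  norm <- percentile_shift_normalize(mat, percentile = 75)
  # log2 75th percentiles are 3 and 4; median target 3.5; shifts +0.5 / -0.5
  expect_equal(unname(norm[, "a"]), log2(mat[, "a"]) + 0.5)
  expect_equal(unname(norm[, "b"]), log2(mat[, "b"]) - 0.5)
  # idempotent: a second application changes nothing
  expect_equal(percentile_shift_normalize(norm), norm)
})

test_that("bh_adjust implements the step-up exactly", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_equal(q, p.adjust(p, method = "BH")) # independent reference
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12)) # monotone along sorted p
  }
})

test_that("two_group_screen applies the joint fold-change + q filter", {
  set.seed(57)
  mat <- matrix(rnorm(200 * 8, 8, 1), 200, 8,
                dimnames = list(NULL, c(paste0("a", 1:4), paste0("b", 1:4))))
  mat <- cbind(mat[, 1:4], mat[, 1:4]) # group B identical to group A
  colnames(mat) <- c(paste0("a", 1:4), paste0("b", 1:4))
  res <- two_group_screen(mat, paste0("a", 1:4), paste0("b", 1:4))
  expect_equal(sum(res$status != "not_significant"), 0L)

  # fold-change gate: huge significance but |log2FC| = 1 stays out at FC > 2
  m2 <- rbind(gated = c(rep(1, 3) + c(0, 1e-3, -1e-3),
                        rep(0, 3) + c(0, 1e-3, -1e-3)))
  m2 <- m2[rep(1, 50), ]
  colnames(m2) <- c(paste0("a", 1:3), paste0("b", 1:3))
  res2 <- two_group_screen(m2, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(res2$log2_fold_change, rep(1, 50))
  expect_equal(res2$status, rep("not_significant", 50))

  expect_error(two_group_screen(mat, "a1", paste0("b", 1:4)), "2 samples")
})

test_that("the vectorised t-test matches stats::t.test per probe", {
  set.seed(59)
  mat <- matrix(rnorm(20 * 10), 20, 10)
  colnames(mat) <- c(paste0("a", 1:5), paste0("b", 1:5))
  res <- two_group_screen(mat, paste0("a", 1:5), paste0("b", 1:5))
  for (i in c(1, 7, 20)) {
    tt <- t.test(mat[i, 1:5], mat[i, 6:10], var.equal = TRUE)
    expect_equal(res$p_value[i], tt$p.value)
    expect_equal(res$t[i], unname(tt$statistic))
  }
  resw <- two_group_screen(mat, paste0("a", 1:5), paste0("b", 1:5),
                           var_equal = FALSE)
  tw <- t.test(mat[3, 1:5], mat[3, 6:10])
  expect_equal(resw$p_value[3], tw$p.value)
})

test_that("zero-variance probes follow the documented edge rule", {
  m <- rbind(equal = rep(5, 6), differ = rep(c(5, 7), each = 3))
  colnames(m) <- c(paste0("a", 1:3), paste0("b", 1:3))
  res <- two_group_screen(m, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(res$p_value[res$probe == "equal"], 1)
  expect_equal(res$p_value[res$probe == "differ"], 0)
})

test_that("screen status is invariant under probe reordering", {
  set.seed(61)
  sim <- simulate_expression(n_probes = 300, n_up = 5, n_down = 3,
                             n_per_group = 3, seed = 61)
  mat <- percentile_shift_normalize(sim$matrix)
  a <- names(sim$groups)[sim$groups == "A"]
  b <- names(sim$groups)[sim$groups == "B"]
  res <- two_group_screen(mat, a, b)
  perm <- sample(nrow(mat))
  res_p <- two_group_screen(mat[perm, ], a, b)
  expect_equal(res_p$status[match(res$probe, res_p$probe)], res$status)
})

test_that("planted differential probes are recovered", {
  sim <- simulate_expression(n_probes = 2000, n_up = 26, n_down = 12,
                             log2fc = 3, noise_sd = 0.25, n_per_group = 6,
                             seed = 63)
  mat <- percentile_shift_normalize(sim$matrix)
  a <- names(sim$groups)[sim$groups == "A"]
  b <- names(sim$groups)[sim$groups == "B"]
  res <- two_group_screen(mat, a, b)
  expect_setequal(res$probe[res$status == "up"],
                  sim$truth$probe[sim$truth$direction == "up"])
  expect_setequal(res$probe[res$status == "down"],
                  sim$truth$probe[sim$truth$direction == "down"])
})

test_that("hierarchical clustering uses 1 - correlation with average linkage", {
  set.seed(67)
  x <- rnorm(50)
  mat <- cbind(s1 = x, s2 = x + 5, s3 = -x, s4 = rnorm(50))
  hc <- hierarchical_cluster(mat)
  # identical-up-to-shift profiles merge first at height ~0
  first <- sort(abs(hc$merge[1, ]))
  expect_equal(first, c(1, 2))
  expect_lt(hc$height[1], 1e-12)
  # exhaustive check against stats::hclust on the same distance
  ref <- hclust(as.dist(1 - cor(mat)), method = "average")
  expect_equal(hc$merge, ref$merge)
  expect_equal(hc$height, ref$height)

  bad <- cbind(s1 = rep(1, 10), s2 = rnorm(10))
  expect_error(hierarchical_cluster(bad), "s1")
})

test_that("delta-delta-Ct relative expression anchors the calibrator at 1", {
  ct_t <- c(es1 = 20, es2 = 21, ips = 22)
  ct_r <- c(es1 = 20, es2 = 21, ips = 21)
  lev <- qpcr_relative_expression(ct_t, ct_r, c("es1", "es2"))
  expect_equal(mean(lev[c("es1", "es2")]), 1)
  # one extra cycle over the reference halves the level
  expect_equal(unname(lev[["ips"]]), 0.5)
  one <- qpcr_relative_expression(c(s = 25), c(s = 25), "s")
  expect_equal(unname(one), 1)
  expect_error(qpcr_relative_expression(ct_t, ct_r, character(0)), "calibrator")
})
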