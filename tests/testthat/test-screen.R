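make_group <- function(n, n_tad = 8, scale = 300, seed = 1) {
  set.seed(seed)
  arr <- array(stats::rnorm(n * n_tad * 3, sd = scale),
               dim = c(n, n_tad, 3))
  dimnames(arr) <- list(sprintf("t%03d", seq_len(n)), NULL,
                        c("x", "y", "z"))
  arr
}

test_that("log2fc distance matrix recovers identity and uniform scaling", {
  ctrl <- make_group(30, seed = 2)
  m0 <- log2fc_distance_matrix(ctrl, ctrl, min_traces = 20)
  expect_true(all(abs(m0[upper.tri(m0)]) < 1e-12))
  m1 <- log2fc_distance_matrix(ctrl * 2, ctrl, min_traces = 20)
  expect_true(all(abs(m1[upper.tri(m1)] - 1) < 1e-12))
  expect_true(all(is.na(diag(m1))))
  expect_error(log2fc_distance_matrix(make_group(5), ctrl), "min_traces")
})

test_that("log2fc matrix matches hand-computed medians on a 4-TAD toy", {
  # perturbation traces: segments along x with known lengths
  mk <- function(lens) {
    arr <- array(0, dim = c(length(lens), 4, 3))
    for (i in seq_along(lens))
      arr[i, , 1] <- cumsum(c(0, rep(lens[i], 3)))
    arr
  }
  pert <- mk(c(10, 20, 30, 40, 50) * 10)
  ctrl <- mk(c(10, 10, 20, 20, 30) * 10)
  m <- log2fc_distance_matrix(pert, ctrl, min_traces = 5)
  # adjacent pair (1,2): medians 300 vs 200
  expect_equal(m[1, 2], log2(300 / 200), tolerance = 1e-12)
  # pair (1,4): medians 900 vs 600
  expect_equal(m[1, 4], log2(900 / 600), tolerance = 1e-12)
})

test_that("paired distance test reacts to uniform scaling and nulls", {
  ctrl <- make_group(40, n_tad = 27, seed = 3)
  t0 <- distance_test(ctrl, ctrl, "all")
  expect_equal(t0$log2fc, 0)
  expect_equal(t0$p, 1)
  # x1.5 scaling: all 351 per-pair differences share a sign
  t1 <- distance_test(ctrl * 1.5, ctrl, "all")
  expect_equal(t1$log2fc, log2(1.5), tolerance = 1e-9)
  expect_lt(t1$p, 1e-10)
  expect_identical(t1$n_pairs, 351L)
  t2 <- distance_test(ctrl * 1.5, ctrl, "adjacent")
  expect_identical(t2$n_pairs, 26L)
  expect_lt(t2$p, 1e-4)
  expect_true(distance_test(make_group(40, n_tad = 4),
                            make_group(40, n_tad = 4, seed = 9),
                            "all", min_pairs = 20)$insufficient)
  # the pair-paired signed-rank display statistic is also available
  t3 <- distance_test(ctrl * 1.5, ctrl, "all", method = "pair_signedrank")
  expect_lt(t3$p, 1e-10)
  expect_equal(t3$log2fc, log2(1.5), tolerance = 1e-9)
})

test_that("trace-level distance tests are calibrated under the null", {
  # split one homogeneous population into pseudo-perturbation and
  # control; p values must look uniform, not enriched near zero
  set.seed(71)
  ps <- replicate(40, {
    arr <- make_group(120, n_tad = 12, seed = sample.int(1e6, 1))
    distance_test(arr[1:40, , ], arr[41:120, , ], "all")$p
  })
  expect_gt(mean(ps < 0.1), 0)  # sanity: some variation exists
  expect_lt(mean(ps < 0.1), 0.25)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rank-sum contact test matches the exact enumeration at n = 5", {
  x <- c(0.8, 0.9, 0.85, 0.95, 0.99)
  y <- c(0.1, 0.2, 0.15, 0.05, 0.12)
  ct <- contact_test(x, y, min_traces = 2)
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  # small untied groups use the exact rank-sum null distribution
  expect_equal(ct$p, exact, tolerance = 1e-12)
  # identical distributions
  ct0 <- contact_test(x, x, min_traces = 2)
  expect_equal(ct0$p, 1)
  expect_equal(ct0$log2fc, 0)
  # log2 of group means: 0.4 vs 0.2 -> 1
  ct1 <- contact_test(rep(0.4, 25), rep(0.2, 25), min_traces = 20)
  expect_equal(ct1$log2fc, 1)
  expect_true(contact_test(x, y, min_traces = 20)$insufficient)
})

test_that("BH correction matches the hand-computed step-up", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_correct(0.37), 0.37)
  expect_equal(fdr_correct(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.01, NA, 0.5, 0.002)
  f <- fdr_correct(p)
  expect_true(is.na(f[2]))
  expect_equal(f[c(1, 3, 4)],
               stats::p.adjust(p[c(1, 3, 4)], "BH"))
  expect_true(all(f >= p, na.rm = TRUE))
  # monotone non-decreasing after sorting by p
  set.seed(12)
  p2 <- stats::runif(50)
  f2 <- fdr_correct(p2)
  expect_true(all(diff(f2[order(p2)]) >= -1e-12))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("hit calling filters, ranks and never lists controls", {
  ph <- data.frame(
    sgrna = c("sgA", "sgB", "sgNT_01", "sgC", "sgD"),
    phenotype = "overall_distance",
    log2fc = c(0.5, -0.4, 0.6, 0.02, 0.3),
    fdr = c(0.01, 0.02, 0.001, 0.01, 0.5),
    is_control = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  h <- call_hits(ph, fdr_threshold = 0.1, effect_floor = 0.05)
  expect_setequal(h$sgrna, c("sgA", "sgB"))   # control and tiny effect out
  expect_identical(h$direction[h$sgrna == "sgB"], "down")
  expect_identical(nrow(call_hits(ph, fdr_threshold = 0)), 0L)
  h1 <- call_hits(ph, effect_floor = 0.05, top_k = 1)
  expect_identical(sort(h1$sgrna), c("sgA", "sgB"))  # one per direction
})

test_that("AB score matrix averages pairs of scores", {
  prof <- toy_profile(c("A", "B", "A", "B"))
  prof$score <- c(1, -1, 0.5, -0.25)
  m <- ab_score_matrix(prof)
  expect_equal(m[1, 2], 0)
  expect_equal(m[1, 3], 0.75)
  # brute-force double loop
  for (i in 1:4) for (j in 1:4)
    expect_equal(m[i, j], (prof$score[i] + prof$score[j]) / 2)
  prof$score <- rep(0.3, 4)
  expect_true(all(ab_score_matrix(prof) == 0.3))
})

test_that("effect-matrix correlation matches the textbook formula", {
  set.seed(21)
  m1 <- matrix(stats::rnorm(27 * 27), 27, 27)
  m1[lower.tri(m1)] <- t(m1)[lower.tri(m1)]
  m2 <- 2 * m1 + 3
  expect_equal(correlate_effect_matrices(m1, m2)$r, 1, tolerance = 1e-12)
  expect_equal(correlate_effect_matrices(m1, -m1)$r, -1, tolerance = 1e-12)
  res <- correlate_effect_matrices(m1, m1 + matrix(stats::rnorm(729), 27))
  expect_identical(res$n_points, 351L)
  m3 <- matrix(stats::rnorm(729), 27); m3[lower.tri(m3)] <- t(m3)[lower.tri(m3)]
  r_loop <- bf_pearson(m1[upper.tri(m1)], m3[upper.tri(m3)])
  res3 <- correlate_effect_matrices(m1, m3)
  expect_equal(res3$r, r_loop, tolerance = 1e-12)
  expect_equal(res3$p,
               stats::cor.test(m1[upper.tri(m1)],
                               m3[upper.tri(m3)])$p.value,
               tolerance = 1e-9)
  expect_true(res3$ci[1] <= res3$r && res3$r <= res3$ci[2])
  expect_true(correlate_effect_matrices(matrix(1, 3, 3),
                                        matrix(1, 3, 3))$insufficient)
})

test_that("short/long-range split follows the genomic cutoff", {
  prof <- default_compartment_profile()     # midpoints 1.25 Mb apart
  m <- matrix(5, 27, 27)
  s <- short_long_range_split(m, prof, 3e6)
  expect_equal(unname(s), c(5, 5))
  # cutoff 0: everything long
  s0 <- short_long_range_split(m, prof, 0)
  expect_true(is.na(s0["short"]))
  expect_equal(unname(s0["long"]), 5)
  # midpoints 1.25 Mb apart: separations 1.25k Mb; short = sep <= 2
  ann_short <- abs(outer(prof$midpoint_bp, prof$midpoint_bp, `-`)) < 3e6
  idx <- which(upper.tri(ann_short), arr.ind = TRUE)
  expect_identical(sort(unique((idx[, 2] - idx[, 1])[ann_short[idx]])),
                   c(1L, 2L))
  m2 <- matrix(0, 27, 27)
  m2[abs(row(m2) - col(m2)) <= 2] <- 1      # short pairs get 1
  s2 <- short_long_range_split(m2, prof, 3e6)
  expect_equal(unname(s2), c(1, 0))
})

test_that("hierarchical clustering groups planted effect families", {
  set.seed(33)
  base1 <- matrix(stats::rnorm(27^2), 27); base1 <- base1 + t(base1)
  base2 <- matrix(stats::rnorm(27^2), 27); base2 <- base2 + t(base2)
  noise <- function() {
    m <- matrix(stats::rnorm(27^2, sd = 0.3), 27); m + t(m)
  }
  mats <- list(a1 = base1 + noise(), a2 = base1 + noise(),
               a3 = base1 + noise(), b1 = base2 + noise(),
               b2 = base2 + noise(), b3 = base2 + noise())
  cl <- cluster_hits(mats)
  grp <- stats::cutree(cl$hclust, k = 2)
  expect_identical(length(unique(grp[c("a1", "a2", "a3")])), 1L)
  expect_identical(length(unique(grp[c("b1", "b2", "b3")])), 1L)
  expect_true(grp[["a1"]] != grp[["b1"]])
  expect_true(all(diag(cl$cor_matrix) == 1))
  expect_match(cl$newick, "^\\(.*\\);$")
  # identical pair merges before the negated outlier
  m0 <- base1
  cl2 <- cluster_hits(list(x = m0, y = m0, z = -m0))
  first <- cl2$hclust$merge[1, ]
  expect_identical(sort(cl2$hclust$labels[-first]), c("x", "y"))
  # constant matrices are excluded with a warning
  expect_warning(cluster_hits(c(mats, list(flat = matrix(0, 27, 27)))),
                 "constant")
})

test_that("cross-feature correlations flag duplicates and respect the null", {
  set.seed(44)
  ft <- data.frame(sgrna = sprintf("h%02d", 1:18),
                   adjacent = stats::rnorm(18))
  ft$adjacent_copy <- ft$adjacent
  ft$other <- stats::rnorm(18)
  cc <- cross_feature_correlation(ft)
  dup <- cc[cc$feature1 == "adjacent" & cc$feature2 == "adjacent_copy", ]
  expect_equal(dup$r, 1)
  expect_identical(dup$n, 18L)
  # independent features: the FDR-significant fraction stays near the
  # nominal level over repeated draws
  set.seed(45)
  sig <- replicate(30, {
    ft2 <- as.data.frame(matrix(stats::rnorm(18 * 5), 18))
    cc2 <- cross_feature_correlation(ft2)
    mean(cc2$fdr < 0.1, na.rm = TRUE)
  })
  expect_lt(mean(sig), 0.12)
})
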