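test_that("UMI join keeps exactly the shared UMIs", {
  sg <- data.frame(umi = c("u1", "u2", "u3"), payload_type = "protospacer",
                   payload = c("sgA", "sgB", "sgC"), pass_qc = TRUE)
  bc <- data.frame(umi = c("u1", "u4"), payload_type = "barcode_full",
                   payload = c("0120211002", "1111111111"), pass_qc = TRUE)
  out <- join_by_umi(sg, bc)
  expect_identical(nrow(out), 1L)
  expect_identical(out$sgrna, "sgA")
  expect_identical(out$code, "0120211002")
  # empty intersection warns and returns an empty table
  expect_warning(out0 <- join_by_umi(sg, bc[2, , drop = FALSE]),
                 "no shared UMIs")
  expect_identical(nrow(out0), 0L)
  # failed-QC rows are excluded before the join
  bc$pass_qc <- c(FALSE, TRUE)
  expect_warning(out1 <- join_by_umi(sg, bc), "no shared UMIs")
  expect_identical(nrow(out1), 0L)
})

test_that("UMI join size matches a counting oracle on generated tables", {
  lib <- make_library(n_targeting = 40, n_controls = 4, n_genes = 20,
                      seed = 2)
  rt <- make_read_tables(lib$truth, umis_per_pair = 5, n_unshared = 200,
                         seed = 3)
  out <- join_by_umi(rt$sgrna_table, rt$barcode_table)
  # every shared UMI contributes exactly one association; the partial
  # codes are constructed with guaranteed overlap, so none drop
  expect_identical(nrow(out), 44L * 5L)
  expect_identical(out$code, unname(lib$truth[out$sgrna]))
})

test_that("partial-code assembly enforces overlap agreement and coverage", {
  full <- trit_digits("0120211002")
  left <- right <- rep(NA_integer_, 10)
  left[1:7] <- full[1:7]
  right[5:10] <- full[5:10]
  expect_identical(assemble_partial_codes(left, right), full)
  # conflict in the overlap
  bad <- right; bad[6] <- (full[6] + 1L) %% 3L
  expect_null(assemble_partial_codes(left, bad))
  # gap between the runs
  l2 <- r2 <- rep(NA_integer_, 10)
  l2[1:4] <- full[1:4]; r2[7:10] <- full[7:10]
  expect_null(assemble_partial_codes(l2, r2))
  # exhaustive: all end-anchored fragment length combinations at n = 10
  for (lend in 1:9) for (rstart in 2:10) {
    l <- r <- rep(NA_integer_, 10)
    l[1:lend] <- full[1:lend]
    r[rstart:10] <- full[rstart:10]
    res <- assemble_partial_codes(l, r)
    if (rstart <= lend) expect_identical(res, full) else expect_null(res)
  }
})

test_that("code classification applies the min-reads supporter rule", {
  pairs <- data.frame(
    sgrna = c(rep("sgA", 5), rep("sgA", 5), rep("sgB", 4), "sgB"),
    code = c(rep("0000000000", 5), rep("1111111111", 5),
             rep("1111111111", 4), "0000000000"))
  cb <- classify_codes(pairs, min_reads = 2)
  # 0000000000: sgA 5 reads, sgB 1 read (below threshold) -> good sgA
  expect_identical(unname(cb$good["0000000000"]), "sgA")
  # 1111111111: sgA 5, sgB 4 -> two supporters -> bad
  expect_true("1111111111" %in% cb$bad)
  # below-threshold-only codes are excluded entirely
  pairs2 <- data.frame(sgrna = "sgC", code = "2222222222")
  cb2 <- classify_codes(pairs2, min_reads = 2)
  expect_false("2222222222" %in% names(cb2$good))
})

test_that("classification recovers a planted assignment exactly", {
  lib <- make_library(n_targeting = 40, n_controls = 4, n_genes = 20,
                      seed = 5)
  rt <- make_read_tables(lib$truth, umis_per_pair = 4, seed = 6)
  pairs <- join_by_umi(rt$sgrna_table, rt$barcode_table)
  cb <- classify_codes(pairs, min_reads = 2)
  expect_identical(length(cb$bad), 0L)
  expect_mapequal(as.list(cb$good), as.list(lib$codebook$good))
  # template switching moves exactly the switched codes to bad
  switched <- unname(lib$truth[c(3, 17)])
  rt2 <- make_read_tables(lib$truth, umis_per_pair = 4,
                          switch_codes = switched, seed = 7)
  cb2 <- classify_codes(join_by_umi(rt2$sgrna_table, rt2$barcode_table),
                        min_reads = 2)
  expect_setequal(cb2$bad, switched)
  expect_mapequal(as.list(cb2$good),
                  as.list(lib$truth[!lib$truth %in% switched] |>
                            (\(x) stats::setNames(names(x), x))()))
})

test_that("library QC reproduces the screen's dropout arithmetic", {
  # 420 designed, 8 + 404 detected -> 1.9%
  lib <- make_library(seed = 1)          # full 420-sgRNA design
  expect_identical(nrow(lib$library), 420L)
  expect_identical(sum(!lib$library$targeting), 10L)
  expect_identical(length(unique(lib$library$gene[lib$library$targeting])),
                   137L)
  per_gene <- table(lib$library$gene[lib$library$targeting])
  expect_true(all(per_gene %in% 2:3))
  detected <- c(lib$library$sgrna[!lib$library$targeting][1:8],
                lib$library$sgrna[lib$library$targeting][1:404])
  cb <- codebook(stats::setNames(detected, lib$truth[detected]))
  qc <- library_qc(cb, lib$library)
  expect_identical(qc$n_detected, 412L)
  expect_identical(qc$dropout_pct, 1.9)
  # no dropout and arithmetic checks
  qc0 <- library_qc(lib$codebook, lib$library)
  expect_identical(qc0$dropout_rate, 0)
  toy <- data.frame(sgrna = sprintf("sg%02d", 1:10))
  cb_toy <- codebook(stats::setNames(toy$sgrna[1:7],
                                     sprintf("%010d", 1:7)))
  expect_identical(library_qc(cb_toy, toy)$dropout_pct, 30)
})

test_that("planted dropout and collisions propagate through QC", {
  lib <- make_library(n_targeting = 100, n_controls = 10, n_genes = 50,
                      dropout_rate = 0.02, seed = 9)
  qc <- library_qc(lib$codebook, lib$library)
  expect_equal(qc$dropout_rate, round(0.02 * 110) / 110, tolerance = 1e-9)
  lib2 <- make_library(n_targeting = 100, n_controls = 10, n_genes = 50,
                       n_bad_codes = 3, seed = 10)
  expect_identical(length(lib2$codebook$bad), 3L)
  expect_true(all(!lib2$codebook$bad %in% names(lib2$codebook$good)))
})

test_that("screen summary reports the target-perturbation combinations", {
  s <- screen_summary()
  expect_identical(s$n_imaging_targets, 30L)
  expect_identical(s$n_combinations, 12600L)
})
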