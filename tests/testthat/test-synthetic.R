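test_that("generated libraries follow the screen composition", {
  lib <- make_library(n_targeting = 44, n_controls = 8, n_genes = 22,
                      seed = 1)
  expect_identical(nrow(lib$library), 52L)
  expect_identical(sum(!lib$library$targeting), 8L)
  per_gene <- table(lib$library$gene[lib$library$targeting])
  expect_true(all(per_gene %in% 2:3))
  expect_identical(anyDuplicated(unname(lib$truth)), 0L)
  expect_identical(length(lib$codebook$good), 52L)
  # all assigned codes live in the 10-trit space
  expect_true(all(nchar(unname(lib$truth)) == 10L))
  expect_error(make_library(n_targeting = 10, n_controls = 2,
                            n_genes = 22), "2-3 sgRNAs")
})

test_that("generators are pure functions of their seeds", {
  a <- make_library(n_targeting = 20, n_controls = 4, n_genes = 10,
                    seed = 5)
  b <- make_library(n_targeting = 20, n_controls = 4, n_genes = 10,
                    seed = 5)
  expect_identical(a, b)
  cells <- make_cells(a$truth, 3, seed = 6)
  expect_identical(cells, make_cells(a$truth, 3, seed = 6))
  tr1 <- make_traces(cells[1:30, ], seed = 7)
  tr2 <- make_traces(cells[1:30, ], seed = 7)
  expect_identical(tr1, tr2)
  ro1 <- make_readouts(cells, seed = 8)
  expect_identical(ro1, make_readouts(cells, seed = 8))
  expect_false(identical(tr1, make_traces(cells[1:30, ], seed = 9)))
})

test_that("trace generator applies dropout at the configured rate", {
  lib <- make_library(n_targeting = 20, n_controls = 4, n_genes = 10,
                      seed = 2)
  cells <- make_cells(lib$truth, 10, seed = 3)
  tr <- make_traces(cells, dropout_rate = 0.1, seed = 4)
  miss <- mean(is.na(tr$x_nm))
  expect_gt(miss, 0.08)
  expect_lt(miss, 0.12)
  tr0 <- make_traces(cells[1:30, ], dropout_rate = 0, seed = 4)
  expect_identical(sum(is.na(tr0$x_nm)), 0L)
  # per-cell trace counts stay in the configured range
  per_cell <- table(unique(tr[, c("cell_id", "trace_id")])$cell_id)
  expect_true(all(per_cell >= 2 & per_cell <= 4))
})

test_that("noiseless readouts decode perfectly; miscalls follow the model", {
  lib <- make_library(n_targeting = 20, n_controls = 4, n_genes = 10,
                      seed = 11)
  cells <- make_cells(lib$truth, 8, seed = 12)
  ro0 <- make_readouts(cells, miscall_rate = 0, lowconf_rate = 0,
                       seed = 13)
  dec0 <- decode_cells(ro0, lib$codebook)
  expect_true(all(dec0$status == "assigned"))
  expect_identical(dec0$sgrna[match(cells$cell_id, dec0$cell_id)],
                   cells$sgrna)
  expect_true(all(dec0$corrected_digits == 0L))
  # binomial error model: with per-round miscall rate m and radius-1
  # correction, a cell decodes to the truth iff <= 1 miscalled round
  m <- 0.05
  ro1 <- make_readouts(cells, miscall_rate = m, lowconf_rate = 0,
                       seed = 14)
  dec1 <- decode_cells(ro1, lib$codebook)
  correct <- mean(dec1$sgrna[match(cells$cell_id, dec1$cell_id)] ==
                    cells$sgrna, na.rm = TRUE)
  p_upper <- stats::pbinom(1, 10, m)   # 0 or 1 corrupted rounds
  # miscalls can also be silently absorbed when >=2 hit the same
  # codeword neighborhood, so observed accuracy is close to but may
  # exceed the binomial bound slightly; allow Monte-Carlo slack
  expect_gt(correct, p_upper - 0.05)
  n_corr <- sum(dec1$corrected_digits > 0, na.rm = TRUE)
  expect_gt(n_corr, 0)
  # heavy corruption rejects many cells (stress direction only)
  ro2 <- make_readouts(cells, miscall_rate = 0.3, lowconf_rate = 0.1,
                       seed = 15)
  dec2 <- decode_cells(ro2, lib$codebook)
  expect_gt(mean(dec2$status != "assigned"),
            mean(dec1$status != "assigned"))
})

test_that("low-confidence rounds become uncalled digits", {
  lib <- make_library(n_targeting = 20, n_controls = 4, n_genes = 10,
                      seed = 21)
  cells <- make_cells(lib$truth, 8, seed = 22)
  ro <- make_readouts(cells, miscall_rate = 0, lowconf_rate = 0.15,
                      seed = 23)
  dec <- decode_cells(ro, lib$codebook)
  expect_gt(mean(dec$n_uncalled), 0.5)
  # wildcards still decode when a unique candidate remains
  expect_gt(mean(dec$status == "assigned"), 0.8)
})

test_that("null effects leave perturbations indistinguishable from controls", {
  scr <- simulate_screen(n_targeting = 8, n_controls = 4, n_genes = 4,
                         n_cells_per_sgrna = 30, nuclei_per_sgrna = 0,
                         seed = 31)
  res <- run_screen(scr, use_truth = TRUE)
  expect_identical(nrow(res$hits), 0L)
  expect_true(all(res$phenotypes$fdr > 0.1 |
                    abs(res$phenotypes$log2fc) < 0.15,
                  na.rm = TRUE))
})

test_that("planted global compaction is recovered through the full pipeline", {
  eff <- list(sgGENE001_1 = effect_spec(global = 0.8))
  scr <- simulate_screen(n_targeting = 8, n_controls = 4, n_genes = 4,
                         n_cells_per_sgrna = 60, nuclei_per_sgrna = 0,
                         effects = eff, seed = 41)
  res <- run_screen(scr)
  od <- res$phenotypes[res$phenotypes$phenotype == "overall_distance" &
                         res$phenotypes$sgrna == "sgGENE001_1", ]
  expect_lt(od$log2fc, -0.15)
  expect_lt(od$fdr, 0.1)
  expect_true("sgGENE001_1" %in%
                res$hits$sgrna[res$hits$direction == "down"])
})

test_that("nuclear phantoms express their planted offsets", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      sgrna = rep(c("sgCTL", "sgLOBE"), each = 10),
                      code = "0000000000")
  eff <- list(sgLOBE = effect_spec(sphericity_lobe = 0.6))
  f <- make_nuclei(cells, effects = eff, seed = 51)
  expect_lt(mean(f$sphericity[f$sgrna == "sgLOBE"]),
            mean(f$sphericity[f$sgrna == "sgCTL"]) - 0.05)
  # condensate blobs raise COV over a blob-free group
  eff2 <- list(sgFLAT = effect_spec(cov_delta = -1))
  f2 <- make_nuclei(cells, effects = list(), seed = 52)
  f3 <- make_nuclei(transform(cells, sgrna = "sgFLAT"),
                    effects = eff2, seed = 52)
  expect_gt(mean(f2$cov), mean(f3$cov))
  # near-spherical control phantoms score near the analytic value
  expect_gt(mean(f$sphericity[f$sgrna == "sgCTL"]), 0.9)
})

test_that("the separated-code construction respects its distance bound", {
  codes <- make_separated_codes(60, seed = 3)
  expect_identical(anyDuplicated(codes), 0L)
  d <- outer(codes, codes, Vectorize(trit_distance))
  expect_gte(min(d[upper.tri(d)]), 3L)
})
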