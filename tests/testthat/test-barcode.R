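test_that("code space size matches closed form and brute enumeration", {
  expect_identical(enumerate_code_space(10, 3), 59049)
  expect_identical(enumerate_code_space(1, 3), 3)
  # brute-force enumeration oracle for a small binary space
  expect_identical(enumerate_code_space(4, 2), 16)
  m <- all_codes(4, 2)
  expect_identical(nrow(m), 16L)
  expect_identical(anyDuplicated(apply(m, 1, paste, collapse = "")), 0L)
  expect_error(enumerate_code_space(0, 3), "positive")
  expect_error(enumerate_code_space(10, 1), ">= 2")
})

test_that("barcode assembly yields the 419-nt body with 41-nt segments", {
  lib <- default_digit_library()
  expect_identical(nrow(lib), 30L)
  expect_true(all(nchar(lib$segment) == 41L))
  # 60 probes: one linear + one padlock per (digit, value)
  expect_identical(length(unique(c(lib$linear_probe, lib$padlock_probe))),
                   60L)
  # channels: the three values of each digit report in distinct colors
  for (d in 1:10)
    expect_identical(length(unique(lib$channel[lib$digit == d])), 3L)
  seq1 <- assemble_barcode_sequence("0120211002", lib)
  expect_identical(nchar(seq1), 419L)
  # locality: one changed digit touches only that digit's window
  seq2 <- assemble_barcode_sequence("0120211012", lib)
  w <- function(i) ((i - 1) * 42 + 1):((i - 1) * 42 + 41)
  same <- which(strsplit(seq1, "")[[1]] != strsplit(seq2, "")[[1]])
  expect_true(all(same %in% w(9)))
  expect_error(assemble_barcode_sequence("01202110N2", lib), "uncalled")
})

test_that("trit calling applies the argmax and confidence-ratio rules", {
  ct <- call_trits(rbind(c(10, 200, 12)), min_ratio = 2)
  expect_identical(ct$digits, 1L)
  expect_equal(ct$quality, 200 / 12)
  ct2 <- call_trits(rbind(c(100, 90, 5)), min_ratio = 2)
  expect_true(is.na(ct2$digits))
  ct3 <- call_trits(rbind(c(0, 0, 0)), min_ratio = 2)
  expect_true(is.na(ct3$digits))
  expect_identical(ct3$quality, 0)
  ct4 <- call_trits(rbind(c(0, 50, 0)), min_ratio = 2)
  expect_identical(ct4$digits, 1L)
  expect_identical(ct4$quality, Inf)
  expect_error(call_trits(rbind(c(-1, 2, 3))), "non-negative")
})

test_that("trit distance counts called mismatches and wildcards match", {
  expect_identical(trit_distance("0120211002", "0120211002"), 0L)
  expect_identical(trit_distance("0000000000", "1001000010"), 3L)
  expect_identical(trit_distance("N120211002", "0120211002"), 0L)
  expect_error(trit_distance("012", "0120"), "equal length")
})

test_that("decoding follows the exact/bad/radius policy", {
  cb <- codebook(c("0000000000" = "sgA", "1111100000" = "sgB",
                   "2222211111" = "sgC"),
                 bad = "2222222222")
  r <- decode("0000000000", cb)
  expect_identical(r$status, "assigned")
  expect_identical(r$sgrna, "sgA")
  expect_identical(r$corrected_digits, 0L)
  # one trit off a unique good code
  r1 <- decode("0000000001", cb)
  expect_identical(r1$status, "assigned")
  expect_identical(r1$sgrna, "sgA")
  expect_identical(r1$corrected_digits, 1L)
  # bad codes are hard-rejected
  expect_identical(decode("2222222222", cb)$status, "rejected_bad_code")
  # nothing within radius
  expect_identical(decode("0011223344", cb)$status, "rejected_no_match")
  # equidistant between two good codes -> ambiguous
  cb2 <- codebook(c("0000000000" = "sgA", "2000000001" = "sgB"))
  expect_identical(decode("0000000001", cb2)$status,
                   "rejected_ambiguous")
  expect_error(decode("0000000000", codebook(character(0))))
})

test_that("decode agrees with a brute-force scan over a toy codebook", {
  set.seed(42)
  idx <- sample(59049, 50)
  codes <- vapply(idx, function(i)
    trit_string(perturbtrace:::index_to_trits(i)), character(1))
  cb <- codebook(stats::setNames(sprintf("sg%02d", 1:50), codes))
  for (k in 1:25) {
    probe <- sample(0:2, 10, replace = TRUE)
    d <- vapply(codes, function(cstr) trit_distance(probe, cstr),
                integer(1))
    cand <- which(d <= 1)
    r <- decode(probe, cb, max_correction = 1)
    if (min(d) == 0) {
      expect_identical(r$status, "assigned")
    } else if (length(cand) == 1) {
      expect_identical(r$status, "assigned")
      expect_identical(unname(cb$good[cand]), r$sgrna)
    } else if (length(cand) > 1) {
      expect_identical(r$status, "rejected_ambiguous")
    } else {
      expect_identical(r$status, "rejected_no_match")
    }
  }
})

test_that("decode is deterministic and independent of codebook order", {
  set.seed(7)
  idx <- sample(59049, 40)
  codes <- vapply(idx, function(i)
    trit_string(perturbtrace:::index_to_trits(i)), character(1))
  good <- stats::setNames(sprintf("sg%02d", 1:40), codes)
  cb1 <- codebook(good)
  cb2 <- codebook(rev(good))
  for (k in 1:10) {
    probe <- sample(0:2, 10, replace = TRUE)
    expect_identical(decode(probe, cb1), decode(probe, cb2))
  }
})

test_that("noiseless readouts round-trip through calling and decoding", {
  lib <- make_library(n_targeting = 24, n_controls = 4, n_genes = 12,
                      seed = 11)
  set.seed(1)
  sample_codes <- sample(names(lib$codebook$good), 200, replace = TRUE)
  for (code in sample_codes[1:30]) {
    ct <- call_trits(clean_readout(code))
    expect_identical(trit_string(ct$digits), code)
    r <- decode(ct$digits, lib$codebook)
    expect_identical(r$status, "assigned")
    expect_identical(r$corrected_digits, 0L)
    expect_identical(r$sgrna, unname(lib$codebook$good[code]))
  }
  # vectorized path gives the same result as the scalar path
  cells <- make_cells(lib$truth, 3, seed = 2)
  ro <- make_readouts(cells, miscall_rate = 0.1, lowconf_rate = 0.1,
                      seed = 3)
  dec <- decode_cells(ro, lib$codebook)
  for (i in sample(nrow(dec), 20)) {
    sub <- ro[ro$cell_id == dec$cell_id[i], ]
    m <- matrix(0, 10, 3)
    m[cbind(sub$round, sub$channel_value + 1)] <- sub$intensity
    ct <- call_trits(m)
    r <- decode(ct$digits, lib$codebook)
    expect_identical(r$status, dec$status[i])
    if (r$status == "assigned")
      expect_identical(r$sgrna, dec$sgrna[i])
  }
})

test_that("separated codebooks correct any single corrupted trit", {
  codes <- make_separated_codes(100, seed = 5)
  dmat <- outer(codes, codes, Vectorize(trit_distance))
  expect_true(all(dmat[upper.tri(dmat)] >= 3))
  cb <- codebook(stats::setNames(sprintf("sg%03d", 1:100), codes))
  set.seed(6)
  for (k in 1:50) {
    code <- sample(codes, 1)
    d <- trit_digits(code)
    pos <- sample(10, 1)
    d[pos] <- (d[pos] + sample(1:2, 1)) %% 3
    r <- decode(d, cb, max_correction = 1)
    expect_identical(r$status, "assigned")
    expect_identical(r$sgrna, unname(cb$good[code]))
    expect_identical(r$corrected_digits, 1L)
  }
})

test_that("bottlenecked sampling matches the birthday-collision closed form", {
  # sampling k codes with replacement from the 59,049-code space:
  # expected distinct fraction is N(1-(1-1/N)^k)/k
  N <- 59049; k <- 5000
  set.seed(123)
  reps <- replicate(40, {
    s <- sample.int(N, k, replace = TRUE)
    1 - length(unique(s)) / k
  })
  expected_dup <- 1 - N * (1 - (1 - 1 / N)^k) / k
  expect_lt(abs(mean(reps) - expected_dup), 3 * stats::sd(reps) / sqrt(40))
  # the bottleneck keeps collisions rare: ~4% of codes at k = 5,000
  expect_lt(expected_dup, 0.05)
})
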