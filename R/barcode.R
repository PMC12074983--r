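#' Ternary combinatorial FISH barcodes
#'
#' A cell's identity barcode is an ordered sequence of `n_digits` ternary
#' digits ("trits"), each taking a value in \{0, 1, 2\}. Ten trits span a
#' code space of 3^10 = 59,049 barcodes. Internally a trit code is an
#' integer vector with `NA` marking an uncalled (low-confidence) digit;
#' on disk codes are serialized as character strings such as
#' `"0120211002"`, with `"N"` for uncalled digits.
#'
#' @name trit-codes
NULL

#' Size of the combinatorial barcode code space
#'
#' @param n_digits number of barcode digits (default design: 10).
#' @param n_values number of values per digit (ternary design: 3).
#' @return The number of distinct codes, `n_values ^ n_digits`.
#' @examples
#' enumerate_code_space(10, 3) # 59049
#' @export
enumerate_code_space <- function(n_digits = 10L, n_values = 3L) {
  if (length(n_digits) != 1L || is.na(n_digits) || n_digits < 1)
    stop("`n_digits` must be a positive integer")
  if (length(n_values) != 1L || is.na(n_values) || n_values < 2)
    stop("`n_values` must be an integer >= 2")
  as.numeric(n_values)^as.numeric(n_digits)
}

#' Enumerate every code in a (small) code space
#'
#' Generates the full code space as a matrix, one code per row. Only
#' intended for small spaces (the default 10-trit space has 59,049 rows
#' and is still fine; refuse anything above 1e6).
#'
#' @inheritParams enumerate_code_space
#' @return integer matrix with `n_values^n_digits` rows and `n_digits`
#'   columns, values in `0:(n_values-1)`.
#' @export
all_codes <- function(n_digits = 10L, n_values = 3L) {
  n <- enumerate_code_space(n_digits, n_values)
  if (n > 1e6) stop("code space too large to enumerate in memory")
  g <- do.call(expand.grid, rep(list(seq_len(n_values) - 1L), n_digits))
  m <- as.matrix(g)[, rev(seq_len(n_digits)), drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Convert between trit vectors and code strings
#'
#' @param digits integer vector of trit values (`NA` = uncalled).
#' @return `trit_string()`: a character scalar such as `"0120211002"`
#'   (`"N"` for uncalled digits); `trit_digits()`: an integer vector.
#' @export
trit_string <- function(digits) {
  ch <- ifelse(is.na(digits), "N", as.character(digits))
  paste(ch, collapse = "")
}

#' @rdname trit_string
#' @param code character scalar over `0:9` and `"N"`.
#' @export
trit_digits <- function(code) {
  ch <- strsplit(code, "", fixed = TRUE)[[1]]
  out <- suppressWarnings(as.integer(ch))
  if (any(is.na(out) & ch != "N"))
    stop("invalid code string: ", code)
  out
}

#' Trit (Hamming) distance between two codes
#'
#' Counts the positions where both digits are called and differ; an
#' uncalled (`NA`) digit matches anything.
#'
#' @param a,b integer trit vectors of equal length (or code strings).
#' @return non-negative integer.
#' @export
trit_distance <- function(a, b) {
  if (is.character(a)) a <- trit_digits(a)
  if (is.character(b)) b <- trit_digits(b)
  if (length(a) != length(b)) stop("codes must have equal length")
  sum(a != b, na.rm = TRUE)
}

#' Default digit library for the 10-trit, 3-value barcode design
#'
#' Each (digit, value) combination is encoded by a 41-nt digit segment:
#' two 20-nt hybridization sequences joined by a single-nucleotide
#' spacer. Each combination is read out by a linear/padlock probe pair,
#' and each of the three values of a digit reports in a distinct
#' secondary-probe fluorescence channel. The 30 segment sequences here
#' are synthetic stand-ins generated deterministically over \{A, T, C\}
#' (the published segments live in a vendor-format supplement); their
#' lengths, pairing structure and channel assignment follow the real
#' design.
#'
#' @param n_digits,n_values code geometry (default 10 x 3).
#' @return data.frame with one row per (digit, value): `digit`, `value`,
#'   `segment` (41 nt), `linear_probe`, `padlock_probe`, `channel`.
#' @export
default_digit_library <- function(n_digits = 10L, n_values = 3L) {
  n_entries <- n_digits * n_values
  # deterministic sequence generation, independent of the caller's RNG
  rng <- local({
    state <- 20210427
    function(n, k) {
      out <- integer(n)
      for (i in seq_len(n)) {
        state <<- (1103515245 * state + 12345) %% 2147483648
        out[i] <- state %% k + 1L
      }
      out
    }
  })
  alphabet <- c("A", "T", "C")
  seg <- character(n_entries)
  for (i in seq_len(n_entries)) {
    s1 <- paste(alphabet[rng(20L, 3L)], collapse = "")
    s2 <- paste(alphabet[rng(20L, 3L)], collapse = "")
    seg[i] <- paste0(s1, "C", s2)
  }
  channels <- c("ch565", "ch647", "ch750")
  d <- rep(seq_len(n_digits), each = n_values)
  v <- rep(seq_len(n_values) - 1L, times = n_digits)
  data.frame(
    digit = d,
    value = v,
    segment = seg,
    linear_probe = sprintf("lin_d%02d_v%d", d, v),
    padlock_probe = sprintf("pad_d%02d_v%d", d, v),
    channel = channels[v %% 3L + 1L],
    stringsAsFactors = FALSE
  )
}

#' Assemble the nucleotide sequence of a barcode
#'
#' Concatenates the chosen 41-nt digit segments in digit order, joined
#' by a single `"C"` spacer between adjacent digits; the default
#' 10-digit body is therefore 10 x 41 + 9 = 419 nt.
#'
#' @param code fully called trit vector or code string.
#' @param lib digit library, see [default_digit_library()].
#' @return character scalar, the barcode body sequence.
#' @export
assemble_barcode_sequence <- function(code, lib = default_digit_library()) {
  if (is.character(code)) code <- trit_digits(code)
  if (anyNA(code)) stop("code has uncalled digits; cannot assemble sequence")
  n_digits <- length(code)
  segs <- character(n_digits)
  for (i in seq_len(n_digits)) {
    row <- lib$digit == i & lib$value == code[i]
    if (sum(row) != 1L)
      stop("digit library does not cover digit ", i, " value ", code[i])
    segs[i] <- lib$segment[row]
  }
  if (any(nchar(segs) != 41L)) stop("digit segments must be 41 nt")
  paste(segs, collapse = "C")
}

#' Call trit values from per-round fluorescence intensities
#'
#' For each imaging round, the called value is the channel with maximal
#' intensity. The call quality is the ratio of the top intensity to the
#' second-highest (infinite when the runner-up is zero); digits whose
#' quality falls below `min_ratio` are left uncalled. An all-zero round
#' is uncalled with quality 0.
#'
#' @param readout numeric matrix, rounds x channels (default 10 x 3),
#'   non-negative intensities; channel j holds value j-1.
#' @param min_ratio minimum top-to-second intensity ratio for a
#'   confident call (default 2).
#' @return list with `digits` (integer, `NA` = uncalled) and `quality`
#'   (numeric ratio per round).
#' @export
call_trits <- function(readout, min_ratio = 2) {
  readout <- as.matrix(readout)
  if (any(readout < 0) || anyNA(readout))
    stop("intensities must be non-negative and finite")
  if (min_ratio <= 0) stop("`min_ratio` must be positive")
  n <- nrow(readout)
  digits <- integer(n)
  quality <- numeric(n)
  for (r in seq_len(n)) {
    v <- readout[r, ]
    ord <- order(v, decreasing = TRUE)
    top <- v[ord[1]]
    second <- v[ord[2]]
    if (top == 0) {
      digits[r] <- NA_integer_
      quality[r] <- 0
      next
    }
    quality[r] <- if (second == 0) Inf else top / second
    digits[r] <- if (quality[r] >= min_ratio) ord[1] - 1L else NA_integer_
  }
  list(digits = digits, quality = quality)
}

#' Codebook: good and bad barcode-to-sgRNA mappings
#'
#' A codebook maps "good" codes (each uniquely associated with one
#' sgRNA) to sgRNA identifiers and records "bad" codes known to project
#' to multiple sgRNAs; bad codes are hard-rejected at decoding.
#'
#' @param good named character vector: names are code strings, values
#'   sgRNA identifiers.
#' @param bad character vector of bad code strings.
#' @return object of class `codebook`.
#' @export
codebook <- function(good, bad = character()) {
  good <- unlist(good)
  if (is.null(good)) good <- character()
  if (length(good) > 0 &&
      (is.null(names(good)) || any(names(good) == "")))
    stop("`good` must be a named vector (code -> sgRNA)")
  if (anyDuplicated(names(good)))
    stop("duplicate codes in `good`")
  bad <- unique(as.character(bad))
  if (length(intersect(names(good), bad)))
    stop("good and bad code sets must be disjoint")
  nd <- unique(nchar(c(names(good), bad)))
  if (length(nd) > 1) stop("all codes must have the same length")
  structure(list(good = good, bad = bad,
                 n_digits = if (length(nd)) nd else NA_integer_),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf(
    "<codebook> %d good codes -> %d sgRNAs, %d bad codes (%s digits)\n",
    length(x$good), length(unique(x$good)), length(x$bad), x$n_digits))
  invisible(x)
}

codebook_digit_matrix <- function(cb) {
  m <- do.call(rbind, lapply(names(cb$good), trit_digits))
  rownames(m) <- names(cb$good)
  m
}

#' Error-correcting decoding of a called barcode
#'
#' Decoding policy: an exact, fully called match to a good code is
#' assigned with zero corrections; an exact match to a bad code is
#' rejected. Otherwise all good codes within trit distance
#' `max_correction` of the called code are collected, treating uncalled
#' digits as free wildcards: a unique candidate is assigned (with
#' `corrected_digits` equal to its distance), several candidates are
#' rejected as ambiguous, and none as no-match.
#'
#' @param called trit vector or code string (`NA`/`"N"` allowed).
#' @param cb a [codebook()].
#' @param max_correction maximum number of corrected trits (default 1).
#' @return list: `status` (one of `assigned`, `rejected_no_match`,
#'   `rejected_ambiguous`, `rejected_bad_code`), `sgrna` (or `NA`),
#'   `corrected_digits`, `n_uncalled`.
#' @export
decode <- function(called, cb, max_correction = 1L) {
  if (!inherits(cb, "codebook")) stop("`cb` must be a codebook")
  if (length(cb$good) == 0) stop("codebook has no good codes")
  if (max_correction < 0) stop("`max_correction` must be >= 0")
  if (is.character(called)) called <- trit_digits(called)
  if (length(called) != cb$n_digits)
    stop("called code length does not match codebook")
  res <- function(status, sgrna = NA_character_, k = NA_integer_) {
    list(status = status, sgrna = unname(sgrna), corrected_digits = k,
         n_uncalled = sum(is.na(called)))
  }
  fully_called <- !anyNA(called)
  if (fully_called) {
    key <- trit_string(called)
    if (key %in% cb$bad) return(res("rejected_bad_code"))
    if (key %in% names(cb$good)) return(res("assigned", cb$good[[key]], 0L))
  }
  gm <- codebook_digit_matrix(cb)
  d <- colSums(t(gm) != called, na.rm = TRUE)
  cand <- which(d <= max_correction)
  if (length(cand) == 0) return(res("rejected_no_match"))
  if (length(cand) > 1) return(res("rejected_ambiguous"))
  res("assigned", cb$good[[cand]], as.integer(d[cand]))
}

#' Decode a table of per-cell readouts
#'
#' Vectorized cell-level pipeline: [call_trits()] per cell followed by
#' [decode()] against the codebook, with identical per-cell semantics.
#'
#' @param readouts long-format data.frame with columns `cell_id`,
#'   `round`, `channel_value` (0/1/2), `intensity`.
#' @param cb a [codebook()].
#' @inheritParams call_trits
#' @inheritParams decode
#' @return data.frame: `cell_id`, `called_code`, `status`, `sgrna`,
#'   `corrected_digits`, `n_uncalled`.
#' @export
decode_cells <- function(readouts, cb, min_ratio = 2, max_correction = 1L) {
  stopifnot(all(c("cell_id", "round", "channel_value", "intensity")
                %in% names(readouts)))
  if (length(cb$good) == 0) stop("codebook has no good codes")
  cells <- unique(readouts$cell_id)
  n_rounds <- cb$n_digits
  cell_idx <- match(readouts$cell_id, cells)

  # per-cell trit calling, vectorized over the (cell, round, channel) cube
  cube <- array(0, dim = c(length(cells), n_rounds, 3L))
  cube[cbind(cell_idx, readouts$round, readouts$channel_value + 1L)] <-
    readouts$intensity
  if (any(cube < 0) || anyNA(cube))
    stop("intensities must be non-negative and finite")
  i1 <- cube[, , 1]; i2 <- cube[, , 2]; i3 <- cube[, , 3]
  top <- pmax(i1, i2, i3)
  tot <- i1 + i2 + i3
  mid_lo <- tot - top                      # second + third
  third <- pmin(i1, i2, i3)
  second <- mid_lo - third
  arg <- max.col(matrix(c(i1, i2, i3), ncol = 3L), ties.method = "first") - 1L
  arg <- matrix(arg, nrow = length(cells))
  quality <- ifelse(top == 0, 0, ifelse(second == 0, Inf, top / second))
  digits <- matrix(as.integer(arg), nrow = length(cells))
  digits[quality < min_ratio | top == 0] <- NA_integer_

  # wildcard trit distance of every cell code to every good code
  gm <- codebook_digit_matrix(cb)
  D <- matrix(0L, length(cells), nrow(gm))
  for (k in seq_len(n_rounds)) {
    dk <- outer(digits[, k], gm[, k], "!=")
    dk[is.na(dk)] <- FALSE
    D <- D + dk
  }
  n_cand <- rowSums(D <= max_correction)
  best <- max.col(-D, ties.method = "first")
  best_d <- D[cbind(seq_len(length(cells)), best)]
  fully_called <- !apply(digits, 1L, anyNA)
  keys <- apply(digits, 1L, trit_string)

  status <- ifelse(n_cand == 0, "rejected_no_match",
            ifelse(n_cand > 1, "rejected_ambiguous", "assigned"))
  # exact full-length matches short-circuit the radius rule
  exact_good <- fully_called & keys %in% names(cb$good)
  status[exact_good] <- "assigned"
  status[fully_called & keys %in% cb$bad] <- "rejected_bad_code"
  assigned <- status == "assigned"
  sgrna <- rep(NA_character_, length(cells))
  sgrna[exact_good] <- unname(cb$good[keys[exact_good]])
  rest <- assigned & !exact_good
  sgrna[rest] <- unname(cb$good[best[rest]])
  corrected <- rep(NA_integer_, length(cells))
  corrected[exact_good] <- 0L
  corrected[rest] <- best_d[rest]

  data.frame(cell_id = cells, called_code = keys, status = status,
             sgrna = sgrna, corrected_digits = corrected,
             n_uncalled = rowSums(is.na(digits)),
             stringsAsFactors = FALSE)
}
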