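#' Join sgRNA and barcode read tables by shared UMIs
#'
#' The sgRNA-barcode correspondence is recovered from two sequencing
#' libraries through the 20-nt unique molecular identifier (UMI) both
#' amplicons share: only UMIs present in both quality-filtered tables
#' are retained, and each shared UMI contributes one (sgRNA, code)
#' association. Barcode reads may carry a full code or a left/right
#' partial code pair, which is assembled with
#' [assemble_partial_codes()]; UMIs whose partials fail to assemble are
#' dropped.
#'
#' @param sgrna_table data.frame with columns `umi`, `payload`
#'   (sgRNA id, already validated against the library) and `pass_qc`.
#' @param barcode_table data.frame with columns `umi`, `payload_type`
#'   (`barcode_full`, `barcode_left` or `barcode_right`), `payload`
#'   (code string, `"N"` for unread digits) and `pass_qc`.
#' @param n_digits barcode length (default 10).
#' @return data.frame of associations: `umi`, `sgrna`, `code`
#'   (one row per retained UMI).
#' @export
join_by_umi <- function(sgrna_table, barcode_table, n_digits = 10L) {
  stopifnot(all(c("umi", "payload") %in% names(sgrna_table)),
            all(c("umi", "payload") %in% names(barcode_table)))
  if ("pass_qc" %in% names(sgrna_table))
    sgrna_table <- sgrna_table[as.logical(sgrna_table$pass_qc), ]
  if ("pass_qc" %in% names(barcode_table))
    barcode_table <- barcode_table[as.logical(barcode_table$pass_qc), ]
  shared <- intersect(sgrna_table$umi, barcode_table$umi)
  if (length(shared) == 0) {
    warning("no shared UMIs between the sgRNA and barcode tables")
    return(data.frame(umi = character(), sgrna = character(),
                      code = character(), stringsAsFactors = FALSE))
  }
  if (!"payload_type" %in% names(barcode_table))
    barcode_table$payload_type <- "barcode_full"
  out <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    u <- shared[i]
    sg <- unique(sgrna_table$payload[sgrna_table$umi == u])
    bt <- barcode_table[barcode_table$umi == u, ]
    code <- NA_character_
    full <- bt$payload[bt$payload_type == "barcode_full"]
    if (length(full)) {
      code <- full[1]
      if (anyNA(suppressWarnings(trit_digits(code)))) code <- NA_character_
    } else {
      left <- bt$payload[bt$payload_type == "barcode_left"]
      right <- bt$payload[bt$payload_type == "barcode_right"]
      if (length(left) && length(right)) {
        asm <- assemble_partial_codes(left[1], right[1], n_digits)
        if (!is.null(asm)) code <- trit_string(asm)
      }
    }
    if (!is.na(code))
      out[[i]] <- data.frame(umi = u, sgrna = sg, code = code,
                             stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(umi = character(), sgrna = character(),
                      code = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Assemble a full barcode from two end-anchored partial codes
#'
#' Sequencing reads cover the barcode from both ends, so each read pair
#' yields a left partial (a contiguous run of called digits anchored at
#' digit 1) and a right partial (anchored at the last digit). If the two
#' runs overlap and agree on every shared position, their union is the
#' full code; a conflict or a gap between the runs is an assembly
#' failure.
#'
#' @param left,right trit vectors of length `n_digits` with `NA` for
#'   unread digits, or code strings with `"N"`.
#' @param n_digits barcode length.
#' @return integer trit vector of length `n_digits`, or `NULL` on
#'   failure.
#' @export
assemble_partial_codes <- function(left, right, n_digits = 10L) {
  if (is.character(left)) left <- trit_digits(left)
  if (is.character(right)) right <- trit_digits(right)
  if (length(left) != n_digits || length(right) != n_digits)
    stop("partial codes must be full-frame vectors of length n_digits")
  lcall <- which(!is.na(left))
  rcall <- which(!is.na(right))
  if (length(lcall) == 0 || length(rcall) == 0) return(NULL)
  # anchoring: left run starts at 1, right run ends at n_digits,
  # both contiguous
  if (lcall[1] != 1L || any(diff(lcall) != 1L)) return(NULL)
  if (rcall[length(rcall)] != n_digits || any(diff(rcall) != 1L)) return(NULL)
  ov <- intersect(lcall, rcall)
  if (length(ov) == 0) return(NULL)                 # gap or abutting ends
  if (any(left[ov] != right[ov])) return(NULL)      # conflict
  full <- left
  full[rcall] <- right[rcall]
  if (anyNA(full)) return(NULL)
  full
}

#' Classify codes as good or bad from sgRNA-code associations
#'
#' An sgRNA supports a code when at least `min_reads` UMI-distinct
#' associations link them. Codes with exactly one supporting sgRNA are
#' good (uniquely decodable), codes with two or more are bad (rejected
#' at decoding), and codes with no supporter above threshold are
#' excluded from the codebook.
#'
#' @param pairs data.frame with columns `sgrna` and `code` (one row per
#'   UMI-distinct association), e.g. from [join_by_umi()].
#' @param min_reads minimum UMI-distinct associations per (code, sgRNA)
#'   (default 2; suppresses singleton chimeras).
#' @return a [codebook()].
#' @export
classify_codes <- function(pairs, min_reads = 2L) {
  stopifnot(all(c("sgrna", "code") %in% names(pairs)), nrow(pairs) > 0)
  counts <- as.data.frame(table(code = pairs$code, sgrna = pairs$sgrna),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq >= min_reads, ]
  supp <- table(counts$code)
  good_codes <- names(supp)[supp == 1]
  bad_codes <- names(supp)[supp >= 2]
  good <- counts$sgrna[match(good_codes, counts$code)]
  names(good) <- good_codes
  codebook(good, bad_codes)
}

#' Library-level QC of a codebook against the designed sgRNA library
#'
#' @param cb a [codebook()].
#' @param library sgRNA library data.frame with a `sgrna` column (see
#'   [make_library()]).
#' @return list: `n_designed`, `n_detected`, `dropout_rate` (fraction),
#'   `dropout_pct` (percentage rounded to one decimal for reporting),
#'   `n_good_codes`, `n_bad_codes`, `reads_per_sgrna` (good codes per
#'   designed sgRNA).
#' @export
library_qc <- function(cb, library) {
  stopifnot("sgrna" %in% names(library))
  designed <- unique(library$sgrna)
  detected <- intersect(designed, unique(unname(cb$good)))
  n_designed <- length(designed)
  n_detected <- length(detected)
  rate <- (n_designed - n_detected) / n_designed
  codes_per <- table(factor(unname(cb$good), levels = designed))
  list(n_designed = n_designed, n_detected = n_detected,
       dropout_rate = rate, dropout_pct = round(100 * rate, 1),
       n_good_codes = length(cb$good), n_bad_codes = length(cb$bad),
       codes_per_sgrna = codes_per)
}

#' Screen design summary
#'
#' Bookkeeping for the screen scale: imaging targets are the traced
#' TADs plus the cellular stains read in the final rounds (nuclear DNA,
#' total protein, cell-cycle marker), and every (imaging target,
#' perturbation) combination is an assayed phenotype cell.
#'
#' @param n_sgrna number of perturbations (default 420).
#' @param n_tads traced genomic targets (default 27).
#' @param n_cellular cellular stain targets (default 3).
#' @return list with `n_imaging_targets` and `n_combinations`.
#' @export
screen_summary <- function(n_sgrna = 420L, n_tads = 27L, n_cellular = 3L) {
  n_targets <- n_tads + n_cellular
  list(n_imaging_targets = n_targets,
       n_combinations = n_sgrna * n_targets)
}
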