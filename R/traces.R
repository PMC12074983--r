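#' Chromatin traces and compartment profiles
#'
#' A chromatin trace is the ordered set of 3D positions (nm) of the
#' traced genomic targets (27 TADs spanning chr22 in the default
#' design) for one chromosome copy. A trace is represented as an
#' `n_tad x 3` numeric matrix; a missing (undetected) target is a row
#' of `NA`. Trace tables on disk are long-format TSVs (`cell_id`,
#' `trace_id`, `tad_index`, `x_nm`, `y_nm`, `z_nm`); populations are
#' held as an `n_traces x n_tad x 3` array (see [trace_array()]).
#'
#' @name chromatin-traces
NULL

#' Compartment profile constructor
#'
#' Per-TAD A/B compartment annotation: a discrete label, the
#' continuous compartment score (A-positive convention) and the
#' genomic midpoint of the TAD's traced region.
#'
#' @param label character vector over \{"A","B"\}.
#' @param score numeric compartment scores; sign must agree with the
#'   label unless `check_sign = FALSE`.
#' @param midpoint_bp integer genomic midpoints, strictly increasing.
#' @param chrom chromosome name (annotation only).
#' @param check_sign enforce label A <=> score > 0.
#' @return data.frame of class `compartment_profile` with columns
#'   `tad_index`, `chrom`, `midpoint_bp`, `label`, `score`.
#' @export
compartment_profile <- function(label, score, midpoint_bp,
                                chrom = "chr22", check_sign = TRUE) {
  n <- length(label)
  stopifnot(length(score) == n, length(midpoint_bp) == n)
  if (!all(label %in% c("A", "B"))) stop("labels must be 'A' or 'B'")
  if (any(diff(midpoint_bp) <= 0))
    stop("genomic midpoints must be strictly increasing")
  if (check_sign && any((label == "A") != (score > 0)))
    stop("label/score sign mismatch (label A <=> score > 0); ",
         "use check_sign = FALSE to override")
  out <- data.frame(tad_index = seq_len(n), chrom = chrom,
                    midpoint_bp = as.numeric(midpoint_bp),
                    label = label, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  class(out) <- c("compartment_profile", "data.frame")
  out
}

as_positions <- function(trace) {
  pos <- as.matrix(trace)
  if (ncol(pos) != 3) stop("a trace must be an n_tad x 3 matrix")
  storage.mode(pos) <- "double"
  pos[!stats::complete.cases(pos), ] <- NA_real_
  pos
}

n_observed <- function(pos) sum(stats::complete.cases(pos))

#' All pairwise Euclidean distances of a trace
#'
#' @param trace `n_tad x 3` position matrix (nm), `NA` rows = missing.
#' @return symmetric `n_tad x n_tad` matrix of distances (nm); entries
#'   touching a missing target are `NA`; zero diagonal on observed
#'   targets. For the 27-TAD design there are 351 distinct inter-TAD
#'   pairs.
#' @export
pairwise_distances <- function(trace) {
  pos <- as_positions(trace)
  if (n_observed(pos) < 2)
    stop("degenerate trace: fewer than 2 observed positions")
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- NULL
  miss <- !stats::complete.cases(pos)
  d[miss, ] <- NA_real_
  d[, miss] <- NA_real_
  diag(d)[!miss] <- 0
  d
}

#' Distances between genomically adjacent targets
#'
#' @inheritParams pairwise_distances
#' @return numeric vector of length `n_tad - 1`; element k is the
#'   distance between targets k and k+1 (`NA` if either is missing).
#' @export
adjacent_distances <- function(trace) {
  d <- pairwise_distances(trace)
  n <- nrow(d)
  d[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)]
}

#' Contact matrix at a spatial threshold
#'
#' Two nonadjacent targets closer than `threshold_nm` (strict `<`) are
#' in contact. Adjacent pairs and the diagonal are not applicable and
#' are returned as `NA`, as are pairs with a missing endpoint.
#'
#' @param dist distance matrix from [pairwise_distances()].
#' @param threshold_nm contact threshold in nm (default 500).
#' @return logical matrix; `TRUE` = contact.
#' @export
contact_matrix <- function(dist, threshold_nm = 500) {
  if (threshold_nm <= 0) stop("`threshold_nm` must be positive")
  ct <- dist < threshold_nm
  n <- nrow(ct)
  sep <- abs(row(ct) - col(ct))
  ct[sep < 2] <- NA
  ct
}

#' Index pairs of traced targets
#'
#' All (i, j) pairs with i < j, ordered row-major; this is the column
#' order of [population_pair_distances()]. 27 targets give 351 pairs.
#'
#' @param n_tad number of traced targets.
#' @return two-column integer matrix.
#' @export
tad_pairs <- function(n_tad) {
  idx <- which(upper.tri(matrix(0, n_tad, n_tad)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# pair class labels ("AA"/"AB"/"BB"), index separation and genomic
# separation for every i<j pair of a profile
pair_annotation <- function(profile) {
  pr <- tad_pairs(nrow(profile))
  lab <- apply(cbind(profile$label[pr[, 1]], profile$label[pr[, 2]]), 1,
               function(x) paste(sort(x), collapse = ""))
  data.frame(i = pr[, 1], j = pr[, 2], class = lab,
             sep = pr[, 2] - pr[, 1],
             genomic_sep = abs(profile$midpoint_bp[pr[, 2]] -
                               profile$midpoint_bp[pr[, 1]]))
}

#' Compartmental long-range contact frequencies of one trace
#'
#' Long-range (nonadjacent) contacts are split by the compartment
#' labels of the two targets: A-A, A-B and B-B. Each frequency is the
#' number of observed nonadjacent pairs of that label combination in
#' contact divided by the number observed; a combination with no
#' observed pair is `NA`.
#'
#' @inheritParams pairwise_distances
#' @param profile a [compartment_profile()] covering all targets.
#' @param threshold_nm contact threshold in nm (default 500).
#' @return named numeric vector `c(AA =, AB =, BB =)`.
#' @export
compartment_contact_frequencies <- function(trace, profile,
                                            threshold_nm = 500) {
  pos <- as_positions(trace)
  if (nrow(pos) != nrow(profile))
    stop("profile length does not match trace")
  ct <- contact_matrix(pairwise_distances(pos), threshold_nm)
  ann <- pair_annotation(profile)
  v <- ct[cbind(ann$i, ann$j)]
  out <- vapply(c("AA", "AB", "BB"), function(cl) {
    x <- v[ann$class == cl]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  out
}

#' Radius of gyration of a trace
#'
#' Root-mean-square distance of the observed positions from their
#' centroid; missing targets are excluded from both the centroid and
#' the mean.
#'
#' @inheritParams pairwise_distances
#' @return length in nm.
#' @export
radius_of_gyration <- function(trace) {
  pos <- as_positions(trace)
  obs <- pos[stats::complete.cases(pos), , drop = FALSE]
  if (nrow(obs) < 2)
    stop("degenerate trace: fewer than 2 observed positions")
  ctr <- colMeans(obs)
  sqrt(mean(rowSums(sweep(obs, 2, ctr)^2)))
}

#' Convert a long trace table to a trace array
#'
#' @param df trace table with columns `cell_id`, `trace_id`,
#'   `tad_index` (1-based), `x_nm`, `y_nm`, `z_nm`.
#' @param n_tad number of traced targets (default 27).
#' @return `n_traces x n_tad x 3` array; dimension 1 is named by
#'   trace id, with the owning cell ids in attribute `cell_id`.
#' @export
trace_array <- function(df, n_tad = 27L) {
  need <- c("cell_id", "trace_id", "tad_index", "x_nm", "y_nm", "z_nm")
  stopifnot(all(need %in% names(df)))
  if (any(df$tad_index < 1 | df$tad_index > n_tad))
    stop("tad_index outside 1..", n_tad)
  ids <- unique(df$trace_id)
  arr <- array(NA_real_, dim = c(length(ids), n_tad, 3L),
               dimnames = list(ids, NULL, c("x", "y", "z")))
  ti <- match(df$trace_id, ids)
  arr[cbind(ti, df$tad_index, 1L)] <- df$x_nm
  arr[cbind(ti, df$tad_index, 2L)] <- df$y_nm
  arr[cbind(ti, df$tad_index, 3L)] <- df$z_nm
  attr(arr, "cell_id") <- df$cell_id[match(ids, df$trace_id)]
  arr
}

#' Pairwise distances for a whole trace population
#'
#' @param arr trace array from [trace_array()].
#' @return `n_traces x n_pairs` matrix of distances (nm), pairs ordered
#'   as [tad_pairs()]; `NA` where an endpoint is missing.
#' @export
population_pair_distances <- function(arr) {
  n_tad <- dim(arr)[2]
  pr <- tad_pairs(n_tad)
  dx <- arr[, pr[, 1], 1, drop = FALSE] - arr[, pr[, 2], 1, drop = FALSE]
  dy <- arr[, pr[, 1], 2, drop = FALSE] - arr[, pr[, 2], 2, drop = FALSE]
  dz <- arr[, pr[, 1], 3, drop = FALSE] - arr[, pr[, 2], 3, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  matrix(d, nrow = dim(arr)[1],
         dimnames = list(dimnames(arr)[[1]], NULL))
}

#' Per-trace compartmental contact frequencies for a population
#'
#' @inheritParams population_pair_distances
#' @inheritParams compartment_contact_frequencies
#' @return `n_traces x 3` matrix with columns AA, AB, BB.
#' @export
population_contact_frequencies <- function(arr, profile,
                                           threshold_nm = 500) {
  d <- population_pair_distances(arr)
  ann <- pair_annotation(profile)
  keep <- ann$sep >= 2
  contact <- d[, keep, drop = FALSE] < threshold_nm
  cls <- ann$class[keep]
  out <- sapply(c("AA", "AB", "BB"), function(cl)
    rowMeans(contact[, cls == cl, drop = FALSE], na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out
}

#' Fraction of observed targets per trace (QC)
#'
#' @inheritParams population_pair_distances
#' @return numeric vector in \[0,1\], one value per trace.
#' @export
trace_completeness <- function(arr) {
  rowMeans(!is.na(arr[, , 1, drop = FALSE]))
}
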