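#' Perturbation-level screen statistics
#'
#' Phenotypes are aggregated per sgRNA against the pooled non-targeting
#' control traces. Distance phenotypes (adjacent-TAD and overall
#' inter-TAD distance) are paired by TAD pair: the per-pair median
#' distances of the perturbation are compared with the control medians
#' by a two-sided Wilcoxon signed-rank test. Contact-frequency and
#' nuclear phenotypes compare per-trace (or per-cell) values by a
#' two-sided Wilcoxon rank-sum test. FDR is Benjamini-Hochberg across
#' perturbations, one family per phenotype.
#'
#' @name screen-statistics
NULL

pair_medians <- function(dist_mat, min_obs = 5L) {
  m <- apply(dist_mat, 2, stats::median, na.rm = TRUE)
  n_obs <- colSums(!is.na(dist_mat))
  m[n_obs < min_obs] <- NA_real_
  m
}

#' log2 fold-change matrix of median pair distances
#'
#' Entry (i, j) is `log2(median d(i,j) in perturbation / median in
#' control)`, medians taken over the traces with that pair observed.
#' Pairs observed in fewer than `min_obs` traces in either group are
#' `NA`.
#'
#' @param perturb_arr,control_arr trace arrays ([trace_array()]).
#' @param min_traces minimum traces in the perturbation group
#'   (default 20).
#' @param min_obs minimum per-pair observations per group (default 5).
#' @return symmetric `n_tad x n_tad` matrix, `NA` diagonal.
#' @export
log2fc_distance_matrix <- function(perturb_arr, control_arr,
                                   min_traces = 20L, min_obs = 5L) {
  if (dim(perturb_arr)[1] < min_traces)
    stop("perturbation group below `min_traces` traces")
  n_tad <- dim(perturb_arr)[2]
  mp <- pair_medians(population_pair_distances(perturb_arr), min_obs)
  mc <- pair_medians(population_pair_distances(control_arr), min_obs)
  v <- log2(mp / mc)
  pr <- tad_pairs(n_tad)
  out <- matrix(NA_real_, n_tad, n_tad)
  out[pr] <- v
  out[pr[, 2:1, drop = FALSE]] <- v
  out
}

#' Distance test between a perturbation and the control pool
#'
#' Compares inter-TAD distances over a pair set (the 26 adjacent
#' pairs, all 351 pairs, or a custom index set). The effect size is
#' always the mean per-pair log2 fold change of median distances.
#'
#' Two p-value methods are offered. The default, `"trace_ranksum"`,
#' summarizes each trace by its mean log2 ratio to the control
#' per-pair medians over the pair set and compares the two groups of
#' per-trace summaries with a two-sided Wilcoxon rank-sum test; traces
#' are independent sampling units, so this test is calibrated under
#' the null. `"pair_signedrank"` pairs the per-pair median distances
#' of the two groups and applies a two-sided Wilcoxon signed-rank test
#' across pairs — the classical display statistic for per-pair
#' fold-change profiles; note that per-pair medians share traces and
#' are therefore positively correlated, which makes this variant
#' anti-conservative as a null-calibrated test (see the methods
#' vignette).
#'
#' @inheritParams log2fc_distance_matrix
#' @param pair_set `"adjacent"`, `"all"`, or an integer vector of pair
#'   indices into [tad_pairs()] order.
#' @param min_pairs minimum usable pairs (default 6; below it the test
#'   is flagged insufficient and `p` is `NA`).
#' @param method `"trace_ranksum"` (default) or `"pair_signedrank"`.
#' @return list: `p`, `log2fc`, `n_pairs`, `insufficient`.
#' @export
distance_test <- function(perturb_arr, control_arr, pair_set = "all",
                          min_traces = 20L, min_obs = 5L,
                          min_pairs = 6L,
                          method = c("trace_ranksum",
                                     "pair_signedrank")) {
  method <- match.arg(method)
  n_tad <- dim(perturb_arr)[2]
  ann_sep <- tad_pairs(n_tad)[, 2] - tad_pairs(n_tad)[, 1]
  idx <- if (is.character(pair_set)) {
    switch(pair_set,
           adjacent = which(ann_sep == 1),
           all = seq_along(ann_sep),
           stop("unknown pair_set"))
  } else as.integer(pair_set)
  Dp <- population_pair_distances(perturb_arr)[, idx, drop = FALSE]
  Dc <- population_pair_distances(control_arr)[, idx, drop = FALSE]
  mp <- pair_medians(Dp, min_obs)
  mc <- pair_medians(Dc, min_obs)
  ok <- !is.na(mp) & !is.na(mc)
  lfc <- mean(log2(mp[ok] / mc[ok]))
  if (sum(ok) < min_pairs || dim(perturb_arr)[1] < min_traces)
    return(list(p = NA_real_, log2fc = lfc, n_pairs = sum(ok),
                insufficient = TRUE))
  if (method == "pair_signedrank") {
    diffs <- mp[ok] - mc[ok]
    p <- if (all(diffs == 0)) 1 else
      stats::wilcox.test(mp[ok], mc[ok], paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value
  } else {
    tp <- rowMeans(log2(sweep(Dp[, ok, drop = FALSE], 2, mc[ok], `/`)),
                   na.rm = TRUE)
    tc <- rowMeans(log2(sweep(Dc[, ok, drop = FALSE], 2, mc[ok], `/`)),
                   na.rm = TRUE)
    tp <- tp[is.finite(tp)]
    tc <- tc[is.finite(tc)]
    p <- if (identical(sort(tp), sort(tc))) 1 else
      stats::wilcox.test(tp, tc, exact = FALSE,
                         correct = TRUE)$p.value
  }
  list(p = p, log2fc = lfc, n_pairs = sum(ok), insufficient = FALSE)
}

#' Rank-sum test on per-trace contact frequencies
#'
#' Two-sided Wilcoxon rank-sum test comparing per-trace contact
#' frequencies of the perturbation against the control pool; the
#' effect size is the log2 ratio of group means (with a pseudocount of
#' 1e-3 applied to both means when either is zero).
#'
#' @param perturb_freqs,control_freqs numeric vectors of per-trace
#'   frequencies (one compartment class), `NA` dropped.
#' @param min_traces minimum perturbation group size (default 20).
#' @param eps pseudocount for zero means.
#' @return list: `p`, `log2fc`, `n`, `insufficient`.
#' @export
contact_test <- function(perturb_freqs, control_freqs, min_traces = 20L,
                         eps = 1e-3) {
  x <- perturb_freqs[!is.na(perturb_freqs)]
  y <- control_freqs[!is.na(control_freqs)]
  mx <- mean(x); my <- mean(y)
  if (length(x) == 0 || length(y) == 0 || mx == 0 || my == 0) {
    mx <- mx + eps; my <- my + eps
  }
  lfc <- log2(mx / my)
  if (length(x) < min_traces)
    return(list(p = NA_real_, log2fc = lfc, n = length(x),
                insufficient = TRUE))
  # exact null distribution when it is computable (small untied
  # groups); normal approximation otherwise
  use_exact <- length(x) < 50 && length(y) < 50 &&
    !anyDuplicated(c(x, y))
  p <- if (identical(sort(x), sort(y))) 1 else
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  list(p = p, log2fc = lfc, n = length(x), insufficient = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up BH over the non-missing p values; missing entries stay
#' missing. Output satisfies `FDR >= p` elementwise.
#'
#' @param p numeric vector of p values in \[0,1\] (`NA` allowed).
#' @return numeric vector of FDR values, same length and order.
#' @export
fdr_correct <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call screen hits from a phenotype table
#'
#' Per phenotype and direction, perturbations passing `FDR <
#' fdr_threshold` and `|log2fc| >= effect_floor` are ranked by
#' `|log2fc|`; non-targeting controls are never listed.
#'
#' @param phenotypes data.frame with columns `sgrna`, `phenotype`,
#'   `log2fc`, `fdr` and logical `is_control`.
#' @param fdr_threshold FDR cut-off (default 0.1).
#' @param effect_floor minimum `|log2fc|` (default 0.15: about half
#'   the smallest effect the screen is designed to detect, a 20%
#'   distance change with |log2fc| = 0.32, and above the null log2fc
#'   dispersion at typical per-sgRNA trace counts; guards against
#'   significance without effect at large n).
#' @param top_k retain at most this many hits per phenotype and
#'   direction (default all).
#' @return data.frame of hits with a `direction` column ("up"/"down"),
#'   ranked within phenotype by `|log2fc|`.
#' @export
call_hits <- function(phenotypes, fdr_threshold = 0.1,
                      effect_floor = 0.15, top_k = Inf) {
  need <- c("sgrna", "phenotype", "log2fc", "fdr", "is_control")
  stopifnot(all(need %in% names(phenotypes)))
  h <- phenotypes[!phenotypes$is_control &
                  !is.na(phenotypes$fdr) &
                  phenotypes$fdr < fdr_threshold &
                  abs(phenotypes$log2fc) >= effect_floor, , drop = FALSE]
  if (nrow(h) == 0) {
    h$direction <- character(0)
    return(h)
  }
  h$direction <- ifelse(h$log2fc > 0, "up", "down")
  h <- h[order(h$phenotype, h$direction, -abs(h$log2fc), h$sgrna), ]
  keep <- unlist(lapply(split(seq_len(nrow(h)),
                              paste(h$phenotype, h$direction)),
                        function(i) utils::head(i, top_k)))
  h <- h[sort(keep), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Average A/B compartment score matrix
#'
#' Converts the 1D compartment score profile into a symmetric 2D
#' matrix: entry (i, j) is the mean of the two TADs' scores.
#'
#' @param profile a [compartment_profile()].
#' @return symmetric `n_tad x n_tad` numeric matrix.
#' @export
ab_score_matrix <- function(profile) {
  s <- profile$score
  outer(s, s, `+`) / 2
}

#' Pearson correlation between two effect matrices
#'
#' Correlates the upper-triangle entries of two symmetric matrices
#' (pairwise-complete), with the two-sided t test
#' `t = r sqrt((n-2)/(1-r^2))` and a Fisher-z 95% confidence interval.
#'
#' @param m1,m2 matrices of identical shape.
#' @param min_points minimum paired entries (default 10).
#' @return list: `r`, `p`, `ci` (length-2), `n_points`,
#'   `insufficient`.
#' @export
correlate_effect_matrices <- function(m1, m2, min_points = 10L) {
  if (!all(dim(m1) == dim(m2))) stop("matrices must share shape")
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_points)
    return(list(r = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n_points = n, insufficient = TRUE))
  r <- stats::cor(x[ok], y[ok])
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  list(r = r, p = p, ci = ci, n_points = n, insufficient = FALSE)
}

#' Split an effect matrix into short- and long-range summaries
#'
#' Short-range pairs are genomic midpoint separations below
#' `cutoff_bp` (default 3 Mb); the summary per class is the mean
#' log2fc over its pairs.
#'
#' @param log2fc_mat symmetric effect matrix.
#' @param profile a [compartment_profile()] providing midpoints.
#' @param cutoff_bp separation cut-off in bp (default 3e6).
#' @return named vector `c(short =, long =)`; a class with no pairs is
#'   `NA`.
#' @export
short_long_range_split <- function(log2fc_mat, profile,
                                   cutoff_bp = 3e6) {
  ann <- pair_annotation(profile)
  v <- log2fc_mat[cbind(ann$i, ann$j)]
  short <- ann$genomic_sep < cutoff_bp
  m <- function(x) if (length(x) == 0) NA_real_ else mean(x, na.rm = TRUE)
  c(short = m(v[short]), long = m(v[!short]))
}

#' Hierarchical clustering of hit effect matrices
#'
#' Vectorizes the upper triangle of each hit's log2fc distance matrix,
#' computes pairwise Pearson correlations, and clusters with average
#' linkage on `1 - r`. Hits with zero variance are excluded with a
#' warning. Leaf order is deterministic (ties broken by sgRNA id via
#' the input ordering).
#'
#' @param mats named list of symmetric effect matrices (>= 3 after
#'   exclusions).
#' @return list: `hclust`, `cor_matrix` (ordered by the dendrogram),
#'   `order` (leaf labels), `newick` (dendrogram as a Newick string).
#' @export
cluster_hits <- function(mats) {
  mats <- mats[order(names(mats))]
  vecs <- lapply(mats, function(m) m[upper.tri(m)])
  sds <- vapply(vecs, stats::sd, numeric(1), na.rm = TRUE)
  drop <- is.na(sds) | sds == 0
  if (any(drop)) {
    warning("excluding constant effect matrices: ",
            paste(names(mats)[drop], collapse = ", "))
    vecs <- vecs[!drop]
  }
  if (length(vecs) < 3) stop("need at least 3 non-constant hits")
  vm <- do.call(cbind, vecs)
  cm <- stats::cor(vm, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  ord <- hc$labels[hc$order]
  phylo <- ape::as.phylo(hc)
  list(hclust = hc, cor_matrix = cm[ord, ord], order = ord,
       newick = ape::write.tree(phylo))
}

#' Cross-feature correlations over the top hits
#'
#' Pearson correlation between every pair of per-hit feature log2fc
#' vectors (pairwise-complete), two-sided t test, BH FDR across the
#' feature pairs.
#'
#' @param feature_table data.frame: one row per hit, one numeric
#'   column per feature (an `sgrna` column is ignored if present).
#' @return data.frame: `feature1`, `feature2`, `r`, `p`, `fdr`, `n`.
#' @export
cross_feature_correlation <- function(feature_table) {
  ft <- feature_table[, setdiff(names(feature_table), "sgrna"),
                      drop = FALSE]
  ft <- ft[, vapply(ft, is.numeric, logical(1)), drop = FALSE]
  if (nrow(ft) < 3) stop("need scalar summaries for at least 3 hits")
  feats <- names(ft)
  combs <- utils::combn(length(feats), 2)
  out <- data.frame(
    feature1 = feats[combs[1, ]], feature2 = feats[combs[2, ]],
    r = NA_real_, p = NA_real_, fdr = NA_real_, n = NA_integer_,
    stringsAsFactors = FALSE)
  for (k in seq_len(ncol(combs))) {
    x <- ft[[combs[1, k]]]; y <- ft[[combs[2, k]]]
    ok <- !is.na(x) & !is.na(y)
    out$n[k] <- sum(ok)
    if (sum(ok) < 3) next
    r <- stats::cor(x[ok], y[ok])
    out$r[k] <- r
    if (abs(r) < 1) {
      tt <- r * sqrt((sum(ok) - 2) / (1 - r^2))
      out$p[k] <- 2 * stats::pt(-abs(tt), df = sum(ok) - 2)
    } else out$p[k] <- 0
  }
  out$fdr <- fdr_correct(out$p)
  out
}
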