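# Independent brute-force oracles and small fixture builders used
# across the suite. These deliberately use plain loops and no package
# internals so they stay independent of the implementations they
# check.

bf_pairwise <- function(pos) {
  n <- nrow(pos)
  d <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (anyNA(pos[i, ]) || anyNA(pos[j, ])) next
    d[i, j] <- sqrt(sum((pos[i, ] - pos[j, ])^2))
  }
  d
}

bf_contact_freqs <- function(pos, labels, thr) {
  n <- nrow(pos)
  num <- den <- c(AA = 0, AB = 0, BB = 0)
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (anyNA(pos[i, ]) || anyNA(pos[j, ])) next
    cl <- paste(sort(c(labels[i], labels[j])), collapse = "")
    den[cl] <- den[cl] + 1
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < thr) num[cl] <- num[cl] + 1
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

bf_rg <- function(pos) {
  obs <- pos[!apply(pos, 1, anyNA), , drop = FALSE]
  ctr <- colMeans(obs)
  s <- 0
  for (i in seq_len(nrow(obs))) s <- s + sum((obs[i, ] - ctr)^2)
  sqrt(s / nrow(obs))
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

random_trace <- function(n_tad, scale = 300, missing = 0) {
  pos <- matrix(stats::rnorm(n_tad * 3, sd = scale), ncol = 3)
  if (missing > 0) {
    idx <- sample(n_tad, missing)
    pos[idx, ] <- NA_real_
  }
  pos
}

# small profile with both compartments represented
toy_profile <- function(labels) {
  compartment_profile(labels,
                      ifelse(labels == "A", 0.5, -0.5),
                      seq_along(labels) * 1e6)
}

# long-format trace table from a list of position matrices
traces_to_df <- function(pos_list, cell_ids = NULL) {
  n_tad <- nrow(pos_list[[1]])
  if (is.null(cell_ids)) cell_ids <- sprintf("c%04d", seq_along(pos_list))
  do.call(rbind, lapply(seq_along(pos_list), function(i)
    data.frame(cell_id = cell_ids[i],
               trace_id = sprintf("%s_t1", cell_ids[i]),
               tad_index = seq_len(n_tad),
               x_nm = pos_list[[i]][, 1], y_nm = pos_list[[i]][, 2],
               z_nm = pos_list[[i]][, 3], stringsAsFactors = FALSE)))
}

# readout matrix that cleanly encodes a code (signal 1000, bg 10)
clean_readout <- function(code) {
  d <- trit_digits(code)
  m <- matrix(10, length(d), 3)
  m[cbind(seq_along(d), d + 1L)] <- 1000
  m
}

# digitized solid phantoms on cubic grids
phantom_sphere <- function(r, pad = 5L) {
  n <- 2L * r + 2L * pad
  ax <- seq_len(n) - (n + 1) / 2
  outer(outer(ax^2, ax^2, `+`), ax^2, `+`) <= r^2
}

phantom_cube <- function(s, pad = 6L) {
  n <- s + 2L * pad
  m <- array(FALSE, c(n, n, n))
  m[pad + seq_len(s), pad + seq_len(s), pad + seq_len(s)] <- TRUE
  m
}

phantom_octahedron <- function(r, pad = 6L) {
  n <- 2L * r + 2L * pad
  ax <- abs(seq_len(n) - (n + 1) / 2)
  outer(outer(ax, ax, `+`), ax, `+`) <= r
}

phantom_dumbbell <- function(r, sep, pad = 6L) {
  nx <- 2L * r + sep + 2L * pad
  n <- 2L * r + 2L * pad
  axx <- seq_len(nx) - (nx + 1) / 2
  ax <- seq_len(n) - (n + 1) / 2
  s1 <- outer(outer((axx + sep / 2)^2, ax^2, `+`), ax^2, `+`) <= r^2
  s2 <- outer(outer((axx - sep / 2)^2, ax^2, `+`), ax^2, `+`) <= r^2
  s1 | s2
}
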