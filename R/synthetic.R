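#' Synthetic Perturb-screen generator
#'
#' Generates a complete ground-truth screen — sgRNA library with
#' barcode assignments, NGS-style read tables, noisy per-round barcode
#' readouts, perturbation-scaled chromatin traces and nuclear phantoms
#' — so the whole pipeline is testable end to end. Every generator is
#' a pure function of its arguments and seed.
#'
#' @name synthetic-screen
NULL

index_to_trits <- function(idx, n_digits = 10L, n_values = 3L) {
  out <- integer(n_digits)
  idx <- idx - 1
  for (k in n_digits:1) {
    out[k] <- idx %% n_values
    idx <- idx %/% n_values
  }
  as.integer(out)
}

random_umis <- function(n, width = 20L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' Ternary codes with guaranteed minimum pairwise trit distance 3
#'
#' Constructs a shortened ternary Hamming code: the kernel of a 3 x 10
#' GF(3) check matrix whose columns are pairwise linearly independent
#' (projective points), giving 3^7 = 2187 codewords at minimum
#' distance 3, and samples `n` of them.
#'
#' @param n number of codes (<= 2187 for the 10-digit design).
#' @param n_digits code length (default 10; needs `n_digits <= 13`).
#' @param seed RNG seed for the sample.
#' @return character vector of `n` distinct code strings.
#' @export
make_separated_codes <- function(n, n_digits = 10L, seed = 1L) {
  # projective representatives of GF(3)^3 (first nonzero coord = 1)
  pts <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  pts <- pts[rowSums(pts) > 0, , drop = FALSE]
  first_nz <- apply(pts, 1, function(v) v[which(v != 0)[1]])
  pts <- pts[first_nz == 1, , drop = FALSE]
  if (n_digits > nrow(pts))
    stop("design supports at most ", nrow(pts), " digits")
  H <- t(pts[seq_len(n_digits), , drop = FALSE])    # 3 x n_digits
  # kernel basis of H over GF(3) by Gaussian elimination
  A <- H %% 3
  m <- nrow(A)
  pivots <- integer(0)
  row_i <- 1L
  for (col in seq_len(n_digits)) {
    if (row_i > m) break
    pr <- which(A[row_i:m, col] != 0)
    if (length(pr) == 0) next
    pr <- pr[1] + row_i - 1L
    A[c(row_i, pr), ] <- A[c(pr, row_i), ]
    A[row_i, ] <- (A[row_i, ] * solve_mod3(A[row_i, col])) %% 3
    for (r in seq_len(m)) if (r != row_i && A[r, col] != 0)
      A[r, ] <- (A[r, ] - A[r, col] * A[row_i, ]) %% 3
    pivots <- c(pivots, col)
    row_i <- row_i + 1L
  }
  free <- setdiff(seq_len(n_digits), pivots)
  basis <- matrix(0L, length(free), n_digits)
  for (b in seq_along(free)) {
    v <- integer(n_digits)
    v[free[b]] <- 1L
    for (r in seq_along(pivots))
      v[pivots[r]] <- (-sum(A[r, free] * v[free])) %% 3
    basis[b, ] <- v
  }
  coeffs <- all_codes(length(free), 3L)
  words <- (coeffs %*% basis) %% 3
  if (n > nrow(words))
    stop("at most ", nrow(words), " codes at minimum distance 3")
  set.seed(seed)
  sel <- words[sample(nrow(words), n), , drop = FALSE]
  apply(sel, 1, trit_string)
}

solve_mod3 <- function(a) if (a %% 3 == 1) 1L else 2L  # inverse in GF(3)

#' Synthetic sgRNA library with barcode assignments
#'
#' Builds the designed library (non-targeting controls plus targeting
#' sgRNAs at 2-3 per gene), assigns each sgRNA a unique barcode
#' sampled without replacement from the code space, and derives the
#' codebook. Optional plants: sgRNA dropout (designed sgRNAs absent
#' from the codebook) and bad codes (one code forced onto two
#' sgRNAs, which removes it from the good set).
#'
#' @param n_targeting,n_controls,n_genes library composition
#'   (defaults 410 / 10 / 137, the screen design).
#' @param n_digits,n_values code geometry.
#' @param dropout_rate fraction of designed sgRNAs dropped from the
#'   codebook.
#' @param n_bad_codes number of planted two-sgRNA collisions.
#' @param separated use [make_separated_codes()] (minimum pairwise
#'   distance 3) instead of uniform sampling.
#' @param seed RNG seed.
#' @return list: `library` (data.frame `sgrna`, `gene`, `targeting`,
#'   `protospacer`), `truth` (named code-per-sgRNA vector, the ground
#'   truth including dropped sgRNAs), `codebook` (a [codebook()]).
#' @export
make_library <- function(n_targeting = 410L, n_controls = 10L,
                         n_genes = 137L, n_digits = 10L, n_values = 3L,
                         dropout_rate = 0, n_bad_codes = 0L,
                         separated = FALSE, seed = 1L) {
  if (n_targeting < 2 * n_genes || n_targeting > 3 * n_genes)
    stop("`n_targeting` must allow 2-3 sgRNAs per gene")
  set.seed(seed)
  n_three <- n_targeting - 2L * n_genes          # genes with 3 sgRNAs
  per_gene <- c(rep(3L, n_three), rep(2L, n_genes - n_three))
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  sg_t <- unlist(lapply(seq_len(n_genes), function(g)
    sprintf("sg%s_%d", genes[g], seq_len(per_gene[g]))))
  sg_c <- sprintf("sgNT_%02d", seq_len(n_controls))
  lib <- data.frame(
    sgrna = c(sg_c, sg_t),
    gene = c(rep("NON_TARGETING", n_controls),
             rep(genes, times = per_gene)),
    targeting = c(rep(FALSE, n_controls), rep(TRUE, n_targeting)),
    protospacer = random_umis(n_controls + n_targeting, 20L),
    stringsAsFactors = FALSE)
  n_sg <- nrow(lib)
  space <- enumerate_code_space(n_digits, n_values)
  if (n_sg + n_bad_codes > space) stop("more sgRNAs than codes")
  if (separated) {
    codes <- make_separated_codes(n_sg + n_bad_codes, n_digits,
                                  seed = seed + 1L)
  } else {
    idx <- sample.int(space, n_sg + n_bad_codes)
    codes <- vapply(idx, function(i)
      trit_string(index_to_trits(i, n_digits, n_values)), character(1))
  }
  truth <- codes[seq_len(n_sg)]
  names(truth) <- lib$sgrna
  good <- lib$sgrna
  names(good) <- truth
  bad <- character(0)
  if (n_bad_codes > 0) {
    # each planted bad code is claimed by two targeting sgRNAs
    bad <- codes[n_sg + seq_len(n_bad_codes)]
    good <- good[!names(good) %in% bad]
  }
  if (dropout_rate > 0) {
    n_drop <- round(dropout_rate * n_sg)
    dropped <- sample(lib$sgrna, n_drop)
    good <- good[!good %in% dropped]
  }
  list(library = lib, truth = truth, codebook = codebook(good, bad))
}

#' Synthetic NGS read tables for codebook construction
#'
#' Emits the two quality-filtered read tables of the UMI-join scheme:
#' an sgRNA-UMI table and a barcode-UMI table whose barcode payloads
#' are end-anchored left/right partial codes with a guaranteed
#' overlap. Optional plants: UMIs private to one table, and
#' template-switching pairs that attach a second sgRNA to a code with
#' full UMI support (inducing a bad code downstream).
#'
#' @param truth named code-per-sgRNA vector (see [make_library()]).
#' @param umis_per_pair UMI-distinct reads per (sgRNA, code)
#'   association (default 5).
#' @param n_unshared UMIs present in only one of the two tables.
#' @param switch_codes character vector of codes to template-switch: a
#'   second random sgRNA gains `umis_per_pair` UMIs on that code.
#' @param seed RNG seed.
#' @return list of data.frames `sgrna_table` and `barcode_table` (see
#'   [join_by_umi()]).
#' @export
make_read_tables <- function(truth, umis_per_pair = 5L, n_unshared = 0L,
                             switch_codes = character(), seed = 1L) {
  set.seed(seed)
  n_digits <- nchar(truth[[1]])
  assoc <- data.frame(sgrna = names(truth), code = unname(truth),
                      stringsAsFactors = FALSE)
  for (code in switch_codes) {
    other <- sample(setdiff(names(truth), assoc$sgrna[assoc$code == code]), 1)
    assoc <- rbind(assoc, data.frame(sgrna = other, code = code))
  }
  assoc <- assoc[rep(seq_len(nrow(assoc)), each = umis_per_pair), ]
  assoc$umi <- random_umis(nrow(assoc))
  # split each code into overlapping end-anchored partials
  left <- right <- character(nrow(assoc))
  for (i in seq_len(nrow(assoc))) {
    d <- trit_digits(assoc$code[i])
    lend <- sample(5:8, 1)                 # left covers 1..lend
    rstart <- sample(3:min(6, lend), 1)    # right covers rstart..n
    l <- r <- rep(NA_integer_, n_digits)
    l[1:lend] <- d[1:lend]
    r[rstart:n_digits] <- d[rstart:n_digits]
    left[i] <- trit_string(l)
    right[i] <- trit_string(r)
  }
  sgrna_table <- data.frame(umi = assoc$umi, payload_type = "protospacer",
                            payload = assoc$sgrna, pass_qc = TRUE,
                            stringsAsFactors = FALSE)
  barcode_table <- data.frame(
    umi = rep(assoc$umi, 2),
    payload_type = rep(c("barcode_left", "barcode_right"),
                       each = nrow(assoc)),
    payload = c(left, right), pass_qc = TRUE, stringsAsFactors = FALSE)
  if (n_unshared > 0) {
    extra <- random_umis(2L * n_unshared)
    sgrna_table <- rbind(sgrna_table, data.frame(
      umi = extra[seq_len(n_unshared)], payload_type = "protospacer",
      payload = sample(names(truth), n_unshared, replace = TRUE),
      pass_qc = TRUE))
    barcode_table <- rbind(barcode_table, data.frame(
      umi = extra[n_unshared + seq_len(n_unshared)],
      payload_type = "barcode_full",
      payload = sample(unname(truth), n_unshared, replace = TRUE),
      pass_qc = TRUE))
  }
  list(sgrna_table = sgrna_table, barcode_table = barcode_table)
}

#' Default 27-TAD compartment profile
#'
#' A synthetic stand-in for the chr22 A/B compartment annotation used
#' throughout: 27 TADs with blockwise A/B labels, continuous scores
#' consistent with the labels, and genomic midpoints spaced along the
#' chr22 q arm. Deterministic.
#'
#' @return a [compartment_profile()].
#' @export
default_compartment_profile <- function() {
  label <- c("B", "B", "A", "A", "A", "B", "B", "B", "A", "A",
             "B", "B", "A", "A", "A", "A", "B", "B", "A", "B",
             "B", "A", "A", "B", "A", "A", "A")
  mag <- c(0.8, 0.6, 0.5, 0.9, 0.7, 0.4, 0.8, 0.6, 0.5, 0.8,
           0.3, 0.7, 0.6, 0.9, 0.8, 0.5, 0.4, 0.6, 0.7, 0.5,
           0.8, 0.6, 0.9, 0.3, 0.7, 0.8, 0.6)
  score <- ifelse(label == "A", mag, -mag)
  midpoints <- 17.5e6 + (seq_len(27) - 1) * 1.25e6
  compartment_profile(label, score, midpoints, chrom = "chr22")
}

#' Perturbation effect specification
#'
#' Ground-truth effect of one sgRNA on the generated phenotypes.
#' Distance scale factors act multiplicatively on the named pair
#' class (1 = no effect, 0.8 = 20% compaction); `sphericity_lobe`
#' (0..1) deforms the nuclear phantom into two lobes; `cov_delta`
#' shifts condensate strength (-1 removes the baseline condensates).
#'
#' @param adjacent,aa,ab,bb,global distance scale factors (> 0).
#' @param sphericity_lobe lobe separation fraction.
#' @param cov_delta condensate-strength offset.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(adjacent = 1, aa = 1, ab = 1, bb = 1,
                        global = 1, sphericity_lobe = 0, cov_delta = 0) {
  stopifnot(adjacent > 0, aa > 0, ab > 0, bb > 0, global > 0)
  structure(list(adjacent = adjacent, aa = aa, ab = ab, bb = bb,
                 global = global, sphericity_lobe = sphericity_lobe,
                 cov_delta = cov_delta), class = "effect_spec")
}

get_effect <- function(effects, sgrna) {
  if (!is.null(effects) && sgrna %in% names(effects))
    effects[[sgrna]] else effect_spec()
}

#' Assign cells to sgRNAs
#'
#' @param truth named code-per-sgRNA vector.
#' @param n_cells_per_sgrna cells per perturbation.
#' @param seed RNG seed.
#' @return data.frame `cell_id`, `sgrna`, `code`.
#' @export
make_cells <- function(truth, n_cells_per_sgrna = 120L, seed = 1L) {
  set.seed(seed)
  sg <- rep(names(truth), each = n_cells_per_sgrna)
  data.frame(cell_id = sprintf("cell%06d", seq_along(sg)),
             sgrna = sg, code = unname(truth[sg]),
             stringsAsFactors = FALSE)
}

# one baseline conformation, n_tad x 3, in nm
baseline_trace <- function(n_tad, profile, model, step_sd, cluster_pull,
                           comp_sep, confine_radius) {
  steps <- matrix(stats::rnorm(3 * (n_tad - 1), sd = step_sd),
                  ncol = 3)
  pos <- rbind(0, apply(steps, 2, cumsum))
  if (model == "confined_walk") {
    ctr <- colMeans(pos)
    pos <- sweep(pos, 2, ctr)
    r <- sqrt(rowSums(pos^2))
    over <- r > confine_radius
    pos[over, ] <- pos[over, ] * (confine_radius / r[over])
  }
  is_a <- profile$label == "A"
  ca <- colMeans(pos[is_a, , drop = FALSE])
  cb <- colMeans(pos[!is_a, , drop = FALSE])
  pos[is_a, ] <- sweep(sweep(pos[is_a, , drop = FALSE], 2, ca) *
                         (1 - cluster_pull), 2, ca, `+`)
  pos[!is_a, ] <- sweep(sweep(pos[!is_a, , drop = FALSE], 2, cb) *
                          (1 - cluster_pull), 2, cb, `+`)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  pos[is_a, ] <- sweep(pos[is_a, , drop = FALSE], 2, u * comp_sep / 2, `+`)
  pos[!is_a, ] <- sweep(pos[!is_a, , drop = FALSE], 2, u * comp_sep / 2, `-`)
  pos
}

apply_effects <- function(pos, profile, eff) {
  is_a <- profile$label == "A"
  if (eff$adjacent != 1) {
    steps <- diff(pos) * eff$adjacent
    pos <- rbind(pos[1, ], pos[rep(1, nrow(pos) - 1), , drop = FALSE] +
                   apply(steps, 2, cumsum))
  }
  if (eff$aa != 1) {
    ca <- colMeans(pos[is_a, , drop = FALSE])
    pos[is_a, ] <- sweep(sweep(pos[is_a, , drop = FALSE], 2, ca) * eff$aa,
                         2, ca, `+`)
  }
  if (eff$bb != 1) {
    cb <- colMeans(pos[!is_a, , drop = FALSE])
    pos[!is_a, ] <- sweep(sweep(pos[!is_a, , drop = FALSE], 2, cb) * eff$bb,
                          2, cb, `+`)
  }
  if (eff$ab != 1) {
    ca <- colMeans(pos[is_a, , drop = FALSE])
    cb <- colMeans(pos[!is_a, , drop = FALSE])
    shift <- (eff$ab - 1) / 2 * (ca - cb)
    pos[is_a, ] <- sweep(pos[is_a, , drop = FALSE], 2, shift, `+`)
    pos[!is_a, ] <- sweep(pos[!is_a, , drop = FALSE], 2, shift, `-`)
  }
  if (eff$global != 1) {
    ctr <- colMeans(pos)
    pos <- sweep(sweep(pos, 2, ctr) * eff$global, 2, ctr, `+`)
  }
  pos
}

#' Generate perturbation-scaled chromatin traces
#'
#' Each cell carries 2-4 chromosome traces. The baseline conformation
#' is a Gaussian chain (or confined walk) with compartment-dependent
#' clustering — A targets are pulled toward the A centroid and shifted
#' away from the B centroid — so polarization and compartmental
#' contacts are non-trivial. The cell's sgRNA effect spec then scales
#' the pair classes; localization jitter and random target dropout are
#' applied last.
#'
#' @param cells data.frame from [make_cells()].
#' @param profile a [compartment_profile()].
#' @param effects named list of [effect_spec()] per sgRNA (missing
#'   sgRNAs get the null effect).
#' @param traces_per_cell integer range sampled per cell
#'   (default 2:4).
#' @param baseline_model `"gaussian_chain"` or `"confined_walk"`.
#' @param step_sd per-axis step SD in nm (default 280, giving
#'   adjacent-TAD distances of a few hundred nm).
#' @param cluster_pull compartment clustering strength in \[0,1)
#'   (default 0.35).
#' @param comp_sep A/B centroid separation in nm (default 600).
#' @param confine_radius confinement radius for the confined walk
#'   (default 1200 nm).
#' @param jitter_sd localization error SD per axis in nm (default 50).
#' @param dropout_rate per-target missing probability (default 0.09,
#'   matching the observed-position census of the screen).
#' @param seed RNG seed.
#' @return long trace table: `cell_id`, `trace_id`, `sgrna`,
#'   `tad_index`, `x_nm`, `y_nm`, `z_nm` (dropped targets have `NA`
#'   coordinates).
#' @export
make_traces <- function(cells, profile = default_compartment_profile(),
                        effects = NULL, traces_per_cell = 2:4,
                        baseline_model = c("gaussian_chain",
                                           "confined_walk"),
                        step_sd = 280, cluster_pull = 0.35,
                        comp_sep = 600, confine_radius = 1200,
                        jitter_sd = 50, dropout_rate = 0.09,
                        seed = 1L) {
  baseline_model <- match.arg(baseline_model)
  set.seed(seed)
  n_tad <- nrow(profile)
  n_tr <- sample(traces_per_cell, nrow(cells), replace = TRUE)
  total <- sum(n_tr)
  out_pos <- matrix(NA_real_, total * n_tad, 3)
  trace_id <- character(total)
  trace_cell <- character(total)
  trace_sg <- character(total)
  t_i <- 0L
  for (ci in seq_len(nrow(cells))) {
    eff <- get_effect(effects, cells$sgrna[ci])
    for (k in seq_len(n_tr[ci])) {
      t_i <- t_i + 1L
      pos <- baseline_trace(n_tad, profile, baseline_model, step_sd,
                            cluster_pull, comp_sep, confine_radius)
      pos <- apply_effects(pos, profile, eff)
      pos <- pos + matrix(stats::rnorm(3 * n_tad, sd = jitter_sd),
                          ncol = 3)
      drop <- stats::runif(n_tad) < dropout_rate
      pos[drop, ] <- NA_real_
      out_pos[(t_i - 1L) * n_tad + seq_len(n_tad), ] <- pos
      trace_id[t_i] <- sprintf("%s_t%d", cells$cell_id[ci], k)
      trace_cell[t_i] <- cells$cell_id[ci]
      trace_sg[t_i] <- cells$sgrna[ci]
    }
  }
  data.frame(cell_id = rep(trace_cell, each = n_tad),
             trace_id = rep(trace_id, each = n_tad),
             sgrna = rep(trace_sg, each = n_tad),
             tad_index = rep(seq_len(n_tad), times = total),
             x_nm = out_pos[, 1], y_nm = out_pos[, 2],
             z_nm = out_pos[, 3], stringsAsFactors = FALSE)
}

#' Generate noisy per-round barcode readouts
#'
#' Per cell and round, the channel of the true digit value receives a
#' high lognormal intensity and the other channels background. With
#' probability `miscall_rate` the high signal lands on a wrong channel
#' (a trit miscall); with probability `lowconf_rate` the true signal
#' is attenuated to near background, producing a low-confidence
#' (uncalled) digit.
#'
#' @param cells data.frame from [make_cells()].
#' @param miscall_rate per-round probability of a wrong-channel swap
#'   (< 1/3).
#' @param lowconf_rate per-round probability of signal attenuation.
#' @param signal_meanlog,signal_sdlog lognormal parameters of the
#'   on-channel intensity.
#' @param background_meanlog,background_sdlog lognormal parameters of
#'   the off-channel background.
#' @param seed RNG seed.
#' @return long readout table: `cell_id`, `round`, `channel_value`,
#'   `intensity`.
#' @export
make_readouts <- function(cells, miscall_rate = 0.02,
                          lowconf_rate = 0.02,
                          signal_meanlog = log(1000),
                          signal_sdlog = 0.25,
                          background_meanlog = log(60),
                          background_sdlog = 0.4, seed = 1L) {
  if (miscall_rate >= 1 / 3) stop("`miscall_rate` must be < 1/3")
  set.seed(seed)
  n_digits <- nchar(cells$code[1])
  n_cells <- nrow(cells)
  true_dig <- t(vapply(cells$code, trit_digits, integer(n_digits)))
  n <- n_cells * n_digits
  chan <- as.vector(true_dig)                     # true channel per (cell,round)
  miscall <- stats::runif(n) < miscall_rate
  shift <- sample(1:2, n, replace = TRUE)
  chan[miscall] <- (chan[miscall] + shift[miscall]) %% 3
  lowconf <- stats::runif(n) < lowconf_rate
  bg <- matrix(stats::rlnorm(3 * n, background_meanlog, background_sdlog),
               ncol = 3)
  sig <- stats::rlnorm(n, signal_meanlog, signal_sdlog)
  sig[lowconf] <- bg[cbind(which(lowconf), chan[lowconf] + 1L)][
    seq_len(sum(lowconf))] * 1.2
  inten <- bg
  inten[cbind(seq_len(n), chan + 1L)] <- sig
  # (cell, round) index layout: cells vary fastest (as.vector over the
  # n_cells x n_digits matrices above)
  data.frame(
    cell_id = rep(cells$cell_id, times = 3L * n_digits),
    round = rep(rep(seq_len(n_digits), each = n_cells), times = 3L),
    channel_value = rep(0:2, each = n),
    intensity = as.vector(inten),
    stringsAsFactors = FALSE)
}

#' Generate nuclear phantoms and their features
#'
#' Ellipsoid nuclei with per-cell size jitter; a positive
#' `sphericity_lobe` in the cell's effect spec splits the phantom into
#' two displaced lobes (multi-lobed, lower sphericity), and
#' `cov_delta` scales the brightness of the condensate blobs painted
#' into an otherwise near-uniform intensity field (higher COV).
#'
#' @param cells data.frame from [make_cells()] (subset to the cells
#'   you want phantoms for).
#' @param effects named list of [effect_spec()] per sgRNA.
#' @param radius_um base ellipsoid semi-axes in um.
#' @param voxel_nm voxel size (x, y, z) in nm.
#' @param n_blobs baseline number of condensate blobs.
#' @param blob_amp baseline condensate amplitude relative to the base
#'   intensity.
#' @param seed RNG seed.
#' @return data.frame of per-cell features (`cell_id`, `sgrna`,
#'   `cov`, `sphericity`, `volume_um3`, `area_um2`); with
#'   `keep_images = TRUE`, attribute `images` holds the phantom list.
#' @param keep_images retain the voxel arrays (memory-heavy).
#' @export
make_nuclei <- function(cells, effects = NULL,
                        radius_um = c(3.0, 2.7, 2.2),
                        voxel_nm = c(250, 250, 500), n_blobs = 6L,
                        blob_amp = 0.9, seed = 1L,
                        keep_images = FALSE) {
  set.seed(seed)
  feats <- vector("list", nrow(cells))
  imgs <- if (keep_images) vector("list", nrow(cells)) else NULL
  for (i in seq_len(nrow(cells))) {
    eff <- get_effect(effects, cells$sgrna[i])
    r_um <- radius_um * stats::runif(3, 0.95, 1.05)
    img <- nucleus_phantom(r_um, voxel_nm, eff$sphericity_lobe,
                           n_blobs, max(0, blob_amp * (1 + eff$cov_delta)))
    f <- nuclear_features(img$intensity, img$mask, voxel_nm,
                          check_connected = FALSE)
    feats[[i]] <- cbind(data.frame(cell_id = cells$cell_id[i],
                                   sgrna = cells$sgrna[i],
                                   stringsAsFactors = FALSE), f)
    if (keep_images) imgs[[i]] <- img
  }
  out <- do.call(rbind, feats)
  if (keep_images) attr(out, "images") <- imgs
  out
}

# single nucleus phantom: ellipsoid or two-lobe union, with condensates
nucleus_phantom <- function(radius_um, voxel_nm, lobe_sep = 0,
                            n_blobs = 6L, blob_amp = 0.9) {
  r_nm <- radius_um * 1000
  margin <- 1.25
  nx <- ceiling(2 * r_nm[1] * (1 + lobe_sep) * margin / voxel_nm[1])
  ny <- ceiling(2 * r_nm[2] * margin / voxel_nm[2])
  nz <- ceiling(2 * r_nm[3] * margin / voxel_nm[3])
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel_nm[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * voxel_nm[2]
  zs <- (seq_len(nz) - (nz + 1) / 2) * voxel_nm[3]
  ell <- function(cx, rx, ry, rz) {
    ex <- ((xs - cx) / rx)^2
    ey <- (ys / ry)^2
    ez <- (zs / rz)^2
    outer(outer(ex, ey, `+`), ez, `+`) <= 1
  }
  if (lobe_sep > 0) {
    shrink <- 0.78
    dx <- lobe_sep * r_nm[1]
    mask <- ell(-dx, r_nm[1] * shrink, r_nm[2] * shrink, r_nm[3] * shrink) |
            ell(dx, r_nm[1] * shrink, r_nm[2] * shrink, r_nm[3] * shrink)
  } else {
    mask <- ell(0, r_nm[1], r_nm[2], r_nm[3])
  }
  base <- 100
  inten <- array(stats::rnorm(length(mask), base, 4), dim(mask))
  inten[inten < 0] <- 0
  if (n_blobs > 0 && blob_amp > 0) {
    idx_in <- which(mask)
    centers <- idx_in[sample(length(idx_in), min(n_blobs, length(idx_in)))]
    pos <- arrayInd(centers, dim(mask))
    sig_vox <- 600 / voxel_nm                    # 600-nm condensates
    for (b in seq_len(nrow(pos))) {
      gx <- exp(-((seq_len(dim(mask)[1]) - pos[b, 1])^2) / (2 * sig_vox[1]^2))
      gy <- exp(-((seq_len(dim(mask)[2]) - pos[b, 2])^2) / (2 * sig_vox[2]^2))
      gz <- exp(-((seq_len(dim(mask)[3]) - pos[b, 3])^2) / (2 * sig_vox[3]^2))
      inten <- inten + blob_amp * base *
        outer(outer(gx, gy, `*`), gz, `*`)
    }
  }
  inten[!mask] <- 0
  list(intensity = inten, mask = mask, voxel_nm = voxel_nm)
}
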