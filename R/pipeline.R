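#' Per-perturbation chromatin phenotypes
#'
#' Aggregates a trace population into the five chromatin-folding
#' phenotypes per sgRNA against the pooled non-targeting controls:
#' adjacent-TAD distance and overall inter-TAD distance (two-sided
#' Wilcoxon rank-sum on per-trace mean log2 ratios to the control
#' pair medians; see [distance_test()] for why the trace-level test
#' is used for inference), and long-range A-A, A-B and B-B contact
#' frequencies (Wilcoxon rank-sum over per-trace frequencies). Effect
#' sizes are mean per-pair log2 fold changes of median distances. Traces with fewer than `completeness_min` of their
#' targets observed are dropped before aggregation. FDR is BH across
#' perturbations, one family per phenotype. The z score is the
#' perturbation mean minus control mean of the per-trace summary, in
#' control SDs.
#'
#' @param traces long trace table (`cell_id`, `trace_id`,
#'   `tad_index`, `x_nm`, `y_nm`, `z_nm`).
#' @param assignments data.frame `cell_id`, `sgrna` (e.g. decoded by
#'   [decode_cells()], or ground truth); cells without an assigned
#'   sgRNA are dropped.
#' @param profile a [compartment_profile()].
#' @param control_sgrnas character vector naming the non-targeting
#'   controls (pooled as the reference distribution).
#' @param threshold_nm contact threshold (default 500).
#' @param min_traces minimum traces per perturbation (default 20).
#' @param completeness_min trace QC floor, fraction of observed
#'   targets (default 0.6).
#' @param keep_matrices also return each perturbation's log2fc
#'   distance matrix (default TRUE).
#' @return list: `phenotypes` (data.frame `sgrna`, `phenotype`, `n`,
#'   `log2fc`, `p`, `fdr`, `z`, `is_control`, `insufficient`),
#'   `matrices` (named list of log2fc matrices), `n_traces` (named
#'   per sgRNA), `n_control_traces`.
#' @export
screen_phenotypes <- function(traces, assignments, profile,
                              control_sgrnas, threshold_nm = 500,
                              min_traces = 20L, completeness_min = 0.6,
                              keep_matrices = TRUE) {
  arr <- trace_array(traces, n_tad = nrow(profile))
  all_cells <- attr(arr, "cell_id")
  keep <- trace_completeness(arr) >= completeness_min
  arr <- arr[keep, , , drop = FALSE]
  cell_of <- all_cells[keep]
  sg_of <- assignments$sgrna[match(cell_of, assignments$cell_id)]
  ok <- !is.na(sg_of)
  arr <- arr[ok, , , drop = FALSE]
  sg_of <- sg_of[ok]

  D <- population_pair_distances(arr)
  Fq <- population_contact_frequencies(arr, profile, threshold_nm)
  ann <- pair_annotation(profile)
  adj_idx <- which(ann$sep == 1)
  per_trace_adj <- rowMeans(D[, adj_idx, drop = FALSE], na.rm = TRUE)
  per_trace_all <- rowMeans(D, na.rm = TRUE)

  is_ctrl_trace <- sg_of %in% control_sgrnas
  if (!any(is_ctrl_trace)) stop("no control traces after QC")
  ctrl_rows <- which(is_ctrl_trace)
  mc_all <- pair_medians(D[ctrl_rows, , drop = FALSE])
  ctrl_fq <- Fq[ctrl_rows, , drop = FALSE]
  # per-trace mean log2 ratio to the control pair medians: the
  # trace-level summary behind the calibrated distance tests
  trace_stat <- function(rows, idx) {
    t_i <- rowMeans(log2(sweep(D[rows, idx, drop = FALSE], 2,
                               mc_all[idx], `/`)), na.rm = TRUE)
    t_i[is.finite(t_i)]
  }

  sgrnas <- sort(unique(sg_of))
  mats <- list()
  rows <- list()
  zdenom <- list(
    adjacent_tad = stats::sd(per_trace_adj[ctrl_rows], na.rm = TRUE),
    overall_distance = stats::sd(per_trace_all[ctrl_rows], na.rm = TRUE),
    freq_AA = stats::sd(ctrl_fq[, "AA"], na.rm = TRUE),
    freq_AB = stats::sd(ctrl_fq[, "AB"], na.rm = TRUE),
    freq_BB = stats::sd(ctrl_fq[, "BB"], na.rm = TRUE))
  zmean_ctrl <- list(
    adjacent_tad = mean(per_trace_adj[ctrl_rows], na.rm = TRUE),
    overall_distance = mean(per_trace_all[ctrl_rows], na.rm = TRUE),
    freq_AA = mean(ctrl_fq[, "AA"], na.rm = TRUE),
    freq_AB = mean(ctrl_fq[, "AB"], na.rm = TRUE),
    freq_BB = mean(ctrl_fq[, "BB"], na.rm = TRUE))

  for (sg in sgrnas) {
    rows_sg <- which(sg_of == sg)
    n_sg <- length(rows_sg)
    insuff <- n_sg < min_traces
    Dp <- D[rows_sg, , drop = FALSE]
    mp <- pair_medians(Dp)

    test_dist <- function(idx) {
      okp <- !is.na(mp[idx]) & !is.na(mc_all[idx])
      lfc <- mean(log2(mp[idx][okp] / mc_all[idx][okp]))
      if (insuff || sum(okp) < 6)
        return(list(p = NA_real_, log2fc = lfc))
      tp <- trace_stat(rows_sg, idx[okp])
      tc <- trace_stat(ctrl_rows, idx[okp])
      p <- if (identical(sort(tp), sort(tc))) 1 else
        stats::wilcox.test(tp, tc, exact = FALSE)$p.value
      list(p = p, log2fc = lfc)
    }
    t_adj <- test_dist(adj_idx)
    t_all <- test_dist(seq_len(ncol(D)))
    res <- list(
      adjacent_tad = c(t_adj,
        z = (mean(per_trace_adj[rows_sg], na.rm = TRUE) -
             zmean_ctrl$adjacent_tad) / zdenom$adjacent_tad),
      overall_distance = c(t_all,
        z = (mean(per_trace_all[rows_sg], na.rm = TRUE) -
             zmean_ctrl$overall_distance) / zdenom$overall_distance))
    for (cls in c("AA", "AB", "BB")) {
      ph <- paste0("freq_", cls)
      ct <- contact_test(Fq[rows_sg, cls], ctrl_fq[, cls],
                         min_traces = min_traces)
      res[[ph]] <- list(p = ct$p, log2fc = ct$log2fc,
        z = (mean(Fq[rows_sg, cls], na.rm = TRUE) -
             zmean_ctrl[[ph]]) / zdenom[[ph]])
    }
    rows[[sg]] <- do.call(rbind, lapply(names(res), function(ph)
      data.frame(sgrna = sg, phenotype = ph, n = n_sg,
                 log2fc = res[[ph]]$log2fc, p = res[[ph]]$p,
                 z = res[[ph]]$z,
                 is_control = sg %in% control_sgrnas,
                 insufficient = insuff, stringsAsFactors = FALSE)))
    if (keep_matrices && !insuff)
      mats[[sg]] <- log2fc_distance_matrix(
        arr[rows_sg, , , drop = FALSE], arr[ctrl_rows, , , drop = FALSE],
        min_traces = min_traces)
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL
  pheno$fdr <- NA_real_
  for (ph in unique(pheno$phenotype)) {
    sel <- pheno$phenotype == ph
    pheno$fdr[sel] <- fdr_correct(pheno$p[sel])
  }
  pheno <- pheno[, c("sgrna", "phenotype", "n", "log2fc", "p", "fdr",
                     "z", "is_control", "insufficient")]
  n_traces <- table(sg_of)
  list(phenotypes = pheno, matrices = mats,
       n_traces = n_traces[sgrnas],
       n_control_traces = length(ctrl_rows))
}

#' Simulate a full synthetic screen
#'
#' One call generating a coherent screen: library + codebook, cells,
#' per-round barcode readouts, chromatin traces and (optionally)
#' nuclear phantoms, all deterministic in `seed`.
#'
#' @param n_targeting,n_controls,n_genes library composition.
#' @param n_cells_per_sgrna cells per perturbation.
#' @param nuclei_per_sgrna cells per perturbation that also get a
#'   nuclear phantom (0 disables nuclei).
#' @param effects named list of [effect_spec()] per sgRNA.
#' @param profile a [compartment_profile()].
#' @param miscall_rate,lowconf_rate barcode readout noise.
#' @param dropout_rate per-target trace dropout.
#' @param traces_per_cell traces sampled per cell.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list: `library`, `truth`, `codebook`, `cells`, `readouts`,
#'   `traces`, `nuclei` (features data.frame or NULL), `profile`,
#'   `effects`.
#' @export
simulate_screen <- function(n_targeting = 44L, n_controls = 8L,
                            n_genes = 22L, n_cells_per_sgrna = 120L,
                            nuclei_per_sgrna = 25L, effects = NULL,
                            profile = default_compartment_profile(),
                            miscall_rate = 0.02, lowconf_rate = 0.02,
                            dropout_rate = 0.09,
                            traces_per_cell = 2:4, seed = 1L) {
  lib <- make_library(n_targeting = n_targeting,
                      n_controls = n_controls, n_genes = n_genes,
                      seed = seed)
  cells <- make_cells(lib$truth, n_cells_per_sgrna, seed = seed + 1L)
  readouts <- make_readouts(cells, miscall_rate = miscall_rate,
                            lowconf_rate = lowconf_rate,
                            seed = seed + 2L)
  traces <- make_traces(cells, profile = profile, effects = effects,
                        traces_per_cell = traces_per_cell,
                        dropout_rate = dropout_rate, seed = seed + 3L)
  nuclei <- NULL
  if (nuclei_per_sgrna > 0) {
    sub <- do.call(rbind, lapply(split(cells, cells$sgrna), function(d)
      utils::head(d, nuclei_per_sgrna)))
    nuclei <- make_nuclei(sub, effects = effects, seed = seed + 4L)
  }
  list(library = lib$library, truth = lib$truth,
       codebook = lib$codebook, cells = cells, readouts = readouts,
       traces = traces, nuclei = nuclei, profile = profile,
       effects = effects)
}

#' Run the screen pipeline: decode, phenotype, call hits
#'
#' Decodes each cell's barcode readout against the codebook, maps
#' assigned cells to their traces, computes the chromatin phenotypes
#' (and nuclear phenotypes when per-cell features are supplied), and
#' calls hits at the FDR and effect-size thresholds.
#'
#' @param screen list as produced by [simulate_screen()], or any list
#'   with `readouts`, `codebook`, `traces`, `profile`, `library` and
#'   optionally `nuclei`.
#' @param fdr_threshold,effect_floor hit-calling thresholds (defaults
#'   0.1 and 0.15; see [call_hits()]).
#' @param min_ratio,max_correction decoding parameters.
#' @param use_truth bypass decoding and use the true cell-sgRNA
#'   assignment (for calibration runs without readouts).
#' @inheritParams screen_phenotypes
#' @return list: `assignments`, `decode_summary` (status counts),
#'   `phenotypes`, `matrices`, `hits`, `controls`.
#' @export
run_screen <- function(screen, fdr_threshold = 0.1, effect_floor = 0.15,
                       min_ratio = 2, max_correction = 1L,
                       min_traces = 20L, use_truth = FALSE) {
  controls <- screen$library$sgrna[!screen$library$targeting]
  if (use_truth || is.null(screen$readouts)) {
    assignments <- screen$cells[, c("cell_id", "sgrna")]
    decode_summary <- c(assigned = nrow(assignments))
  } else {
    dec <- decode_cells(screen$readouts, screen$codebook,
                        min_ratio = min_ratio,
                        max_correction = max_correction)
    decode_summary <- table(dec$status)
    assignments <- dec[dec$status == "assigned", c("cell_id", "sgrna")]
  }
  ph <- screen_phenotypes(screen$traces, assignments, screen$profile,
                          control_sgrnas = controls,
                          min_traces = min_traces)
  pheno <- ph$phenotypes
  if (!is.null(screen$nuclei)) {
    nuc <- screen$nuclei
    nuc$sgrna_decoded <- assignments$sgrna[
      match(nuc$cell_id, assignments$cell_id)]
    nuc_cells <- data.frame(sgrna = nuc$sgrna_decoded,
                            is_control = nuc$sgrna_decoded %in% controls,
                            cov = nuc$cov, sphericity = nuc$sphericity,
                            stringsAsFactors = FALSE)
    nuc_cells <- nuc_cells[!is.na(nuc_cells$sgrna), ]
    nt <- nuclear_tests(nuc_cells)
    nt$phenotype <- ifelse(nt$phenotype == "cov", "intensity_cov",
                           "sphericity")
    pheno <- rbind(pheno, nt[, names(pheno)])
  }
  hits <- call_hits(pheno, fdr_threshold = fdr_threshold,
                    effect_floor = effect_floor)
  list(assignments = assignments, decode_summary = decode_summary,
       phenotypes = pheno, matrices = ph$matrices, hits = hits,
       controls = controls)
}
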