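#' Interchange formats
#'
#' Plain-text readers and writers for the pipeline's interchange
#' tables, with strict schema validation (errors name the file and
#' line) and atomic writes (temp file + rename). Conventions: nm for
#' positions, bp for genomic midpoints, 1-based `tad_index` on disk.
#'
#' @name interchange-io
NULL

stop_schema <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

read_checked_tsv <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_schema(path, 1, paste("missing columns:",
                               paste(miss, collapse = ", ")))
  df
}

atomic_write <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Read / write a trace table
#'
#' TSV columns: `cell_id`, `trace_id`, `tad_index` (1-based), `x_nm`,
#' `y_nm`, `z_nm`; empty coordinate fields are missing targets. An
#' optional `sgrna` column is carried through.
#'
#' @param path TSV path.
#' @param n_tad expected number of targets (rows with `tad_index`
#'   outside 1..n_tad are schema errors).
#' @return data.frame.
#' @export
read_trace_table <- function(path, n_tad = 27L) {
  df <- read_checked_tsv(path, c("cell_id", "trace_id", "tad_index",
                                 "x_nm", "y_nm", "z_nm"))
  bad <- which(df$tad_index < 1 | df$tad_index > n_tad |
                 df$tad_index != round(df$tad_index))
  if (length(bad))
    stop_schema(path, bad[1] + 1,
                sprintf("tad_index %s outside 1..%d",
                        df$tad_index[bad[1]], n_tad))
  partial <- which(rowSums(is.na(df[, c("x_nm", "y_nm", "z_nm")])) %in%
                     c(1L, 2L))
  if (length(partial))
    stop_schema(path, partial[1] + 1,
                "coordinates must be all present or all missing")
  df
}

#' @rdname read_trace_table
#' @param traces trace table data.frame.
#' @export
write_trace_table <- function(traces, path) {
  atomic_write(function(tmp)
    utils::write.table(traces, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""), path)
}

#' Read / write a compartment profile
#'
#' TSV columns: `tad_index`, `chrom`, `midpoint_bp`, `label`, `score`.
#'
#' @param path TSV path.
#' @return a [compartment_profile()].
#' @export
read_profile <- function(path) {
  df <- read_checked_tsv(path, c("tad_index", "chrom", "midpoint_bp",
                                 "label", "score"))
  df <- df[order(df$tad_index), ]
  if (!identical(as.integer(df$tad_index), seq_len(nrow(df))))
    stop_schema(path, 1, "tad_index must be 1..n without gaps")
  compartment_profile(df$label, df$score, df$midpoint_bp,
                      chrom = df$chrom[1], check_sign = FALSE)
}

#' @rdname read_profile
#' @param profile a [compartment_profile()].
#' @export
write_profile <- function(profile, path) {
  atomic_write(function(tmp)
    utils::write.table(as.data.frame(profile), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE), path)
}

#' Read / write a codebook (JSON)
#'
#' Schema: `{"good": {"<code>": "<sgRNA>", ...}, "bad": ["<code>",
#' ...]}`, codes serialized as digit strings.
#'
#' @param path JSON path.
#' @return a [codebook()].
#' @export
read_codebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$good)) stop("codebook JSON lacks a 'good' map: ", path)
  codebook(unlist(x$good),
           if (is.null(x$bad)) character() else unlist(x$bad))
}

#' @rdname read_codebook
#' @param cb a [codebook()].
#' @export
write_codebook <- function(cb, path) {
  atomic_write(function(tmp)
    jsonlite::write_json(list(good = as.list(cb$good),
                              bad = cb$bad),
                         tmp, auto_unbox = TRUE, pretty = TRUE), path)
}

#' Read a barcode readout table (CSV)
#'
#' Columns: `cell_id`, `round`, `channel_value`, `intensity`.
#'
#' @param path CSV path.
#' @param n_rounds expected round count.
#' @return data.frame.
#' @export
read_readouts <- function(path, n_rounds = 10L) {
  df <- read_checked_tsv(path, c("cell_id", "round", "channel_value",
                                 "intensity"), sep = ",")
  if (any(df$intensity < 0))
    stop_schema(path, which(df$intensity < 0)[1] + 1,
                "negative intensity")
  if (any(df$round < 1 | df$round > n_rounds))
    stop_schema(path, 1, paste("round outside 1..", n_rounds))
  df
}

#' @rdname read_readouts
#' @param readouts readout data.frame.
#' @export
write_readouts <- function(readouts, path) {
  atomic_write(function(tmp)
    utils::write.csv(readouts, tmp, row.names = FALSE, quote = FALSE),
    path)
}

#' Read an NGS read table (TSV)
#'
#' Columns: `umi`, `payload_type`, `payload`, `pass_qc`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_read_table <- function(path) {
  df <- read_checked_tsv(path, c("umi", "payload_type", "payload",
                                 "pass_qc"))
  ok_types <- c("protospacer", "barcode_left", "barcode_right",
                "barcode_full")
  bad <- which(!df$payload_type %in% ok_types)
  if (length(bad))
    stop_schema(path, bad[1] + 1,
                paste("unknown payload_type", df$payload_type[bad[1]]))
  df
}

#' Write result tables with a provenance manifest
#'
#' Writes each table as TSV into `dir` and a `manifest.json` listing
#' file names, row counts, md5 hashes and the run configuration, so a
#' deterministic run can be reproduced byte for byte.
#'
#' @param dir output directory (created if absent).
#' @param tables named list of data.frames.
#' @param config optional named list echoed into the manifest
#'   (thresholds, seeds).
#' @return path of the manifest, invisibly.
#' @export
write_results <- function(dir, tables, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    atomic_write(function(tmp)
      utils::write.table(tables[[nm]], tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = ""), p)
    entries[[nm]] <- list(file = basename(p),
                          n_rows = nrow(tables[[nm]]),
                          md5 = unname(tools::md5sum(p)))
  }
  manifest <- file.path(dir, "manifest.json")
  atomic_write(function(tmp)
    jsonlite::write_json(list(
      package = "perturbtrace",
      version = as.character(utils::packageVersion("perturbtrace")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = config, tables = entries),
      tmp, auto_unbox = TRUE, pretty = TRUE), manifest)
  invisible(manifest)
}
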