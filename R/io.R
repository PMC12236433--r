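#' Read a feature-by-sample abundance table from TSV
#'
#' The single tabular dialect is TSV (tab-separated, UTF-8, "." decimal):
#' header row of sample ids, first column feature ids. Values must be
#' non-negative; duplicate feature or sample ids are rejected with a
#' diagnostic naming the offender.
#'
#' @param path TSV file path.
#' @param kind table kind tag, see [abundance_table()].
#' @param annotations optional annotation `data.frame` to attach.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, kind, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character"),
    error = function(e) stop(sprintf("%s: no features", path), call. = FALSE))
  if (nrow(raw) == 0L)
    stop(sprintf("%s: no features", path), call. = FALSE)
  feature_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (length(sample_ids) == 0L)
    stop(sprintf("%s: no sample columns", path), call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop(sprintf("%s: duplicate sample id '%s'", path,
                 sample_ids[duplicated(sample_ids)][1L]), call. = FALSE)
  if (anyDuplicated(feature_ids))
    stop(sprintf("%s: duplicate feature id '%s'", path,
                 feature_ids[duplicated(feature_ids)][1L]), call. = FALSE)
  vals <- matrix(NA_real_, nrow(raw), length(sample_ids),
                 dimnames = list(feature_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col))
    if (length(bad))
      stop(sprintf("%s: unparseable value '%s' at row '%s', column '%s'",
                   path, raw[[j + 1L]][bad[1L]], feature_ids[bad[1L]],
                   sample_ids[j]), call. = FALSE)
    neg <- which(col < 0)
    if (length(neg))
      stop(sprintf("%s: negative value at row '%s', column '%s'",
                   path, feature_ids[neg[1L]], sample_ids[j]), call. = FALSE)
    vals[, j] <- col
  }
  abundance_table(vals, kind, annotations)
}

#' Write an abundance table to TSV
#'
#' Inverse of [read_abundance_table()]: feature/sample order preserved,
#' values at 12 significant digits so a read-back round-trips losslessly.
#'
#' @param tab an [abundance_table()].
#' @param path output TSV path.
#' @export
write_abundance_table <- function(tab, path) {
  df <- data.frame(feature_id = features(tab),
                   signif(tab$values, 12), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from TSV
#'
#' Required columns: `sample_id`, `eddy` (one of cyclone, anticyclone,
#' front). Optional: `depth_m`, `dcm_depth_m`, `volume_ml`, `timepoint`,
#' `station`. Depth is absent (NA) for purely diel samples.
#'
#' @param path TSV file path.
#' @return a `data.frame` of class `sample_meta`, one row per sample.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  req <- c("sample_id", "eddy")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  num_cols <- c("depth_m", "dcm_depth_m", "volume_ml", "timepoint")
  for (col in intersect(num_cols, names(df))) {
    v <- df[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(parsed))
    if (length(bad))
      stop(sprintf("%s: unparseable number '%s' in column '%s', row %d",
                   path, v[bad[1L]], col, bad[1L]), call. = FALSE)
    df[[col]] <- parsed
  }
  for (col in setdiff(num_cols, names(df))) df[[col]] <- NA_real_
  if (!"station" %in% names(df)) df$station <- ""
  sample_meta(df)
}

#' Construct and validate sample metadata
#'
#' @param df data.frame with at least `sample_id` and `eddy` columns.
#' @return validated `sample_meta` data.frame.
#' @export
sample_meta <- function(df) {
  allowed <- c("cyclone", "anticyclone", "front")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L], call. = FALSE)
  bad <- setdiff(unique(df$eddy), allowed)
  if (length(bad))
    stop(sprintf("unknown eddy label '%s'; allowed: %s", bad[1L],
                 paste(allowed, collapse = ", ")), call. = FALSE)
  if (any(!is.na(df$depth_m) & df$depth_m < 0))
    stop("depth_m must be >= 0", call. = FALSE)
  if (any(!is.na(df$dcm_depth_m) & df$dcm_depth_m <= 0))
    stop("dcm_depth_m must be > 0", call. = FALSE)
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param meta a `sample_meta` data.frame.
#' @param path output TSV path.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a homogeneous list of result records to TSV
#'
#' Records are data.frames of one result type (enrichment, differential,
#' expression, calibration...). Column order is deterministic (as in the
#' first record) and numeric values are written at 12 significant digits so
#' [read_records()] round-trips losslessly.
#'
#' @param records a data.frame of records, or a list of single-row
#'   data.frames of identical shape.
#' @param path output TSV path.
#' @export
write_records <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (!length(records)) stop("empty record list without a prototype; pass a data.frame", call. = FALSE)
    shapes <- vapply(records, function(r) paste(names(r), collapse = "\t"), "")
    if (length(unique(shapes)) > 1L)
      stop("records of mixed types cannot be written together", call. = FALSE)
    df <- do.call(rbind, records)
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 12)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a records TSV written by [write_records()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_records <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Load run configuration from YAML or JSON
#'
#' Any field absent from the file keeps its [run_config()] default.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, cfg)
}

#' Pipeline thresholds and options
#'
#' Defaults mirror the study's stated cutoffs: correlation screen r > 0.5
#' with p < 0.01, difference/total ratio > 0.5, taxon fold-change flag at 3
#' (and 1/3), transcript |log2FC| flag at 2, FDR q < 0.05, pathways retained
#' only with more than two (>= 3) overexpressed transcripts.
#'
#' @param r_min minimum Pearson r for the trait screen.
#' @param diff_total_min minimum difference/total ratio.
#' @param p_corr_max maximum correlation p-value.
#' @param fc_flag taxon fold-change threshold (strict; flags at FC > 3 or
#'   FC < 1/3).
#' @param log2fc_flag transcript |log2 fold change| threshold (strict).
#' @param q_max BH-adjusted p-value cutoff, in (0,1).
#' @param pathway_min_transcripts minimum retained transcripts per pathway.
#' @param window_mode depth-window mode, `"at_or_above_dcm"` or `"custom"`.
#' @param seed integer seed for the synthetic generator.
#' @return a classed list of settings.
#' @export
run_config <- function(r_min = 0.5, diff_total_min = 0.5, p_corr_max = 0.01,
                       fc_flag = 3.0, log2fc_flag = 2.0, q_max = 0.05,
                       pathway_min_transcripts = 3L,
                       window_mode = c("at_or_above_dcm", "custom"),
                       seed = 1L) {
  window_mode <- match.arg(window_mode)
  num <- c(r_min = r_min, diff_total_min = diff_total_min,
           p_corr_max = p_corr_max, fc_flag = fc_flag,
           log2fc_flag = log2fc_flag, q_max = q_max,
           pathway_min_transcripts = pathway_min_transcripts)
  if (any(num <= 0))
    stop("all thresholds must be strictly positive: ",
         paste(names(num)[num <= 0], collapse = ", "), call. = FALSE)
  if (q_max >= 1) stop("q_max must lie in (0,1)", call. = FALSE)
  structure(list(r_min = r_min, diff_total_min = diff_total_min,
                 p_corr_max = p_corr_max, fc_flag = fc_flag,
                 log2fc_flag = log2fc_flag, q_max = q_max,
                 pathway_min_transcripts = as.integer(pathway_min_transcripts),
                 window_mode = window_mode, seed = as.integer(seed)),
            class = "run_config")
}

# structured log line on stderr: stage, elapsed, record counts
eo_log <- function(stage, ..., t0 = NULL) {
  elapsed <- if (is.null(t0)) "" else
    sprintf(" [%.2fs]", as.numeric(Sys.time()) - as.numeric(t0))
  message(sprintf("[eddyomics] %s: %s%s", stage,
                  paste0(..., collapse = ""), elapsed))
}
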