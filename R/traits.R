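#' Aggregate gene abundances by KEGG Orthology
#'
#' KO value per sample = sum of member-gene values. Genes without a KO are
#' dropped with a logged count; total annotated abundance per sample is
#' conserved.
#'
#' @param gene_table gene-level [abundance_table()].
#' @param ko_map named character vector gene id -> KO id ("" = unannotated),
#'   or `NULL` to use the table's `KO` annotation column.
#' @return an [abundance_table()] of kind `ko_rpb`.
#' @export
aggregate_by_ko <- function(gene_table, ko_map = NULL) {
  if (is.null(ko_map)) ko_map <- annotation_field(gene_table, "KO")
  ko <- ko_map[features(gene_table)]
  ko[is.na(ko)] <- ""
  keep <- nzchar(ko)
  if (!any(keep))
    stop("no gene carries a KO annotation", call. = FALSE)
  n_drop <- sum(!keep)
  if (n_drop) eo_log("aggregate_by_ko", n_drop, " unannotated gene(s) dropped")
  vals <- rowsum(gene_table$values[keep, , drop = FALSE], ko[keep],
                 reorder = FALSE)
  abundance_table(vals, "ko_rpb")
}

#' Correlate each KO with an ecotype's marker abundance
#'
#' Per-KO Pearson r and p against the per-sample ecotype marker vector
#' (mean RPB over the ecotype's reference sequences), across the pooled
#' depth samples of both eddies. Constant KO rows are flagged
#' (`constant = TRUE`, r and p NA) rather than erroring.
#'
#' @param ko_table `ko_rpb` [abundance_table()].
#' @param ecotype_rpb named numeric vector, one value per sample.
#' @return data.frame: `ko_id`, `r`, `p`, `constant`.
#' @export
correlate_with_ecotype <- function(ko_table, ecotype_rpb) {
  shared <- intersect(samples(ko_table), names(ecotype_rpb))
  if (length(shared) < 3L)
    stop("need >= 3 shared samples", call. = FALSE)
  eco <- ecotype_rpb[shared]
  if (stats::sd(eco) == 0)
    stop("constant input: ecotype vector has zero variance", call. = FALSE)
  res <- lapply(features(ko_table), function(k) {
    v <- ko_table$values[k, shared]
    if (stats::sd(v) == 0)
      return(data.frame(ko_id = k, r = NA_real_, p = NA_real_,
                        constant = TRUE))
    tr <- pearson_test(v, eco)
    data.frame(ko_id = k, r = tr$statistic, p = tr$p_value, constant = FALSE)
  })
  do.call(rbind, res)
}

#' Difference/total ratio and log ratio for one feature
#'
#' With C = sum of the feature over cyclone-window samples and A = the sum
#' over anticyclone-window samples: D = (C - A)/(C + A), an antisymmetric
#' enrichment score in \[-1, 1\], and log_ratio = log2((C + 1)/(A + 1)).
#' The same depth window is applied to both eddies.
#'
#' @param values named per-sample numeric vector for the feature.
#' @param meta `sample_meta`.
#' @param window a [window_spec()].
#' @return list with `D` (NA with `flagged = TRUE` when C + A = 0),
#'   `log_ratio`, `sum_cyclone`, `sum_anticyclone`, `flagged`.
#' @export
difference_total_ratio <- function(values, meta,
                                   window = window_spec("at_or_above_dcm")) {
  in_win <- select_window(meta, window)
  ids_c <- intersect(meta$sample_id[meta$eddy == "cyclone"], in_win)
  ids_a <- intersect(meta$sample_id[meta$eddy == "anticyclone"], in_win)
  ids_c <- intersect(ids_c, names(values))
  ids_a <- intersect(ids_a, names(values))
  if (!length(ids_c) || !length(ids_a))
    stop("both eddy groups must be nonempty within the window", call. = FALSE)
  C <- sum(values[ids_c]); A <- sum(values[ids_a])
  lr <- log2((C + 1) / (A + 1))
  if (C + A == 0)
    return(list(D = NA_real_, log_ratio = lr, sum_cyclone = C,
                sum_anticyclone = A, flagged = TRUE))
  list(D = (C - A) / (C + A), log_ratio = lr, sum_cyclone = C,
       sum_anticyclone = A, flagged = FALSE)
}

#' Trait-enrichment screen of KOs against an ecotype marker
#'
#' For every KO: Pearson r and p against the target ecotype's marker vector
#' (and, for reporting, the comparison ecotype), plus the cyclone-vs-
#' anticyclone difference/total ratio over the depth window. A KO passes
#' when r_target > r_min, difference/total > diff_total_min and p_target <
#' p_corr_max. Records are sorted by total RPB; `top_k` truncates the
#' passing set (descending abundance), mirroring a "top 20 KOs" report.
#'
#' @param ko_table `ko_rpb` [abundance_table()].
#' @param ecotype_target,ecotype_other named per-sample marker vectors.
#' @param meta `sample_meta`.
#' @param config a [run_config()].
#' @param window a [window_spec()].
#' @param top_k truncate passers to the k most abundant (NULL = no limit).
#' @return data.frame of class `enrichment_records`: one row per KO with
#'   `ko_id`, `r_target`, `p_target`, `r_other`, `p_other`, `diff_total`,
#'   `log_ratio`, `sum_cyclone_rpb`, `sum_anticyclone_rpb`, `passes`.
#' @export
trait_screen <- function(ko_table, ecotype_target, ecotype_other = NULL,
                         meta, config = run_config(),
                         window = window_spec("at_or_above_dcm"),
                         top_k = NULL) {
  ct <- correlate_with_ecotype(ko_table, ecotype_target)
  co <- if (is.null(ecotype_other)) NULL else
    correlate_with_ecotype(ko_table, ecotype_other)
  rows <- lapply(seq_len(nrow(ct)), function(i) {
    k <- ct$ko_id[i]
    dt <- difference_total_ratio(ko_table$values[k, ], meta, window)
    passes <- !ct$constant[i] && !dt$flagged &&
      ct$r[i] > config$r_min && dt$D > config$diff_total_min &&
      ct$p[i] < config$p_corr_max
    data.frame(ko_id = k, r_target = ct$r[i], p_target = ct$p[i],
               r_other = if (is.null(co)) NA_real_ else co$r[i],
               p_other = if (is.null(co)) NA_real_ else co$p[i],
               diff_total = dt$D, log_ratio = dt$log_ratio,
               sum_cyclone_rpb = dt$sum_cyclone,
               sum_anticyclone_rpb = dt$sum_anticyclone,
               passes = passes)
  })
  rec <- do.call(rbind, rows)
  tot <- rec$sum_cyclone_rpb + rec$sum_anticyclone_rpb
  rec <- rec[order(-tot), , drop = FALSE]
  if (!is.null(top_k)) {
    pass <- rec[rec$passes, , drop = FALSE]
    rec <- pass[seq_len(min(top_k, nrow(pass))), , drop = FALSE]
  }
  rownames(rec) <- NULL
  class(rec) <- c("enrichment_records", "data.frame")
  rec
}
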