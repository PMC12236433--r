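#' Sum per-ml transcript abundances to taxon level
#'
#' Per-sample sum of member-transcript molecules-per-ml values. When
#' `exclude_below_detection = TRUE` (the default) entries flagged below the
#' sample's spike-in detection limit are excluded from the sums; with the
#' flag off, total abundance over taxa equals the total over annotated
#' transcripts.
#'
#' @param transcripts `transcript_per_ml` [abundance_table()] (from
#'   [normalize_to_per_ml()]).
#' @param taxon_map named character vector transcript id -> taxon id, or
#'   `NULL` to use the table's `taxon` annotation column.
#' @param exclude_below_detection drop below-detection entries before
#'   summing.
#' @return an [abundance_table()] of kind `species_sum` (taxa x samples).
#' @export
sum_by_taxon <- function(transcripts, taxon_map = NULL,
                         exclude_below_detection = TRUE) {
  if (is.null(taxon_map)) taxon_map <- annotation_field(transcripts, "taxon")
  tx <- taxon_map[features(transcripts)]
  tx[is.na(tx)] <- ""
  keep <- nzchar(tx)
  if (!any(keep)) stop("no transcript carries a taxon annotation", call. = FALSE)
  vals <- transcripts$values
  if (exclude_below_detection && !is.null(transcripts$below_detection))
    vals[transcripts$below_detection] <- 0
  sums <- rowsum(vals[keep, , drop = FALSE], tx[keep], reorder = FALSE)
  # carry per-taxon ecotype labels forward when the transcripts had them
  eco <- annotation_field(transcripts, "ecotype")[keep]
  ann <- NULL
  if (any(nzchar(eco))) {
    first <- !duplicated(tx[keep])
    ann <- data.frame(feature_id = tx[keep][first], ecotype = eco[first])
  }
  abundance_table(sums, "species_sum", ann)
}

#' Anticyclone/cyclone fold change of one taxon
#'
#' FC = mean(anticyclone diel sums) / mean(cyclone diel sums). A zero
#' cyclone mean with positive anticyclone mean yields +Inf (reported,
#' flaggable); both-zero taxa are undefined (NA, to be dropped with a log).
#'
#' @param taxon_row named per-sample numeric vector of taxon sums.
#' @param meta diel `sample_meta`.
#' @return the fold change (possibly Inf or NA).
#' @export
fold_change <- function(taxon_row, meta) {
  ids_c <- intersect(meta$sample_id[meta$eddy == "cyclone"], names(taxon_row))
  ids_a <- intersect(meta$sample_id[meta$eddy == "anticyclone"],
                     names(taxon_row))
  if (!length(ids_c) || !length(ids_a))
    stop("both eddy groups must be nonempty", call. = FALSE)
  mc <- mean(taxon_row[ids_c]); ma <- mean(taxon_row[ids_a])
  if (mc == 0 && ma == 0) return(NA_real_)
  if (mc == 0) return(Inf)
  ma / mc
}

#' Taxon-level differential representation between eddies
#'
#' Per taxon: anticyclone/cyclone fold change of the mean diel sums, a
#' Kruskal-Wallis test across the two diel sample groups, and a single
#' Benjamini-Hochberg pass over all tested taxa. Flags use strict
#' inequalities: anticyclone_enriched iff q < q_max and FC > fc_flag,
#' cyclone_enriched iff q < q_max and FC < 1/fc_flag. All-zero taxa are
#' dropped before testing so they never dilute the correction.
#'
#' @param species_table `species_sum` [abundance_table()].
#' @param meta diel `sample_meta` with >= 2 samples per eddy.
#' @param config a [run_config()] supplying `fc_flag` and `q_max`.
#' @return data.frame of class `differential_records` sorted by decreasing
#'   |log2 FC|: `taxon_id`, `ecotype_label`, `mean_sum_anticyclone`,
#'   `mean_sum_cyclone`, `fold_change`, `p_value`, `q_value`, `flag`.
#' @export
differential_taxa <- function(species_table, meta, config = run_config()) {
  ids_c <- intersect(meta$sample_id[meta$eddy == "cyclone"],
                     samples(species_table))
  ids_a <- intersect(meta$sample_id[meta$eddy == "anticyclone"],
                     samples(species_table))
  if (length(ids_c) < 2L || length(ids_a) < 2L)
    stop("need >= 2 samples per eddy", call. = FALSE)
  vals <- species_table$values
  nonzero <- rowSums(vals[, c(ids_c, ids_a), drop = FALSE]) > 0
  n_drop <- sum(!nonzero)
  if (n_drop) eo_log("differential_taxa", n_drop, " all-zero taxa dropped")
  taxa <- features(species_table)[nonzero]
  if (!length(taxa)) stop("no testable taxa", call. = FALSE)
  eco <- annotation_field(species_table, "ecotype")
  rows <- lapply(taxa, function(t) {
    row <- vals[t, ]
    kt <- kruskal_wallis_test(list(row[ids_c], row[ids_a]))
    data.frame(taxon_id = t, ecotype_label = eco[[t]],
               mean_sum_anticyclone = mean(row[ids_a]),
               mean_sum_cyclone = mean(row[ids_c]),
               fold_change = fold_change(row, meta),
               p_value = kt$p_value)
  })
  rec <- do.call(rbind, rows)
  rec$q_value <- bh_adjust(rec$p_value)$adjusted
  rec$flag <- "none"
  sig <- rec$q_value < config$q_max
  rec$flag[sig & rec$fold_change > config$fc_flag] <- "anticyclone_enriched"
  rec$flag[sig & rec$fold_change < 1 / config$fc_flag] <- "cyclone_enriched"
  rec <- rec[order(-abs(log2(rec$fold_change))), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("differential_records", "data.frame")
  rec
}
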