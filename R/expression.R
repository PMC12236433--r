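#' Normalize transcripts to their taxon's per-sample expression total
#'
#' value(t, s) = per_ml(t, s) / taxon_total(s), giving within-taxon
#' expression fractions in \[0, 1\] that reflect cellular regulation rather
#' than cell abundance. Below-detection entries are excluded from totals
#' and zeroed when the table carries detection flags. A sample where a
#' taxon's total is zero is excluded for that taxon (NA fractions, logged).
#'
#' @param transcripts `transcript_per_ml` [abundance_table()].
#' @param taxon_map named transcript id -> taxon id vector, or `NULL` to
#'   use the `taxon` annotation column.
#' @param exclude_below_detection zero out below-detection entries first.
#' @return an [abundance_table()] of kind `transcript_per_ml` holding
#'   fractions, with the taxon map attached as `$taxon`.
#' @export
within_taxon_normalize <- function(transcripts, taxon_map = NULL,
                                   exclude_below_detection = TRUE) {
  if (is.null(taxon_map)) taxon_map <- annotation_field(transcripts, "taxon")
  tx <- taxon_map[features(transcripts)]
  tx[is.na(tx)] <- ""
  keep <- nzchar(tx)
  if (!any(keep)) stop("no transcript carries a taxon annotation", call. = FALSE)
  vals <- transcripts$values[keep, , drop = FALSE]
  if (exclude_below_detection && !is.null(transcripts$below_detection))
    vals[transcripts$below_detection[keep, , drop = FALSE]] <- 0
  tx <- tx[keep]
  frac <- vals
  n_excl <- 0L
  for (taxon in unique(tx)) {
    rows <- which(tx == taxon)
    tot <- colSums(vals[rows, , drop = FALSE])
    zero <- tot == 0
    n_excl <- n_excl + sum(zero)
    tot[zero] <- NA_real_
    frac[rows, ] <- sweep(vals[rows, , drop = FALSE], 2L, tot, "/")
  }
  if (n_excl)
    eo_log("within_taxon_normalize",
           n_excl, " zero-total taxon-sample pair(s) excluded")
  out <- structure(list(values = frac, kind = "transcript_per_ml",
                        annotations = transcripts$annotations),
                   class = "abundance_table")
  out$taxon <- tx
  out
}

#' Within-taxon differential expression between eddies
#'
#' Per transcript, a two-group negative-binomial Wald test comparing the
#' eddies on pseudo-counts (fractions x `scale`, rounded; size factors 1
#' because the normalization chain is already applied), then a single BH
#' pass over all transcripts of all tested taxa together. A side is called
#' when q < q_max and |log2FC| > log2fc_flag (strict), log2FC being
#' anticyclone over cyclone.
#'
#' @param fractions output of [within_taxon_normalize()] (or any
#'   [abundance_table()] of comparable non-negative values with a `$taxon`
#'   map).
#' @param meta diel `sample_meta` with >= 2 samples per eddy.
#' @param config a [run_config()].
#' @param scale pseudo-count scale applied to fractions before rounding.
#' @return data.frame of class `expression_records`: `transcript_id`,
#'   `taxon_id`, `eggnog_id`, `ko_id`, `cog_category`, `log2_fold_change`,
#'   `p_value`, `q_value`, `side` (anticyclone / cyclone / none).
#' @export
differential_expression <- function(fractions, meta, config = run_config(),
                                    scale = 1e6) {
  ids_c <- intersect(meta$sample_id[meta$eddy == "cyclone"],
                     samples(fractions))
  ids_a <- intersect(meta$sample_id[meta$eddy == "anticyclone"],
                     samples(fractions))
  if (length(ids_c) < 2L || length(ids_a) < 2L)
    stop("need >= 2 samples per eddy", call. = FALSE)
  tx <- fractions$taxon
  if (is.null(tx)) tx <- annotation_field(fractions, "taxon")
  egg <- annotation_field(fractions, "eggNOG")
  ko <- annotation_field(fractions, "KO")
  cog <- annotation_field(fractions, "COG_category")
  rows <- lapply(features(fractions), function(t) {
    vc <- fractions$values[t, ids_c]
    va <- fractions$values[t, ids_a]
    vc <- vc[!is.na(vc)]; va <- va[!is.na(va)]
    if (length(vc) < 2L || length(va) < 2L) return(NULL)
    res <- nb_wald_two_group(round(vc * scale), round(va * scale))
    data.frame(transcript_id = t, taxon_id = tx[[t]], eggnog_id = egg[[t]],
               ko_id = ko[[t]], cog_category = cog[[t]],
               log2_fold_change = res$log2_fold_change,
               p_value = res$p_value)
  })
  rec <- do.call(rbind, rows)
  if (is.null(rec)) stop("no testable transcripts", call. = FALSE)
  rec$q_value <- bh_adjust(rec$p_value)$adjusted
  rec$side <- "none"
  sig <- rec$q_value < config$q_max &
    abs(rec$log2_fold_change) > config$log2fc_flag
  rec$side[sig & rec$log2_fold_change > 0] <- "anticyclone"
  rec$side[sig & rec$log2_fold_change < 0] <- "cyclone"
  rownames(rec) <- NULL
  class(rec) <- c("expression_records", "data.frame")
  rec
}

#' Summarize significant transcripts by COG category or pathway
#'
#' Applies the retention rules for functional summaries: (1) transcripts
#' whose eggNOG annotation has significant members on both sides are
#' dropped (ambiguous annotations); (2) remaining sided transcripts are
#' grouped by COG letter (each letter of a multi-letter annotation counts)
#' or by pathway; (3) in pathway mode only categories with more than two
#' retained transcripts (>= 3, `config$pathway_min_transcripts`) survive;
#' (4) an optional merge map collapses related pathways before retention.
#'
#' @param records [differential_expression()] output.
#' @param mode `"cog"` or `"pathway"`.
#' @param config a [run_config()].
#' @param pathways named transcript id -> ";"-separated pathway string
#'   (pathway mode; defaults to the records' `pathway` annotation when the
#'   table carried one via `cog_category`-style columns is not available).
#' @param merge_map optional named character vector pathway id -> merged id.
#' @return data.frame of class `category_summaries`: `category_id`,
#'   `n_cyclone`, `n_anticyclone`, `member_log2fc` (";"-joined).
#' @export
summarize_by_category <- function(records, mode = c("cog", "pathway"),
                                  config = run_config(), pathways = NULL,
                                  merge_map = NULL) {
  mode <- match.arg(mode)
  sided <- records[records$side != "none", , drop = FALSE]
  # both-sides rule: drop every transcript of an eggNOG annotation that has
  # significant members in both eddies
  egg <- sided$eggnog_id
  has_egg <- nzchar(egg)
  both <- intersect(unique(egg[has_egg & sided$side == "cyclone"]),
                    unique(egg[has_egg & sided$side == "anticyclone"]))
  sided <- sided[!(has_egg & egg %in% both), , drop = FALSE]
  cats <- if (mode == "cog") {
    lapply(sided$cog_category, function(cc) {
      ltr <- strsplit(cc, "")[[1L]]
      ltr[ltr %in% c(LETTERS, letters)]
    })
  } else {
    if (is.null(pathways)) stop("pathway mode needs a 'pathways' map", call. = FALSE)
    lapply(sided$transcript_id, function(t) {
      pw <- pathways[[t]]
      if (is.null(pw) || is.na(pw) || !nzchar(pw)) character()
      else strsplit(pw, ";", fixed = TRUE)[[1L]]
    })
  }
  if (!is.null(merge_map) && mode == "pathway")
    cats <- lapply(cats, function(v) {
      hit <- v %in% names(merge_map)
      v[hit] <- merge_map[v[hit]]
      unique(v)
    })
  long <- data.frame(
    category_id = unlist(cats, use.names = FALSE),
    side = rep(sided$side, lengths(cats)),
    log2fc = rep(sided$log2_fold_change, lengths(cats)))
  if (!nrow(long)) {
    out <- data.frame(category_id = character(), n_cyclone = integer(),
                      n_anticyclone = integer(), member_log2fc = character())
    class(out) <- c("category_summaries", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(split(long, long$category_id), function(d) {
    data.frame(category_id = d$category_id[1L],
               n_cyclone = sum(d$side == "cyclone"),
               n_anticyclone = sum(d$side == "anticyclone"),
               member_log2fc = paste(signif(d$log2fc, 6), collapse = ";"))
  }))
  if (mode == "pathway")
    out <- out[out$n_cyclone + out$n_anticyclone >=
                 config$pathway_min_transcripts, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("category_summaries", "data.frame")
  out
}
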