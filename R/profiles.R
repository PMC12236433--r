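#' Convert counts to per-sample relative abundances
#'
#' value(f, s) = count(f, s) / column total; every output column sums to 1.
#'
#' @param counts an [abundance_table()] with positive per-sample totals.
#' @return an [abundance_table()] of the same kind with values in \[0, 1\].
#' @export
to_relative_abundance <- function(counts) {
  tot <- colSums(counts$values)
  zero <- which(tot == 0)
  if (length(zero))
    stop("all-zero sample(s): ",
         paste(samples(counts)[zero], collapse = ", "), call. = FALSE)
  abundance_table(sweep(counts$values, 2L, tot, "/"), counts$kind,
                  counts$annotations)
}

#' Depth window around the deep chlorophyll maximum
#'
#' `at_or_above_dcm` keeps samples with depth <= the sample's own DCM depth
#' (inclusive of the DCM sample). `custom` keeps dcm + min_offset <= depth
#' <= dcm + max_offset, with negative offsets above the DCM.
#'
#' @param mode `"at_or_above_dcm"` or `"custom"`.
#' @param min_offset_m,max_offset_m window bounds in meters relative to the
#'   DCM (custom mode only); `min_offset_m <= max_offset_m`.
#' @return a `window_spec` list.
#' @export
window_spec <- function(mode = c("at_or_above_dcm", "custom"),
                        min_offset_m = NA_real_, max_offset_m = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "custom") {
    if (is.na(min_offset_m) || is.na(max_offset_m))
      stop("custom window needs min_offset_m and max_offset_m", call. = FALSE)
    if (min_offset_m > max_offset_m)
      stop("min_offset_m must be <= max_offset_m", call. = FALSE)
  }
  structure(list(mode = mode, min_offset_m = min_offset_m,
                 max_offset_m = max_offset_m), class = "window_spec")
}

#' Select samples inside a depth window
#'
#' @param meta `sample_meta` with `depth_m` and `dcm_depth_m` for the
#'   candidate samples (depth-less diel samples are never selected).
#' @param window a [window_spec()].
#' @return character vector of retained sample ids, order-stable.
#' @export
select_window <- function(meta, window) {
  has_depth <- !is.na(meta$depth_m) & !is.na(meta$dcm_depth_m)
  m <- meta[has_depth, , drop = FALSE]
  keep <- if (window$mode == "at_or_above_dcm") {
    m$depth_m <= m$dcm_depth_m
  } else {
    m$depth_m >= m$dcm_depth_m + window$min_offset_m &
      m$depth_m <= m$dcm_depth_m + window$max_offset_m
  }
  ids <- m$sample_id[keep]
  if (!length(ids)) stop("no sample retained by window", call. = FALSE)
  ids
}

#' Depth-profile enrichment test between eddy types
#'
#' Kruskal-Wallis rank test on one feature's relative abundances between the
#' two eddy groups, restricted to samples inside the depth window. Direction
#' is the sign of median(group_a) - median(group_b).
#'
#' @param rel relative-abundance [abundance_table()].
#' @param meta `sample_meta` covering the table's samples.
#' @param feature feature id to test.
#' @param window a [window_spec()].
#' @param group_a,group_b eddy labels (default cyclone vs anticyclone).
#' @return a `test_result` with an added `direction` field (+1 means
#'   group_a-enriched).
#' @export
enrichment_test <- function(rel, meta, feature,
                            window = window_spec("at_or_above_dcm"),
                            group_a = "cyclone", group_b = "anticyclone") {
  if (!feature %in% features(rel))
    stop("feature not in table: ", feature, call. = FALSE)
  in_win <- select_window(meta, window)
  ids_a <- meta$sample_id[meta$eddy == group_a & meta$sample_id %in% in_win]
  ids_b <- meta$sample_id[meta$eddy == group_b & meta$sample_id %in% in_win]
  ids_a <- intersect(ids_a, samples(rel))
  ids_b <- intersect(ids_b, samples(rel))
  if (length(ids_a) < 2L || length(ids_b) < 2L)
    stop("need >= 2 samples per group inside the window", call. = FALSE)
  va <- rel$values[feature, ids_a]
  vb <- rel$values[feature, ids_b]
  res <- kruskal_wallis_test(list(va, vb))
  res$direction <- sign(stats::median(va) - stats::median(vb))
  res
}

#' Extract per-eddy depth profiles for a feature
#'
#' @param rel relative-abundance [abundance_table()].
#' @param meta `sample_meta`.
#' @param feature feature id.
#' @return data.frame (`feature_id`, `eddy`, `depth_m`, `depth_offset_m`,
#'   `relative_abundance`) sorted by eddy then depth.
#' @export
depth_profile <- function(rel, meta, feature) {
  if (!feature %in% features(rel))
    stop("feature not in table: ", feature, call. = FALSE)
  m <- meta[!is.na(meta$depth_m) & meta$sample_id %in% samples(rel), ,
            drop = FALSE]
  out <- data.frame(feature_id = feature, eddy = m$eddy, depth_m = m$depth_m,
                    depth_offset_m = m$depth_m - m$dcm_depth_m,
                    relative_abundance = rel$values[feature, m$sample_id])
  out[order(out$eddy, out$depth_m), , drop = FALSE]
}
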