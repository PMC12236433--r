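#' Feature-by-sample abundance table
#'
#' The universal currency of every pipeline stage: a features x samples matrix
#' of non-negative values with a kind tag saying what the values are, and an
#' optional per-feature annotation table (taxon, ecotype, KO, eggNOG id, COG
#' categories, pathways).
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   have row and column names and contain no negative or missing cells
#'   (absence is encoded as 0).
#' @param kind one of `"asv_count"`, `"its_rpb"`, `"ko_rpb"`,
#'   `"transcript_count"`, `"transcript_per_ml"`, `"species_sum"`.
#' @param annotations optional `data.frame` keyed by a `feature_id` column;
#'   absent annotation fields are empty strings, never sentinel numbers.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, kind, annotations = NULL) {
  kinds <- c("asv_count", "its_rpb", "ko_rpb", "transcript_count",
             "transcript_per_ml", "species_sum")
  kind <- match.arg(kind, kinds)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values))
    stop("missing cells are not allowed; encode absence as 0", call. = FALSE)
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at feature '%s', sample '%s'",
                 rownames(values)[idx[1L]], colnames(values)[idx[2L]]),
         call. = FALSE)
  }
  if (!is.null(annotations)) {
    if (!is.data.frame(annotations) || is.null(annotations$feature_id))
      stop("'annotations' must be a data.frame with a feature_id column",
           call. = FALSE)
    annotations[] <- lapply(annotations, function(col) {
      if (is.character(col)) { col[is.na(col)] <- ""; col } else col
    })
  }
  structure(list(values = values, kind = kind, annotations = annotations),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> kind=%s: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations))
    cat("  annotations: ",
        paste(setdiff(names(x$annotations), "feature_id"), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Feature ids of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of feature ids in table order.
#' @export
features <- function(x) rownames(x$values)

#' Sample ids of an abundance table
#' @param x an `abundance_table`.
#' @return character vector of sample ids in table order.
#' @export
samples <- function(x) colnames(x$values)

# subset samples keeping feature/sample order stable
subset_samples <- function(tab, sample_ids) {
  missing <- setdiff(sample_ids, samples(tab))
  if (length(missing))
    stop("samples absent from table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- samples(tab)[samples(tab) %in% sample_ids]
  abundance_table(tab$values[, keep, drop = FALSE], tab$kind, tab$annotations)
}

# annotation lookup for a set of features; returns "" where absent
annotation_field <- function(tab, field) {
  out <- setNames(rep("", nrow(tab$values)), features(tab))
  ann <- tab$annotations
  if (!is.null(ann) && field %in% names(ann)) {
    hit <- intersect(features(tab), ann$feature_id)
    out[hit] <- as.character(ann[[field]][match(hit, ann$feature_id)])
    out[is.na(out)] <- ""
  }
  out
}
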