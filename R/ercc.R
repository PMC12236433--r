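#' Synthetic ERCC-style spike-in reference
#'
#' A 92-entry reference of plausible molar amounts (molecules added per
#' sample) spanning six orders of magnitude, generated deterministically.
#' These are synthetic fixture values for self-contained testing, not the
#' vendor's certified concentrations.
#'
#' @return data.frame with columns `ercc_id`, `molecules`.
#' @export
ercc_reference <- function() {
  n <- 92L
  # log-uniform ladder over 1e1..1e7 molecules, fixed small jitter
  lad <- 10^seq(1, 7, length.out = n)
  jit <- 1 + 0.2 * sin(seq_len(n) * 2.399963)   # deterministic, golden-angle
  data.frame(ercc_id = sprintf("ERCC-%05d", seq_len(n)),
             molecules = signif(lad * jit, 6))
}

#' Fit the per-sample spike-in correction factor
#'
#' Least-squares slope of observed spike counts on known spiked molecules,
#' with the intercept forced to the origin: f = sum(m*c) / sum(m^2), in
#' counts per molecule. By default all reference spikes enter the fit,
#' including undetected (count 0) ones, since zeros carry information in a
#' forced-origin fit; `detected_only = TRUE` restricts to counts > 0.
#'
#' @param molecules known molecules added per spike (> 0).
#' @param counts observed mapped counts per spike (same length, >= 2).
#' @param detected_only drop zero-count spikes before fitting.
#' @return the slope f (counts per molecule).
#' @export
fit_correction_factor <- function(molecules, counts, detected_only = FALSE) {
  if (length(molecules) != length(counts) || length(molecules) < 2L)
    stop("molecules and counts must be equal-length vectors of length >= 2",
         call. = FALSE)
  if (any(molecules <= 0)) stop("molecules must be > 0", call. = FALSE)
  if (all(counts == 0)) stop("no spike-ins detected", call. = FALSE)
  if (detected_only) {
    keep <- counts > 0
    molecules <- molecules[keep]; counts <- counts[keep]
  }
  sum(molecules * counts) / sum(molecules^2)
}

#' Per-sample spike-in detection limit
#'
#' The lowest molar amount among spikes observed (count > 0) in the sample.
#'
#' @inheritParams fit_correction_factor
#' @return the detection limit L in molecules.
#' @export
detection_limit <- function(molecules, counts) {
  if (length(molecules) != length(counts))
    stop("molecules and counts must have equal length", call. = FALSE)
  if (all(counts == 0)) stop("no spike-ins detected", call. = FALSE)
  min(molecules[counts > 0])
}

#' Calibrate every sample against the spike-in reference
#'
#' @param spikes an [abundance_table()] of spike counts (spike ids x
#'   samples).
#' @param reference data.frame with `ercc_id` and `molecules` columns; every
#'   spike id in `spikes` must be present.
#' @param detected_only passed to [fit_correction_factor()].
#' @return data.frame of class `spikein_calibration`: `sample_id`,
#'   `correction_factor`, `detection_limit`, `n_spikes_detected`.
#' @export
calibrate_spikes <- function(spikes, reference, detected_only = FALSE) {
  miss <- setdiff(features(spikes), reference$ercc_id)
  if (length(miss))
    stop("spike ids absent from reference: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mol <- reference$molecules[match(features(spikes), reference$ercc_id)]
  out <- do.call(rbind, lapply(samples(spikes), function(s) {
    cnt <- spikes$values[, s]
    data.frame(sample_id = s,
               correction_factor = fit_correction_factor(mol, cnt, detected_only),
               detection_limit = detection_limit(mol, cnt),
               n_spikes_detected = sum(cnt > 0))
  }))
  class(out) <- c("spikein_calibration", "data.frame")
  out
}

#' Convert raw transcript counts to molecules per ml
#'
#' value(t, s) = raw(t, s) / f_s / volume_ml_s, where f_s is the sample's
#' spike-in correction factor. Entries whose molecule estimate raw/f_s falls
#' below the sample's detection limit are flagged below-detection; the value
#' is retained (never zeroed) and downstream stages choose exclusion.
#'
#' @param counts `transcript_count` [abundance_table()].
#' @param calib [calibrate_spikes()] output covering every sample.
#' @param meta `sample_meta` with `volume_ml` for every sample.
#' @return an [abundance_table()] of kind `transcript_per_ml` with a logical
#'   `below_detection` matrix attached as `$below_detection`.
#' @export
normalize_to_per_ml <- function(counts, calib, meta) {
  smp <- samples(counts)
  miss_c <- setdiff(smp, calib$sample_id)
  if (length(miss_c))
    stop("no spike-in calibration for sample(s): ",
         paste(miss_c, collapse = ", "), call. = FALSE)
  mrow <- match(smp, meta$sample_id)
  if (anyNA(mrow))
    stop("no metadata for sample(s): ",
         paste(smp[is.na(mrow)], collapse = ", "), call. = FALSE)
  vol <- meta$volume_ml[mrow]
  if (any(is.na(vol) | vol <= 0))
    stop("volume_ml missing or <= 0 for sample(s): ",
         paste(smp[is.na(vol) | vol <= 0], collapse = ", "), call. = FALSE)
  crow <- match(smp, calib$sample_id)
  f <- calib$correction_factor[crow]
  L <- calib$detection_limit[crow]
  mol_est <- sweep(counts$values, 2L, f, "/")
  per_ml <- sweep(mol_est, 2L, vol, "/")
  out <- abundance_table(per_ml, "transcript_per_ml", counts$annotations)
  out$below_detection <- sweep(mol_est, 2L, L, "<")
  out
}
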