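# Stage-derived substreams off one global seed: reruns of a single stage
# reproduce it without replaying earlier stages. Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 1009L)
}

#' Simulate the two-eddy sampling design
#'
#' Per eddy: 15 depth samples at 5 m intervals centered on that eddy's DCM
#' (cyclone DCM 100 m, anticyclone 120 m by default, the ~20 m displacement
#' typical of opposite-polarity eddy pairs), plus 18 diel samples at the
#' DCM taken at 4 h spacing. Filtered volumes are drawn uniform in
#' \[1000, 2000\] ml.
#'
#' @param seed integer seed.
#' @param dcm_cyclone_m,dcm_anticyclone_m DCM depths in meters.
#' @param n_depths,depth_step_m depth-profile design (odd count, meters).
#' @param n_diel,diel_step_h diel design at the DCM.
#' @return a `sample_meta` data.frame with 2 x (n_depths + n_diel) rows;
#'   diel samples have `depth_m = NA` and a `timepoint` in hours.
#' @export
simulate_design <- function(seed = 1L, dcm_cyclone_m = 100,
                            dcm_anticyclone_m = 120, n_depths = 15L,
                            depth_step_m = 5, n_diel = 18L, diel_step_h = 4) {
  set.seed(stage_seed(seed, "design"))
  half <- (n_depths - 1L) %/% 2L
  offsets <- seq(-half, half) * depth_step_m
  rows <- list()
  for (eddy in c("cyclone", "anticyclone")) {
    dcm <- if (eddy == "cyclone") dcm_cyclone_m else dcm_anticyclone_m
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_d%03d", substr(eddy, 1, 4), dcm + offsets),
      eddy = eddy, depth_m = dcm + offsets, dcm_depth_m = dcm,
      volume_ml = NA_real_, timepoint = NA_real_, station = "center")
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sprintf("%s_t%02d", substr(eddy, 1, 4),
                          seq_len(n_diel) - 1L),
      eddy = eddy, depth_m = NA_real_, dcm_depth_m = dcm,
      volume_ml = NA_real_,
      timepoint = (seq_len(n_diel) - 1L) * diel_step_h, station = "center")
  }
  meta <- do.call(rbind, rows)
  meta$volume_ml <- stats::runif(nrow(meta), 1000, 2000)
  sample_meta(meta)
}

#' Default ecotype depth-profile model
#'
#' Gaussian-in-depth peaks per ecotype and eddy. The high-light HLI ecotype
#' peaks 10 m above the cyclone DCM with a large height, but is a minor,
#' DCM-centered population in the anticyclone, so noise-free HLI never
#' exceeds HLII at any anticyclone depth; HLII is the DCM-centered majority
#' in both eddies.
#'
#' @return data.frame: `ecotype`, `eddy`, `offset_m`, `width_m`, `height`.
#' @export
default_ecotype_model <- function() {
  data.frame(
    ecotype = c("HLI", "HLI", "HLII", "HLII"),
    eddy = c("cyclone", "anticyclone", "cyclone", "anticyclone"),
    offset_m = c(-10, 0, 0, 0),
    width_m = c(15, 15, 15, 15),
    height = c(2000, 100, 1500, 1500))
}

#' Simulate ecotype marker abundances over the depth profiles
#'
#' value(ecotype, sample) = height * exp(-(depth - (dcm + offset))^2 /
#' (2 width^2)) * lognormal(0, sigma); sigma = 0 gives the noise-free
#' closed form.
#'
#' @param model data.frame as [default_ecotype_model()].
#' @param meta `sample_meta`; every row must carry a depth.
#' @param sigma lognormal noise sd on the log scale.
#' @param seed integer seed.
#' @return an [abundance_table()] of kind `its_rpb` (ecotypes x samples).
#' @export
simulate_ecotype_rpb <- function(model, meta, sigma = 0.2, seed = 1L) {
  if (any(is.na(meta$depth_m)))
    stop("sample without depth: ",
         meta$sample_id[is.na(meta$depth_m)][1L], call. = FALSE)
  set.seed(stage_seed(seed, "ecotype"))
  ecos <- unique(model$ecotype)
  vals <- matrix(0, length(ecos), nrow(meta),
                 dimnames = list(ecos, meta$sample_id))
  for (e in ecos) for (i in seq_len(nrow(meta))) {
    par <- model[model$ecotype == e & model$eddy == meta$eddy[i], ]
    if (!nrow(par))
      stop("model does not cover ecotype ", e, " in eddy ", meta$eddy[i],
           call. = FALSE)
    peak <- meta$dcm_depth_m[i] + par$offset_m
    mu <- par$height * exp(-(meta$depth_m[i] - peak)^2 / (2 * par$width_m^2))
    noise <- if (sigma > 0) stats::rlnorm(1, 0, sigma) else 1
    vals[e, i] <- mu * noise
  }
  abundance_table(vals, "its_rpb")
}

#' Simulate a KO abundance table coupled to an ecotype marker
#'
#' Enriched KOs track the target ecotype: value = beta * ecotype RPB *
#' lognormal(0, sigma). Null KOs are depth-independent baselines with the
#' same multiplicative noise.
#'
#' @param ecotype_table [simulate_ecotype_rpb()] output.
#' @param target_ecotype ecotype the enriched KOs are coupled to.
#' @param beta named vector of coupling slopes (> 0), one per enriched KO.
#' @param n_null_kos number of null (uncoupled) KOs.
#' @param sigma lognormal noise sd.
#' @param seed integer seed.
#' @return list: `ko_table` (an [abundance_table()] of kind `ko_rpb`),
#'   `enriched_kos` (character vector).
#' @export
simulate_ko_table <- function(ecotype_table, target_ecotype = "HLI",
                              beta = NULL, n_null_kos = 200L, sigma = 0.5,
                              seed = 1L) {
  if (!target_ecotype %in% features(ecotype_table))
    stop("ecotype_table lacks ecotype ", target_ecotype, call. = FALSE)
  set.seed(stage_seed(seed, "ko"))
  if (is.null(beta))
    beta <- stats::setNames(exp(stats::runif(10, log(0.5), log(2))),
                            sprintf("K%05d", 1:10))
  if (any(beta <= 0)) stop("coupling slope beta must be > 0", call. = FALSE)
  eco <- ecotype_table$values[target_ecotype, ]
  n_s <- length(eco)
  noise <- function(n) if (sigma > 0) stats::rlnorm(n, 0, sigma) else rep(1, n)
  enr <- t(vapply(beta, function(b) b * eco * noise(n_s), numeric(n_s)))
  null_ids <- sprintf("K%05d", 100 + seq_len(n_null_kos))
  base <- exp(stats::runif(n_null_kos, log(10), log(2000)))
  nul <- base * matrix(noise(n_null_kos * n_s), n_null_kos, n_s)
  vals <- rbind(enr, nul)
  dimnames(vals) <- list(c(names(beta), null_ids), names(eco))
  list(ko_table = abundance_table(vals, "ko_rpb"),
       enriched_kos = names(beta))
}

#' Simulate diel metatranscriptomes with ERCC-style spike-ins
#'
#' Transcript counts are negative binomial with mean
#' efficiency_s * volume_s * conc, where conc = base concentration *
#' transcript weight * taxon fold change (applied in the anticyclone) *
#' within-taxon DE shift (2^log2FC in the anticyclone). Per-sample capture
#' efficiency is uniform in \[0.2, 0.8\] and also generates the spike
#' counts: Poisson with mean efficiency * molecules (exactly
#' efficiency * molecules when `poisson_noise = FALSE`).
#'
#' @param meta diel `sample_meta` (18 samples per eddy by default design).
#' @param reference spike-in reference data.frame (`ercc_id`, `molecules`).
#' @param taxon_fc named vector of true anticyclone/cyclone fold changes.
#' @param taxon_ecotype named vector taxon -> ecotype label ("" allowed).
#' @param de_transcripts data.frame (`transcript_id`, `taxon_id`, `log2fc`)
#'   of within-taxon differentially expressed transcripts.
#' @param transcripts_per_taxon baseline transcripts simulated per taxon.
#' @param n_null_transcripts_de_taxon extra null transcripts added to the
#'   taxon hosting the DE transcripts.
#' @param base_conc baseline transcript concentration (molecules per ml).
#' @param dispersion NB dispersion (var = mu + dispersion * mu^2).
#' @param poisson_noise Poisson-sample the spike counts.
#' @param seed integer seed.
#' @return list: `counts` (`transcript_count` [abundance_table()] with
#'   taxon/ecotype/eggNOG/COG/pathway annotations), `spikes` (spike-count
#'   [abundance_table()]), `efficiency` (named per-sample truth),
#'   `annotations` (the annotation data.frame).
#' @export
simulate_transcriptomes <- function(meta, reference = ercc_reference(),
                                    taxon_fc = default_taxon_fc(),
                                    taxon_ecotype = NULL,
                                    de_transcripts = default_de_transcripts(),
                                    transcripts_per_taxon = 5L,
                                    n_null_transcripts_de_taxon = 200L,
                                    base_conc = 0.2, dispersion = 0.1,
                                    poisson_noise = TRUE, seed = 1L) {
  if (is.null(reference$ercc_id) || is.null(reference$molecules))
    stop("missing ERCC reference entry columns (ercc_id, molecules)",
         call. = FALSE)
  set.seed(stage_seed(seed, "transcriptome"))
  n_s <- nrow(meta)
  eff <- stats::setNames(stats::runif(n_s, 0.2, 0.8), meta$sample_id)
  is_anti <- meta$eddy == "anticyclone"

  taxa <- names(taxon_fc)
  if (is.null(taxon_ecotype))
    taxon_ecotype <- stats::setNames(
      ifelse(taxon_fc < 1, "HLI", ifelse(taxon_fc > 1, "HLII", "")), taxa)
  de_taxon <- unique(de_transcripts$taxon_id)
  if (length(de_taxon) && !all(de_taxon %in% taxa))
    stop("de_transcripts name taxa absent from taxon_fc", call. = FALSE)

  tx_rows <- list()
  for (t in taxa) {
    n_tx <- transcripts_per_taxon +
      if (t %in% de_taxon) n_null_transcripts_de_taxon else 0L
    ids <- sprintf("%s_tx%03d", t, seq_len(n_tx))
    lfc <- stats::setNames(rep(0, n_tx), ids)
    if (t %in% de_taxon) {
      de <- de_transcripts[de_transcripts$taxon_id == t, ]
      ids[seq_len(nrow(de))] <- de$transcript_id
      names(lfc) <- ids
      lfc[de$transcript_id] <- de$log2fc
    }
    tx_rows[[t]] <- data.frame(transcript_id = ids, taxon_id = t,
                               de_log2fc = unname(lfc))
  }
  tx <- do.call(rbind, tx_rows)
  rownames(tx) <- NULL
  n_t <- nrow(tx)
  weight <- exp(stats::runif(n_t, log(0.5), log(2)))

  counts <- matrix(0, n_t, n_s, dimnames = list(tx$transcript_id,
                                                meta$sample_id))
  for (j in seq_len(n_s)) {
    fc_mult <- if (is_anti[j]) taxon_fc[tx$taxon_id] else rep(1, n_t)
    de_mult <- if (is_anti[j]) 2^tx$de_log2fc else rep(1, n_t)
    mu <- eff[j] * meta$volume_ml[j] * base_conc * weight * fc_mult * de_mult
    counts[, j] <- stats::rnbinom(n_t, mu = mu, size = 1 / dispersion)
  }

  spikes <- matrix(0, nrow(reference), n_s,
                   dimnames = list(reference$ercc_id, meta$sample_id))
  for (j in seq_len(n_s)) {
    lam <- eff[j] * reference$molecules
    spikes[, j] <- if (poisson_noise) stats::rpois(nrow(reference), lam) else lam
  }

  cogs <- c("J", "K", "L", "C", "E", "P", "T", "O")
  pw_pool <- sprintf("map%05d", 1:12)
  ann <- data.frame(
    feature_id = tx$transcript_id, taxon = tx$taxon_id,
    ecotype = unname(taxon_ecotype[tx$taxon_id]),
    KO = sprintf("K%05d", 5000 + seq_len(n_t)),
    eggNOG = sprintf("COG%04d", seq_len(n_t)),
    COG_category = sample(cogs, n_t, replace = TRUE),
    pathway = vapply(seq_len(n_t), function(i)
      paste(sample(pw_pool, sample(1:2, 1)), collapse = ";"), ""))

  list(counts = abundance_table(counts, "transcript_count", ann),
       spikes = abundance_table(spikes, "transcript_count"),
       efficiency = eff, annotations = ann,
       truth = list(taxon_fc = taxon_fc,
                    de_transcripts = de_transcripts,
                    spike_efficiency = eff))
}

#' Default true taxon fold changes
#'
#' Twelve differentially represented taxa (six at FC 4, anticyclone-
#' enriched; six at FC 1/4, cyclone-enriched, labelled HLI) plus 100 null
#' taxa at FC 1.
#'
#' @param n_null number of null taxa.
#' @return named numeric vector of anticyclone/cyclone fold changes.
#' @export
default_taxon_fc <- function(n_null = 100L) {
  fc <- c(rep(4, 6), rep(0.25, 6), rep(1, n_null))
  names(fc) <- c(sprintf("sp_anti%02d", 1:6), sprintf("sp_cyc%02d", 1:6),
                 sprintf("sp_null%03d", seq_len(n_null)))
  fc
}

#' Default within-taxon DE transcripts
#'
#' Five truly differentially expressed transcripts (|log2FC| = 3) hosted by
#' the first cyclone-enriched taxon, alongside that taxon's null
#' transcripts.
#'
#' @return data.frame: `transcript_id`, `taxon_id`, `log2fc`.
#' @export
default_de_transcripts <- function() {
  data.frame(transcript_id = sprintf("sp_cyc01_de%02d", 1:5),
             taxon_id = "sp_cyc01",
             log2fc = c(3, 3, 3, -3, -3))
}

#' Simulate a complete two-eddy study
#'
#' Convenience wrapper chaining the design, ecotype depth profiles, coupled
#' KO table, and diel metatranscriptomes with spike-ins, under one seed
#' with per-stage substreams.
#'
#' @param seed integer seed.
#' @param sigma_ecotype,sigma_ko lognormal noise sd for the depth-profile
#'   and KO stages.
#' @param ... passed to [simulate_transcriptomes()].
#' @return list: `meta`, `depth_meta`, `diel_meta`, `ecotypes`, `ko`,
#'   `transcriptome`, `reference`, `truth`.
#' @export
simulate_eddy_study <- function(seed = 1L, sigma_ecotype = 0.2,
                                sigma_ko = 0.5, ...) {
  meta <- simulate_design(seed)
  depth_meta <- meta[!is.na(meta$depth_m), , drop = FALSE]
  diel_meta <- meta[is.na(meta$depth_m), , drop = FALSE]
  eco <- simulate_ecotype_rpb(default_ecotype_model(), depth_meta,
                              sigma = sigma_ecotype, seed = seed)
  ko <- simulate_ko_table(eco, target_ecotype = "HLI",
                          sigma = sigma_ko, seed = seed)
  ref <- ercc_reference()
  tr <- simulate_transcriptomes(diel_meta, reference = ref, seed = seed, ...)
  list(meta = meta, depth_meta = depth_meta, diel_meta = diel_meta,
       ecotypes = eco, ko = ko$ko_table, transcriptome = tr,
       reference = ref,
       truth = list(enriched_kos = ko$enriched_kos,
                    taxon_fc = tr$truth$taxon_fc,
                    de_transcripts = tr$truth$de_transcripts,
                    spike_efficiency = tr$truth$spike_efficiency))
}
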