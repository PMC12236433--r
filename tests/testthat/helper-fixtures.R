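# small in-code fixtures shared across test files

toy_table <- function(values = matrix(c(1, 3, 2, 4), 2,
                                      dimnames = list(c("f1", "f2"),
                                                      c("s1", "s2"))),
                      kind = "asv_count", annotations = NULL) {
  abundance_table(values, kind, annotations)
}

toy_meta <- function() {
  sample_meta(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    eddy = c("cyclone", "cyclone", "anticyclone", "anticyclone"),
    depth_m = c(95, 105, 115, 125),
    dcm_depth_m = c(100, 100, 120, 120),
    volume_ml = c(1500, 1200, 1400, 1600),
    timepoint = NA_real_, station = "center"))
}

# random non-negative table for property tests
random_table <- function(n_f = 8L, n_s = 5L, kind = "asv_count") {
  vals <- matrix(stats::rexp(n_f * n_s) + 0.01, n_f, n_s,
                 dimnames = list(sprintf("f%02d", seq_len(n_f)),
                                 sprintf("s%02d", seq_len(n_s))))
  abundance_table(vals, kind)
}

# diel metadata with n samples per eddy, equal volumes unless given
diel_meta <- function(n = 18L, volume_ml = 1500) {
  sample_meta(data.frame(
    sample_id = c(sprintf("c%02d", seq_len(n)), sprintf("a%02d", seq_len(n))),
    eddy = rep(c("cyclone", "anticyclone"), each = n),
    depth_m = NA_real_, dcm_depth_m = rep(c(100, 120), each = n),
    volume_ml = volume_ml,
    timepoint = rep((seq_len(n) - 1) * 4, 2), station = "center"))
}

# swap cyclone/anticyclone labels in a metadata set
swap_eddies <- function(meta) {
  m <- meta
  m$eddy <- c(cyclone = "anticyclone", anticyclone = "cyclone",
              front = "front")[meta$eddy]
  m
}
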