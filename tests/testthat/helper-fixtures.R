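# Small study conditions for fast tests; scientific defaults are unchanged,
# only the problem size is reduced.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_arrays = 2L, n_tiling_probes = 300L,
                   n_control_probes = 80L, n_promoter_probes = 200L,
                   n_planted_sites = 1L, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# Deterministic limb of the generator: no noise, no bias, no floor, full
# occupancy — the log-ratio of a probe with weight w is exactly w * shift.
exact_config <- function(...) {
  quick_config(noise_sd = 0, dye_trend_coeffs = 0, array_trend_sd = 0,
               array_scale_sd = 0, array_offset_sd = 0, array_ip_sd = 0,
               background_floor_drop = Inf, nonspecific_retention = 1,
               occupancy = 1, ...)
}

# 1/5-scale MeDIP-like and ChIP-like conditions (full probe-mix proportions)
small_medip_config <- function(seed, ...) {
  medip_like_config(n_tiling_probes = 1600L, n_promoter_probes = 6000L,
                    n_control_probes = 400L, seed = seed, ...)
}
small_chip_config <- function(seed, ...) {
  chip_like_config(n_tiling_probes = 1600L, n_promoter_probes = 6000L,
                   n_control_probes = 400L, seed = seed, ...)
}

write_toy_pair <- function(path, probe_id, chrom, position, pm,
                           comments = FALSE) {
  lines <- c(
    if (comments) c("# platform: toy", "# date: never"),
    paste(c("PROBE_ID", "SEQ_ID", "POSITION", "PM"), collapse = "\t"),
    paste(probe_id, chrom, position, pm, sep = "\t"))
  writeLines(lines, path)
  path
}

toy_annotation <- function(n = 3L, category = "TILING", chrom = "chr1",
                           spacing = 100L, probe_length = 50L) {
  probe_annotation(probe_id = sprintf("P%03d", seq_len(n)),
                   chrom = rep(chrom, length.out = n),
                   position = (seq_len(n) - 1L) * spacing,
                   probe_length = probe_length,
                   category = rep(category, length.out = n))
}

# annotation subset helper preserving class
subset_annotation <- function(ann, idx) {
  out <- ann[idx, , drop = FALSE]
  class(out) <- class(ann)
  out
}

random_experiment <- function(n = 500L, n_arrays = 3L, seed = 7L) {
  set.seed(seed)
  ann <- probe_annotation(
    probe_id = sprintf("R%04d", seq_len(n)),
    chrom = "chr1",
    position = (seq_len(n) - 1L) * 100L,
    probe_length = 50L,
    category = sample(PROBE_CATEGORIES, n, replace = TRUE,
                      prob = c(0.2, 0.4, 0.4)))
  arrays <- lapply(seq_len(n_arrays), function(j)
    two_channel_array(paste0("a", j),
                      green = 2^rnorm(n, 10, 1),
                      red = 2^rnorm(n, 10 + 0.1 * j, 1)))
  experiment_set(ann, arrays)
}
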