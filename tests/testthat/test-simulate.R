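test_that("identical config and seed reproduce the experiment bit-for-bit", {
  a <- simulate_experiment(quick_config(seed = 9L))
  b <- simulate_experiment(quick_config(seed = 9L))
  expect_identical(a, b)
  c <- simulate_experiment(quick_config(seed = 10L))
  expect_false(identical(a$experiment, c$experiment))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(simulate_experiment(quick_config()))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("null model: no enrichment, no noise, no bias gives M == 0", {
  sim <- simulate_experiment(exact_config(enriched_fraction = 0,
                                          n_planted_sites = 0L))
  ma <- compute_ma(sim$experiment)
  expect_lt(max(abs(ma$M)), 1e-12)
  expect_true(all(sim$truth$weight == 0))
})

test_that("deterministic limb: controls at 0, enriched promoters at the shift", {
  sim <- simulate_experiment(exact_config(enrichment_shift = 1.5,
                                          enriched_fraction = 0.5,
                                          n_planted_sites = 0L))
  ann <- sim$experiment$annotation
  ma <- compute_ma(sim$experiment)
  ctrl <- ann$category == "NEGATIVE_CONTROL"
  enr <- sim$truth$weight == 1
  unenr <- ann$category == "PROMOTER" & sim$truth$weight == 0
  expect_lt(max(abs(ma$M[ctrl, ])), 1e-12)
  expect_lt(max(abs(ma$M[unenr, ])), 1e-12)
  expect_lt(max(abs(ma$M[enr, ] - 1.5)), 1e-12)
})

test_that("tiling peak shape follows the exponential fragment-coverage decay", {
  sim <- simulate_experiment(exact_config(n_tiling_probes = 500L,
                                          enrichment_shift = 1.5,
                                          enriched_fraction = 0,
                                          n_planted_sites = 1L,
                                          mean_fragment_length = 600))
  ann <- sim$experiment$annotation
  ma <- compute_ma(sim$experiment)
  til <- which(ann$category == "TILING")
  center <- sim$truth$site_intervals$center[1]
  d <- abs(ann$position[til] - center)
  # closed form: M = shift * exp(-d / L)
  expect_equal(ma$M[til, 1], 1.5 * exp(-d / 600), tolerance = 1e-12,
               ignore_attr = TRUE)
  # probe at exactly one fragment length from the center
  at_L <- til[d == 600][1]
  expect_equal(ma$M[at_L, 1], 1.5 * exp(-1), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(ma$M[at_L, 1], 0.5518, tolerance = 1e-4, ignore_attr = TRUE)

  # expected M is unimodal with its peak at the probe nearest the center
  peak <- which.max(ma$M[til, 1])
  expect_equal(d[peak], min(d))
  expect_true(all(diff(ma$M[til, 1][seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(ma$M[til, 1][peak:length(til)]) <= 1e-12))
})

test_that("enriched-minus-control mean difference recovers the shift", {
  cfg <- exact_config(noise_sd = 0.25, n_arrays = 1L,
                      n_promoter_probes = 4000L, n_control_probes = 2000L,
                      n_tiling_probes = 50L, n_planted_sites = 0L,
                      enriched_fraction = 0.5, enrichment_shift = 1.5,
                      seed = 11L)
  sim <- simulate_experiment(cfg)
  ann <- sim$experiment$annotation
  ma <- compute_ma(sim$experiment)
  enr <- sim$truth$weight == 1
  ctrl <- ann$category == "NEGATIVE_CONTROL"
  diff_hat <- mean(ma$M[enr, 1]) - mean(ma$M[ctrl, 1])
  se <- sqrt(2 * 0.25^2) * sqrt(1 / sum(enr) + 1 / sum(ctrl))
  expect_lt(abs(diff_hat - 1.5), 3 * se)
})

test_that("ChIP-like data overlap while MeDIP-like data separate", {
  auc_of <- function(cfg) {
    sim <- simulate_experiment(cfg)
    ann <- sim$experiment$annotation
    ma <- compute_ma(sim$experiment)
    ctrl <- ann$category == "NEGATIVE_CONTROL"
    prom <- ann$category == "PROMOTER"
    roc_auc(as.vector(ma$M[ctrl, ]), as.vector(ma$M[prom, ]))$auc
  }
  auc_chip <- auc_of(small_chip_config(seed = 5L, n_arrays = 3L))
  auc_medip <- auc_of(small_medip_config(seed = 5L, n_arrays = 3L))
  expect_gt(auc_medip, auc_chip + 0.05)
  expect_gt(auc_medip, 0.75)
  expect_lt(auc_chip, 0.85)
})

test_that("ground truth honors its invariants", {
  sim <- simulate_experiment(quick_config(n_planted_sites = 2L,
                                          n_tiling_probes = 600L))
  ann <- sim$experiment$annotation
  ctrl <- ann$category == "NEGATIVE_CONTROL"
  expect_true(all(sim$truth$weight[ctrl] == 0))
  expect_false(any(sim$truth$enriched_mask[ctrl]))
  sites <- sim$truth$site_intervals
  expect_identical(nrow(sites), 2L)
  til <- which(ann$category == "TILING")
  for (i in seq_len(nrow(sites))) {
    inside <- til[ann$position[til] >= sites$start[i] &
                    ann$position[til] <= sites$end[i]]
    expect_gt(max(sim$truth$weight[inside]), 0.5)
  }
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(n_arrays = 0), "positive")
  expect_error(simulation_config(noise_sd = -1), "non-negative")
  expect_error(simulation_config(enriched_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(occupancy = 0), "occupancy")
  expect_error(simulation_config(occupancy = c(1, 2, 3)), "occupancy")
  expect_error(simulation_config(nonspecific_retention = 0), "retention")
  expect_error(simulation_config(background_floor_drop = -1), "positive")
})

test_that("shipped preset configs load and match the constructors", {
  for (preset in c("chip-like", "medip-like")) {
    path <- system.file("extdata", paste0(preset, ".yaml"),
                        package = "regnorm")
    expect_true(nzchar(path))
    from_file <- read_simulation_config(path)
    from_fun <- if (preset == "chip-like") chip_like_config()
    else medip_like_config()
    expect_equal(from_file, from_fun)
    from_seeded <- read_simulation_config(path, seed = 99L)
    expect_identical(from_seeded$seed, 99L)
  }
})

test_that("truth tables are written as TSV alongside the experiment", {
  sim <- simulate_experiment(quick_config(n_tiling_probes = 400L))
  dir <- withr::local_tempdir()
  write_truth(sim$truth, sim$experiment$annotation, dir)
  probes <- read.delim(file.path(dir, "truth_probes.tsv"))
  expect_identical(nrow(probes), nrow(sim$experiment$annotation))
  expect_equal(probes$weight, sim$truth$weight, tolerance = 1e-6)
  sites <- read.delim(file.path(dir, "truth_sites.tsv"))
  expect_identical(nrow(sites), 1L)
})
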