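#' Simulation configuration
#'
#' Parameters of the synthetic regulation-microarray generator. The generator
#' emulates the statistical structure of two-channel ChIP-on-chip /
#' MeDIP-on-chip data: a two-component log-ratio distribution (enriched vs
#' un-enriched), tiling-probe peaks whose shape follows the
#' Poisson-fragmentation model of sonicated DNA (coverage probability
#' decaying exponentially with distance from the binding-site center),
#' an intensity-dependent dye trend, and per-array scale/offset jitter.
#'
#' @param n_arrays number of replicate arrays.
#' @param n_tiling_probes,n_control_probes,n_promoter_probes probe counts per
#'   category.
#' @param probe_spacing bp between consecutive tiling probes.
#' @param probe_length probe length, bp.
#' @param enriched_fraction fraction of promoter probes whose targets are
#'   present in the IP sample, in [0, 1].
#' @param enrichment_shift mean log2-ratio increase of a fully enriched probe
#'   (log2 units).
#' @param site_weight multiplier in (0, 1] applied to every enrichment
#'   weight; default 1.
#' @param occupancy per-target fractional occupancy / methylation model:
#'   enrichment is not an all-or-nothing condition, so each enriched target
#'   (each enriched promoter probe, each planted tiling site) carries a
#'   fraction in (0, 1] scaling its log2 enrichment. Either a scalar in
#'   (0, 1] (constant occupancy, 1 = fully enriched) or a length-2 vector
#'   of Beta shape parameters from which per-target fractions are drawn;
#'   default \code{c(2, 1)} (density 2f, favouring high occupancy), which
#'   yields the continuous, partially overlapping enriched component seen
#'   in real regulation data.
#' @param mean_fragment_length mean sonication fragment length, bp; sets the
#'   decay length of tiling peak shapes.
#' @param site_halfwidth half-width of a planted binding-site interval, bp.
#' @param background_mean,background_sd mean and probe-to-probe sd (probe
#'   affinity effect, shared between channels and arrays) of the log2
#'   abundance of a probe's genomic target in the input channel.
#' @param background_floor_drop additive background-fluorescence floor of
#'   both channels, in log2 units below \code{background_mean}: every
#'   intensity is signal + floor and negative-control probes (no genomic
#'   target) measure the floor alone. \code{Inf} disables the floor,
#'   making enrichment an exact log2 shift.
#' @param ip_floor_drop additional drop of the red (IP) channel's
#'   fluorescence floor relative to the green floor, log2 units: the
#'   immunoprecipitated pool contains far less total DNA than the input,
#'   so its non-specific background is lower. Ignored when the floor is
#'   disabled.
#' @param nonspecific_retention fraction (0, 1] of an un-enriched target's
#'   abundance carried into the IP sample by non-specific pull-down;
#'   un-enriched targets are largely absent from the experimental sample,
#'   but not perfectly so. Enrichment interpolates geometrically: red
#'   target abundance is T * 2^(w * ip * shift - (1 - w) *
#'   log2(1/retention)), linear in w on the log scale, so with the floor
#'   disabled and retention 1 the log-ratio of a probe with weight w is
#'   exactly w * shift.
#' @param noise_sd per-channel, per-array log2 measurement noise sd.
#' @param dye_trend_coeffs polynomial coefficients (constant first) of the
#'   systematic M-vs-A trend, evaluated in centered A.
#' @param array_trend_sd log-scale sd of the per-array amplitude of the
#'   dye trend (amplitude ~ LogNormal(0, array_trend_sd) multiplying the
#'   polynomial): intensity-dependent bias differs between arrays scanned
#'   on different days or settings, a between-array heterogeneity that
#'   shifts each array's control-vs-promoter separation differently.
#' @param array_scale_sd log-scale sd of the per-array multiplicative M
#'   jitter (scale ~ LogNormal(0, array_scale_sd)).
#' @param array_offset_sd sd of the per-array additive M offset.
#' @param array_ip_sd log-scale sd of the per-array immunoprecipitation
#'   efficiency (efficiency ~ LogNormal(0, array_ip_sd), multiplying the
#'   enrichment shift of that array). IP efficiency differences between
#'   replicate arrays scale the enriched component's amplitude — a
#'   between-array heterogeneity that channel scale/offset jitter cannot
#'   produce, and that only between-array normalization can remove.
#' @param n_planted_sites number of binding sites planted along the tiling
#'   path.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_arrays = 8L,
                              n_tiling_probes = 8000L,
                              n_control_probes = 2000L,
                              n_promoter_probes = 30000L,
                              probe_spacing = 100L,
                              probe_length = 50L,
                              enriched_fraction = 0.35,
                              enrichment_shift = 2,
                              site_weight = 1,
                              occupancy = c(2, 1),
                              mean_fragment_length = 600,
                              site_halfwidth = 500L,
                              background_mean = 10,
                              background_sd = 1,
                              background_floor_drop = 2.5,
                              ip_floor_drop = 2,
                              nonspecific_retention = 0.25,
                              noise_sd = 0.25,
                              dye_trend_coeffs = c(0, 0.1, -0.03),
                              array_trend_sd = 0.4,
                              array_scale_sd = 0.15,
                              array_offset_sd = 0.15,
                              array_ip_sd = 0.15,
                              n_planted_sites = 20L,
                              seed = 1L) {
  cfg <- list(n_arrays = as.integer(n_arrays),
              n_tiling_probes = as.integer(n_tiling_probes),
              n_control_probes = as.integer(n_control_probes),
              n_promoter_probes = as.integer(n_promoter_probes),
              probe_spacing = as.integer(probe_spacing),
              probe_length = as.integer(probe_length),
              enriched_fraction = as.numeric(enriched_fraction),
              enrichment_shift = as.numeric(enrichment_shift),
              site_weight = as.numeric(site_weight),
              occupancy = as.numeric(occupancy),
              mean_fragment_length = as.numeric(mean_fragment_length),
              site_halfwidth = as.integer(site_halfwidth),
              background_mean = as.numeric(background_mean),
              background_sd = as.numeric(background_sd),
              background_floor_drop = as.numeric(background_floor_drop),
              ip_floor_drop = as.numeric(ip_floor_drop),
              nonspecific_retention = as.numeric(nonspecific_retention),
              noise_sd = as.numeric(noise_sd),
              dye_trend_coeffs = as.numeric(dye_trend_coeffs),
              array_trend_sd = as.numeric(array_trend_sd),
              array_scale_sd = as.numeric(array_scale_sd),
              array_offset_sd = as.numeric(array_offset_sd),
              array_ip_sd = as.numeric(array_ip_sd),
              n_planted_sites = as.integer(n_planted_sites),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  pos <- c("n_arrays", "n_tiling_probes", "n_control_probes",
           "n_promoter_probes", "probe_spacing", "probe_length")
  for (f in pos)
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("simulation_config: ", f, " must be a positive integer")
  nonneg <- c("enrichment_shift", "mean_fragment_length", "background_sd",
              "noise_sd", "array_scale_sd", "array_offset_sd", "array_ip_sd",
              "array_trend_sd")
  for (f in nonneg)
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("simulation_config: ", f, " must be non-negative")
  if (cfg$mean_fragment_length <= 0)
    stop("simulation_config: mean_fragment_length must be > 0")
  if (is.na(cfg$background_floor_drop) || cfg$background_floor_drop <= 0)
    stop("simulation_config: background_floor_drop must be positive ",
         "(Inf disables the floor)")
  if (is.na(cfg$ip_floor_drop) || cfg$ip_floor_drop < 0 ||
      !is.finite(cfg$ip_floor_drop))
    stop("simulation_config: ip_floor_drop must be finite and >= 0")
  if (is.na(cfg$nonspecific_retention) || cfg$nonspecific_retention <= 0 ||
      cfg$nonspecific_retention > 1)
    stop("simulation_config: nonspecific_retention must lie in (0, 1]")
  if (cfg$enriched_fraction < 0 || cfg$enriched_fraction > 1)
    stop("simulation_config: enriched_fraction must lie in [0, 1]")
  if (cfg$site_weight <= 0 || cfg$site_weight > 1)
    stop("simulation_config: site_weight must lie in (0, 1]")
  if (!length(cfg$occupancy) %in% c(1L, 2L))
    stop("simulation_config: occupancy must be a scalar fraction or two ",
         "Beta shape parameters")
  if (length(cfg$occupancy) == 1L &&
      (cfg$occupancy <= 0 || cfg$occupancy > 1))
    stop("simulation_config: constant occupancy must lie in (0, 1]")
  if (length(cfg$occupancy) == 2L && any(cfg$occupancy <= 0))
    stop("simulation_config: Beta occupancy shapes must be positive")
  if (cfg$n_planted_sites < 0L)
    stop("simulation_config: n_planted_sites must be >= 0")
  if (is.na(cfg$seed)) stop("simulation_config: seed is required")
  invisible(cfg)
}

#' ChIP-like and MeDIP-like presets
#'
#' The two shipped study conditions, differing only in the enriched fraction
#' and the number of planted tiling sites: ChIP-on-chip data have a small
#' enriched component (binding sites cover little of the genome), so control
#' and promoter log-ratio densities largely overlap; MeDIP data have a
#' substantial methylated fraction, giving visibly separated components.
#'
#' @param ... overrides passed to \code{\link{simulation_config}}.
#' @return A \code{\link{simulation_config}}.
#' @export
chip_like_config <- function(...) {
  args <- utils::modifyList(
    list(enriched_fraction = 0.02, n_planted_sites = 5L), list(...))
  do.call(simulation_config, args)
}

#' @rdname chip_like_config
#' @export
medip_like_config <- function(...) {
  args <- utils::modifyList(
    list(enriched_fraction = 0.35, n_planted_sites = 20L), list(...))
  do.call(simulation_config, args)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds \code{simulation_config} fields name-for-name; missing
#' fields take the defaults. Two presets ship with the package, see
#' \code{system.file("extdata", "chip-like.yaml", package = "regnorm")} and
#' \code{"medip-like.yaml"}.
#'
#' @param path YAML file path.
#' @param seed overrides the file's seed if non-NULL.
#' @return A \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path, seed = NULL) {
  vals <- yaml::read_yaml(path)
  if (!is.null(seed)) vals$seed <- seed
  do.call(simulation_config, vals)
}

polyval_centered <- function(coeffs, a) {
  ac <- a - mean(a)
  out <- 0
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * ac^(k - 1L)
  out
}

simulated_annotation <- function(cfg) {
  spacing_np <- 1000L
  probe_annotation(
    probe_id = c(sprintf("TIL%06d", seq_len(cfg$n_tiling_probes)),
                 sprintf("PRM%06d", seq_len(cfg$n_promoter_probes)),
                 sprintf("NEG%06d", seq_len(cfg$n_control_probes))),
    chrom = c(rep("chr1", cfg$n_tiling_probes),
              rep("chr2", cfg$n_promoter_probes),
              rep("chrC", cfg$n_control_probes)),
    position = c((seq_len(cfg$n_tiling_probes) - 1L) * cfg$probe_spacing,
                 (seq_len(cfg$n_promoter_probes) - 1L) * spacing_np,
                 (seq_len(cfg$n_control_probes) - 1L) * spacing_np),
    probe_length = cfg$probe_length,
    category = c(rep("TILING", cfg$n_tiling_probes),
                 rep("PROMOTER", cfg$n_promoter_probes),
                 rep("NEGATIVE_CONTROL", cfg$n_control_probes)))
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a regulation-microarray experiment with known ground truth
#'
#' Generative model, per probe i and array j:
#' \enumerate{
#'   \item target abundance T = 2^(background_mean + probe effect), with the
#'     probe (affinity) effect ~ Normal(0, background_sd) shared between
#'     channels and across arrays; negative-control probes have no genomic
#'     target (T = 0) and measure only the additive background-fluorescence
#'     floor 2^(background_mean - background_floor_drop + probe effect),
#'     which every intensity receives (with
#'     \code{background_floor_drop = Inf} the floor is absent and controls
#'     carry T like any other probe, making enrichment an exact log2
#'     shift);
#'   \item enrichment weight w: 0 for negative controls and un-enriched
#'     promoter probes, occupancy * site_weight for enriched promoter
#'     probes; for a tiling probe at distance d from the nearest planted
#'     site center, w = occupancy * site_weight *
#'     exp(-d / mean_fragment_length) — the probability that a random
#'     sonication fragment covering the site also covers the probe, under
#'     an exponential fragment-length tail;
#'   \item channel log2 intensities with independent Normal(0, noise_sd)
#'     measurement noise per channel:
#'     green = log2(T + floor) + noise,
#'     red = log2(T * 2^(w * ip_j * enrichment_shift) + floor) + noise,
#'     with ip_j ~ LogNormal(0, array_ip_sd) the array's IP efficiency — an
#'     un-enriched target contributes only the floor to the red (IP)
#'     channel's signal above which nothing hybridizes;
#'   \item systematic bias: M_obs = scale_j * (red - green) +
#'     polynomial(dye_trend_coeffs, centered A) + offset_j, with
#'     offset_j ~ Normal(0, array_offset_sd) and
#'     scale_j ~ LogNormal(0, array_scale_sd); channel intensities are then
#'     back-computed from (M_obs, A) and exponentiated.
#' }
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{experiment} (an
#'   \code{\link{experiment_set}}) and \code{truth} (class
#'   \code{synthetic_truth}: \code{enriched_mask}, \code{weight},
#'   \code{site_intervals}, per-array \code{scale} and \code{offset}).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  cfg <- config
  ann <- simulated_annotation(cfg)
  n <- nrow(ann)
  with_seed(cfg$seed, {
    til <- which(ann$category == "TILING")
    prm <- which(ann$category == "PROMOTER")

    ## enrichment weights
    draw_occupancy <- function(k) {
      if (length(cfg$occupancy) == 1L) rep(cfg$occupancy, k)
      else stats::rbeta(k, cfg$occupancy[1L], cfg$occupancy[2L])
    }
    w <- numeric(n)
    n_enr <- round(cfg$enriched_fraction * length(prm))
    enr_prm <- if (n_enr > 0L) sample(prm, n_enr) else integer(0L)
    w[enr_prm] <- cfg$site_weight * draw_occupancy(n_enr)

    sites <- data.frame(chrom = character(0L), start = integer(0L),
                        end = integer(0L), center = integer(0L))
    if (cfg$n_planted_sites > 0L) {
      ## site centers on distinct tiling probes, kept apart so peaks and
      ## called regions do not run into each other
      min_gap_probes <- max(1L, ceiling(
        (2L * cfg$site_halfwidth + 6 * cfg$mean_fragment_length) /
          cfg$probe_spacing))
      slots <- floor(cfg$n_tiling_probes / min_gap_probes)
      if (slots < cfg$n_planted_sites)
        stop("tiling path too short for ", cfg$n_planted_sites,
             " planted sites")
      chosen <- sort(sample(slots, cfg$n_planted_sites)) - 1L
      center_idx <- chosen * min_gap_probes +
        sample(min_gap_probes %/% 2L, cfg$n_planted_sites, replace = TRUE)
      centers <- ann$position[til][center_idx + 1L]
      sites <- data.frame(chrom = "chr1",
                          start = pmax(0L, centers - cfg$site_halfwidth),
                          end = centers + cfg$site_halfwidth,
                          center = centers)
      site_occ <- draw_occupancy(cfg$n_planted_sites)
      nearest <- vapply(ann$position[til],
                        function(p) which.min(abs(p - centers)), integer(1L))
      d <- abs(ann$position[til] - centers[nearest])
      w[til] <- cfg$site_weight * site_occ[nearest] *
        exp(-d / cfg$mean_fragment_length)
    }

    probe_effect <- stats::rnorm(n, 0, cfg$background_sd)
    has_floor <- is.finite(cfg$background_floor_drop)
    target <- 2^(cfg$background_mean + probe_effect)
    if (has_floor) target[ann$category == "NEGATIVE_CONTROL"] <- 0
    floor_g <- if (has_floor)
      2^(cfg$background_mean - cfg$background_floor_drop + probe_effect)
    else 0
    floor_r <- floor_g * 2^(-cfg$ip_floor_drop)
    retention_penalty <- -log2(cfg$nonspecific_retention)
    scale_j <- exp(stats::rnorm(cfg$n_arrays, 0, cfg$array_scale_sd))
    offset_j <- stats::rnorm(cfg$n_arrays, 0, cfg$array_offset_sd)
    ip_j <- exp(stats::rnorm(cfg$n_arrays, 0, cfg$array_ip_sd))
    trend_j <- exp(stats::rnorm(cfg$n_arrays, 0, cfg$array_trend_sd))

    arrays <- vector("list", cfg$n_arrays)
    for (j in seq_len(cfg$n_arrays)) {
      g <- log2(target + floor_g) + stats::rnorm(n, 0, cfg$noise_sd)
      r <- log2(target * 2^(w * ip_j[j] * cfg$enrichment_shift -
                              (1 - w) * retention_penalty) +
                  floor_r) +
        stats::rnorm(n, 0, cfg$noise_sd)
      a <- (r + g) / 2
      m_obs <- scale_j[j] * (r - g) +
        trend_j[j] * polyval_centered(cfg$dye_trend_coeffs, a) + offset_j[j]
      arrays[[j]] <- two_channel_array(sprintf("array%02d", j),
                                       green = 2^(a - m_obs / 2),
                                       red = 2^(a + m_obs / 2))
    }
    truth <- structure(list(enriched_mask = w > 0.5,
                            weight = w,
                            site_intervals = sites,
                            scale = scale_j,
                            offset = offset_j,
                            ip_efficiency = ip_j,
                            trend_amplitude = trend_j,
                            config = cfg),
                       class = "synthetic_truth")
    list(experiment = experiment_set(ann, arrays), truth = truth)
  })
}

#' Write the ground truth of a simulated experiment as TSV files
#'
#' \code{truth_probes.tsv} (probe_id, weight, enriched) and
#' \code{truth_sites.tsv} (chrom, start, end, center) in \code{dir}.
#'
#' @param truth a \code{synthetic_truth} (from
#'   \code{\link{simulate_experiment}}).
#' @param annotation the matching \code{\link{probe_annotation}}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_truth <- function(truth, annotation, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(probe_id = annotation$probe_id,
               weight = truth$weight,
               enriched = truth$enriched_mask),
    file.path(dir, "truth_probes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$site_intervals,
                     file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
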