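#' Sliding-window upper-quantile enrichment p-values
#'
#' ACME-style enrichment detection: the upper quantile of the log-ratio
#' distribution is assumed to contain mostly enriched probes, and a window
#' of tiling probes is significantly enriched when it over-samples that
#' upper quantile. Concretely: the threshold t is the empirical
#' \code{threshold_quantile} of all supplied log-ratios; for each probe the
#' window consists of all probes on the same chromosome within
#' \code{window_bp / 2} of its position; with k probes above t among n in
#' the window, against K above t among N overall, the p-value is the
#' one-sided (upper tail, 1 df, continuity-corrected) chi-square test on the
#' 2x2 table \code{[[k, n-k], [K-k, (N-n)-(K-k)]]}, set to 1 whenever
#' \code{k/n <= K/N}. Only the threshold RANK matters, so any strictly
#' increasing transform of the log-ratios — per-array shifts in particular —
#' leaves the p-values unchanged.
#'
#' @param annotation a \code{\link{probe_annotation}} for exactly the probes
#'   scored in \code{m_values} (typically the tiling probes), sorted by
#'   (chrom, position).
#' @param m_values per-probe log-ratios (single array or combined), aligned
#'   to \code{annotation}.
#' @param window_bp sliding-window width in bp.
#' @param threshold_quantile upper-quantile definition, in (0, 1).
#' @return An object of class \code{enrichment_result}: a data.frame with
#'   columns \code{probe_id}, \code{chrom}, \code{position},
#'   \code{n_in_window}, \code{k_above}, \code{pvalue},
#'   \code{single_probe_window}; attributes \code{threshold},
#'   \code{window_bp}, \code{threshold_quantile}.
#' @export
enrichment_pvalues <- function(annotation, m_values, window_bp = 1000L,
                               threshold_quantile = 0.95) {
  stopifnot(inherits(annotation, "probe_annotation"))
  m <- as.numeric(m_values)
  if (length(m) != nrow(annotation))
    stop("m_values must be aligned to the annotation")
  if (any(!is.finite(m))) stop("m_values must be finite")
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop("threshold_quantile must lie in (0, 1)")
  if (window_bp <= 0) stop("window_bp must be positive")
  o <- order(annotation$chrom, annotation$position)
  if (!identical(o, seq_len(nrow(annotation))))
    stop("annotation must be sorted by (chrom, position)")

  thr <- stats::quantile(m, threshold_quantile, names = FALSE)
  above <- m > thr
  N <- length(m)
  K <- sum(above)
  half <- window_bp / 2

  n_in <- k_in <- integer(N)
  for (ch in unique(annotation$chrom)) {
    idx <- which(annotation$chrom == ch)
    pos <- annotation$position[idx]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    cum <- c(0L, cumsum(above[idx]))
    n_in[idx] <- hi - lo + 1L
    k_in[idx] <- cum[hi + 1L] - cum[lo]
  }

  p <- window_chisq_p(k_in, n_in, K, N)
  single <- n_in == 1L
  p[single] <- 1

  out <- data.frame(probe_id = annotation$probe_id,
                    chrom = annotation$chrom,
                    position = annotation$position,
                    probe_length = annotation$probe_length,
                    n_in_window = n_in, k_above = k_in,
                    pvalue = p,
                    single_probe_window = single,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "window_bp") <- window_bp
  attr(out, "threshold_quantile") <- threshold_quantile
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' One-sided continuity-corrected chi-square p for window 2x2 tables
#'
#' Vectorized over windows: table \code{[[k, n-k], [K-k, (N-n)-(K-k)]]},
#' Yates-corrected chi-square with 1 df, upper-tail probability halved for
#' the one-sided (over-sampling) alternative; p = 1 when \code{k/n <= K/N}.
#'
#' @param k,n per-window counts (above threshold, total).
#' @param K,N experiment-wide counts.
#' @return Vector of p-values in (0, 1].
#' @export
window_chisq_p <- function(k, n, K, N) {
  k <- as.numeric(k); n <- as.numeric(n)
  K <- as.numeric(K); N <- as.numeric(N)
  a <- k; b <- n - k; cc <- K - k; d <- (N - n) - (K - k)
  p <- rep(1, length(k))
  enriched <- (a / n) > (K / N) & n > 0 & n < N
  if (!any(enriched)) return(p)
  a <- a[enriched]; b <- b[enriched]; cc <- cc[enriched]; d <- d[enriched]
  num <- abs(a * d - b * cc) - N / 2
  num <- pmax(num, 0)
  stat <- N * num^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  p[enriched] <- stats::pchisq(stat, df = 1L, lower.tail = FALSE) / 2
  pmin(p, 1)
}

#' Call enriched regions from per-probe enrichment p-values
#'
#' Maximal runs of probes with p below \code{alpha} are merged across gaps
#' smaller than half the window width and emitted as 0-based half-open
#' intervals (BED convention); a region runs from the first probe's start to
#' the last probe's end.
#'
#' @param result an \code{\link{enrichment_pvalues}} result.
#' @param alpha significance cut-off in (0, 1).
#' @param merge_gap_bp maximal bp gap between consecutive significant probes
#'   joined into one region; defaults to half the window width.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{n_probes}, \code{min_pvalue}, sorted and non-overlapping.
#' @export
call_regions <- function(result, alpha = 0.05,
                         merge_gap_bp = attr(result, "window_bp") / 2) {
  stopifnot(inherits(result, "enrichment_result"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  sig <- result[result$pvalue < alpha, , drop = FALSE]
  empty <- data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), n_probes = integer(0L),
                      min_pvalue = numeric(0L), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L) return(empty)
  regions <- list()
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    pos <- s$position
    new_run <- c(TRUE, diff(pos) > merge_gap_bp)
    run_id <- cumsum(new_run)
    for (rid in unique(run_id)) {
      r <- s[run_id == rid, , drop = FALSE]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch,
        start = min(r$position),
        end = max(r$position + r$probe_length),
        n_probes = nrow(r),
        min_pvalue = min(r$pvalue),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region counts at a set of p-value cut-offs
#'
#' @param result an \code{\link{enrichment_pvalues}} result.
#' @param alphas significance cut-offs.
#' @return Named integer vector of region counts.
#' @export
region_counts <- function(result, alphas = c(0.05, 0.10, 0.20, 0.50)) {
  counts <- vapply(alphas, function(a) nrow(call_regions(result, a)),
                   integer(1L))
  stats::setNames(counts, sprintf("p<%.2f", alphas))
}

#' Fraction of planted sites recovered by called regions
#'
#' A site counts as recovered when at least one called region overlaps its
#' interval.
#'
#' @param regions data.frame from \code{\link{call_regions}}.
#' @param sites data.frame of planted site intervals (\code{chrom},
#'   \code{start}, \code{end}), e.g. \code{truth$site_intervals}.
#' @return Fraction in [0, 1] (NA when no sites).
#' @export
site_recovery <- function(regions, sites) {
  if (nrow(sites) == 0L) return(NA_real_)
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    any(regions$chrom == sites$chrom[i] &
          regions$start < sites$end[i] &
          regions$end > sites$start[i])
  }, logical(1L))
  mean(hit)
}
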