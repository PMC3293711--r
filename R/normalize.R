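#' Normalization result container
#'
#' All six normalization methods return this structure: the normalized M and
#' A matrices (aligned to the input) plus per-array diagnostics specific to
#' the method (subtracted constants, rotation angles, calibration
#' parameters, ...).
#'
#' @param method method name, one of \code{NORMALIZATION_METHODS}.
#' @param M,A normalized matrices.
#' @param diagnostics method-specific list.
#' @return An object of class \code{normalization_result} (also an
#'   \code{\link{ma_matrix}}).
#' @export
normalization_result <- function(method, M, A, diagnostics = list()) {
  out <- ma_matrix(M, A)
  out$method <- match.arg(method, NORMALIZATION_METHODS)
  out$diagnostics <- diagnostics
  class(out) <- c("normalization_result", class(out))
  out
}

#' The six supported normalization methods
#' @export
NORMALIZATION_METHODS <- c("lowess", "quantile", "vsn", "tquantile",
                           "tbw", "peng")

as_ma <- function(x) {
  if (inherits(x, "ma_matrix")) x
  else if (inherits(x, "experiment_set")) compute_ma(x)
  else stop("expected an ma_matrix or experiment_set")
}

## Robust local trend fit of y on x: local-quadratic loess with bisquare
## robustifying iterations, fitted on an x-ordered thinned subset for large
## inputs and evaluated at every point.
fit_robust_trend <- function(x, y, span, iterations, max_fit_points = 5000L) {
  n <- length(x)
  if (diff(range(y)) == 0) return(rep(y[1L], n))  # constant input
  ord <- order(x)
  idx <- if (n > max_fit_points)
    ord[unique(round(seq(1L, n, length.out = max_fit_points)))]
  else ord
  fit <- stats::loess(
    yy ~ xx, data = data.frame(xx = x[idx], yy = y[idx]),
    span = span, degree = 2, family = "symmetric",
    control = stats::loess.control(surface = "interpolate",
                                   iterations = iterations))
  pred <- stats::predict(fit, newdata = data.frame(xx = x))
  ## interpolation never extrapolates: the thinned subset contains the range
  if (anyNA(pred)) pred[is.na(pred)] <- 0
  pred
}

#' LOWESS normalization
#'
#' Per array, fits a robust locally weighted regression of M on A and
#' subtracts the fitted trend; A is unchanged. Assumes the log-ratio
#' distribution is centered around zero at every intensity — the standard
#' two-channel transcriptomics assumption, which regulation arrays with a
#' sizable enriched component violate.
#'
#' @param ma an \code{\link{ma_matrix}} or \code{\link{experiment_set}}.
#' @param span loess span in (0, 1].
#' @param iterations robustifying (bisquare) iterations.
#' @return A \code{\link{normalization_result}} with per-array fitted-trend
#'   ranges in diagnostics.
#' @export
lowess_normalize <- function(ma, span = 0.3, iterations = 4L) {
  ma <- as_ma(ma)
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  if (nrow(ma$M) < 10L) stop("need at least 10 probes per array")
  M <- ma$M
  trend_range <- matrix(NA_real_, 2L, ncol(M))
  for (j in seq_len(ncol(M))) {
    fitj <- fit_robust_trend(ma$A[, j], ma$M[, j], span, iterations)
    M[, j] <- ma$M[, j] - fitj
    trend_range[, j] <- range(fitj)
  }
  normalization_result("lowess", M, ma$A,
                       list(span = span, iterations = iterations,
                            trend_range = trend_range))
}

#' Quantile normalization (channels pooled)
#'
#' Pools all 2 * n_arrays channel log2-intensity vectors — green and red
#' together — and replaces each value by the mean of same-rank values across
#' channels; afterwards every channel has an identical sorted vector. M and
#' A are recomputed from the normalized channels. Forcing the red (enriched)
#' channel onto the pooled distribution compresses the enriched component.
#'
#' @param experiment an \code{\link{experiment_set}}.
#' @return A \code{\link{normalization_result}}.
#' @export
quantile_normalize <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_set"))
  X <- channel_log2_matrix(experiment)
  if (ncol(X) < 2L) stop("need at least 2 channels")
  Xn <- quantile_normalize_matrix(X)
  channels_to_result("quantile", Xn, experiment)
}

#' Rank-mean quantile normalization of a matrix
#'
#' The workhorse behind \code{\link{quantile_normalize}} and
#' \code{\link{tquantile_normalize}}: each column's values are replaced by
#' the mean over columns of same-rank values (limma's implementation, with
#' ties averaged). Monotone within each column.
#'
#' @param X numeric matrix, columns are channels.
#' @return Matrix of the same shape.
#' @export
quantile_normalize_matrix <- function(X) {
  limma::normalizeQuantiles(as.matrix(X), ties = TRUE)
}

channels_to_result <- function(method, Xn, experiment, diagnostics = list()) {
  m <- n_arrays(experiment)
  G <- Xn[, seq_len(m), drop = FALSE]
  R <- Xn[, m + seq_len(m), drop = FALSE]
  M <- R - G
  A <- (R + G) / 2
  colnames(M) <- colnames(A) <- array_ids(experiment)
  rownames(M) <- rownames(A) <- experiment$annotation$probe_id
  normalization_result(method, M, A, diagnostics)
}

#' T-quantile normalization (channels separate)
#'
#' Quantile normalization applied in subgroups: once across all green
#' channels and once across all red channels. Within-array, within-channel
#' probe ranks are preserved exactly, and the red (enriched) distribution is
#' never forced onto the green (input) one, so the enriched/un-enriched
#' separation survives while between-array comparability improves.
#'
#' @param experiment an \code{\link{experiment_set}} with at least 2 arrays.
#' @return A \code{\link{normalization_result}}.
#' @export
tquantile_normalize <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_set"))
  m <- n_arrays(experiment)
  if (m < 2L) stop("T-quantile is a between-array method; need >= 2 arrays")
  X <- channel_log2_matrix(experiment)
  Xn <- cbind(quantile_normalize_matrix(X[, seq_len(m), drop = FALSE]),
              quantile_normalize_matrix(X[, m + seq_len(m), drop = FALSE]))
  colnames(Xn) <- colnames(X)
  channels_to_result("tquantile", Xn, experiment)
}

#' Generalized logarithm, base 2
#'
#' \code{glog2(y) = log2(y + sqrt(y^2 + 1))}: behaves like \code{log2(2 * y)}
#' for large y but stays defined and smooth through zero and negative
#' values; the transform underlying variance stabilization. \code{inv_glog2}
#' is its inverse.
#'
#' @param y,h numeric vectors.
#' @return Transformed vector.
#' @export
glog2 <- function(y) log2(y + sqrt(y^2 + 1))

#' @rdname glog2
#' @export
inv_glog2 <- function(h) (2^h - 2^(-h)) / 2

#' VSN-style variance stabilizing normalization
#'
#' A calibrated generalized-log model fitted between arrays and between
#' channels: each channel c is transformed by
#' \code{h_c(x) = glog2((x - a_c) / b_c)} with
#' \code{glog2(y) = log2(y + sqrt(y^2 + 1))}. The affine parameters are
#' estimated by trimmed Gaussian maximum likelihood: squared deviations of
#' each probe's transformed value from its across-channel mean are
#' minimized over the majority subset of probes (least-trimmed-squares,
#' retaining \code{1 - trim_fraction} of probes), with the log-Jacobian of
#' the transform entering the objective. The Jacobian term is what makes
#' the calibration identifiable — under plain least squares, flattening
#' every transform (b to infinity) drives the agreement objective to zero.
#' The estimation rests on the assumption that the majority of probes agree
#' across all channels — which enriched regulation data violate.
#' \code{M = h_red - h_green}, \code{A = (h_red + h_green)/2};
#' each channel transform is monotone increasing.
#'
#' Parameters are estimated by block coordinate descent on a deterministic
#' subsample of probes (up to \code{max_fit_rows}, evenly spaced along the
#' mean-intensity rank so the whole dynamic range is covered): given the
#' current reference, each channel's \code{(a_c, log b_c)} is optimized
#' numerically; then the reference and the trimmed probe subset are
#' refreshed. Each block step decreases the trimmed objective, and the
#' trimmed subset is frozen after ten sweeps, so the alternation converges
#' monotonically.
#'
#' @param experiment an \code{\link{experiment_set}}.
#' @param trim_fraction fraction of probes trimmed during calibration.
#' @param max_iter,tol convergence control: iteration stops when the
#'   relative change of the trimmed objective falls below \code{tol}.
#'   Beyond that point the only remaining movement is along the
#'   near-invariant common rescaling of all channel transforms, which
#'   leaves the normalized log-ratios unchanged up to an overall scale.
#' @param max_fit_rows subsample size used for parameter estimation; the
#'   fitted transform is applied to all probes.
#' @return A \code{\link{normalization_result}} carrying the per-channel
#'   \code{(a, b)} parameters and objective trace in diagnostics.
#' @export
vsn_normalize <- function(experiment, trim_fraction = 0.1,
                          max_iter = 100L, tol = 1e-4,
                          max_fit_rows = 5000L) {
  stopifnot(inherits(experiment, "experiment_set"))
  if (trim_fraction < 0 || trim_fraction >= 1)
    stop("trim_fraction must lie in [0, 1)")
  X <- 2^channel_log2_matrix(experiment)  # raw intensities
  if (ncol(X) < 2L) stop("need at least 2 channels")
  nc <- ncol(X)
  n <- nrow(X)
  sub <- if (n > max_fit_rows) {
    ord <- order(rowMeans(X))
    ord[unique(round(seq(1L, n, length.out = max_fit_rows)))]
  } else seq_len(n)
  Xs <- X[sub, , drop = FALSE]
  a <- rep(0, nc)
  b <- apply(Xs, 2L, stats::median)
  trace <- numeric(0L)
  keep <- rep(TRUE, nrow(Xs))
  converged <- FALSE
  ## trimmed negative profile log-likelihood (up to constants):
  ## (nk * nc / 2) * log(RSS) + sum over kept cells of -log h'(x),
  ## with -log h'(x) = log(b) + log(y^2 + 1) / 2 up to a constant.
  neg_log_jac <- function(xk, ac, bc) {
    y <- (xk - ac) / bc
    length(xk) * log(bc) + 0.5 * sum(log1p(y^2))
  }
  for (it in seq_len(max_iter)) {
    H <- glog2(sweep(sweep(Xs, 2L, a, "-"), 2L, b, "/"))
    ref <- rowMeans(H)
    rss_row <- rowSums((H - ref)^2)
    if (it <= 10L && trim_fraction > 0)
      keep <- rss_row <=
        stats::quantile(rss_row, 1 - trim_fraction, names = FALSE)
    nk <- sum(keep)
    jac <- sum(vapply(seq_len(nc),
                      function(cc) neg_log_jac(Xs[keep, cc], a[cc], b[cc]),
                      numeric(1L)))
    obj <- (nk * nc / 2) * log(sum(rss_row[keep]) + 1e-12 * nk) + jac
    trace <- c(trace, obj)
    if (it > 1L &&
        abs(trace[it - 1L] - obj) <= tol * max(abs(obj), 1)) {
      converged <- TRUE
      break
    }
    ## one Gauss-Seidel sweep: each channel is fitted against the
    ## leave-one-out mean of the others, which profiles the reference out
    ## exactly (row RSS = (1 - 1/nc) * (h - loo_mean)^2 + others' spread)
    Hk <- H[keep, , drop = FALSE]
    S <- rowSums(Hk)
    w <- 1 - 1 / nc
    for (cc in seq_len(nc)) {
      xk <- Xs[keep, cc]
      tgt <- (S - Hk[, cc]) / (nc - 1)
      c_other <- sum((Hk[, -cc, drop = FALSE] - tgt)^2)
      opt <- stats::optim(c(a[cc], log(b[cc])), function(par) {
        bc <- exp(par[2L])
        h <- glog2((xk - par[1L]) / bc)
        (nk * nc / 2) * log(w * sum((h - tgt)^2) + c_other + 1e-12 * nk) +
          neg_log_jac(xk, par[1L], bc)
      }, method = "BFGS", control = list(maxit = 100L))
      a[cc] <- opt$par[1L]
      b[cc] <- exp(opt$par[2L])
      hnew <- glog2((xk - a[cc]) / b[cc])
      S <- S - Hk[, cc] + hnew
      Hk[, cc] <- hnew
    }
    ## common-mode step: per-channel moves cannot explore a shared shift
    ## or rescaling of all transforms (the reference follows them), yet
    ## the shared scale is what sets where the glog bends — optimize it
    ## jointly over (delta a, delta log b)
    Xk <- Xs[keep, , drop = FALSE]
    common_obj <- function(par) {
      ac <- a + par[1L]; bc <- b * exp(par[2L])
      H <- glog2(sweep(sweep(Xk, 2L, ac, "-"), 2L, bc, "/"))
      ref <- rowMeans(H)
      rss <- sum((H - ref)^2)
      jac <- sum(vapply(seq_len(nc),
                        function(cc) neg_log_jac(Xk[, cc], ac[cc], bc[cc]),
                        numeric(1L)))
      (nk * nc / 2) * log(rss + 1e-12 * nk) + jac
    }
    opt <- stats::optim(c(0, 0), common_obj, method = "BFGS",
                        control = list(maxit = 40L))
    a <- a + opt$par[1L]
    b <- b * exp(opt$par[2L])
  }
  if (!converged)
    stop("VSN-style calibration did not converge after ", max_iter,
         " iterations; objective trace (last 5): ",
         paste(signif(utils::tail(trace, 5L), 6L), collapse = ", "))
  H <- glog2(sweep(sweep(X, 2L, a, "-"), 2L, b, "/"))
  colnames(H) <- colnames(X)
  channels_to_result("vsn", H, experiment,
                     list(a = a, b = b, channels = colnames(X),
                          objective_trace = trace,
                          trim_fraction = trim_fraction,
                          iterations = length(trace)))
}

#' Tukey biweight robust location estimate
#'
#' Starts at the median with scale = MAD (unscaled median absolute
#' deviation) and iterates bisquare-weighted means: weights
#' \code{w = (1 - u^2)^2} for \code{|u| < 1}, else 0, with
#' \code{u = (x - current) / (c * MAD)}. Points far from the center get
#' weight zero, so outliers barely influence the estimate. Iteration stops
#' when the estimate moves less than \code{tol} or after \code{max_iter}
#' steps. If the MAD is zero (all values equal up to a majority tie) the
#' median is returned.
#'
#' @param values numeric vector with at least one finite value.
#' @param c bisquare tuning constant.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the location estimate.
#' @return Scalar location estimate.
#' @export
tukey_biweight <- function(values, c = 5, max_iter = 50L, tol = 1e-6) {
  x <- values[is.finite(values)]
  if (!length(x)) stop("need at least one finite value")
  center <- stats::median(x)
  scale <- stats::median(abs(x - center))
  if (scale == 0) return(center)
  for (it in seq_len(max_iter)) {
    u <- (x - center) / (c * scale)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) break
    new <- sum(w * x) / sum(w)
    delta <- abs(new - center)
    center <- new
    if (delta < tol) break
  }
  center
}

#' Tukey's biweight scaling
#'
#' NimbleGen's in-house two-step normalization: compute per-probe
#' log-ratios, then subtract from each array's M vector its Tukey biweight
#' location estimate. A per-array constant shift is rank-preserving, so
#' per-array ROC curves (and any rank-based downstream statistic) are
#' identical to those of the raw data.
#'
#' @param ma an \code{\link{ma_matrix}} or \code{\link{experiment_set}}.
#' @param c,max_iter,tol passed to \code{\link{tukey_biweight}}.
#' @return A \code{\link{normalization_result}}; the subtracted per-array
#'   constants are in \code{diagnostics$shift}.
#' @export
tbw_scale <- function(ma, c = 5, max_iter = 50L, tol = 1e-6) {
  ma <- as_ma(ma)
  shift <- apply(ma$M, 2L, tukey_biweight, c = c, max_iter = max_iter,
                 tol = tol)
  M <- sweep(ma$M, 2L, shift, "-")
  normalization_result("tbw", M, ma$A, list(shift = shift, c = c))
}

#' Peng's rotation + LOWESS normalization
#'
#' Per array: (1) the major-axis slope of the centered (A, M) point cloud is
#' estimated by total least squares (first principal direction);
#' (2) the cloud is rotated about its centroid so that this major trend is
#' horizontal; (3) the rotated coordinates are detrended with the same
#' robust local regression as \code{\link{lowess_normalize}}. Makes strong
#' assumptions about the shape of the MA plot: when enrichment itself tilts
#' the cloud, the rotation mixes intensity into the log-ratio.
#'
#' @param ma an \code{\link{ma_matrix}} or \code{\link{experiment_set}}.
#' @param span,iterations passed to the loess detrend step.
#' @return A \code{\link{normalization_result}} with per-array rotation
#'   angles (radians) and major-axis slopes in diagnostics.
#' @export
peng_normalize <- function(ma, span = 0.3, iterations = 4L) {
  ma <- as_ma(ma)
  if (nrow(ma$M) < 10L) stop("need at least 10 probes per array")
  M <- ma$M; A <- ma$A
  angle <- slope <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    x <- ma$A[, j]; y <- ma$M[, j]
    if (stats::var(x) < .Machine$double.eps)
      stop("degenerate array ", j, ": zero-variance A")
    cx <- x - mean(x); cy <- y - mean(y)
    cv <- crossprod(cbind(cx, cy)) / (length(x) - 1L)
    v <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    if (v[1L] < 0) v <- -v
    angle[j] <- atan2(v[2L], v[1L])
    slope[j] <- v[2L] / v[1L]
    co <- cos(angle[j]); si <- sin(angle[j])
    xr <- co * cx + si * cy     # rotate by -angle
    yr <- -si * cx + co * cy
    fitj <- fit_robust_trend(xr, yr, span, iterations)
    M[, j] <- yr - fitj
    A[, j] <- xr + mean(x)
  }
  normalization_result("peng", M, A,
                       list(angle = angle, slope = slope, span = span,
                            iterations = iterations))
}

#' Apply one of the six normalization methods to an experiment
#'
#' Dispatcher used by the comparison pipeline: methods defined on log-ratios
#' (\code{lowess}, \code{tbw}, \code{peng}) receive the experiment's MA
#' matrices; channel-based methods (\code{quantile}, \code{tquantile},
#' \code{vsn}) receive the experiment itself.
#'
#' @param experiment an \code{\link{experiment_set}}.
#' @param method one of \code{NORMALIZATION_METHODS}.
#' @param ... passed on to the method.
#' @return A \code{\link{normalization_result}}.
#' @export
normalize_experiment <- function(experiment, method, ...) {
  method <- match.arg(method, NORMALIZATION_METHODS)
  switch(method,
         lowess = lowess_normalize(compute_ma(experiment), ...),
         quantile = quantile_normalize(experiment, ...),
         vsn = vsn_normalize(experiment, ...),
         tquantile = tquantile_normalize(experiment, ...),
         tbw = tbw_scale(compute_ma(experiment), ...),
         peng = peng_normalize(compute_ma(experiment), ...))
}
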