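#' Control-vs-promoter separation report
#'
#' The quality metric of the normalization comparison: for each supplied
#' log-ratio matrix (typically the raw data plus one entry per normalization
#' method), computes the ROC AUC between negative-control and gene-promoter
#' probes per array and on the combined (all arrays pooled) data, together
#' with numeric density summaries of both classes. The across-array AUC
#' standard deviation quantifies how comparable individual arrays are.
#'
#' @param annotation a \code{\link{probe_annotation}} with at least one
#'   NEGATIVE_CONTROL and one PROMOTER probe.
#' @param m_by_method named list of probes x arrays log-ratio matrices, all
#'   aligned to the annotation. \code{\link{ma_matrix}} /
#'   \code{\link{normalization_result}} objects are accepted and their M
#'   taken.
#' @return An object of class \code{separation_report}: a data.frame with
#'   one row per (method, array) and per (method, "combined"), columns
#'   \code{method}, \code{array}, \code{auc}, \code{n_negative},
#'   \code{n_positive} and per-class mean / sd / quartiles, plus an
#'   \code{auc_sd} attribute (per-method across-array AUC dispersion).
#' @export
separation_report <- function(annotation, m_by_method) {
  stopifnot(inherits(annotation, "probe_annotation"))
  if (is.null(names(m_by_method)) || any(names(m_by_method) == ""))
    stop("m_by_method must be a named list")
  neg_idx <- category_index(annotation, "NEGATIVE_CONTROL")
  pos_idx <- category_index(annotation, "PROMOTER")
  if (!length(neg_idx)) stop("annotation has no NEGATIVE_CONTROL probes")
  if (!length(pos_idx)) stop("annotation has no PROMOTER probes")

  rows <- list()
  auc_sd <- numeric(0L)
  for (method in names(m_by_method)) {
    M <- m_by_method[[method]]
    if (inherits(M, "ma_matrix")) M <- M$M
    M <- as.matrix(M)
    if (nrow(M) != nrow(annotation))
      stop("matrix for method '", method,
           "' is not aligned to the annotation")
    arrays <- colnames(M)
    if (is.null(arrays)) arrays <- sprintf("array%02d", seq_len(ncol(M)))
    per_array_auc <- numeric(ncol(M))
    for (j in seq_len(ncol(M))) {
      roc <- roc_auc(M[neg_idx, j], M[pos_idx, j])
      per_array_auc[j] <- roc$auc
      rows[[length(rows) + 1L]] <-
        summary_row(method, arrays[j], roc, M[neg_idx, j], M[pos_idx, j])
    }
    roc_comb <- roc_auc(as.vector(M[neg_idx, ]), as.vector(M[pos_idx, ]))
    rows[[length(rows) + 1L]] <-
      summary_row(method, "combined", roc_comb,
                  as.vector(M[neg_idx, ]), as.vector(M[pos_idx, ]))
    auc_sd[method] <- if (ncol(M) > 1L) stats::sd(per_array_auc) else NA_real_
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "auc_sd") <- auc_sd
  class(out) <- c("separation_report", "data.frame")
  out
}

summary_row <- function(method, array, roc, neg, pos) {
  qn <- stats::quantile(neg, c(0.25, 0.5, 0.75), names = FALSE)
  qp <- stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(method = method, array = array, auc = roc$auc,
             n_negative = roc$n_negative, n_positive = roc$n_positive,
             mean_neg = mean(neg), sd_neg = stats::sd(neg),
             q25_neg = qn[1L], median_neg = qn[2L], q75_neg = qn[3L],
             mean_pos = mean(pos), sd_pos = stats::sd(pos),
             q25_pos = qp[1L], median_pos = qp[2L], q75_pos = qp[3L],
             stringsAsFactors = FALSE)
}

#' Across-array AUC dispersion of a separation report
#'
#' @param report a \code{\link{separation_report}}.
#' @return Named numeric vector: per-method standard deviation of the
#'   per-array AUC values.
#' @export
auc_dispersion <- function(report) {
  stopifnot(inherits(report, "separation_report"))
  attr(report, "auc_sd")
}

#' Combined-data AUC per method
#'
#' @param report a \code{\link{separation_report}}.
#' @return Named numeric vector of pooled-array AUCs.
#' @export
combined_auc <- function(report) {
  stopifnot(inherits(report, "separation_report"))
  comb <- report[report$array == "combined", ]
  stats::setNames(comb$auc, comb$method)
}
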