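#' ROC curve and AUC between negative-control and promoter scores
#'
#' Builds the ROC curve by a threshold sweep over the pooled unique scores:
#' negative-control probes are the negative class, gene-promoter probes the
#' positive class, and a probe is called positive when its score (log-ratio)
#' is at or above the threshold. The AUC is computed both as the trapezoidal
#' integral of the swept curve and by the Mann-Whitney rank formula
#' (U / (n1 * n2), ties counted half); the two routes must agree to 1e-10 or
#' the function errors — a permanent internal consistency check.
#'
#' @param negative_scores log-ratios of the negative class (controls).
#' @param positive_scores log-ratios of the positive class (promoters).
#' @return An object of class \code{roc_result}: \code{fpr}, \code{tpr}
#'   (starting at (0,0), ending at (1,1), non-decreasing), \code{auc},
#'   \code{n_negative}, \code{n_positive}.
#' @export
roc_auc <- function(negative_scores, positive_scores) {
  neg <- as.numeric(negative_scores)
  pos <- as.numeric(positive_scores)
  if (!length(neg) || !length(pos))
    stop("both score vectors must be non-empty")
  if (any(!is.finite(neg)) || any(!is.finite(pos)))
    stop("scores must be finite")
  nn <- as.numeric(length(neg)); np <- as.numeric(length(pos))

  thresholds <- sort(unique(c(neg, pos)), decreasing = TRUE)
  ## counts >= threshold via cumulative counts on the sorted grid
  pos_sorted <- sort(pos)
  neg_sorted <- sort(neg)
  n_pos_ge <- np - findInterval(thresholds, pos_sorted, left.open = TRUE)
  n_neg_ge <- nn - findInterval(thresholds, neg_sorted, left.open = TRUE)
  fpr <- c(0, n_neg_ge / nn)
  tpr <- c(0, n_pos_ge / np)

  auc_trap <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)

  r <- rank(c(neg, pos))  # average ranks: half credit for ties
  auc_rank <- (sum(r[nn + seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  if (abs(auc_trap - auc_rank) > 1e-10)
    stop("ROC sweep and rank-formula AUC disagree: ",
         auc_trap, " vs ", auc_rank)

  structure(list(fpr = fpr, tpr = tpr, auc = auc_rank,
                 n_negative = nn, n_positive = np),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d negatives, %d positives, %d points)\n",
              x$auc, x$n_negative, x$n_positive, length(x$fpr)))
  invisible(x)
}
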