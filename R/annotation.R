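#' Probe categories
#'
#' The three probe classes of a regulation (ChIP-on-chip / MeDIP-on-chip)
#' array design: negative-control probes with no genomic target (measuring
#' non-specific annealing and background fluorescence), gene-promoter probes,
#' and genome-tiling probes.
#'
#' @export
PROBE_CATEGORIES <- c("NEGATIVE_CONTROL", "PROMOTER", "TILING")

#' Construct a probe annotation table
#'
#' A probe annotation holds the probe universe of an experiment: one row per
#' probe with its genomic location and category. Negative-control probes form
#' the negative class and promoter probes the positive class of the ROC-based
#' separation metric; tiling probes are the substrate of sliding-window
#' enrichment detection.
#'
#' Positions are stored 0-based (half-open interval convention); file readers
#' and writers convert from/to the 1-based coordinates used in pair and
#' annotation files.
#'
#' @param probe_id character vector of unique probe identifiers.
#' @param chrom chromosome / sequence identifier per probe.
#' @param position 0-based genomic start coordinate per probe (bp).
#' @param probe_length probe length in bp (recycled if scalar).
#' @param category one of \code{PROBE_CATEGORIES} per probe.
#' @return A \code{data.frame} of class \code{probe_annotation} with columns
#'   \code{probe_id}, \code{chrom}, \code{position}, \code{probe_length},
#'   \code{category}.
#' @export
probe_annotation <- function(probe_id, chrom, position, probe_length = 50L,
                             category) {
  probe_id <- as.character(probe_id)
  position <- as.integer(position)
  n <- length(probe_id)
  chrom <- as.character(rep_len(chrom, n))
  category <- as.character(rep_len(category, n))
  probe_length <- as.integer(rep_len(probe_length, n))
  if (length(position) != n)
    stop("annotation fields must have equal length")
  if (anyDuplicated(probe_id))
    stop("probe_id values must be unique; first duplicate: ",
         probe_id[duplicated(probe_id)][1L])
  if (any(position < 0L)) stop("position must be >= 0")
  if (any(probe_length <= 0L)) stop("probe_length must be > 0")
  bad <- setdiff(unique(category), PROBE_CATEGORIES)
  if (length(bad))
    stop("unknown probe category: ", bad[1L])
  ann <- data.frame(probe_id = probe_id, chrom = chrom, position = position,
                    probe_length = probe_length, category = category,
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Read a probe annotation TSV
#'
#' Expects a tab-separated file with a header naming at least
#' \code{probe_id}, \code{chrom}, \code{position}, \code{length},
#' \code{category}; \code{position} is interpreted as a 1-based start and
#' converted to the internal 0-based convention. Lines starting with
#' \code{#} are comments.
#'
#' @param path file path.
#' @return A \code{probe_annotation}.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("probe_id", "chrom", "position", "length", "category")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file lacks required column(s): ",
         paste(miss, collapse = ", "))
  probe_annotation(df$probe_id, df$chrom, as.integer(df$position) - 1L,
                   df$length, df$category)
}

#' Write a probe annotation TSV
#'
#' Inverse of \code{\link{read_annotation}}: positions are written 1-based.
#'
#' @param annotation a \code{probe_annotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "probe_annotation"))
  out <- data.frame(probe_id = annotation$probe_id,
                    chrom = annotation$chrom,
                    position = annotation$position + 1L,
                    length = annotation$probe_length,
                    category = annotation$category)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

category_index <- function(annotation, category) {
  which(annotation$category == category)
}
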