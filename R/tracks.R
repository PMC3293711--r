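#' Write a per-probe p-value track as GFF (version 2)
#'
#' One GFF line per probe with score = -log10(p), the conventional display
#' scale for enrichment tracks. GFF coordinates are 1-based inclusive;
#' internal probe positions (0-based) are converted on write.
#'
#' @param annotation a \code{\link{probe_annotation}} aligned to
#'   \code{pvalues}.
#' @param pvalues per-probe enrichment p-values in (0, 1].
#' @param path output file path.
#' @param source source field of the GFF lines.
#' @param feature feature field of the GFF lines.
#' @return \code{path}, invisibly.
#' @export
write_pvalue_gff <- function(annotation, pvalues, path,
                             source = "regnorm", feature = "enrichment") {
  stopifnot(inherits(annotation, "probe_annotation"))
  if (length(pvalues) != nrow(annotation))
    stop("pvalues must be aligned to the annotation")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  score <- -log10(pvalues)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%.6f\t.\t.\tprobe \"%s\"",
                   annotation$chrom, source, feature,
                   annotation$position + 1L,
                   annotation$position + annotation$probe_length,
                   score, annotation$probe_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GFF p-value track written by \code{write_pvalue_gff}
#'
#' @param path GFF file path.
#' @return data.frame with columns \code{chrom}, \code{start} (0-based),
#'   \code{end}, \code{score}, \code{probe_id}.
#' @export
read_pvalue_gff <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 9L) stop("not a GFF file: ", path)
  data.frame(chrom = df[[1L]],
             start = as.integer(df[[4L]]) - 1L,
             end = as.integer(df[[5L]]),
             score = as.numeric(df[[6L]]),
             probe_id = sub('^probe "(.*)"$', "\\1", df[[9L]]),
             stringsAsFactors = FALSE)
}

#' Write called regions as BED3
#'
#' BED intervals are 0-based half-open, matching the internal coordinate
#' convention.
#'
#' @param regions data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (as returned by \code{\link{call_regions}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  if (nrow(regions) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3 file
#'
#' @param path BED file path.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}.
#' @export
read_regions_bed <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L)
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = df[[1L]], start = as.integer(df[[2L]]),
             end = as.integer(df[[3L]]), stringsAsFactors = FALSE)
}
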