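#' Construct a two-channel array
#'
#' Holds the raw probe-level intensities of one two-channel regulation
#' microarray. The green (Cy3) channel carries the total-DNA input reference;
#' the red (Cy5) channel carries the immunoprecipitated (enriched) sample.
#' Vectors are aligned by index to the experiment's probe annotation.
#'
#' @param array_id array identifier string.
#' @param green raw Cy3 intensities, one per probe, strictly positive.
#' @param red raw Cy5 intensities, one per probe, strictly positive.
#' @return An object of class \code{two_channel_array}.
#' @export
two_channel_array <- function(array_id, green, red) {
  green <- as.numeric(green)
  red <- as.numeric(red)
  if (length(green) != length(red))
    stop("green and red channels must have identical length")
  if (!all(is.finite(green)) || !all(is.finite(red)))
    stop("intensities must be finite")
  if (any(green <= 0) || any(red <= 0))
    stop("intensities must be strictly positive")
  structure(list(array_id = as.character(array_id)[1L],
                 green = green, red = red),
            class = "two_channel_array")
}

#' Construct an experiment set
#'
#' Container for one probe annotation shared by one or more replicate
#' two-channel arrays.
#'
#' @param annotation a \code{\link{probe_annotation}}.
#' @param arrays list of \code{\link{two_channel_array}} objects, all with the
#'   same number of probes as the annotation.
#' @return An object of class \code{experiment_set}.
#' @export
experiment_set <- function(annotation, arrays) {
  stopifnot(inherits(annotation, "probe_annotation"))
  if (inherits(arrays, "two_channel_array")) arrays <- list(arrays)
  if (length(arrays) < 1L) stop("need at least one array")
  ok <- vapply(arrays, inherits, logical(1L), "two_channel_array")
  if (!all(ok)) stop("arrays must be two_channel_array objects")
  n <- nrow(annotation)
  len <- vapply(arrays, function(a) length(a$green), integer(1L))
  if (any(len != n))
    stop("all arrays must have ", n, " probes to match the annotation")
  ids <- vapply(arrays, `[[`, character(1L), "array_id")
  if (anyDuplicated(ids)) stop("array_id values must be unique")
  names(arrays) <- ids
  structure(list(annotation = annotation, arrays = arrays),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  tab <- table(x$annotation$category)
  cat("experiment_set:", length(x$arrays), "array(s),",
      nrow(x$annotation), "probes\n")
  cat("  categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  arrays:", paste(names(x$arrays), collapse = ", "), "\n")
  invisible(x)
}

n_arrays <- function(experiment) length(experiment$arrays)
n_probes <- function(experiment) nrow(experiment$annotation)

array_ids <- function(experiment) names(experiment$arrays)

#' Per-channel log2 intensity matrix
#'
#' Internal helper: probes x (2 * arrays) matrix of log2 intensities, green
#' channels first, then red, with column names \code{<array>.G} /
#' \code{<array>.R}.
#' @noRd
channel_log2_matrix <- function(experiment) {
  g <- vapply(experiment$arrays, function(a) log2(a$green),
              numeric(n_probes(experiment)))
  r <- vapply(experiment$arrays, function(a) log2(a$red),
              numeric(n_probes(experiment)))
  g <- matrix(g, nrow = n_probes(experiment))
  r <- matrix(r, nrow = n_probes(experiment))
  colnames(g) <- paste0(array_ids(experiment), ".G")
  colnames(r) <- paste0(array_ids(experiment), ".R")
  cbind(g, r)
}

#' Construct an MA matrix
#'
#' @param M probes x arrays matrix of log2(red/green) log-ratios.
#' @param A probes x arrays matrix of average log2 intensities.
#' @return An object of class \code{ma_matrix} with elements \code{M},
#'   \code{A}.
#' @export
ma_matrix <- function(M, A) {
  M <- as.matrix(M); A <- as.matrix(A)
  if (!identical(dim(M), dim(A))) stop("M and A must share dimensions")
  structure(list(M = M, A = A), class = "ma_matrix")
}

#' Compute log-ratio (M) and average log-intensity (A) matrices
#'
#' For every probe i and array j, \code{M[i,j] = log2(red) - log2(green)} and
#' \code{A[i,j] = (log2(red) + log2(green)) / 2}. M is the enrichment measure
#' that all normalization methods transform; A is the abscissa of the MA
#' plot.
#'
#' @param experiment an \code{\link{experiment_set}}.
#' @return An \code{\link{ma_matrix}} with one column per array.
#' @export
compute_ma <- function(experiment) {
  stopifnot(inherits(experiment, "experiment_set"))
  X <- channel_log2_matrix(experiment)
  m <- n_arrays(experiment)
  G <- X[, seq_len(m), drop = FALSE]
  R <- X[, m + seq_len(m), drop = FALSE]
  M <- R - G
  A <- (R + G) / 2
  colnames(M) <- colnames(A) <- array_ids(experiment)
  rownames(M) <- rownames(A) <- experiment$annotation$probe_id
  ma_matrix(M, A)
}

#' Reconstruct channel intensities from an MA matrix
#'
#' Inverse of \code{\link{compute_ma}}: red = 2^(A + M/2),
#' green = 2^(A - M/2).
#'
#' @param ma an \code{\link{ma_matrix}}.
#' @return list with matrices \code{green} and \code{red}.
#' @export
ma_to_intensities <- function(ma) {
  stopifnot(inherits(ma, "ma_matrix"))
  list(green = 2^(ma$A - ma$M / 2), red = 2^(ma$A + ma$M / 2))
}

read_one_pair <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("PROBE_ID", "SEQ_ID", "POSITION", "PM")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pair file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "))
  df
}

align_pair <- function(df, annotation, path) {
  unknown <- setdiff(df$PROBE_ID, annotation$probe_id)
  if (length(unknown))
    stop("pair file ", path, " contains probe(s) absent from annotation; ",
         "first offending id: ", unknown[1L])
  idx <- match(annotation$probe_id, df$PROBE_ID)
  if (anyNA(idx))
    stop("pair file ", path, " is missing annotation probe(s); first: ",
         annotation$probe_id[which(is.na(idx))[1L]])
  as.numeric(df$PM[idx])
}

#' Read a NimbleGen-style pair file per channel
#'
#' Each channel of an array is a tab-separated file with a header naming at
#' least \code{PROBE_ID}, \code{SEQ_ID}, \code{POSITION} and \code{PM} (the
#' probe intensity); additional columns are ignored and lines starting with
#' \code{#} are comments. Intensities are reordered to match the annotation
#' by \code{PROBE_ID}.
#'
#' Non-positive intensities are rejected by default; with
#' \code{floor_intensities = TRUE} they are floored at \code{floor_eps}
#' fluorescence units instead.
#'
#' @param green_path pair file of the green (Cy3, input) channel.
#' @param red_path pair file of the red (Cy5, enriched) channel.
#' @param annotation a \code{\link{probe_annotation}}.
#' @param array_id identifier for the resulting array; defaults to the green
#'   file's base name.
#' @param floor_intensities floor non-positive intensities instead of
#'   erroring.
#' @param floor_eps floor value in fluorescence units.
#' @return A \code{\link{two_channel_array}}.
#' @export
read_pair_files <- function(green_path, red_path, annotation,
                            array_id = NULL, floor_intensities = FALSE,
                            floor_eps = 0.5) {
  stopifnot(inherits(annotation, "probe_annotation"))
  g <- align_pair(read_one_pair(green_path), annotation, green_path)
  r <- align_pair(read_one_pair(red_path), annotation, red_path)
  fix <- function(x, path) {
    if (any(!is.finite(x))) stop("non-finite intensity in ", path)
    if (any(x <= 0)) {
      if (floor_intensities) x <- pmax(x, floor_eps)
      else stop("non-positive intensity in ", path,
                "; use floor_intensities = TRUE to floor at ", floor_eps)
    }
    x
  }
  if (is.null(array_id))
    array_id <- sub("\\.[^.]*$", "", basename(green_path))
  two_channel_array(array_id, fix(g, green_path), fix(r, red_path))
}

#' Write one channel of an array as a pair file
#'
#' Writes \code{PROBE_ID}, \code{SEQ_ID}, \code{POSITION} (1-based) and
#' \code{PM} columns; round-trips with \code{\link{read_pair_files}}.
#'
#' @param annotation a \code{\link{probe_annotation}}.
#' @param intensities numeric vector aligned to the annotation.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pair_file <- function(annotation, intensities, path) {
  stopifnot(inherits(annotation, "probe_annotation"),
            length(intensities) == nrow(annotation))
  out <- data.frame(PROBE_ID = annotation$probe_id,
                    SEQ_ID = annotation$chrom,
                    POSITION = annotation$position + 1L,
                    PM = intensities)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an experiment set as pair + annotation files
#'
#' One pair file per channel per array (\code{<array>_G.pair},
#' \code{<array>_R.pair}) plus \code{annotation.tsv} in \code{dir}.
#'
#' @param experiment an \code{\link{experiment_set}}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "experiment_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(experiment$annotation, file.path(dir, "annotation.tsv"))
  for (a in experiment$arrays) {
    write_pair_file(experiment$annotation, a$green,
                    file.path(dir, paste0(a$array_id, "_G.pair")))
    write_pair_file(experiment$annotation, a$red,
                    file.path(dir, paste0(a$array_id, "_R.pair")))
  }
  invisible(dir)
}

#' Read an experiment set written by \code{write_experiment}
#'
#' @param dir directory containing \code{annotation.tsv} and
#'   \code{<array>_G.pair} / \code{<array>_R.pair} file pairs.
#' @param ... passed to \code{\link{read_pair_files}}.
#' @return An \code{\link{experiment_set}}.
#' @export
read_experiment <- function(dir, ...) {
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  gfiles <- sort(list.files(dir, pattern = "_G\\.pair$", full.names = TRUE))
  if (!length(gfiles)) stop("no *_G.pair files in ", dir)
  arrays <- lapply(gfiles, function(g) {
    r <- sub("_G\\.pair$", "_R.pair", g)
    read_pair_files(g, r, ann,
                    array_id = sub("_G\\.pair$", "", basename(g)), ...)
  })
  experiment_set(ann, arrays)
}
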