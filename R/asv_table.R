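#' Construct and validate an ASV count table
#'
#' An ASV table is the universal exchange object of the package: a
#' non-negative integer matrix with ASVs as rows and samples as columns,
#' identified by unique `rownames` (ASV ids) and `colnames` (sample ids).
#' The orientation is fixed; nothing is auto-detected.
#'
#' @param counts numeric matrix of non-negative integral counts with unique
#'   rownames (ASV identifiers) and unique colnames (sample identifiers).
#' @return the validated table as an integer matrix.
#' @examples
#' tab <- asv_table(matrix(c(5, 1, 0, 0, 2, 7), nrow = 3,
#'                         dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
#' colSums(tab)
#' @export
asv_table <- function(counts) {
  if (!is.matrix(counts)) {
    stop("counts must be a matrix (ASVs x samples)", call. = FALSE)
  }
  validate_asv_table(counts)
  storage.mode(counts) <- "integer"
  counts
}

validate_asv_table <- function(counts) {
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("ASV table must have rownames (ASV identifiers)", call. = FALSE)
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("ASV table must have colnames (sample identifiers)", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate ASV identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (length(counts)) {
    if (anyNA(counts)) stop("ASV table contains missing values", call. = FALSE)
    if (any(counts < 0)) stop("ASV table contains negative counts", call. = FALSE)
    if (any(counts != round(counts))) {
      stop("ASV table contains non-integral counts", call. = FALSE)
    }
  }
  invisible(counts)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each sample (column) by its read total, giving proportions in
#' \[0, 1\] that sum to 1 per sample. Samples with zero reads cannot be
#' normalised and raise an error naming the offending sample.
#'
#' @param table ASV count table (see [asv_table()]).
#' @return numeric matrix with the same dimnames; columns sum to 1.
#' @export
to_relative_abundance <- function(table) {
  validate_asv_table(table)
  totals <- colSums(table)
  if (any(totals == 0)) {
    stop("sample(s) with zero reads cannot be normalised: ",
         paste(colnames(table)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sweep(table + 0, 2, totals, "/")
}
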