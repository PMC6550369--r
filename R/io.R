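# File I/O for the three plain-text exchange formats: ASV count tables,
# sample metadata, and expected-ASV reference lists. All files are
# tab-separated UTF-8 with "." as the decimal mark and no quoting.

SAMPLE_TYPES <- c("dilution_sample", "negative_control")

#' Read an ASV count table from a TSV file
#'
#' Expects a header row of sample identifiers whose first cell is literally
#' `asv_id`, followed by one row per ASV: identifier, then non-negative
#' integer counts. Row and column order are preserved. Malformed cells and
#' duplicated identifiers are rejected with a message naming the offender.
#'
#' @param path path to a tab-separated file.
#' @return an integer count matrix (ASVs x samples), see [asv_table()].
#' @export
read_asv_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (header[[1]] != "asv_id") {
    stop("first header cell must be 'asv_id', got '", header[[1]], "'",
         call. = FALSE)
  }
  sample_ids <- header[-1]
  body <- lines[-1]
  body <- body[nzchar(body)]
  n_asv <- length(body)
  counts <- matrix(0L, nrow = n_asv, ncol = length(sample_ids))
  asv_ids <- character(n_asv)
  for (i in seq_len(n_asv)) {
    cells <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    if (length(cells) != length(sample_ids) + 1) {
      stop("row ", i + 1, " has ", length(cells), " fields, expected ",
           length(sample_ids) + 1, call. = FALSE)
    }
    asv_ids[[i]] <- cells[[1]]
    vals <- suppressWarnings(as.numeric(cells[-1]))
    bad <- which(is.na(vals) | vals < 0 | vals != round(vals))
    if (length(bad)) {
      stop("malformed count at row '", cells[[1]], "', column '",
           sample_ids[[bad[[1]]]], "': '", cells[[bad[[1]] + 1]], "'",
           call. = FALSE)
    }
    counts[i, ] <- as.integer(vals)
  }
  dimnames(counts) <- list(asv_ids, sample_ids)
  asv_table(counts)
}

#' Write an ASV count table to a TSV file
#'
#' Inverse of [read_asv_table()]: `read_asv_table(write_asv_table(t, f))`
#' reproduces `t` exactly.
#'
#' @param table ASV count table.
#' @param path destination path.
#' @export
write_asv_table <- function(table, path) {
  validate_asv_table(table)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("asv_id", colnames(table)), collapse = "\t"), con)
  if (nrow(table)) {
    rows <- apply(table, 1, paste, collapse = "\t")
    if (ncol(table) == 0) {
      writeLines(rownames(table), con)
    } else {
      writeLines(paste(rownames(table), rows, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read per-sample metadata from a TSV file
#'
#' Requires the four columns `sample_id`, `dilution_round`,
#' `dna_concentration`, `sample_type`. `dilution_round` is empty for
#' negative controls; `sample_type` must be one of `dilution_sample` or
#' `negative_control`.
#'
#' @param path path to a tab-separated file.
#' @return data frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  needed <- c("sample_id", "dilution_round", "dna_concentration", "sample_type")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad_type)) {
    stop("unknown sample_type '", bad_type[[1]], "'; allowed: ",
         paste(SAMPLE_TYPES, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    sample_id = df$sample_id,
    dilution_round = suppressWarnings(as.integer(df$dilution_round)),
    dna_concentration = suppressWarnings(as.numeric(df$dna_concentration)),
    sample_type = df$sample_type,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  if (anyNA(out$dna_concentration)) {
    stop("unreadable dna_concentration for sample(s): ",
         paste(out$sample_id[is.na(out$dna_concentration)], collapse = ", "),
         call. = FALSE)
  }
  if (any(out$dna_concentration < 0)) {
    stop("negative dna_concentration for sample(s): ",
         paste(out$sample_id[out$dna_concentration < 0], collapse = ", "),
         call. = FALSE)
  }
  unreadable <- !is.na(df$dilution_round) & nzchar(df$dilution_round) &
    is.na(out$dilution_round)
  if (any(unreadable)) {
    stop("unreadable dilution_round for sample(s): ",
         paste(out$sample_id[unreadable], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write per-sample metadata to a TSV file
#' @param metadata data frame as returned by [read_metadata()].
#' @param path destination path.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$dilution_round <- ifelse(is.na(out$dilution_round), "",
                               as.character(out$dilution_round))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expected-ASV reference list
#'
#' Plain text, one ASV identifier per line, with an optional second
#' tab-separated taxon-label column.
#'
#' @param path path to the reference file.
#' @return data frame with columns `asv_id` and `taxon_label` (NA when the
#'   file has no label column).
#' @export
read_reference <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty reference file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1)
  labels <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_, "")
  if (anyDuplicated(ids)) stop("duplicate ASV id in reference", call. = FALSE)
  data.frame(asv_id = ids, taxon_label = labels, stringsAsFactors = FALSE)
}

#' Write an expected-ASV reference list
#' @param reference data frame with columns `asv_id` and optionally
#'   `taxon_label`.
#' @param path destination path.
#' @export
write_reference <- function(reference, path) {
  has_label <- "taxon_label" %in% names(reference) &&
    any(!is.na(reference$taxon_label))
  lines <- if (has_label) {
    paste(reference$asv_id, reference$taxon_label, sep = "\t")
  } else {
    reference$asv_id
  }
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
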