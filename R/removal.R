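# Shared container for the output of every contaminant-removal method, and
# the two filtering methods (negative-control presence, relative abundance).

#' Construct a removal result
#'
#' Every method maps an ASV table to a `removal_result`: a per-(ASV, sample)
#' retained fraction in \[0, 1\], a binary call (`kept`/`removed`), and an
#' optional per-ASV score. Binary methods have retained fractions in
#' \{0, 1\} agreeing with the call; proportional methods (source
#' attribution) carry fractional retention and a call binarised at a
#' threshold. The corrected table is `counts * retained_fraction`, rounded
#' toward zero.
#'
#' @param method_name method identifier.
#' @param params named list of the parameters used.
#' @param retained_fraction numeric matrix (ASVs x samples) in \[0, 1\].
#' @param call character matrix of `"kept"`/`"removed"`, same shape; when
#'   `NULL`, derived as `removed` iff `retained_fraction < call_threshold`.
#' @param score optional named per-ASV numeric score.
#' @param call_threshold binarisation threshold for proportional methods.
#' @param unscored character vector of ASVs the method could not score
#'   (kept by definition).
#' @return a `removal_result` list.
#' @export
removal_result <- function(method_name, params, retained_fraction,
                           call = NULL, score = NULL, call_threshold = 0.5,
                           unscored = character(0)) {
  stopifnot(is.matrix(retained_fraction))
  if (any(retained_fraction < 0 | retained_fraction > 1)) {
    stop("retained_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(call)) {
    call <- ifelse(retained_fraction < call_threshold, "removed", "kept")
    dimnames(call) <- dimnames(retained_fraction)
  }
  stopifnot(identical(dim(call), dim(retained_fraction)))
  structure(list(method_name = method_name, params = params,
                 retained_fraction = retained_fraction, call = call,
                 score = score, unscored = unscored),
            class = "removal_result")
}

#' Apply a removal result to a count table
#'
#' @param table ASV count table covering the result's ASVs and samples.
#' @param result a [removal_result()].
#' @return corrected integer count matrix over the result's samples:
#'   `floor(counts * retained_fraction)`.
#' @export
corrected_counts <- function(table, result) {
  validate_asv_table(table)
  rf <- result$retained_fraction
  missing_asv <- setdiff(rownames(rf), rownames(table))
  missing_smp <- setdiff(colnames(rf), colnames(table))
  if (length(missing_asv) || length(missing_smp)) {
    stop("removal result refers to ASVs/samples absent from the table",
         call. = FALSE)
  }
  sub <- table[rownames(rf), colnames(rf), drop = FALSE]
  out <- matrix(as.integer(floor(sub * rf)), nrow = nrow(rf),
                dimnames = dimnames(rf))
  out
}

#' Filter ASVs present in the negative control
#'
#' An ASV is removed from every non-control sample iff it has a nonzero
#' count in any of the listed control samples. Binary, dataset-wide across
#' the non-control samples.
#'
#' @param table ASV count table including the control column(s).
#' @param control_sample_ids character vector of control sample ids.
#' @return a [removal_result()] over the non-control samples.
#' @export
filter_by_negative_control <- function(table, control_sample_ids) {
  validate_asv_table(table)
  missing <- setdiff(control_sample_ids, colnames(table))
  if (length(missing)) {
    stop("unknown control sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- table[, control_sample_ids, drop = FALSE]
  in_control <- rowSums(ctrl) > 0
  keep_samples <- setdiff(colnames(table), control_sample_ids)
  rf <- matrix(rep(as.numeric(!in_control), length(keep_samples)),
               nrow = nrow(table),
               dimnames = list(rownames(table), keep_samples))
  removal_result("negctrl", list(control_sample_ids = control_sample_ids), rf)
}

#' Filter ASVs by per-sample relative abundance
#'
#' An ASV is removed in a sample iff its relative abundance in that sample
#' is strictly below `threshold`. Zeroing is per sample, not dataset-wide:
#' the same ASV may be kept in one sample and removed in another.
#'
#' @param table ASV count table (every sample must have reads).
#' @param threshold proportion in (0, 1); a percent threshold is divided by
#'   100 before this call.
#' @return a [removal_result()].
#' @export
filter_by_abundance <- function(table, threshold) {
  validate_asv_table(table)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single proportion in (0, 1)", call. = FALSE)
  }
  rel <- to_relative_abundance(table)
  rf <- matrix(as.numeric(rel >= threshold), nrow = nrow(table),
               dimnames = dimnames(table))
  removal_result("abundance", list(threshold = threshold), rf)
}
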