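# Scoring of removal methods against ground truth: per-ASV labels, percent
# contaminant reads, confusion counts and accuracy, alpha diversity, and
# recovery of the expected community composition.

#' Label ASVs as mock or contaminant
#'
#' An ASV is `mock` iff its identifier appears in the expected reference;
#' everything else is `contaminant`. Matching is exact string equality.
#'
#' @param table ASV count table.
#' @param reference expected-ASV reference (data frame with `asv_id`, or a
#'   character vector of ids).
#' @return named character vector over the table's ASVs with values
#'   `"mock"` / `"contaminant"`.
#' @export
label_ground_truth <- function(table, reference) {
  validate_asv_table(table)
  ids <- if (is.data.frame(reference)) reference$asv_id else reference
  stats::setNames(ifelse(rownames(table) %in% ids, "mock", "contaminant"),
                  rownames(table))
}

#' Percent contaminant reads per sample
#'
#' 100 times the fraction of each sample's reads carried by
#' contaminant-labeled ASVs. Zero-read samples are reported as `NA`.
#'
#' @param table ASV count table.
#' @param labels per-ASV labels from [label_ground_truth()].
#' @return named numeric vector in \[0, 100\] per sample.
#' @export
percent_contaminants <- function(table, labels) {
  validate_asv_table(table)
  labels <- labels[rownames(table)]
  totals <- colSums(table)
  cont <- colSums(table[labels == "contaminant", , drop = FALSE])
  out <- ifelse(totals > 0, 100 * cont / totals, NA_real_)
  stats::setNames(out, colnames(table))
}

#' Confusion counts and accuracy of a removal result
#'
#' Per sample, over the ASVs with nonzero count in that sample: `tp` =
#' contaminant ASVs removed, `fn` = contaminant ASVs kept, `tn` = mock ASVs
#' kept, `fp` = mock ASVs removed; `accuracy = (tp + tn) / (tp+tn+fp+fn)`.
#' Also reports the percentage of contaminant ASVs correctly removed and of
#' mock ASVs misclassified, as percentages in \[0, 100\] (NA when a sample
#' holds no ASV of that class).
#'
#' @param result a [removal_result()].
#' @param labels per-ASV labels from [label_ground_truth()].
#' @param table ASV count table covering the result's ASVs and samples.
#' @return data frame with one row per sample.
#' @export
confusion_and_accuracy <- function(result, labels, table) {
  validate_asv_table(table)
  call <- result$call
  if (length(setdiff(colnames(call), colnames(table)))) {
    stop("result covers samples absent from the table", call. = FALSE)
  }
  rows <- lapply(colnames(call), function(sid) {
    present <- rownames(table)[table[, sid] > 0]
    miss <- setdiff(present, rownames(call))
    if (length(miss)) {
      stop("no call for ASV(s) present in sample ", sid, ": ",
           paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
    }
    lab <- labels[present]
    removed <- call[present, sid] == "removed"
    tp <- sum(lab == "contaminant" & removed)
    fn <- sum(lab == "contaminant" & !removed)
    fp <- sum(lab == "mock" & removed)
    tn <- sum(lab == "mock" & !removed)
    n <- tp + fn + fp + tn
    data.frame(
      sample_id = sid, tp = tp, fn = fn, tn = tn, fp = fp,
      accuracy = if (n > 0) (tp + tn) / n else NA_real_,
      pct_contaminant_correct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
      pct_mock_misclassified = if (tn + fp > 0) 100 * fp / (tn + fp) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$method <- result$method_name
  out[, c("method", setdiff(names(out), "method"))]
}

#' Dataset-wide confusion counts
#'
#' ASV-level companion to the per-sample view: each ASV is counted once,
#' with the call `removed` iff the method removed it in every sample where
#' it is present (for dataset-wide classifiers such as the frequency
#' method the two views coincide on scored ASVs).
#'
#' @inheritParams confusion_and_accuracy
#' @return one-row data frame of ASV-level confusion counts and accuracy.
#' @export
confusion_dataset_wide <- function(result, labels, table) {
  validate_asv_table(table)
  call <- result$call
  sub <- table[rownames(call), colnames(call), drop = FALSE]
  present_any <- rowSums(sub) > 0
  removed <- vapply(seq_len(nrow(call)), function(i) {
    pres <- sub[i, ] > 0
    all(call[i, pres] == "removed")
  }, logical(1))
  lab <- labels[rownames(call)]
  tp <- sum(present_any & lab == "contaminant" & removed)
  fn <- sum(present_any & lab == "contaminant" & !removed)
  fp <- sum(present_any & lab == "mock" & removed)
  tn <- sum(present_any & lab == "mock" & !removed)
  n <- tp + fn + fp + tn
  data.frame(method = result$method_name, tp = tp, fn = fn, tn = tn, fp = fp,
             accuracy = if (n > 0) (tp + tn) / n else NA_real_,
             stringsAsFactors = FALSE)
}

#' Alpha diversity of one count vector
#'
#' `observed` counts taxa with nonzero count; `shannon` is
#' `-sum(p_i * ln(p_i))` (natural log by default); `inv_simpson` is
#' `1 / sum(p_i^2)`.
#'
#' @param counts non-negative count (or abundance) vector with at least one
#'   positive entry.
#' @param metric one of `"observed"`, `"shannon"`, `"inv_simpson"`.
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @return scalar diversity value.
#' @export
alpha_diversity <- function(counts,
                            metric = c("observed", "shannon", "inv_simpson"),
                            base = exp(1)) {
  metric <- match.arg(metric)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero count vector", call. = FALSE)
  switch(metric,
         observed = sum(counts > 0),
         shannon = unname(vegan::diversity(counts, index = "shannon",
                                           base = base)),
         inv_simpson = unname(vegan::diversity(counts, index = "invsimpson")))
}

#' Alpha diversity for every sample of a table
#'
#' @param table ASV count table (zero-read samples yield NA).
#' @param metrics which metrics to compute.
#' @param base logarithm base for Shannon.
#' @return data frame with one row per sample and one column per metric.
#' @export
alpha_diversity_table <- function(table,
                                  metrics = c("observed", "shannon",
                                              "inv_simpson"),
                                  base = exp(1)) {
  validate_asv_table(table)
  out <- data.frame(sample_id = colnames(table), stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[m]] <- vapply(seq_len(ncol(table)), function(j) {
      if (sum(table[, j]) == 0) NA_real_
      else as.numeric(alpha_diversity(table[, j], m, base = base))
    }, numeric(1))
  }
  out
}

#' Expected alpha diversity from the expected-ASV subset
#'
#' The expected value of a diversity metric for each sample is the metric
#' computed on that sample's counts restricted to the expected reference
#' ASVs; contaminant counts cannot influence it. Samples without expected
#' reads are reported as NA.
#'
#' @param table ASV count table.
#' @param reference expected-ASV reference (data frame with `asv_id` or
#'   character vector).
#' @param metric one of `"observed"`, `"shannon"`, `"inv_simpson"`.
#' @param base logarithm base for Shannon.
#' @return named numeric vector per sample.
#' @export
expected_alpha <- function(table, reference,
                           metric = c("observed", "shannon", "inv_simpson"),
                           base = exp(1)) {
  metric <- match.arg(metric)
  ids <- if (is.data.frame(reference)) reference$asv_id else reference
  sub <- table[rownames(table) %in% ids, , drop = FALSE]
  vapply(stats::setNames(seq_len(ncol(table)), colnames(table)), function(j) {
    if (sum(sub[, j]) == 0) NA_real_
    else as.numeric(alpha_diversity(sub[, j], metric, base = base))
  }, numeric(1))
}

#' Composition recovery after correction
#'
#' Compares each corrected sample's relative abundances against the true
#' expected-community profile. Contaminant ASVs have true share 0, so any
#' contaminant mass left contributes fully to the error; removed expected
#' ASVs contribute their true share. `l1_error` is the total variation
#' times two: `sum |observed - expected|`, in \[0, 2\].
#'
#' @param corrected corrected ASV count table (columns must have reads).
#' @param truth_profile named probability vector over the expected ASVs.
#' @param labels per-ASV labels from [label_ground_truth()].
#' @return list with `l1_error` (named per-sample vector) and `expected`
#'   (data frame of per-sample observed vs expected relative abundance for
#'   each expected ASV).
#' @export
composition_recovery <- function(corrected, truth_profile, labels) {
  validate_asv_table(corrected)
  totals <- colSums(corrected)
  if (any(totals == 0)) {
    stop("corrected sample(s) with zero reads: ",
         paste(colnames(corrected)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  rel <- to_relative_abundance(corrected)
  exp_ids <- names(truth_profile)
  obs_expected <- matrix(0, nrow = length(exp_ids), ncol = ncol(rel),
                         dimnames = list(exp_ids, colnames(rel)))
  in_tab <- intersect(exp_ids, rownames(rel))
  obs_expected[in_tab, ] <- rel[in_tab, , drop = FALSE]

  cont_mass <- colSums(rel[labels[rownames(rel)] == "contaminant", ,
                           drop = FALSE])
  l1 <- colSums(abs(obs_expected - truth_profile)) + cont_mass
  per_asv <- data.frame(
    sample_id = rep(colnames(rel), each = length(exp_ids)),
    asv_id = rep(exp_ids, ncol(rel)),
    observed = as.vector(obs_expected),
    expected = rep(unname(truth_profile), ncol(rel)),
    stringsAsFactors = FALSE
  )
  list(l1_error = stats::setNames(l1, colnames(rel)), expected = per_asv)
}
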