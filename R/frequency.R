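# Frequency-versus-concentration contaminant classifier.
#
# Contaminant DNA enters at a roughly constant amount per reaction, so a
# contaminant ASV's relative frequency varies inversely with the total DNA
# concentration of the sample, while a genuine community member's frequency
# is independent of it. For each ASV the classifier compares, on log10
# scales, the fit of a line with slope fixed at -1 (contaminant model)
# against a line with slope fixed at 0 (non-contaminant model) and scores
# the ASV by the F-CDF of the residual-sum-of-squares ratio.

#' Score ASVs by the inverse frequency-concentration relationship
#'
#' For each ASV, over the non-control samples where it has nonzero relative
#' frequency, fits two one-parameter models to
#' `(x = log10 concentration, y = log10 frequency)`: slope fixed at -1
#' (intercept free) and slope fixed at 0 (intercept free). The score is the
#' CDF at `ss_contaminant / ss_noncontaminant` of the F distribution with
#' `(n_used - 1, n_used - 1)` degrees of freedom; low scores are
#' contaminant-like (0 = perfect inverse fit, 1 = perfect constant fit).
#' ASVs with fewer than `min_points` usable samples are not scored.
#'
#' @param table ASV count table.
#' @param metadata sample metadata with `sample_id`, `dna_concentration`,
#'   `sample_type`; negative controls are excluded from the fit.
#' @param min_points minimum nonzero-frequency samples required to score an
#'   ASV (default 3).
#' @return a `frequency_fit` data frame with one row per ASV: `asv_id`,
#'   `n_used`, `ss_contaminant`, `ss_noncontaminant`, `score` (NA when
#'   unscoreable).
#' @export
decontam_frequency_scores <- function(table, metadata, min_points = 3) {
  validate_asv_table(table)
  md <- metadata[match(colnames(table), metadata$sample_id), , drop = FALSE]
  if (anyNA(md$sample_id)) {
    stop("metadata is missing sample(s): ",
         paste(setdiff(colnames(table), metadata$sample_id), collapse = ", "),
         call. = FALSE)
  }
  use_sample <- md$sample_type != "negative_control"
  sub <- table[, use_sample, drop = FALSE]
  conc <- md$dna_concentration[use_sample]
  totals <- colSums(sub)
  if (any(totals == 0)) {
    stop("zero-read sample(s): ",
         paste(colnames(sub)[totals == 0], collapse = ", "), call. = FALSE)
  }
  freq <- sweep(sub + 0, 2, totals, "/")

  fit_one <- function(freq_row) {
    nz <- freq_row > 0
    n <- sum(nz)
    if (n < min_points) {
      return(c(n_used = n, ss_contaminant = NA_real_,
               ss_noncontaminant = NA_real_, score = NA_real_))
    }
    if (any(conc[nz] <= 0)) {
      stop("non-positive DNA concentration for sample(s) used in the fit: ",
           paste(colnames(sub)[nz & conc <= 0], collapse = ", "),
           call. = FALSE)
    }
    x <- log10(conc[nz])
    y <- log10(freq_row[nz])
    # slope -1, free intercept: y = b - x  =>  b = mean(y + x)
    ss1 <- sum((y + x - mean(y + x))^2)
    # slope 0, free intercept: y = b      =>  b = mean(y)
    ss0 <- sum((y - mean(y))^2)
    score <- if (ss0 == 0 && ss1 == 0) {
      0.5
    } else if (ss0 == 0) {
      1
    } else {
      stats::pf(ss1 / ss0, n - 1, n - 1)
    }
    c(n_used = n, ss_contaminant = ss1, ss_noncontaminant = ss0,
      score = score)
  }

  stats_mat <- t(apply(freq, 1, fit_one))
  out <- data.frame(asv_id = rownames(table), stats_mat,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_used <- as.integer(out$n_used)
  class(out) <- c("frequency_fit", class(out))
  out
}

#' Classify ASVs from frequency scores
#'
#' Dataset-wide binary classification: an ASV is removed from every sample
#' iff its score is strictly below `p_star`. Unscored ASVs are kept and
#' reported in the result's `unscored` field.
#'
#' @param fit a `frequency_fit` from [decontam_frequency_scores()].
#' @param p_star classification threshold in (0, 1\]; 0.5 is the point at
#'   which the contaminant model merely has to fit better than the
#'   non-contaminant model.
#' @param table ASV count table whose samples the calls should cover
#'   (typically the non-control samples).
#' @return a [removal_result()].
#' @export
decontam_classify <- function(fit, p_star, table) {
  if (!is.numeric(p_star) || length(p_star) != 1 || p_star <= 0 || p_star > 1) {
    stop("p_star must be a single value in (0, 1]", call. = FALSE)
  }
  validate_asv_table(table)
  score <- stats::setNames(fit$score, fit$asv_id)[rownames(table)]
  removed <- !is.na(score) & score < p_star
  rf <- matrix(rep(as.numeric(!removed), ncol(table)), nrow = nrow(table),
               dimnames = dimnames(table))
  removal_result("frequency", list(p_star = p_star), rf,
                 score = score,
                 unscored = rownames(table)[is.na(score)])
}
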