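#!/usr/bin/env Rscript

# Stage 3: score every method's calls against the ground truth.
#
# Reads the experiment from results/experiment/ and the calls TSVs from
# results/calls/, then writes confusion.tsv, diversity.tsv, recovery.tsv,
# and summary.tsv under results/, and prints the per-method accuracy
# ranking together with the headline findings.

library(contamSeries)

exp_dir <- "results/experiment"
calls_dir <- "results/calls"
out_dir <- "results"

table <- read_asv_table(file.path(exp_dir, "table.tsv"))
metadata <- read_metadata(file.path(exp_dir, "metadata.tsv"))
reference <- read_reference(file.path(exp_dir, "reference.tsv"))
truth <- utils::read.delim(file.path(exp_dir, "ground_truth.tsv"))
labels <- label_ground_truth(table, reference)
dil_ids <- metadata$sample_id[metadata$sample_type == "dilution_sample"]
dilution <- table[, dil_ids]

call_files <- sort(list.files(calls_dir, pattern = "^calls_.*\\.tsv$",
                              full.names = TRUE))
stopifnot(length(call_files) > 0)

confusion <- list()
diversity <- list(
  within(alpha_diversity_table(dilution), method <- "uncorrected"),
  data.frame(sample_id = dil_ids,
             observed = expected_alpha(dilution, reference, "observed"),
             shannon = expected_alpha(dilution, reference, "shannon"),
             inv_simpson = expected_alpha(dilution, reference, "inv_simpson"),
             method = "expected"))
recovery <- list()

# the true expected profile is estimated from the undiluted sample, which
# is >99% mock by construction
d0 <- dilution[reference$asv_id, "D0"]
truth_profile <- d0 / sum(d0)

for (path in call_files) {
  result <- read_calls(path)
  confusion[[result$method_name]] <-
    confusion_and_accuracy(result, labels, dilution)
  corr <- corrected_counts(dilution, result)
  ok <- colSums(corr) > 0
  if (!any(ok)) next
  corr <- asv_table(corr[, ok, drop = FALSE])
  dv <- alpha_diversity_table(corr)
  dv$method <- result$method_name
  diversity[[result$method_name]] <- dv
  rec <- composition_recovery(corr, truth_profile, labels)
  recovery[[result$method_name]] <- data.frame(
    method = result$method_name, sample_id = names(rec$l1_error),
    l1_error = unname(rec$l1_error))
}

conf_all <- do.call(rbind, c(confusion, list(make.row.names = FALSE)))
div_all <- do.call(rbind, c(diversity, list(make.row.names = FALSE)))
rec_all <- do.call(rbind, c(recovery, list(make.row.names = FALSE)))
summary_df <- data.frame(sample_id = colnames(table),
                         reads = colSums(table),
                         unique_asvs = colSums(table > 0),
                         pct_contaminants = percent_contaminants(table, labels),
                         row.names = NULL)
utils::write.table(conf_all, file.path(out_dir, "confusion.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(div_all, file.path(out_dir, "diversity.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(rec_all, file.path(out_dir, "recovery.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

ranking <- aggregate(cbind(accuracy, pct_contaminant_correct,
                           pct_mock_misclassified) ~ method,
                     conf_all, mean)
ranking <- ranking[order(-ranking$accuracy), ]
cat("Method ranking by mean per-sample accuracy:\n\n")
print(transform(ranking,
                accuracy = round(accuracy, 3),
                pct_contaminant_correct = round(pct_contaminant_correct, 1),
                pct_mock_misclassified = round(pct_mock_misclassified, 1)),
      row.names = FALSE)

l1 <- aggregate(l1_error ~ method, rec_all, mean)
cat("\nMean L1 composition error (uncorrected mean:",
    round(mean(composition_recovery(dilution, truth_profile,
                                    labels)$l1_error), 3), "):\n\n")
print(transform(l1[order(l1$l1_error), ], l1_error = round(l1_error, 3)),
      row.names = FALSE)
cat("\nWrote confusion/diversity/recovery/summary TSVs to", out_dir, "\n")
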