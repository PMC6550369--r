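# contamSeries

Benchmarking contaminant-removal methods for 16S rRNA amplicon sequencing
on mock-community dilution series with known ground truth.

## The problem

In low-microbial-biomass samples (urine, airway, atmosphere), reagent-borne
bacterial DNA can dominate 16S rRNA gene sequencing results: as genuine
template is diluted away, a constant contaminant background takes over,
inflating diversity estimates and distorting community profiles. A dilution
series of a mock community of known composition turns this failure mode
into a measurable benchmark — every amplicon sequence variant (ASV) not in
the mock reference is an error — and lets contaminant-identification
methods be scored exactly.

`contamSeries` is aimed at microbiome methodologists and analysts of
low-biomass experiments. It provides:

* a **seeded simulator** of a mock dilution series: a 9-ASV mock community
  (8 species, one split into two sequence variants) serially diluted
  `r`-fold for `n` rounds against a constant contaminant background, with
  barcode cross-talk singletons and a negative control carrying a small
  mock leak. The contaminant read fraction at round `d` follows the
  two-compartment model `f_d = C / (C + M0 * r^(-d))`;
* **four removal methods**: negative-control filtering, per-sample relative
  abundance filtering, a frequency-vs-DNA-concentration classifier (per
  ASV, the F-CDF score `pf(SS_slope=-1 / SS_slope=0, n-1, n-1)` on log10
  scales; 0 = contaminant-like, removed when below the threshold P*), and
  Bayesian source attribution by a collapsed Gibbs sampler over defined
  source environments plus an unknown source (compiled with Rcpp);
* **evaluation**: per-sample confusion counts and accuracy, percent
  contaminant reads, alpha diversity (observed ASVs, Shannon, inverse
  Simpson) against expected values computed on the expected-ASV subset,
  and L1 recovery error of the corrected community composition.

All exchange formats are plain TSV (ASV table, sample metadata, reference
list, per-method calls), and every stage is deterministic given a seed.

## Worked example

```r
library(contamSeries)

cfg <- simulation_config(seed = 1)          # 9 mock ASVs, 200 contaminants,
ex  <- simulate_dilution_series(cfg)        # 8 three-fold dilutions + control
labels <- label_ground_truth(ex$table, ex$reference)
round(percent_contaminants(ex$table, labels), 1)
#>   D0   D1   D2   D3   D4   D5   D6   D7   D8   NC
#>  0.2  0.6  1.8  5.5 14.4 32.7 59.7 82.1 92.2 98.8
```

Contaminants overtake half the community after the sixth dilution round.
Scoring the frequency classifier at its strictest threshold:

```r
md  <- ex$metadata
dil <- ex$table[, md$sample_id[md$sample_type == "dilution_sample"]]
fit <- decontam_frequency_scores(ex$table, md)
res <- decontam_classify(fit, p_star = 0.5, dil)
conf <- confusion_and_accuracy(res, labels, dil)
range(conf$pct_contaminant_correct)   # 70.1 88.6  (% contaminants removed)
sum(conf$fp)                          # 0          (no mock ASV removed)
```

The full benchmark — all 13 method configurations plus reports and a
checksummed manifest — is one call:

```r
run_all(run_config(output_dir = "results", seed = 1))
```

or, staged, the three scripts under `analysis/`
(`01_simulate.R`, `02_apply_methods.R`, `03_evaluate.R`). The evaluation
stage prints the method ranking; with the default seed:

```
              method accuracy pct_contaminant_correct pct_mock_misclassified
 sourcetracker_s1_c1    1.000                   100.0                    0.0
 sourcetracker_s1_c2    1.000                   100.0                    0.0
 sourcetracker_s2_c1    0.928                    90.4                    0.0
      abundance_0.01    0.887                    88.4                    8.6
       frequency_p50    0.822                    78.7                    0.0
       ...
             negctrl    0.616                    61.4                   33.3
```

Source attribution with a well-defined experimental environment is nearly
perfect; the frequency classifier removes most contaminants without ever
touching a mock ASV; the 1% abundance filter is accurate but sacrifices
mock ASVs; the negative-control filter misclassifies a third of the mock
community (three of its nine ASVs leak into the control) while missing
tail contaminants absent from the control.

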