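test_that("simulation config is validated", {
  expect_error(simulation_config(n_mock_asvs = 1), "n_mock_asvs")
  expect_error(simulation_config(dilution_factor = 1), "dilution_factor")
  expect_error(simulation_config(crosstalk_rate = 1), "crosstalk_rate")
  expect_error(simulation_config(reads_per_sample = c(10, 10)),
               "n_dilutions")
  cfg <- simulation_config(paper_scale = TRUE)
  expect_identical(cfg$n_contaminant_asvs, 937L)
})

test_that("mock profile is a near-even split community", {
  cfg <- simulation_config()
  set.seed(1)
  p <- make_mock_profile(cfg)
  expect_length(p, 9)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0.01))

  even <- make_mock_profile(simulation_config(mock_profile_concentration = Inf))
  # 8 species slots exactly even; one slot split unevenly into two ASVs
  expect_equal(sum(even), 1)
  expect_equal(max(even) , 1 / 8, tolerance = 1e-12)
  expect_equal(sort(unique(round(even, 12))), round(c(0.3, 0.7, 1) / 8, 12))

  set.seed(1)
  p2 <- make_mock_profile(simulation_config(n_mock_asvs = 2))
  expect_length(p2, 2)
  expect_true(all(p2 > 0))
  expect_equal(sum(p2), 1)
})

test_that("contaminant profile is long-tailed with dominant taxa", {
  cfg <- simulation_config()
  set.seed(1)
  p <- make_contaminant_profile(cfg)
  expect_length(p, 200)
  expect_equal(sum(p), 1)
  expect_gte(max(p), 10 * stats::median(p))
  expect_true(max(p) >= 0.02 && max(p) <= 0.3)

  unif <- make_contaminant_profile(
    simulation_config(contaminant_profile_shape = Inf))
  expect_true(all(abs(unif - 1 / 200) < 1e-12))

  one <- make_contaminant_profile(simulation_config(n_contaminant_asvs = 1))
  expect_equal(unname(one), 1)
})

test_that("analytic contaminant fraction follows the two-compartment model", {
  cfg0 <- simulation_config(contaminant_template = 0)
  expect_equal(unname(expected_contaminant_fraction(0:8, cfg0)), rep(0, 9))

  cfg1 <- simulation_config(mock_template_d0 = 0, contaminant_template = 5)
  expect_equal(unname(expected_contaminant_fraction(0:8, cfg1)), rep(1, 9))

  cfg <- simulation_config(mock_template_d0 = 1000, contaminant_template = 1,
                           dilution_factor = 3)
  expect_equal(expected_contaminant_fraction(6, cfg), 729 / 1729)

  f <- expected_contaminant_fraction(0:8, simulation_config())
  expect_true(all(diff(f) > 0))
  expect_error(expected_contaminant_fraction(
    2, simulation_config(mock_template_d0 = 0, contaminant_template = 0)),
    "undefined")
})

test_that("simulated experiments respect depth, metadata, and purity limits", {
  cfg <- simulation_config(contaminant_template = 0, crosstalk_rate = 0,
                           seed = 3)
  ex <- simulate_dilution_series(cfg)
  labels <- label_ground_truth(ex$table, ex$reference)
  dil <- ex$metadata$sample_id[ex$metadata$sample_type == "dilution_sample"]
  pct <- percent_contaminants(ex$table[, dil], labels)
  expect_equal(unname(pct), rep(0, length(dil)))

  # conservation: per-sample totals match the configured schedule exactly
  cfg2 <- simulation_config(reads_per_sample = rep(1234L, 9), seed = 5)
  ex2 <- simulate_dilution_series(cfg2)
  dil2 <- ex2$metadata$sample_id[ex2$metadata$sample_type == "dilution_sample"]
  expect_true(all(colSums(ex2$table[, dil2]) == 1234L))
  expect_identical(sum(ex2$table[, "NC"]), cfg2$reads_negative_control)

  # every sample has metadata; reference equals the truth's expected set
  expect_setequal(colnames(ex2$table), ex2$metadata$sample_id)
  expect_identical(ex2$reference$asv_id, ex2$truth$expected_asv_ids)
})

test_that("the negative control contains mock reads only via the leak", {
  ex0 <- simulate_dilution_series(
    simulation_config(negative_control_mock_leak = 0, seed = 2))
  mock_in_nc <- ex0$table[ex0$truth$expected_asv_ids, "NC"]
  expect_true(all(mock_in_nc == 0))

  ex <- simulate_dilution_series(simulation_config(seed = 2))
  nc <- ex$table[, "NC"]
  frac_mock <- sum(nc[ex$truth$expected_asv_ids]) / sum(nc)
  expect_equal(frac_mock, 0.017, tolerance = 0.5)
  expect_lte(length(ex$truth$control_mock_asv_ids), 3)
})

test_that("ground truth partitions the ASV universe", {
  for (sd in c(1, 9, 23)) {
    ex <- simulate_dilution_series(simulation_config(seed = sd))
    tr <- ex$truth
    expect_length(intersect(tr$expected_asv_ids, tr$contaminant_asv_ids), 0)
    expect_setequal(c(tr$expected_asv_ids, tr$contaminant_asv_ids),
                    rownames(ex$table))
    expect_setequal(names(tr$origin)[tr$origin == "crosstalk"],
                    grep("^xtalk", tr$contaminant_asv_ids, value = TRUE))
    expect_false(any(tr$shared_with_control[tr$origin == "crosstalk"]))
  }
})

test_that("identical seed and config give a bit-identical experiment", {
  a <- simulate_dilution_series(simulation_config(seed = 17))
  b <- simulate_dilution_series(simulation_config(seed = 17))
  expect_identical(a, b)
  c <- simulate_dilution_series(simulation_config(seed = 18))
  expect_false(identical(a$table, c$table))
})

test_that("cross-talk produces rare single-sample ASVs labeled contaminant", {
  ex <- simulate_dilution_series(simulation_config(seed = 4))
  xt <- grep("^xtalk", rownames(ex$table), value = TRUE)
  emitted <- xt[rowSums(ex$table[xt, , drop = FALSE]) > 0]
  expect_gt(length(emitted), 0)
  per_asv_samples <- rowSums(ex$table[emitted, , drop = FALSE] > 0)
  expect_true(all(rowSums(ex$table[emitted, , drop = FALSE]) <= 5))
  expect_gte(mean(per_asv_samples == 1), 0.7)
})
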