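test_that("ground-truth labeling partitions by reference membership", {
  tab <- asv_table(matrix(1L, 3, 1, dimnames = list(c("a", "b", "c"), "s")))
  lab <- label_ground_truth(tab, c("a", "b"))
  expect_identical(unname(lab), c("mock", "mock", "contaminant"))
  expect_identical(unname(label_ground_truth(tab, character(0))),
                   rep("contaminant", 3))
  expect_identical(unname(label_ground_truth(tab, c("a", "b", "c", "d"))),
                   rep("mock", 3))
})

test_that("percent contaminants is the contaminant read share x 100", {
  tab <- asv_table(matrix(c(999L, 1L, 0L, 5L, 20L, 80L), nrow = 3,
                          dimnames = list(c("m", "c1", "c2"),
                                          c("sA", "sB"))))
  lab <- label_ground_truth(tab, "m")
  pct <- percent_contaminants(tab, lab)
  expect_equal(unname(pct["sA"]), 0.1)
  expect_equal(unname(pct["sB"]), 100 * 100 / 105)

  all_cont <- percent_contaminants(tab, label_ground_truth(tab, character(0)))
  expect_equal(unname(all_cont), c(100, 100))
  zero <- asv_table(matrix(c(1L, 0L), nrow = 1,
                           dimnames = list("m", c("ok", "void"))))
  expect_true(is.na(percent_contaminants(zero, c(m = "mock"))["void"]))
})

test_that("confusion counts and accuracy follow the definitions", {
  ids <- c(sprintf("c%d", 1:8), "m1", "m2")
  tab <- asv_table(matrix(1L, 10, 1, dimnames = list(ids, "s")))
  lab <- label_ground_truth(tab, c("m1", "m2"))
  rf <- matrix(1, 10, 1, dimnames = dimnames(tab))
  rf[1:6, 1] <- 0  # remove 6 of the 8 contaminants
  res <- removal_result("toy", list(), rf)
  conf <- confusion_and_accuracy(res, lab, tab)
  expect_identical(conf$tp, 6L); expect_identical(conf$fn, 2L)
  expect_identical(conf$tn, 2L); expect_identical(conf$fp, 0L)
  expect_equal(conf$accuracy, 0.8)

  perfect <- removal_result("perfect", list(),
                            matrix(as.numeric(lab == "mock"), 10, 1,
                                   dimnames = dimnames(tab)))
  expect_equal(confusion_and_accuracy(perfect, lab, tab)$accuracy, 1)

  # a sample of only mock ASVs, nothing removed: accuracy 1
  mock_tab <- asv_table(matrix(1L, 2, 1, dimnames = list(c("m1", "m2"), "s")))
  keep_all <- removal_result("none", list(),
                             matrix(1, 2, 1, dimnames = dimnames(mock_tab)))
  conf2 <- confusion_and_accuracy(keep_all, label_ground_truth(mock_tab, c("m1", "m2")),
                                  mock_tab)
  expect_equal(conf2$accuracy, 1)
  expect_true(is.na(conf2$pct_contaminant_correct))
})

test_that("accuracy equals a brute-force recount on random fixtures", {
  set.seed(13)
  for (rep in 1:15) {
    tab <- random_asv_table(n_asv = 10, n_sample = 3)
    tab[1, ] <- tab[1, ] + 1L
    tab <- asv_table(tab)
    ref <- sample(rownames(tab), 3)
    lab <- label_ground_truth(tab, ref)
    rf <- matrix(sample(c(0, 1), length(tab), replace = TRUE),
                 nrow = nrow(tab), dimnames = dimnames(tab))
    res <- removal_result("rand", list(), rf)
    conf <- confusion_and_accuracy(res, lab, tab)
    for (j in seq_len(ncol(tab))) {
      sid <- colnames(tab)[j]
      correct <- 0; total <- 0
      for (i in seq_len(nrow(tab))) {
        if (tab[i, j] == 0) next
        total <- total + 1
        is_cont <- lab[i] == "contaminant"
        removed <- rf[i, j] == 0
        if (is_cont == removed) correct <- correct + 1
      }
      expect_equal(conf$accuracy[conf$sample_id == sid], correct / total)
    }
  }
})

test_that("a present ASV without a call is an error", {
  tab <- asv_table(matrix(c(1L, 1L), 2, 1, dimnames = list(c("a", "b"), "s")))
  rf <- matrix(1, 1, 1, dimnames = list("a", "s"))
  res <- removal_result("partial", list(), rf)
  expect_error(confusion_and_accuracy(res, c(a = "mock", b = "mock"), tab),
               "no call")
})

test_that("alpha diversity matches its closed forms", {
  expect_identical(alpha_diversity(rep(5, 4), "observed"), 4L)
  expect_equal(alpha_diversity(rep(5, 4), "shannon"), log(4))
  expect_equal(alpha_diversity(rep(5, 4), "inv_simpson"), 4)

  v <- c(0.5, 0.25, 0.25)
  expect_equal(alpha_diversity(v, "shannon"), 1.039721, tolerance = 1e-6)
  expect_equal(alpha_diversity(v, "inv_simpson"), 2.666667, tolerance = 1e-6)

  expect_identical(alpha_diversity(c(0, 7, 0), "observed"), 1L)
  expect_equal(alpha_diversity(c(0, 7, 0), "shannon"), 0)
  expect_equal(alpha_diversity(c(0, 7, 0), "inv_simpson"), 1)
  expect_error(alpha_diversity(c(0, 0), "shannon"), "all-zero")
})

test_that("alpha diversity obeys formula and ordering invariants", {
  set.seed(17)
  for (rep in 1:200) {
    v <- stats::rpois(sample(2:20, 1), lambda = sample(1:50, 1))
    if (sum(v) == 0) v[1] <- 1
    p <- v[v > 0] / sum(v)
    obs <- alpha_diversity(v, "observed")
    sh <- alpha_diversity(v, "shannon")
    inv <- alpha_diversity(v, "inv_simpson")
    expect_equal(sh, -sum(p * log(p)), tolerance = 1e-10)
    expect_equal(inv, 1 / sum(p^2), tolerance = 1e-10)
    expect_lte(inv, obs + 1e-9)
    expect_lte(sh, log(obs) + 1e-9)
  }
})

test_that("expected alpha diversity ignores contaminant counts", {
  tab <- asv_table(matrix(c(10L, 10L, 10L, 0L,
                            10L, 10L, 10L, 500L), nrow = 4,
                          dimnames = list(c("m1", "m2", "m3", "c1"),
                                          c("clean", "dirty"))))
  ref <- c("m1", "m2", "m3")
  for (metric in c("observed", "shannon", "inv_simpson")) {
    ea <- expected_alpha(tab, ref, metric)
    expect_equal(unname(ea["clean"]), unname(ea["dirty"]))
    expect_equal(unname(ea["clean"]),
                 as.numeric(alpha_diversity(rep(10, 3), metric)))
  }
  none <- asv_table(matrix(c(0L, 9L), nrow = 2,
                           dimnames = list(c("m1", "c1"), "s")))
  expect_true(is.na(expected_alpha(none, "m1", "observed")["s"]))
})

test_that("composition recovery measures L1 distortion", {
  truth <- stats::setNames(rep(0.2, 5), sprintf("m%d", 1:5))
  perfect <- asv_table(matrix(rep(20L, 5), ncol = 1,
                              dimnames = list(names(truth), "s")))
  lab <- label_ground_truth(perfect, names(truth))
  rec <- composition_recovery(perfect, truth, lab)
  expect_equal(unname(rec$l1_error["s"]), 0)

  # removing one expected ASV carrying share 0.2 distorts the rest
  dropped <- asv_table(matrix(rep(20L, 4), ncol = 1,
                              dimnames = list(sprintf("m%d", 1:4), "s")))
  rec2 <- composition_recovery(dropped, truth,
                               label_ground_truth(dropped, names(truth)))
  expect_equal(unname(rec2$l1_error["s"]), 0.4)

  # a 50% contaminated sample against an even truth has L1 error 1
  half <- asv_table(matrix(c(rep(10L, 5), 50L), ncol = 1,
                           dimnames = list(c(names(truth), "cont"), "s")))
  rec3 <- composition_recovery(half, truth,
                               label_ground_truth(half, names(truth)))
  expect_equal(unname(rec3$l1_error["s"]), 1)
  expect_error(composition_recovery(
    asv_table(matrix(0L, 1, 1, dimnames = list("m1", "s"))), truth,
    c(m1 = "mock")), "zero reads")
})
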