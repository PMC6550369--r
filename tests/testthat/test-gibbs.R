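# Correctness of the collapsed Gibbs source-attribution sampler against
# symmetry arguments and the exhaustive-enumeration oracle.

smoothed_lik <- function(sources, alpha_known = 0.001) {
  tau <- length(sources$asv_ids)
  vapply(sources$profiles, function(m) {
    (m + alpha_known) / (sum(m) + alpha_known * tau)
  }, numeric(tau))
}

test_that("a single known source without unknown receives everything", {
  src <- source_set(list(only = c(t1 = 50, t2 = 50)), include_unknown = FALSE)
  at <- gibbs_source_attribution(c(t1 = 3L, t2 = 1L), src, seed = 1)
  expect_equal(unname(at$proportions), 1)
  expect_equal(sum(at$proportions), 1, tolerance = 1e-9)
})

test_that("proportions and per-ASV attributions are normalised", {
  set.seed(5)
  src <- source_set(list(a = c(t1 = 90, t2 = 10, t3 = 5),
                         b = c(t1 = 5, t2 = 80, t3 = 40)))
  sink <- c(t1 = 20L, t2 = 10L, t3 = 0L)
  at <- gibbs_source_attribution(sink, src, seed = 2)
  expect_equal(sum(at$proportions), 1, tolerance = 1e-9)
  rows <- at$attribution[sink > 0, ]
  expect_true(all(abs(rowSums(rows) - 1) < 1e-9))
  expect_true(all(is.na(at$attribution["t3", ])))
})

test_that("symmetric sources and sink give equal proportions", {
  src <- source_set(list(a = c(t1 = 100, t2 = 100),
                         b = c(t1 = 100, t2 = 100)),
                    include_unknown = FALSE)
  sink <- c(t1 = 30L, t2 = 30L)
  at <- gibbs_source_attribution(sink, src, seed = 3,
                                 hyperparams = list(n_restarts = 20L,
                                                    n_draws = 200L,
                                                    draw_spacing = 2L))
  expect_lt(abs(unname(at$proportions[1]) - unname(at$proportions[2])), 0.02)
})

test_that("tiny sinks match exhaustive enumeration (two strong sources)", {
  # three reads of one taxon; P(t|source1) ~ 0.9, P(t|source2) ~ 0.1
  probs <- cbind(s1 = c(t1 = 0.9, t2 = 0.1), s2 = c(t1 = 0.1, t2 = 0.9))
  src <- source_set_from_probs(probs, include_unknown = FALSE)
  lik <- smoothed_lik(src)
  oracle <- oracle_enum_proportions(c(1L, 1L, 1L), lik,
                                    include_unknown = FALSE,
                                    alpha_unknown = 0.1, beta = 1)
  at <- gibbs_source_attribution(
    c(t1 = 3L, t2 = 0L), src, seed = 4,
    hyperparams = list(beta = 1, n_restarts = 40L, n_draws = 200L,
                       draw_spacing = 2L))
  expect_lt(max(abs(unname(at$proportions) - unname(oracle))), 0.02)
})

test_that("tiny sinks match enumeration across a grid of cases", {
  probs2 <- cbind(s1 = c(t1 = 0.7, t2 = 0.2, t3 = 0.1),
                  s2 = c(t1 = 0.1, t2 = 0.3, t3 = 0.6))
  grid_hyper <- list(alpha_unknown = 0.1, beta = 2,
                     n_restarts = 40L, n_burnin = 50L,
                     n_draws = 200L, draw_spacing = 2L)
  cases <- list(
    list(reads = c(1L), unknown = FALSE, k = 1),
    list(reads = c(1L, 2L), unknown = TRUE, k = 1),
    list(reads = c(1L, 1L, 3L), unknown = FALSE, k = 2),
    list(reads = c(2L, 3L), unknown = TRUE, k = 2),
    list(reads = c(1L, 2L, 3L, 3L), unknown = TRUE, k = 2),
    list(reads = c(1L, 1L, 2L, 2L), unknown = FALSE, k = 2)
  )
  for (case in cases) {
    probs <- probs2[, seq_len(case$k), drop = FALSE]
    src <- source_set_from_probs(probs, include_unknown = case$unknown)
    lik <- smoothed_lik(src)
    oracle <- oracle_enum_proportions(case$reads, lik, case$unknown,
                                      alpha_unknown = 0.1, beta = 2)
    sink <- stats::setNames(tabulate(case$reads, 3L), c("t1", "t2", "t3"))
    at <- gibbs_source_attribution(sink, src,
                                   hyperparams = grid_hyper,
                                   seed = 100 + case$k)
    expect_lt(max(abs(unname(at$proportions) - unname(oracle))), 0.02,
              label = paste("max attribution error, reads",
                            paste(case$reads, collapse = ",")))
  }
})

test_that("a sink drawn from one source is attributed to it", {
  set.seed(6)
  profile <- stats::rgamma(50, 0.5); profile <- profile / sum(profile)
  names(profile) <- sprintf("t%02d", 1:50)
  other <- rev(profile); names(other) <- names(profile)
  src <- source_set(list(origin = round(profile * 1e5),
                         decoy = round(other * 1e5)))
  sink <- stats::setNames(
    as.integer(stats::rmultinom(1, 10000, profile)), names(profile))
  at <- gibbs_source_attribution(sink, src, seed = 7)
  expect_gte(unname(at$proportions["origin"]), 0.9)
})

test_that("sink validation and rarefaction behave as specified", {
  src <- source_set(list(a = c(t1 = 10, t2 = 10)))
  expect_error(gibbs_source_attribution(c(t1 = 0L, t2 = 0L), src), "empty sink")
  expect_error(gibbs_source_attribution(
    c(t1 = 3L, t2 = 1L), src,
    hyperparams = list(rarefaction_depth = 10L)), "rarefaction_depth")
  at <- gibbs_source_attribution(c(t1 = 30L, t2 = 10L), src, seed = 8,
                                 hyperparams = list(rarefaction_depth = 20L))
  expect_identical(at$diagnostics$n_reads, 20L)
  expect_error(gibbs_source_attribution(
    c(t1 = 1L), src, hyperparams = list(bogus = 1)), "unknown hyperparameter")
})
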