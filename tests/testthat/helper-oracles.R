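# Independent oracles and small fixture builders used across the suite.

# Least-squares oracle for the frequency classifier: fits the two
# fixed-slope models by QR decomposition (lm with an offset) instead of the
# closed-form means used by the implementation.
oracle_frequency_score <- function(x, y) {
  n <- length(x)
  ss1 <- sum(stats::resid(stats::lm(y ~ 1, offset = -x))^2)
  ss0 <- sum(stats::resid(stats::lm(y ~ 1))^2)
  list(ss_contaminant = ss1, ss_noncontaminant = ss0,
       score = stats::pf(ss1 / ss0, n - 1, n - 1))
}

# Exhaustive-enumeration oracle for the collapsed Gibbs sampler: sums the
# exact posterior over all V^N assignment vectors of a small sink.
# read_taxa: 1-based taxon index per read; known_lik: tau x K matrix of
# fixed per-source taxon probabilities.
oracle_enum_proportions <- function(read_taxa, known_lik, include_unknown,
                                    alpha_unknown, beta) {
  N <- length(read_taxa)
  K <- ncol(known_lik)
  tau <- nrow(known_lik)
  V <- K + include_unknown
  U <- K + 1  # unknown index when enabled
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(V)), N)))
  log_w <- apply(grid, 1, function(z) {
    n_v <- tabulate(z, nbins = V)
    lw <- sum(lgamma(beta + n_v) - lgamma(beta))
    for (i in seq_len(N)) {
      if (z[i] <= K) lw <- lw + log(known_lik[read_taxa[i], z[i]])
    }
    if (include_unknown) {
      q_t <- integer(tau); q <- 0
      for (i in seq_len(N)) {
        if (z[i] == U) {
          t <- read_taxa[i]
          lw <- lw + log((q_t[t] + alpha_unknown) / (q + alpha_unknown * tau))
          q_t[t] <- q_t[t] + 1; q <- q + 1
        }
      }
    }
    lw
  })
  w <- exp(log_w - max(log_w))
  w <- w / sum(w)
  props <- vapply(seq_len(V), function(v) {
    sum(w * rowSums(grid == v) / N)
  }, numeric(1))
  names(props) <- c(colnames(known_lik),
                    if (include_unknown) "unknown")
  props
}

# Source set with two known sources whose per-taxon probabilities are
# (approximately) the given matrix, constructed from large counts.
source_set_from_probs <- function(probs, include_unknown = TRUE,
                                  scale = 1e7) {
  profiles <- lapply(seq_len(ncol(probs)), function(j) {
    stats::setNames(round(probs[, j] * scale), rownames(probs))
  })
  names(profiles) <- colnames(probs)
  source_set(profiles, include_unknown = include_unknown)
}

# Random valid ASV table for property tests.
random_asv_table <- function(n_asv = 6, n_sample = 4, max_count = 50) {
  counts <- matrix(sample.int(max_count + 1, n_asv * n_sample,
                              replace = TRUE) - 1L,
                   nrow = n_asv,
                   dimnames = list(sprintf("asv%02d", seq_len(n_asv)),
                                   sprintf("s%02d", seq_len(n_sample))))
  counts
}

# One focal ASV with the requested per-sample frequencies plus a filler
# ASV absorbing the rest of each sample, with matching metadata.
freq_fixture <- function(freqs, conc, total = 1e6) {
  # one focal ASV with the requested per-sample frequencies plus a filler
  # ASV absorbing the rest of each sample
  n <- length(conc)
  counts <- rbind(focal = as.integer(round(freqs * total)),
                  filler = as.integer(total - round(freqs * total)))
  colnames(counts) <- sprintf("S%d", seq_len(n))
  md <- data.frame(sample_id = colnames(counts),
                   dilution_round = seq_len(n) - 1L,
                   dna_concentration = conc,
                   sample_type = "dilution_sample",
                   stringsAsFactors = FALSE)
  list(table = asv_table(counts), metadata = md)
}
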