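# Synthetic mock-community dilution series with known ground truth.
#
# The generator emulates the structure of a serially diluted whole-cell mock
# community sequenced against a constant reagent-contaminant background: the
# mock template is diluted `dilution_factor`-fold per round while the
# contaminant template stays constant per reaction, so the contaminant read
# fraction rises with dilution round d as
#   f_d = C / (C + M0 * dilution_factor^(-d)),
# a two-compartment mixing model. Reads are drawn multinomially from the
# mixture, a small fraction is replaced by barcode cross-talk singletons
# drawn from a disjoint pool, and a negative control is dominated by a
# shared subset of the contaminant pool with a small leak of mock reads.

MOCK_SPECIES <- c("Pseudomonas aeruginosa", "Escherichia coli",
                  "Salmonella enterica", "Lactobacillus fermentum",
                  "Enterococcus faecalis", "Staphylococcus aureus",
                  "Listeria monocytogenes", "Bacillus subtilis")

# Ratio used to split one species slot into its two ASVs (a single-nucleotide
# variant of the same 16S region).
SPLIT_RATIO <- 0.7

#' Configuration for the dilution-series simulator
#'
#' Defaults emulate a 9-ASV mock community (8 species, one represented by two
#' ASVs) diluted 3-fold for 8 rounds, a reagent background skewed enough that
#' a few contaminants exceed 1% relative abundance, mock/contaminant template
#' amounts chosen so contaminants exceed 50% of reads after the 6th round,
#' rare barcode cross-talk, and a negative control receiving about 1.7% of
#' its reads from a subset of mock ASVs.
#'
#' @param n_mock_asvs number of expected mock ASVs (>= 2); one species slot
#'   is split into two ASVs, so there are `n_mock_asvs - 1` species slots.
#' @param mock_profile_concentration Dirichlet concentration controlling
#'   evenness of the species slots; `Inf` gives exactly even slots.
#' @param n_contaminant_asvs size of the reagent-contaminant pool.
#' @param contaminant_profile_shape gamma shape controlling skew of the
#'   contaminant profile; small values give a long tail with dominant taxa;
#'   `Inf` gives a uniform profile.
#' @param n_dilutions number of serial dilution rounds beyond the undiluted
#'   sample (samples D0..D`n_dilutions`).
#' @param dilution_factor fold-dilution per round (> 1).
#' @param mock_template_d0 mock template amount in the undiluted reaction
#'   (arbitrary template units), `M0`.
#' @param contaminant_template contaminant template amount per reaction
#'   (same units), `C`; constant across dilutions.
#' @param reads_per_sample optional explicit integer read-depth schedule of
#'   length `n_dilutions + 1`; when `NULL` a decreasing schedule with
#'   lognormal jitter is drawn from `depth_base`, `depth_decay`,
#'   `depth_jitter_sd`.
#' @param depth_base,depth_decay,depth_jitter_sd parameters of the default
#'   read-depth schedule `round(depth_base * depth_decay^d * exp(N(0, sd)))`.
#' @param reads_negative_control read depth of the negative control.
#' @param crosstalk_rate per-read probability of replacement by a barcode
#'   cross-talk read.
#' @param n_crosstalk_asvs size of the disjoint cross-talk ASV pool.
#' @param negative_control_mock_leak fraction of negative-control reads
#'   drawn from mock ASVs.
#' @param n_mock_in_control number of distinct mock ASVs leaking into the
#'   negative control.
#' @param control_shared_fraction fraction of the contaminant pool present
#'   in the negative control (selected with probability proportional to
#'   contaminant profile mass).
#' @param concentration_gain instrument gain mapping template units to
#'   measured DNA concentration (ng/ul per template unit).
#' @param concentration_noise_sd Gaussian measurement noise (ng/ul).
#' @param concentration_floor instrument baseline; readings never fall below
#'   this value.
#' @param seed integer seed; all randomness derives deterministically from it.
#' @param paper_scale when TRUE, switch to the full-scale preset: 937
#'   contaminant ASVs and read depths in the hundreds of thousands.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_mock_asvs = 9,
                              mock_profile_concentration = 50,
                              n_contaminant_asvs = 200,
                              contaminant_profile_shape = 0.1,
                              n_dilutions = 8,
                              dilution_factor = 3,
                              mock_template_d0 = 1000,
                              contaminant_template = 2,
                              reads_per_sample = NULL,
                              depth_base = 10000,
                              depth_decay = 0.8,
                              depth_jitter_sd = 0.1,
                              reads_negative_control = 2000,
                              crosstalk_rate = 3e-4,
                              n_crosstalk_asvs = 80,
                              negative_control_mock_leak = 0.017,
                              n_mock_in_control = 3,
                              control_shared_fraction = 0.2,
                              concentration_gain = 0.02,
                              concentration_noise_sd = 0.005,
                              concentration_floor = 0.01,
                              seed = 1,
                              paper_scale = FALSE) {
  if (isTRUE(paper_scale)) {
    n_contaminant_asvs <- 937
    depth_base <- 250000
    reads_negative_control <- 100000
    n_crosstalk_asvs <- 675
  }
  n_mock_in_control <- min(n_mock_in_control, n_mock_asvs)
  cfg <- list(
    n_mock_asvs = as.integer(n_mock_asvs),
    mock_profile_concentration = mock_profile_concentration,
    n_contaminant_asvs = as.integer(n_contaminant_asvs),
    contaminant_profile_shape = contaminant_profile_shape,
    n_dilutions = as.integer(n_dilutions),
    dilution_factor = dilution_factor,
    mock_template_d0 = mock_template_d0,
    contaminant_template = contaminant_template,
    reads_per_sample = if (is.null(reads_per_sample)) NULL else as.integer(reads_per_sample),
    depth_base = depth_base,
    depth_decay = depth_decay,
    depth_jitter_sd = depth_jitter_sd,
    reads_negative_control = as.integer(reads_negative_control),
    crosstalk_rate = crosstalk_rate,
    n_crosstalk_asvs = as.integer(n_crosstalk_asvs),
    negative_control_mock_leak = negative_control_mock_leak,
    n_mock_in_control = as.integer(n_mock_in_control),
    control_shared_fraction = control_shared_fraction,
    concentration_gain = concentration_gain,
    concentration_noise_sd = concentration_noise_sd,
    concentration_floor = concentration_floor,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_cfg(cfg$n_mock_asvs >= 2, "n_mock_asvs must be >= 2")
  stopifnot_cfg(cfg$mock_profile_concentration > 0,
                "mock_profile_concentration must be positive")
  stopifnot_cfg(cfg$n_contaminant_asvs >= 1, "n_contaminant_asvs must be >= 1")
  stopifnot_cfg(cfg$contaminant_profile_shape > 0,
                "contaminant_profile_shape must be positive")
  stopifnot_cfg(cfg$n_dilutions >= 1, "n_dilutions must be >= 1")
  stopifnot_cfg(cfg$dilution_factor > 1, "dilution_factor must be > 1")
  stopifnot_cfg(cfg$mock_template_d0 >= 0 && cfg$contaminant_template >= 0,
                "template amounts must be non-negative")
  if (!is.null(cfg$reads_per_sample)) {
    stopifnot_cfg(length(cfg$reads_per_sample) == cfg$n_dilutions + 1,
                  "reads_per_sample must have length n_dilutions + 1")
    stopifnot_cfg(all(cfg$reads_per_sample > 0), "reads_per_sample must be positive")
  } else {
    stopifnot_cfg(cfg$depth_base > 0, "depth_base must be positive")
  }
  stopifnot_cfg(cfg$reads_negative_control > 0,
                "reads_negative_control must be positive")
  stopifnot_cfg(cfg$crosstalk_rate >= 0 && cfg$crosstalk_rate < 1,
                "crosstalk_rate must be in [0, 1)")
  stopifnot_cfg(cfg$negative_control_mock_leak >= 0 &&
                  cfg$negative_control_mock_leak < 1,
                "negative_control_mock_leak must be in [0, 1)")
  stopifnot_cfg(cfg$control_shared_fraction > 0 &&
                  cfg$control_shared_fraction <= 1,
                "control_shared_fraction must be in (0, 1]")
  stopifnot_cfg(cfg$n_mock_in_control >= 0 &&
                  cfg$n_mock_in_control <= cfg$n_mock_asvs,
                "n_mock_in_control must be in [0, n_mock_asvs]")
  stopifnot_cfg(cfg$concentration_gain > 0, "concentration_gain must be positive")
  stopifnot_cfg(cfg$concentration_noise_sd >= 0 && cfg$concentration_floor >= 0,
                "concentration noise/floor must be non-negative")
  invisible(cfg)
}

# Deterministic per-stream seed derivation so that adding a sample or method
# does not perturb the randomness of the others. Lehmer-style mixing kept
# below 2^31.
derive_seed <- function(seed, stream) {
  m <- 2147483563
  x <- abs(as.numeric(seed)) %% m
  s <- abs(as.numeric(stream)) %% m
  for (k in 1:3) x <- (x * 40014 + s * 40692 + k) %% m
  as.integer(x)
}

#' Mock-community ASV profile
#'
#' Draws near-even relative abundances for the species slots from a
#' symmetric Dirichlet, then splits one slot into two ASVs at a fixed
#' uneven ratio (emulating a species represented by two sequence variants).
#' Uses the current RNG state.
#'
#' @param config a [simulation_config()].
#' @return strictly positive probability vector of length `n_mock_asvs`.
#' @export
make_mock_profile <- function(config) {
  n <- config$n_mock_asvs
  n_slots <- n - 1
  conc <- config$mock_profile_concentration
  slots <- if (is.infinite(conc)) {
    rep(1 / n_slots, n_slots)
  } else {
    g <- stats::rgamma(n_slots, shape = conc)
    g <- pmax(g, .Machine$double.xmin)
    g / sum(g)
  }
  split_idx <- min(3L, n_slots)
  # keep species order: insert the split pair at its slot position
  before <- if (split_idx > 1) slots[seq_len(split_idx - 1)] else numeric(0)
  after <- if (split_idx < n_slots) slots[(split_idx + 1):n_slots] else numeric(0)
  profile <- c(before, slots[split_idx] * c(SPLIT_RATIO, 1 - SPLIT_RATIO), after)
  names(profile) <- mock_asv_ids(n)
  profile
}

mock_asv_ids <- function(n) sprintf("mock_%02d", seq_len(n))

mock_taxon_labels <- function(n) {
  n_slots <- n - 1
  split_idx <- min(3L, n_slots)
  species <- rep(MOCK_SPECIES, length.out = n_slots)
  labels <- c(if (split_idx > 1) species[seq_len(split_idx - 1)],
              paste0(species[split_idx], c(" (variant 1)", " (variant 2)")),
              if (split_idx < n_slots) species[(split_idx + 1):n_slots])
  labels
}

#' Reagent-contaminant ASV profile
#'
#' Long-tailed relative abundances drawn as normalised gamma variates
#' (a symmetric Dirichlet with shape < 1 by default), admitting a few
#' dominant contaminants above 1% relative abundance. Uses the current
#' RNG state.
#'
#' @param config a [simulation_config()].
#' @return strictly positive probability vector of length
#'   `n_contaminant_asvs`.
#' @export
make_contaminant_profile <- function(config) {
  n <- config$n_contaminant_asvs
  shape <- config$contaminant_profile_shape
  profile <- if (is.infinite(shape)) {
    rep(1 / n, n)
  } else {
    g <- stats::rgamma(n, shape = shape)
    g <- pmax(g, .Machine$double.xmin)
    g / sum(g)
  }
  names(profile) <- sprintf("cont_%04d", seq_len(n))
  profile
}

#' Analytic contaminant read fraction at dilution round d
#'
#' Two-compartment mixing model: mock template `M0 * dilution_factor^(-d)`
#' against constant contaminant template `C`, giving
#' `f_d = C / (C + M0 * dilution_factor^(-d))`. Strictly increasing in `d`
#' whenever both templates are positive.
#'
#' @param d dilution round (non-negative integer; 0 = undiluted).
#' @param config a [simulation_config()].
#' @return contaminant fraction in \[0, 1\].
#' @export
expected_contaminant_fraction <- function(d, config) {
  if (any(d < 0)) stop("dilution round must be >= 0", call. = FALSE)
  M0 <- config$mock_template_d0
  C <- config$contaminant_template
  if (M0 == 0 && C == 0) {
    stop("contaminant fraction undefined when both templates are zero",
         call. = FALSE)
  }
  C / (C + M0 * config$dilution_factor^(-d))
}

#' Simulate a mock-community dilution-series experiment
#'
#' Generates samples D0..D`n_dilutions` plus one negative control `NC`,
#' together with sample metadata (dilution round, measured DNA
#' concentration, sample role), the expected-ASV reference, and a full
#' ground-truth record. Identical config and seed give a bit-identical
#' result.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_experiment` list with elements `table` (ASV count
#'   matrix), `metadata`, `reference`, and `truth`. `truth` carries the
#'   expected and contaminant ASV sets, the per-contaminant origin
#'   (`reagent` or `crosstalk`), negative-control sharing flags, the mock
#'   and contaminant profiles used, and per-sample analytic read fractions.
#' @export
simulate_dilution_series <- function(config) {
  validate_simulation_config(config)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  # setup stream: profiles, depth schedule, control subsets
  set.seed(derive_seed(config$seed, 0L))
  mock_p <- make_mock_profile(config)
  cont_p <- make_contaminant_profile(config)
  n_samples <- config$n_dilutions + 1L
  depths <- if (!is.null(config$reads_per_sample)) {
    config$reads_per_sample
  } else {
    pmax(1L, as.integer(round(
      config$depth_base * config$depth_decay^(0:config$n_dilutions) *
        exp(stats::rnorm(n_samples, 0, config$depth_jitter_sd)))))
  }
  n_shared <- max(1L, round(config$control_shared_fraction *
                              config$n_contaminant_asvs))
  shared_ids <- if (config$n_contaminant_asvs == 1) {
    names(cont_p)
  } else {
    sample(names(cont_p), n_shared, prob = cont_p)
  }
  leak_ids <- if (config$n_mock_in_control > 0) {
    sample(names(mock_p), config$n_mock_in_control, prob = mock_p)
  } else {
    character(0)
  }

  xt_ids <- if (config$n_crosstalk_asvs > 0) {
    sprintf("xtalk_%04d", seq_len(config$n_crosstalk_asvs))
  } else {
    character(0)
  }
  all_ids <- c(names(mock_p), names(cont_p), xt_ids)
  sample_ids <- c(paste0("D", 0:config$n_dilutions), "NC")
  counts <- matrix(0L, nrow = length(all_ids), ncol = length(sample_ids),
                   dimnames = list(all_ids, sample_ids))
  conc <- numeric(length(sample_ids))

  f_d <- expected_contaminant_fraction(0:config$n_dilutions, config)
  for (i in seq_len(n_samples)) {
    d <- i - 1L
    set.seed(derive_seed(config$seed, i))
    depth <- depths[[i]]
    n_xt <- if (config$crosstalk_rate > 0 && length(xt_ids)) {
      stats::rbinom(1, depth, config$crosstalk_rate)
    } else 0L
    n_main <- depth - n_xt
    p_mix <- c((1 - f_d[[i]]) * mock_p, f_d[[i]] * cont_p)
    main <- as.integer(stats::rmultinom(1, n_main, p_mix))
    counts[seq_along(p_mix), i] <- main
    if (n_xt > 0) {
      xt <- tabulate(sample.int(length(xt_ids), n_xt, replace = TRUE),
                     nbins = length(xt_ids))
      counts[length(p_mix) + seq_along(xt_ids), i] <-
        counts[length(p_mix) + seq_along(xt_ids), i] + as.integer(xt)
    }
    template <- config$mock_template_d0 * config$dilution_factor^(-d) +
      config$contaminant_template
    conc[[i]] <- max(config$concentration_floor,
                     config$concentration_gain * template +
                       stats::rnorm(1, 0, config$concentration_noise_sd))
  }

  # negative control: shared contaminant subset + small mock leak
  i_nc <- length(sample_ids)
  set.seed(derive_seed(config$seed, n_samples + 1L))
  depth_nc <- config$reads_negative_control
  n_leak <- if (length(leak_ids)) {
    stats::rbinom(1, depth_nc, config$negative_control_mock_leak)
  } else 0L
  nc_profile <- cont_p[shared_ids] / sum(cont_p[shared_ids])
  nc_cont <- stats::rmultinom(1, depth_nc - n_leak, nc_profile)
  counts[names(nc_profile), i_nc] <- as.integer(nc_cont)
  if (n_leak > 0) {
    leak_p <- mock_p[leak_ids] / sum(mock_p[leak_ids])
    leak_counts <- stats::rmultinom(1, n_leak, leak_p)
    counts[leak_ids, i_nc] <- as.integer(leak_counts)
  }
  conc[[i_nc]] <- max(config$concentration_floor,
                      config$concentration_gain * config$contaminant_template +
                        stats::rnorm(1, 0, config$concentration_noise_sd))

  metadata <- data.frame(
    sample_id = sample_ids,
    dilution_round = c(0:config$n_dilutions, NA_integer_),
    dna_concentration = conc,
    sample_type = c(rep("dilution_sample", n_samples), "negative_control"),
    stringsAsFactors = FALSE
  )

  contaminant_ids <- c(names(cont_p), xt_ids)
  origin <- stats::setNames(
    c(rep("reagent", length(cont_p)), rep("crosstalk", length(xt_ids))),
    contaminant_ids)
  shared <- stats::setNames(contaminant_ids %in% shared_ids, contaminant_ids)
  mock_frac <- c((1 - f_d) * (1 - config$crosstalk_rate),
                 config$negative_control_mock_leak)
  truth <- list(
    expected_asv_ids = names(mock_p),
    contaminant_asv_ids = contaminant_ids,
    origin = origin,
    shared_with_control = shared,
    mock_profile = mock_p,
    contaminant_profile = cont_p,
    control_mock_asv_ids = leak_ids,
    sample_fractions = data.frame(
      sample_id = sample_ids,
      true_mock_fraction = mock_frac,
      contaminant_fraction = 1 - mock_frac,
      stringsAsFactors = FALSE
    )
  )
  reference <- data.frame(asv_id = names(mock_p),
                          taxon_label = mock_taxon_labels(config$n_mock_asvs),
                          stringsAsFactors = FALSE)

  structure(list(table = asv_table(counts), metadata = metadata,
                 reference = reference, truth = truth, config = config),
            class = "simulated_experiment")
}

#' Write a simulated experiment to disk
#'
#' Emits `table.tsv`, `metadata.tsv`, `reference.tsv`, and
#' `ground_truth.tsv` (asv_id, class, origin, shared_with_control) into
#' `dir`.
#'
#' @param experiment a `simulated_experiment` from
#'   [simulate_dilution_series()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("table.tsv", "metadata.tsv", "reference.tsv",
                            "ground_truth.tsv"))
  write_asv_table(experiment$table, paths[[1]])
  write_metadata(experiment$metadata, paths[[2]])
  write_reference(experiment$reference, paths[[3]])
  tr <- experiment$truth
  gt <- data.frame(
    asv_id = c(tr$expected_asv_ids, tr$contaminant_asv_ids),
    class = c(rep("mock", length(tr$expected_asv_ids)),
              rep("contaminant", length(tr$contaminant_asv_ids))),
    origin = c(rep("mock", length(tr$expected_asv_ids)),
               unname(tr$origin[tr$contaminant_asv_ids])),
    shared_with_control = c(tr$expected_asv_ids %in% tr$control_mock_asv_ids,
                            unname(tr$shared_with_control[tr$contaminant_asv_ids])),
    stringsAsFactors = FALSE
  )
  utils::write.table(gt, paths[[4]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
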