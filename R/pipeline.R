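# End-to-end orchestration: simulate -> apply every method of the
# parameter grid -> evaluate, writing flat TSV artifacts plus a JSON
# manifest. Identical config + seed give byte-identical outputs (the
# manifest's wall-clock stamp aside).

#' The benchmark's default method grid
#'
#' One negative-control filter; abundance thresholds 0.01%, 0.1%, 1%;
#' frequency classification thresholds 0.1 through 0.5; source attribution
#' in both scenarios (defined / undefined experimental source), each with
#' two source cases.
#'
#' @return list of method specifications consumed by [run_all()].
#' @export
default_method_grid <- function() {
  c(list(list(name = "negctrl")),
    lapply(c(1e-4, 1e-3, 1e-2), function(thr) {
      list(name = "abundance", threshold = thr)
    }),
    lapply(seq(0.1, 0.5, by = 0.1), function(p) {
      list(name = "frequency", p_star = p)
    }),
    unlist(lapply(1:2, function(sc) lapply(1:2, function(ca) {
      list(name = "sourcetracker", scenario = sc, case = ca)
    })), recursive = FALSE))
}

#' Short label for a method specification
#' @param spec a method spec (see [default_method_grid()]).
#' @return character label such as `"frequency_p05"`.
#' @export
method_label <- function(spec) {
  switch(spec$name,
         negctrl = "negctrl",
         abundance = sprintf("abundance_%g", spec$threshold),
         frequency = sprintf("frequency_p%02.0f", 100 * spec$p_star),
         sourcetracker = sprintf("sourcetracker_s%d_c%d", spec$scenario,
                                 spec$case),
         stop("unknown method '", spec$name, "'", call. = FALSE))
}

validate_method_spec <- function(spec) {
  if (is.null(spec$name)) stop("method spec without a name", call. = FALSE)
  switch(spec$name,
         negctrl = invisible(),
         abundance = {
           if (is.null(spec$threshold) || spec$threshold <= 0 ||
               spec$threshold >= 1) {
             stop("abundance method needs a threshold in (0, 1)", call. = FALSE)
           }
         },
         frequency = {
           if (is.null(spec$p_star) || spec$p_star <= 0 || spec$p_star > 1) {
             stop("frequency method needs p_star in (0, 1]", call. = FALSE)
           }
         },
         sourcetracker = {
           if (is.null(spec$scenario) || !spec$scenario %in% 1:2 ||
               is.null(spec$case) || !spec$case %in% 1:2) {
             stop("sourcetracker method needs scenario and case in {1, 2}",
                  call. = FALSE)
           }
         },
         stop("unknown method '", spec$name, "'", call. = FALSE))
  invisible(spec)
}

#' Configuration of one full benchmark run
#'
#' @param simulation a [simulation_config()].
#' @param methods list of method specs (see [default_method_grid()]).
#' @param output_dir directory for all artifacts.
#' @param seed master seed; the simulation seed and every method's RNG
#'   stream derive from it.
#' @param sourcetracker_hyperparams overrides for
#'   [sourcetracker_defaults()].
#' @param verbose log stage progress to standard error.
#' @return a validated `run_config` list.
#' @export
run_config <- function(simulation = NULL, methods = default_method_grid(),
                       output_dir = "results", seed = 1,
                       sourcetracker_hyperparams = list(), verbose = FALSE) {
  if (is.null(simulation)) simulation <- simulation_config(seed = seed)
  for (spec in methods) validate_method_spec(spec)
  structure(list(simulation = simulation, methods = methods,
                 output_dir = output_dir, seed = as.integer(seed),
                 sourcetracker_hyperparams = sourcetracker_hyperparams,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Apply one method specification to an experiment
#'
#' Dispatches a method spec from the grid to the corresponding removal
#' method, using the experiment's table, metadata, and reference; methods
#' are applied to the non-control samples, with RNG streams derived from
#' the run seed.
#'
#' @param spec a method spec (see [default_method_grid()]).
#' @param experiment list with `table`, `metadata`, `reference` (a
#'   `simulated_experiment` works).
#' @param config a [run_config()].
#' @return a [removal_result()].
#' @export
apply_method <- function(spec, experiment, config) {
  tab <- experiment$table
  md <- experiment$metadata
  control_ids <- md$sample_id[md$sample_type == "negative_control"]
  dilution <- tab[, setdiff(colnames(tab), control_ids), drop = FALSE]
  switch(spec$name,
    negctrl = filter_by_negative_control(tab, control_ids),
    abundance = filter_by_abundance(dilution, spec$threshold),
    frequency = {
      fit <- decontam_frequency_scores(tab, md)
      decontam_classify(fit, spec$p_star, dilution)
    },
    sourcetracker = {
      sources <- build_source_set(tab, experiment$reference, control_ids,
                                  scenario = spec$scenario, case = spec$case)
      attr <- sourcetracker_attribution(
        tab, sources, sink_sample_ids = colnames(dilution),
        hyperparams = config$sourcetracker_hyperparams,
        seed = derive_seed(config$seed, 1000L + spec$scenario * 10L + spec$case))
      sourcetracker_correct(
        tab, attr,
        scenario = if (spec$scenario == 1) "defined_experimental_source"
                   else "undefined_experimental_source",
        experimental_source_name = if (spec$scenario == 1) "mock")
    })
}

#' Write a removal result as a calls TSV
#'
#' One row per (ASV, sample): identifiers, the binary call, the retained
#' fraction, and the per-ASV score where the method has one. Inverse of
#' [read_calls()].
#'
#' @param result a [removal_result()].
#' @param path destination path.
#' @export
write_calls <- function(result, path) {
  rf <- result$retained_fraction
  score <- result$score
  df <- data.frame(
    asv_id = rep(rownames(rf), ncol(rf)),
    sample_id = rep(colnames(rf), each = nrow(rf)),
    call = as.vector(result$call),
    retained_fraction = formatC(as.vector(rf), digits = 6, format = "g"),
    score = if (is.null(score)) "" else
      formatC(rep(unname(score[rownames(rf)]), ncol(rf)), digits = 6,
              format = "g"),
    stringsAsFactors = FALSE
  )
  df$score[df$score == "NA"] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_stage <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
}

#' Run the full benchmark
#'
#' Simulates the dilution-series experiment, applies every method of the
#' grid, evaluates all of them, and writes: the experiment files
#' (`table.tsv`, `metadata.tsv`, `reference.tsv`, `ground_truth.tsv`), one
#' `calls_<method>.tsv` per method, the reports `confusion.tsv`,
#' `diversity.tsv`, `recovery.tsv`, the per-sample `summary.tsv` (reads,
#' unique ASVs, percent contaminants), and `manifest.json` (config
#' snapshot, file checksums, package version, wall-clock stamp).
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest as a list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage(config$verbose, "simulating experiment (seed ", config$seed, ")")
  experiment <- simulate_dilution_series(config$simulation)
  paths <- as.character(write_experiment(experiment, config$output_dir))

  tab <- experiment$table
  md <- experiment$metadata
  control_ids <- md$sample_id[md$sample_type == "negative_control"]
  dilution <- tab[, setdiff(colnames(tab), control_ids), drop = FALSE]
  labels <- label_ground_truth(tab, experiment$reference)

  confusion <- list()
  diversity <- list()
  recovery <- list()

  # uncorrected + expected baselines
  div0 <- alpha_diversity_table(dilution)
  div0$method <- "uncorrected"
  expd <- data.frame(sample_id = colnames(dilution),
                     observed = expected_alpha(dilution, experiment$reference,
                                               "observed"),
                     shannon = expected_alpha(dilution, experiment$reference,
                                              "shannon"),
                     inv_simpson = expected_alpha(dilution,
                                                  experiment$reference,
                                                  "inv_simpson"),
                     method = "expected", stringsAsFactors = FALSE)
  diversity <- list(div0, expd)
  none <- removal_result("uncorrected", list(),
                         matrix(1, nrow(dilution), ncol(dilution),
                                dimnames = dimnames(dilution)))
  confusion[["uncorrected"]] <- confusion_and_accuracy(none, labels, dilution)

  for (spec in config$methods) {
    lab <- method_label(spec)
    log_stage(config$verbose, "applying method ", lab)
    res <- apply_method(spec, experiment, config)
    p <- file.path(config$output_dir, paste0("calls_", lab, ".tsv"))
    write_calls(res, p)
    paths <- c(paths, p)
    res$method_name <- lab
    confusion[[lab]] <- confusion_and_accuracy(res, labels, dilution)
    corr <- corrected_counts(dilution, res)
    ok <- colSums(corr) > 0
    if (any(ok)) {
      dv <- alpha_diversity_table(asv_table(corr[, ok, drop = FALSE]))
      dv$method <- lab
      diversity[[lab]] <- dv
      rec <- composition_recovery(asv_table(corr[, ok, drop = FALSE]),
                                  experiment$truth$mock_profile, labels)
      recovery[[lab]] <- data.frame(method = lab,
                                    sample_id = names(rec$l1_error),
                                    l1_error = unname(rec$l1_error),
                                    stringsAsFactors = FALSE)
    }
  }

  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
    df
  }
  report <- function(df, name) {
    p <- file.path(config$output_dir, name)
    utils::write.table(fmt(df), p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  uncorr_rec <- composition_recovery(dilution, experiment$truth$mock_profile,
                                     labels)
  recovery[["uncorrected"]] <- data.frame(
    method = "uncorrected", sample_id = names(uncorr_rec$l1_error),
    l1_error = unname(uncorr_rec$l1_error), stringsAsFactors = FALSE)

  paths <- c(paths,
             report(do.call(rbind, confusion), "confusion.tsv"),
             report(do.call(rbind, diversity), "diversity.tsv"),
             report(do.call(rbind, recovery), "recovery.tsv"),
             report(data.frame(
               sample_id = colnames(tab),
               reads = colSums(tab),
               unique_asvs = colSums(tab > 0),
               pct_contaminants = percent_contaminants(tab, labels),
               stringsAsFactors = FALSE), "summary.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("contamSeries")),
    seed = config$seed,
    simulation = unclass(config$simulation),
    methods = vapply(config$methods, method_label, character(1)),
    files = data.frame(path = basename(paths),
                       md5 = unname(tools::md5sum(paths)),
                       stringsAsFactors = FALSE),
    wall_clock = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  log_stage(config$verbose, "wrote ", length(paths) + 1, " artifacts to ",
            config$output_dir)
  invisible(manifest)
}

#' Read a calls TSV back into a removal result
#'
#' Inverse of the calls files written by [run_all()]: reconstructs the
#' retained-fraction and call matrices (and per-ASV scores where present)
#' so written results can be re-evaluated without re-running the method.
#'
#' @param path path to a `calls_<method>.tsv` file.
#' @param method_name method label; defaults to the file name.
#' @return a [removal_result()].
#' @export
read_calls <- function(path, method_name = NULL) {
  if (is.null(method_name)) {
    method_name <- sub("^calls_", "", sub("\\.tsv$", "", basename(path)))
  }
  df <- utils::read.delim(path, colClasses = c(
    asv_id = "character", sample_id = "character", call = "character",
    retained_fraction = "numeric", score = "numeric"))
  asvs <- unique(df$asv_id)
  samples <- unique(df$sample_id)
  idx <- cbind(match(df$asv_id, asvs), match(df$sample_id, samples))
  rf <- matrix(NA_real_, length(asvs), length(samples),
               dimnames = list(asvs, samples))
  cl <- matrix(NA_character_, length(asvs), length(samples),
               dimnames = list(asvs, samples))
  rf[idx] <- df$retained_fraction
  cl[idx] <- df$call
  if (anyNA(rf) || anyNA(cl)) {
    stop("calls file does not cover the full ASV x sample grid: ", path,
         call. = FALSE)
  }
  score <- NULL
  if (any(!is.na(df$score))) {
    first <- df[!duplicated(df$asv_id), ]
    score <- stats::setNames(first$score, first$asv_id)[asvs]
  }
  removal_result(method_name, list(), rf, call = cl, score = score,
                 unscored = if (!is.null(score)) asvs[is.na(score)] else character(0))
}
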