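# Formats, configuration and the end-to-end pipeline runner:
# simulate -> preprocess -> detect -> fit -> summarise.

coerceNumericCol <- function(x, col) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "" & x != "NA")
  if (length(bad))
    stop("malformed numeric value in column '", col, "' at row ", bad[1],
         ": '", x[bad[1]], "'")
  out
}

#' Read a measurement table
#'
#' Reads a tab-separated measurement table in either the canonical schema
#' (see [simulateMeasurements()]) or the MaxQuant evidence dialect. For the
#' evidence dialect a design table mapping raw files to replicate, time and
#' label orientation is required; the modification state is inferred from
#' the modified-sequence string (`(ph)` marks phosphorylation, protein
#' N-terminal `(ac)` marks N-terminal acetylation). Unknown columns are
#' preserved.
#'
#' @param path TSV file with a header.
#' @param format `"canonical"` or `"maxquant"`.
#' @param design for `"maxquant"`: data.frame with columns `raw_file`,
#'   `replicate`, `time_h`, `label_orientation`.
#' @return a schema-validated `MeasurementTable` data.frame.
#' @export
readMeasurements <- function(path, format = c("canonical", "maxquant"),
                             design = NULL) {
  format <- match.arg(format)
  raw <- read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (format == "maxquant") {
    needed <- c("Modified sequence", "Proteins", "Intensity L",
                "Intensity H", "PEP", "Raw file")
    missing <- setdiff(needed, names(raw))
    if (length(missing))
      stop("evidence file is missing required column(s): ",
           paste(missing, collapse = ", "))
    if (is.null(design))
      stop("the MaxQuant dialect needs a design table (raw_file -> ",
           "replicate, time_h, label_orientation)")
    idx <- match(raw[["Raw file"]], design$raw_file)
    if (anyNA(idx))
      stop("design table has no entry for raw file(s): ",
           paste(unique(raw[["Raw file"]][is.na(idx)]), collapse = ", "))
    seqs <- raw[["Modified sequence"]]
    mod_type <- rep("none", nrow(raw))
    mod_type[grepl("(ph)", seqs, fixed = TRUE)] <- "phospho"
    mod_type[grepl("^_?\\(ac\\)", seqs)] <- "nterm_ac"
    raw2 <- data.frame(
      protein_id = raw[["Proteins"]],
      peptide_id = seqs,
      mod_type = mod_type,
      site_positions = if ("Site positions" %in% names(raw))
        raw[["Site positions"]] else "",
      replicate = design$replicate[idx],
      label_orientation = design$label_orientation[idx],
      time_h = raw[["Raw file"]],  # replaced below
      intensity_light = raw[["Intensity L"]],
      intensity_heavy = raw[["Intensity H"]],
      id_score = raw[["PEP"]],
      stringsAsFactors = FALSE, check.names = FALSE)
    raw2$time_h <- design$time_h[idx]
    extra <- setdiff(names(raw), needed)
    raw <- cbind(raw2, raw[, extra, drop = FALSE])
  }
  checkMeasurementSchema(raw)
  for (col in c("time_h", "intensity_light", "intensity_heavy", "id_score"))
    raw[[col]] <- coerceNumericCol(raw[[col]], col)
  raw
}

#' Write a pipeline table as TSV
#'
#' Tab-separated, UTF-8, '.' decimal separator; no quoting, no row names.
#'
#' @param x data.frame.
#' @param path output file.
#' @export
writeTSV <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the generator settings, thresholds and per-stage seeds of a full
#' run. Every stochastic stage carries an explicit seed so runs are exactly
#' reproducible.
#'
#' @param sim a [simConfig()] (used when no `input` path is given).
#' @param input optional path to a canonical measurement TSV; when set, the
#'   simulation stage is skipped.
#' @param long_lived_fraction fraction of proteins used for cell-cycle
#'   estimation (default 0.01).
#' @param n_sd reproducibility-filter cutoff in SDs (default 2).
#' @param alpha BH-adjusted significance threshold (default 0.001).
#' @param n_permutations permutations per comparison for the null.
#' @param n_starts optimisation starts per site fit.
#' @param sd_cutoff relative-SD cutoff for high-confidence fits.
#' @param max_fit_sites cap on the number of sites fitted per run
#'   (default 60, which keeps a default-sized run within a few minutes on
#'   one CPU; set `Inf` to fit every collated site).
#' @param seeds named list of integer seeds for the `sim`, `null` and `fit`
#'   stages.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(sim = simConfig(), input = NULL,
                           long_lived_fraction = 0.01, n_sd = 2,
                           alpha = 0.001, n_permutations = 10,
                           n_starts = 20, sd_cutoff = 0.5,
                           max_fit_sites = 60,
                           seeds = list(sim = 1, null = 2, fit = 3)) {
  stopifnot(all(c("sim", "null", "fit") %in% names(seeds)))
  cfg <- list(sim = sim, input = input,
              long_lived_fraction = long_lived_fraction, n_sd = n_sd,
              alpha = alpha, n_permutations = n_permutations,
              n_starts = n_starts, sd_cutoff = sd_cutoff,
              max_fit_sites = max_fit_sites, seeds = seeds)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' The file round-trips losslessly through [pipelineConfig()].
#'
#' @param path YAML file.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$replicates))
    sim_args$replicates <- as.data.frame(
      lapply(sim_args$replicates, unlist), stringsAsFactors = FALSE)
  if (!is.null(sim_args$rates))
    sim_args$rates <- lapply(sim_args$rates, function(r)
      c(meanlog = r$meanlog, sdlog = r$sdlog))
  for (nm in c("peptides_per_protein", "times", "intensity"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  sim <- do.call(simConfig, sim_args)
  args <- y[setdiff(names(y), "sim")]
  if (!is.null(args$max_fit_sites) && args$max_fit_sites < 0)
    args$max_fit_sites <- Inf
  do.call(pipelineConfig, c(list(sim = sim), args))
}

#' @rdname readPipelineConfig
#' @param config a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  y$sim$replicates <- as.list(y$sim$replicates)
  y$sim$rates <- lapply(y$sim$rates, function(r)
    list(meanlog = unname(r[["meanlog"]]), sdlog = unname(r[["sdlog"]])))
  if (is.infinite(y$max_fit_sites)) y$max_fit_sites <- -1
  yaml::write_yaml(y, path)
  invisible(path)
}

logLine <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Simulate (or read) measurements, filter, estimate growth, correct, apply
#' the reproducibility filter, run the calibrated comparative test, collate
#' sites, fit the simplified two-species model, and summarise fitted groups
#' when exactly two modification kinds are present. All outputs are TSV
#' files in `out_dir`; a run log records the configuration, seeds and the
#' row counts of every stage. Deterministic given the configured seeds.
#'
#' @param config a `PipelineConfig`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory artifacts: `traces`,
#'   `results`, `fits`, `summary`, `reports`.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("# pipeline run", con)
  writeLines(yaml::as.yaml(list(
    seeds = config$seeds, alpha = config$alpha,
    n_permutations = config$n_permutations, n_starts = config$n_starts,
    long_lived_fraction = config$long_lived_fraction, n_sd = config$n_sd)),
    con)

  if (is.null(config$input)) {
    truth <- sampleProteome(config$sim, seed = config$seeds$sim)
    meas <- simulateMeasurements(truth, config$sim,
                                 seed = config$seeds$sim + 1L)
    writeGroundTruthTSV(truth, file.path(out_dir, "truth.tsv"))
    writeTSV(meas, file.path(out_dir, "measurements.tsv"))
    logLine(con, "simulated ", nrow(meas), " measurement rows for ",
            config$sim$n_proteins, " proteins")
  } else {
    meas <- readMeasurements(config$input)
    logLine(con, "read ", nrow(meas), " measurement rows from ",
            config$input)
  }

  filt <- filterMeasurements(meas)
  writeTSV(filt$report, file.path(out_dir, "filter_report.tsv"))
  logLine(con, "filtered to ", nrow(filt$table), " rows (removed: ",
          paste(filt$report$rule, filt$report$removed, collapse = ", "), ")")

  growth <- estimateCellCycle(filt$table,
                              long_lived_fraction = config$long_lived_fraction)
  writeTSV(growth, file.path(out_dir, "growth_estimate.tsv"))
  logLine(con, "estimated doubling times: ",
          paste(sprintf("rep%s=%.1fh", growth$replicate, growth$t_cc),
                collapse = ", "))

  traces <- correctGrowth(filt$table, growth)
  rf <- reproducibilityFilter(traces, n_sd = config$n_sd)
  traces <- rf$traces
  writeTSV(rf$report, file.path(out_dir, "reproducibility_report.tsv"))
  writeTSV(traces, file.path(out_dir, "traces.tsv"))
  logLine(con, "reproducibility filter removed ",
          paste(sprintf("%s: %.2f%%", rf$report$fraction,
                        rf$report$pct_removed), collapse = ", "))

  det <- testClearance(traces, alpha = config$alpha,
                       n_permutations = config$n_permutations,
                       seed = config$seeds$null)
  if (!is.null(det$results)) {
    writeTSV(det$results, file.path(out_dir, "results.tsv"))
    writeTSV(as.data.frame(det$calibration),
             file.path(out_dir, "calibration.tsv"))
    writeTSV(det$skipped, file.path(out_dir, "skipped_comparisons.tsv"))
    logLine(con, "tested ", nrow(det$results), " peptides; ",
            sum(det$results$significant), " hits (",
            sum(det$results$class == "faster"), " faster, ",
            sum(det$results$class == "slower"), " slower)")
  } else {
    logLine(con, "no testable comparisons")
  }

  pairing <- collateSites(traces)
  writeTSV(pairing, file.path(out_dir, "sites.tsv"))
  fits <- NULL; summary_tab <- NULL
  if (nrow(pairing)) {
    if (is.finite(config$max_fit_sites) &&
        nrow(pairing) > config$max_fit_sites)
      pairing_fit <- pairing[seq_len(config$max_fit_sites), , drop = FALSE]
    else pairing_fit <- pairing
    asm <- assembleObservables(traces, pairing_fit, growth = growth)
    fits <- fitAllSites(asm, n_starts = config$n_starts,
                        seed = config$seeds$fit,
                        exclude_time = max(traces$time_h),
                        sd_cutoff = config$sd_cutoff)
    if (!is.null(fits)) {
      writeTSV(fits, file.path(out_dir, "fits.tsv"))
      logLine(con, "fitted ", nrow(fits), " sites (",
              sum(fits$high_confidence), " high confidence)")
      summary_tab <- tryCatch(summarizeFits(fits), error = function(e) NULL)
      if (!is.null(summary_tab))
        writeTSV(summary_tab, file.path(out_dir, "fit_summary.tsv"))
    }
  }
  logLine(con, "pipeline complete")
  invisible(list(traces = traces, results = det$results, fits = fits,
                 summary = summary_tab,
                 reports = list(filter = filt$report,
                                reproducibility = rf$report,
                                growth = growth)))
}
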