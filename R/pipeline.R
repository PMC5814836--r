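# End-to-end orchestration: config handling, the SIP calling pipeline
# and report generation.

#' Assemble (or load) a pipeline run configuration
#'
#' Thresholds default to the standard SIP calling parameters: FDR 0.1,
#' log2 fold change 0.25, sparsity filters of 10 total reads / 20%
#' prevalence, and a minimum mean normalised count of 1.25 for a
#' confirmed call.
#'
#' @param path optional YAML or JSON file whose fields override the
#'   defaults.
#' @param ... named overrides applied after the file.
#' @return list of class `sip_run_config`.
#' @export
sip_run_config <- function(path = NULL, ...) {
  cfg <- list(mode = "within-gradient", alpha = 0.1, lfc_threshold = 0.25,
              min_total = 10, min_prevalence = 0.20, min_base_mean = 1.25,
              hump_smooth = 3, hump_prominence = 2,
              windows = "RNA", seed = 1L, counts_path = NULL,
              output_dir = NULL, write_plots = FALSE)
  if (!is.null(path)) {
    loaded <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    cfg[names(loaded)] <- loaded
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$lfc_threshold >= 0,
            cfg$min_total >= 0, cfg$min_prevalence >= 0,
            cfg$min_prevalence <= 1, cfg$min_base_mean >= 0)
  class(cfg) <- "sip_run_config"
  cfg
}

# Hash of the analysis-relevant configuration (output location excluded,
# so runs into different directories still produce identical files).
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(utils::str(cfg)),
                   collapse = "\n"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full SIP enrichment-calling pipeline
#'
#' Reads (or accepts) a fraction count table, fits [sip_enrichment()]
#' under the configured thresholds, checks the control gradients for
#' spurious calls, and writes per-gradient results TSVs, a consolidated
#' calls TSV and a machine-readable JSON report (all stamped with the
#' seed and a hash of the configuration, so identical configs give
#' byte-identical outputs).
#'
#' @param config a [sip_run_config()].
#' @param experiment optional `sip_experiment` (otherwise read from
#'   `config$counts_path`).
#' @return a list of class `sip_run` with `fit`, `report` and `paths`.
#' @export
run_sip_pipeline <- function(config, experiment = NULL) {
  stopifnot(inherits(config, "sip_run_config"))
  if (is.null(experiment)) {
    if (is.null(config$counts_path))
      stop("either an experiment or config$counts_path is required")
    experiment <- read_sip_experiment(config$counts_path)
  }
  windows <- if (inherits(config$windows, "density_windows")) config$windows
             else if (identical(config$windows, "DNA")) dna_windows()
             else rna_windows()
  fit <- sip_enrichment(experiment, windows = windows, mode = config$mode,
                        alpha = config$alpha,
                        lfc_threshold = config$lfc_threshold,
                        min_total = config$min_total,
                        min_prevalence = config$min_prevalence,
                        min_base_mean = config$min_base_mean,
                        hump_smooth = config$hump_smooth,
                        hump_prominence = config$hump_prominence)
  control_results <- Filter(function(r) r$label_status[1] == "14N-control",
                            fit$results)
  control_calls <- sum(vapply(control_results,
                              function(r) sum(r$confirmed), 0L))
  report <- generate_report(fit, config = config,
                            control_call_count = control_calls)
  paths <- character()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# config_hash: %s seed: %s", report$config_hash,
                     config$seed)
    for (id in names(fit$results)) {
      p <- file.path(config$output_dir, paste0("results_", id, ".tsv"))
      writeLines(stamp, p)
      suppressWarnings(utils::write.table(fit$results[[id]], p, sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          append = TRUE))
      paths <- c(paths, p)
    }
    cp <- file.path(config$output_dir, "confirmed_calls.tsv")
    writeLines(stamp, cp)
    suppressWarnings(utils::write.table(report$calls, cp, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    rp <- file.path(config$output_dir, "report.json")
    jsonlite::write_json(report[setdiff(names(report), "calls")], rp,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    paths <- c(paths, cp, rp)
    if (isTRUE(config$write_plots) && length(confirmed_otus(fit))) {
      pp <- file.path(config$output_dir, "density_profiles.pdf")
      grDevices::pdf(pp, width = 9, height = 4)
      plot(fit)
      grDevices::dev.off()
      paths <- c(paths, pp)
    }
  }
  structure(list(fit = fit, report = report, paths = paths,
                 config = config),
            class = "sip_run")
}

#' Percentage retained, rounded to the nearest integer percent
#'
#' @param retained,total non-negative integers.
#' @return integer percentage.
#' @export
#' @examples
#' retained_percent(367425, 561195)  # 65
retained_percent <- function(retained, total) {
  stopifnot(total > 0, retained >= 0, retained <= total)
  as.integer(round(100 * retained / total))
}

#' Percentage of OTUs shared between two sample sets
#'
#' By inclusion-exclusion from the three printed totals: shared =
#' n_a + n_b - n_union, expressed as a percentage of the union and
#' rounded to the nearest integer.
#'
#' @param n_union OTUs in the union of the two sets.
#' @param n_a,n_b OTUs in each set.
#' @return integer percentage.
#' @export
#' @examples
#' shared_otu_percent(2668, 2469, 2410)  # 83
shared_otu_percent <- function(n_union, n_a, n_b) {
  shared <- n_a + n_b - n_union
  stopifnot(shared >= 0, n_union > 0)
  as.integer(round(100 * shared / n_union))
}

#' Build the run report for a fitted SIP model
#'
#' Accounts for reads and OTUs (totals, retained after the sparsity
#' filter, integer percentages), summarises per-gradient calls, the
#' consolidated confirmed set and the control-gradient negative check
#' (expected 0 calls).
#'
#' @param fit a `sip_fit`.
#' @param config optional `sip_run_config` (hashed into the report).
#' @param control_call_count confirmed calls seen in control gradients.
#' @param taxonomy optional data frame (`otu_id`, `phylum`) merged into
#'   the call table.
#' @return list of class `sip_report`.
#' @export
generate_report <- function(fit, config = NULL, control_call_count = NULL,
                            taxonomy = NULL) {
  stopifnot(inherits(fit, "sip_fit"))
  fr <- fit$filter_report
  total_reads <- sum(fr$total)
  retained_reads <- sum(fr$total[!fr$removed])
  labelled_results <- Filter(function(r) r$label_status[1] == "15N",
                             fit$results)
  cons <- consolidate_calls(if (length(labelled_results)) labelled_results
                            else fit$results,
                            fit$min_base_mean, taxonomy = taxonomy)
  if (is.null(control_call_count)) {
    ctrl <- Filter(function(r) r$label_status[1] == "14N-control",
                   fit$results)
    control_call_count <- sum(vapply(ctrl, function(r) sum(r$confirmed), 0L))
  }
  calls <- cons$summary
  if (!is.null(taxonomy))
    calls <- merge(calls, taxonomy, by = "otu_id", all.x = TRUE)
  report <- list(
    otus_total = nrow(fr),
    otus_retained = sum(!fr$removed),
    otus_retained_percent = retained_percent(sum(!fr$removed), nrow(fr)),
    reads_total = total_reads,
    reads_retained = retained_reads,
    reads_retained_percent = retained_percent(retained_reads, total_reads),
    per_gradient = lapply(fit$results, function(r)
      list(label_status = r$label_status[1],
           model_enriched = sum(r$model_enriched),
           confirmed = sum(r$confirmed))),
    confirmed_otus = cons$confirmed,
    n_confirmed = length(cons$confirmed),
    control_confirmed_calls = control_call_count,
    mode = fit$mode, alpha = fit$alpha,
    lfc_threshold = fit$lfc_threshold,
    fold_enrichment_equivalent = round(2^fit$lfc_threshold, 2),
    seed = if (!is.null(config)) config$seed else NA,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    calls = calls)
  class(report) <- c("sip_report", "list")
  report
}

#' @export
print.sip_report <- function(x, ...) {
  cat("SIP run report\n")
  cat(sprintf("  OTUs: %.0f/%.0f retained (%d%%)\n", x$otus_retained,
              x$otus_total, x$otus_retained_percent))
  cat(sprintf("  reads: %.0f/%.0f retained (%d%%)\n", x$reads_retained,
              x$reads_total, x$reads_retained_percent))
  cat(sprintf("  confirmed labelled OTUs: %d%s\n", x$n_confirmed,
              if (x$n_confirmed) paste0(" (", paste(x$confirmed_otus,
                                                    collapse = ", "), ")")
              else " (zero calls)"))
  cat(sprintf("  control-gradient confirmed calls: %d (expected 0)\n",
              x$control_confirmed_calls))
  invisible(x)
}
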