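#' Write / read a gaze trace as delimited text
#'
#' Traces are stored as tab-separated text with columns `time_ms`, `x_deg`,
#' `y_deg` and a commented header carrying the sampling rate and
#' identifiers. Values round-trip to within 1e-9. On reading, a missing
#' column or a non-monotone/non-uniform time grid is rejected with a
#' diagnostic naming the offending content.
#'
#' @param trace A [gaze_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `gaze_trace`.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sampling_rate: %.10g", attr(trace, "sampling_rate")),
    sprintf("# subject: %s", attr(trace, "subject")),
    sprintf("# trial: %s", attr(trace, "trial"))
  ), con)
  utils::write.table(format(as.data.frame(trace), digits = 15,
                            trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 10)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(name) {
    m <- grep(sprintf("^# %s:", name), hdr, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    trimws(sub(sprintf("^# %s:", name), "", m[1]))
  }
  fs <- suppressWarnings(as.numeric(get_field("sampling_rate")))
  if (is.na(fs))
    stop("trace file lacks a '# sampling_rate:' header: ", path,
         call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("time_ms", "x_deg", "y_deg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trace file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad) > 0)
    stop("non-monotone time column at data row(s): ",
         paste(utils::head(bad + 1, 5), collapse = ", "), call. = FALSE)
  trial_raw <- get_field("trial")
  gaze_trace(df$time_ms, df$x_deg, df$y_deg, sampling_rate = fs,
             subject = get_field("subject"),
             trial = suppressWarnings(as.integer(trial_raw)))
}

#' Write / read delimited record tables
#'
#' Latency records, trial events and feature tables are stored as plain
#' tab-separated text with a header row.
#'
#' @param x A `data.frame`.
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns a `data.frame`.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# strip sl_test / nested classes down to plain lists for JSON
report_to_list <- function(x) {
  if (inherits(x, "sl_test"))
    return(list(name = x$name, statistic = x$statistic, df = x$df,
                p = x$p, tails = x$tails, effect = x$effect))
  if (inherits(x, "classification_result"))
    x <- unclass(x)
  if (is.list(x) && !is.data.frame(x))
    return(lapply(x, report_to_list))
  x
}

#' Write a statistics or classification report as JSON
#'
#' @param report An `sl_report` from [analyze_cohort()], a
#'   `classification_result`, or any nested list of results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

# stable hash of a configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  drop_fn <- rapply(config, function(x) x, how = "list",
                    classes = c("numeric", "integer", "character",
                                "logical", "data.frame"))
  jsonlite::write_json(drop_fn, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end pipeline
#'
#' Simulate -> preprocess -> detect -> latency extraction -> group
#' statistics -> Monte Carlo SVM classification, writing all outputs to
#' `out_dir`: `latencies.tsv`, `qc.tsv`, `stats.json`,
#' `classification.json` and `provenance.json` (configuration hash, seed,
#' package version, per-stage counts). Outputs are bitwise reproducible
#' for a fixed config and seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param detection A [detection_config()].
#' @param schemes Character vector of classification scheme ids to run.
#' @param iterations Monte Carlo iterations per scheme.
#' @param seed Seed for the whole run (overrides `config$seed`).
#' @param use_truth_latencies If `TRUE`, skip trace synthesis/detection and
#'   run the statistics on ground-truth latencies (fast path).
#'
#' @return A list with `latencies`, `summaries`, `stats`,
#'   `classification`, `qc`, `provenance`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         detection = detection_config(),
                         schemes = c("P_vs_C", "P_vs_RC", "PR_vs_C"),
                         iterations = 1000, seed = NULL,
                         use_truth_latencies = FALSE) {
  seed <- if (!is.null(seed)) seed else config$seed
  cohort <- simulate_cohort(config, traces = !use_truth_latencies,
                            seed = seed)
  records <- if (use_truth_latencies) truth_latency_records(cohort)
  else extract_latencies(cohort, cfg = detection)
  qc <- qc_summary(records)
  summaries <- task_means(records, events = cohort$events)
  report <- analyze_cohort(summaries)
  features <- build_features(summaries)
  classification <- lapply(schemes, function(s)
    monte_carlo_svm(features, sampling_scheme(s),
                    iterations = iterations,
                    seed = if (is.null(seed)) NULL else
                      seed + match(s, schemes)))
  names(classification) <- schemes
  provenance <- list(
    package_version = as.character(utils::packageVersion("sacmod")),
    config_hash = config_hash(config),
    seed = seed,
    stages = list(
      simulate = list(subjects = nrow(cohort$subjects),
                      trials = nrow(cohort$events)),
      detect = list(records = nrow(records),
                    valid = sum(records$valid)),
      stats = list(subjects_summarized = nrow(summaries)),
      classify = list(schemes = schemes, iterations = iterations)
    )
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_tsv(records, file.path(out_dir, "latencies.tsv"))
    write_table_tsv(qc, file.path(out_dir, "qc.tsv"))
    write_report(report, file.path(out_dir, "stats.json"))
    write_report(classification, file.path(out_dir,
                                           "classification.json"))
    write_report(provenance, file.path(out_dir, "provenance.json"))
  }
  list(latencies = records, summaries = summaries, stats = report,
       classification = classification, qc = qc, provenance = provenance)
}
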