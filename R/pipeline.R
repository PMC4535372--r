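# File-to-file driver: dataset directory in, report bundle out. All
# randomness lives in the simulator; assessment is fully deterministic, so
# re-running on the same inputs reproduces the bundle byte for byte
# (timestamps live only in run.json).

#' Run the full completeness-assessment pipeline on a dataset directory
#'
#' Reads (or accepts) a dataset, runs [assess_emr()], and writes the report
#' bundle: `rates.csv` (per-physician final-year and physician-year rates),
#' `summaries.csv` (stratified means with CIs), `benchmarks.csv`,
#' `below_benchmark.csv`, `histogram.csv`, and `run.json` capturing the
#' options, package version, and every exclusion count (units dropped at
#' any stage are conserved into the log).
#'
#' @param dataset an [emr_dataset()] or a path readable by
#'   [read_emr_dataset()].
#' @param out_dir output directory (created if absent).
#' @param ... options forwarded to [assess_emr()].
#' @param bin_width histogram bin width for `histogram.csv`.
#' @return the `emr_assessment`, invisibly.
#' @export
run_pipeline <- function(dataset, out_dir, ..., bin_width = 0.05) {
  if (is.character(dataset)) dataset <- read_emr_dataset(dataset)
  stopifnot(inherits(dataset, "emr_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)

  a <- assess_emr(dataset, ...)

  rates <- a$final_year_rates
  rates$stratum_type <- "final_year"
  rates$stratum <- NA_character_
  if (!is.null(a$physician_year_rates)) {
    pyr <- a$physician_year_rates
    pyr$stratum_type <- "physician_year"
    rates <- rbind(rates, pyr[, names(rates)])
  }
  write_run_csv <- function(df, name) {
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  write_run_csv(rates, "rates.csv")
  write_run_csv(a$summaries, "summaries.csv")

  bm <- do.call(rbind, lapply(a$benchmarks, function(b)
    data.frame(field = b$field, rule_kind = b$rule_kind, sd_kind = b$sd_kind,
               threshold = b$threshold, n = b$n_physicians,
               n_below = length(b$below),
               proportion_meeting = b$proportion_meeting,
               stringsAsFactors = FALSE)))
  write_run_csv(bm, "benchmarks.csv")

  below <- do.call(rbind, lapply(a$benchmarks, function(b) {
    if (!length(b$below)) return(NULL)
    r <- a$final_year_rates
    r <- r[r$field == b$field & r$physician_id %in% b$below, ]
    data.frame(field = b$field, physician_id = r$physician_id,
               rate = r$rate, threshold = b$threshold,
               stringsAsFactors = FALSE)
  }))
  if (is.null(below))
    below <- data.frame(field = character(0), physician_id = character(0),
                        rate = numeric(0), threshold = numeric(0))
  write_run_csv(below, "below_benchmark.csv")

  hist_df <- do.call(rbind, lapply(names(a$benchmarks), function(f) {
    r <- a$final_year_rates
    h <- rate_histogram(r$rate[r$field == f & !is.na(r$rate)], bin_width)
    cbind(data.frame(field = f, stringsAsFactors = FALSE), h)
  }))
  if (is.null(hist_df))
    hist_df <- data.frame(field = character(0), bin_start = numeric(0),
                          bin_end = numeric(0), count = integer(0))
  write_run_csv(hist_df, "histogram.csv")

  run_meta <- list(
    package = "emrqual",
    version = as.character(utils::packageVersion("emrqual")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    extraction_date = format(dataset$extraction_date, "%Y-%m-%d"),
    n_physicians = nrow(dataset$physicians),
    n_patients = nrow(dataset$patients),
    options = a$options,
    exclusions = as.list(a$exclusions))
  jsonlite::write_json(run_meta, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(a)
}

#' Write a simulated dataset and its ground truth to disk
#'
#' Convenience wrapper pairing [simulate_emr()] with [write_emr_dataset()];
#' the ground truth goes to `ground_truth.json` beside the tables.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @return the simulation result, invisibly.
#' @export
simulate_to_dir <- function(config, out_dir) {
  sim <- simulate_emr(config)
  write_emr_dataset(sim$dataset, out_dir)
  gt <- sim$ground_truth
  gt$physicians$initiation_date <- format(gt$physicians$initiation_date, "%Y-%m-%d")
  gt$patients$entry_date <- format(gt$patients$entry_date, "%Y-%m-%d")
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(sim)
}
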