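#' Assess EMR documentation completeness for a whole dataset
#'
#' The package's main entry point. Detects each physician's EMR initiation
#' date, computes per-physician per-field completeness rates, stratifies
#' them by physician time on EMR and/or patient time on EMR with 95%
#' confidence intervals, computes each physician's final-year rates (the
#' year before extraction), and applies the benchmark rules to those
#' final-year distributions.
#'
#' @param dataset an [emr_dataset()].
#' @param fields fields to assess (default all fourteen; see
#'   [emr_fields()]).
#' @param modes any of `"physician_time"`, `"patient_time"`.
#' @param variant visit-documentation numerator variant: `"per_patient"`
#'   (canonical) or `"per_visit"`.
#' @param initiation_mode `"single_day"` (default) or `"cumulative"`, see
#'   [detect_initiation_date()].
#' @param min_pairs initiation-date pair threshold (default 10).
#' @param sd_kind standard-deviation flavour for the mean-minus-sd
#'   benchmark (`"sample"` or `"population"`).
#' @param weighted weight physicians by denominator size when aggregating
#'   (default `FALSE`: physician is the unit of analysis).
#' @return an object of class `emr_assessment` with components
#'   `initiation_dates`, `summaries` (stacked stratum summaries),
#'   `final_year_rates` (per physician x field in the last year before
#'   extraction), `benchmarks` (list of [compute_benchmark()] results on
#'   the final-year rates), `exclusions`, and the call options.
#' @seealso [run_pipeline()] for the file-to-file driver.
#' @export
assess_emr <- function(dataset, fields = emr_fields(),
                       modes = c("physician_time", "patient_time"),
                       variant = c("per_patient", "per_visit"),
                       initiation_mode = c("single_day", "cumulative"),
                       min_pairs = 10,
                       sd_kind = c("sample", "population"),
                       weighted = FALSE) {
  stopifnot(inherits(dataset, "emr_dataset"))
  check_fields(fields)
  modes <- match.arg(modes, several.ok = TRUE)
  variant <- match.arg(variant)
  initiation_mode <- match.arg(initiation_mode)
  sd_kind <- match.arg(sd_kind)

  inits <- all_initiation_dates(dataset, min_pairs, initiation_mode)
  exclusions <- c(attr(dataset, "exclusions"),
                  physicians_without_initiation = sum(is.na(inits)))

  summaries <- empty_summary_frame()
  rates <- NULL
  if ("physician_time" %in% modes) {
    pt <- physician_time_analysis(dataset, fields, min_pairs = min_pairs,
                                  variant = variant, weighted = weighted)
    summaries <- rbind(summaries, pt)
    rates <- attr(pt, "rates")
  }
  if ("patient_time" %in% modes) {
    tt <- patient_time_analysis(dataset, fields, variant = variant,
                                weighted = weighted)
    summaries <- rbind(summaries, tt)
    exclusions <- c(exclusions, attr(tt, "exclusions"))
  }

  # Final-year cross-section: every physician's rates in the year before
  # extraction; the distributions the benchmarks are drawn on.
  final_window <- c(add_anniversary_years(dataset$extraction_date, -1L),
                    dataset$extraction_date)
  final_rates <- do.call(rbind, lapply(dataset$physicians$physician_id,
    function(p) do.call(rbind, lapply(fields, function(f)
      field_completeness(p, f, final_window, dataset, variant = variant)))))
  n_undef <- sum(is.na(final_rates$rate))
  exclusions <- c(exclusions, undefined_final_year_rates = n_undef)

  benchmarks <- lapply(fields, function(f) {
    r <- final_rates[final_rates$field == f & !is.na(final_rates$rate), ]
    if (nrow(r) < if (benchmark_rule_for(f) == "mean_minus_sd") 2L else 1L)
      return(NULL)
    compute_benchmark(f, stats::setNames(r$rate, r$physician_id),
                      sd_kind = sd_kind)
  })
  names(benchmarks) <- fields
  benchmarks <- Filter(Negate(is.null), benchmarks)

  structure(list(
    initiation_dates = inits,
    summaries = summaries,
    physician_year_rates = rates,
    final_year_rates = final_rates,
    final_window = final_window,
    benchmarks = benchmarks,
    exclusions = exclusions,
    options = list(fields = fields, modes = modes, variant = variant,
                   initiation_mode = initiation_mode, min_pairs = min_pairs,
                   sd_kind = sd_kind, weighted = weighted),
    extraction_date = dataset$extraction_date,
    n_physicians = nrow(dataset$physicians),
    n_patients = nrow(dataset$patients)),
    class = "emr_assessment")
}

#' @export
print.emr_assessment <- function(x, ...) {
  cat("<emr_assessment>", x$n_physicians, "physicians,", x$n_patients,
      "patients; extracted", format(x$extraction_date), "\n")
  cat("  fields:", length(x$options$fields),
      "| modes:", paste(x$options$modes, collapse = ", "),
      "| visit documentation:", x$options$variant, "\n")
  vd <- x$summaries[x$summaries$field == "visit_documentation" &
                      x$summaries$stratum_type == "physician_year", ]
  if (nrow(vd)) {
    f1 <- vd[vd$stratum == "1", ]; fl <- vd[nrow(vd), ]
    cat(sprintf("  visit documentation: %.0f%% (year 1) -> %.0f%% (year %s)\n",
                100 * f1$mean, 100 * fl$mean, fl$stratum))
  }
  n_meet <- vapply(x$benchmarks, function(b) b$proportion_meeting, numeric(1))
  if (length(n_meet))
    cat(sprintf("  benchmarks (final year): %d fields, median %.0f%% of physicians meeting\n",
                length(n_meet), 100 * stats::median(n_meet)))
  if (any(x$exclusions > 0))
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
              collapse = " "), "\n")
  invisible(x)
}

#' Summarise an EMR completeness assessment
#'
#' @param object an `emr_assessment`.
#' @param ... unused.
#' @return invisibly, a list with the stratum-summary table and a
#'   benchmark table (field, rule, threshold, n, n_below,
#'   proportion_meeting); both are printed.
#' @export
summary.emr_assessment <- function(object, ...) {
  bm <- do.call(rbind, lapply(object$benchmarks, function(b)
    data.frame(field = b$field, rule_kind = b$rule_kind,
               threshold = b$threshold, n = b$n_physicians,
               n_below = length(b$below),
               proportion_meeting = b$proportion_meeting,
               stringsAsFactors = FALSE)))
  rownames(bm) <- NULL
  cat("Stratified completeness (mean rate across physicians, 95% CI):\n")
  print(object$summaries, row.names = FALSE, digits = 3)
  cat("\nBenchmarks on final-year physician rates:\n")
  print(bm, row.names = FALSE, digits = 3)
  invisible(list(summaries = object$summaries, benchmarks = bm))
}

#' Plot physician rate distributions with benchmark thresholds
#'
#' Draws, for each requested field, the final-year frequency distribution
#' of physician rates (via [rate_histogram()]) with the benchmark
#' threshold as a vertical line — the graphical form in which benchmarks
#' are read.
#'
#' @param x an `emr_assessment`.
#' @param fields fields to plot (default: all benchmarked fields).
#' @param bin_width histogram bin width (default 0.05).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, `x`.
#' @export
plot.emr_assessment <- function(x, fields = names(x$benchmarks),
                                bin_width = 0.05, ...) {
  fields <- intersect(fields, names(x$benchmarks))
  if (!length(fields)) stop("no benchmarked fields to plot", call. = FALSE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(fields)))
  on.exit(graphics::par(old))
  for (f in fields) {
    r <- x$final_year_rates
    r <- r$rate[r$field == f & !is.na(r$rate)]
    h <- rate_histogram(r, bin_width)
    b <- x$benchmarks[[f]]
    mid <- graphics::barplot(h$count, names.arg = sprintf("%.2f", h$bin_start),
                             main = f, xlab = "completeness rate",
                             ylab = "physicians", las = 2, ...)
    # threshold position interpolated onto the bar axis
    pos <- mid[1] + (b$threshold / bin_width) * (mid[2] - mid[1])
    graphics::abline(v = pos, lty = 2, col = "red3")
  }
  invisible(x)
}
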