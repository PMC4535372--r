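# Benchmark rules and physician frequency distributions. Practice-style
# independent fields get fixed thresholds (95% for the two patient-safety
# critical fields, 80% for the rest); practice-style dependent fields get a
# data-driven mean minus one standard deviation threshold that flags only
# low outliers, since a low-but-typical rate there may just be clinical
# style, not poor EMR use.

#' Benchmark rule for an EMR field
#'
#' `visit_documentation` and `cpp_allergies` (the most patient-safety
#' critical) carry a fixed 95% benchmark; the remaining practice-style
#' independent fields (blood pressure, weight, the other CPP categories)
#' carry a fixed 80% benchmark; the four practice-style dependent fields
#' (labs, prescriptions, referrals, consult letters) use the data-driven
#' mean minus one standard deviation rule.
#'
#' @param field one of [emr_fields()].
#' @return one of `"fixed_95"`, `"fixed_80"`, `"mean_minus_sd"`.
#' @export
benchmark_rule_for <- function(field) {
  check_fields(field)
  if (field %in% c("visit_documentation", "cpp_allergies")) return("fixed_95")
  if (field %in% c("lab_test", "prescription", "referral", "consult_letter"))
    return("mean_minus_sd")
  "fixed_80"
}

#' Apply a benchmark rule to a vector of physician rates
#'
#' Computes the threshold (fixed, or `max(0, mean - sd)` over the supplied
#' rates) and flags physicians strictly below it; a physician exactly at a
#' benchmark meets it. The rate vector should come from a single stratum
#' (the distributions are cross-sectional), and `NA` rates must already be
#' removed.
#'
#' @param field one of [emr_fields()].
#' @param rates named numeric vector of defined physician rates (names are
#'   physician ids).
#' @param rule_kind override the default rule from [benchmark_rule_for()].
#' @param sd_kind `"sample"` (n-1 denominator, default) or `"population"`
#'   for the mean-minus-sd rule.
#' @return a `benchmark_result` list: `field`, `rule_kind`, `sd_kind`,
#'   `threshold`, `n_physicians`, `below` (ids strictly below),
#'   `proportion_meeting`.
#' @examples
#' compute_benchmark("referral",
#'                   c(a = 0.2, b = 0.8, c = 0.8, d = 0.8))  # threshold 0.35
#' @export
compute_benchmark <- function(field, rates,
                              rule_kind = benchmark_rule_for(field),
                              sd_kind = c("sample", "population")) {
  sd_kind <- match.arg(sd_kind)
  rule_kind <- match.arg(rule_kind, c("fixed_95", "fixed_80", "mean_minus_sd"))
  if (anyNA(rates))
    stop("rates must be defined (drop NA before benchmarking)", call. = FALSE)
  n <- length(rates)
  min_n <- if (rule_kind == "mean_minus_sd") 2L else 1L
  if (n < min_n)
    stop(sprintf("benchmark for field '%s' needs at least %d defined rate(s)",
                 field, min_n), call. = FALSE)
  if (is.null(names(rates))) names(rates) <- as.character(seq_len(n))
  threshold <- switch(rule_kind,
    fixed_95 = 0.95,
    fixed_80 = 0.80,
    mean_minus_sd = {
      s <- stats::sd(rates)
      if (sd_kind == "population") s <- s * sqrt((n - 1) / n)
      max(0, mean(rates) - s)
    })
  below <- names(rates)[rates < threshold]
  structure(list(
    field = field, rule_kind = rule_kind, sd_kind = sd_kind,
    threshold = threshold, n_physicians = n, below = below,
    proportion_meeting = 1 - length(below) / n),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s [%s] threshold %.3f: %d/%d meet (%.1f%%)\n",
              x$field, x$rule_kind, x$threshold,
              x$n_physicians - length(x$below), x$n_physicians,
              100 * x$proportion_meeting))
  if (length(x$below))
    cat("  below:", paste(x$below, collapse = ", "), "\n")
  invisible(x)
}

#' Frequency distribution of physician rates
#'
#' Bins rates into half-open intervals `[0, w), [w, 2w), ..., [1-w, 1]`
#' (top bin closed so a rate of exactly 1 is counted); counts always sum to
#' the number of supplied rates. The machine-readable twin of the
#' physician frequency-distribution graphs on which benchmarks are drawn.
#'
#' @param rates numeric vector of defined rates in `[0, 1]`.
#' @param bin_width bin width; must divide 1 evenly (default 0.05).
#' @return data frame `bin_start`, `bin_end`, `count`.
#' @export
rate_histogram <- function(rates, bin_width = 0.05) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 1 evenly", call. = FALSE)
  nb <- as.integer(round(nb))
  if (anyNA(rates) || (length(rates) && (min(rates) < 0 || max(rates) > 1)))
    stop("rates must be defined proportions in [0, 1]", call. = FALSE)
  idx <- pmin(floor(rates / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)
  data.frame(bin_start = (seq_len(nb) - 1L) * bin_width,
             bin_end = seq_len(nb) * bin_width,
             count = counts)
}
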