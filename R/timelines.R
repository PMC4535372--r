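# Stratification of completeness by physician time on EMR and by patient
# time on EMR, and the cross-physician mean +/- 95% CI aggregation.

TENURE_BINS <- c("<1", "1-2", "2-3", ">3")

#' A physician's k-th anniversary year on the EMR
#'
#' Half-open window `[initiation + (k-1) years, initiation + k years)` by
#' anniversary arithmetic (February 29 rolls forward to March 1), so
#' consecutive windows tile the time since initiation without drift.
#'
#' @param initiation_date the physician's EMR initiation date.
#' @param k 1-based year index.
#' @return length-2 `Date` vector `(start, end)`.
#' @export
physician_year_window <- function(initiation_date, k) {
  stopifnot(k >= 1)
  initiation_date <- as.Date(initiation_date)
  c(add_anniversary_years(initiation_date, k - 1L),
    add_anniversary_years(initiation_date, k))
}

#' Physicians with a full k-th year of EMR data
#'
#' Only physicians whose year-k window closes on or before the extraction
#' date contribute to the year-k stratum; a physician initiated k years
#' minus one day before extraction is not yet eligible. Eligible sets are
#' nested: `eligible(k + 1)` is a subset of `eligible(k)`.
#'
#' @param k 1-based year index.
#' @param dataset an [emr_dataset()].
#' @param initiation_dates named `Date` vector (physician id -> initiation
#'   date), e.g. from [detect_initiation_date()]; computed if omitted.
#'   Physicians with no detectable initiation date are never eligible.
#' @param min_pairs threshold passed to [detect_initiation_date()].
#' @return character vector of eligible physician ids.
#' @export
eligible_physicians <- function(k, dataset, initiation_dates = NULL,
                                min_pairs = 10) {
  if (is.null(initiation_dates))
    initiation_dates <- all_initiation_dates(dataset, min_pairs)
  ends <- add_anniversary_years(initiation_dates, k)
  names(initiation_dates)[!is.na(ends) & ends <= dataset$extraction_date]
}

all_initiation_dates <- function(dataset, min_pairs = 10,
                                 mode = "single_day") {
  ids <- dataset$physicians$physician_id
  out <- as.Date(vapply(ids, function(p)
    as.character(detect_initiation_date(p, dataset, min_pairs, mode)),
    character(1)))
  names(out) <- ids
  out
}

#' Patient tenure bin
#'
#' Patient time on EMR runs from the first documented-visit date to the
#' extraction date and is binned into `<1`, `1-2`, `2-3` and `>3`
#' anniversary years, half-open so the four labels partition: tenure of
#' exactly 2 years falls in `2-3`, exactly 3 years in `>3`.
#'
#' @param patient_id patient to bin.
#' @param dataset an [emr_dataset()].
#' @return one of `"<1"`, `"1-2"`, `"2-3"`, `">3"`, or `NA` when the
#'   patient has no documented visit.
#' @export
assign_tenure_bin <- function(patient_id, dataset) {
  first <- patient_first_emr_date(patient_id, dataset)
  tenure_bin_from_dates(first, dataset$extraction_date)
}

tenure_bin_from_dates <- function(first_dates, extraction_date) {
  cut1 <- add_anniversary_years(extraction_date, -1L)
  cut2 <- add_anniversary_years(extraction_date, -2L)
  cut3 <- add_anniversary_years(extraction_date, -3L)
  out <- rep(NA_character_, length(first_dates))
  ok <- !is.na(first_dates)
  out[ok & first_dates > cut1] <- "<1"
  out[ok & first_dates <= cut1 & first_dates > cut2] <- "1-2"
  out[ok & first_dates <= cut2 & first_dates > cut3] <- "2-3"
  out[ok & first_dates <= cut3] <- ">3"
  out
}

#' Cross-physician mean and 95% confidence interval
#'
#' The physician is the unit of analysis: rates enter unweighted by panel
#' size, and the interval is the normal approximation
#' `mean +/- 1.96 sd / sqrt(n)` on the physician-level rates, clamped to
#' `[0, 1]`. A single rate yields a zero-width interval. `NA` rates
#' (undefined, zero-denominator) must be removed by the caller; passing
#' none at all is an error.
#'
#' @param rates numeric vector of defined physician-level rates.
#' @param weights optional non-negative weights (e.g. panel sizes) for a
#'   panel-weighted variant; default unweighted.
#' @return named numeric `(mean, ci_low, ci_high)`.
#' @export
aggregate_mean_ci <- function(rates, weights = NULL) {
  if (length(rates) == 0L || anyNA(rates))
    stop("aggregate_mean_ci requires at least one defined rate and no NA",
         call. = FALSE)
  n <- length(rates)
  if (is.null(weights)) {
    m <- mean(rates)
    s <- if (n > 1L) stats::sd(rates) else 0
  } else {
    stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
    w <- weights / sum(weights)
    m <- sum(w * rates)
    s <- if (n > 1L) sqrt(sum(w * (rates - m)^2) * n / (n - 1L)) else 0
  }
  half <- 1.96 * s / sqrt(n)
  c(mean = m, ci_low = max(0, m - half), ci_high = min(1, m + half))
}

empty_summary_frame <- function() {
  data.frame(field = character(0), stratum_type = character(0),
             stratum = character(0), n_units = integer(0),
             mean = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
             stringsAsFactors = FALSE)
}

summary_row <- function(field, stratum_type, stratum, n_units, agg) {
  data.frame(field = field, stratum_type = stratum_type, stratum = stratum,
             n_units = n_units, mean = agg[["mean"]], ci_low = agg[["ci_low"]],
             ci_high = agg[["ci_high"]], stringsAsFactors = FALSE)
}

#' Completeness by physician time on EMR
#'
#' For each EMR year k with at least one eligible physician, computes every
#' eligible physician's completeness of each field over their own year-k
#' anniversary window and aggregates across physicians with
#' [aggregate_mean_ci()]. Physicians with no detectable initiation date are
#' dropped and counted in the `exclusions` attribute.
#'
#' @param dataset an [emr_dataset()].
#' @param fields fields to assess (default all fourteen).
#' @param max_years cap on the year index (default: run until no physician
#'   is eligible).
#' @param min_pairs initiation-date threshold.
#' @param variant visit-documentation numerator variant (see
#'   [field_completeness()]).
#' @param weighted aggregate physicians weighted by their denominator size
#'   instead of equally (default `FALSE`).
#' @return data frame of stratum summaries (`field`, `stratum_type =
#'   "physician_year"`, `stratum`, `n_units`, `mean`, `ci_low`, `ci_high`)
#'   with attributes `rates` (the underlying per-physician rates) and
#'   `exclusions`.
#' @export
physician_time_analysis <- function(dataset, fields = emr_fields(),
                                    max_years = NULL, min_pairs = 10,
                                    variant = "per_patient",
                                    weighted = FALSE) {
  check_fields(fields)
  inits <- all_initiation_dates(dataset, min_pairs)
  n_dropped <- sum(is.na(inits))
  inits <- inits[!is.na(inits)]

  out <- list(); rates_acc <- list()
  k <- 1L
  repeat {
    if (!is.null(max_years) && k > max_years) break
    elig <- eligible_physicians(k, dataset, inits)
    if (length(elig) == 0L) break
    rates_k <- do.call(rbind, lapply(elig, function(p) {
      w <- physician_year_window(inits[[p]], k)
      do.call(rbind, lapply(fields, function(f)
        field_completeness(p, f, w, dataset, variant = variant)))
    }))
    rates_k$stratum <- as.character(k)
    rates_acc[[k]] <- rates_k
    for (f in fields) {
      r <- rates_k[rates_k$field == f & !is.na(rates_k$rate), , drop = FALSE]
      if (nrow(r) == 0L) next
      agg <- aggregate_mean_ci(r$rate,
                               weights = if (weighted) r$denominator)
      out[[length(out) + 1L]] <-
        summary_row(f, "physician_year", as.character(k), nrow(r), agg)
    }
    k <- k + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else empty_summary_frame()
  structure(res,
            rates = if (length(rates_acc)) do.call(rbind, rates_acc),
            exclusions = c(physicians_without_initiation = n_dropped))
}

#' Completeness by patient time on EMR
#'
#' Evaluates the final year before extraction. Patients with a documented
#' visit anywhere in the record are binned by tenure; within each bin the
#' event-field denominators are confined to patients active in that final
#' year, while CPP fields are evaluated on all binned rostered patients.
#' Rates are computed per physician within each bin, then aggregated across
#' physicians. Physician-bin cells with a zero denominator are skipped and
#' counted in the `exclusions` attribute.
#'
#' @inheritParams physician_time_analysis
#' @return data frame of stratum summaries (`stratum_type =
#'   "patient_tenure"`, `stratum` one of `<1`, `1-2`, `2-3`, `>3`) with
#'   attribute `exclusions`.
#' @export
patient_time_analysis <- function(dataset, fields = emr_fields(),
                                  variant = "per_patient",
                                  weighted = FALSE) {
  check_fields(fields)
  extraction <- dataset$extraction_date
  window <- c(add_anniversary_years(extraction, -1L), extraction)
  first <- all_first_emr_dates(dataset)
  bins <- tenure_bin_from_dates(first, extraction)
  names(bins) <- names(first)

  ros <- dataset$rosters
  n_unbinned <- sum(is.na(bins[ros$patient_id]))
  n_undefined <- 0L
  out <- list()
  for (bin in TENURE_BINS) {
    in_bin <- names(bins)[!is.na(bins) & bins == bin]
    if (length(in_bin) == 0L) next
    for (f in fields) {
      per_phys <- lapply(dataset$physicians$physician_id, function(p) {
        panel <- ros$patient_id[ros$physician_id == p]
        denom <- intersect(panel, in_bin)
        if (!(f %in% CPP_FIELDS))
          denom <- intersect(denom, active_patients(p, dataset, window))
        if (length(denom) == 0L) return(NULL)
        if (f == "visit_documentation" && variant == "per_visit") {
          nd <- per_visit_documentation(dataset, p, window, denom)
          if (nd[["denominator"]] == 0L) return(NULL)
          return(c(rate = nd[["numerator"]] / nd[["denominator"]],
                   n = nd[["denominator"]]))
        }
        ok <- field_satisfied(dataset, p, f, window, denom)
        c(rate = mean(ok), n = length(denom))
      })
      per_phys <- do.call(rbind, per_phys)
      n_undefined <- n_undefined +
        (nrow(dataset$physicians) - NROW(per_phys))
      if (is.null(per_phys) || nrow(per_phys) == 0L) next
      agg <- aggregate_mean_ci(per_phys[, "rate"],
                               weights = if (weighted) per_phys[, "n"])
      out[[length(out) + 1L]] <-
        summary_row(f, "patient_tenure", bin, nrow(per_phys), agg)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_summary_frame()
  structure(res, exclusions = c(
    rostered_patients_without_first_emr_date = n_unbinned,
    physician_bin_cells_with_zero_denominator = n_undefined))
}
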