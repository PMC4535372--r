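# Core measures: same-day billing/progress-note matching, EMR initiation-date
# detection, active-patient classification, and per-physician per-field
# completeness rates.

#' Match billed office visits to same-day progress notes
#'
#' A documented visit is a distinct (patient, physician, date) triple that
#' carries at least one office-visit billing and at least one progress note
#' on the same calendar day; duplicated event rows collapse. This triple is
#' the atom of "documented care" on which activity, initiation dates and
#' patient tenure are all built.
#'
#' @param billings billing table (only rows with `is_office_visit` count).
#' @param notes progress-note table.
#' @return data frame with columns `patient_id`, `physician_id`, `date`,
#'   one row per documented visit, ordered by physician, patient, date.
#' @export
match_documented_visits <- function(billings, notes) {
  b <- billings[billings$is_office_visit,
                c("patient_id", "physician_id", "service_date")]
  names(b)[3L] <- "date"
  n <- notes[, c("patient_id", "physician_id", "note_date")]
  names(n)[3L] <- "date"
  b <- unique(b)
  n <- unique(n)
  v <- merge(b, n, by = c("patient_id", "physician_id", "date"))
  v <- v[order(v$physician_id, v$patient_id, v$date), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# Documented visits for a dataset, computed once and cached on the object.
dataset_visits <- function(dataset) {
  cache <- attr(dataset, "cache")
  if (is.null(cache)) return(match_documented_visits(dataset$billings, dataset$notes))
  if (is.null(cache$visits))
    cache$visits <- match_documented_visits(dataset$billings, dataset$notes)
  cache$visits
}

check_physician <- function(physician_id, dataset) {
  if (!physician_id %in% dataset$physicians$physician_id)
    stop("unknown physician_id: ", physician_id, call. = FALSE)
  invisible(physician_id)
}

#' Detect a physician's EMR initiation date
#'
#' The operational start of EMR use: the earliest calendar day on which the
#' physician has at least `min_pairs` billed office visits each matched by a
#' same-day progress note. In `"cumulative"` mode the threshold instead
#' applies to the running total of matched pairs up to and including the
#' day, an alternative reading for practices that ramped up gradually.
#'
#' @param physician_id physician to assess.
#' @param dataset an [emr_dataset()].
#' @param min_pairs pair threshold (default 10).
#' @param mode `"single_day"` (default) or `"cumulative"`.
#' @return a `Date`, or `NA` if no day (or cumulative total) reaches the
#'   threshold.
#' @export
detect_initiation_date <- function(physician_id, dataset, min_pairs = 10,
                                   mode = c("single_day", "cumulative")) {
  mode <- match.arg(mode)
  check_physician(physician_id, dataset)
  v <- dataset_visits(dataset)
  v <- v[v$physician_id == physician_id, , drop = FALSE]
  if (nrow(v) == 0L) return(as.Date(NA))
  counts <- table(v$date)
  days <- as.Date(names(counts))
  o <- order(days)
  days <- days[o]
  n <- as.integer(counts)[o]
  hit <- if (mode == "single_day") n >= min_pairs else cumsum(n) >= min_pairs
  if (!any(hit)) return(as.Date(NA))
  days[which(hit)[1L]]
}

#' Active patients of a physician in a window
#'
#' A rostered patient is active in a window when they have at least one
#' documented visit (same-day office billing and note) with that physician
#' dated in the half-open window `[start, end)`. Event-field completeness
#' denominators are restricted to active patients.
#'
#' @param physician_id physician whose panel is assessed.
#' @param dataset an [emr_dataset()].
#' @param window length-2 `Date` vector, half-open `[start, end)`.
#' @return character vector of active patient ids.
#' @export
active_patients <- function(physician_id, dataset, window) {
  check_physician(physician_id, dataset)
  window <- as_window(window[1L], window[2L])
  cache <- attr(dataset, "cache")
  key <- paste0("active|", physician_id, "|", window[1L], "|", window[2L])
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  panel <- dataset$rosters$patient_id[dataset$rosters$physician_id == physician_id]
  v <- dataset_visits(dataset)
  hit <- v$physician_id == physician_id & in_window(v$date, window)
  out <- intersect(panel, v$patient_id[hit])
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' First EMR date of a patient
#'
#' The earliest documented-visit date for the patient (any physician); the
#' anchor from which patient tenure on the EMR is measured.
#'
#' @param patient_id patient to assess.
#' @param dataset an [emr_dataset()].
#' @return a `Date`, or `NA` when the patient has billings but never a
#'   same-day note (or no events at all).
#' @export
patient_first_emr_date <- function(patient_id, dataset) {
  if (!patient_id %in% dataset$patients$patient_id)
    stop("unknown patient_id: ", patient_id, call. = FALSE)
  v <- dataset_visits(dataset)
  d <- v$date[v$patient_id == patient_id]
  if (length(d) == 0L) return(as.Date(NA))
  min(d)
}

# First EMR date for every patient at once (NA where no documented visit).
all_first_emr_dates <- function(dataset) {
  v <- dataset_visits(dataset)
  first <- tapply(as.integer(v$date), v$patient_id, min)
  out <- rep(as.Date(NA), nrow(dataset$patients))
  names(out) <- dataset$patients$patient_id
  hit <- intersect(names(first), names(out))
  out[hit] <- as.Date(as.integer(first[hit]), origin = "1970-01-01")
  out
}

# Which of `patients` satisfy `field` within `window`. For CPP fields the
# window is irrelevant (snapshot at extraction). For visit_documentation the
# per-patient reading is "all in-window office billings with this physician
# have a same-day note" (vacuously true with no billings).
field_satisfied <- function(dataset, physician_id, field, window, patients) {
  if (length(patients) == 0L) return(logical(0))
  has_event <- function(tb, date_col, extra = TRUE) {
    hit <- tb$patient_id %in% patients & extra & in_window(tb[[date_col]], window)
    patients %in% tb$patient_id[hit]
  }
  switch(field,
    visit_documentation = {
      b <- dataset$billings
      sel <- b$is_office_visit & b$physician_id == physician_id &
        b$patient_id %in% patients & in_window(b$service_date, window)
      b <- unique(b[sel, c("patient_id", "service_date")])
      if (nrow(b) == 0L) return(rep(TRUE, length(patients)))
      nt <- unique(dataset$notes[dataset$notes$physician_id == physician_id,
                                 c("patient_id", "note_date")])
      matched <- paste(b$patient_id, b$service_date) %in%
        paste(nt$patient_id, nt$note_date)
      bad <- unique(b$patient_id[!matched])
      !(patients %in% bad)
    },
    blood_pressure = has_event(dataset$measurements, "date",
                               dataset$measurements$kind == "blood_pressure" &
                                 dataset$measurements$structured),
    weight = has_event(dataset$measurements, "date",
                       dataset$measurements$kind == "weight" &
                         dataset$measurements$structured),
    lab_test = has_event(dataset$labs, "date", dataset$labs$structured),
    prescription = has_event(dataset$prescriptions, "date"),
    referral = has_event(dataset$referrals, "date"),
    consult_letter = has_event(dataset$consults, "date"),
    {
      # CPP snapshot fields
      col <- sub("^cpp_", "", field)
      cpp <- dataset$cpp
      val <- if (col == "medical_history") {
        cpp$past_health | cpp$problem_list
      } else {
        cpp[[col]]
      }
      idx <- match(patients, cpp$patient_id)
      v2 <- val[ifelse(is.na(idx), NA_integer_, idx)]
      !is.na(idx) & !is.na(v2) & v2
    })
}

# Per-visit documentation rate for one physician: documented office billings
# over all office billings (distinct patient-day pairs) in the window.
per_visit_documentation <- function(dataset, physician_id, window, patients) {
  b <- dataset$billings
  sel <- b$is_office_visit & b$physician_id == physician_id &
    b$patient_id %in% patients & in_window(b$service_date, window)
  b <- unique(b[sel, c("patient_id", "service_date")])
  nt <- unique(dataset$notes[dataset$notes$physician_id == physician_id,
                             c("patient_id", "note_date")])
  matched <- paste(b$patient_id, b$service_date) %in%
    paste(nt$patient_id, nt$note_date)
  c(numerator = sum(matched), denominator = nrow(b))
}

completeness_row <- function(physician_id, field, window, num, den) {
  data.frame(
    physician_id = physician_id, field = field,
    window_start = window[1L], window_end = window[2L],
    numerator = as.integer(num), denominator = as.integer(den),
    rate = if (den > 0L) num / den else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-physician completeness rate of one EMR field in one window
#'
#' For the seven event fields the denominator is the physician's active
#' rostered patients in the window and the numerator counts those with the
#' field populated in-window (for `visit_documentation`, those all of whose
#' in-window office billings carry a same-day note — the canonical
#' per-patient reading; `variant = "per_visit"` instead rates documented
#' billings over billed office visits). For the seven CPP fields the
#' denominator is all rostered patients and the numerator counts non-empty
#' snapshot categories, `cpp_medical_history` being past health OR problem
#' list. A zero denominator yields an `NA` rate, flagged rather than
#' silently zero, and is excluded from any cross-physician aggregation.
#'
#' @param physician_id physician to assess.
#' @param field one of [emr_fields()].
#' @param window length-2 `Date` vector, half-open one-year interval.
#' @param dataset an [emr_dataset()].
#' @param variant visit-documentation numerator: `"per_patient"` (canonical)
#'   or `"per_visit"`.
#' @return one-row data frame: `physician_id`, `field`, `window_start`,
#'   `window_end`, `numerator`, `denominator`, `rate`.
#' @export
field_completeness <- function(physician_id, field, window, dataset,
                               variant = c("per_patient", "per_visit")) {
  variant <- match.arg(variant)
  check_fields(field)
  check_physician(physician_id, dataset)
  window <- as_window(window[1L], window[2L])
  denom_patients <- if (field %in% CPP_FIELDS) {
    dataset$rosters$patient_id[dataset$rosters$physician_id == physician_id]
  } else {
    active_patients(physician_id, dataset, window)
  }
  if (field == "visit_documentation" && variant == "per_visit") {
    nd <- per_visit_documentation(dataset, physician_id, window, denom_patients)
    return(completeness_row(physician_id, field, window, nd[["numerator"]],
                            nd[["denominator"]]))
  }
  ok <- field_satisfied(dataset, physician_id, field, window, denom_patients)
  completeness_row(physician_id, field, window, sum(ok), length(denom_patients))
}
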