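# Relational data model for an extracted primary-care EMR: one registry of
# physicians and rostered patients plus flat event tables, all keyed by opaque
# character ids, with a single dataset-level extraction date. Dates are
# calendar dates (day granularity); every documented rule in the assessment
# operates on whole days.

# Column schema per table: name -> class ("character", "Date", "logical").
TABLE_SPECS <- list(
  physicians    = c(physician_id = "character"),
  patients      = c(patient_id = "character", birth_date = "Date",
                    valid_insurance = "logical"),
  rosters       = c(patient_id = "character", physician_id = "character",
                    roster_start = "Date"),
  billings      = c(patient_id = "character", physician_id = "character",
                    service_date = "Date", is_office_visit = "logical"),
  notes         = c(patient_id = "character", physician_id = "character",
                    note_date = "Date"),
  measurements  = c(patient_id = "character", date = "Date",
                    kind = "character", structured = "logical"),
  labs          = c(patient_id = "character", date = "Date",
                    structured = "logical"),
  prescriptions = c(patient_id = "character", physician_id = "character",
                    date = "Date"),
  referrals     = c(patient_id = "character", date = "Date"),
  consults      = c(patient_id = "character", date = "Date"),
  cpp           = c(patient_id = "character",
                    stats::setNames(rep("logical", 8L), CPP_COLUMNS))
)

MEASUREMENT_KINDS <- c("blood_pressure", "weight")

empty_table <- function(name) {
  spec <- TABLE_SPECS[[name]]
  cols <- lapply(spec, function(cl) switch(cl,
    character = character(0),
    Date      = as.Date(character(0)),
    logical   = logical(0)))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerce_table <- function(df, name) {
  spec <- TABLE_SPECS[[name]]
  if (is.null(df)) return(empty_table(name))
  missing_cols <- setdiff(names(spec), names(df))
  if (length(missing_cols))
    stop(sprintf("table '%s' is missing column(s): %s", name,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df <- df[names(spec)]
  for (col in names(spec)) {
    df[[col]] <- switch(spec[[col]],
      character = as.character(df[[col]]),
      Date      = as.Date(df[[col]]),
      logical   = as.logical(df[[col]]))
  }
  rownames(df) <- NULL
  df
}

#' Construct a validated EMR dataset
#'
#' Bundles the eleven event/registry tables and the extraction date into an
#' `emr_dataset` object, the unit every downstream stage consumes. Patients
#' failing the inclusion criteria (no valid insurance flag or missing birth
#' date) are dropped at construction together with all their rows, and the
#' dropped count is recorded in the object's exclusion log.
#'
#' @param physicians,patients,rosters,billings,notes,measurements,labs,prescriptions,referrals,consults,cpp
#'   data frames following the canonical schemas (see [read_emr_dataset()]
#'   for the on-disk layout); missing tables default to empty.
#' @param extraction_date the date the EMR extract was taken; no event may
#'   postdate it.
#' @param validate run full invariant validation (default `TRUE`).
#' @return an object of class `emr_dataset`: a list of the coerced tables
#'   plus `extraction_date`, with attribute `exclusions` counting patients
#'   dropped by the inclusion criteria.
#' @seealso [validate_emr_dataset()], [read_emr_dataset()], [simulate_emr()]
#' @export
emr_dataset <- function(physicians = NULL, patients = NULL, rosters = NULL,
                        billings = NULL, notes = NULL, measurements = NULL,
                        labs = NULL, prescriptions = NULL, referrals = NULL,
                        consults = NULL, cpp = NULL,
                        extraction_date, validate = TRUE) {
  tables <- list(
    physicians = physicians, patients = patients, rosters = rosters,
    billings = billings, notes = notes, measurements = measurements,
    labs = labs, prescriptions = prescriptions, referrals = referrals,
    consults = consults, cpp = cpp)
  tables <- Map(coerce_table, tables, names(tables))
  extraction_date <- as.Date(extraction_date)
  if (length(extraction_date) != 1L || is.na(extraction_date))
    stop("extraction_date must be a single valid date", call. = FALSE)

  # Inclusion criteria: valid insurance and a known birth date.
  pat <- tables$patients
  bad <- is.na(pat$valid_insurance) | !pat$valid_insurance | is.na(pat$birth_date)
  n_excluded <- sum(bad)
  if (n_excluded > 0L) {
    drop_ids <- pat$patient_id[bad]
    tables$patients <- pat[!bad, , drop = FALSE]
    for (nm in setdiff(names(tables), c("physicians", "patients"))) {
      tb <- tables[[nm]]
      tables[[nm]] <- tb[!(tb$patient_id %in% drop_ids), , drop = FALSE]
    }
    tables <- lapply(tables, function(tb) { rownames(tb) <- NULL; tb })
  }

  x <- structure(
    c(tables, list(extraction_date = extraction_date)),
    class = "emr_dataset",
    exclusions = c(patients_failing_inclusion = n_excluded),
    cache = new.env(parent = emptyenv())
  )
  if (validate) validate_emr_dataset(x)
  x
}

#' Validate an EMR dataset's structural invariants
#'
#' Checks, with row-level diagnostics: unique physician and patient ids;
#' every foreign key in the event tables resolves to the registry; at most
#' one roster link per patient (Ontario enrolment is exclusive); no event
#' dated after the extraction date; no birth date after the extraction date;
#' measurement kinds restricted to blood pressure and weight.
#'
#' @param x an `emr_dataset`.
#' @return `x`, invisibly; stops with an informative error on the first
#'   violated invariant.
#' @export
validate_emr_dataset <- function(x) {
  stopifnot(inherits(x, "emr_dataset"))
  fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
  rows <- function(idx) paste(utils::head(which(idx), 10L), collapse = ", ")

  if (anyDuplicated(x$physicians$physician_id))
    fail("physicians: duplicated physician_id at row(s) %s",
         rows(duplicated(x$physicians$physician_id)))
  if (anyDuplicated(x$patients$patient_id))
    fail("patients: duplicated patient_id at row(s) %s",
         rows(duplicated(x$patients$patient_id)))
  if (anyDuplicated(x$rosters$patient_id))
    fail("rosters: patient rostered to more than one physician at row(s) %s",
         rows(duplicated(x$rosters$patient_id)))
  if (anyDuplicated(x$cpp$patient_id))
    fail("cpp: more than one snapshot for a patient at row(s) %s",
         rows(duplicated(x$cpp$patient_id)))

  pids <- x$patients$patient_id
  dids <- x$physicians$physician_id
  date_cols <- c(billings = "service_date", notes = "note_date",
                 measurements = "date", labs = "date",
                 prescriptions = "date", referrals = "date",
                 consults = "date", rosters = "roster_start")
  for (nm in c("rosters", "billings", "notes", "measurements", "labs",
               "prescriptions", "referrals", "consults", "cpp")) {
    tb <- x[[nm]]
    dangling <- !(tb$patient_id %in% pids)
    if (any(dangling))
      fail("%s: patient_id not in patient registry at row(s) %s", nm,
           rows(dangling))
    if ("physician_id" %in% names(tb)) {
      dangling <- !(tb$physician_id %in% dids)
      if (any(dangling))
        fail("%s: physician_id not in physician registry at row(s) %s", nm,
             rows(dangling))
    }
    if (nm %in% names(date_cols)) {
      d <- tb[[date_cols[[nm]]]]
      if (anyNA(d))
        fail("%s: unparseable or missing date at row(s) %s", nm, rows(is.na(d)))
      late <- d > x$extraction_date
      if (any(late))
        fail("%s: event dated after extraction_date at row(s) %s", nm,
             rows(late))
    }
  }
  if (any(x$patients$birth_date > x$extraction_date))
    fail("patients: birth_date after extraction_date at row(s) %s",
         rows(x$patients$birth_date > x$extraction_date))
  bad_kind <- !(x$measurements$kind %in% MEASUREMENT_KINDS)
  if (any(bad_kind))
    fail("measurements: kind must be one of {%s}; offending row(s) %s",
         paste(MEASUREMENT_KINDS, collapse = ", "), rows(bad_kind))
  invisible(x)
}

#' @export
print.emr_dataset <- function(x, ...) {
  cat("<emr_dataset> extracted", format(x$extraction_date), "\n")
  cat(sprintf("  %d physicians, %d patients, %d roster links\n",
              nrow(x$physicians), nrow(x$patients), nrow(x$rosters)))
  ev <- c("billings", "notes", "measurements", "labs", "prescriptions",
          "referrals", "consults")
  counts <- vapply(x[ev], nrow, integer(1))
  cat("  events:", paste(sprintf("%s=%d", ev, counts), collapse = " "), "\n")
  cat(sprintf("  cpp snapshots: %d\n", nrow(x$cpp)))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && any(excl > 0))
    cat("  excluded at load:",
        paste(sprintf("%s=%d", names(excl), excl), collapse = " "), "\n")
  invisible(x)
}

#' Read an EMR dataset from a directory of delimited files
#'
#' The canonical layout is one directory holding `physicians.csv`,
#' `patients.csv`, `rosters.csv`, `billings.csv`, `notes.csv`,
#' `measurements.csv`, `labs.csv`, `prescriptions.csv`, `referrals.csv`,
#' `consults.csv`, `cpp.csv` (comma-delimited, UTF-8, header row, RFC 4180
#' quoting, ISO 8601 dates) plus `metadata.json` carrying the extraction
#' date. [write_emr_dataset()] inverts this reader exactly.
#'
#' @param path directory containing the dataset files.
#' @param validate run invariant validation after loading (default `TRUE`).
#' @return a validated [emr_dataset()].
#' @export
read_emr_dataset <- function(path, validate = TRUE) {
  if (!dir.exists(path))
    stop("dataset directory not found: ", path, call. = FALSE)
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("missing dataset file: metadata.json", call. = FALSE)
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$extraction_date))
    stop("metadata.json lacks extraction_date", call. = FALSE)

  tables <- lapply(names(TABLE_SPECS), function(nm) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f))
      stop("missing dataset file: ", paste0(nm, ".csv"), call. = FALSE)
    spec <- TABLE_SPECS[[nm]]
    df <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
    for (col in names(spec)) {
      if (!col %in% names(df))
        stop(sprintf("%s.csv: missing column '%s'", nm, col), call. = FALSE)
      if (spec[[col]] == "Date") {
        d <- as.Date(df[[col]], format = "%Y-%m-%d")
        bad <- is.na(d) & nzchar(df[[col]])
        if (any(bad))
          stop(sprintf("%s.csv: unparseable date in '%s' at row(s) %s", nm,
                       col, paste(utils::head(which(bad), 10L), collapse = ", ")),
               call. = FALSE)
        df[[col]] <- d
      } else if (spec[[col]] == "logical") {
        df[[col]] <- as.logical(df[[col]])
      }
    }
    df
  })
  names(tables) <- names(TABLE_SPECS)

  do.call(emr_dataset, c(tables, list(
    extraction_date = as.Date(meta$extraction_date), validate = validate)))
}

#' Write an EMR dataset to a directory of delimited files
#'
#' Writes the canonical layout read by [read_emr_dataset()]; the two are
#' exact inverses on valid datasets (field-by-field table equality).
#'
#' @param x an `emr_dataset`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_emr_dataset <- function(x, path) {
  stopifnot(inherits(x, "emr_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path))
    stop("cannot create dataset directory: ", path, call. = FALSE)
  for (nm in names(TABLE_SPECS)) {
    df <- x[[nm]]
    spec <- TABLE_SPECS[[nm]]
    out <- df
    for (col in names(spec))
      if (spec[[col]] == "Date") out[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(out, file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(extraction_date = format(x$extraction_date, "%Y-%m-%d")),
    file.path(path, "metadata.json"), auto_unbox = TRUE)
  invisible(path)
}
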