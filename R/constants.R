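#' EMR documentation fields assessed by the package
#'
#' Fourteen fields are assessed. Seven are per-window event fields
#' (`visit_documentation`, `blood_pressure`, `weight`, `lab_test`,
#' `prescription`, `referral`, `consult_letter`) and seven are cumulative
#' patient profile (CPP) categories evaluated on the un-timestamped CPP
#' snapshot taken at extraction. `cpp_medical_history` merges the EMR's
#' separate "history of past health" and "problem list" panels, which
#' clinicians do not use consistently as distinct fields.
#'
#' @return character vector of the fourteen field names.
#' @export
emr_fields <- function() {
  c(EVENT_FIELDS, CPP_FIELDS)
}

EVENT_FIELDS <- c(
  "visit_documentation", "blood_pressure", "weight", "lab_test",
  "prescription", "referral", "consult_letter"
)

CPP_FIELDS <- c(
  "cpp_allergies", "cpp_immunizations", "cpp_active_treatment",
  "cpp_risk_factors", "cpp_personal_traits", "cpp_family_history",
  "cpp_medical_history"
)

# CPP snapshot columns as stored (past health and problem list kept separate
# in the data model; merged only when the cpp_medical_history measure is
# evaluated).
CPP_COLUMNS <- c(
  "allergies", "immunizations", "active_treatment", "risk_factors",
  "personal_traits", "family_history", "past_health", "problem_list"
)

check_fields <- function(fields) {
  bad <- setdiff(fields, emr_fields())
  if (length(bad))
    stop("unknown EMR field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  fields
}
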