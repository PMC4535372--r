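# Brute-force enumeration oracles, deliberately independent of the package
# implementation: explicit nested loops and per-patient scans.

oracle_match <- function(billings, notes) {
  b <- billings[billings$is_office_visit, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(b))) {
    hit <- FALSE
    for (j in seq_len(nrow(notes))) {
      if (notes$patient_id[j] == b$patient_id[i] &&
          notes$physician_id[j] == b$physician_id[i] &&
          notes$note_date[j] == b$service_date[i]) { hit <- TRUE; break }
    }
    if (hit)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = b$patient_id[i], physician_id = b$physician_id[i],
        date = b$service_date[i])
  }
  if (!length(out))
    return(data.frame(patient_id = character(0), physician_id = character(0),
                      date = as.Date(character(0))))
  v <- unique(do.call(rbind, out))
  v <- v[order(v$physician_id, v$patient_id, v$date), , drop = FALSE]
  rownames(v) <- NULL
  v
}

oracle_active <- function(physician_id, dataset, window,
                          v = oracle_match(dataset$billings, dataset$notes)) {
  panel <- dataset$rosters$patient_id[dataset$rosters$physician_id == physician_id]
  act <- character(0)
  for (p in panel) {
    d <- v$date[v$patient_id == p & v$physician_id == physician_id]
    if (any(d >= window[1] & d < window[2])) act <- c(act, p)
  }
  act
}

oracle_first_date <- function(patient_id, dataset,
                              v = oracle_match(dataset$billings, dataset$notes)) {
  d <- v$date[v$patient_id == patient_id]
  if (!length(d)) as.Date(NA) else min(d)
}

# Per-patient scan for one event field (prescription here, the field the
# random fixtures populate).
oracle_prescription_rate <- function(physician_id, dataset, window,
                                     v = oracle_match(dataset$billings,
                                                      dataset$notes)) {
  act <- oracle_active(physician_id, dataset, window, v)
  num <- 0L
  for (p in act) {
    d <- dataset$prescriptions$date[dataset$prescriptions$patient_id == p]
    if (any(d >= window[1] & d < window[2])) num <- num + 1L
  }
  c(numerator = num, denominator = length(act))
}

# Per-patient all-billings-documented scan for visit documentation.
oracle_visit_doc_rate <- function(physician_id, dataset, window,
                                  v = oracle_match(dataset$billings,
                                                   dataset$notes)) {
  act <- oracle_active(physician_id, dataset, window, v)
  num <- 0L
  for (p in act) {
    b <- dataset$billings
    bd <- unique(b$service_date[b$patient_id == p &
                                  b$physician_id == physician_id &
                                  b$is_office_visit &
                                  b$service_date >= window[1] &
                                  b$service_date < window[2]])
    ok <- TRUE
    for (d in bd) {
      if (!any(v$patient_id == p & v$physician_id == physician_id &
                 v$date == d)) { ok <- FALSE; break }
    }
    if (ok) num <- num + 1L
  }
  c(numerator = num, denominator = length(act))
}
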