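# Programmatic fixtures: no data files, everything built in code.

# Minimal valid registry scaffolding.
tiny_registry <- function(n_phys = 1, n_pat = 3,
                          extraction = as.Date("2012-07-01")) {
  phys <- sprintf("md%02d", seq_len(n_phys))
  pats <- sprintf("pt%03d", seq_len(n_pat))
  list(
    physicians = data.frame(physician_id = phys),
    patients = data.frame(patient_id = pats,
                          birth_date = as.Date("1970-01-15"),
                          valid_insurance = TRUE),
    rosters = data.frame(patient_id = pats,
                         physician_id = rep(phys, length.out = n_pat),
                         roster_start = as.Date("2005-01-01")),
    extraction = extraction)
}

# Hand-built dataset: 2 physicians, hand-countable completeness in the
# window [2011-07-01, 2012-07-01).
#  md01: pt001 visit 2011-08-01 documented, rx in window; pt002 visit
#        2011-09-01 documented plus an UNdocumented billing 2011-10-01, no
#        rx; pt003 no visits (inactive), cpp allergies TRUE.
#  md02: pt004 visit 2011-08-15 documented, rx in window.
tiny_dataset <- function() {
  reg <- tiny_registry(n_phys = 2, n_pat = 4)
  reg$rosters$physician_id <- c("md01", "md01", "md01", "md02")
  billings <- data.frame(
    patient_id = c("pt001", "pt002", "pt002", "pt004"),
    physician_id = c("md01", "md01", "md01", "md02"),
    service_date = as.Date(c("2011-08-01", "2011-09-01", "2011-10-01",
                             "2011-08-15")),
    is_office_visit = TRUE)
  notes <- data.frame(
    patient_id = c("pt001", "pt002", "pt004"),
    physician_id = c("md01", "md01", "md02"),
    note_date = as.Date(c("2011-08-01", "2011-09-01", "2011-08-15")))
  prescriptions <- data.frame(
    patient_id = c("pt001", "pt004"),
    physician_id = c("md01", "md02"),
    date = as.Date(c("2011-08-20", "2011-09-01")))
  cpp <- data.frame(patient_id = c("pt001", "pt002", "pt003", "pt004"),
                    allergies = c(TRUE, FALSE, TRUE, TRUE),
                    immunizations = FALSE, active_treatment = FALSE,
                    risk_factors = FALSE, personal_traits = FALSE,
                    family_history = FALSE,
                    past_health = c(FALSE, FALSE, FALSE, TRUE),
                    problem_list = c(TRUE, FALSE, FALSE, FALSE))
  emr_dataset(physicians = reg$physicians, patients = reg$patients,
              rosters = reg$rosters, billings = billings, notes = notes,
              prescriptions = prescriptions, cpp = cpp,
              extraction_date = reg$extraction)
}

final_year_window <- function(dataset) {
  c(add_anniversary_years(dataset$extraction_date, -1L),
    dataset$extraction_date)
}

# Random event fixture for oracle-equivalence checks: raw billing/note/event
# tables over a small id space so same-day collisions actually occur.
random_fixture <- function(seed, n_events = 200,
                           extraction = as.Date("2012-07-01")) {
  set.seed(seed)
  n_phys <- sample(2:4, 1)
  n_pat <- sample(5:25, 1)
  reg <- tiny_registry(n_phys, n_pat, extraction)
  reg$rosters$physician_id <-
    sample(reg$physicians$physician_id, n_pat, replace = TRUE)
  days <- extraction - sample.int(700, n_events, replace = TRUE)
  pick <- function(n) data.frame(
    patient_id = sample(reg$patients$patient_id, n, replace = TRUE),
    physician_id = sample(reg$physicians$physician_id, n, replace = TRUE),
    date = sample(days, n, replace = TRUE))
  nb <- sample.int(n_events, 1)
  b <- pick(nb)
  billings <- data.frame(patient_id = b$patient_id,
                         physician_id = b$physician_id,
                         service_date = b$date,
                         is_office_visit = stats::runif(nb) < 0.8)
  nn <- n_events - nb + 1L
  nt <- pick(nn)
  notes <- data.frame(patient_id = nt$patient_id,
                      physician_id = nt$physician_id, note_date = nt$date)
  nrx <- sample.int(50, 1)
  rx <- pick(nrx)
  prescriptions <- data.frame(patient_id = rx$patient_id,
                              physician_id = rx$physician_id, date = rx$date)
  emr_dataset(physicians = reg$physicians, patients = reg$patients,
              rosters = reg$rosters, billings = billings, notes = notes,
              prescriptions = prescriptions,
              extraction_date = extraction)
}

expect_same_tables <- function(a, b) {
  for (nm in c("physicians", "patients", "rosters", "billings", "notes",
               "measurements", "labs", "prescriptions", "referrals",
               "consults", "cpp")) {
    expect_equal(a[[nm]], b[[nm]], info = nm)
  }
  expect_equal(a$extraction_date, b$extraction_date)
}
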