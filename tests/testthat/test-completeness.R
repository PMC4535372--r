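test_that("visit matching pairs office billings with same-day notes only", {
  reg <- tiny_registry()
  b <- data.frame(patient_id = "pt001", physician_id = "md01",
                  service_date = as.Date("2011-03-01"),
                  is_office_visit = TRUE)
  n_same <- data.frame(patient_id = "pt001", physician_id = "md01",
                       note_date = as.Date("2011-03-01"))
  n_next <- data.frame(patient_id = "pt001", physician_id = "md01",
                       note_date = as.Date("2011-03-02"))
  v <- match_documented_visits(b, n_same)
  expect_identical(nrow(v), 1L)
  expect_identical(v$date, as.Date("2011-03-01"))
  expect_identical(nrow(match_documented_visits(b, n_next)), 0L)

  # non-office billings never match; duplicated rows collapse
  b2 <- rbind(b, b, transform(b, is_office_visit = FALSE))
  expect_identical(nrow(match_documented_visits(b2, rbind(n_same, n_same))), 1L)
})

test_that("visit matching agrees with the nested-loop oracle on random fixtures", {
  for (seed in 1:12) {
    d <- random_fixture(seed, n_events = sample(40:160, 1))
    got <- match_documented_visits(d$billings, d$notes)
    expect_equal(got, oracle_match(d$billings, d$notes), info = seed)
  }
})

test_that("initiation date is the earliest day reaching the pair threshold", {
  reg <- tiny_registry(n_pat = 12)
  mk <- function(ids, date) list(
    b = data.frame(patient_id = ids, physician_id = "md01",
                   service_date = date, is_office_visit = TRUE),
    n = data.frame(patient_id = ids, physician_id = "md01",
                   note_date = date))
  dayA <- as.Date("2008-01-10"); dayB <- as.Date("2008-02-20")
  e9 <- mk(sprintf("pt%03d", 1:9), dayA)
  e10 <- mk(sprintf("pt%03d", 1:10), dayB)
  d <- emr_dataset(physicians = reg$physicians, patients = reg$patients,
                   rosters = reg$rosters, billings = rbind(e9$b, e10$b),
                   notes = rbind(e9$n, e10$n),
                   extraction_date = reg$extraction)
  expect_identical(detect_initiation_date("md01", d), dayB)
  expect_identical(detect_initiation_date("md01", d, min_pairs = 9), dayA)

  # cumulative reading: 9 pairs on day A plus 1 on day B reach the
  # threshold only as a running total
  e1 <- mk("pt010", dayB)
  d2 <- emr_dataset(physicians = reg$physicians, patients = reg$patients,
                    rosters = reg$rosters, billings = rbind(e9$b, e1$b),
                    notes = rbind(e9$n, e1$n),
                    extraction_date = reg$extraction)
  expect_true(is.na(detect_initiation_date("md01", d2)))
  expect_identical(detect_initiation_date("md01", d2, mode = "cumulative"),
                   dayB)
  expect_error(detect_initiation_date("ghost", d), "unknown physician")

  empty <- emr_dataset(physicians = reg$physicians, patients = reg$patients,
                       rosters = reg$rosters,
                       extraction_date = reg$extraction)
  expect_true(is.na(detect_initiation_date("md01", empty)))
})

test_that("initiation detection recovers the generated ground truth exactly", {
  sim <- simulate_emr(sim_config(n_physicians = 8, panel_size_mean = 25,
                                 years_span = 4,
                                 physician_start_spread_years = 2, seed = 17))
  gt <- sim$ground_truth$physicians
  got <- vapply(gt$physician_id, function(p)
    as.character(detect_initiation_date(p, sim$dataset)), character(1))
  expect_identical(as.Date(got, origin = "1970-01-01") |> unname(),
                   gt$initiation_date)
})

test_that("active patients respect the half-open window and the oracle", {
  d <- tiny_dataset()
  w <- c(as.Date("2011-08-01"), as.Date("2011-09-01"))
  # visit on the window start date is in; visit on the end date is out
  expect_setequal(active_patients("md01", d, w), "pt001")
  expect_setequal(active_patients("md01", d, c(w[1] - 40, w[1])), character(0))
  for (seed in 13:18) {
    rf <- random_fixture(seed, 120)
    w2 <- c(rf$extraction_date - 400, rf$extraction_date - 100)
    for (p in rf$physicians$physician_id)
      expect_setequal(active_patients(p, rf, w2), oracle_active(p, rf, w2))
  }
})

test_that("patient first EMR date is the earliest documented visit, never a bare billing", {
  d <- tiny_dataset()
  expect_identical(patient_first_emr_date("pt001", d), as.Date("2011-08-01"))
  expect_true(is.na(patient_first_emr_date("pt003", d)))
  expect_error(patient_first_emr_date("ghost", d), "unknown patient")

  reg <- tiny_registry()
  bills_only <- data.frame(patient_id = "pt001", physician_id = "md01",
                           service_date = as.Date("2011-01-01"),
                           is_office_visit = TRUE)
  d2 <- emr_dataset(physicians = reg$physicians, patients = reg$patients,
                    rosters = reg$rosters, billings = bills_only,
                    extraction_date = reg$extraction)
  expect_true(is.na(patient_first_emr_date("pt001", d2)))

  for (seed in 19:24) {
    rf <- random_fixture(seed, 120)
    for (p in utils::head(rf$patients$patient_id, 8))
      expect_identical(patient_first_emr_date(p, rf), oracle_first_date(p, rf))
  }
})

test_that("field completeness counts patients with the field over the right denominator", {
  d <- tiny_dataset()
  w <- final_year_window(d)
  rx <- field_completeness("md01", "prescription", w, d)
  # md01 actives: pt001 (rx) and pt002 (no rx); pt003 inactive
  expect_identical(rx$numerator, 1L)
  expect_identical(rx$denominator, 2L)
  expect_equal(rx$rate, 0.5)

  # per-patient visit documentation: pt002 has an undocumented billing
  vd <- field_completeness("md01", "visit_documentation", w, d)
  expect_equal(vd$rate, 0.5)
  # per-visit variant: 2 of 3 office billings documented
  vv <- field_completeness("md01", "visit_documentation", w, d,
                           variant = "per_visit")
  expect_identical(c(vv$numerator, vv$denominator), c(2L, 3L))

  # CPP fields run over all rostered patients, snapshot at extraction;
  # medical history merges past health OR problem list
  al <- field_completeness("md01", "cpp_allergies", w, d)
  expect_identical(al$denominator, 3L)
  expect_equal(al$rate, 2 / 3)
  mh <- field_completeness("md01", "cpp_medical_history", w, d)
  expect_equal(mh$rate, 1 / 3)  # only pt001 via problem_list
  mh2 <- field_completeness("md02", "cpp_medical_history", w, d)
  expect_equal(mh2$rate, 1)     # pt004 via past_health

  # zero denominator is flagged undefined, not zero
  empty_w <- c(as.Date("2006-01-01"), as.Date("2007-01-01"))
  z <- field_completeness("md01", "prescription", empty_w, d)
  expect_identical(z$denominator, 0L)
  expect_true(is.na(z$rate))
})

test_that("only structured labs and measurements count toward their fields", {
  reg <- tiny_registry()
  b <- data.frame(patient_id = "pt001", physician_id = "md01",
                  service_date = as.Date("2012-01-05"), is_office_visit = TRUE)
  n <- data.frame(patient_id = "pt001", physician_id = "md01",
                  note_date = as.Date("2012-01-05"))
  labs <- data.frame(patient_id = "pt001",
                     date = as.Date(c("2012-02-01", "2012-02-02")),
                     structured = c(FALSE, FALSE))
  meas <- data.frame(patient_id = "pt001", date = as.Date("2012-02-03"),
                     kind = "blood_pressure", structured = FALSE)
  d <- emr_dataset(physicians = reg$physicians, patients = reg$patients,
                   rosters = reg$rosters, billings = b, notes = n,
                   labs = labs, measurements = meas,
                   extraction_date = reg$extraction)
  w <- final_year_window(d)
  expect_equal(field_completeness("md01", "lab_test", w, d)$rate, 0)
  expect_equal(field_completeness("md01", "blood_pressure", w, d)$rate, 0)
  d$labs$structured[1] <- TRUE
  expect_equal(field_completeness("md01", "lab_test", w, d)$rate, 1)
})

test_that("rates are invariant under row order and duplicated rows, and monotone in qualifying events", {
  for (seed in 25:28) {
    rf <- random_fixture(seed, 150)
    w <- c(rf$extraction_date - 365, rf$extraction_date)
    p <- rf$physicians$physician_id[1]
    base <- field_completeness(p, "prescription", w, rf)

    shuf <- rf
    set.seed(seed)
    for (nm in c("billings", "notes", "prescriptions")) {
      shuf[[nm]] <- shuf[[nm]][sample(nrow(shuf[[nm]])), , drop = FALSE]
      rownames(shuf[[nm]]) <- NULL
    }
    attr(shuf, "cache") <- new.env(parent = emptyenv())
    expect_equal(field_completeness(p, "prescription", w, shuf), base)

    dup <- rf
    dup$prescriptions <- rbind(dup$prescriptions, dup$prescriptions)
    attr(dup, "cache") <- new.env(parent = emptyenv())
    expect_equal(field_completeness(p, "prescription", w, dup)$rate, base$rate)

    # adding a qualifying prescription for a denominator patient never
    # lowers the rate; a new prescription never changes the denominator
    act <- active_patients(p, rf, w)
    if (length(act)) {
      plus <- rf
      plus$prescriptions <- rbind(plus$prescriptions, data.frame(
        patient_id = act[1], physician_id = p, date = w[1]))
      attr(plus, "cache") <- new.env(parent = emptyenv())
      after <- field_completeness(p, "prescription", w, plus)
      expect_gte(after$rate, base$rate)
      expect_identical(after$denominator, base$denominator)
    }
  }
})

test_that("random-fixture field completeness matches the per-patient scan oracle", {
  for (seed in 29:34) {
    rf <- random_fixture(seed, 150)
    w <- c(rf$extraction_date - 365, rf$extraction_date)
    for (p in rf$physicians$physician_id) {
      got <- field_completeness(p, "prescription", w, rf)
      exp <- oracle_prescription_rate(p, rf, w)
      expect_identical(c(got$numerator, got$denominator), unname(
        c(exp["numerator"], exp["denominator"])), info = paste(seed, p))
      gvd <- field_completeness(p, "visit_documentation", w, rf)
      evd <- oracle_visit_doc_rate(p, rf, w)
      expect_identical(c(gvd$numerator, gvd$denominator),
                       unname(c(evd["numerator"], evd["denominator"])),
                       info = paste(seed, p))
    }
  }
})
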