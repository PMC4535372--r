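# Synthetic primary-care EMR generator. Every downstream stage of the
# assessment is exercised against datasets produced here, whose completeness
# structure is known exactly (the "ground truth"), because real extracted EMR
# data cannot be shared.

#' Field-probability schedule and cohort configuration for the simulator
#'
#' The completeness structure of a simulated practice is governed by
#' per-field probability schedules of the form
#' `clamp(p0 + jump * [k >= 2] + slope * (k - 1), 0, ceiling)` in the
#' physician's k-th year on the EMR: a base rate in year one, a distinct
#' year-1-to-year-2 jump (field population improves most between the first
#' and second year of use), a slower steady per-year drift, and a ceiling.
#'
#' Defaults describe a desk-scale cohort of 40 community family practices
#' with mean rostered panel 50, observed over a 7-year extract window with
#' EMR adoption staggered across the first 2 years (so every physician has
#' at least five full years of data and year-k eligibility shrinks with k).
#' The default visit-documentation schedule runs from 0.69 in year one to a
#' ceiling of 0.88; the remaining schedules are set at rates typical of
#' community primary care (prescriptions the best-populated practice-style
#' field, weights and consult letters the worst, laboratory feeds flat once
#' switched on).
#'
#' @param n_physicians number of physicians in the cohort.
#' @param panel_size_mean mean rostered panel size per physician (Poisson;
#'   floored at 10 so the adoption-day burst is well defined).
#' @param years_span years between the earliest possible EMR initiation and
#'   the extraction date.
#' @param physician_start_spread_years initiation dates are drawn uniformly
#'   over this many years at the start of the span.
#' @param visits_per_patient_year expected office visits per patient-year
#'   (homogeneous Poisson counts).
#' @param visit_documentation_prob schedule `(p0, jump, slope, ceiling)` for
#'   the per-visit probability that a billed office visit gets a same-day
#'   progress note.
#' @param field_prob_schedule named list of `(p0, jump, slope, ceiling)`
#'   schedules for the six at-least-one-event fields (`blood_pressure`,
#'   `weight`, `lab_test`, `prescription`, `referral`, `consult_letter`).
#' @param cpp_prob named probabilities for the eight CPP snapshot columns.
#' @param cpp_tenure_slope additive increase in each CPP probability per
#'   year of patient tenure (clamped to 0.98), emulating profiles filling in
#'   as patients accumulate history.
#' @param nonoffice_billing_rate expected non-office billings per
#'   patient-year (never count toward visit documentation).
#' @param scanned_lab_rate probability per patient-year of a scanned
#'   (unstructured) lab report, which the lab measure must ignore.
#' @param extraction_date date the simulated extract is taken.
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return a `sim_config` list.
#' @seealso [simulate_emr()], [field_probability()]
#' @export
sim_config <- function(n_physicians = 40,
                       panel_size_mean = 50,
                       years_span = 7,
                       physician_start_spread_years = 2,
                       visits_per_patient_year = 3,
                       visit_documentation_prob =
                         c(p0 = 0.69, jump = 0.10, slope = 0.03, ceiling = 0.88),
                       field_prob_schedule = default_field_schedule(),
                       cpp_prob = default_cpp_prob(),
                       cpp_tenure_slope = 0.04,
                       nonoffice_billing_rate = 0.3,
                       scanned_lab_rate = 0.15,
                       extraction_date = as.Date("2012-07-01"),
                       seed = 1L) {
  cfg <- list(
    n_physicians = as.integer(n_physicians),
    panel_size_mean = panel_size_mean,
    years_span = as.integer(years_span),
    physician_start_spread_years = physician_start_spread_years,
    visits_per_patient_year = visits_per_patient_year,
    visit_documentation_prob = check_schedule(visit_documentation_prob,
                                              "visit_documentation"),
    field_prob_schedule = field_prob_schedule,
    cpp_prob = cpp_prob,
    cpp_tenure_slope = cpp_tenure_slope,
    nonoffice_billing_rate = nonoffice_billing_rate,
    scanned_lab_rate = scanned_lab_rate,
    extraction_date = as.Date(extraction_date),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_field_schedule <- function() {
  list(
    blood_pressure = c(p0 = 0.40, jump = 0.15, slope = 0.03, ceiling = 0.85),
    weight         = c(p0 = 0.30, jump = 0.10, slope = 0.03, ceiling = 0.70),
    lab_test       = c(p0 = 0.50, jump = 0.05, slope = 0.00, ceiling = 0.90),
    prescription   = c(p0 = 0.60, jump = 0.10, slope = 0.02, ceiling = 0.95),
    referral       = c(p0 = 0.35, jump = 0.10, slope = 0.02, ceiling = 0.80),
    consult_letter = c(p0 = 0.30, jump = 0.05, slope = 0.00, ceiling = 0.70))
}

default_cpp_prob <- function() {
  c(allergies = 0.80, immunizations = 0.60, active_treatment = 0.70,
    risk_factors = 0.50, personal_traits = 0.50, family_history = 0.45,
    past_health = 0.70, problem_list = 0.60)
}

check_schedule <- function(s, name) {
  need <- c("p0", "jump", "slope", "ceiling")
  if (!is.numeric(s) || !all(need %in% names(s)))
    stop(sprintf("schedule for '%s' must be a named numeric (p0, jump, slope, ceiling)",
                 name), call. = FALSE)
  s <- s[need]
  if (s[["p0"]] < 0 || s[["p0"]] > 1 || s[["ceiling"]] < 0 || s[["ceiling"]] > 1)
    stop(sprintf("schedule for '%s': p0 and ceiling must lie in [0, 1]", name),
         call. = FALSE)
  s
}

validate_sim_config <- function(cfg) {
  if (cfg$n_physicians < 1L || cfg$years_span < 1L || cfg$panel_size_mean < 1)
    stop("infeasible simulation config: counts must be >= 1", call. = FALSE)
  if (cfg$physician_start_spread_years < 0 ||
      cfg$physician_start_spread_years >= cfg$years_span)
    stop("physician_start_spread_years must lie in [0, years_span)",
         call. = FALSE)
  if (cfg$visits_per_patient_year <= 0)
    stop("visits_per_patient_year must be positive", call. = FALSE)
  probs <- c(cfg$cpp_prob, cfg$cpp_tenure_slope, cfg$nonoffice_billing_rate,
             cfg$scanned_lab_rate)
  if (any(probs < 0) || any(cfg$cpp_prob > 1) || cfg$scanned_lab_rate > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (!setequal(names(cfg$field_prob_schedule),
                setdiff(EVENT_FIELDS, "visit_documentation")))
    stop("field_prob_schedule must name exactly the six event fields",
         call. = FALSE)
  for (nm in names(cfg$field_prob_schedule))
    cfg$field_prob_schedule[[nm]] <- check_schedule(cfg$field_prob_schedule[[nm]], nm)
  invisible(cfg)
}

#' Scheduled population probability of a field in a physician's k-th EMR year
#'
#' Evaluates the closed-form schedule
#' `clamp(p0 + jump * [k >= 2] + slope * (k - 1), 0, ceiling)`.
#' Non-decreasing in `k` whenever `jump` and `slope` are non-negative.
#'
#' @param field one of the seven event fields (including
#'   `visit_documentation`).
#' @param k 1-based physician year on the EMR (vectorised).
#' @param config a [sim_config()].
#' @return probability vector, same length as `k`.
#' @examples
#' cfg <- sim_config()
#' field_probability("prescription", 1:5, cfg)
#' @export
field_probability <- function(field, k, config) {
  stopifnot(all(k >= 1))
  s <- if (identical(field, "visit_documentation")) {
    config$visit_documentation_prob
  } else if (field %in% names(config$field_prob_schedule)) {
    config$field_prob_schedule[[field]]
  } else {
    stop("no schedule configured for field: ", field, call. = FALSE)
  }
  p <- s[["p0"]] + s[["jump"]] * (k >= 2) + s[["slope"]] * (k - 1)
  pmin(pmax(p, 0), s[["ceiling"]])
}

# Deterministic substream seed for unit i under master seed s: adding a
# physician to the cohort never perturbs the draws of existing physicians.
substream_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1048573 + i * 7919 + 12345) %% 2147483629)
}

#' Generate a synthetic EMR dataset with known completeness structure
#'
#' Simulates, per physician: an EMR initiation day marked by a burst of 10
#' same-day billing/progress-note pairs from 10 distinct patients (so the
#' initiation-date detector has a well-defined target); a rostered panel
#' whose patients enter care at staggered dates; Poisson office-visit
#' streams where each billed visit receives a same-day note with the
#' scheduled per-visit probability for that physician-year; per
#' patient-year at-least-one-event draws for the six practice fields at the
#' scheduled probabilities; and one un-timestamped CPP snapshot per patient
#' whose category probabilities rise with patient tenure. All events fall in
#' `[initiation, extraction_date]`.
#'
#' @param config a [sim_config()].
#' @return a list with components `dataset` (a validated [emr_dataset()])
#'   and `ground_truth`, itself a list of data frames: `physicians`
#'   (`physician_id`, `initiation_date`), `patients` (`patient_id`,
#'   `physician_id`, `entry_date`, `tenure_years`) and `schedule` (`field`,
#'   `year`, `prob` — the scheduled probabilities per physician-year).
#' @export
simulate_emr <- function(config = sim_config()) {
  validate_sim_config(config)
  extraction <- config$extraction_date
  span_start <- add_anniversary_years(extraction, -config$years_span)
  spread_days <- round(config$physician_start_spread_years * 365.25)

  acc <- list(physicians = list(), patients = list(), rosters = list(),
              billings = list(), notes = list(), measurements = list(),
              labs = list(), prescriptions = list(), referrals = list(),
              consults = list(), cpp = list())
  gt_phys <- vector("list", config$n_physicians)
  gt_pat <- vector("list", config$n_physicians)

  for (i in seq_len(config$n_physicians)) {
    set.seed(substream_seed(config$seed, i))
    phys_id <- sprintf("md%03d", i)
    offset <- if (spread_days > 0) sample.int(spread_days + 1L, 1L) - 1L else 0L
    init <- span_start + offset
    sim <- simulate_practice(phys_id, init, extraction, config)
    for (nm in names(acc)) acc[[nm]][[i]] <- sim[[nm]]
    gt_phys[[i]] <- data.frame(physician_id = phys_id, initiation_date = init,
                               stringsAsFactors = FALSE)
    gt_pat[[i]] <- sim$gt_patients
  }

  tables <- lapply(acc, function(lst) do.call(rbind, lst))
  dataset <- emr_dataset(
    physicians = tables$physicians, patients = tables$patients,
    rosters = tables$rosters, billings = tables$billings,
    notes = tables$notes, measurements = tables$measurements,
    labs = tables$labs, prescriptions = tables$prescriptions,
    referrals = tables$referrals, consults = tables$consults,
    cpp = tables$cpp, extraction_date = extraction)

  max_k <- config$years_span
  schedule <- do.call(rbind, lapply(EVENT_FIELDS, function(f)
    data.frame(field = f, year = seq_len(max_k),
               prob = field_probability(f, seq_len(max_k), config),
               stringsAsFactors = FALSE)))
  ground_truth <- list(
    physicians = do.call(rbind, gt_phys),
    patients = do.call(rbind, gt_pat),
    schedule = schedule)
  list(dataset = dataset, ground_truth = ground_truth)
}

# One physician's practice. Called with the physician's RNG substream active.
simulate_practice <- function(phys_id, init, extraction, config) {
  span_days <- as.integer(extraction - init)
  n_pat <- max(10L, stats::rpois(1L, config$panel_size_mean))
  pat_ids <- sprintf("%s-pt%04d", phys_id, seq_len(n_pat))

  # First 10 patients enter on the initiation day and form the adoption-day
  # burst; the rest enter uniformly over the span (at least 90 days before
  # extraction so every patient can contribute some follow-up).
  entry_off <- integer(n_pat)
  late_max <- max(span_days - 90L, 1L)
  if (n_pat > 10L)
    entry_off[11:n_pat] <- sample.int(late_max, n_pat - 10L, replace = TRUE) - 1L
  entry <- init + entry_off

  # Physician-year windows [init + (k-1)y, min(init + ky, extraction)).
  max_k <- 1L
  while (add_anniversary_years(init, max_k) < extraction) max_k <- max_k + 1L
  wstart <- add_anniversary_years(init, 0:(max_k - 1L))
  wend <- pmin(add_anniversary_years(init, seq_len(max_k)), extraction)

  # Patient x physician-year grid restricted to non-empty intersections
  # [max(window start, entry), window end).
  g_pat <- rep(seq_len(n_pat), each = max_k)
  g_k <- rep(seq_len(max_k), times = n_pat)
  g_start <- pmax(wstart[g_k], entry[g_pat])
  g_end <- wend[g_k]
  keep <- g_start < g_end
  g_pat <- g_pat[keep]; g_k <- g_k[keep]
  g_start <- g_start[keep]; g_end <- g_end[keep]
  g_len <- as.integer(g_end - g_start)

  rand_dates <- function(idx) {
    # one uniform day in each selected grid cell
    g_start[idx] + floor(stats::runif(length(idx)) * g_len[idx])
  }

  # Office-visit stream: Poisson count per grid cell, same-day note with the
  # scheduled per-visit probability for that physician-year.
  n_vis <- stats::rpois(length(g_pat), config$visits_per_patient_year * g_len / 365.25)
  v_cell <- rep(seq_along(g_pat), n_vis)
  v_dates <- rand_dates(v_cell)
  v_pat <- g_pat[v_cell]
  v_doc <- stats::rbinom(length(v_cell), 1L,
                         field_probability("visit_documentation", g_k[v_cell],
                                           config)) == 1L

  burst_idx <- seq_len(10L)
  billings <- data.frame(
    patient_id = c(pat_ids[v_pat], pat_ids[burst_idx]),
    physician_id = phys_id,
    service_date = c(v_dates, rep(init, 10L)),
    is_office_visit = TRUE, stringsAsFactors = FALSE)
  notes <- data.frame(
    patient_id = c(pat_ids[v_pat[v_doc]], pat_ids[burst_idx]),
    physician_id = phys_id,
    note_date = c(v_dates[v_doc], rep(init, 10L)),
    stringsAsFactors = FALSE)

  # Non-office billings (never visit documentation material).
  n_non <- stats::rpois(length(g_pat), config$nonoffice_billing_rate * g_len / 365.25)
  no_cell <- rep(seq_along(g_pat), n_non)
  if (length(no_cell)) {
    billings <- rbind(billings, data.frame(
      patient_id = pat_ids[g_pat[no_cell]], physician_id = phys_id,
      service_date = rand_dates(no_cell), is_office_visit = FALSE,
      stringsAsFactors = FALSE))
  }

  # At-least-one-event fields: one Bernoulli per patient-year per field.
  draw_field <- function(field) {
    hit <- stats::rbinom(length(g_pat), 1L,
                         field_probability(field, g_k, config)) == 1L
    list(pat = pat_ids[g_pat[hit]], date = rand_dates(which(hit)))
  }
  bp <- draw_field("blood_pressure")
  wt <- draw_field("weight")
  lab <- draw_field("lab_test")
  rx <- draw_field("prescription")
  ref <- draw_field("referral")
  con <- draw_field("consult_letter")

  measurements <- data.frame(
    patient_id = c(bp$pat, wt$pat),
    date = c(bp$date, wt$date),
    kind = rep(c("blood_pressure", "weight"), c(length(bp$pat), length(wt$pat))),
    structured = TRUE, stringsAsFactors = FALSE)

  # Scanned lab reports arrive unstructured; the lab measure must ignore them.
  scanned <- stats::rbinom(length(g_pat), 1L, config$scanned_lab_rate) == 1L
  labs <- data.frame(
    patient_id = c(lab$pat, pat_ids[g_pat[scanned]]),
    date = c(lab$date, rand_dates(which(scanned))),
    structured = rep(c(TRUE, FALSE), c(length(lab$pat), sum(scanned))),
    stringsAsFactors = FALSE)

  prescriptions <- data.frame(patient_id = rx$pat, physician_id = phys_id,
                              date = rx$date, stringsAsFactors = FALSE)
  referrals <- data.frame(patient_id = ref$pat, date = ref$date,
                          stringsAsFactors = FALSE)
  consults <- data.frame(patient_id = con$pat, date = con$date,
                         stringsAsFactors = FALSE)

  # CPP snapshot: one row per patient, probabilities rising with tenure.
  tenure <- as.numeric(extraction - entry) / 365.25
  cpp_cols <- lapply(CPP_COLUMNS, function(col) {
    p <- pmin(config$cpp_prob[[col]] + config$cpp_tenure_slope * tenure, 0.98)
    stats::rbinom(n_pat, 1L, p) == 1L
  })
  names(cpp_cols) <- CPP_COLUMNS
  cpp <- cbind(data.frame(patient_id = pat_ids, stringsAsFactors = FALSE),
               as.data.frame(cpp_cols))

  birth <- extraction - (stats::rgeom(n_pat, 1 / 40) * 365L +
                           sample.int(365L, n_pat, replace = TRUE))
  list(
    physicians = data.frame(physician_id = phys_id, stringsAsFactors = FALSE),
    patients = data.frame(patient_id = pat_ids, birth_date = birth,
                          valid_insurance = TRUE, stringsAsFactors = FALSE),
    rosters = data.frame(patient_id = pat_ids, physician_id = phys_id,
                         roster_start = entry, stringsAsFactors = FALSE),
    billings = billings, notes = notes, measurements = measurements,
    labs = labs, prescriptions = prescriptions, referrals = referrals,
    consults = consults, cpp = cpp,
    gt_patients = data.frame(patient_id = pat_ids, physician_id = phys_id,
                             entry_date = entry, tenure_years = tenure,
                             stringsAsFactors = FALSE))
}
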