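# Independent brute-force oracles. These deliberately avoid the package's
# interval-sweep / rule-pipeline implementations: exposures are recomputed by
# per-day enumeration and cohort rules by a literal per-person scan, so the
# two routes share no code.

# Per-day enumeration of the average daily drug count.
brute_force_avg_drugs <- function(rx, index_date, config, window_days = 730L) {
  index_date <- as.integer(data.table::as.IDate(index_date))
  win_days <- seq(index_date - window_days, index_date - 1L)
  total <- 0L
  for (d in win_days) {
    active <- rx[as.integer(rx$dispense_date) <= d &
                   d < as.integer(rx$dispense_date) + rx$days_supplied, ]
    if (!nrow(active)) next
    per_code <- tapply(active$ingredient_count, active$drug_code, max)
    w <- ifelse(names(per_code) %in% config$combo_codes, per_code, 1)
    total <- total + sum(w)
  }
  total / window_days
}

# Integer drug-day sum (same enumeration, before division).
brute_force_drug_days <- function(rx, index_date, config, window_days = 730L)
  brute_force_avg_drugs(rx, index_date, config, window_days) * window_days

# Day-set union MPR for one PIM class.
brute_force_mpr <- function(rx, pim_class, index_date, config,
                            window_days = 730L) {
  cls <- config$pim_class_map[rx$drug_code]
  rx <- rx[!is.na(cls) & cls == pim_class, ]
  if (!nrow(rx)) return(0)
  index_date <- as.integer(data.table::as.IDate(index_date))
  days <- unlist(lapply(seq_len(nrow(rx)), function(i)
    seq(as.integer(rx$dispense_date[i]),
        length.out = rx$days_supplied[i])))
  days <- unique(days[days >= index_date - window_days & days < index_date])
  100 * length(days) / window_days
}

# Literal per-person evaluation of every incident-case rule.
brute_force_cases <- function(persons, diagnoses, config,
                              case_window_start = 2005L,
                              case_window_end = 2013L,
                              min_outpatient_visits = 2L, min_age = 65L) {
  window_open <- data.table::as.IDate(sprintf("%d-01-01", case_window_start))
  window_close <- data.table::as.IDate(sprintf("%d-12-31", case_window_end))
  out <- character()
  for (i in seq_len(nrow(persons))) {
    p <- persons[i, ]
    dx <- diagnoses[diagnoses$person_id == p$person_id, ]
    is_dem <- code_matches(dx$icd10_code, config$dementia_codes)
    dem_dates <- sort(dx$service_date[is_dem])
    k <- config$min_dementia_claims
    if (length(dem_dates) < k) next
    idx <- dem_dates[k]
    if (dem_dates[1] < window_open) next          # washout / not incident
    if (idx < window_open || idx > window_close) next
    if (data.table::year(idx) - p$birth_year < min_age) next
    inpt <- dx$service_date[dx$setting == "inpatient"]
    if (length(inpt) && min(inpt) < idx) next
    n_outp <- sum(dx$setting == "outpatient" & dx$service_date <= idx)
    if (n_outp < min_outpatient_visits) next
    if (idx < p$enroll_start || idx > p$enroll_end) next
    out <- c(out, p$person_id)
  }
  out
}

# Re-check every eligibility predicate of an emitted pair set.
validate_pairs <- function(pairs, persons, diagnoses, config,
                           min_outpatient_visits = 2L) {
  ok <- TRUE
  seen_ctrl <- character()
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    ctrl <- persons[persons$person_id == pr$control_person_id, ]
    dx <- diagnoses[diagnoses$person_id == pr$control_person_id, ]
    idx <- pr$index_date
    checks <- c(
      one_to_one = !pr$control_person_id %in% seen_ctrl,
      not_self = pr$case_person_id != pr$control_person_id,
      enrolled = ctrl$enroll_start <= idx && ctrl$enroll_end >= idx,
      alive = is.na(ctrl$death_date) || ctrl$death_date > idx,
      key_age = (pr$index_year - ctrl$birth_year) == pr$age_at_index,
      key_sex = ctrl$sex == pr$sex,
      key_income = ctrl$income_index == pr$income_index,
      dementia_free = !any(code_matches(dx$icd10_code,
                                        config$dementia_codes) &
                             dx$service_date <= idx),
      no_prior_hosp = !any(dx$setting == "inpatient" &
                             dx$service_date < idx),
      outpatient_use = sum(dx$setting == "outpatient" &
                             dx$service_date <= idx) >=
        min_outpatient_visits)
    if (!all(checks)) {
      ok <- FALSE
      attr(ok, "failed") <- list(pair = pr, checks = checks)
      return(ok)
    }
    seen_ctrl <- c(seen_ctrl, pr$control_person_id)
  }
  ok
}

# Small handmade claims fixture: 2 persons, a few claims each.
tiny_claims <- function() {
  persons <- data.table::data.table(
    person_id = c("A1", "B2"),
    birth_year = c(1935L, 1930L),
    sex = c("female", "male"),
    income_index = c(3L, 0L),
    enroll_start = data.table::as.IDate(c("2002-01-01", "2002-01-01")),
    enroll_end = data.table::as.IDate(c("2013-12-31", "2010-06-30")),
    death_date = data.table::as.IDate(c(NA, "2010-06-30")))
  diagnoses <- data.table::data.table(
    person_id = c("A1", "A1", "B2"),
    icd10_code = c("I109", "F001", "E119"),
    service_date = data.table::as.IDate(
      c("2005-03-01", "2006-03-01", "2004-07-15")),
    setting = c("outpatient", "outpatient", "inpatient"))
  prescriptions <- data.table::data.table(
    person_id = c("A1", "B2"),
    drug_code = c("D001", "C001"),
    dispense_date = data.table::as.IDate(c("2005-01-01", "2004-01-01")),
    days_supplied = c(30L, 90L),
    ingredient_count = c(1L, 2L))
  list(persons = persons, diagnoses = diagnoses,
       prescriptions = prescriptions)
}

# Random single-person prescription sets around a fixed index date.
random_rx_set <- function(n_rx, index_date = as.Date("2010-06-15"),
                          config) {
  codes <- c(sprintf("D%03d", 1:6), "C001", "C002", "BZS01", "ACH01",
             "H2R01")
  idx <- as.integer(data.table::as.IDate(index_date))
  drug_code <- sample(codes, n_rx, replace = TRUE)
  # ingredient count is a property of the product, constant per code
  data.table::data.table(
    person_id = "X",
    drug_code = drug_code,
    dispense_date = data.table::as.IDate(
      idx - sample.int(900L, n_rx, replace = TRUE),
      origin = "1970-01-01"),
    days_supplied = sample.int(180L, n_rx, replace = TRUE),
    ingredient_count = data.table::fcase(drug_code == "C001", 2L,
                                         drug_code == "C002", 3L,
                                         default = 1L))
}

# codeset config with the synthetic drug dictionary attached
test_codesets <- function() {
  dict <- polydem:::synthetic_drug_dictionary(simulation_config(1L))
  default_codesets(pim_class_map = dict$pim_class_map,
                   combo_codes = dict$combo)
}
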