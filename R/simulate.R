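#' Simulation configuration for synthetic claims
#'
#' Defines every distributional choice of the synthetic claims generator:
#' demographics of an elderly (65-95 at baseline) insured population followed
#' over twelve calendar years, comorbidity prevalences, a prescription
#' process (chronic drug regimens realised as back-to-back refill episodes,
#' combination antihypertensive/antidiabetic products with 2-3 active
#' ingredients, chronic and intermittent PIM use, short acute scripts), and a
#' discrete-time outcome model: in each calendar year from
#' `case_window_start` onward, an at-risk person develops dementia with
#' probability `plogis(intercept + X beta)` where the covariates are the
#' person's polypharmacy category (from the stationary chronic drug count),
#' PIM any-use flags and comorbidity flags, plus optional
#' polypharmacy-by-covariate interaction products.
#'
#' Chronic regimens are generated with gap-free refill coverage from
#' `rx_start_year` to the end of enrollment, so the average daily drug count
#' over any look-back window equals the latent chronic count up to a small
#' fractional contribution from intermittent/acute scripts; the configured
#' odds ratios are therefore the exact estimands of the downstream analysis.
#'
#' @param n_persons number of enrollees.
#' @param outcome_model list with `intercept` (per-year logit for the
#'   reference group), `or_poly` (odds ratios for categories `one_to_lt5`,
#'   `five_to_lt10`, `ge10` vs `lt1`), `or_pim` (per-PIM-class any-use ORs),
#'   `or_comorbidity` (per-group ORs) and `interactions` (named log-OR
#'   products polypharmacy-flag x comorbidity group).
#' @param comorbidity_prevalence named per-group probabilities; defaults sit
#'   inside the control-arm ranges of a large elderly claims population.
#' @param prescription_process list of prescription-process parameters; see
#'   the source of `simulation_config` for fields and defaults.
#' @param female_share,income_weights,age_weights demographic sampling
#'   weights.
#' @param mortality_annual per-year death probability.
#' @param prevalent_dementia_frac fraction with dementia codes already during
#'   the washout years (exercises the incident-case rule).
#' @param hospitalization_rate fraction with an inpatient claim at some time
#'   (such persons are excluded by the community-dwelling rule once the claim
#'   precedes the index date).
#' @param subtype_probs probabilities of Alzheimer / other-cause / mixed
#'   dementia codes among cases.
#' @param benign_visit_rate outpatient visits per person-year with a neutral
#'   code (ensures the outpatient-utilisation rule is mostly met).
#' @param comorbidity_claim_rate claims per flagged comorbidity group per
#'   year.
#' @param study_start,study_end,case_window_start,rx_start_year calendar
#'   bounds.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(
    n_persons = 10000L,
    outcome_model = list(),
    comorbidity_prevalence = NULL,
    prescription_process = list(),
    female_share = 0.718,
    income_weights = c(0.08, rep(0.092, 10)),
    age_weights = exp(-0.10 * (0:30)),
    mortality_annual = 0.045,
    prevalent_dementia_frac = 0.02,
    hospitalization_rate = 0.08,
    subtype_probs = c(alzheimer = 0.331, other_cause = 0.385, mixed = 0.284),
    benign_visit_rate = 3,
    comorbidity_claim_rate = 1.2,
    study_start = 2002L, study_end = 2013L,
    case_window_start = 2005L, rx_start_year = 2003L) {

  default_prev <- c(
    mi = 0.015, chf = 0.07, pvd = 0.18, cerebrovascular = 0.14,
    copd = 0.28, rheumatic = 0.04, pud = 0.25, mild_liver = 0.16,
    diabetes = 0.20, diabetes_complicated = 0.08, hemiplegia = 0.015,
    renal = 0.012, cancer = 0.06, severe_liver = 0.004, metastatic = 0.006,
    aids = 0.0005, hypertension = 0.55, depression = 0.09, delirium = 0.004,
    alcohol = 0.005, psychotic = 0.008, other_mental = 0.28)
  prev <- default_prev
  if (!is.null(comorbidity_prevalence)) {
    stopifnot(all(names(comorbidity_prevalence) %in% names(prev)))
    prev[names(comorbidity_prevalence)] <- comorbidity_prevalence
  }
  stopifnot(all(prev >= 0 & prev <= 1))

  rx_default <- list(
    slot_mu = 1.55, slot_size = 1.25, max_slots = 14L,
    combo_fraction = 0.10, combo_codes_three_ingredient = 0.25,
    refill_min = 60L, refill_max = 120L,
    overlap_fraction = 0.30, overlap_days = 10L,
    acute_rate = 0.4, acute_min = 7L, acute_max = 30L,
    pim_any = c(bzd_short_intermediate = 0.21, bzd_long = 0.23,
                bzd_receptor_agonist = 0.05, anticholinergic = 0.44,
                h2ra = 0.47),
    pim_heavy = c(bzd_short_intermediate = 0.10, bzd_long = 0.05,
                  bzd_receptor_agonist = 0.05, anticholinergic = 0.05,
                  h2ra = 0.05),
    pim_episodes_min = 1L, pim_episodes_max = 2L,
    pim_ep_min = 7L, pim_ep_max = 20L)
  rx <- utils::modifyList(rx_default, prescription_process)
  stopifnot(rx$refill_min >= 1, rx$acute_min >= 1, rx$pim_ep_min >= 1)

  om_default <- list(
    intercept = -6.4,
    or_poly = c(one_to_lt5 = 1.72, five_to_lt10 = 2.64, ge10 = 3.35),
    or_pim = c(bzd_short_intermediate = 1.25, bzd_long = 1.10,
               bzd_receptor_agonist = 1.40, anticholinergic = 1.25,
               h2ra = 1.15),
    or_comorbidity = c(
      mi = 1.9, chf = 1.8, pvd = 2.0, cerebrovascular = 4.5, copd = 1.5,
      rheumatic = 2.0, pud = 1.6, mild_liver = 1.7, diabetes = 1.8,
      diabetes_complicated = 1.8, hemiplegia = 5.0, renal = 1.7,
      cancer = 1.7, severe_liver = 2.5, metastatic = 1.4, aids = 2.0,
      hypertension = 2.0, depression = 3.2, delirium = 10.0, alcohol = 4.0,
      psychotic = 12.0, other_mental = 2.6),
    interactions = numeric())
  om <- utils::modifyList(om_default, outcome_model)
  stopifnot(all(om$or_poly > 0), all(om$or_pim > 0),
            all(om$or_comorbidity > 0))

  structure(list(
    n_persons = as.integer(n_persons),
    outcome_model = om, comorbidity_prevalence = prev,
    prescription_process = rx, female_share = female_share,
    income_weights = income_weights, age_weights = age_weights,
    mortality_annual = mortality_annual,
    prevalent_dementia_frac = prevalent_dementia_frac,
    hospitalization_rate = hospitalization_rate,
    subtype_probs = subtype_probs,
    benign_visit_rate = benign_visit_rate,
    comorbidity_claim_rate = comorbidity_claim_rate,
    study_start = as.integer(study_start), study_end = as.integer(study_end),
    case_window_start = as.integer(case_window_start),
    rx_start_year = as.integer(rx_start_year)
  ), class = "sim_config")
}

# Synthetic drug dictionary: tokens pre-labelled with PIM class, combination
# status and ingredient count (the real national dictionary is proprietary).
synthetic_drug_dictionary <- function(config) {
  rx <- config$prescription_process
  combo <- sprintf("C%03d", seq_len(24L))
  n3 <- round(length(combo) * rx$combo_codes_three_ingredient)
  combo_ing <- c(rep(3L, n3), rep(2L, length(combo) - n3))
  pim_pools <- list(
    bzd_short_intermediate = sprintf("BZS%02d", 1:6),
    bzd_long = sprintf("BZL%02d", 1:5),
    bzd_receptor_agonist = sprintf("BZA%02d", 1:4),
    anticholinergic = sprintf("ACH%02d", 1:10),
    h2ra = sprintf("H2R%02d", 1:6))
  pim_map <- unlist(lapply(names(pim_pools), function(cl)
    setNames(rep(cl, length(pim_pools[[cl]])), pim_pools[[cl]])))
  list(plain = sprintf("D%03d", seq_len(300L)),
       combo = combo, combo_ingredients = setNames(combo_ing, combo),
       acute = sprintf("A%03d", seq_len(60L)),
       pim_pools = pim_pools,
       pim_class_map = pim_map)
}

# Codes emitted for each simulated comorbidity group, chosen so each code
# matches exactly its own group in the default code sets (groups may overlap
# in real dictionaries; keeping them disjoint here makes latent flags
# recoverable).
.sim_group_codes <- list(
  mi = c("I210", "I220"), chf = c("I500", "I509", "I430"),
  pvd = c("I700", "I710"), cerebrovascular = c("I630", "I640", "I650"),
  copd = c("J440", "J449", "J429"), rheumatic = c("M050", "M060"),
  pud = c("K250", "K269"), mild_liver = c("K740", "K739"),
  diabetes = c("E119", "E110", "E109"),
  diabetes_complicated = c("E112", "E113"), hemiplegia = c("G810", "G820"),
  renal = c("N180", "N189"), cancer = c("C349", "C169"),
  severe_liver = c("K721", "I850"), metastatic = c("C780", "C795"),
  aids = c("B200", "B210"), hypertension = c("I100", "I109"),
  depression = c("F320", "F329", "F331"), delirium = "F0500",
  alcohol = c("F101", "F102"), psychotic = c("F200", "F209", "F250"),
  other_mental = c("F410", "F412", "F432"))

.sim_ad_codes <- c("F000", "F009", "G300", "G309")
.sim_other_codes <- c("F010", "F019", "F030", "F020", "F0510", "G3110")

# Integer day number of Jan 1 for years 1990-2030 (avoids string parsing on
# million-row vectors).
.year_start <- local({
  yrs <- 1990:2030
  setNames(as.integer(data.table::as.IDate(sprintf("%d-01-01", yrs))), yrs)
})

year_start_date <- function(year)
  data.table::as.IDate(unname(.year_start[as.character(year)]))

rand_day_in_year <- function(year) {
  year_start_date(year) + sample.int(365L, length(year), replace = TRUE) - 1L
}

#' Generate synthetic claims tables with known truth
#'
#' Draws a complete synthetic claims extract (persons, diagnoses,
#' prescriptions) plus a truth record holding each person's latent
#' covariates, chronic drug count, outcome assignment and dementia subtype.
#' The truth record is for validation only and is never read by the analysis
#' stages. Identical seeds give identical output.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed fixing every draw.
#' @return list with `persons`, `diagnoses`, `prescriptions` (claims tables,
#'   see [claims-schemas]), `truth` (one row per person), `codesets` (a
#'   [codeset_config()] carrying the synthetic drug dictionary) and `config`.
#' @export
simulate_claims <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_claims_impl(config))
}

simulate_claims_impl <- function(config) {
  n <- config$n_persons
  dict <- synthetic_drug_dictionary(config)
  codesets <- default_codesets(pim_class_map = dict$pim_class_map,
                               combo_codes = dict$combo)
  empty <- function() list(
    persons = data.table(person_id = character(), birth_year = integer(),
                         sex = character(), income_index = integer(),
                         enroll_start = as_idate(character()),
                         enroll_end = as_idate(character()),
                         death_date = as_idate(character())),
    diagnoses = data.table(person_id = character(), icd10_code = character(),
                           service_date = as_idate(character()),
                           setting = character()),
    prescriptions = data.table(person_id = character(),
                               drug_code = character(),
                               dispense_date = as_idate(character()),
                               days_supplied = integer(),
                               ingredient_count = integer()),
    truth = data.table(person_id = character()),
    codesets = codesets, config = config)
  if (n == 0L) return(empty())

  om <- config$outcome_model
  rx <- config$prescription_process
  y0 <- config$study_start
  yN <- config$study_end
  end_of_study <- data.table::as.IDate(sprintf("%d-12-31", yN))

  ## ---- persons -------------------------------------------------------------
  ages <- sample(65:95, n, replace = TRUE, prob = config$age_weights)
  persons <- data.table(
    person_id = sprintf("P%06d", seq_len(n)),
    birth_year = y0 - ages,
    sex = ifelse(runif(n) < config$female_share, "female", "male"),
    income_index = sample(0:10, n, replace = TRUE,
                          prob = config$income_weights),
    enroll_start = data.table::as.IDate(sprintf("%d-01-01", y0)))
  death_offset <- rgeom_years(n, config$mortality_annual)
  death_year <- y0 + death_offset
  has_death <- death_year <= yN
  persons[, death_date := data.table::as.IDate(NA)]
  persons[has_death, death_date := rand_day_in_year(death_year[has_death])]
  persons[, enroll_end := pmin(data.table::fifelse(is.na(death_date),
                                                   end_of_study, death_date),
                               end_of_study)]

  ## ---- latent covariates ---------------------------------------------------
  groups <- names(config$comorbidity_prevalence)
  com <- vapply(groups, function(g)
    runif(n) < config$comorbidity_prevalence[[g]], logical(n))
  if (is.null(dim(com))) com <- matrix(com, nrow = n,
                                       dimnames = list(NULL, groups))

  classes <- names(rx$pim_any)
  pim_user <- vapply(classes, function(cl) runif(n) < rx$pim_any[[cl]],
                     logical(n))
  if (is.null(dim(pim_user))) pim_user <- matrix(pim_user, nrow = n,
                                                 dimnames = list(NULL, classes))
  pim_heavy <- vapply(classes, function(cl)
    pim_user[, cl] & runif(n) < rx$pim_heavy[[cl]], logical(n))
  if (is.null(dim(pim_heavy))) pim_heavy <- matrix(pim_heavy, nrow = n,
                                                   dimnames = list(NULL, classes))

  ## ---- chronic regimen (slots, dedup within person) ------------------------
  n_slots <- pmin(rnbinom(n, size = rx$slot_size, mu = rx$slot_mu),
                  rx$max_slots)
  slot <- data.table(pidx = rep(seq_len(n), n_slots))
  if (nrow(slot)) {
    slot[, is_combo := runif(.N) < rx$combo_fraction]
    slot[, drug_code := data.table::fifelse(
      is_combo, sample(dict$combo, .N, replace = TRUE),
      sample(dict$plain, .N, replace = TRUE))]
    slot <- unique(slot, by = c("pidx", "drug_code"))
    slot[, weight := data.table::fifelse(
      is_combo, as.numeric(dict$combo_ingredients[drug_code]), 1)]
  } else slot[, `:=`(is_combo = logical(), drug_code = character(),
                     weight = numeric())]
  # chronic PIM slots (at most one per class per person)
  heavy_idx <- which(pim_heavy, arr.ind = TRUE)
  if (length(heavy_idx)) {
    pim_slot <- data.table(pidx = heavy_idx[, 1],
                           class = classes[heavy_idx[, 2]])
    pim_slot[, drug_code := vapply(class, function(cl)
      sample(dict$pim_pools[[cl]], 1L), character(1))]
    pim_slot[, `:=`(is_combo = FALSE, weight = 1)]
    slot <- rbind(slot, pim_slot[, .(pidx, is_combo, drug_code, weight)])
  }
  c_chronic <- rep(0, n)
  if (nrow(slot)) {
    agg <- slot[, .(w = sum(weight)), by = pidx]
    c_chronic[agg$pidx] <- agg$w
  }
  cat_true <- categorize_polypharmacy(c_chronic)
  pp_flag <- c_chronic >= 5

  ## ---- outcome model (discrete yearly hazard) ------------------------------
  beta_cat <- c(lt1 = 0, log(om$or_poly))
  lp <- om$intercept + beta_cat[as.character(cat_true)]
  for (cl in classes) lp <- lp + log(om$or_pim[[cl]]) * pim_user[, cl]
  for (g in groups) lp <- lp + log(om$or_comorbidity[[g]]) * com[, g]
  if (length(om$interactions))
    for (g in names(om$interactions))
      lp <- lp + om$interactions[[g]] * pp_flag * com[, g]
  p_year <- plogis(unname(lp))

  prevalent <- runif(n) < config$prevalent_dementia_frac
  event_year <- rep(NA_integer_, n)
  index_date <- data.table::as.IDate(rep(NA_integer_, n))
  at_risk <- !prevalent
  for (y in config$case_window_start:yN) {
    alive <- is.na(persons$death_date) | death_year > y
    idx <- which(at_risk & alive)
    if (!length(idx)) next
    ev <- idx[runif(length(idx)) < p_year[idx]]
    if (length(ev)) {
      d <- rand_day_in_year(rep(y, length(ev)))
      ok <- is.na(persons$death_date[ev]) | d < persons$death_date[ev]
      ev <- ev[ok]; d <- d[ok]
      event_year[ev] <- y
      index_date[ev] <- d
      at_risk[ev] <- FALSE
    }
  }
  is_case_truth <- !is.na(event_year)
  subtype <- rep(NA_character_, n)
  n_dem <- sum(is_case_truth)
  if (n_dem)
    subtype[is_case_truth] <- sample(names(config$subtype_probs), n_dem,
                                     replace = TRUE,
                                     prob = config$subtype_probs)

  hospitalized <- runif(n) < config$hospitalization_rate

  ## ---- diagnoses -----------------------------------------------------------
  last_year <- pmin(yN, data.table::year(persons$enroll_end))
  py <- data.table(pidx = rep(seq_len(n), last_year - y0 + 1L))
  py[, year := (y0:yN)[data.table::rowid(pidx)]]

  dx_list <- list()
  # benign outpatient visits
  nv <- rpois(nrow(py), config$benign_visit_rate)
  ben <- py[rep(seq_len(.N), nv)]
  if (nrow(ben)) {
    ben[, `:=`(icd10_code = "Z000",
               service_date = rand_day_in_year(year), setting = "outpatient")]
    dx_list$benign <- ben[, .(pidx, icd10_code, service_date, setting)]
  }
  # comorbidity claims (flagged groups, yearly Poisson)
  for (g in groups) {
    sub <- py[com[pidx, g]]
    if (!nrow(sub)) next
    k <- rpois(nrow(sub), config$comorbidity_claim_rate)
    sub <- sub[rep(seq_len(.N), k)]
    if (!nrow(sub)) next
    pool <- .sim_group_codes[[g]]
    sub[, `:=`(icd10_code = sample(pool, .N, replace = TRUE),
               service_date = rand_day_in_year(year), setting = "outpatient")]
    dx_list[[g]] <- sub[, .(pidx, icd10_code, service_date, setting)]
  }
  # dementia claims for incident cases
  if (n_dem) {
    ci <- which(is_case_truth)
    first_pool <- ifelse(subtype[ci] == "other_cause",
                         sample(.sim_other_codes, n_dem, replace = TRUE),
                         sample(.sim_ad_codes, n_dem, replace = TRUE))
    dem1 <- data.table(pidx = ci, icd10_code = first_pool,
                       service_date = index_date[ci], setting = "outpatient")
    n_extra <- sample(1:3, n_dem, replace = TRUE)
    ext <- data.table(pidx = rep(ci, n_extra),
                      subtype = rep(subtype[ci], n_extra),
                      base = rep(index_date[ci], n_extra),
                      end = rep(persons$enroll_end[ci], n_extra))
    ext[, service_date := pmin(base + sample.int(540L, .N, replace = TRUE),
                               end)]
    ext[, icd10_code := data.table::fcase(
      subtype == "alzheimer", sample(.sim_ad_codes, .N, replace = TRUE),
      subtype == "other_cause", sample(.sim_other_codes, .N, replace = TRUE),
      default = sample(.sim_other_codes, .N, replace = TRUE))]
    ext[, setting := "outpatient"]
    dx_list$dementia <- rbind(dem1,
                              ext[, .(pidx, icd10_code, service_date, setting)])
  }
  # prevalent dementia codes during the washout years
  if (any(prevalent)) {
    pv <- which(prevalent)
    yr <- sample(y0:(config$case_window_start - 1L), length(pv),
                 replace = TRUE)
    dx_list$prevalent <- data.table(
      pidx = pv,
      icd10_code = sample(c(.sim_ad_codes, .sim_other_codes), length(pv),
                          replace = TRUE),
      service_date = pmin(rand_day_in_year(yr), persons$enroll_end[pv]),
      setting = "outpatient")
  }
  # hospitalizations (any-cause inpatient claims)
  if (any(hospitalized)) {
    hi <- which(hospitalized)
    yr <- pmin(sample(y0:yN, length(hi), replace = TRUE), last_year[hi])
    dx_list$inpatient <- data.table(
      pidx = hi, icd10_code = "Z000",
      service_date = pmin(rand_day_in_year(yr), persons$enroll_end[hi]),
      setting = "inpatient")
  }
  diagnoses <- data.table::rbindlist(dx_list, use.names = TRUE)
  diagnoses[, person_id := persons$person_id[pidx]]
  diagnoses[, pidx := NULL]
  data.table::setcolorder(diagnoses, .diagnosis_cols)

  ## ---- prescriptions -------------------------------------------------------
  rx_start <- data.table::as.IDate(sprintf("%d-01-01", config$rx_start_year))
  rx_list <- list()
  if (nrow(slot)) {
    sl <- copy(slot)
    sl[, span_end := persons$enroll_end[pidx]]
    sl <- sl[span_end > rx_start]
    sl[, len := sample(rx$refill_min:rx$refill_max, .N, replace = TRUE)]
    sl[, step := data.table::fifelse(runif(.N) < rx$overlap_fraction,
                                     len - rx$overlap_days, as.integer(len))]
    sl[, n_refill := as.integer(floor(as.numeric(span_end - rx_start) / step) + 1L)]
    chron <- sl[rep(seq_len(.N), n_refill)]
    chron[, offset := (sequence(sl$n_refill) - 1L) * step]
    chron[, dispense_date := rx_start + offset]
    chron <- chron[dispense_date <= span_end]
    chron[, days_supplied := pmin(len, as.integer(span_end - dispense_date) + 1L)]
    rx_list$chronic <- chron[, .(pidx, drug_code, dispense_date, days_supplied)]
  }
  # intermittent PIM episodes: fixed per person-class yearly pattern
  int_idx <- which(pim_user & !pim_heavy, arr.ind = TRUE)
  if (length(int_idx)) {
    ip <- data.table(pidx = int_idx[, 1], class = classes[int_idx[, 2]])
    ip[, drug_code := vapply(class, function(cl)
      sample(dict$pim_pools[[cl]], 1L), character(1))]
    ip[, n_ep := sample(rx$pim_episodes_min:rx$pim_episodes_max, .N,
                        replace = TRUE)]
    ip[, ep_len := sample(rx$pim_ep_min:rx$pim_ep_max, .N, replace = TRUE)]
    ip[, span_end := persons$enroll_end[pidx]]
    ep <- ip[rep(seq_len(.N), n_ep)]
    ep[, doy := sample.int(330L, .N, replace = TRUE)]  # fixed day-of-year
    yrs <- config$rx_start_year:yN
    ep <- ep[rep(seq_len(.N), each = length(yrs))]
    ep[, year := rep(yrs, length.out = .N)]
    ep[, dispense_date := year_start_date(year) + doy]
    ep <- ep[dispense_date <= span_end]
    ep[, days_supplied := pmin(ep_len,
                               as.integer(span_end - dispense_date) + 1L)]
    rx_list$pim <- ep[, .(pidx, drug_code, dispense_date, days_supplied)]
  }
  # acute short scripts
  yrs_alive <- pmax(last_year - config$rx_start_year + 1L, 0L)
  n_acute <- rpois(n, rx$acute_rate * yrs_alive)
  if (sum(n_acute)) {
    ac <- data.table(pidx = rep(seq_len(n), n_acute))
    ac[, span_end := persons$enroll_end[pidx]]
    ac[, span_days := as.integer(span_end - rx_start)]
    ac <- ac[span_days > 0]
    ac[, dispense_date := rx_start +
         floor(runif(.N) * (span_days + 1L))]
    ac[, drug_code := sample(dict$acute, .N, replace = TRUE)]
    ac[, days_supplied := pmin(sample(rx$acute_min:rx$acute_max, .N,
                                      replace = TRUE),
                               as.integer(span_end - dispense_date) + 1L)]
    rx_list$acute <- ac[, .(pidx, drug_code, dispense_date, days_supplied)]
  }
  prescriptions <- data.table::rbindlist(rx_list, use.names = TRUE)
  if (nrow(prescriptions)) {
    prescriptions[, person_id := persons$person_id[pidx]]
    prescriptions[, ingredient_count := 1L]
    has_ing <- prescriptions$drug_code %in% dict$combo
    prescriptions[has_ing,
                  ingredient_count := dict$combo_ingredients[drug_code]]
    prescriptions[, pidx := NULL]
  } else {
    prescriptions <- data.table(person_id = character(),
                                drug_code = character(),
                                dispense_date = as_idate(character()),
                                days_supplied = integer(),
                                ingredient_count = integer())
  }
  data.table::setcolorder(prescriptions, .prescription_cols)

  ## ---- truth record --------------------------------------------------------
  truth <- data.table(
    person_id = persons$person_id,
    c_chronic = c_chronic,
    category_true = cat_true,
    polypharmacy_true = pp_flag,
    lp = unname(lp), p_year = p_year,
    event_year = event_year, index_date = index_date,
    subtype = subtype, prevalent = prevalent, hospitalized = hospitalized)
  for (cl in classes) truth[, (paste0("pim_", cl)) := pim_user[, cl]]
  for (g in groups) truth[, (paste0("com_", g)) := com[, g]]

  data.table::setkey(diagnoses, person_id, service_date, icd10_code)
  data.table::setkey(prescriptions, person_id, dispense_date, drug_code)
  list(persons = persons[, .SD, .SDcols = .person_cols],
       diagnoses = diagnoses, prescriptions = prescriptions,
       truth = truth, codesets = codesets, config = config)
}

# Geometric years-to-death with annual hazard p (0 = dies in first year);
# a zero hazard means nobody dies during the study.
rgeom_years <- function(n, p) if (p <= 0) rep(Inf, n) else rgeom(n, p)

#' Synthetic claims with documented population defaults
#'
#' Convenience wrapper around [simulate_claims()] whose defaults target the
#' descriptive ranges reported for a large elderly claims population:
#' comorbidity prevalences between the control-arm and case-arm values (e.g.
#' hypertension between 48.6% and 66.6%), a mean average daily drug count
#' between the control mean 1.75 and the case mean 2.54, 71.8% women, and
#' polypharmacy odds ratios of 1.72 / 2.64 / 3.35 for the 1-<5 / 5-<10 / >=10
#' categories. See the package vignette for each default's provenance.
#'
#' @param n_persons number of enrollees.
#' @param seed integer seed.
#' @param ... overrides passed to [simulation_config()].
#' @return same structure as [simulate_claims()].
#' @export
simulate_from_table1_defaults <- function(n_persons, seed = 1L, ...) {
  simulate_claims(simulation_config(n_persons = n_persons, ...), seed = seed)
}
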