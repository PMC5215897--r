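#' Look-back window before an index date
#'
#' The exposure window is the fixed 730-day period before the index date.
#' For prescriptions the window is the half-open interval
#' `[index - 730, index)`; diagnoses additionally include the index date
#' itself, so a case's own dementia claim is visible to the comorbidity
#' profile.
#'
#' @param index_date index date (case diagnosis date, shared by the matched
#'   control).
#' @param days window length in days (default 730).
#' @return list with `start`, `end` (exclusive for drugs), `index`, `length`.
#' @export
lookback_window <- function(index_date, days = 730L) {
  index_date <- as_idate(index_date)
  list(start = index_date - as.integer(days), end = index_date,
       index = index_date, length = as.integer(days))
}

#' Polypharmacy categories from the average daily drug count
#'
#' Half-open binning with inclusive lower bounds: `lt1` (< 1),
#' `one_to_lt5` (1 to < 5), `five_to_lt10` (5 to < 10), `ge10` (>= 10).
#' An average of exactly 5 is polypharmacy.
#'
#' @param avg_daily_drugs nonnegative numeric vector.
#' @return factor with the four category levels.
#' @export
categorize_polypharmacy <- function(avg_daily_drugs) {
  if (any(is.na(avg_daily_drugs)) || any(avg_daily_drugs < 0))
    stop("avg_daily_drugs must be nonnegative")
  cut(avg_daily_drugs, breaks = c(-Inf, 1, 5, 10, Inf), right = FALSE,
      labels = c("lt1", "one_to_lt5", "five_to_lt10", "ge10"))
}

#' @rdname categorize_polypharmacy
#' @export
polypharmacy_levels <- c("lt1", "one_to_lt5", "five_to_lt10", "ge10")

# Union length of half-open integer-day intervals per group.
# dt: data.table(gid, start, end) with end exclusive; returns (gid, days).
interval_union_days <- function(dt) {
  dt <- dt[end > start]
  if (!nrow(dt)) return(data.table(gid = dt$gid[0], days = integer()))
  data.table::setorder(dt, gid, start, end)
  dt[, run_end := cummax(as.integer(end)), by = gid]
  dt[, island := cumsum(
    start > data.table::shift(run_end, fill = -.Machine$integer.max)),
    by = gid]
  isl <- dt[, .(s = min(start), e = max(run_end)), by = .(gid, island)]
  isl[, .(days = sum(e - s)), by = gid]
}

# Shared engine: one row of `cohort` per (person, index_date) pair.
# Returns per-row drug-day sums and per-class covered days.
sweep_prescriptions <- function(cohort, prescriptions, config,
                                window_days = 730L) {
  rx <- prescriptions[cohort[, .(row_id, person_id, index_date)],
                      on = "person_id", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(rx))
    return(list(drug_days = data.table(row_id = integer(), drug_days = numeric()),
                class_days = data.table(row_id = integer(), class = character(),
                                        days = integer())))
  rx[, win_start := index_date - as.integer(window_days)]
  rx[, start := pmax(as.integer(dispense_date), as.integer(win_start))]
  rx[, end := pmin(as.integer(dispense_date) + days_supplied,
                   as.integer(index_date))]
  rx <- rx[end > start]
  if (!nrow(rx))
    return(list(drug_days = data.table(row_id = integer(),
                                       drug_days = numeric()),
                class_days = data.table(row_id = integer(),
                                        class = character(),
                                        days = integer())))
  # distinct drug codes per day: union per (row, code), then weight
  rx[, gid := .GRP, by = .(row_id, drug_code)]
  key <- unique(rx[, .(gid, row_id, drug_code, ingredient_count)],
                by = "gid")[order(gid)]
  key <- key[, .(row_id = row_id[1], drug_code = drug_code[1],
                 ingredient_count = max(ingredient_count)), by = gid]
  u <- interval_union_days(rx[, .(gid, start, end)])
  u <- key[u, on = "gid"]
  u[, weight := data.table::fifelse(drug_code %in% config$combo_codes,
                                    as.numeric(ingredient_count), 1)]
  drug_days <- u[, .(drug_days = sum(weight * days)), by = row_id]
  # PIM class coverage: union per (row, class) across codes of the class
  cls <- config$pim_class_map
  rx[, class := "none"]
  if (length(cls)) {
    mapped <- cls[rx$drug_code]
    rx[!is.na(mapped), class := mapped[!is.na(mapped)]]
  }
  rxc <- rx[class != "none"]
  if (nrow(rxc)) {
    rxc[, gid := .GRP, by = .(row_id, class)]
    keyc <- unique(rxc[, .(gid, row_id, class)], by = "gid")
    uc <- interval_union_days(rxc[, .(gid, start, end)])
    class_days <- keyc[uc, on = "gid"][, .(row_id, class, days)]
  } else {
    class_days <- data.table(row_id = integer(), class = character(),
                             days = integer())
  }
  list(drug_days = drug_days, class_days = class_days)
}

#' Average daily prescribed drug count over the look-back window
#'
#' Sums, over every day of the 730-day look-back window, the number of
#' distinct drug codes with an active prescription on that day (a
#' prescription covers `[dispense_date, dispense_date + days_supplied)`,
#' clipped to the window; simultaneous prescriptions of one code count once),
#' and divides by 730. Combination antihypertensive/antidiabetic codes
#' (listed in `config$combo_codes`) contribute their active-ingredient count
#' instead of 1. Implemented as an interval sweep, not per-day enumeration.
#'
#' @param prescriptions prescription rows of one person.
#' @param window a [lookback_window()].
#' @param config a [codeset_config()] (supplies combo codes).
#' @return nonnegative scalar.
#' @export
average_daily_drug_count <- function(prescriptions, window, config) {
  cohort <- data.table(row_id = 1L, person_id = "self",
                       index_date = window$end)
  rx <- copy(as.data.table(prescriptions))
  rx[, person_id := "self"]
  sw <- sweep_prescriptions(cohort, rx, config, window$length)
  if (!nrow(sw$drug_days)) return(0)
  sw$drug_days$drug_days[1] / window$length
}

#' Medication possession ratio for one PIM class
#'
#' Percentage of look-back days covered by at least one prescription of the
#' class; overlapping same-class prescriptions count each day once.
#'
#' @param prescriptions prescription rows of one person.
#' @param pim_class one of the configured PIM classes.
#' @param window a [lookback_window()].
#' @param config a [codeset_config()] with `pim_class_map`.
#' @return percent in \[0, 100\].
#' @export
compute_mpr <- function(prescriptions, pim_class, window, config) {
  if (!pim_class %in% config$pim_classes)
    stop("unknown PIM class: ", pim_class)
  cohort <- data.table(row_id = 1L, person_id = "self",
                       index_date = window$end)
  rx <- copy(as.data.table(prescriptions))
  rx[, person_id := "self"]
  sw <- sweep_prescriptions(cohort, rx, config, window$length)
  d <- sw$class_days[class == pim_class]
  if (!nrow(d)) return(0)
  100 * d$days[1] / window$length
}

#' Bin an MPR value / binary any-use indicator
#'
#' `bin_mpr` maps an MPR percentage to the strata `zero` (exactly 0),
#' `gt0_lt50` (> 0 and < 50) and `ge50_le100` (50 to 100). `pim_any` is the
#' binary any-use collapse (MPR > 0).
#'
#' @param mpr numeric vector in \[0, 100\].
#' @return factor (`bin_mpr`) or logical (`pim_any`).
#' @export
bin_mpr <- function(mpr) {
  if (any(is.na(mpr)) || any(mpr < 0 | mpr > 100))
    stop("mpr must lie in [0, 100]")
  factor(data.table::fcase(mpr == 0, "zero",
                           mpr < 50, "gt0_lt50",
                           default = "ge50_le100"),
         levels = c("zero", "gt0_lt50", "ge50_le100"))
}

#' @rdname bin_mpr
#' @export
pim_any <- function(mpr) {
  if (any(is.na(mpr)) || any(mpr < 0 | mpr > 100))
    stop("mpr must lie in [0, 100]")
  mpr > 0
}

#' Comorbidity flags and Charlson score over the look-back window
#'
#' Flags each configured comorbidity group when at least one claim in the
#' window (index date inclusive) carries a matching ICD-10 code, and sums the
#' Charlson weights over the flagged weighted groups.
#'
#' @param diagnoses diagnosis rows of one person.
#' @param window a [lookback_window()]; claims with
#'   `start <= service_date <= index` are considered.
#' @param config a [codeset_config()].
#' @return list with `flags` (named logical) and `cci_score` (integer).
#' @export
comorbidity_profile <- function(diagnoses, window, config) {
  dx <- as.data.table(diagnoses)
  dx <- dx[service_date >= window$start & service_date <= window$index]
  flags <- setNames(rep(FALSE, length(config$comorbidity_map)),
                    names(config$comorbidity_map))
  if (nrow(dx)) {
    m <- match_code_groups(dx$icd10_code, config$comorbidity_map)
    flags <- apply(m, 2, any)
  }
  score <- sum(config$cci_weights[flags[names(config$cci_weights)]])
  list(flags = flags, cci_score = as.integer(score))
}

#' Derive the full exposure profile for every cohort member
#'
#' Computes, for each (person, index date) row of the cohort, the average
#' daily drug count and polypharmacy category, per-PIM-class MPR with binned
#' and any-use versions, comorbidity flags and the Charlson score, all over
#' the 2-year look-back window.
#'
#' @param cohort data.frame with columns `person_id` and `index_date` (one
#'   row per subject; e.g. cases and controls from [select_controls()]
#'   stacked).
#' @param prescriptions,diagnoses full claims tables.
#' @param config a [codeset_config()].
#' @param window_days look-back length (default 730).
#' @param include_comorbidities set FALSE to skip the diagnosis scan (drug
#'   exposures only; used by simulation harnesses that only need the
#'   polypharmacy variables).
#' @return data.table with one row per cohort row: `avg_daily_drugs`,
#'   `polypharmacy_category`, `polypharmacy_flag`, `mpr_<class>`,
#'   `mpr_bin_<class>`, `pim_any_<class>`, `com_<group>`, `cci_score`.
#' @export
derive_exposures <- function(cohort, prescriptions, diagnoses, config,
                             window_days = 730L,
                             include_comorbidities = TRUE) {
  cohort <- as.data.table(cohort)
  stopifnot(all(c("person_id", "index_date") %in% names(cohort)))
  out <- copy(cohort)
  out[, row_id := .I]
  out[, index_date := as_idate(index_date)]

  sw <- sweep_prescriptions(out[, .(row_id, person_id, index_date)],
                            as.data.table(prescriptions), config, window_days)
  out[, avg_daily_drugs := 0]
  if (nrow(sw$drug_days))
    out[sw$drug_days, avg_daily_drugs := i.drug_days / window_days,
        on = "row_id"]
  out[, polypharmacy_category := categorize_polypharmacy(avg_daily_drugs)]
  out[, polypharmacy_flag := avg_daily_drugs >= 5]

  for (cl in config$pim_classes) {
    mcol <- paste0("mpr_", cl)
    out[, (mcol) := 0]
    d <- sw$class_days[class == cl]
    if (nrow(d))
      out[d, (mcol) := pmin(100, 100 * i.days / window_days), on = "row_id"]
    out[, (paste0("mpr_bin_", cl)) := bin_mpr(get(mcol))]
    out[, (paste0("pim_any_", cl)) := get(mcol) > 0]
  }

  if (!include_comorbidities) {
    out[, row_id := NULL]
    return(out[])
  }

  # comorbidity flags: claims within [index - window, index]
  dx <- as.data.table(diagnoses)[
    out[, .(row_id, person_id, index_date)], on = "person_id",
    nomatch = NULL, allow.cartesian = TRUE]
  dx <- dx[service_date >= index_date - as.integer(window_days) &
             service_date <= index_date]
  gcols <- paste0("com_", names(config$comorbidity_map))
  for (col in gcols) out[, (col) := FALSE]
  if (nrow(dx)) {
    m <- match_code_groups(dx$icd10_code, config$comorbidity_map)
    for (g in names(config$comorbidity_map)) {
      hit <- unique(dx$row_id[m[, g]])
      if (length(hit))
        out[row_id %in% hit, (paste0("com_", g)) := TRUE]
    }
  }
  wts <- config$cci_weights
  out[, cci_score := as.integer(Reduce(`+`, lapply(names(wts), function(g)
    wts[[g]] * get(paste0("com_", g))), accumulate = FALSE))]
  out[, row_id := NULL]
  out[]
}
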