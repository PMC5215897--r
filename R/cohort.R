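#' Identify incident dementia cases
#'
#' Applies the incidence rules of a nested case-control design to the claims
#' tables: a case is a person whose dementia diagnosis is established inside
#' the case window (default 2005-2013) with no dementia-coded claim during
#' the preceding washout years, who is aged >= `min_age` at the index date,
#' community-dwelling (no inpatient claim of any cause strictly before the
#' index date) and an outpatient-service user (at least
#' `min_outpatient_visits` outpatient claims on or before the index date).
#' The index date is the date of the claim at which the
#' `config$min_dementia_claims`-th qualifying dementia code is observed (the
#' first claim under the default threshold of 1).
#'
#' @param persons,diagnoses claims tables ([claims-schemas]).
#' @param config a [codeset_config()].
#' @param case_window_start,case_window_end calendar years of eligible index
#'   dates.
#' @param washout_years length of the claim-free washout preceding
#'   `case_window_start` (default 3, i.e. 2002-2004 for a 2005 window open).
#' @param min_outpatient_visits minimum outpatient claims on or before index
#'   (default 2: "more than once").
#' @param min_age minimum age at index (default 65).
#' @return data.table of case records: `person_id`, `index_date`,
#'   `age_at_index`, `subtype` (`alzheimer` / `other_cause` / `mixed`),
#'   `sex`, `income_index`, `index_year`, with attribute `exclusions`
#'   (named counts per rule, in application order).
#' @export
identify_incident_cases <- function(persons, diagnoses, config,
                                    case_window_start = 2005L,
                                    case_window_end = 2013L,
                                    washout_years = 3L,
                                    min_outpatient_visits = 2L,
                                    min_age = 65L) {
  persons <- as.data.table(persons)
  diagnoses <- as.data.table(diagnoses)
  orphan <- setdiff(unique(diagnoses$person_id), persons$person_id)
  if (length(orphan))
    stop("diagnoses reference unknown person_id(s): ",
         paste(head(orphan, 10), collapse = ", "))

  window_open <- data.table::as.IDate(sprintf("%d-01-01", case_window_start))
  window_close <- data.table::as.IDate(sprintf("%d-12-31", case_window_end))
  washout_open <- data.table::as.IDate(
    sprintf("%d-01-01", case_window_start - washout_years))

  dem <- diagnoses[code_matches(icd10_code, config$dementia_codes)]
  if (!nrow(dem)) {
    out <- data.table(person_id = character(),
                      index_date = as_idate(character()),
                      age_at_index = integer(), subtype = character(),
                      sex = character(), income_index = integer(),
                      index_year = integer())
    data.table::setattr(out, "exclusions",
                        c(no_qualifying_claims = 0L, washout_violation = 0L,
                          index_outside_window = 0L, under_age = 0L,
                          prior_hospitalization = 0L,
                          insufficient_outpatient = 0L, not_enrolled = 0L))
    return(out)
  }
  data.table::setorder(dem, person_id, service_date)
  k <- max(1L, config$min_dementia_claims)
  per <- dem[, .(
    n_claims = .N,
    first_claim = service_date[1],
    index_date = if (.N >= k) service_date[k] else as_idate(NA),
    codes = list(unique(icd10_code))
  ), by = person_id]

  excl <- c(no_qualifying_claims = 0L, washout_violation = 0L,
            index_outside_window = 0L, under_age = 0L,
            prior_hospitalization = 0L, insufficient_outpatient = 0L,
            not_enrolled = 0L)
  per <- per[!is.na(index_date)]
  excl["no_qualifying_claims"] <- length(unique(dem$person_id)) - nrow(per)

  washed <- per$first_claim < window_open & per$first_claim >= washout_open
  excl["washout_violation"] <- sum(washed)
  per <- per[!washed]
  inwin <- per$index_date >= window_open & per$index_date <= window_close
  excl["index_outside_window"] <- sum(!inwin)
  per <- per[inwin]

  per <- persons[, .(person_id, birth_year, sex, income_index, enroll_start,
                     enroll_end)][per, on = "person_id"]
  per[, index_year := data.table::year(index_date)]
  per[, age_at_index := index_year - birth_year]
  ok <- per$age_at_index >= min_age
  excl["under_age"] <- sum(!ok)
  per <- per[ok]

  first_inpt <- diagnoses[setting == "inpatient",
                          .(first_inpt = min(service_date)), by = person_id]
  per <- first_inpt[per, on = "person_id"]
  ok <- is.na(per$first_inpt) | per$first_inpt >= per$index_date
  excl["prior_hospitalization"] <- sum(!ok)
  per <- per[ok]

  outp <- diagnoses[setting == "outpatient", .(person_id, service_date)]
  outp <- outp[per[, .(person_id, index_date)], on = "person_id",
               nomatch = NULL]
  n_outp <- outp[service_date <= index_date, .N, by = person_id]
  per <- n_outp[per, on = "person_id"]
  per[is.na(N), N := 0L]
  ok <- per$N >= min_outpatient_visits
  excl["insufficient_outpatient"] <- sum(!ok)
  per <- per[ok]

  ok <- per$index_date >= per$enroll_start & per$index_date <= per$enroll_end
  excl["not_enrolled"] <- sum(!ok)
  per <- per[ok]

  per[, subtype := vapply(codes, classify_dementia_subtype, character(1),
                          config = config)]
  out <- per[, .(person_id, index_date, age_at_index, subtype, sex,
                 income_index, index_year)]
  data.table::setorder(out, index_date, person_id)
  data.table::setattr(out, "exclusions", excl)
  out
}

#' Classify dementia subtype from a person's qualifying codes
#'
#' `alzheimer` when only Alzheimer-set prefixes (F00, G30) are present,
#' `other_cause` when only other-set prefixes (F01, F02, F03, F051, G311)
#' are present, `mixed` when codes from both sets occur.
#'
#' @param codes character vector of the person's observed dementia-qualifying
#'   ICD-10 codes (all of follow-up).
#' @param config a [codeset_config()].
#' @return one of `"alzheimer"`, `"other_cause"`, `"mixed"`.
#' @export
classify_dementia_subtype <- function(codes, config) {
  codes <- unlist(codes)
  if (!length(codes)) stop("empty code set: not a dementia case")
  ad <- any(code_matches(codes, config$subtype_ad_codes))
  oth <- any(code_matches(codes, config$subtype_other_codes))
  if (ad && oth) return("mixed")
  if (ad) return("alzheimer")
  if (oth) return("other_cause")
  stop("codes match no dementia subtype set")
}

#' Select 1:1 matched controls
#'
#' For each case, draws one control uniformly at random (seeded) from the
#' eligible candidates sharing the matching key (age at index, sex, income
#' index, index year). A candidate is eligible when, at the case's index
#' date, they are enrolled and alive, dementia-free (no qualifying code on or
#' before the index date), community-dwelling (no inpatient claim strictly
#' before the index date) and have at least `min_outpatient_visits`
#' outpatient claims on or before it. Controls are sampled without
#' replacement across pairs (configurable); cases are processed in index-date
#' order; cases without any eligible candidate are dropped and reported.
#'
#' @param cases output of [identify_incident_cases()].
#' @param persons,diagnoses claims tables.
#' @param config a [codeset_config()].
#' @param seed integer seed for the uniform draws.
#' @param min_outpatient_visits as in [identify_incident_cases()].
#' @param age_band allowed absolute difference in age at index (default 0 =
#'   exact match).
#' @param allow_control_reuse if TRUE a person may serve as control for
#'   several cases (default FALSE).
#' @return data.table of matched pairs: `pair_id`, `case_person_id`,
#'   `control_person_id`, `index_date`, `age_at_index`, `sex`,
#'   `income_index`, `index_year`, `subtype`; attribute `unmatched` lists the
#'   dropped case ids.
#' @export
select_controls <- function(cases, persons, diagnoses, config, seed = 1L,
                            min_outpatient_visits = 2L, age_band = 0L,
                            allow_control_reuse = FALSE) {
  cases <- as.data.table(cases)
  persons <- as.data.table(persons)
  diagnoses <- as.data.table(diagnoses)

  dem <- diagnoses[code_matches(icd10_code, config$dementia_codes),
                   .(first_dem = min(service_date)), by = person_id]
  inpt <- diagnoses[setting == "inpatient",
                    .(first_inpt = min(service_date)), by = person_id]
  outp <- diagnoses[setting == "outpatient"]
  data.table::setorder(outp, person_id, service_date)
  outp[, k := seq_len(.N), by = person_id]
  qual <- outp[k == min_outpatient_visits,
               .(person_id, outpt_qualify = service_date)]

  pool <- copy(persons)
  pool <- dem[pool, on = "person_id"]
  pool <- inpt[pool, on = "person_id"]
  pool <- qual[pool, on = "person_id"]

  # plain vectors + a key-indexed candidate list keep the per-case work tiny
  pid <- pool$person_id
  v_start <- as.integer(pool$enroll_start)
  v_end <- as.integer(pool$enroll_end)
  v_death <- as.integer(pool$death_date)
  v_dem <- as.integer(pool$first_dem)
  v_inpt <- as.integer(pool$first_inpt)
  v_qual <- as.integer(pool$outpt_qualify)
  key_of <- function(sex, income, by) paste(sex, income, by, sep = "|")
  cand_groups <- split(seq_along(pid),
                       key_of(pool$sex, pool$income_index, pool$birth_year))

  with_seed(seed, {
    data.table::setorder(cases, index_date, person_id)
    used <- rep(FALSE, length(pid))
    res <- vector("list", nrow(cases))
    unmatched <- character()
    c_pid <- cases$person_id
    c_idx <- as.integer(cases$index_date)
    c_age <- cases$age_at_index
    c_sex <- cases$sex
    c_inc <- cases$income_index
    c_year <- cases$index_year
    for (i in seq_len(nrow(cases))) {
      keys <- key_of(c_sex[i], c_inc[i],
                     c_year[i] - c_age[i] + (-age_band):age_band)
      cand <- unlist(cand_groups[keys], use.names = FALSE)
      idx <- c_idx[i]
      if (length(cand)) {
        ok <- pid[cand] != c_pid[i] &
          v_start[cand] <= idx & v_end[cand] >= idx &
          (is.na(v_death[cand]) | v_death[cand] > idx) &
          (is.na(v_dem[cand]) | v_dem[cand] > idx) &
          (is.na(v_inpt[cand]) | v_inpt[cand] >= idx) &
          (!is.na(v_qual[cand]) & v_qual[cand] <= idx)
        if (!allow_control_reuse) ok <- ok & !used[cand]
        cand <- cand[ok]
      }
      if (!length(cand)) {
        unmatched <- c(unmatched, c_pid[i])
        next
      }
      pick <- cand[sample.int(length(cand), 1L)]
      if (!allow_control_reuse) used[pick] <- TRUE
      res[[i]] <- pick
    }
    hit <- !vapply(res, is.null, logical(1))
    if (any(hit)) {
      pairs <- data.table(
        case_person_id = c_pid[hit],
        control_person_id = pid[unlist(res[hit])],
        index_date = data.table::as.IDate(c_idx[hit],
                                          origin = "1970-01-01"),
        age_at_index = c_age[hit], sex = c_sex[hit],
        income_index = c_inc[hit], index_year = c_year[hit],
        subtype = cases$subtype[hit])
      pairs[, pair_id := .I]
    } else {
      pairs <- data.table(case_person_id = character(),
                          control_person_id = character(),
                          index_date = as_idate(character()),
                          age_at_index = integer(), sex = character(),
                          income_index = integer(), index_year = integer(),
                          subtype = character(), pair_id = integer())
    }
    data.table::setcolorder(pairs, "pair_id")
    if (length(unmatched))
      message(length(unmatched), " case(s) had no eligible control and were dropped")
    data.table::setattr(pairs, "unmatched", unmatched)
    pairs
  })
}

#' Stack a pair table into one row per subject
#'
#' @param pairs output of [select_controls()].
#' @return data.table with `person_id`, `index_date`, `pair_id`, `role`
#'   (case/control), `subtype` and the matching key columns.
#' @export
pairs_to_subjects <- function(pairs) {
  pairs <- as.data.table(pairs)
  rbind(
    pairs[, .(person_id = case_person_id, index_date, pair_id, role = "case",
              subtype, age_at_index, sex, income_index, index_year)],
    pairs[, .(person_id = control_person_id, index_date, pair_id,
              role = "control", subtype, age_at_index, sex, income_index,
              index_year)])
}
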