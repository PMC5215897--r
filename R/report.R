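#' Table-1-style cohort description
#'
#' Per-arm counts and percentages for sex, age bands (65-<75, >=75) and every
#' comorbidity flag, plus means and SDs for age, Charlson score and the
#' average daily drug count. Percentages are `100 n / total` rounded to one
#' decimal; an empty arm yields zero counts with percentages marked NA.
#'
#' @param exposures output of [derive_exposures()] on a subject table from
#'   [pairs_to_subjects()] (must carry `role`, `sex`, `age_at_index`).
#' @return long data.table: `section`, `item`, `arm`, `n`, `pct`, `mean`,
#'   `sd`.
#' @export
describe_cohort <- function(exposures) {
  ex <- as.data.table(exposures)
  stopifnot(all(c("role", "sex", "age_at_index") %in% names(ex)))
  rows <- list()
  add_count <- function(section, item, flag_col_or_vec) {
    for (arm in c("case", "control")) {
      sub <- ex[role == arm]
      v <- if (is.character(flag_col_or_vec)) sub[[flag_col_or_vec]]
           else flag_col_or_vec[ex$role == arm]
      n <- sum(v); tot <- nrow(sub)
      rows[[length(rows) + 1L]] <<- data.table(
        section = section, item = item, arm = arm, n = n,
        pct = if (tot > 0) round(100 * n / tot, 1) else NA_real_,
        mean = NA_real_, sd = NA_real_)
    }
  }
  add_numeric <- function(section, item, col) {
    for (arm in c("case", "control")) {
      sub <- ex[role == arm]
      rows[[length(rows) + 1L]] <<- data.table(
        section = section, item = item, arm = arm, n = nrow(sub),
        pct = NA_real_,
        mean = if (nrow(sub)) mean(sub[[col]]) else NA_real_,
        sd = if (nrow(sub) > 1) sd(sub[[col]]) else NA_real_)
    }
  }
  add_count("sex", "female", ex$sex == "female")
  add_count("sex", "male", ex$sex == "male")
  add_numeric("age", "age_at_index", "age_at_index")
  add_count("age_band", "65_to_lt75", ex$age_at_index < 75)
  add_count("age_band", "ge75", ex$age_at_index >= 75)
  add_numeric("cci", "cci_score", "cci_score")
  for (col in grep("^com_", names(ex), value = TRUE))
    add_count("comorbidity", sub("^com_", "", col), col)
  for (col in grep("^pim_any_", names(ex), value = TRUE))
    add_count("pim_any", sub("^pim_any_", "", col), col)
  add_numeric("drugs", "avg_daily_drugs", "avg_daily_drugs")
  add_count("polypharmacy", "ge5_flag", "polypharmacy_flag")
  data.table::rbindlist(rows)
}

#' Polypharmacy prevalence by arm
#'
#' Share of each arm with an average daily drug count >= 5, and the
#' case/control prevalence ratio rounded to one decimal.
#'
#' @param exposures as in [describe_cohort()].
#' @return one-row data.table: `pct_cases`, `pct_controls`, `ratio`.
#' @export
polypharmacy_prevalence <- function(exposures) {
  ex <- as.data.table(exposures)
  pc <- 100 * mean(ex[role == "case"]$polypharmacy_flag)
  pk <- 100 * mean(ex[role == "control"]$polypharmacy_flag)
  data.table(pct_cases = pc, pct_controls = pk,
             ratio = round(pc / pk, 1))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param simulate NULL, or a list passed to [simulation_config()] to
#'   generate the input claims instead of reading them.
#' @param input_paths NULL, or named paths for [read_claims()].
#' @param codeset_path optional YAML path ([read_codeset_config()]); ignored
#'   when simulating (the generator supplies its dictionary-aware config).
#' @param out_dir output directory, or NULL to skip writing.
#' @param seed run seed (simulation and control sampling).
#' @param washout_years,min_outpatient_visits,age_band,allow_control_reuse
#'   cohort parameters, see [identify_incident_cases()] / [select_controls()].
#' @param interaction_threshold p-value threshold for the interaction screen.
#' @param version free-form version string echoed into the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulate = list(n_persons = 5000L), input_paths = NULL,
                       codeset_path = NULL, out_dir = NULL, seed = 1L,
                       washout_years = 3L, min_outpatient_visits = 2L,
                       age_band = 0L, allow_control_reuse = FALSE,
                       interaction_threshold = 0.001,
                       version = "polydem-0.1.0") {
  structure(list(simulate = simulate, input_paths = input_paths,
                 codeset_path = codeset_path, out_dir = out_dir,
                 seed = as.integer(seed), washout_years = washout_years,
                 min_outpatient_visits = min_outpatient_visits,
                 age_band = age_band,
                 allow_control_reuse = allow_control_reuse,
                 interaction_threshold = interaction_threshold,
                 version = version), class = "run_config")
}

analysis_comorbidity_groups <- function(config)
  setdiff(names(config$comorbidity_map), "dementia")

# Table-2-style PIM exposure analysis: any-use and MPR-stratum crude ORs.
pim_exposure_table <- function(exposures, config) {
  ex <- as.data.table(exposures)
  rows <- list()
  for (cl in config$pim_classes) {
    bcol <- paste0("mpr_bin_", cl)
    tab <- function(lv) c(
      a = sum(ex$role == "case" & ex[[bcol]] %in% lv),
      c = sum(ex$role == "control" & ex[[bcol]] %in% lv))
    z <- tab("zero")
    for (stratum in list(c("gt0_lt50", "ge50_le100"), "gt0_lt50",
                         "ge50_le100")) {
      s <- tab(stratum)
      est <- two_by_two_or(s["a"], z["a"], s["c"], z["c"])
      rows[[length(rows) + 1L]] <- cbind(
        data.table(pim_class = cl,
                   stratum = paste(stratum, collapse = "+"),
                   n_case = s[["a"]], n_control = s[["c"]],
                   n_case_ref = z[["a"]], n_control_ref = z[["c"]]),
        est[, .(or, ci_low, ci_high, p_value, flag)])
    }
  }
  data.table::rbindlist(rows)
}

#' Run the full nested case-control pipeline
#'
#' Executes simulate (optional) -> cohort -> exposures -> analysis ->
#' description, collecting every tabular artifact plus a manifest with the
#' attrition counts at each selection step and a parameter echo. With
#' `out_dir` set, writes all tables as TSV, the manifest as JSON and a
#' structured log. Identical config + seed give identical manifests.
#'
#' @param cfg a [run_config()].
#' @return list with `claims`, `cases`, `pairs`, `exposures`, `tables`
#'   (pim_exposure, category_or, subtype_or, integrated_or, subgroups,
#'   interactions, multivariable), `description`, `prevalence`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  ## inputs
  if (!is.null(cfg$simulate)) {
    sim <- stage("simulate", simulate_claims(
      do.call(simulation_config, cfg$simulate), seed = cfg$seed))
    claims <- sim[c("persons", "diagnoses", "prescriptions")]
    codesets <- sim$codesets
    truth <- sim$truth
    logf("simulate", "n_persons=%d diagnoses=%d prescriptions=%d",
         nrow(claims$persons), nrow(claims$diagnoses),
         nrow(claims$prescriptions))
  } else {
    claims <- stage("read", read_claims(cfg$input_paths))
    codesets <- if (!is.null(cfg$codeset_path))
      read_codeset_config(cfg$codeset_path) else default_codesets()
    truth <- NULL
    logf("read", "persons=%d diagnoses=%d prescriptions=%d",
         nrow(claims$persons), nrow(claims$diagnoses),
         nrow(claims$prescriptions))
  }

  ## cohort
  cases <- stage("build-cohort", identify_incident_cases(
    claims$persons, claims$diagnoses, codesets,
    washout_years = cfg$washout_years,
    min_outpatient_visits = cfg$min_outpatient_visits))
  pairs <- stage("build-cohort", select_controls(
    cases, claims$persons, claims$diagnoses, codesets, seed = cfg$seed + 1L,
    min_outpatient_visits = cfg$min_outpatient_visits,
    age_band = cfg$age_band,
    allow_control_reuse = cfg$allow_control_reuse))
  matched_cases <- cases[person_id %in% pairs$case_person_id]
  subjects <- pairs_to_subjects(pairs)
  logf("build-cohort", "cases=%d pairs=%d unmatched=%d", nrow(cases),
       nrow(pairs), length(attr(pairs, "unmatched")))

  ## exposures
  exposures <- stage("derive-exposures", derive_exposures(
    subjects, claims$prescriptions, claims$diagnoses, codesets))
  exposures[, is_case := role == "case"]
  logf("derive-exposures", "rows=%d polypharmacy=%.1f%%", nrow(exposures),
       100 * mean(exposures$polypharmacy_flag))

  ## analysis
  groups <- analysis_comorbidity_groups(codesets)
  tables <- if (nrow(pairs) == 0L) {
    # empty cohort (e.g. zero persons): schema-valid empty artifacts
    list(pim_exposure = data.table(), category_or = data.table(),
         integrated_or = data.table(), subgroups = data.table(),
         interactions = data.table(), multivariable_stepwise = data.table(),
         multivariable_stratified = data.table())
  } else stage("analyze", {
    pim_tab <- pim_exposure_table(exposures, codesets)
    cat_or <- fit_logistic(is_case ~ polypharmacy_category, exposures)
    cat_or[, population := "total"]
    sub_or <- data.table::rbindlist(lapply(
      intersect(c("alzheimer", "other_cause", "mixed"),
                unique(exposures$subtype)), function(st) {
        keep <- exposures[subtype == st]
        if (!nrow(keep) || length(unique(keep$is_case)) < 2) return(NULL)
        tab <- fit_logistic(is_case ~ polypharmacy_category, keep)
        tab[, population := st]
        tab
      }), use.names = TRUE)
    subgroups <- subgroup_or_table(exposures, groups)
    integrated <- data.table::rbindlist(lapply(
      c("without", "with"), function(s) {
        data.table::rbindlist(lapply(
          setdiff(polypharmacy_levels, "lt1"), function(cat) {
            comp <- subgroups[stratum == s & category == cat &
                                suppressed == FALSE]
            if (!nrow(comp)) return(NULL)
            p <- pool_or_inverse_variance(comp)
            cbind(data.table(stratum = s, category = cat), p)
          }), use.names = TRUE)
      }), use.names = TRUE)
    pim_flags <- paste0("pim_any_", codesets$pim_classes)
    inter <- data.table::rbindlist(c(
      lapply(pim_flags, function(v) test_interaction(
        exposures, "is_case", "polypharmacy_flag", v,
        threshold = cfg$interaction_threshold)),
      lapply(paste0("com_", groups), function(v) test_interaction(
        exposures, "is_case", "polypharmacy_flag", v,
        threshold = cfg$interaction_threshold))), use.names = TRUE)
    int_pims <- sub("^pim_any_", "",
                    grep("^pim_any_",
                         inter[significant %in% TRUE]$covariate_name,
                         value = TRUE))
    int_coms <- sub("^com_",
                    "", grep("^com_",
                             inter[significant %in% TRUE]$covariate_name,
                             value = TRUE))
    multi <- stratified_multivariable_models(
      exposures, pim_classes = codesets$pim_classes,
      interacting_pims = int_pims,
      interacting_comorbidities = int_coms,
      non_interacting_comorbidities = setdiff(groups, int_coms))
    list(pim_exposure = pim_tab,
         category_or = rbind(cat_or, sub_or, use.names = TRUE, fill = TRUE),
         integrated_or = integrated, subgroups = subgroups,
         interactions = inter, multivariable_stepwise = multi$stepwise,
         multivariable_stratified = multi$stratified)
  })
  logf("analyze", "interaction screens=%d significant=%d",
       nrow(tables$interactions),
       sum(tables$interactions$significant %in% TRUE))

  ## description
  description <- stage("describe", if (nrow(exposures)) describe_cohort(exposures)
                       else data.table())
  prevalence <- stage("describe", if (nrow(exposures))
    polypharmacy_prevalence(exposures)
    else data.table(pct_cases = NA_real_, pct_controls = NA_real_,
                    ratio = NA_real_))

  ## manifest
  excl <- attr(cases, "exclusions")
  n_dem_claimants <- length(unique(
    claims$diagnoses[code_matches(icd10_code, codesets$dementia_codes)]$person_id))
  subtype_counts <- table(factor(matched_cases$subtype,
                                 levels = c("alzheimer", "other_cause",
                                            "mixed")))
  subtype_pct <- if (nrow(matched_cases))
    round(100 * as.numeric(subtype_counts) / nrow(matched_cases), 1)
  else rep(NA_real_, 3)
  manifest <- list(
    version = cfg$version,
    seed = cfg$seed,
    parameters = cfg[c("washout_years", "min_outpatient_visits", "age_band",
                       "allow_control_reuse", "interaction_threshold")],
    attrition = list(
      persons = nrow(claims$persons),
      dementia_claimants = n_dem_claimants,
      incident_cases = nrow(cases),
      matched_cases = nrow(pairs),
      exclusion_counts = as.list(excl)),
    subtypes = list(counts = as.list(setNames(as.integer(subtype_counts),
                                              names(subtype_counts))),
                    percentages = as.list(setNames(subtype_pct,
                                                   names(subtype_counts)))),
    polypharmacy = as.list(prevalence))
  logf("describe", "elapsed=%.1fs",
       as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(claims = claims, truth = truth, codesets = codesets,
              cases = cases, pairs = pairs, exposures = exposures,
              tables = tables, description = description,
              prevalence = prevalence, manifest = manifest, log = log_lines)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_claims(out$claims, file.path(dir, "claims"))
  if (!is.null(out$truth))
    data.table::fwrite(out$truth, file.path(dir, "truth.tsv"), sep = "\t")
  data.table::fwrite(out$cases, file.path(dir, "cases.tsv"), sep = "\t")
  data.table::fwrite(out$pairs, file.path(dir, "pairs.tsv"), sep = "\t")
  data.table::fwrite(out$exposures, file.path(dir, "exposures.tsv"),
                     sep = "\t")
  for (nm in names(out$tables))
    data.table::fwrite(out$tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t")
  data.table::fwrite(out$description, file.path(dir, "table1.tsv"),
                     sep = "\t")
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(out$log, file.path(dir, "run.log"))
  invisible(dir)
}
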