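#' Parameter-recovery study for the polypharmacy odds ratios
#'
#' Replicates the full pipeline — simulate claims with known polypharmacy
#' effect sizes, select incident cases, match controls, derive look-back
#' exposures, fit the univariate category model — across many seeds and
#' records, per upper category, whether the configured true OR falls inside
#' the estimated 95% CI. The recovery outcome model sets all PIM and
#' comorbidity coefficients to 1 so the marginal crude OR coincides with the
#' conditional truth (odds ratios are non-collapsible otherwise).
#'
#' @param n_seeds number of replicate seeds (default 50).
#' @param n_persons persons per replicate (default 20000).
#' @param base_seed first seed; replicate i uses `base_seed + i - 1`.
#' @param or_poly named true ORs for the upper categories.
#' @param intercept per-year logit for the reference group.
#' @return data.table with one row per seed x category: `seed`, `term`,
#'   `or`, `ci_low`, `ci_high`, `truth`, `covered`, `n_pairs`; attribute
#'   `coverage` holds the per-category coverage proportions.
#' @export
run_recovery_study <- function(n_seeds = 50L, n_persons = 20000L,
                               base_seed = 1L,
                               or_poly = c(one_to_lt5 = 1.72,
                                           five_to_lt10 = 2.64,
                                           ge10 = 3.35),
                               intercept = -4.6) {
  null1 <- function(x) setNames(rep(1, length(x)), names(x))
  template <- simulation_config(n_persons = 1L)
  om <- list(intercept = intercept, or_poly = or_poly,
             or_pim = null1(template$outcome_model$or_pim),
             or_comorbidity = null1(template$outcome_model$or_comorbidity),
             interactions = numeric())
  cfg <- simulation_config(n_persons = n_persons, outcome_model = om)
  truth_terms <- setNames(
    log(or_poly),
    paste0("polypharmacy_category", names(or_poly)))
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    seed <- base_seed + i - 1L
    sim <- simulate_claims(cfg, seed = seed)
    cases <- identify_incident_cases(sim$persons, sim$diagnoses,
                                     sim$codesets)
    pairs <- suppressMessages(select_controls(
      cases, sim$persons, sim$diagnoses, sim$codesets, seed = seed + 1L))
    subjects <- pairs_to_subjects(pairs)
    ex <- derive_exposures(subjects, sim$prescriptions, sim$diagnoses,
                           sim$codesets, include_comorbidities = FALSE)
    ex[, is_case := role == "case"]
    tab <- fit_logistic(is_case ~ polypharmacy_category, ex)
    tab <- tab[term %in% names(truth_terms)]
    tab[, `:=`(seed = seed, truth = exp(truth_terms[term]),
               covered = ci_low <= exp(truth_terms[term]) &
                 exp(truth_terms[term]) <= ci_high,
               n_pairs = nrow(pairs))]
    rows[[i]] <- tab[, .(seed, term, or, ci_low, ci_high, truth, covered,
                         n_pairs)]
  }
  out <- data.table::rbindlist(rows)
  cov <- out[, .(coverage = mean(covered)), by = term]
  data.table::setattr(out, "coverage",
                      setNames(cov$coverage, cov$term))
  out
}
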