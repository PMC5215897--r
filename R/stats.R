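#' Construct an odds-ratio estimate
#'
#' The atom tabulated and pooled throughout the analysis: an OR with
#' log-scale standard error, 95% Wald confidence interval
#' (`exp(log_or +- 1.96 se)`), p-value and cell sizes.
#'
#' @param log_or log odds ratio.
#' @param se_log_or log-scale standard error.
#' @param n_case,n_control arm sizes (optional).
#' @param flag optional character note (`"zero_cells"`, `"undefined"`,
#'   `"not_converged"`, ...); `NA` for a clean estimate.
#' @return object of class `or_estimate` (a one-row data.table with columns
#'   `or`, `log_or`, `se_log_or`, `ci_low`, `ci_high`, `p_value`, `n_case`,
#'   `n_control`, `flag`).
#' @export
or_estimate <- function(log_or, se_log_or, n_case = NA_integer_,
                        n_control = NA_integer_, flag = NA_character_) {
  z <- log_or / se_log_or
  out <- data.table(
    or = exp(log_or), log_or = log_or, se_log_or = se_log_or,
    ci_low = exp(log_or - 1.96 * se_log_or),
    ci_high = exp(log_or + 1.96 * se_log_or),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    flag = flag)
  class(out) <- c("or_estimate", class(out))
  out
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f)%s\n", x$or, x$ci_low, x$ci_high,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Odds ratio from a 2x2 table
#'
#' Cross-product OR with the Woolf log-scale standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero the Haldane-Anscombe
#' continuity correction adds 0.5 to all four cells (flag `"zero_cells"`);
#' two zero cells in one margin leave the OR undefined (flag `"undefined"`).
#'
#' @param a_case_exp,b_case_unexp,c_ctrl_exp,d_ctrl_unexp cell counts:
#'   exposed/unexposed cases, exposed/unexposed controls.
#' @param correction apply the continuity correction for zero cells
#'   (default TRUE).
#' @return an [or_estimate()].
#' @examples
#' two_by_two_or(539, 5023, 285, 5277)  # OR ~ 1.987
#' @export
two_by_two_or <- function(a_case_exp, b_case_unexp, c_ctrl_exp, d_ctrl_unexp,
                          correction = TRUE) {
  cells <- c(a_case_exp, b_case_unexp, c_ctrl_exp, d_ctrl_unexp)
  stopifnot(all(cells >= 0))
  n_case <- a_case_exp + b_case_unexp
  n_control <- c_ctrl_exp + d_ctrl_unexp
  margin_dead <- (a_case_exp == 0 && c_ctrl_exp == 0) ||
    (b_case_unexp == 0 && d_ctrl_unexp == 0) ||
    (a_case_exp == 0 && b_case_unexp == 0) ||
    (c_ctrl_exp == 0 && d_ctrl_unexp == 0)
  if (margin_dead)
    return(or_estimate(NA_real_, NA_real_, n_case, n_control, "undefined"))
  flag <- NA_character_
  if (any(cells == 0)) {
    if (!correction)
      return(or_estimate(NA_real_, NA_real_, n_case, n_control, "zero_cells"))
    cells <- cells + 0.5
    flag <- "zero_cells"
  }
  lo <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  or_estimate(lo, se, n_case, n_control, flag)
}

# Tidy a glm/clogit coefficient table into OR rows.
coef_to_or_table <- function(est, se, terms, n_case = NA, n_control = NA) {
  rows <- lapply(seq_along(terms), function(i) {
    flag <- NA_character_
    if (is.na(est[i])) flag <- "dropped"
    else if (abs(est[i]) > 15 || se[i] > 10) flag <- "not_converged"
    cbind(data.table(term = terms[i]),
          or_estimate(est[i], se[i], n_case, n_control, flag))
  })
  data.table::rbindlist(rows)
}

#' Univariate / multivariable logistic regression OR table
#'
#' Maximum-likelihood logistic fit via [stats::glm()], returning one
#' [or_estimate()] row per non-intercept term. Categorical exposures should
#' be factors whose first level is the reference (the polypharmacy category
#' factor from [categorize_polypharmacy()] uses `lt1`). Aliased
#' (e.g. all-zero) covariates are reported with flag `"dropped"` and a
#' warning; quasi-separated terms are flagged `"not_converged"` rather than
#' raising an error.
#'
#' @param formula model formula with a binary (0/1 or logical) outcome.
#' @param data data.frame.
#' @return data.table with a `term` column plus the [or_estimate()] columns;
#'   the fitted `glm` object is attached as attribute `fit`.
#' @export
fit_logistic <- function(formula, data) {
  fit <- suppressWarnings(stats::glm(
    formula, data = data, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 50)))
  cf <- coef(fit)
  keep <- names(cf) != "(Intercept)"
  terms <- names(cf)[keep]
  est <- cf[keep]
  se <- rep(NA_real_, length(est))
  ok <- !is.na(est)
  if (any(ok)) {
    V <- vcov(fit)
    vterms <- intersect(terms[ok], colnames(V))
    se[match(vterms, terms)] <- sqrt(diag(V)[vterms])
  }
  if (any(!ok)) warning("dropped aliased term(s): ",
                        paste(terms[!ok], collapse = ", "))
  y <- fit$y
  out <- coef_to_or_table(est, se, terms, n_case = sum(y == 1),
                          n_control = sum(y == 0))
  out[is.na(flag) & !fit$converged, flag := "not_converged"]
  data.table::setattr(out, "fit", fit)
  out
}

#' Conditional logistic regression for matched pairs
#'
#' Conditional maximum likelihood on within-stratum contrasts via
#' [survival::clogit()]. For a single binary exposure in 1:1 pairs the
#' estimate equals the discordant-pair ratio. When no pair is discordant the
#' estimate is undefined and flagged rather than fatal.
#'
#' @param formula formula `outcome ~ terms` (the pair stratum is added
#'   internally).
#' @param data data.frame with one row per subject.
#' @param strata_col name of the pair-identifier column (default
#'   `"pair_id"`).
#' @return data.table as in [fit_logistic()].
#' @export
fit_conditional_logistic <- function(formula, data, strata_col = "pair_id") {
  data <- as.data.frame(data)
  lhs <- all.vars(formula)[1]
  y <- as.integer(data[[lhs]])
  # conditional logistic = stratified exact Cox fit on unit follow-up times
  data$.time <- 1
  data$.status <- y
  rhs <- attr(stats::terms(formula), "term.labels")
  f <- as.formula(sprintf(
    "survival::Surv(.time, .status) ~ %s + survival::strata(%s)",
    paste(rhs, collapse = " + "), strata_col))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(f, data = data, method = "exact")),
    error = function(e) NULL)
  if (is.null(fit)) {
    terms <- attr(stats::terms(formula), "term.labels")
    return(coef_to_or_table(rep(NA_real_, length(terms)),
                            rep(NA_real_, length(terms)), terms,
                            sum(y == 1), sum(y == 0))[, flag := "undefined"][])
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- coef_to_or_table(cf, se[names(cf)], names(cf),
                          n_case = sum(y == 1), n_control = sum(y == 0))
  out[is.na(or) | se_log_or > 10 | is.nan(se_log_or), flag := "undefined"]
  data.table::setattr(out, "fit", fit)
  out
}

#' Likelihood-ratio interaction test
#'
#' Compares the logistic model with and without the product term
#' `exposure x covariate` by a likelihood-ratio chi-square test (Wald
#' available via `method`). Polypharmacy enters as the binary >= 5 flag.
#'
#' @param data data.frame.
#' @param outcome,exposure,covariate column names (outcome binary/logical;
#'   exposure and covariate binary).
#' @param adjustment_terms optional character vector of additional covariate
#'   columns.
#' @param threshold significance threshold (default 0.001).
#' @param method `"lrt"` (default) or `"wald"`.
#' @return one-row data.table: `covariate_name`, `statistic`, `df`,
#'   `p_value`, `significant`, `flag`.
#' @export
test_interaction <- function(data, outcome, exposure, covariate,
                             adjustment_terms = character(),
                             threshold = 0.001, method = c("lrt", "wald")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  flagged <- function(flag) data.table(
    covariate_name = covariate, statistic = NA_real_, df = NA_integer_,
    p_value = NA_real_, significant = NA, flag = flag)
  if (length(unique(data[[covariate]])) < 2 ||
      length(unique(data[[exposure]])) < 2)
    return(flagged("constant_covariate"))
  adj <- if (length(adjustment_terms))
    paste("+", paste(adjustment_terms, collapse = " + ")) else ""
  f0 <- as.formula(sprintf("%s ~ %s + %s %s", outcome, exposure, covariate,
                           adj))
  f1 <- as.formula(sprintf("%s ~ %s + %s + %s:%s %s", outcome, exposure,
                           covariate, exposure, covariate, adj))
  m0 <- suppressWarnings(stats::glm(f0, data = data, family = stats::binomial()))
  m1 <- suppressWarnings(stats::glm(f1, data = data, family = stats::binomial()))
  if (!m0$converged || !m1$converged) return(flagged("not_converged"))
  df <- length(coef(m1)) - length(coef(m0))
  if (df < 1 || anyNA(coef(m1))) return(flagged("not_nested"))
  if (method == "lrt") {
    stat <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  } else {
    term <- setdiff(names(coef(m1)), names(coef(m0)))
    w <- coef(m1)[term] / sqrt(diag(vcov(m1))[term])
    stat <- sum(w^2)
    p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  data.table(covariate_name = covariate, statistic = stat, df = df,
             p_value = p, significant = p < threshold, flag = NA_character_)
}

#' Crude OR tables within comorbidity-defined subgroups
#'
#' For each listed comorbidity, splits the subjects into the with-disease and
#' without-disease strata and computes, within each stratum, the crude 2x2
#' OR of each upper polypharmacy category against the `lt1` reference. Any
#' stratum/category whose 2x2 table has a cell below `min_cell` is suppressed
#' (estimate set to NA, `suppressed = TRUE`), mirroring small-cell reporting
#' practice.
#'
#' @param subjects data.frame with logical `is_case`, factor
#'   `polypharmacy_category` and logical `com_<group>` columns.
#' @param comorbidities character vector of group names (without the `com_`
#'   prefix).
#' @param min_cell suppression threshold (default 5).
#' @return data.table with columns `comorbidity`, `stratum`
#'   (`with`/`without`), `category`, the OR columns and `suppressed`.
#' @export
subgroup_or_table <- function(subjects, comorbidities, min_cell = 5L) {
  subjects <- as.data.table(subjects)
  cats <- setdiff(levels(subjects$polypharmacy_category), "lt1")
  out <- list()
  for (g in comorbidities) {
    col <- paste0("com_", g)
    if (!col %in% names(subjects)) stop("missing column ", col)
    for (stratum in c("without", "with")) {
      sub <- subjects[get(col) == (stratum == "with")]
      ref_case <- sum(sub$is_case & sub$polypharmacy_category == "lt1")
      ref_ctrl <- sum(!sub$is_case & sub$polypharmacy_category == "lt1")
      for (cat in cats) {
        a <- sum(sub$is_case & sub$polypharmacy_category == cat)
        c_ <- sum(!sub$is_case & sub$polypharmacy_category == cat)
        suppressed <- min(a, ref_case, c_, ref_ctrl) < min_cell
        est <- if (suppressed)
          or_estimate(NA_real_, NA_real_, a + ref_case, c_ + ref_ctrl,
                      "suppressed")
        else two_by_two_or(a, ref_case, c_, ref_ctrl)
        out[[length(out) + 1L]] <- cbind(
          data.table(comorbidity = g, stratum = stratum, category = cat,
                     n_case_exp = a, n_ctrl_exp = c_),
          est, data.table(suppressed = suppressed))
      }
    }
  }
  data.table::rbindlist(out)
}

#' Fixed-effect inverse-variance pooling of odds ratios
#'
#' Pools log-ORs with weights `w_i = 1 / se_i^2`; the pooled standard error
#' is `sqrt(1 / sum(w))`. Pooling a single estimate returns it unchanged;
#' pooling K copies of one estimate shrinks its SE by `sqrt(K)`.
#'
#' @param estimates data.frame with columns `log_or` and `se_log_or` (rows
#'   with NA estimates are dropped), e.g. stacked [or_estimate()] rows.
#' @return one-row data.table: `or`, `log_or`, `se_log_or`, `ci_low`,
#'   `ci_high`, `p_value`, `component_count`.
#' @export
pool_or_inverse_variance <- function(estimates) {
  est <- as.data.table(estimates)[!is.na(log_or) & !is.na(se_log_or) &
                                    se_log_or > 0]
  if (!nrow(est)) stop("no well-defined estimates to pool")
  w <- 1 / est$se_log_or^2
  lo <- sum(w * est$log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  out <- or_estimate(lo, se)
  out[, `:=`(n_case = NULL, n_control = NULL, flag = NULL)]
  out[, component_count := nrow(est)]
  out[]
}

#' Multivariable models with and without interaction products
#'
#' Reproduces the structure of a stepwise multivariable analysis: (i) models
#' without product terms, adding covariate blocks cumulatively — polypharmacy
#' category + PIM any-use flags; + the non-interacting comorbidity group
#' indicator; + the interacting comorbidity group indicator — and (ii) a
#' model with category-by-factor products for every interacting factor, from
#' which the polypharmacy-category ORs are reported separately for absence
#' and presence of each interacting factor (`exp(b_cat)` vs
#' `exp(b_cat + b_cat:factor)`, SE by the delta method). Category/factor
#' combinations observed in fewer than `min_cell` subjects are suppressed.
#'
#' @param subjects data.frame with logical `is_case`, factor
#'   `polypharmacy_category`, logical `pim_any_<class>` and `com_<group>`
#'   columns.
#' @param pim_classes character vector of PIM classes entered as any-use
#'   flags.
#' @param interacting_pims subset of `pim_classes` with significant
#'   polypharmacy interaction.
#' @param interacting_comorbidities,non_interacting_comorbidities character
#'   vectors of comorbidity group names; each set enters as a single
#'   any-of-group indicator.
#' @param min_cell suppression threshold (default 5).
#' @return list with `stepwise` (data.table of OR rows per model block) and
#'   `stratified` (data.table of category ORs by interacting factor
#'   absence/presence).
#' @export
stratified_multivariable_models <- function(subjects, pim_classes,
                                            interacting_pims = character(),
                                            interacting_comorbidities = character(),
                                            non_interacting_comorbidities = character(),
                                            min_cell = 5L) {
  dat <- as.data.table(subjects)
  dat[, y := as.integer(is_case)]
  pim_cols <- paste0("pim_any_", pim_classes)
  dat[, noninteracting_group :=
        if (length(non_interacting_comorbidities))
          Reduce(`|`, lapply(paste0("com_", non_interacting_comorbidities),
                             function(c) dat[[c]]))
        else FALSE]
  dat[, interacting_group :=
        if (length(interacting_comorbidities))
          Reduce(`|`, lapply(paste0("com_", interacting_comorbidities),
                             function(c) dat[[c]]))
        else FALSE]

  base_terms <- c("polypharmacy_category", pim_cols)
  blocks <- list(
    pims = base_terms,
    plus_noninteracting = c(base_terms, "noninteracting_group"),
    plus_interacting = c(base_terms, "noninteracting_group",
                         "interacting_group"))
  stepwise <- data.table::rbindlist(lapply(names(blocks), function(b) {
    f <- as.formula(paste("y ~", paste(blocks[[b]], collapse = " + ")))
    tab <- fit_logistic(f, dat)
    tab[, model := b]
    tab
  }), use.names = TRUE)

  # interaction model: category x each interacting factor
  int_factors <- c(
    if (length(interacting_pims)) paste0("pim_any_", interacting_pims),
    if (length(interacting_comorbidities)) "interacting_group")
  if (!length(int_factors))
    return(list(stepwise = stepwise, stratified = data.table()))
  f_int <- as.formula(paste(
    "y ~", paste(blocks$plus_interacting, collapse = " + "), "+",
    paste(sprintf("polypharmacy_category:%s", int_factors), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f_int, data = dat,
                                     family = stats::binomial()))
  cf <- coef(fit); V <- vcov(fit)
  cats <- setdiff(levels(dat$polypharmacy_category), "lt1")
  rows <- list()
  for (fac in int_factors) {
    for (cat in cats) {
      main <- paste0("polypharmacy_category", cat)
      intr <- paste0("polypharmacy_category", cat, ":", fac, "TRUE")
      if (!intr %in% names(cf))
        intr <- paste0(fac, "TRUE:polypharmacy_category", cat)
      for (presence in c(FALSE, TRUE)) {
        n_cell <- sum(dat$polypharmacy_category == cat &
                        dat[[fac]] == presence)
        if (n_cell < min_cell || !main %in% names(cf) ||
            (presence && (!intr %in% names(cf) || is.na(cf[intr])))) {
          est <- or_estimate(NA_real_, NA_real_, flag = "suppressed")
        } else if (!presence) {
          est <- or_estimate(cf[main], sqrt(V[main, main]))
        } else {
          lo <- cf[main] + cf[intr]
          se <- sqrt(V[main, main] + V[intr, intr] + 2 * V[main, intr])
          est <- or_estimate(lo, se)
        }
        rows[[length(rows) + 1L]] <- cbind(
          data.table(factor = fac, category = cat,
                     presence = presence, n = n_cell), est)
      }
    }
  }
  list(stepwise = stepwise, stratified = data.table::rbindlist(rows),
       interaction_fit = fit)
}
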