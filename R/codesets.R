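#' Test ICD-10 codes against a prefix set
#'
#' Claims analyses define disease concepts by ICD-10 code lists held at mixed
#' specificity (e.g. a list entry "F00" covers "F00", "F000", "F009").
#' A code matches when it equals, or begins with, any prefix in the set;
#' comparison is case-insensitive.
#'
#' @param codes character vector of ICD-10 codes.
#' @param prefix_set character vector of code prefixes.
#' @return logical vector, one element per code.
#' @examples
#' code_matches(c("F001", "F052", "G30"), c("F00", "F051"))
#' @export
code_matches <- function(codes, prefix_set) {
  codes <- toupper(trimws(as.character(codes)))
  prefix_set <- toupper(trimws(as.character(prefix_set)))
  out <- rep(FALSE, length(codes))
  for (p in prefix_set) out <- out | startsWith(codes, p)
  out
}

# For each code, TRUE/FALSE per named group of prefixes. Returns a logical
# matrix codes x groups; operates on unique codes internally so cost scales
# with the code dictionary, not the claim count.
match_code_groups <- function(codes, group_map) {
  u <- unique(toupper(trimws(as.character(codes))))
  m <- matrix(FALSE, nrow = length(u), ncol = length(group_map),
              dimnames = list(u, names(group_map)))
  for (g in names(group_map)) m[, g] <- code_matches(u, group_map[[g]])
  m[match(toupper(trimws(as.character(codes))), u), , drop = FALSE]
}

#' Construct a code-set configuration
#'
#' Bundles every code list the analysis depends on: the dementia-defining
#' ICD-10 prefixes and their aetiological split (Alzheimer vs other cause),
#' the comorbidity groups with Charlson weights, the drug-code to PIM-class
#' mapping, and the combination antihypertensive/antidiabetic codes whose
#' active-ingredient counts replace a count of one in the daily drug total.
#'
#' @param dementia_codes,subtype_ad_codes,subtype_other_codes character
#'   vectors of ICD-10 prefixes; `dementia_codes` must equal the union of the
#'   two subtype sets.
#' @param comorbidity_map named list of ICD-10 prefix vectors (the 17 Charlson
#'   groups plus dementia-related comorbidities).
#' @param cci_weights named integer vector of Charlson weights; every name
#'   must be a `comorbidity_map` group.
#' @param pim_class_map named character vector mapping drug codes to PIM
#'   classes (`bzd_short_intermediate`, `bzd_long`, `bzd_receptor_agonist`,
#'   `anticholinergic`, `h2ra`); unmapped codes are class `none`.
#' @param combo_codes character vector of drug codes treated as combination
#'   antihypertensive/antidiabetic products.
#' @param min_dementia_claims minimum number of qualifying dementia claims for
#'   case status (default 1).
#' @return object of class `codeset_config`.
#' @seealso [default_codesets()]
#' @export
codeset_config <- function(dementia_codes, subtype_ad_codes,
                           subtype_other_codes, comorbidity_map, cci_weights,
                           pim_class_map = character(),
                           combo_codes = character(),
                           min_dementia_claims = 1L) {
  dementia_codes <- sort(unique(toupper(dementia_codes)))
  subtype_ad_codes <- sort(unique(toupper(subtype_ad_codes)))
  subtype_other_codes <- sort(unique(toupper(subtype_other_codes)))
  if (!setequal(dementia_codes, union(subtype_ad_codes, subtype_other_codes)))
    stop("dementia_codes must equal the union of the AD and other-cause sets")
  stopifnot(is.list(comorbidity_map), !is.null(names(comorbidity_map)))
  if (!all(names(cci_weights) %in% names(comorbidity_map)))
    stop("every cci_weights name must be a comorbidity_map group")
  w <- as.integer(cci_weights)
  if (any(is.na(w)) || any(w < 0))
    stop("cci weights must be nonnegative integers")
  names(w) <- names(cci_weights)
  valid_classes <- c("bzd_short_intermediate", "bzd_long",
                     "bzd_receptor_agonist", "anticholinergic", "h2ra")
  if (length(pim_class_map) &&
      !all(pim_class_map %in% c(valid_classes, "none")))
    stop("unknown PIM class in pim_class_map")
  structure(list(
    dementia_codes = dementia_codes,
    subtype_ad_codes = subtype_ad_codes,
    subtype_other_codes = subtype_other_codes,
    comorbidity_map = lapply(comorbidity_map, function(x) toupper(x)),
    cci_weights = w,
    pim_class_map = pim_class_map,
    pim_classes = valid_classes,
    combo_codes = toupper(combo_codes),
    min_dementia_claims = as.integer(min_dementia_claims)
  ), class = "codeset_config")
}

#' @export
print.codeset_config <- function(x, ...) {
  cat("<codeset_config>\n")
  cat("  dementia prefixes:", paste(x$dementia_codes, collapse = ", "), "\n")
  cat("  AD subtype:       ", paste(x$subtype_ad_codes, collapse = ", "), "\n")
  cat("  other subtype:    ", paste(x$subtype_other_codes, collapse = ", "), "\n")
  cat("  comorbidity groups:", length(x$comorbidity_map),
      sprintf("(%d Charlson-weighted)", length(x$cci_weights)), "\n")
  cat("  PIM-mapped drug codes:", length(x$pim_class_map),
      " combo codes:", length(x$combo_codes), "\n")
  invisible(x)
}

#' Default code-set configuration
#'
#' Ships the analysis defaults: the seven dementia-defining ICD-10 prefixes
#' split into Alzheimer (`F00`, `G30`) and other-cause (`F01`, `F02`, `F03`,
#' `F051`, `G311`) sets; a Quan-style ICD-10 mapping for the 17 Charlson
#' comorbidity groups with the classic 1/2/3/6 weights; and dementia-related
#' comorbidity groups (hypertension, depression, delirium, alcohol-related
#' behaviour disorders, schizophrenia/psychotic disorders, all other mental
#' disorders). The delirium group deliberately uses prefix `F050` so that
#' `F051` (delirium superimposed on dementia) stays exclusively a
#' dementia-defining code. The comorbidity lists are documented stand-ins for
#' a study-specific dictionary and are expected to be overridden per run; the
#' configuration file, not this function, is the source of truth.
#'
#' @param pim_class_map,combo_codes optional drug-code dictionaries, normally
#'   supplied by the claims source (the synthetic generator provides its own).
#' @param min_dementia_claims see [codeset_config()].
#' @return a `codeset_config`.
#' @export
default_codesets <- function(pim_class_map = character(),
                             combo_codes = character(),
                             min_dementia_claims = 1L) {
  comorbidity_map <- list(
    mi = c("I21", "I22", "I252"),
    chf = c("I099", "I110", "I130", "I132", "I255", "I420", "I425", "I426",
            "I427", "I428", "I429", "I43", "I50", "P290"),
    pvd = c("I70", "I71", "I731", "I738", "I739", "I771", "I790", "I792",
            "K551", "K558", "K559", "Z958", "Z959"),
    cerebrovascular = c("G45", "G46", "H340", "I60", "I61", "I62", "I63",
                        "I64", "I65", "I66", "I67", "I68", "I69"),
    dementia = c("F00", "F01", "F02", "F03", "F051", "G30", "G311"),
    copd = c("I278", "I279", "J40", "J41", "J42", "J43", "J44", "J45", "J46",
             "J47", "J60", "J61", "J62", "J63", "J64", "J65", "J66", "J67",
             "J684", "J701", "J703"),
    rheumatic = c("M05", "M06", "M315", "M32", "M33", "M34", "M351", "M353",
                  "M360"),
    pud = c("K25", "K26", "K27", "K28"),
    mild_liver = c("B18", "K700", "K701", "K702", "K703", "K709", "K713",
                   "K714", "K715", "K717", "K73", "K74", "K760", "K762",
                   "K763", "K764", "K768", "K769", "Z944"),
    diabetes = c("E100", "E101", "E106", "E108", "E109", "E110", "E111",
                 "E116", "E118", "E119", "E130", "E131", "E136", "E138",
                 "E139", "E140", "E141", "E146", "E148", "E149"),
    diabetes_complicated = c("E102", "E103", "E104", "E105", "E107", "E112",
                             "E113", "E114", "E115", "E117", "E132", "E133",
                             "E134", "E135", "E137", "E142", "E143", "E144",
                             "E145", "E147"),
    hemiplegia = c("G041", "G114", "G801", "G802", "G81", "G82", "G830",
                   "G831", "G832", "G833", "G834", "G839"),
    renal = c("I120", "I131", "N032", "N033", "N034", "N035", "N036", "N037",
              "N052", "N053", "N054", "N055", "N056", "N057", "N18", "N19",
              "N250", "Z490", "Z491", "Z492", "Z940", "Z992"),
    cancer = c("C0", "C1", "C2", "C30", "C31", "C32", "C33", "C34", "C37",
               "C38", "C39", "C40", "C41", "C43", "C45", "C46", "C47", "C48",
               "C49", "C5", "C60", "C61", "C62", "C63", "C64", "C65", "C66",
               "C67", "C68", "C69", "C70", "C71", "C72", "C73", "C74", "C75",
               "C76", "C81", "C82", "C83", "C84", "C85", "C88", "C90", "C91",
               "C92", "C93", "C94", "C95", "C96", "C97"),
    severe_liver = c("I850", "I859", "I864", "I982", "K704", "K711", "K721",
                     "K729", "K765", "K766", "K767"),
    metastatic = c("C77", "C78", "C79", "C80"),
    aids = c("B20", "B21", "B22", "B24"),
    hypertension = c("I10", "I11", "I12", "I13", "I15"),
    depression = c("F32", "F33"),
    delirium = "F050",
    alcohol = "F10",
    psychotic = c("F20", "F21", "F22", "F23", "F24", "F25", "F28", "F29"),
    other_mental = c("F04", "F060", "F07", "F09", "F40", "F41", "F42", "F43",
                     "F44", "F45", "F48")
  )
  cci_weights <- c(
    mi = 1L, chf = 1L, pvd = 1L, cerebrovascular = 1L, dementia = 1L,
    copd = 1L, rheumatic = 1L, pud = 1L, mild_liver = 1L, diabetes = 1L,
    diabetes_complicated = 2L, hemiplegia = 2L, renal = 2L, cancer = 2L,
    severe_liver = 3L, metastatic = 6L, aids = 6L
  )
  codeset_config(
    dementia_codes = c("F00", "F01", "F02", "F03", "F051", "G30", "G311"),
    subtype_ad_codes = c("F00", "G30"),
    subtype_other_codes = c("F01", "F02", "F03", "F051", "G311"),
    comorbidity_map = comorbidity_map,
    cci_weights = cci_weights,
    pim_class_map = pim_class_map,
    combo_codes = combo_codes,
    min_dementia_claims = min_dementia_claims
  )
}

#' Names of the 17 Charlson comorbidity groups in a configuration
#' @param config a `codeset_config`.
#' @return character vector.
#' @export
cci_groups <- function(config) names(config$cci_weights)

#' Read / write a code-set configuration as YAML
#'
#' The on-disk YAML file is the per-run source of truth for every code list;
#' [default_codesets()] only provides a starting point.
#'
#' @param path file path.
#' @param config a `codeset_config`.
#' @return `read_codeset_config` returns a `codeset_config`;
#'   `write_codeset_config` returns `path` invisibly.
#' @export
read_codeset_config <- function(path) {
  y <- yaml::read_yaml(path)
  pim <- character()
  if (length(y$pim_class_map))
    pim <- setNames(unlist(y$pim_class_map, use.names = FALSE),
                    names(y$pim_class_map))
  codeset_config(
    dementia_codes = y$dementia_codes,
    subtype_ad_codes = y$subtype_ad_codes,
    subtype_other_codes = y$subtype_other_codes,
    comorbidity_map = y$comorbidity_map,
    cci_weights = setNames(as.integer(unlist(y$cci_weights)),
                           names(y$cci_weights)),
    pim_class_map = pim,
    combo_codes = y$combo_codes %||% character(),
    min_dementia_claims = y$min_dementia_claims %||% 1L
  )
}

#' @rdname read_codeset_config
#' @export
write_codeset_config <- function(config, path) {
  stopifnot(inherits(config, "codeset_config"))
  yaml::write_yaml(list(
    dementia_codes = config$dementia_codes,
    subtype_ad_codes = config$subtype_ad_codes,
    subtype_other_codes = config$subtype_other_codes,
    comorbidity_map = config$comorbidity_map,
    cci_weights = as.list(config$cci_weights),
    pim_class_map = as.list(config$pim_class_map),
    combo_codes = config$combo_codes,
    min_dementia_claims = config$min_dementia_claims
  ), path)
  invisible(path)
}
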