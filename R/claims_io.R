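#' Claims table schemas
#'
#' Three delimited-text tables emulate a claims-database extract:
#' \describe{
#'   \item{persons}{`person_id`, `birth_year`, `sex` (male/female),
#'     `income_index` (0 = medical aid, 1-10 = insurance deciles),
#'     `enroll_start`, `enroll_end`, `death_date` (blank when alive).}
#'   \item{diagnoses}{`person_id`, `icd10_code`, `service_date`,
#'     `setting` (outpatient/inpatient).}
#'   \item{prescriptions}{`person_id`, `drug_code`, `dispense_date`,
#'     `days_supplied` (>= 1), `ingredient_count` (>= 1; relevant for
#'     combination antihypertensive/antidiabetic products).}
#' }
#' Dates are ISO-8601 whole days. All readers/writers use UTF-8 with a header
#' row; the delimiter defaults to tab.
#' @name claims-schemas
NULL

.person_cols <- c("person_id", "birth_year", "sex", "income_index",
                  "enroll_start", "enroll_end", "death_date")
.diagnosis_cols <- c("person_id", "icd10_code", "service_date", "setting")
.prescription_cols <- c("person_id", "drug_code", "dispense_date",
                        "days_supplied", "ingredient_count")

parse_date_col <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  suppressWarnings(data.table::as.IDate(x, format = "%Y-%m-%d"))
}

# Validate one table, returning list(keep = data.table, rejected = diagnostics)
validate_rows <- function(dt, table) {
  bad <- data.table(line = integer(), rule = character())
  note <- function(idx, rule) {
    if (any(idx)) bad <<- rbind(bad, data.table(line = which(idx) + 1L,
                                                rule = rule))
  }
  if (table == "persons") {
    note(is.na(dt$enroll_start) | is.na(dt$enroll_end), "unparseable date")
    note(!dt$sex %in% c("male", "female"), "sex not in {male, female}")
    note(!is.na(dt$enroll_start) & !is.na(dt$enroll_end) &
           dt$enroll_start > dt$enroll_end, "enroll_start > enroll_end")
    note(!is.na(dt$death_date) & !is.na(dt$enroll_start) &
           dt$death_date < dt$enroll_start, "death_date before enroll_start")
  } else if (table == "diagnoses") {
    note(is.na(dt$service_date), "unparseable date")
    note(!grepl("^[A-Za-z][0-9A-Za-z]+$", dt$icd10_code),
         "icd10_code not letter+alphanumerics")
    note(!dt$setting %in% c("outpatient", "inpatient"),
         "setting not in {outpatient, inpatient}")
  } else if (table == "prescriptions") {
    note(is.na(dt$dispense_date), "unparseable date")
    note(is.na(dt$days_supplied) | dt$days_supplied < 1, "days_supplied < 1")
    note(is.na(dt$ingredient_count) | dt$ingredient_count < 1,
         "ingredient_count < 1")
  }
  bad[, table := rep(table, .N)]
  if (nrow(bad)) keep <- dt[-unique(bad$line - 1L)] else keep <- dt
  list(keep = keep, rejected = bad)
}

read_one_claims_table <- function(path, table, cols, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          encoding = "UTF-8", na.strings = NULL)
  missing <- setdiff(cols, names(dt))
  if (length(missing))
    stop(sprintf("schema error in %s (%s): missing column(s) %s",
                 table, path, paste(missing, collapse = ", ")))
  dt <- dt[, ..cols]
  if (table == "persons") {
    dt[, birth_year := suppressWarnings(as.integer(birth_year))]
    dt[, income_index := suppressWarnings(as.integer(income_index))]
    dt[, enroll_start := parse_date_col(enroll_start)]
    dt[, enroll_end := parse_date_col(enroll_end)]
    dt[, death_date := parse_date_col(death_date)]
  } else if (table == "diagnoses") {
    dt[, icd10_code := toupper(icd10_code)]
    dt[, service_date := parse_date_col(service_date)]
  } else {
    dt[, dispense_date := parse_date_col(dispense_date)]
    dt[, days_supplied := suppressWarnings(as.integer(days_supplied))]
    dt[, ingredient_count := suppressWarnings(as.integer(ingredient_count))]
  }
  validate_rows(dt, table)
}

#' Read the three claims tables
#'
#' Reads, types and validates the persons, diagnoses and prescriptions tables
#' (see [claims-schemas]). Rows violating a record invariant are dropped with
#' a row-level diagnostic (file line number and the rule violated), collected
#' in the `rejected` element and reported once as a warning; a missing column
#' is a hard schema error naming the column.
#'
#' @param paths named list or vector with elements `persons`, `diagnoses`,
#'   `prescriptions` (file paths), e.g. as produced by [write_claims()].
#' @param sep field delimiter (default tab).
#' @return list with elements `persons`, `diagnoses`, `prescriptions`
#'   (data.tables) and `rejected` (diagnostics, zero rows when clean).
#' @export
read_claims <- function(paths, sep = "\t") {
  paths <- as.list(paths)
  stopifnot(all(c("persons", "diagnoses", "prescriptions") %in% names(paths)))
  p <- read_one_claims_table(paths$persons, "persons", .person_cols, sep)
  d <- read_one_claims_table(paths$diagnoses, "diagnoses", .diagnosis_cols, sep)
  rx <- read_one_claims_table(paths$prescriptions, "prescriptions",
                              .prescription_cols, sep)
  rejected <- rbind(p$rejected, d$rejected, rx$rejected)
  if (nrow(rejected))
    warning(sprintf("%d row(s) rejected; see $rejected (first: %s line %d, %s)",
                    nrow(rejected), rejected$table[1], rejected$line[1],
                    rejected$rule[1]))
  list(persons = p$keep, diagnoses = d$keep, prescriptions = rx$keep,
       rejected = rejected)
}

#' Write the three claims tables
#'
#' Writes UTF-8 delimited text with a header row and ISO-8601 dates, with a
#' stable column order, so that [read_claims()] reproduces every field
#' exactly.
#'
#' @param claims list with `persons`, `diagnoses`, `prescriptions`.
#' @param dir output directory (created if needed).
#' @param sep field delimiter (default tab).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_claims <- function(claims, dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(persons = file.path(dir, "persons.tsv"),
             diagnoses = file.path(dir, "diagnoses.tsv"),
             prescriptions = file.path(dir, "prescriptions.tsv"))
  data.table::fwrite(claims$persons[, .SD, .SDcols = .person_cols],
                     paths["persons"], sep = sep, dateTimeAs = "ISO")
  data.table::fwrite(claims$diagnoses[, .SD, .SDcols = .diagnosis_cols],
                     paths["diagnoses"], sep = sep, dateTimeAs = "ISO")
  data.table::fwrite(claims$prescriptions[, .SD, .SDcols = .prescription_cols],
                     paths["prescriptions"], sep = sep, dateTimeAs = "ISO")
  invisible(paths)
}
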