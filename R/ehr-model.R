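#' Controlled vocabularies for the EHR data model
#'
#' The data model covers five flat tables (patients, prescriptions, labs,
#' diagnoses, procedures) emulating a hospital-network extract. Drug codes
#' cover the direct-acting antivirals (DAAs) marketed in Japan during the
#' study window plus the interferon-era backbone drugs; combination products
#' (e.g. ledipasvir/sofosbuvir) are single codes and are never decomposed.
#' Strings outside a vocabulary are bucketed to `"OTHER"` on import.
#'
#' @return A character vector of valid codes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
daa_codes <- function() {
  c("TVR", "SMV", "ASV", "DCV", "VAN", "SOF", "GZR", "EBV",
    "LDV_SOF", "OBV_PTV_r", "DCV_ASV_BCV")
}

#' @rdname vocabularies
#' @export
drug_codes <- function() {
  c(daa_codes(), "PEG_IFN", "RIB", "OTHER")
}

#' @rdname vocabularies
#' @export
condition_codes <- function() {
  c("diabetes", "heart_failure", "hypertension",
    "chronic_kidney_disease", "renal_failure", "OTHER")
}

#' @rdname vocabularies
#' @export
procedure_codes <- function() {
  c("renal_dialysis", "renal_transplantation", "OTHER")
}

#' @rdname vocabularies
#' @export
analyte_codes <- function() {
  c("eGFR", "sCRE")
}

table_schemas <- function() {
  list(
    patients      = c("patient_id", "sex", "birth_date"),
    prescriptions = c("patient_id", "drug", "start_date", "days_supply"),
    labs          = c("patient_id", "date", "analyte", "value"),
    diagnoses     = c("patient_id", "date", "condition"),
    procedures    = c("patient_id", "date", "procedure")
  )
}

empty_table <- function(name) {
  switch(name,
    patients = tibble::tibble(
      patient_id = character(), sex = character(),
      birth_date = as.Date(character())),
    prescriptions = tibble::tibble(
      patient_id = character(), drug = character(),
      start_date = as.Date(character()), days_supply = integer()),
    labs = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      analyte = character(), value = double()),
    diagnoses = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      condition = character()),
    procedures = tibble::tibble(
      patient_id = character(), date = as.Date(character()),
      procedure = character()),
    stop("unknown table: ", name)
  )
}

stop_rows <- function(table, rows, what) {
  stop(sprintf("%s: %s at row(s) %s", table, what,
               paste(utils::head(rows, 10), collapse = ", ")),
       call. = FALSE)
}

validate_tables <- function(patients, prescriptions, labs, diagnoses,
                            procedures, study_end) {
  if (anyDuplicated(patients$patient_id))
    stop_rows("patients", which(duplicated(patients$patient_id)),
              "duplicate patient_id")
  bad <- which(!patients$sex %in% c("male", "female"))
  if (length(bad)) stop_rows("patients", bad, "sex must be male/female")

  bad <- which(is.na(prescriptions$days_supply) | prescriptions$days_supply < 1)
  if (length(bad)) stop_rows("prescriptions", bad, "days_supply must be >= 1")
  bad <- which(!prescriptions$drug %in% drug_codes())
  if (length(bad)) stop_rows("prescriptions", bad, "unknown drug code")

  bad <- which(is.na(labs$value) | labs$value <= 0)
  if (length(bad)) stop_rows("labs", bad, "value must be > 0")
  bad <- which(!labs$analyte %in% analyte_codes())
  if (length(bad)) stop_rows("labs", bad, "analyte must be eGFR or sCRE")

  bad <- which(!diagnoses$condition %in% condition_codes())
  if (length(bad)) stop_rows("diagnoses", bad, "unknown condition code")
  bad <- which(!procedures$procedure %in% procedure_codes())
  if (length(bad)) stop_rows("procedures", bad, "unknown procedure code")

  for (nm in c("prescriptions", "labs", "diagnoses", "procedures")) {
    tab <- switch(nm, prescriptions = prescriptions, labs = labs,
                  diagnoses = diagnoses, procedures = procedures)
    dates <- if (nm == "prescriptions") tab$start_date else tab$date
    bad <- which(is.na(dates))
    if (length(bad)) stop_rows(nm, bad, "unparseable date")
    bad <- which(dates > study_end)
    if (length(bad)) stop_rows(nm, bad, "date after study_end")
  }
  invisible(TRUE)
}

#' Assemble and validate a study dataset
#'
#' Bundles the five EHR tables with the study window into a validated
#' `study_dataset` object. Dates are calendar dates (class `Date`) with
#' integer-day arithmetic; no times of day exist in the model. The first
#' recorded date per patient — the quantity the new-user rule is anchored
#' on — is computed as the minimum date over all four dated tables.
#'
#' @param patients,prescriptions,labs,diagnoses,procedures Tibbles following
#'   the documented CSV schemas (see [read_dataset()]).
#' @param study_start,study_end Calendar dates delimiting the study period.
#' @return A `study_dataset`: a list with the five tables, the study window,
#'   and a `first_record` tibble (`patient_id`, `first_record_date`).
#' @export
study_dataset <- function(patients, prescriptions, labs, diagnoses, procedures,
                          study_start, study_end) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(!is.na(study_start), !is.na(study_end), study_start <= study_end)
  patients <- tibble::as_tibble(patients)
  prescriptions <- tibble::as_tibble(prescriptions)
  labs <- tibble::as_tibble(labs)
  diagnoses <- tibble::as_tibble(diagnoses)
  procedures <- tibble::as_tibble(procedures)
  validate_tables(patients, prescriptions, labs, diagnoses, procedures,
                  study_end)

  dated <- dplyr::bind_rows(
    dplyr::select(prescriptions, "patient_id", date = "start_date"),
    dplyr::select(labs, "patient_id", "date"),
    dplyr::select(diagnoses, "patient_id", "date"),
    dplyr::select(procedures, "patient_id", "date")
  )
  first_record <- if (nrow(dated) == 0) {
    tibble::tibble(patient_id = character(),
                   first_record_date = as.Date(character()))
  } else {
    dplyr::summarise(dplyr::group_by(dated, .data$patient_id),
                     first_record_date = min(.data$date), .groups = "drop")
  }

  structure(
    list(patients = patients, prescriptions = prescriptions, labs = labs,
         diagnoses = diagnoses, procedures = procedures,
         study_start = study_start, study_end = study_end,
         first_record = first_record),
    class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", format(x$study_start), " .. ", format(x$study_end),
      "\n", sep = "")
  cat(sprintf("  patients: %d  prescriptions: %d  labs: %d  diagnoses: %d  procedures: %d\n",
              nrow(x$patients), nrow(x$prescriptions), nrow(x$labs),
              nrow(x$diagnoses), nrow(x$procedures)))
  invisible(x)
}

read_one_table <- function(path, name) {
  schema <- table_schemas()[[name]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(schema, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  tab <- tab[schema]
  if (name == "prescriptions")
    tab$days_supply <- suppressWarnings(as.integer(tab$days_supply))
  if (name == "labs")
    tab$value <- suppressWarnings(as.numeric(tab$value))
  tab
}

parse_date_col <- function(x, table, col) {
  d <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & is.na(d))
  if (length(bad))
    stop_rows(table, bad, sprintf("unparseable date in '%s'", col))
  bad <- which(is.na(x))
  if (length(bad)) stop_rows(table, bad, sprintf("missing date in '%s'", col))
  d
}

bucket_vocab <- function(x, vocab, table, col) {
  unknown <- !x %in% vocab
  if (any(unknown)) {
    warning(sprintf("%s: %d unknown %s value(s) bucketed to OTHER",
                    table, sum(unknown), col), call. = FALSE)
    x[unknown] <- "OTHER"
  }
  x
}

#' Read a study dataset from five CSV files
#'
#' Files are comma-separated UTF-8 with a mandatory header row and ISO-8601
#' (`YYYY-MM-DD`) dates. Missing required columns raise a schema error naming
#' the column; unparseable dates and non-positive lab values raise row-level
#' errors with the offending row index. Drug, condition and procedure strings
#' outside the controlled vocabularies are bucketed to `"OTHER"` with a
#' warning reporting the count — malformed rows are never silently dropped.
#'
#' @param paths Either a directory containing `patients.csv`,
#'   `prescriptions.csv`, `labs.csv`, `diagnoses.csv`, `procedures.csv`, or a
#'   named character vector/list with those five names.
#' @param study_start,study_end The study window (defaults: 2009-01-01 to
#'   2017-12-31).
#' @return A validated [study_dataset()].
#' @export
read_dataset <- function(paths, study_start = "2009-01-01",
                         study_end = "2017-12-31") {
  nms <- names(table_schemas())
  if (length(paths) == 1 && is.null(names(paths))) {
    paths <- stats::setNames(file.path(paths, paste0(nms, ".csv")), nms)
  }
  missing <- setdiff(nms, names(paths))
  if (length(missing))
    stop("missing table path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  patients <- read_one_table(paths[["patients"]], "patients")
  patients$birth_date <- parse_date_col(patients$birth_date, "patients",
                                        "birth_date")
  prescriptions <- read_one_table(paths[["prescriptions"]], "prescriptions")
  prescriptions$start_date <- parse_date_col(prescriptions$start_date,
                                             "prescriptions", "start_date")
  prescriptions$drug <- bucket_vocab(prescriptions$drug, drug_codes(),
                                     "prescriptions", "drug")
  labs <- read_one_table(paths[["labs"]], "labs")
  labs$date <- parse_date_col(labs$date, "labs", "date")
  diagnoses <- read_one_table(paths[["diagnoses"]], "diagnoses")
  diagnoses$date <- parse_date_col(diagnoses$date, "diagnoses", "date")
  diagnoses$condition <- bucket_vocab(diagnoses$condition, condition_codes(),
                                      "diagnoses", "condition")
  procedures <- read_one_table(paths[["procedures"]], "procedures")
  procedures$date <- parse_date_col(procedures$date, "procedures", "date")
  procedures$procedure <- bucket_vocab(procedures$procedure,
                                       procedure_codes(), "procedures",
                                       "procedure")

  study_dataset(patients, prescriptions, labs, diagnoses, procedures,
                study_start, study_end)
}

#' Write a study dataset to five CSV files
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(d, dir))`
#' reproduces `d` exactly (dates, values, vocabularies). An empty dataset
#' yields five header-only files.
#'
#' @param dataset A [study_dataset()].
#' @param directory Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, directory) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  nms <- names(table_schemas())
  paths <- stats::setNames(file.path(directory, paste0(nms, ".csv")), nms)
  for (nm in nms) readr::write_csv(dataset[[nm]], paths[[nm]], progress = FALSE)
  invisible(paths)
}
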