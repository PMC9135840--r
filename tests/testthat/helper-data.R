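# Small dataset builders for constructing targeted test cases in code.

tbl_patients <- function(ids, sex = "male", birth = "1950-06-15") {
  tibble::tibble(patient_id = ids, sex = sex, birth_date = as.Date(birth))
}

tbl_rx <- function(id, drug, start, supply = 84L) {
  tibble::tibble(patient_id = id, drug = drug, start_date = as.Date(start),
                 days_supply = as.integer(supply))
}

tbl_lab <- function(id, date, value, analyte = "eGFR") {
  tibble::tibble(patient_id = id, date = as.Date(date), analyte = analyte,
                 value = value)
}

tbl_dx <- function(id, date, condition = "OTHER") {
  tibble::tibble(patient_id = id, date = as.Date(date),
                 condition = condition)
}

tbl_px <- function(id, date, procedure) {
  tibble::tibble(patient_id = id, date = as.Date(date),
                 procedure = procedure)
}

# one LDV/SOF user with a clean baseline and long history, as a base case
basic_dataset <- function(patients, prescriptions, labs,
                          diagnoses = NULL, procedures = NULL,
                          study_start = "2009-01-01",
                          study_end = "2017-12-31") {
  study_dataset(
    patients, prescriptions, labs,
    diagnoses %||% tibble::tibble(patient_id = character(),
                                  date = as.Date(character()),
                                  condition = character()),
    procedures %||% tibble::tibble(patient_id = character(),
                                   date = as.Date(character()),
                                   procedure = character()),
    study_start, study_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a single-patient dataset: LDV/SOF at t0, anchor record 200 days before,
# baseline eGFR at t0 - 10; extra rows appended via arguments
one_user_dataset <- function(t0 = as.Date("2016-03-01"), baseline = 75,
                             extra_rx = NULL, extra_labs = NULL,
                             extra_dx = NULL, extra_px = NULL,
                             drug = "LDV_SOF", supply = 84L,
                             sex = "male", birth = "1950-06-15",
                             study_end = "2017-12-31") {
  rx <- dplyr::bind_rows(tbl_rx("X1", drug, t0, supply), extra_rx)
  labs <- dplyr::bind_rows(tbl_lab("X1", t0 - 10, baseline), extra_labs)
  dx <- dplyr::bind_rows(tbl_dx("X1", t0 - 200), extra_dx)
  basic_dataset(tbl_patients("X1", sex, birth), rx, labs, dx, extra_px,
                study_end = study_end)
}

# random valid study dataset for round-trip property tests
random_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(3:10, 1)
  ids <- sprintf("R%03d", seq_len(n))
  start <- as.Date("2009-01-01")
  rdate <- function(k) start + sample(0:3200, k, replace = TRUE)
  patients <- tibble::tibble(
    patient_id = ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    birth_date = as.Date("1940-01-01") + sample(0:10000, n, TRUE))
  k <- sample(1:20, 1)
  prescriptions <- tibble::tibble(
    patient_id = sample(ids, k, TRUE),
    drug = sample(drug_codes(), k, TRUE),
    start_date = rdate(k),
    days_supply = sample(1:90, k, TRUE))
  k <- sample(1:30, 1)
  labs <- tibble::tibble(
    patient_id = sample(ids, k, TRUE), date = rdate(k),
    analyte = sample(c("eGFR", "sCRE"), k, TRUE),
    value = round(stats::runif(k, 0.4, 120), 4))
  k <- sample(1:10, 1)
  diagnoses <- tibble::tibble(
    patient_id = sample(ids, k, TRUE), date = rdate(k),
    condition = sample(condition_codes(), k, TRUE))
  k <- sample(1:5, 1)
  procedures <- tibble::tibble(
    patient_id = sample(ids, k, TRUE), date = rdate(k),
    procedure = sample(procedure_codes(), k, TRUE))
  study_dataset(patients, prescriptions, labs, diagnoses, procedures,
                "2009-01-01", "2017-12-31")
}
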