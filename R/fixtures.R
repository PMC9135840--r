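# Hand-constructed fixtures with exhaustively known pipeline outputs.

fixture_user_records <- function(pid, pattern, t0, baseline = 75,
                                 sex = "male", birth = "1955-06-15",
                                 post_labs = c(20, 50),
                                 post_values = NULL, supply = 84L) {
  t0 <- as.Date(t0)
  epat <- exposure_patterns()
  k <- match(pattern, epat$pattern)
  anchors <- if (pattern == "P3_DCV_ASV") c("DCV", "ASV")
             else if (pattern == "P6_EBV_GZR") c("EBV", "GZR")
             else epat$anchor[[k]]
  drugs <- c(anchors, epat$required[[k]])
  if (is.null(post_values)) post_values <- rep(baseline, length(post_labs))
  list(
    patients = tibble::tibble(patient_id = pid, sex = sex,
                              birth_date = as.Date(birth)),
    prescriptions = tibble::tibble(
      patient_id = pid, drug = drugs, start_date = t0,
      days_supply = ifelse(drugs %in% anchors, supply, 28L)),
    labs = tibble::tibble(
      patient_id = pid,
      date = c(t0 - 10, t0 + post_labs),
      analyte = "eGFR", value = c(baseline, post_values)),
    diagnoses = tibble::tibble(patient_id = pid, date = t0 - 200,
                               condition = "OTHER"))
}

bind_fixture <- function(parts, study_start = "2009-01-01",
                         study_end = "2017-12-31") {
  get <- function(nm) {
    rows <- lapply(parts, function(p) p[[nm]])
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) dplyr::bind_rows(rows) else empty_table(nm)
  }
  study_dataset(get("patients"), get("prescriptions"), get("labs"),
                get("diagnoses"), get("procedures"),
                study_start, study_end)
}

fixture_truth_row <- function(pid, role, pattern, t0, baseline,
                              event_day = NA_real_, eligible = FALSE,
                              history = 200L, insufficient = FALSE, ...) {
  carriers <- list(excl_diabetes = FALSE, excl_heart_failure = FALSE,
                   excl_hypertension = FALSE, excl_ckd_renal = FALSE,
                   excl_dialysis_transplant = FALSE,
                   excl_missing_baseline_lab = FALSE,
                   excl_low_baseline = FALSE)
  carriers[names(list(...))] <- list(...)
  tibble::tibble(patient_id = pid, role = role, pattern = pattern,
                 t0 = as.Date(t0), history_days = history,
                 baseline_egfr = baseline, true_event_day = event_day,
                 !!!carriers, insufficient_history = insufficient,
                 eligible = eligible)
}

make_tiny_fixture <- function() {
  t0 <- as.Date("2016-03-01")
  pats <- pattern_names()
  parts <- lapply(seq_along(pats), function(i) {
    fixture_user_records(sprintf("T%02d", i), pats[i], t0 + i)
  })
  # the P1 patient has a one-category drop on day 20 (75 -> 55)
  parts[[1]]$labs$value[2] <- 55
  # a non-user and an insufficient-history user
  parts[[11]] <- list(
    patients = tibble::tibble(patient_id = "T11", sex = "female",
                              birth_date = as.Date("1960-01-01")),
    prescriptions = tibble::tibble(patient_id = "T11", drug = "OTHER",
                                   start_date = t0, days_supply = 30L),
    labs = tibble::tibble(patient_id = "T11", date = t0 - 10,
                          analyte = "eGFR", value = 80))
  short <- fixture_user_records("T12", "P7_LDV_SOF", t0)
  short$diagnoses$date <- t0 - 30  # records start only 30 days before t0
  parts[[12]] <- short

  truth <- dplyr::bind_rows(c(
    lapply(seq_along(pats), function(i) {
      fixture_truth_row(sprintf("T%02d", i), "user", pats[i], t0 + i, 75,
                        event_day = if (i == 1) 20 else NA_real_,
                        eligible = TRUE)
    }),
    list(fixture_truth_row("T11", "non_user", NA_character_, t0, 80),
         fixture_truth_row("T12", "user", "P7_LDV_SOF", t0, 75,
                           history = 30L, insufficient = TRUE))))
  list(dataset = bind_fixture(parts), truth = truth)
}

make_attrition_fixture <- function() {
  t0 <- as.Date("2016-06-01")
  p7 <- function(pid, ...) fixture_user_records(pid, "P7_LDV_SOF", t0, ...)

  a1 <- p7("A1", baseline = 40)           # eGFR < 45 in window
  a1$labs <- a1$labs[1, ]                  # only the low pre-t0 value
  a1$labs$date <- t0 - 30

  a2 <- p7("A2")                           # dialysis before t0
  a2$procedures <- tibble::tibble(patient_id = "A2", date = t0 - 300,
                                  procedure = "renal_dialysis")

  a3 <- p7("A3")                           # diabetes before t0
  a3$diagnoses <- dplyr::bind_rows(
    a3$diagnoses,
    tibble::tibble(patient_id = "A3", date = t0 - 1000,
                   condition = "diabetes"))

  a4 <- p7("A4")                           # no kidney lab in window
  a4$labs <- a4$labs[1, ]
  a4$labs$date <- t0 - 120

  a5 <- p7("A5")                           # multiple DAAs at t0
  a5$prescriptions <- tibble::tibble(
    patient_id = "A5", drug = c("LDV_SOF", "SOF"), start_date = t0,
    days_supply = 84L)

  a6 <- fixture_user_records("A6", "P1_TVR_PegIFN_Rib", t0)
  a6$prescriptions <- a6$prescriptions[a6$prescriptions$drug == "TVR", ]
  # telaprevir without peginterferon/ribavirin: criterion (6)

  a8 <- p7("A8")                           # carries criteria (2) and (3)
  a8$diagnoses <- dplyr::bind_rows(
    a8$diagnoses,
    tibble::tibble(patient_id = "A8", date = c(t0 - 400, t0 - 500),
                   condition = c("chronic_kidney_disease", "hypertension")))

  a7 <- p7("A7")                           # records start 30 days before t0
  a7$diagnoses$date <- t0 - 30

  e1 <- p7("E1")
  e2 <- fixture_user_records("E2", "P3_DCV_ASV", t0)
  e3 <- fixture_user_records("E3", "P5_SOF_Rib", t0)

  dataset <- bind_fixture(list(a1, a2, a3, a4, a5, a6, a7, a8, e1, e2, e3))
  truth <- dplyr::bind_rows(
    fixture_truth_row("A1", "user", "P7_LDV_SOF", t0, 40,
                      excl_low_baseline = TRUE),
    fixture_truth_row("A2", "user", "P7_LDV_SOF", t0, 75,
                      excl_dialysis_transplant = TRUE),
    fixture_truth_row("A3", "user", "P7_LDV_SOF", t0, 75,
                      excl_diabetes = TRUE),
    fixture_truth_row("A4", "user", "P7_LDV_SOF", t0, 75,
                      excl_missing_baseline_lab = TRUE),
    fixture_truth_row("A5", "user", NA_character_, t0, 75),
    fixture_truth_row("A6", "user", NA_character_, t0, 75),
    fixture_truth_row("A7", "user", "P7_LDV_SOF", t0, 75, history = 30L,
                      insufficient = TRUE),
    fixture_truth_row("A8", "user", "P7_LDV_SOF", t0, 75,
                      excl_ckd_renal = TRUE, excl_hypertension = TRUE),
    fixture_truth_row("E1", "user", "P7_LDV_SOF", t0, 75, eligible = TRUE),
    fixture_truth_row("E2", "user", "P3_DCV_ASV", t0, 75, eligible = TRUE),
    fixture_truth_row("E3", "user", "P5_SOF_Rib", t0, 75, eligible = TRUE))
  expected <- list(
    new_users_identified = 11L, insufficient_history = 1L,
    candidates = 10L,
    excluded = c(c1_low_egfr = 1L, c2_renal_history = 2L,
                 c3_comorbidity = 2L, c4_no_baseline_lab = 1L,
                 c5_multiple_daas = 1L, c6_missing_concomitant = 1L),
    final_cohort = c("E1", "E2", "E3"))
  list(dataset = dataset, truth = truth, expected_attrition = expected)
}

#' Packaged fixtures with constructed ground truth
#'
#' * `"tiny"` — 12 hand-built patients covering all ten prescription
#'   patterns (the P1 patient has a one-category eGFR drop on day 20), a
#'   non-user, and an insufficient-history user; the eligible cohort is the
#'   ten pattern patients.
#' * `"attrition"` — one patient per exclusion criterion plus one carrying
#'   two criteria, an insufficient-history patient, and three eligible
#'   patients; `expected_attrition` carries the constructed flowchart
#'   counts.
#' * `"null"` — a simulated dataset (default 500 patients) with every true
#'   rate ratio equal to 1, for type-I-error calibration; `config` carries
#'   the generating configuration.
#'
#' @param name `"tiny"`, `"attrition"` or `"null"`.
#' @param seed Seed for the `"null"` simulation (ignored otherwise).
#' @param n_patients Size of the `"null"` simulation.
#' @return A list with `dataset`, `truth` and fixture-specific extras.
#' @export
make_fixture <- function(name, seed = 1, n_patients = 500) {
  switch(name,
    tiny = make_tiny_fixture(),
    attrition = make_attrition_fixture(),
    null = {
      cfg <- simulation_config(n_patients = n_patients, seed = seed)
      c(simulate_dataset(cfg), list(config = cfg))
    },
    stop("unknown fixture: ", name, call. = FALSE))
}
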