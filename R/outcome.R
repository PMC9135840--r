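#' eGFR from serum creatinine (Japanese GFR equation)
#'
#' Estimated glomerular filtration rate from serum creatinine by the
#' Japanese Society of Nephrology equation:
#' male `194 * sCRE^-1.094 * age^-0.287`, female the male value times 0.739.
#'
#' @param scre Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0); completed years at the measurement date.
#' @param sex `"male"` or `"female"` (vectorised).
#' @return eGFR in mL/min/1.73 m^2.
#' @seealso [scre_from_egfr()] for the exact inverse.
#' @export
egfr_from_scre <- function(scre, age, sex) {
  if (any(is.na(scre)) || any(scre <= 0))
    stop("scre must be > 0", call. = FALSE)
  if (any(is.na(age)) || any(age <= 0))
    stop("age must be > 0", call. = FALSE)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  194 * scre^-1.094 * age^-0.287 * ifelse(sex == "female", 0.739, 1)
}

#' Serum creatinine yielding a given eGFR
#'
#' Exact algebraic inverse of [egfr_from_scre()] in `scre`; used by the
#' synthetic-data generator to plant creatinine values whose converted eGFR
#' is known, and convenient for constructing boundary cases in tests.
#'
#' @param egfr Target eGFR, mL/min/1.73 m^2 (> 0).
#' @inheritParams egfr_from_scre
#' @return Serum creatinine in mg/dL.
#' @export
scre_from_egfr <- function(egfr, age, sex) {
  if (any(is.na(egfr)) || any(egfr <= 0))
    stop("egfr must be > 0", call. = FALSE)
  base <- 194 * age^-0.287 * ifelse(sex == "female", 0.739, 1)
  (egfr / base)^(-1 / 1.094)
}

# KDIGO G-category lower bounds, best to worst; index 0 = normal/high.
category_lower_bounds <- c(90, 60, 45, 30, 15, 0)

category_labels <- c("G_normal", "G_mild", "G_mild_mod",
                     "G_mod_sev", "G_sev", "G_failure")

#' KDIGO eGFR category boundaries
#'
#' @return A tibble with the six ordered kidney-function categories, their
#'   ordinal index (0 best .. 5 worst) and half-open eGFR bounds
#'   (lower inclusive, upper exclusive), in mL/min/1.73 m^2.
#' @export
category_bounds <- function() {
  tibble::tibble(
    index = 0:5,
    category = category_labels,
    lower = category_lower_bounds,
    upper = c(Inf, 90, 60, 45, 30, 15)
  )
}

#' Ordinal KDIGO category index of an eGFR value
#'
#' Categories follow the KDIGO G staging with inclusive lower bounds:
#' >= 90 normal/high, 90 > x >= 60 mild, 60 > x >= 45 mild-moderate,
#' 45 > x >= 30 moderate-severe, 30 > x >= 15 severe, < 15 kidney failure.
#' The outcome of interest is an increase of this index from baseline.
#'
#' @param egfr eGFR values, mL/min/1.73 m^2 (> 0).
#' @return Integer index, 0 (best) to 5 (worst).
#' @export
egfr_category_index <- function(egfr) {
  if (any(is.na(egfr)) || any(egfr <= 0))
    stop("egfr must be > 0", call. = FALSE)
  5L - findInterval(egfr, c(15, 30, 45, 60, 90))
}

#' @rdname egfr_category_index
#' @return `egfr_category()`: an ordered factor, best to worst.
#' @export
egfr_category <- function(egfr) {
  factor(category_labels[egfr_category_index(egfr) + 1L],
         levels = category_labels, ordered = TRUE)
}

#' Collapse lab results to one eGFR value per patient-day
#'
#' Recorded eGFR takes precedence: if one or more eGFR results exist on a
#' day, the value is their mean (source `mean_of_multiple` when more than
#' one). Only when no eGFR was recorded is serum creatinine converted via
#' [egfr_from_scre()] (mean of converted values, source
#' `converted_from_sCRE`); age enters the conversion as completed years at
#' the laboratory date.
#'
#' @param labs Lab table (`patient_id`, `date`, `analyte`, `value`).
#' @param patients Patient table (`patient_id`, `sex`, `birth_date`).
#' @return A tibble, one row per patient-day: `patient_id`, `date`, `value`,
#'   `source` in `{recorded, mean_of_multiple, converted_from_sCRE}`.
#' @export
build_daily_egfr <- function(labs, patients) {
  if (nrow(labs) == 0) {
    return(tibble::tibble(patient_id = character(),
                          date = as.Date(character()),
                          value = double(), source = character()))
  }
  pm <- match(labs$patient_id, patients$patient_id)
  rec <- labs$analyte == "eGFR"
  egfr <- labs$value
  if (any(!rec)) {
    i <- which(!rec)
    egfr[i] <- egfr_from_scre(
      labs$value[i],
      age_from_ints(day_int(patients$birth_date[pm[i]]),
                    day_int(labs$date[i])),
      patients$sex[pm[i]])
  }
  key <- paste0(labs$patient_id, "\r", unclass(labs$date))
  first <- which(!duplicated(key))
  g <- match(key, key[first])
  n_rec <- unname(rowsum(as.numeric(rec), g)[, 1])
  sum_rec <- unname(rowsum(ifelse(rec, egfr, 0), g)[, 1])
  n_conv <- unname(rowsum(as.numeric(!rec), g)[, 1])
  sum_conv <- unname(rowsum(ifelse(rec, 0, egfr), g)[, 1])
  value <- ifelse(n_rec > 0, sum_rec / pmax(n_rec, 1),
                  sum_conv / pmax(n_conv, 1))
  out <- tibble::tibble(
    patient_id = labs$patient_id[first],
    date = labs$date[first],
    value = value,
    source = ifelse(n_rec > 1, "mean_of_multiple",
                    ifelse(n_rec == 1, "recorded", "converted_from_sCRE")))
  out[order(out$patient_id, out$date), ]
}

#' Baseline eGFR for a cohort entry
#'
#' The baseline is the daily eGFR value closest to the index date `t0`
#' within the 90 days before it — the window `[t0 - 90, t0 - 1]`. The value
#' at `t0` itself is never used (event timing within a day is unknown, so a
#' same-day value could post-date the first prescription).
#'
#' @param t0 Index date (first DAA prescription date).
#' @param daily Daily eGFR rows for one patient (from [build_daily_egfr()]).
#' @return A list: `value`, `category` (label), `index`, `date`.
#' @export
baseline_egfr <- function(t0, daily) {
  t0 <- as.Date(t0)
  w <- daily$date >= t0 - 90 & daily$date <= t0 - 1
  if (!any(w))
    stop("no eGFR value in [t0-90, t0-1]; entry should have been excluded",
         call. = FALSE)
  d <- daily[w, ]
  i <- which.max(as.integer(d$date))
  idx <- egfr_category_index(d$value[i])
  list(value = d$value[i], category = category_labels[idx + 1L],
       index = idx, date = d$date[i])
}

# Core follow-up scan on integer days. Censor candidates are evaluated in
# the listed precedence (treatment end, pattern change, study end); an
# outcome on the same day as a censor wins.
follow_up_core <- function(t0, base_index, lab_days, lab_index,
                           grace_end, change_day, study_end, drop_threshold) {
  ends <- c(treatment_end = grace_end,
            pattern_change = if (is.na(change_day)) NA_integer_
                             else change_day - 1L,
            study_end = study_end)
  cap <- min(ends, na.rm = TRUE)
  reason <- names(ends)[which.min(ends)]
  hit <- which(lab_days > t0 & lab_days <= cap &
                 lab_index >= base_index + drop_threshold)
  if (length(hit)) {
    ev <- min(lab_days[hit])
    list(event = TRUE, end_day = ev, reason = "outcome",
         person_days = ev - t0)
  } else {
    list(event = FALSE, end_day = cap, reason = reason,
         person_days = max(cap - t0, 0L))
  }
}

#' Follow a cohort entry to event or censoring
#'
#' Scans the patient's daily eGFR series over `(t0, end]` in date order and
#' returns the first of four terminating dates: occurrence of the outcome (a
#' drop of at least `drop_threshold` KDIGO categories from baseline), end of
#' the treatment episode, the day before a change to another prescription
#' pattern, or the end of the study period. Ties on the same day resolve in
#' that order, so an outcome on a censoring day is still an event. Values on
#' `t0` itself are ignored. Person-days equal `end_date - t0` and are 0 when
#' follow-up ends at `t0`.
#'
#' @param t0 Index date.
#' @param baseline_index Baseline KDIGO category index (0..5).
#' @param daily Daily eGFR rows for the patient (`date`, `value`).
#' @param episode A treatment episode from [build_treatment_episode()].
#' @param change_date Pattern-change date from [detect_pattern_change()], or
#'   `NULL`/`NA` if none.
#' @param study_end End of the study period.
#' @param drop_threshold 1 (primary outcome) or 2 (sensitivity definition).
#' @return One-row tibble: `outcome` (`event`/`censored`), `end_date`,
#'   `end_reason` (`outcome`, `treatment_end`, `pattern_change`,
#'   `study_end`), `person_days`.
#' @export
follow_up <- function(t0, baseline_index, daily, episode, change_date = NULL,
                      study_end, drop_threshold = 1) {
  stopifnot(drop_threshold %in% c(1, 2))
  t0 <- as.Date(t0)
  change_day <- if (is.null(change_date) || all(is.na(change_date)))
    NA_integer_ else day_int(change_date)
  res <- follow_up_core(
    t0 = day_int(t0), base_index = as.integer(baseline_index),
    lab_days = day_int(daily$date),
    lab_index = egfr_category_index(daily$value),
    grace_end = day_int(episode$grace_end),
    change_day = change_day,
    study_end = day_int(as.Date(study_end)),
    drop_threshold = as.integer(drop_threshold))
  tibble::tibble(
    outcome = if (res$event) "event" else "censored",
    end_date = int_day(res$end_day),
    end_reason = res$reason,
    person_days = as.integer(res$person_days))
}
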