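#' Follow every cohort patient to event or censoring
#'
#' Builds each patient's treatment episode and pattern-change date and runs
#' the follow-up scan, returning one row per cohort patient.
#'
#' @param cohort Cohort tibble from [apply_exclusions()].
#' @param dataset The [study_dataset()].
#' @param daily Optional precomputed [build_daily_egfr()] table.
#' @param drop_threshold 1 (primary) or 2 (sensitivity outcome).
#' @return A tibble: cohort columns plus `episode_start`, `episode_end`,
#'   `change_date`, `outcome`, `end_date`, `end_reason`, `person_days`.
#' @export
follow_up_cohort <- function(cohort, dataset, daily = NULL,
                             drop_threshold = 1) {
  stopifnot(drop_threshold %in% c(1, 2))
  if (is.null(daily)) daily <- build_daily_egfr(dataset$labs,
                                                dataset$patients)
  n <- nrow(cohort)
  empty <- tibble::tibble(
    episode_start = as.Date(character()), episode_end = as.Date(character()),
    change_date = as.Date(character()), outcome = character(),
    end_date = as.Date(character()), end_reason = character(),
    person_days = integer())
  if (n == 0) return(dplyr::bind_cols(cohort, empty))

  epat <- exposure_patterns()
  k <- match(cohort$pattern, epat$pattern)
  study_end_i <- day_int(dataset$study_end)
  t0_i <- day_int(cohort$t0)
  thr <- as.integer(drop_threshold)
  daa <- daa_codes()

  rx <- dataset$prescriptions[
    dataset$prescriptions$patient_id %in% cohort$patient_id, , drop = FALSE]
  rx_start <- day_int(rx$start_date)
  rx_idx <- split(seq_len(nrow(rx)), rx$patient_id)
  dl <- daily[daily$patient_id %in% cohort$patient_id, , drop = FALSE]
  dl_day <- day_int(dl$date)
  dl_cat <- egfr_category_index(dl$value)
  dl_idx <- split(seq_len(nrow(dl)), dl$patient_id)

  ep_end <- ep_change <- end_day <- pdays <- integer(n)
  ev <- logical(n)
  reason <- character(n)

  for (i in seq_len(n)) {
    pid <- cohort$patient_id[i]
    ri <- rx_idx[[pid]]
    edrug <- epat$episode_drug[k[i]]
    anchor <- epat$anchor[[k[i]]]
    er <- ri[rx$drug[ri] == edrug & rx_start[ri] >= t0_i[i]]
    if (length(er) == 0 || min(rx_start[er]) != t0_i[i])
      stop("no prescription of episode drug ", edrug, " at t0 for ", pid,
           call. = FALSE)
    supply_end <- merge_supply_core(rx_start[er],
                                    as.integer(rx$days_supply[er]))
    grace_end <- supply_end + 7L
    ep_end[i] <- min(grace_end, study_end_i)

    ch <- ri[rx$drug[ri] %in% daa & !(rx$drug[ri] %in% anchor) &
               rx_start[ri] > t0_i[i] & rx_start[ri] <= ep_end[i]]
    change_day <- if (length(ch)) min(rx_start[ch]) else NA_integer_
    ep_change[i] <- change_day

    di <- dl_idx[[pid]]
    res <- follow_up_core(t0_i[i], cohort$baseline_index[i],
                          dl_day[di], dl_cat[di], grace_end, change_day,
                          study_end_i, thr)
    ev[i] <- res$event
    end_day[i] <- res$end_day
    reason[i] <- res$reason
    pdays[i] <- res$person_days
  }

  dplyr::bind_cols(cohort, tibble::tibble(
    episode_start = cohort$t0, episode_end = int_day(ep_end),
    change_date = int_day(ep_change),
    outcome = ifelse(ev, "event", "censored"),
    end_date = int_day(end_day), end_reason = reason,
    person_days = pdays))
}

#' Run the full analysis pipeline on a study dataset
#'
#' New-user identification, the six exclusion criteria with attrition
#' accounting, pattern classification, treatment-episode construction,
#' follow-up with the category-drop outcome, and per-pattern incidence
#' rates with exact rate ratios versus the control, plus the baseline
#' characteristics comparison.
#'
#' @param dataset A [study_dataset()].
#' @param drop_threshold 1 (primary outcome) or 2 (sensitivity definition).
#' @param alpha CI level parameter for [rate_ratio()].
#' @param method `"exact"` or `"wald"` interval/test method.
#' @param control Control pattern id.
#' @param baseline_comparison Set `FALSE` to skip the baseline table (e.g.
#'   in tight simulation loops).
#' @return A list: `new_users`, `cohort`, `attrition`, `flags`,
#'   `followups`, `rates`, `baseline`, `daily`.
#' @export
run_pipeline <- function(dataset, drop_threshold = 1, alpha = 0.05,
                         method = "exact", control = control_pattern(),
                         baseline_comparison = TRUE) {
  daily <- build_daily_egfr(dataset$labs, dataset$patients)
  nu <- find_new_users(dataset)
  ex <- apply_exclusions(nu, dataset, daily)
  followups <- follow_up_cohort(ex$cohort, dataset, daily, drop_threshold)
  rates <- if (nrow(followups) > 0 &&
               control %in% followups$pattern)
    pattern_rates(followups, control, alpha, method) else NULL
  baseline <- if (baseline_comparison && nrow(ex$cohort) > 0 &&
                  control %in% ex$cohort$pattern)
    suppressMessages(compare_baseline(ex$cohort, dataset$patients, control))
  else NULL
  list(new_users = nu, cohort = ex$cohort, attrition = ex$report,
       flags = ex$flags, followups = followups, rates = rates,
       baseline = baseline, daily = daily)
}
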