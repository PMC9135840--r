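#' Identify new users of the target DAAs
#'
#' The index date `t0` is the earliest prescription date of any target DAA
#' within the study window. New users must have medical records starting 90
#' days or more before `t0` (`first_record_date <= t0 - 90`, boundary
#' inclusive); later-starting patients are excluded and counted under
#' insufficient history.
#'
#' @param dataset A [study_dataset()].
#' @return A list: `candidates` (tibble `patient_id`, `t0`,
#'   `daa_drugs_at_t0` list-column), `n_new_users`, `n_insufficient_history`,
#'   `insufficient_ids`.
#' @export
find_new_users <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  rx <- dataset$prescriptions
  rx <- rx[rx$drug %in% daa_codes() &
             rx$start_date >= dataset$study_start &
             rx$start_date <= dataset$study_end, , drop = FALSE]
  if (nrow(rx) == 0) {
    return(list(candidates = tibble::tibble(
      patient_id = character(), t0 = as.Date(character()),
      daa_drugs_at_t0 = list()),
      n_new_users = 0L, n_insufficient_history = 0L,
      insufficient_ids = character()))
  }
  t0_tbl <- rx |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(t0 = min(.data$start_date), .groups = "drop")
  at_t0 <- dplyr::inner_join(rx, t0_tbl,
                             by = dplyr::join_by("patient_id",
                                                 "start_date" == "t0")) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(daa_drugs_at_t0 = list(sort(unique(.data$drug))),
                     .groups = "drop")
  cand <- dplyr::left_join(t0_tbl, at_t0, by = "patient_id") |>
    dplyr::left_join(dataset$first_record, by = "patient_id")
  insufficient <- cand$first_record_date > cand$t0 - 90
  list(candidates = cand[!insufficient,
                         c("patient_id", "t0", "daa_drugs_at_t0")],
       n_new_users = nrow(cand),
       n_insufficient_history = sum(insufficient),
       insufficient_ids = cand$patient_id[insufficient])
}

#' Apply the six exclusion criteria and build the analyzable cohort
#'
#' In flowchart order: (1) any eGFR below 45 mL/min/1.73 m^2 within the 90
#' days before `t0` (serum-creatinine-converted values included); (2) any
#' renal dialysis or transplantation procedure, or chronic-kidney-disease or
#' renal-failure diagnosis, strictly before `t0`; (3) any diabetes, heart
#' failure or hypertension diagnosis strictly before `t0`; (4) no eGFR and
#' no serum creatinine result within the 90 days before `t0`; (5) multiple
#' distinct target DAAs at `t0`, unless the set is a package-insert
#' combination (grazoprevir with elbasvir, daclatasvir with asunaprevir);
#' (6) package-insert-required concomitant drugs absent within
#' `[t0 - 30, t0 + 30]`, assessed via the pattern classification. A patient
#' meeting several criteria is counted under each (duplicated counting, as
#' in the source flowchart); the final cohort removes the union.
#'
#' The lookback window "within 90 days before t0" is `[t0 - 90, t0 - 1]`:
#' the index day itself is consistently excluded.
#'
#' @param new_users Result of [find_new_users()].
#' @param dataset The [study_dataset()].
#' @param daily Optional precomputed [build_daily_egfr()] table.
#' @return A list: `cohort` (tibble `patient_id`, `t0`, `pattern`,
#'   `baseline_egfr`, `baseline_category`, `baseline_index`,
#'   `baseline_date`), `report` (an `attrition_report`), and `flags` (the
#'   per-candidate criterion flags, for auditing).
#' @export
apply_exclusions <- function(new_users, dataset, daily = NULL) {
  cand <- new_users$candidates
  if (is.null(daily)) daily <- build_daily_egfr(dataset$labs,
                                                dataset$patients)
  n <- nrow(cand)
  if (n == 0) {
    report <- attrition_report(new_users, integer(6), 0L)
    return(list(cohort = tibble::tibble(
      patient_id = character(), t0 = as.Date(character()),
      pattern = character(), baseline_egfr = double(),
      baseline_category = character(), baseline_index = integer(),
      baseline_date = as.Date(character())),
      report = report, flags = tibble::tibble(patient_id = character())))
  }

  # kidney labs in the 90-day lookback window
  w <- dplyr::inner_join(daily, cand[c("patient_id", "t0")],
                         by = "patient_id")
  w <- w[w$date >= w$t0 - 90 & w$date <= w$t0 - 1, , drop = FALSE]
  wsum <- w |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(any_low = any(.data$value < 45),
                     baseline_egfr = .data$value[which.max(.data$date)],
                     baseline_date = max(.data$date), .groups = "drop")

  dx <- dplyr::inner_join(dataset$diagnoses, cand[c("patient_id", "t0")],
                          by = "patient_id")
  dx <- dx[dx$date < dx$t0, , drop = FALSE]
  px <- dplyr::inner_join(dataset$procedures, cand[c("patient_id", "t0")],
                          by = "patient_id")
  px <- px[px$date < px$t0, , drop = FALSE]
  renal_dx_ids <- unique(dx$patient_id[dx$condition %in%
    c("chronic_kidney_disease", "renal_failure")])
  renal_px_ids <- unique(px$patient_id[px$procedure %in%
    c("renal_dialysis", "renal_transplantation")])
  comorb_ids <- unique(dx$patient_id[dx$condition %in%
    c("diabetes", "heart_failure", "hypertension")])

  # concomitancy flags for classification
  rx <- dplyr::inner_join(dataset$prescriptions,
                          cand[c("patient_id", "t0")], by = "patient_id")
  rx_win <- rx[rx$start_date >= rx$t0 - 30 & rx$start_date <= rx$t0 + 30, ,
               drop = FALSE]
  conc <- rx_win |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(has_peg = any(.data$drug == "PEG_IFN"),
                     has_rib = any(.data$drug == "RIB"), .groups = "drop")

  keys <- vapply(cand$daa_drugs_at_t0, paste, "", collapse = "+")
  idx_conc <- match(cand$patient_id, conc$patient_id)
  has_peg <- !is.na(idx_conc) & conc$has_peg[idx_conc]
  has_rib <- !is.na(idx_conc) & conc$has_rib[idx_conc]
  cls <- classify_pattern_tbl(keys, has_peg, has_rib)

  idx_w <- match(cand$patient_id, wsum$patient_id)
  n_daa <- lengths(cand$daa_drugs_at_t0)
  permitted <- keys %in% vapply(permitted_daa_combos(), paste, "",
                                collapse = "+")
  flags <- tibble::tibble(
    patient_id = cand$patient_id,
    c1_low_egfr = !is.na(idx_w) & wsum$any_low[idx_w],
    c2_renal_history = cand$patient_id %in% renal_dx_ids |
      cand$patient_id %in% renal_px_ids,
    c3_comorbidity = cand$patient_id %in% comorb_ids,
    c4_no_baseline_lab = is.na(idx_w),
    c5_multiple_daas = n_daa > 1 & !permitted,
    c6_missing_concomitant = !is.na(cls$reason) &
      cls$reason %in% c("missing_concomitant", "missing_partner_daa",
                        "no_matching_pattern")
  )
  excluded <- flags$c1_low_egfr | flags$c2_renal_history |
    flags$c3_comorbidity | flags$c4_no_baseline_lab |
    flags$c5_multiple_daas | flags$c6_missing_concomitant
  keep <- !excluded

  cohort <- tibble::tibble(
    patient_id = cand$patient_id[keep],
    t0 = cand$t0[keep],
    pattern = cls$pattern[keep],
    baseline_egfr = wsum$baseline_egfr[idx_w[keep]],
    baseline_date = wsum$baseline_date[idx_w[keep]])
  cohort$baseline_index <- egfr_category_index(cohort$baseline_egfr)
  cohort$baseline_category <- category_labels[cohort$baseline_index + 1L]
  cohort <- cohort[c("patient_id", "t0", "pattern", "baseline_egfr",
                     "baseline_category", "baseline_index",
                     "baseline_date")]

  counts <- c(sum(flags$c1_low_egfr), sum(flags$c2_renal_history),
              sum(flags$c3_comorbidity), sum(flags$c4_no_baseline_lab),
              sum(flags$c5_multiple_daas), sum(flags$c6_missing_concomitant))
  report <- attrition_report(new_users, as.integer(counts),
                             as.integer(sum(keep)))
  list(cohort = cohort, report = report, flags = flags)
}

attrition_report <- function(new_users, criterion_counts, final_size) {
  structure(list(
    new_users_identified = as.integer(new_users$n_new_users),
    insufficient_history = as.integer(new_users$n_insufficient_history),
    candidates = as.integer(new_users$n_new_users -
                              new_users$n_insufficient_history),
    excluded = stats::setNames(criterion_counts, c(
      "c1_low_egfr", "c2_renal_history", "c3_comorbidity",
      "c4_no_baseline_lab", "c5_multiple_daas", "c6_missing_concomitant")),
    final_cohort_size = final_size),
    class = "attrition_report")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Patient selection flowchart\n")
  cat(sprintf("  new users of target DAAs identified .......... %6d\n",
              x$new_users_identified))
  cat(sprintf("  excluded: records < 90 days before t0 ........ %6d\n",
              x$insufficient_history))
  cat(sprintf("  candidates ................................... %6d\n",
              x$candidates))
  lab <- c("(1) eGFR < 45 within 90 days before t0",
           "(2) dialysis/transplant/CKD/renal failure",
           "(3) diabetes/heart failure/hypertension",
           "(4) no eGFR or sCRE within 90 days before t0",
           "(5) multiple DAAs at t0 (not PI combination)",
           "(6) required concomitant drugs absent")
  for (i in seq_along(lab))
    cat(sprintf("  excluded %-44s %6d\n", lab[i], x$excluded[i]))
  cat("  (a patient meeting several criteria is counted under each)\n")
  cat(sprintf("  final cohort ................................. %6d\n",
              x$final_cohort_size))
  invisible(x)
}

#' @export
as.data.frame.attrition_report <- function(x, ...) {
  data.frame(
    step = c("new_users_identified", "insufficient_history", "candidates",
             names(x$excluded), "final_cohort_size"),
    count = c(x$new_users_identified, x$insufficient_history, x$candidates,
              unname(x$excluded), x$final_cohort_size))
}
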