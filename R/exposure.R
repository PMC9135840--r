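#' The ten DAA prescription patterns
#'
#' Exposure groups are defined by the anchor DAA(s) dispensed at the index
#' date plus the concomitant drugs required by each product's package
#' insert, assessed within 30 days before and after `t0` (closed window).
#' Ledipasvir/sofosbuvir (`P7_LDV_SOF`) is the control pattern. The
#' `episode_drug` column names the DAA whose prescriptions define the
#' treatment episode; asunaprevir and grazoprevir follow their partner drug
#' (daclatasvir, elbasvir), so P3 and P6 episodes are built from the
#' partner's prescriptions.
#'
#' @return A tibble with one row per pattern: `pattern`, `anchor` (list of
#'   drug-code sets), `required` (list of required concomitant sets),
#'   `episode_drug`, `control`.
#' @export
exposure_patterns <- function() {
  tibble::tibble(
    pattern = c("P1_TVR_PegIFN_Rib", "P2_SMV_PegIFN_Rib", "P3_DCV_ASV",
                "P4_VAN_PegIFN_Rib", "P5_SOF_Rib", "P6_EBV_GZR",
                "P7_LDV_SOF", "P8_OBV_PTV_r", "P9_OBV_PTV_r_Rib",
                "P10_DCV_ASV_BCV"),
    anchor = list("TVR", "SMV", c("ASV", "DCV"), "VAN", "SOF",
                  c("EBV", "GZR"), "LDV_SOF", "OBV_PTV_r", "OBV_PTV_r",
                  "DCV_ASV_BCV"),
    required = list(c("PEG_IFN", "RIB"), c("PEG_IFN", "RIB"), character(),
                    c("PEG_IFN", "RIB"), "RIB", character(), character(),
                    character(), "RIB", character()),
    episode_drug = c("TVR", "SMV", "DCV", "VAN", "SOF", "EBV", "LDV_SOF",
                     "OBV_PTV_r", "OBV_PTV_r", "DCV_ASV_BCV"),
    control = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                FALSE, FALSE)
  )
}

#' @rdname exposure_patterns
#' @return `pattern_names()`: character vector of the ten pattern ids;
#'   `control_pattern()`: the control pattern id.
#' @export
pattern_names <- function() exposure_patterns()$pattern

#' @rdname exposure_patterns
#' @export
control_pattern <- function() "P7_LDV_SOF"

# DAA sets allowed at t0 despite being multiple distinct products
permitted_daa_combos <- function() list(c("ASV", "DCV"), c("EBV", "GZR"))

#' Classify a cohort entry into a prescription pattern
#'
#' The anchor DAA set at `t0` plus concomitant prescriptions started within
#' `[t0 - 30, t0 + 30]` determine the pattern. `P8_OBV_PTV_r` and
#' `P9_OBV_PTV_r_Rib` are distinguished solely by the presence of ribavirin
#' in that window. Entries whose package-insert-required concomitants are
#' absent, or whose anchor lacks its required partner DAA, are returned as
#' not-classifiable with a reason code; these feed exclusion criterion (6).
#'
#' @param entry A list/row with `t0` and `daa_drugs_at_t0` (character
#'   vector of DAA codes prescribed on `t0`).
#' @param prescriptions Prescription rows for this patient.
#' @return A list: `pattern` (id or `NA`), `reason` (`NA` when classified;
#'   otherwise `missing_concomitant`, `missing_partner_daa`,
#'   `unpermitted_daa_combination`, or `no_matching_pattern`).
#' @export
classify_pattern <- function(entry, prescriptions) {
  t0 <- as.Date(entry$t0)
  daa <- sort(unique(unlist(entry$daa_drugs_at_t0)))
  win <- prescriptions$start_date >= t0 - 30 &
    prescriptions$start_date <= t0 + 30
  conc <- unique(prescriptions$drug[win])
  key <- paste(daa, collapse = "+")

  not_ok <- function(reason) list(pattern = NA_character_, reason = reason)
  ok <- function(p) list(pattern = p, reason = NA_character_)

  if (key == "ASV+DCV") return(ok("P3_DCV_ASV"))
  if (key == "EBV+GZR") return(ok("P6_EBV_GZR"))
  if (length(daa) > 1) return(not_ok("unpermitted_daa_combination"))
  if (key %in% c("ASV", "DCV", "EBV", "GZR"))
    return(not_ok("missing_partner_daa"))

  need <- switch(key,
    TVR = c("PEG_IFN", "RIB"), SMV = c("PEG_IFN", "RIB"),
    VAN = c("PEG_IFN", "RIB"), SOF = "RIB",
    LDV_SOF = character(), OBV_PTV_r = character(),
    DCV_ASV_BCV = character(), NULL)
  if (is.null(need)) return(not_ok("no_matching_pattern"))
  if (!all(need %in% conc)) return(not_ok("missing_concomitant"))

  pattern <- switch(key,
    TVR = "P1_TVR_PegIFN_Rib", SMV = "P2_SMV_PegIFN_Rib",
    VAN = "P4_VAN_PegIFN_Rib", SOF = "P5_SOF_Rib",
    LDV_SOF = "P7_LDV_SOF",
    OBV_PTV_r = if ("RIB" %in% conc) "P9_OBV_PTV_r_Rib" else "P8_OBV_PTV_r",
    DCV_ASV_BCV = "P10_DCV_ASV_BCV")
  ok(pattern)
}

# Vectorised classification used by the cohort stage: one row per candidate
# with the anchor-set key and concomitancy flags precomputed.
classify_pattern_tbl <- function(keys, has_peg, has_rib) {
  n <- length(keys)
  pattern <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  single <- c(TVR = "P1_TVR_PegIFN_Rib", SMV = "P2_SMV_PegIFN_Rib",
              VAN = "P4_VAN_PegIFN_Rib", SOF = "P5_SOF_Rib",
              LDV_SOF = "P7_LDV_SOF", OBV_PTV_r = "P8_OBV_PTV_r",
              DCV_ASV_BCV = "P10_DCV_ASV_BCV")
  needs_both <- keys %in% c("TVR", "SMV", "VAN")

  pattern[keys == "ASV+DCV"] <- "P3_DCV_ASV"
  pattern[keys == "EBV+GZR"] <- "P6_EBV_GZR"
  multi <- is.na(pattern) & grepl("+", keys, fixed = TRUE)
  reason[multi] <- "unpermitted_daa_combination"
  partner <- is.na(pattern) & !multi & keys %in% c("ASV", "DCV", "EBV", "GZR")
  reason[partner] <- "missing_partner_daa"

  rest <- is.na(pattern) & !multi & !partner
  known <- rest & keys %in% names(single)
  reason[rest & !known] <- "no_matching_pattern"

  miss <- known & ((needs_both & !(has_peg & has_rib)) |
                     (keys == "SOF" & !has_rib))
  reason[miss] <- "missing_concomitant"
  hit <- known & !miss
  pattern[hit] <- unname(single[keys[hit]])
  pattern[hit & keys == "OBV_PTV_r" & has_rib] <- "P9_OBV_PTV_r_Rib"

  tibble::tibble(pattern = pattern, reason = reason)
}

# Core drug-era merge on integer days: prescriptions whose start falls at
# most `gap` days after the current merged supply end extend the era; the
# grace period is appended once, at the end. Returns the merged supply end.
merge_supply_core <- function(starts, supplies, gap = 28L) {
  o <- order(starts)
  starts <- starts[o]
  ends <- starts + supplies[o] - 1L
  cur_end <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_end + gap) cur_end <- max(cur_end, ends[i])
    else break
  }
  cur_end
}

#' Build the treatment episode (drug era) for a cohort entry
#'
#' Prescriptions of the pattern's episode-defining DAA are merged into a
#' single era: each prescription covers `[start, start + days_supply - 1]`;
#' a subsequent prescription starting at most 28 days after the current
#' merged supply end extends the era; a 7-day grace period is appended at
#' the era end, truncated at the study end. Only the first era from `t0` is
#' analysed. For P3 and P6 the partner drug's prescriptions (daclatasvir,
#' elbasvir) define the episode, the asunaprevir/grazoprevir supply being
#' tied to the partner's.
#'
#' @param entry A list/row with `patient_id` and `t0`.
#' @param pattern Pattern id (see [exposure_patterns()]).
#' @param prescriptions Prescription rows for this patient.
#' @param study_end End of the study period.
#' @param gap,grace Era-construction parameters in days (defaults 28 and 7).
#' @return A list: `patient_id`, `pattern`, `start` (= `t0`), `supply_end`,
#'   `grace_end` (untruncated), `end` (truncated at `study_end`),
#'   `truncated`, `n_prescriptions`.
#' @export
build_treatment_episode <- function(entry, pattern, prescriptions, study_end,
                                    gap = 28L, grace = 7L) {
  t0 <- as.Date(entry$t0)
  study_end <- as.Date(study_end)
  drug <- exposure_patterns()$episode_drug[match(pattern,
                                                 exposure_patterns()$pattern)]
  if (is.na(drug)) stop("unknown pattern: ", pattern, call. = FALSE)
  rx <- prescriptions[prescriptions$drug == drug &
                        prescriptions$start_date >= t0, , drop = FALSE]
  if (nrow(rx) == 0 || min(rx$start_date) != t0)
    stop("no prescription of episode drug ", drug, " at t0", call. = FALSE)
  supply_end <- merge_supply_core(day_int(rx$start_date),
                                  as.integer(rx$days_supply), as.integer(gap))
  grace_end <- supply_end + as.integer(grace)
  end <- min(grace_end, day_int(study_end))
  list(patient_id = entry$patient_id, pattern = pattern, start = t0,
       supply_end = int_day(supply_end), grace_end = int_day(grace_end),
       end = int_day(end), truncated = grace_end > day_int(study_end),
       n_prescriptions = nrow(rx))
}

#' First change to another prescription pattern
#'
#' Returns the first date after `t0`, within the treatment episode, on
#' which a target-DAA prescription outside the pattern's anchor set was
#' started — the patient is censored the day before. Prescriptions after
#' the episode end are irrelevant (follow-up has already ended).
#'
#' @inheritParams build_treatment_episode
#' @param episode Episode from [build_treatment_episode()].
#' @return The change date (`Date`) or `NA` if none.
#' @export
detect_pattern_change <- function(entry, pattern, prescriptions, episode) {
  t0 <- as.Date(entry$t0)
  anchor <- exposure_patterns()$anchor[[match(pattern,
                                              exposure_patterns()$pattern)]]
  other <- prescriptions$drug %in% daa_codes() &
    !prescriptions$drug %in% anchor &
    prescriptions$start_date > t0 &
    prescriptions$start_date <= episode$end
  if (!any(other)) return(as.Date(NA))
  min(prescriptions$start_date[other])
}
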