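#' Configuration for the synthetic EHR generator
#'
#' Defines the statistical structure of a simulated hospital-network
#' extract: patient mix over the ten prescription patterns plus a non-user
#' background, demographics, baseline kidney function, kidney-test
#' frequency, per-pattern event hazards, and prevalences of the exclusion
#' criteria. Defaults emulate the cohort features of the source setting:
#' pattern shares proportional to the published per-pattern cohort sizes,
#' kidney-function tests roughly every 3 weeks (about 4 tests over a
#' ~87-day follow-up), 12-week treatment durations (24 weeks for
#' daclatasvir + asunaprevir), and an elderly, majority-female population.
#' Event rates are free parameters (the source reports no usable
#' per-pattern counts); the default control rate of 0.5 events per
#' person-year gives realistic, analyzable event counts.
#'
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; each patient draws from a per-patient
#'   substream derived from it, so increasing `n_patients` leaves earlier
#'   patients' records unchanged.
#' @param pattern_probabilities Named simplex over the ten patterns plus
#'   `"non_user"`; must sum to 1.
#' @param age_distribution Truncated-normal parameters (`mean`, `sd`,
#'   `min`, `max`), years.
#' @param female_fraction Probability of female sex.
#' @param baseline_egfr_distribution Truncated-normal parameters for the
#'   true baseline eGFR, mL/min/1.73 m^2.
#' @param lab_interval_days Mean gap between kidney-function tests during
#'   follow-up, days.
#' @param event_rate_control Events per person-year in the control pattern.
#' @param rate_ratio_per_pattern Named multiplicative true incidence-rate
#'   ratio per pattern; the control entry must be 1.
#' @param exclusion_prevalences Named probabilities for the exclusion
#'   carriers: `diabetes`, `heart_failure`, `hypertension`, `ckd_renal`,
#'   `dialysis_transplant`, `missing_baseline_lab`.
#' @param history_days_distribution Gamma parameters (`shape`, `scale`) for
#'   the pre-t0 record-history length, days.
#' @param treatment_duration_days Named intended anchor-drug treatment
#'   duration per pattern, days.
#' @param scre_fraction Fraction of kidney labs recorded as serum
#'   creatinine rather than eGFR (exercising the conversion path).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(
    n_patients = 2000,
    seed = 1,
    pattern_probabilities = NULL,
    age_distribution = list(mean = 65, sd = 10, min = 18, max = 95),
    female_fraction = 0.57,
    baseline_egfr_distribution = list(mean = 75, sd = 12, min = 20,
                                      max = 115),
    lab_interval_days = 21,
    event_rate_control = 0.5,
    rate_ratio_per_pattern = NULL,
    exclusion_prevalences = c(diabetes = 0.06, heart_failure = 0.02,
                              hypertension = 0.08, ckd_renal = 0.02,
                              dialysis_transplant = 0.01,
                              missing_baseline_lab = 0.04),
    history_days_distribution = list(shape = 2, scale = 300),
    treatment_duration_days = NULL,
    scre_fraction = 0.2) {
  pats <- pattern_names()
  if (is.null(pattern_probabilities)) {
    share <- c(71, 76, 186, 8, 145, 14, 220, 34, 6, 0) / 760
    pattern_probabilities <- stats::setNames(c(0.8 * share, 0.2),
                                             c(pats, "non_user"))
  }
  if (is.null(rate_ratio_per_pattern))
    rate_ratio_per_pattern <- stats::setNames(rep(1, 10), pats)
  if (is.null(treatment_duration_days))
    treatment_duration_days <- stats::setNames(
      c(84, 84, 168, 84, 84, 84, 84, 84, 84, 84), pats)

  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              pattern_probabilities = pattern_probabilities,
              age_distribution = age_distribution,
              female_fraction = female_fraction,
              baseline_egfr_distribution = baseline_egfr_distribution,
              lab_interval_days = lab_interval_days,
              event_rate_control = event_rate_control,
              rate_ratio_per_pattern = rate_ratio_per_pattern,
              exclusion_prevalences = exclusion_prevalences,
              history_days_distribution = history_days_distribution,
              treatment_duration_days = treatment_duration_days,
              scre_fraction = scre_fraction)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  pp <- cfg$pattern_probabilities
  need <- c(pattern_names(), "non_user")
  if (!setequal(names(pp), need))
    stop("pattern_probabilities must be named over the 10 patterns plus ",
         "'non_user'", call. = FALSE)
  if (any(pp < 0) || any(pp > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(pp) - 1) > 1e-6)
    stop("pattern_probabilities must sum to 1 (got ", sum(pp), ")",
         call. = FALSE)
  rr <- cfg$rate_ratio_per_pattern
  if (!setequal(names(rr), pattern_names()) || any(rr < 0))
    stop("rate_ratio_per_pattern must be a non-negative vector named over ",
         "the 10 patterns", call. = FALSE)
  if (rr[[control_pattern()]] != 1)
    stop("rate_ratio_per_pattern for the control pattern must be 1",
         call. = FALSE)
  ep <- cfg$exclusion_prevalences
  if (!setequal(names(ep), exclusion_carrier_names()))
    stop("exclusion_prevalences must be named: ",
         paste(exclusion_carrier_names(), collapse = ", "), call. = FALSE)
  if (any(ep < 0) || any(ep > 1))
    stop("exclusion_prevalences must lie in [0, 1]", call. = FALSE)
  if (cfg$event_rate_control < 0)
    stop("event_rate_control must be >= 0", call. = FALSE)
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1 ||
      cfg$scre_fraction < 0 || cfg$scre_fraction > 1)
    stop("fractions must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

exclusion_carrier_names <- function() {
  c("diabetes", "heart_failure", "hypertension", "ckd_renal",
    "dialysis_transplant", "missing_baseline_lab")
}

# one truncated-normal draw via a single uniform (keeps draw counts stable)
rtnorm1 <- function(mean, sd, lo, hi) {
  stats::qnorm(stats::runif(1, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

category_upper_bounds <- c(Inf, 90, 60, 45, 30, 15)

# plausible values inside the same category as `baseline` (truncated normal)
in_category_values <- function(baseline, n, sd = 3) {
  if (n == 0) return(double())
  idx <- egfr_category_index(baseline)
  lo <- category_lower_bounds[idx + 1L] + 0.05
  hi <- category_upper_bounds[idx + 1L] - 0.05
  if (!is.finite(hi)) hi <- max(baseline + 25, 95)
  stats::qnorm(stats::runif(n, stats::pnorm(lo, baseline, sd),
                            stats::pnorm(hi, baseline, sd)), baseline, sd)
}

# values strictly below the baseline category's lower bound (one category
# down, uniform within the next-worse category)
dropped_values <- function(baseline, n) {
  if (n == 0) return(double())
  idx <- egfr_category_index(baseline)
  if (idx >= 5L) return(stats::runif(n, 1, 10))  # already kidney failure
  lb <- category_lower_bounds[idx + 1L]
  next_lb <- category_lower_bounds[idx + 2L]
  stats::runif(n, max(next_lb, 0.5) + 0.05, lb - 0.05)
}

patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 1664525) %%
               2147483647)
}

#' Simulate a study dataset with injected ground truth
#'
#' Generates the five EHR tables plus a per-patient ground-truth table.
#' Each DAA user receives prescriptions matching their pattern's drug set
#' (anchor DAAs at `t0` with 28-day refills over the intended duration,
#' plus the required concomitants near `t0`). A latent event time is drawn
#' from an exponential with rate `event_rate_control *
#' rate_ratio_per_pattern[pattern]`; the event is only observable on a
#' lab-test day — on the first test at or after the latent time the
#' generated eGFR falls strictly below the lower bound of the baseline
#' category, and stays in the dropped category thereafter. Non-event labs
#' fluctuate within the baseline category, so the ground truth is
#' unambiguous. Exclusion-criterion carriers receive the corresponding
#' diagnosis/procedure records (or lose their baseline-window labs), and a
#' record anchor is planted exactly `history_days` before `t0`, so carriers
#' are exactly the patients the cohort stage removes at each step.
#'
#' Deterministic given the seed; a per-patient substream means earlier
#' patients' records do not change when `n_patients` grows.
#'
#' @param config A [simulation_config()].
#' @return A list: `dataset` (a [study_dataset()]) and `truth` (tibble with
#'   per-patient pattern, true baseline eGFR, latent event day, exclusion
#'   carriers and eligibility).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  n <- config$n_patients
  study_start <- as.Date("2009-01-01")
  study_end <- as.Date("2017-12-31")
  if (n == 0) {
    ds <- study_dataset(empty_table("patients"), empty_table("prescriptions"),
                        empty_table("labs"), empty_table("diagnoses"),
                        empty_table("procedures"), study_start, study_end)
    return(list(dataset = ds, truth = empty_truth()))
  }

  pp <- config$pattern_probabilities
  groups <- names(pp)
  cum_pp <- cumsum(pp)
  t0_lo <- day_int(as.Date("2011-09-01"))
  t0_hi <- day_int(as.Date("2017-10-01"))
  end_i <- day_int(study_end)
  ep <- config$exclusion_prevalences[exclusion_carrier_names()]
  ages <- config$age_distribution
  egd <- config$baseline_egfr_distribution
  hist_d <- config$history_days_distribution
  epat <- exposure_patterns()

  P <- vector("list", n)  # per-patient record bundles
  tr <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%06d", i)
    sex <- if (stats::runif(1) < config$female_fraction) "female" else "male"
    age <- rtnorm1(ages$mean, ages$sd, ages$min, ages$max)
    baseline <- rtnorm1(egd$mean, egd$sd, egd$min, egd$max)
    grp <- groups[findInterval(stats::runif(1), cum_pp,
                               rightmost.closed = TRUE) + 1L]
    history <- min(3000L, max(1L, as.integer(round(stats::qgamma(
      stats::runif(1), shape = hist_d$shape, scale = hist_d$scale)))))
    t0i <- as.integer(t0_lo + floor(stats::runif(1) * (t0_hi - t0_lo + 1)))
    birth_i <- as.integer(t0i - round(age * 365.25) -
                            floor(stats::runif(1) * 365))

    is_user <- grp != "non_user"
    carriers <- stats::runif(6) < ep  # order of ep names
    names(carriers) <- names(ep)
    if (!is_user) carriers[] <- FALSE

    rr <- if (is_user) config$rate_ratio_per_pattern[[grp]] else 0
    rate_day <- config$event_rate_control * rr / 365.25
    u_ev <- stats::runif(1)
    event_t <- if (rate_day > 0) stats::qexp(u_ev, rate = rate_day)
               else NA_real_

    rx_drug <- character(); rx_start <- integer(); rx_supply <- integer()
    lab_day <- integer(); lab_target <- double()
    dx_cond <- character(); dx_day <- integer()
    pr_proc <- character(); pr_day <- integer()

    # record anchor fixing first_record_date at exactly t0 - history
    dx_cond <- c(dx_cond, "OTHER"); dx_day <- c(dx_day, t0i - history)

    if (is_user) {
      dur <- config$treatment_duration_days[[grp]]
      k <- match(grp, epat$pattern)
      anchors <- if (grp == "P3_DCV_ASV") c("DCV", "ASV")
                 else if (grp == "P6_EBV_GZR") c("EBV", "GZR")
                 else epat$anchor[[k]]
      starts <- t0i + seq(0L, dur - 1L, by = 28L)
      supplies <- pmin(28L, as.integer(dur) - (starts - t0i))
      keep_rx <- starts <= end_i
      for (d in anchors) {
        rx_drug <- c(rx_drug, rep(d, sum(keep_rx)))
        rx_start <- c(rx_start, starts[keep_rx])
        rx_supply <- c(rx_supply, supplies[keep_rx])
      }
      for (d in epat$required[[k]]) {
        off <- floor(stats::runif(1, -7, 8))
        rx_drug <- c(rx_drug, d)
        rx_start <- c(rx_start, t0i + off)
        rx_supply <- c(rx_supply, 28L)
      }

      # carrier records
      if (carriers[["diabetes"]] || carriers[["heart_failure"]] ||
          carriers[["hypertension"]]) {
        for (cond in c("diabetes", "heart_failure", "hypertension")) {
          if (carriers[[cond]]) {
            dx_cond <- c(dx_cond, cond)
            dx_day <- c(dx_day,
                        t0i - sample.int(min(history, 400L), 1))
          }
        }
      }
      if (carriers[["ckd_renal"]]) {
        dx_cond <- c(dx_cond, "chronic_kidney_disease")
        dx_day <- c(dx_day, t0i - sample.int(min(history, 400L), 1))
      }
      if (carriers[["dialysis_transplant"]]) {
        pr_proc <- c(pr_proc, "renal_dialysis")
        pr_day <- c(pr_day, t0i - sample.int(min(history, 400L), 1))
      }

      # pre-t0 kidney labs
      d0 <- 3L + floor(stats::runif(1) * 28)
      if (!carriers[["missing_baseline_lab"]]) {
        pre_days <- t0i - c(d0, d0 + 60L, d0 + 120L)
        pre_days <- pre_days[pre_days >= t0i - history]
      } else {
        pre_days <- t0i - (d0 + 120L)
        pre_days <- pre_days[pre_days >= t0i - history]
      }
      if (stats::runif(1) < 0.3) pre_days <- c(pre_days, t0i)
      lab_day <- c(lab_day, pre_days)
      lab_target <- c(lab_target,
                      in_category_values(baseline, length(pre_days)))

      # follow-up labs on an irregular grid
      horizon <- t0i + dur + 40L
      n_gap <- ceiling((dur + 40) / 3) + 2
      gaps <- pmax(3, round(stats::rnorm(n_gap, config$lab_interval_days,
                                         5)))
      fu_days <- t0i + cumsum(gaps)
      fu_days <- fu_days[fu_days <= horizon & fu_days <= end_i]
      ev_day <- if (!is.na(event_t)) t0i + event_t else Inf
      post_ev <- fu_days >= ev_day
      vals <- numeric(length(fu_days))
      vals[!post_ev] <- in_category_values(baseline, sum(!post_ev))
      vals[post_ev] <- dropped_values(baseline, sum(post_ev))
      lab_day <- c(lab_day, fu_days)
      lab_target <- c(lab_target, vals)
    } else {
      # non-user background patient: unrelated prescription + two labs
      rx_drug <- c(rx_drug, "OTHER")
      rx_start <- c(rx_start, t0i)
      rx_supply <- c(rx_supply, 30L)
      lab_day <- c(lab_day, t0i - min(history, 30L), t0i + 15L)
      lab_target <- c(lab_target, in_category_values(baseline, 2))
    }

    # representation: some kidney labs recorded as serum creatinine
    keep_lab <- lab_day <= end_i
    lab_day <- lab_day[keep_lab]; lab_target <- lab_target[keep_lab]
    n_lab <- length(lab_day)
    analyte <- rep("eGFR", n_lab)
    value <- lab_target
    if (n_lab > 0 && config$scre_fraction > 0) {
      as_scre <- stats::runif(n_lab) < config$scre_fraction
      if (any(as_scre)) {
        age_at <- age_from_ints(birth_i, lab_day[as_scre])
        analyte[as_scre] <- "sCRE"
        value[as_scre] <- scre_from_egfr(lab_target[as_scre], age_at, sex)
      }
    }

    P[[i]] <- list(pid = pid, sex = sex, birth = birth_i,
                   rx_drug = rx_drug, rx_start = rx_start,
                   rx_supply = rx_supply,
                   lab_day = lab_day, analyte = analyte, value = value,
                   dx_cond = dx_cond, dx_day = dx_day,
                   pr_proc = pr_proc, pr_day = pr_day)
    tr[[i]] <- list(
      pid = pid, role = if (is_user) "user" else "non_user",
      pattern = if (is_user) grp else NA_character_,
      t0 = t0i, history_days = history, baseline_egfr = baseline,
      true_event_day = event_t, carriers = carriers,
      low_baseline = is_user && baseline < 45 &&
        !carriers[["missing_baseline_lab"]])
  }

  rep_each <- function(field, lenfield) {
    unlist(lapply(P, function(p) rep(p$pid, length(p[[lenfield]]))),
           use.names = FALSE)
  }
  patients <- tibble::tibble(
    patient_id = vapply(P, `[[`, "", "pid"),
    sex = vapply(P, `[[`, "", "sex"),
    birth_date = int_day(vapply(P, `[[`, 0L, "birth")))
  prescriptions <- tibble::tibble(
    patient_id = rep_each("pid", "rx_drug"),
    drug = unlist(lapply(P, `[[`, "rx_drug"), use.names = FALSE),
    start_date = int_day(unlist(lapply(P, `[[`, "rx_start"),
                                use.names = FALSE)),
    days_supply = as.integer(unlist(lapply(P, `[[`, "rx_supply"),
                                    use.names = FALSE)))
  labs <- tibble::tibble(
    patient_id = rep_each("pid", "lab_day"),
    date = int_day(unlist(lapply(P, `[[`, "lab_day"), use.names = FALSE)),
    analyte = unlist(lapply(P, `[[`, "analyte"), use.names = FALSE),
    value = unlist(lapply(P, `[[`, "value"), use.names = FALSE))
  diagnoses <- tibble::tibble(
    patient_id = rep_each("pid", "dx_cond"),
    date = int_day(unlist(lapply(P, `[[`, "dx_day"), use.names = FALSE)),
    condition = unlist(lapply(P, `[[`, "dx_cond"), use.names = FALSE))
  procedures <- tibble::tibble(
    patient_id = rep_each("pid", "pr_proc"),
    date = int_day(unlist(lapply(P, `[[`, "pr_day"), use.names = FALSE)),
    procedure = unlist(lapply(P, `[[`, "pr_proc"), use.names = FALSE))

  ds <- study_dataset(patients, prescriptions, labs, diagnoses, procedures,
                      study_start, study_end)

  carr <- do.call(rbind, lapply(tr, function(x) x$carriers))
  truth <- tibble::tibble(
    patient_id = vapply(tr, `[[`, "", "pid"),
    role = vapply(tr, `[[`, "", "role"),
    pattern = vapply(tr, `[[`, "", "pattern"),
    t0 = int_day(vapply(tr, `[[`, 0L, "t0")),
    history_days = vapply(tr, function(x) x$history_days, 0L),
    baseline_egfr = vapply(tr, `[[`, 0, "baseline_egfr"),
    true_event_day = vapply(tr, `[[`, 0, "true_event_day"),
    excl_diabetes = carr[, "diabetes"],
    excl_heart_failure = carr[, "heart_failure"],
    excl_hypertension = carr[, "hypertension"],
    excl_ckd_renal = carr[, "ckd_renal"],
    excl_dialysis_transplant = carr[, "dialysis_transplant"],
    excl_missing_baseline_lab = carr[, "missing_baseline_lab"],
    excl_low_baseline = vapply(tr, `[[`, TRUE, "low_baseline"))
  truth$insufficient_history <- truth$role == "user" &
    truth$history_days < 90
  truth$eligible <- truth$role == "user" & !truth$insufficient_history &
    !truth$excl_diabetes & !truth$excl_heart_failure &
    !truth$excl_hypertension & !truth$excl_ckd_renal &
    !truth$excl_dialysis_transplant & !truth$excl_missing_baseline_lab &
    truth$baseline_egfr >= 45

  list(dataset = ds, truth = truth)
}

empty_truth <- function() {
  tibble::tibble(
    patient_id = character(), role = character(), pattern = character(),
    t0 = as.Date(character()), history_days = integer(),
    baseline_egfr = double(), true_event_day = double(),
    excl_diabetes = logical(), excl_heart_failure = logical(),
    excl_hypertension = logical(), excl_ckd_renal = logical(),
    excl_dialysis_transplant = logical(),
    excl_missing_baseline_lab = logical(), excl_low_baseline = logical(),
    insufficient_history = logical(), eligible = logical())
}
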