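#' Person-years from follow-up days
#'
#' Follow-up days divided by 365.25; exactly 0 when follow-up ended at the
#' index date.
#'
#' @param days Non-negative integer days.
#' @return Person-years (double).
#' @export
person_years <- function(days) {
  if (any(is.na(days)) || any(days < 0))
    stop("days must be >= 0", call. = FALSE)
  days / 365.25
}

#' Incidence rate
#'
#' Events per person-year; `NA` (not available) when person-time is zero.
#'
#' @param events Non-negative event count.
#' @param py Person-years (>= 0).
#' @return Events per person-year, or `NA_real_` when `py` is 0.
#' @export
incidence_rate <- function(events, py) {
  if (any(is.na(events)) || any(events < 0))
    stop("events must be >= 0", call. = FALSE)
  ifelse(py > 0, events / py, NA_real_)
}

#' Incidence-rate ratio with exact conditional inference
#'
#' Conditional on the total number of events, the exposed count is binomial
#' with null probability `py_e / (py_e + py_c)`; the two-sided p-value and
#' the Clopper-Pearson interval for that binomial proportion (computed via
#' [stats::binom.test()]) are transformed to the rate-ratio scale. This
#' exact method stays valid at the small event counts typical of the rarer
#' prescription patterns. A log-normal (Wald) interval is available via
#' `method = "wald"` for comparison. Significance is flagged at p < 0.01,
#' with raw p-values always returned.
#'
#' @param events_exposed,py_exposed Events and person-years in the exposed
#'   pattern (`py_exposed` > 0).
#' @param events_control,py_control Events and person-years in the control
#'   (`py_control` > 0).
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @param method `"exact"` (default) or `"wald"`.
#' @return One-row tibble: `irr` (point estimate; `Inf` when the control
#'   has zero events), `ci_low`, `ci_high`, `p_value`, `significant`
#'   (p < 0.01).
#' @export
rate_ratio <- function(events_exposed, py_exposed, events_control,
                       py_control, alpha = 0.05, method = c("exact", "wald")) {
  method <- match.arg(method)
  stopifnot(py_exposed > 0, py_control > 0,
            events_exposed >= 0, events_control >= 0)
  x <- as.integer(events_exposed)
  m <- as.integer(events_control)
  total <- x + m
  irr <- if (m > 0) (x / py_exposed) / (m / py_control)
         else if (x > 0) Inf else NA_real_

  if (total == 0) {
    return(tibble::tibble(irr = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p_value = 1,
                          significant = FALSE))
  }
  if (method == "exact") {
    p0 <- py_exposed / (py_exposed + py_control)
    bt <- stats::binom.test(x, total, p = p0, conf.level = 1 - alpha)
    pv <- bt$p.value
    pi_ci <- bt$conf.int
    to_irr <- function(p) if (p >= 1) Inf else
      (p / (1 - p)) * (py_control / py_exposed)
    lo <- to_irr(pi_ci[1])
    hi <- to_irr(pi_ci[2])
  } else {
    if (x == 0 || m == 0) {
      lo <- NA_real_; hi <- NA_real_; pv <- NA_real_
    } else {
      se <- sqrt(1 / x + 1 / m)
      z <- stats::qnorm(1 - alpha / 2)
      lo <- exp(log(irr) - z * se)
      hi <- exp(log(irr) + z * se)
      pv <- 2 * stats::pnorm(-abs(log(irr)) / se)
    }
  }
  tibble::tibble(irr = irr, ci_low = lo, ci_high = hi, p_value = pv,
                 significant = !is.na(pv) & pv < 0.01)
}

#' Per-pattern incidence rates and rate ratios versus the control
#'
#' Aggregates follow-up results by prescription pattern and computes, per
#' pattern, patient count, events, person-years (days / 365.25), the
#' incidence rate, and the incidence-rate ratio versus the control pattern
#' with its exact 95% CI and two-sided p-value. The control row carries
#' `irr = 1` as the reference with no interval or p-value.
#'
#' @param followups Tibble with `pattern`, `outcome`, `person_days` (one row
#'   per cohort patient, e.g. from [run_pipeline()]).
#' @param control Control pattern id (default [control_pattern()]).
#' @param alpha CI level parameter passed to [rate_ratio()].
#' @param method Interval/test method passed to [rate_ratio()].
#' @return A tibble, one row per pattern present in `followups`.
#' @export
pattern_rates <- function(followups, control = control_pattern(),
                          alpha = 0.05, method = "exact") {
  agg <- followups |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(n_patients = dplyr::n(),
                     events = sum(.data$outcome == "event"),
                     person_years = person_years(sum(.data$person_days)),
                     .groups = "drop")
  agg$incidence_rate <- incidence_rate(agg$events, agg$person_years)
  ctrl <- agg[agg$pattern == control, ]
  if (nrow(ctrl) == 0)
    stop("control pattern ", control, " absent from follow-up results",
         call. = FALSE)
  res <- lapply(seq_len(nrow(agg)), function(i) {
    if (agg$pattern[i] == control || agg$person_years[i] == 0 ||
        ctrl$person_years == 0) {
      tibble::tibble(irr = if (agg$pattern[i] == control) 1 else NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     p_value = NA_real_, significant = FALSE)
    } else {
      rate_ratio(agg$events[i], agg$person_years[i], ctrl$events,
                 ctrl$person_years, alpha = alpha, method = method)
    }
  })
  out <- dplyr::bind_cols(agg, dplyr::bind_rows(res))
  # control first, then the canonical pattern order
  out[order(match(out$pattern, c(control, setdiff(pattern_names(),
                                                  control)))), ]
}

#' Baseline characteristics per pattern, compared with the control
#'
#' Median (IQR) age at `t0`, female count and percentage, and median (IQR)
#' baseline eGFR per prescription pattern, with Wilcoxon rank-sum p-values
#' for the continuous variables and Fisher's exact p-value for sex, each
#' versus the control pattern. Patterns with no patients are omitted with a
#' message. The control row has no p-values.
#'
#' @param cohort Cohort tibble with `patient_id`, `t0`, `pattern`,
#'   `baseline_egfr` (from [apply_exclusions()]).
#' @param patients Patient table (`patient_id`, `sex`, `birth_date`).
#' @param control Control pattern id.
#' @return A tibble, one row per non-empty pattern.
#' @export
compare_baseline <- function(cohort, patients, control = control_pattern()) {
  x <- dplyr::left_join(cohort, patients[c("patient_id", "sex",
                                           "birth_date")],
                        by = "patient_id")
  x$age <- age_completed_years(x$birth_date, x$t0)
  empty <- setdiff(pattern_names(), unique(x$pattern))
  if (length(empty))
    message("omitting pattern(s) with no patients: ",
            paste(empty, collapse = ", "))
  ctrl <- x[x$pattern == control, ]
  if (nrow(ctrl) == 0)
    stop("control pattern ", control, " absent from cohort", call. = FALSE)

  one <- function(d) {
    qs_age <- stats::quantile(d$age, c(.25, .5, .75), names = FALSE, type = 2)
    qs_eg <- stats::quantile(d$baseline_egfr, c(.25, .5, .75),
                             names = FALSE, type = 2)
    is_ctrl <- d$pattern[1] == control
    p_age <- p_egfr <- p_sex <- NA_real_
    if (!is_ctrl) {
      p_age <- suppressWarnings(
        stats::wilcox.test(d$age, ctrl$age)$p.value)
      p_egfr <- suppressWarnings(
        stats::wilcox.test(d$baseline_egfr, ctrl$baseline_egfr)$p.value)
      tab <- rbind(c(sum(d$sex == "female"), sum(d$sex == "male")),
                   c(sum(ctrl$sex == "female"), sum(ctrl$sex == "male")))
      p_sex <- stats::fisher.test(tab)$p.value
    }
    tibble::tibble(
      pattern = d$pattern[1], n_patients = nrow(d),
      median_age = qs_age[2], age_q1 = qs_age[1], age_q3 = qs_age[3],
      n_female = sum(d$sex == "female"),
      pct_female = 100 * sum(d$sex == "female") / nrow(d),
      median_egfr = qs_eg[2], egfr_q1 = qs_eg[1], egfr_q3 = qs_eg[3],
      p_age = p_age, p_egfr = p_egfr, p_sex = p_sex)
  }
  out <- dplyr::bind_rows(lapply(split(x, x$pattern), one))
  out[order(match(out$pattern, pattern_names())), ]
}

#' Mask small cells per the publication rule
#'
#' Patient and event counts below the threshold are rendered as `"< 10"`
#' (for the default threshold) and percentages that depend on a masked
#' count as `"NA"`, mirroring the small-cell suppression applied to
#' released tables. Counts at or above the threshold are printed unmasked.
#'
#' @param report A tibble with any of the count columns `n_patients`,
#'   `n_female`, `events` and the dependent percentage column `pct_female`.
#' @param threshold Masking threshold (default 10).
#' @return The report with the affected columns as character.
#' @export
mask_small_cells <- function(report, threshold = 10) {
  out <- report
  masked <- list()
  for (cc in intersect(c("n_patients", "n_female", "events"), names(out))) {
    m <- !is.na(out[[cc]]) & out[[cc]] < threshold
    masked[[cc]] <- m
    out[[cc]] <- ifelse(m, paste0("< ", threshold),
                        as.character(out[[cc]]))
  }
  if ("pct_female" %in% names(out)) {
    dep <- masked[["n_female"]] %||% rep(FALSE, nrow(out))
    out$pct_female <- ifelse(dep, "NA",
                             formatC(report$pct_female, format = "f",
                                     digits = 1))
  }
  out
}
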