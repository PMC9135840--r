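# Independent oracles used to check the implementation by a different route.

# log-space evaluation of the Japanese GFR equation
oracle_egfr <- function(scre, age, sex) {
  exp(log(194) - 1.094 * log(scre) - 0.287 * log(age) +
        ifelse(sex == "female", log(0.739), 0))
}

# day-coverage drug-era oracle: mark every supply day, collapse the marked
# days into runs, dilate inter-run gaps of at most `gap` days (a gap being
# measured from the merged supply end to the next covered day), keep the
# run containing the first prescription, append `grace` days
oracle_episode_end <- function(starts, supplies, gap = 28, grace = 7) {
  days <- sort(unique(unlist(Map(function(s, n) s:(s + n - 1),
                                 starts, supplies))))
  brk <- which(diff(days) > 1)
  runs_start <- days[c(1, brk + 1)]
  runs_end <- days[c(brk, length(days))]
  merged_end <- runs_end[1]
  for (i in seq_along(runs_start)[-1]) {
    if (runs_start[i] <= merged_end + gap)
      merged_end <- max(merged_end, runs_end[i])
    else break
  }
  merged_end + grace
}

# day-by-day enumeration of the four follow-up end conditions, checked in
# the stated precedence on every single day
oracle_follow_up <- function(t0, base_idx, lab_days, lab_idx, grace_end,
                             change_day, study_end, thr) {
  cap_change <- if (is.na(change_day)) Inf else change_day - 1
  horizon <- max(grace_end, study_end, lab_days, t0) + 1
  for (d in t0:horizon) {
    if (d > t0) {
      hit <- any(lab_days == d & lab_idx >= base_idx + thr) &&
        d <= min(grace_end, cap_change, study_end)
      if (hit) return(list(outcome = "event", end = d, reason = "outcome"))
    }
    if (d == min(grace_end, cap_change, study_end)) {
      reason <- if (d == grace_end) "treatment_end"
      else if (d == cap_change) "pattern_change" else "study_end"
      return(list(outcome = "censored", end = d, reason = reason))
    }
  }
  stop("oracle ran past horizon")
}

# two-sided exact binomial p-value by tail enumeration (no binom.test)
oracle_binom_p <- function(x, n, p0) {
  probs <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k),
                  0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Clopper-Pearson bounds by root-finding on enumerated binomial tails
oracle_binom_ci <- function(x, n, alpha = 0.05) {
  upper_tail <- function(p) sum(vapply(x:n, function(k)
    choose(n, k) * p^k * (1 - p)^(n - k), 0))
  lower_tail <- function(p) sum(vapply(0:x, function(k)
    choose(n, k) * p^k * (1 - p)^(n - k), 0))
  lo <- if (x == 0) 0 else
    stats::uniroot(function(p) upper_tail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  hi <- if (x == n) 1 else
    stats::uniroot(function(p) lower_tail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  c(lo, hi)
}

oracle_rate_ratio_ci <- function(x, m, py_e, py_c, alpha = 0.05) {
  ci <- oracle_binom_ci(x, x + m, alpha)
  sapply(ci, function(p) if (p >= 1) Inf else
    (p / (1 - p)) * (py_c / py_e))
}
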