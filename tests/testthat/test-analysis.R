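test_that("person-years are days over 365.25, zero at zero", {
  expect_identical(person_years(0), 0)
  expect_identical(person_years(365.25), 1)
  expect_equal(person_years(87), 0.23819302, tolerance = 1e-8)
  expect_equal(person_years(365), 365 / 365.25)
  expect_error(person_years(-1), ">= 0")
})

test_that("incidence rates handle zero events and zero person-time", {
  expect_identical(incidence_rate(0, 10), 0)
  expect_identical(incidence_rate(10, 2), 5)
  expect_true(is.na(incidence_rate(3, 0)))
  expect_error(incidence_rate(-1, 2), ">= 0")
})

test_that("rate-ratio point estimates and degenerate cases are correct", {
  r <- rate_ratio(10, 2, 5, 4)
  expect_identical(r$irr, 4)
  expect_true(r$ci_low < 4 && r$ci_high > 4)
  # zero exposed events: estimate 0 with a finite upper bound
  r0 <- rate_ratio(0, 2, 5, 4)
  expect_identical(r0$irr, 0)
  expect_identical(r0$ci_low, 0)
  expect_true(is.finite(r0$ci_high))
  # zero control events: infinite-marked estimate, finite lower bound
  rc <- rate_ratio(4, 2, 0, 4)
  expect_identical(rc$irr, Inf)
  expect_true(is.finite(rc$ci_low) && rc$ci_low > 0)
  expect_identical(rc$ci_high, Inf)
  # no events anywhere
  rn <- rate_ratio(0, 2, 0, 4)
  expect_true(is.na(rn$irr))
  expect_identical(rn$p_value, 1)
})

test_that("exact CI and p agree with binomial tail enumeration", {
  cases <- expand.grid(x = c(0, 1, 2, 5, 8), m = c(0, 1, 2, 4, 10),
                       py_e = c(1, 2.5), py_c = c(4))
  cases <- cases[cases$x + cases$m > 0, ]
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    r <- rate_ratio(cc$x, cc$py_e, cc$m, cc$py_c)
    p0 <- cc$py_e / (cc$py_e + cc$py_c)
    expect_equal(r$p_value, oracle_binom_p(cc$x, cc$x + cc$m, p0),
                 tolerance = 1e-8, info = paste(cc, collapse = "/"))
    ci <- oracle_rate_ratio_ci(cc$x, cc$m, cc$py_e, cc$py_c)
    expect_equal(c(r$ci_low, r$ci_high), ci, tolerance = 1e-6,
                 info = paste(cc, collapse = "/"))
  }
})

test_that("the exact method agrees with poisson.test as a second route", {
  for (case in list(c(8, 1, 2, 4), c(3, 2, 7, 3), c(12, 5, 9, 5))) {
    r <- rate_ratio(case[1], case[2], case[3], case[4])
    pt <- stats::poisson.test(c(case[1], case[3]), c(case[2], case[4]))
    expect_equal(r$p_value, pt$p.value, tolerance = 1e-12)
    expect_equal(c(r$ci_low, r$ci_high), as.numeric(pt$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("the rate ratio is invariant to rescaling both person-times", {
  for (c_scale in c(0.1, 3, 250)) {
    a <- rate_ratio(7, 2.2, 4, 5.1)
    b <- rate_ratio(7, 2.2 * c_scale, 4, 5.1 * c_scale)
    expect_equal(a$irr, b$irr)
    expect_equal(a$ci_low, b$ci_low)
    expect_equal(a$ci_high, b$ci_high)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("pattern aggregation reports the control as the reference row", {
  fu <- tibble::tibble(
    pattern = rep(c("P7_LDV_SOF", "P3_DCV_ASV"), c(40, 30)),
    outcome = rep(c("event", "censored", "event", "censored"),
                  c(5, 35, 9, 21)),
    person_days = rep(90L, 70))
  r <- pattern_rates(fu)
  expect_identical(r$pattern[1], "P7_LDV_SOF")
  expect_identical(r$irr[1], 1)
  expect_true(is.na(r$p_value[1]))
  p3 <- r[r$pattern == "P3_DCV_ASV", ]
  expect_equal(p3$person_years, 30 * 90 / 365.25)
  expect_equal(p3$irr, (9 / 30) / (5 / 40))
  expect_error(pattern_rates(fu[fu$pattern != "P7_LDV_SOF", ]), "control")
})

test_that("baseline comparisons return unit p-values for identical groups", {
  t0 <- as.Date("2016-03-01")
  mk <- function(pat, n_f, n_m, ages = NULL) tibble::tibble(
    patient_id = paste0(pat, seq_len(n_f + n_m)),
    t0 = t0, pattern = pat,
    baseline_egfr = rep(c(70, 75, 80), length.out = n_f + n_m),
    sex_ = rep(c("female", "male"), c(n_f, n_m)),
    age_ = ages %||% rep(c(50, 60, 70), length.out = n_f + n_m))
  coh <- dplyr::bind_rows(mk("P7_LDV_SOF", 5, 5), mk("P5_SOF_Rib", 5, 5))
  pts <- tibble::tibble(patient_id = coh$patient_id, sex = coh$sex_,
                        birth_date = t0 - round(coh$age_ * 365.25) - 100)
  res <- compare_baseline(coh[, 1:4], pts)
  p5 <- res[res$pattern == "P5_SOF_Rib", ]
  expect_equal(p5$p_sex, 1, tolerance = 1e-9)
  expect_equal(p5$p_age, 1, tolerance = 1e-9)
  expect_true(is.na(res$p_age[res$pattern == "P7_LDV_SOF"]))
  expect_identical(p5$median_age, 60)
  expect_identical(p5$n_female, 5L)
  expect_identical(p5$pct_female, 50)
})

test_that("the exact sex test matches hypergeometric enumeration for 3/7 vs 30/70", {
  # 2x2 table [[3,7],[30,70]]: equal proportions, p must be 1
  tab <- rbind(c(3, 7), c(30, 70))
  p_fisher <- stats::fisher.test(tab)$p.value
  # enumeration over the hypergeometric support
  n1 <- 10; n2 <- 100; k <- 33
  probs <- stats::dhyper(0:k, n1, n2, k)
  pk <- stats::dhyper(3, n1, n2, k)
  p_enum <- sum(probs[probs <= pk * (1 + 1e-7)])
  expect_equal(p_fisher, p_enum, tolerance = 1e-9)
  expect_equal(p_fisher, 1, tolerance = 1e-9)
})

test_that("small cells are masked with dependent percentages suppressed", {
  rep_tbl <- tibble::tibble(
    pattern = c("A", "B", "C"),
    n_patients = c(120, 9, 10),
    n_female = c(60, 3, 10),
    pct_female = c(50, 33.3, 100),
    events = c(12, 2, 10))
  m <- mask_small_cells(rep_tbl)
  expect_identical(m$n_patients, c("120", "< 10", "10"))
  expect_identical(m$n_female, c("60", "< 10", "10"))
  expect_identical(m$pct_female, c("50.0", "NA", "100.0"))
  expect_identical(m$events, c("12", "< 10", "10"))
  # threshold boundary: 10 is shown unmasked
  expect_false(any(grepl("<", m$n_patients[3])))
})
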