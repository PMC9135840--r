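test_that("the GFR equation matches its printed worked values", {
  expect_equal(egfr_from_scre(1, 60, "male"), 59.90628, tolerance = 1e-6)
  expect_equal(egfr_from_scre(1, 60, "female"), 44.27074, tolerance = 1e-6)
  expect_equal(egfr_from_scre(2, 60, "male"), 28.06374, tolerance = 1e-6)
  # the female value is exactly the male value times 0.739
  expect_identical(egfr_from_scre(1.3, 72, "female"),
                   egfr_from_scre(1.3, 72, "male") * 0.739)
  expect_error(egfr_from_scre(0, 60, "male"), "scre")
  expect_error(egfr_from_scre(1, -1, "male"), "age")
  expect_error(egfr_from_scre(1, 60, "unknown"), "sex")
})

test_that("the GFR equation is strictly decreasing in creatinine and age", {
  set.seed(8)
  scre <- runif(50, 0.3, 6)
  age <- runif(50, 20, 90)
  for (sex in c("male", "female")) {
    v1 <- egfr_from_scre(scre, age, sex)
    expect_true(all(egfr_from_scre(scre + 0.2, age, sex) < v1))
    expect_true(all(egfr_from_scre(scre, age + 2, sex) < v1))
  }
  expect_true(all(egfr_from_scre(scre, age, "female") <
                    egfr_from_scre(scre, age, "male")))
  # scre_from_egfr is the exact inverse
  e <- egfr_from_scre(scre, age, "female")
  expect_equal(scre_from_egfr(e, age, "female"), scre, tolerance = 1e-12)
})

test_that("category boundaries sit exactly at the printed thresholds", {
  b <- c(90, 60, 45, 30, 15)
  expect_identical(egfr_category_index(b), 0:4)
  expect_identical(egfr_category_index(b - 1e-9), 1:5)
  expect_identical(as.character(egfr_category(90)), "G_normal")
  expect_identical(as.character(egfr_category(89.999)), "G_mild")
  expect_identical(as.character(egfr_category(15)), "G_sev")
  expect_identical(as.character(egfr_category(14.999)), "G_failure")
  expect_error(egfr_category_index(0), "egfr")
})

test_that("daily series averages same-day values and prefers recorded eGFR", {
  pts <- tbl_patients("A", birth = "1950-06-15")
  d1 <- as.Date("2016-05-01")
  labs <- dplyr::bind_rows(
    tbl_lab("A", d1, 70), tbl_lab("A", d1, 80),         # same-day pair
    tbl_lab("A", d1 + 1, 1.0, analyte = "sCRE"),        # creatinine only
    tbl_lab("A", d1 + 2, 70),
    tbl_lab("A", d1 + 2, scre_from_egfr(50, 65, "male"), analyte = "sCRE"))
  dd <- build_daily_egfr(labs, pts)
  expect_identical(nrow(dd), 3L)
  expect_identical(dd$value[dd$date == d1], 75)
  expect_identical(dd$source[dd$date == d1], "mean_of_multiple")
  age <- age_completed_years(as.Date("1950-06-15"), d1 + 1)
  expect_equal(dd$value[dd$date == d1 + 1],
               oracle_egfr(1.0, age, "male"), tolerance = 1e-9)
  expect_identical(dd$source[dd$date == d1 + 1], "converted_from_sCRE")
  # recorded eGFR wins over a same-day creatinine implying 50
  expect_identical(dd$value[dd$date == d1 + 2], 70)
  expect_identical(dd$source[dd$date == d1 + 2], "recorded")
})

test_that("baseline is the value closest to t0 within [t0-90, t0-1]", {
  t0 <- as.Date("2016-03-01")
  daily <- tibble::tibble(
    patient_id = "A",
    date = c(t0 - 40, t0 - 5),
    value = c(80, 72), source = "recorded")
  b <- baseline_egfr(t0, daily)
  expect_identical(b$value, 72)
  expect_identical(b$category, "G_mild")
  # single value at the window edge
  b2 <- baseline_egfr(t0, tibble::tibble(patient_id = "A", date = t0 - 90,
                                         value = 68, source = "recorded"))
  expect_identical(b2$value, 68)
  # a t0-day value is never the baseline
  daily3 <- tibble::tibble(patient_id = "A", date = c(t0 - 10, t0),
                           value = c(66, 99), source = "recorded")
  expect_identical(baseline_egfr(t0, daily3)$value, 66)
  expect_error(baseline_egfr(t0, daily3[daily3$date == t0, ]), "excluded")
})

test_that("follow-up detects the first qualifying drop and honours t0 exclusion", {
  t0 <- as.Date("2016-03-01")
  ep <- list(grace_end = t0 + 90)
  daily <- tibble::tibble(
    patient_id = "A", date = t0 + c(0, 10, 20),
    value = c(50, 65, 59), source = "recorded")
  # baseline 74 (G_mild): 65 stays, 59 crosses into G_mild_mod on day 20;
  # the eGFR of 50 on t0 itself is ignored
  r1 <- follow_up(t0, 1, daily, ep, NULL, "2017-12-31", 1)
  expect_identical(r1$outcome, "event")
  expect_identical(r1$person_days, 20L)
  # threshold 2: no value below 45, censored at the episode end
  r2 <- follow_up(t0, 1, daily, ep, NULL, "2017-12-31", 2)
  expect_identical(r2$outcome, "censored")
  expect_identical(r2$end_reason, "treatment_end")
  expect_identical(r2$person_days, 90L)
})

test_that("censoring reasons follow the first-of-four rule with its precedence", {
  t0 <- as.Date("2016-03-01")
  daily <- tibble::tibble(patient_id = "A", date = t0 + 5, value = 80,
                          source = "recorded")
  # pattern change on day 31 censors on day 30
  r <- follow_up(t0, 1, daily, list(grace_end = t0 + 90), t0 + 31,
                 "2017-12-31", 1)
  expect_identical(r$end_reason, "pattern_change")
  expect_identical(r$person_days, 30L)
  # study end before the episode end
  r2 <- follow_up(t0, 1, daily, list(grace_end = t0 + 90), NULL, t0 + 40, 1)
  expect_identical(r2$end_reason, "study_end")
  expect_identical(r2$person_days, 40L)
  # an event on the episode-end day still counts as the outcome
  daily3 <- tibble::tibble(patient_id = "A", date = t0 + 90, value = 50,
                           source = "recorded")
  r3 <- follow_up(t0, 1, daily3, list(grace_end = t0 + 90), NULL,
                  "2017-12-31", 1)
  expect_identical(r3$end_reason, "outcome")
  # a change on day 1 ends follow-up at t0 with zero person-days
  r4 <- follow_up(t0, 1, daily, list(grace_end = t0 + 90), t0 + 1,
                  "2017-12-31", 1)
  expect_identical(r4$person_days, 0L)
})

test_that("threshold-2 events nest within threshold-1 events", {
  set.seed(99)
  t0 <- as.Date("2016-03-01")
  for (rep in 1:60) {
    k <- sample(2:10, 1)
    daily <- tibble::tibble(
      patient_id = "A",
      date = t0 + sort(sample(1:120, k)),
      value = runif(k, 10, 110), source = "recorded")
    ep <- list(grace_end = t0 + sample(30:150, 1))
    base <- sample(0:3, 1)
    r1 <- follow_up(t0, base, daily, ep, NULL, "2017-12-31", 1)
    r2 <- follow_up(t0, base, daily, ep, NULL, "2017-12-31", 2)
    if (r2$outcome == "event") {
      expect_identical(r1$outcome, "event")
      expect_gte(r2$person_days, r1$person_days)
    }
  }
})

test_that("follow-up equals the day-by-day enumeration oracle on random cases", {
  set.seed(123)
  t0 <- as.Date("2016-03-01")
  t0i <- as.integer(t0)
  for (rep in 1:100) {
    k <- sample(1:8, 1)
    lab_off <- sort(sample(0:150, k))
    vals <- runif(k, 10, 110)
    daily <- tibble::tibble(patient_id = "A", date = t0 + lab_off,
                            value = vals, source = "recorded")
    grace_off <- sample(10:160, 1)
    change_off <- if (runif(1) < 0.4) sample(1:150, 1) else NA
    send_off <- if (runif(1) < 0.3) sample(20:160, 1) else 600
    base <- sample(0:4, 1)
    thr <- sample(1:2, 1)
    got <- follow_up(t0, base, daily, list(grace_end = t0 + grace_off),
                     if (is.na(change_off)) NULL else t0 + change_off,
                     t0 + send_off, thr)
    want <- oracle_follow_up(t0i, base, t0i + lab_off,
                             egfr_category_index(vals), t0i + grace_off,
                             if (is.na(change_off)) NA else t0i + change_off,
                             t0i + send_off, thr)
    expect_identical(got$outcome, want$outcome, info = paste("rep", rep))
    expect_identical(as.integer(got$end_date), as.integer(want$end),
                     info = paste("rep", rep))
    expect_identical(got$end_reason, want$reason, info = paste("rep", rep))
  }
})
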