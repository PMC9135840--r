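t0 <- as.Date("2016-03-01")

entry <- function(daa, id = "X1", t = t0) {
  list(patient_id = id, t0 = t, daa_drugs_at_t0 = daa)
}

test_that("anchor DAAs plus concomitants in the +/-30-day window set the pattern", {
  rx <- dplyr::bind_rows(tbl_rx("X1", "TVR", t0),
                         tbl_rx("X1", "PEG_IFN", t0 + 5, 28),
                         tbl_rx("X1", "RIB", t0 - 12, 28))
  expect_identical(classify_pattern(entry("TVR"), rx)$pattern,
                   "P1_TVR_PegIFN_Rib")
  # daclatasvir + asunaprevir is a permitted pair, classified as P3
  expect_identical(classify_pattern(entry(c("DCV", "ASV")),
                                    tbl_rx("X1", "DCV", t0))$pattern,
                   "P3_DCV_ASV")
  # telaprevir without its backbone is not classifiable
  res <- classify_pattern(entry("TVR"), tbl_rx("X1", "TVR", t0))
  expect_true(is.na(res$pattern))
  expect_identical(res$reason, "missing_concomitant")
  # daclatasvir alone lacks its required partner
  expect_identical(
    classify_pattern(entry("DCV"), tbl_rx("X1", "DCV", t0))$reason,
    "missing_partner_daa")
})

test_that("ribavirin at the window edge separates P8 from P9", {
  base <- tbl_rx("X1", "OBV_PTV_r", t0)
  rib_in <- dplyr::bind_rows(base, tbl_rx("X1", "RIB", t0 + 30, 28))
  rib_out <- dplyr::bind_rows(base, tbl_rx("X1", "RIB", t0 + 31, 28))
  expect_identical(classify_pattern(entry("OBV_PTV_r"), rib_in)$pattern,
                   "P9_OBV_PTV_r_Rib")
  expect_identical(classify_pattern(entry("OBV_PTV_r"), rib_out)$pattern,
                   "P8_OBV_PTV_r")
  rib_before <- dplyr::bind_rows(base, tbl_rx("X1", "RIB", t0 - 30, 28))
  expect_identical(classify_pattern(entry("OBV_PTV_r"), rib_before)$pattern,
                   "P9_OBV_PTV_r_Rib")
})

test_that("removing or adding ribavirin flips P9 and P8 classifications", {
  sim <- simulate_dataset(simulation_config(n_patients = 500, seed = 42))
  truth <- sim$truth
  rx <- sim$dataset$prescriptions
  for (p in c("P8_OBV_PTV_r", "P9_OBV_PTV_r_Rib")) {
    ids <- truth$patient_id[!is.na(truth$pattern) & truth$pattern == p]
    expect_gt(length(ids), 0)
    for (id in ids[seq_len(min(3, length(ids)))]) {
      t <- truth$t0[truth$patient_id == id]
      prx <- rx[rx$patient_id == id, ]
      e <- entry("OBV_PTV_r", id, t)
      if (p == "P9_OBV_PTV_r_Rib") {
        flipped <- prx[prx$drug != "RIB", ]
        expect_identical(classify_pattern(e, flipped)$pattern,
                         "P8_OBV_PTV_r")
      } else {
        flipped <- dplyr::bind_rows(prx, tbl_rx(id, "RIB", t + 3, 28))
        expect_identical(classify_pattern(e, flipped)$pattern,
                         "P9_OBV_PTV_r_Rib")
      }
    }
  }
})

test_that("episode construction follows the 28-day gap / 7-day grace rule", {
  e <- entry("LDV_SOF")
  # one 14-day prescription: supply ends day 13, episode ends day 20
  ep <- build_treatment_episode(e, "P7_LDV_SOF",
                                tbl_rx("X1", "LDV_SOF", t0, 14),
                                "2017-12-31")
  expect_identical(as.integer(ep$supply_end - t0), 13L)
  expect_identical(as.integer(ep$end - t0), 20L)
  # refill at day 41: gap 41 - 13 = 28, still one era ending day 61
  rx2 <- dplyr::bind_rows(tbl_rx("X1", "LDV_SOF", t0, 14),
                          tbl_rx("X1", "LDV_SOF", t0 + 41, 14))
  ep2 <- build_treatment_episode(e, "P7_LDV_SOF", rx2, "2017-12-31")
  expect_identical(as.integer(ep2$end - t0), 61L)
  # refill at day 42: gap 29 breaks the era, episode ends day 20
  rx3 <- dplyr::bind_rows(tbl_rx("X1", "LDV_SOF", t0, 14),
                          tbl_rx("X1", "LDV_SOF", t0 + 42, 14))
  ep3 <- build_treatment_episode(e, "P7_LDV_SOF", rx3, "2017-12-31")
  expect_identical(as.integer(ep3$end - t0), 20L)
})

test_that("episodes are truncated at the study end", {
  late <- as.Date("2017-12-01")
  ep <- build_treatment_episode(entry("LDV_SOF", t = late), "P7_LDV_SOF",
                                tbl_rx("X1", "LDV_SOF", late, 84),
                                "2017-12-31")
  expect_identical(ep$end, as.Date("2017-12-31"))
  expect_true(ep$truncated)
})

test_that("P3/P6 episodes follow the partner drug, not asunaprevir/grazoprevir", {
  rx <- dplyr::bind_rows(tbl_rx("X1", "DCV", t0, 28),
                         tbl_rx("X1", "DCV", t0 + 28, 28),
                         tbl_rx("X1", "ASV", t0, 84))
  ep <- build_treatment_episode(entry(c("DCV", "ASV")), "P3_DCV_ASV", rx,
                                "2017-12-31")
  # two 28-day daclatasvir fills: supply ends day 55 despite the longer
  # asunaprevir record
  expect_identical(as.integer(ep$supply_end - t0), 55L)
})

test_that("episode end matches the day-coverage oracle on random prescription sets", {
  set.seed(2024)
  for (rep in 1:200) {
    k <- sample(1:8, 1)
    starts <- sort(sample(0:200, k))
    starts[1] <- 0L
    supplies <- sample(1:60, k, replace = TRUE)
    rx <- tbl_rx("X1", "LDV_SOF", t0 + starts, supplies)
    ep <- build_treatment_episode(entry("LDV_SOF"), "P7_LDV_SOF", rx,
                                  "2017-12-31")
    expect_identical(as.integer(ep$grace_end - t0),
                     as.integer(oracle_episode_end(starts, supplies)),
                     info = paste("rep", rep))
  }
})

test_that("pattern change is the first other-DAA prescription inside the episode", {
  e <- entry("LDV_SOF")
  rx <- tbl_rx("X1", "LDV_SOF", t0, 84)
  ep <- build_treatment_episode(e, "P7_LDV_SOF", rx, "2017-12-31")
  expect_true(is.na(detect_pattern_change(e, "P7_LDV_SOF", rx, ep)))
  rx2 <- dplyr::bind_rows(rx, tbl_rx("X1", "OBV_PTV_r", t0 + 30, 28))
  expect_identical(detect_pattern_change(e, "P7_LDV_SOF", rx2, ep), t0 + 30)
  # after the episode end: already censored, no change
  rx3 <- dplyr::bind_rows(rx, tbl_rx("X1", "OBV_PTV_r", t0 + 120, 28))
  expect_true(is.na(detect_pattern_change(e, "P7_LDV_SOF", rx3, ep)))
  # a ribavirin addition is not a DAA and never a change
  rx4 <- dplyr::bind_rows(rx, tbl_rx("X1", "RIB", t0 + 30, 28))
  expect_true(is.na(detect_pattern_change(e, "P7_LDV_SOF", rx4, ep)))
})

test_that("patterns partition the cohort", {
  sim <- simulate_dataset(simulation_config(n_patients = 300, seed = 55))
  res <- run_pipeline(sim$dataset, baseline_comparison = FALSE)
  expect_false(any(is.na(res$cohort$pattern)))
  expect_true(all(res$cohort$pattern %in% pattern_names()))
  expect_identical(anyDuplicated(res$cohort$patient_id), 0L)
})
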