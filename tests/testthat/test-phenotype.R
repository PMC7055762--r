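test_that("the MDRD eGFR equation reproduces frozen reference values", {
  # 175 * 60^(-0.203) for a non-black male with creatinine 1.0
  base <- 175 * 60^(-0.203)
  expect_equal(compute_egfr(1.0, 60, "male"), base, tolerance = 1e-12)
  expect_equal(compute_egfr(1.0, 60, "male"), 76.23, tolerance = 0.01)
  expect_equal(compute_egfr(1.0, 60, "female"), base * 0.742,
               tolerance = 1e-12)
  expect_equal(compute_egfr(1.0, 60, "female"), 56.56, tolerance = 0.01)
  expect_equal(compute_egfr(1.0, 60, "male", "black"), base * 1.212)
  expect_error(compute_egfr(0, 60, "male"), "positive")
  expect_error(compute_egfr(1, 17, "male"), "age")
})

test_that("kidney abnormality thresholds are exactly as prescribed", {
  expect_true(classify_kidney_abnormal(egfr = 59.9))
  expect_false(classify_kidney_abnormal(egfr = 60.0, acr = 29.9))
  expect_true(classify_kidney_abnormal(acr = 30.0))
  expect_true(classify_kidney_abnormal(pcr = 30.0))
  expect_false(classify_kidney_abnormal(pcr = 29.999))
  expect_error(classify_kidney_abnormal(), "at least one")
  # monotone: decreasing eGFR or increasing ACR never flips true -> false
  set.seed(11)
  for (i in 1:30) {
    e <- runif(1, 20, 100); a <- runif(1, 1, 60)
    if (classify_kidney_abnormal(egfr = e, acr = a)) {
      expect_true(classify_kidney_abnormal(egfr = e - runif(1, 0, 10),
                                           acr = a))
      expect_true(classify_kidney_abnormal(egfr = e,
                                           acr = a + runif(1, 0, 10)))
    }
  }
})

test_that("diabetes onset follows the earliest qualifying criterion", {
  # two qualifying HbA1c within two years -> earliest date
  t1 <- rbind(tl_demo(),
              tl_row(100, "laboratory", "hba1c", 6.6),
              tl_row(400, "laboratory", "hba1c", 7.0))
  expect_identical(detect_dm_onset(t1), 100L)
  # a single qualifying lab is not enough
  t2 <- rbind(tl_demo(), tl_row(100, "laboratory", "hba1c", 6.6))
  expect_true(is.na(detect_dm_onset(t2)))
  # two qualifying labs more than two years apart do not pair
  t3 <- rbind(tl_demo(),
              tl_row(100, "laboratory", "hba1c", 6.6),
              tl_row(900, "laboratory", "hba1c", 7.0))
  expect_true(is.na(detect_dm_onset(t3)))
  # sub-threshold labs never qualify
  t4 <- rbind(tl_demo(),
              tl_row(100, "laboratory", "hba1c", 6.4),
              tl_row(200, "laboratory", "hba1c", 6.4))
  expect_true(is.na(detect_dm_onset(t4)))
  # one glucose-lowering medication record suffices
  t5 <- rbind(tl_demo(), tl_row(250, "medications",
                                "glucose_lowering_med"))
  expect_identical(detect_dm_onset(t5), 250L)
  # two diagnoses on different days within two years
  t6 <- rbind(tl_demo(),
              tl_row(50, "diagnoses", "dm_dx"),
              tl_row(60, "diagnoses", "dm_dx"))
  expect_identical(detect_dm_onset(t6), 50L)
  # criterion 4: two distinct incomplete types (one lab + one diagnosis)
  t7 <- rbind(tl_demo(),
              tl_row(120, "laboratory", "random_glucose", 220),
              tl_row(3000, "diagnoses", "dm_dx"))
  expect_identical(detect_dm_onset(t7), 120L)
  # gestational events never count
  t8 <- rbind(tl_demo(),
              tl_row(10, "diagnoses", "gestational_dm"),
              tl_row(20, "diagnoses", "gestational_dm"))
  expect_true(is.na(detect_dm_onset(t8)))
  # fasting glucose threshold is 126, random is 200
  t9 <- rbind(tl_demo(),
              tl_row(10, "laboratory", "fasting_glucose", 126),
              tl_row(30, "laboratory", "fasting_glucose", 130))
  expect_identical(detect_dm_onset(t9), 10L)
})

test_that("the worked outcome sequence (0, NA, 1) arises from a three-lab timeline", {
  tlx <- rbind(tl_demo(age = 60),
               tl_row(100, "laboratory", "serum_creatinine", scr_for(90)),
               tl_row(800, "laboratory", "serum_creatinine", scr_for(45)))
  os <- build_outcome_sequence(tlx, 0L, horizon_T = 3)
  expect_identical(os$statuses, c(0L, NA, 1L))
  expect_identical(os$end_point_day, 800L)
})

test_that("outcome sequences truncate, default to NA, and use the last lab of a window", {
  # abnormal in year 0 -> sequence of length 1
  t1 <- rbind(tl_demo(), tl_row(10, "laboratory", "uacr", 120))
  expect_identical(build_outcome_sequence(t1, 0L, 3)$statuses, 1L)
  # no qualifying labs -> all NA
  t2 <- tl_demo()
  expect_identical(build_outcome_sequence(t2, 0L, 3)$statuses,
                   rep(NA_integer_, 3))
  # two labs in the same window: the later one decides
  t3 <- rbind(tl_demo(),
              tl_row(20, "laboratory", "uacr", 120),
              tl_row(300, "laboratory", "uacr", 5))
  expect_identical(build_outcome_sequence(t3, 0L, 2)$statuses[1], 0L)
  # inpatient labs do not determine yearly status
  t4 <- rbind(tl_demo(),
              tl_row(20, "laboratory", "uacr", 120, enc = "inpatient"))
  expect_identical(build_outcome_sequence(t4, 0L, 2)$statuses,
                   rep(NA_integer_, 2))
})

test_that("landmark eligibility skips missing years without censoring later ones", {
  s <- c(0L, NA, 1L)
  expect_true(landmark_eligibility(s, 0))
  expect_false(landmark_eligibility(s, 1))
  expect_true(landmark_eligibility(s, 2))
  expect_true(landmark_eligibility(c(1L), 0))
  expect_true(landmark_eligibility(c(0L, 0L), 1))
  expect_false(landmark_eligibility(c(0L, 1L, 0L), 2))
  expect_false(landmark_eligibility(c(0L, 0L), 3))  # beyond the sequence
})

test_that("cohort filters exclude as specified and report overlapping counts", {
  mk <- function(pid, extra) {
    rbind(tl_demo(pid = pid),
          tl_row(0, "laboratory", "hba1c", 7, pid = pid),
          tl_row(100, "laboratory", "hba1c", 7.5, pid = pid),
          extra)
  }
  ok <- mk("A", tl_row(50, "laboratory", "uacr", 5, pid = "A"))
  prior_kidney <- mk("B", tl_row(-100, "laboratory", "serum_creatinine",
                                 scr_for(50), pid = "B"))
  no_lab <- mk("C", NULL)
  t1dm <- mk("D", rbind(tl_row(10, "diagnoses", "t1dm_dx", pid = "D"),
                        tl_row(60, "laboratory", "uacr", 5, pid = "D")))
  # E hits two criteria at once: type 1 flag and prior kidney disease
  both <- mk("E", rbind(tl_row(10, "diagnoses", "t1dm_dx", pid = "E"),
                        tl_row(-30, "laboratory", "uacr", 80, pid = "E"),
                        tl_row(60, "laboratory", "uacr", 5, pid = "E")))
  res <- apply_cohort_filters(rbind(ok, prior_kidney, no_lab, t1dm, both),
                              horizon_T = 3)
  expect_identical(res$cohort$patient_id, "A")
  ex <- setNames(res$exclusions$n_excluded, res$exclusions$criterion)
  expect_identical(ex[["kidney_disease_before_onset"]], 2L)
  expect_identical(ex[["t1dm_or_cf_diabetes"]], 2L)
  expect_identical(ex[["no_valid_outpatient_kidney_lab"]], 1L)
  # counts sum to more than the number of excluded patients
  expect_gt(sum(ex), 5L - nrow(res$cohort))
})

test_that("cases and controls get the prescribed end points", {
  case <- rbind(tl_demo(pid = "A"),
                tl_row(0, "laboratory", "hba1c", 7, pid = "A"),
                tl_row(100, "laboratory", "hba1c", 7.5, pid = "A"),
                tl_row(200, "laboratory", "uacr", 10, pid = "A"),
                tl_row(500, "laboratory", "uacr", 90, pid = "A"))
  ctrl <- rbind(tl_demo(pid = "B"),
                tl_row(0, "laboratory", "hba1c", 7, pid = "B"),
                tl_row(100, "laboratory", "hba1c", 7.5, pid = "B"),
                tl_row(200, "laboratory", "uacr", 10, pid = "B"),
                tl_row(600, "laboratory", "uacr", 12, pid = "B"))
  res <- apply_cohort_filters(rbind(case, ctrl), horizon_T = 3)
  a <- res$cohort[res$cohort$patient_id == "A", ]
  b <- res$cohort[res$cohort$patient_id == "B", ]
  expect_identical(a$group, "case")
  expect_identical(a$end_point_day, 500L)   # first abnormal lab
  expect_identical(b$group, "control")
  expect_identical(b$end_point_day, 600L)   # last normal lab
  expect_identical(a$sequence, "0,1")
})
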