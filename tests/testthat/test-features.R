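# A tiny hand-built multi-patient event table used across design tests:
# three patients, diabetes onset at day 0, outcomes over two years.
mini_events <- function() {
  pats <- lapply(c("A", "B", "C"), function(pid) {
    rbind(tl_demo(age = 60, pid = pid),
          tl_row(0, "laboratory", "hba1c", 7, pid = pid),
          tl_row(100, "laboratory", "hba1c", 7.5, pid = pid),
          tl_row(50, "laboratory", "uacr", 5, pid = pid),
          tl_row(400, "laboratory", "uacr", 6, pid = pid))
  })
  do.call(rbind, pats)
}

test_that("rare features are dropped by training-split prevalence", {
  ev <- do.call(rbind, lapply(sprintf("P%03d", 1:200), function(pid)
    tl_row(1, "diagnoses", "common", pid = pid)))
  ev <- rbind(ev, tl_row(1, "diagnoses", "rare", pid = "P001"))
  # 1 of 200 carriers = 0.5% < 1% -> dropped
  kept <- filter_rare_features(ev, 0.01)
  expect_identical(kept, "diagnoses:common")
  # threshold 0 retains everything
  expect_length(filter_rare_features(ev, 0), 2L)
  # 1 of 10 patients is exactly at a 1% threshold -> retained
  kept10 <- filter_rare_features(ev, 0.01,
                                 patient_ids = sprintf("P%03d", 1:10))
  expect_true("diagnoses:rare" %in% kept10)
})

test_that("latest-value cells take the most recent pre-landmark observation", {
  ev <- rbind(mini_events(),
              tl_row(100, "laboratory", "creat_extra", 1.0, pid = "A"),
              tl_row(500, "laboratory", "creat_extra", 2.0, pid = "A"),
              tl_row(800, "laboratory", "creat_extra", 9.0, pid = "A"))
  coh <- apply_cohort_filters(ev, horizon_T = 2)
  d <- latest_value_design(ev, coh, 2,
                           patient_ids = coh$cohort$patient_id)
  col <- "laboratory:creat_extra"
  a <- d$X[match("A", d$patient_id), col]
  expect_equal(unname(a), 2.0)       # day-500 value; day-800 is post-landmark
  # patients without any observation stay missing (numeric) or 0 (binary)
  expect_true(is.na(d$X[match("B", d$patient_id), col]))
  # same-day duplicates average
  ev2 <- rbind(mini_events(),
               tl_row(80, "laboratory", "dup", 1.0, pid = "B"),
               tl_row(80, "laboratory", "dup", 3.0, pid = "B"))
  coh2 <- apply_cohort_filters(ev2, horizon_T = 1)
  d2 <- latest_value_design(ev2, coh2, 1,
                            patient_ids = coh2$cohort$patient_id)
  expect_equal(unname(d2$X[match("B", d2$patient_id), "laboratory:dup"]),
               2.0)
})

test_that("latest-value designs ignore deletions of non-latest events", {
  sim <- small_sim(n = 60, T_ = 2, seed = 21)
  coh <- apply_cohort_filters(sim$events, 2)
  feats <- filter_rare_features(sim$events, 0)
  d1 <- latest_value_design(sim$events, coh, 1, feats)
  # drop one numeric event that is not its (patient, feature) maximum day
  ev <- sim$events
  num <- which(!is.na(ev$value) & ev$domain == "laboratory" &
                 ev$day < 365 & ev$feature_code == "laboratory_f1")
  key <- paste(ev$patient_id, ev$feature_code)
  last_day <- ave(ev$day, key, FUN = max)
  victim <- num[ev$day[num] < last_day[num]][1]
  skip_if(is.na(victim))
  d2 <- latest_value_design(ev[-victim, ], coh, 1, feats)
  expect_identical(d1$X, d2$X)
})

test_that("stacked designs have one column per feature per window", {
  ev <- mini_events()
  coh <- apply_cohort_filters(ev, horizon_T = 2)
  feats <- c("laboratory:f_a", "laboratory:f_b", "laboratory:f_c")
  d1 <- stack_temporal_design(ev, coh, 1, feats,
                              patient_ids = coh$cohort$patient_id)
  expect_identical(sum(grepl("@w", colnames(d1$X))), 6L)  # 3 features x 2
  d0 <- stack_temporal_design(ev, coh, 0, feats,
                              patient_ids = coh$cohort$patient_id)
  expect_identical(sum(grepl("@w", colnames(d0$X))), 3L)
  # linear growth in t + 1
  for (t in 0:1) {
    dt <- stack_temporal_design(ev, coh, t, feats,
                                patient_ids = coh$cohort$patient_id)
    expect_identical(sum(grepl("@w", colnames(dt$X))),
                     length(feats) * (t + 1L))
  }
  # at t = 0 the stacked window-0 columns equal the latest-value columns
  lv0 <- latest_value_design(ev, coh, 0, feats,
                             patient_ids = coh$cohort$patient_id)
  w0 <- d0$X[, paste0(feats, "@w0")]
  colnames(w0) <- feats
  expect_identical(w0, lv0$X[, feats])
})

test_that("discrete-survival pseudo-observations stack eligible windows", {
  sim <- small_sim(n = 80, T_ = 3, seed = 31)
  coh <- apply_cohort_filters(sim$events, 3)
  feats <- filter_rare_features(sim$events, 0.05)
  d <- discrete_survival_design(sim$events, coh, 3, feats)
  expected_rows <- sum(vapply(0:2, function(t)
    length(landboost:::.lb_eligible_ids(coh, t)), 0L))
  expect_identical(d$n, expected_rows)
  expect_true("window_index" %in% colnames(d$X))
  expect_identical(unname(d$X[, "window_index"]), as.numeric(d$landmark))
  # a patient with sequence (1) contributes exactly one row
  one <- names(coh$sequences)[vapply(coh$sequences, function(s)
    length(s) == 1L && !is.na(s[1]) && s[1] == 1L, TRUE)]
  skip_if(length(one) == 0)
  expect_identical(sum(d$patient_id == one[1]), 1L)
})

test_that("history counts are cumulative distinct codes with increments", {
  ev <- rbind(tl_demo(pid = "A"),
              tl_row(0, "laboratory", "hba1c", 7, pid = "A"),
              tl_row(100, "laboratory", "hba1c", 7.5, pid = "A"),
              tl_row(10, "laboratory", "uacr", 4, pid = "A"),
              tl_row(400, "laboratory", "uacr", 4, pid = "A"),
              # five distinct codes before t=1, three more in year 1
              tl_row(-20, "diagnoses", "d1", pid = "A"),
              tl_row(30, "diagnoses", "d2", pid = "A"),
              tl_row(40, "medications", "m1", pid = "A"),
              tl_row(400, "diagnoses", "d3", pid = "A"),
              tl_row(410, "orders", "o1", pid = "A"),
              tl_row(420, "orders", "o1", pid = "A"),   # duplicate code
              tl_row(430, "alerts", "a1", pid = "A"))
  coh <- apply_cohort_filters(ev, horizon_T = 2)
  h1 <- history_count_features(ev, coh, 1, "A")
  h2 <- history_count_features(ev, coh, 2, "A")
  expect_equal(unname(h1[1, ]), c(5, 4))   # hba1c, uacr, d1, d2, m1;
                                           # increment excludes pre-onset d1
  expect_equal(unname(h2[1, ]), c(8, 3))   # + d3, o1 (once), a1
  h0 <- history_count_features(ev, coh, 0, "A")
  expect_equal(unname(h0[1, ]), c(1, 1))   # only the pre-onset d1
  coh_none <- coh
  expect_equal(unname(history_count_features(ev[ev$day > 1e6, ], coh, 0,
                                             "A")[1, ]), c(0, 0))
})

test_that("no design cell depends on events at or after the landmark", {
  sim <- small_sim(n = 50, T_ = 2, seed = 41)
  coh <- apply_cohort_filters(sim$events, 2)
  feats <- filter_rare_features(sim$events, 0)
  d1 <- latest_value_design(sim$events, coh, 1, feats)
  s1 <- stack_temporal_design(sim$events, coh, 1, feats)
  ev <- sim$events
  late <- ev$day >= 365
  ev$value[late & !is.na(ev$value)] <- 9999
  d2 <- latest_value_design(ev, coh, 1, feats)
  s2 <- stack_temporal_design(ev, coh, 1, feats)
  expect_identical(d1$X, d2$X)
  expect_identical(s1$X, s2$X)
})

test_that("sparse-triplet serialisation round-trips designs exactly", {
  sim <- small_sim(n = 40, T_ = 2, seed = 51)
  coh <- apply_cohort_filters(sim$events, 2)
  feats <- filter_rare_features(sim$events, 0)
  d <- latest_value_design(sim$events, coh, 1, feats)
  prefix <- tempfile()
  write_design(d, prefix)
  back <- read_design(prefix)
  expect_identical(back$X, d$X)
  expect_identical(back$patient_id, d$patient_id)
  expect_equal(back$y, unname(d$y))
  expect_identical(back$col_type, d$col_type)
})
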