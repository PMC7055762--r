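# shared small fitted setup (time-constant, strong signal)
lm_setup <- function(n = 300, T_ = 3, seed = 7) {
  sim <- small_sim(n = n, T_ = T_, seed = seed,
                   beta = c(laboratory_f2 = 1.0, diagnoses_f2 = 0.9))
  coh <- apply_cohort_filters(sim$events, T_)
  feats <- filter_rare_features(sim$events, 0.01)
  list(sim = sim, coh = coh, feats = feats)
}

test_that("a single-landmark fit is bit-identical to a plain boosted fit", {
  s <- lm_setup(T_ = 1)
  ctl <- gbm_control(max_trees = 30, seed = 5)
  ds <- build_landmark_datasets(s$sim$events, s$coh, 1, s$feats)
  lb <- fit_landmark_boosting(ds, ctl)
  holdout <- landboost:::.lb_stratified_holdout(ds[[1]]$y,
                                                ctl$holdout_fraction,
                                                ctl$seed)
  plain <- fit_gbm(ds[[1]]$X, ds[[1]]$y, 0, control = ctl,
                   holdout = holdout)
  expect_identical(predict(lb$models[[1]], ds[[1]]$X),
                   predict(plain, ds[[1]]$X))
})

test_that("a zero-tree landmark update carries the previous prediction forward", {
  s <- lm_setup(T_ = 3)
  ctl <- gbm_control(max_trees = 30, seed = 5)
  ds <- build_landmark_datasets(s$sim$events, s$coh, 3, s$feats)
  lb <- fit_landmark_boosting(ds, ctl)
  # freeze landmark 2: replace its model with an empty ensemble
  lb0 <- lb
  lb0$models[[3]] <- fit_gbm(ds[[3]]$X, ds[[3]]$y, 0,
                             control = gbm_control(max_trees = 0))
  pr <- predict_rolling(lb0, s$sim$events, s$coh, 3, s$feats)
  p1 <- pr[pr$landmark == 1, ]
  p2 <- pr[pr$landmark == 2, ]
  both <- intersect(p1$patient_id, p2$patient_id)
  expect_gt(length(both), 10)
  expect_equal(p2$probability[match(both, p2$patient_id)],
               p1$probability[match(both, p1$patient_id)],
               tolerance = 1e-12)
})

test_that("cold-start margins are the training prevalence log-odds", {
  s <- lm_setup(T_ = 2)
  ds <- build_landmark_datasets(s$sim$events, s$coh, 2, s$feats)
  lb <- fit_landmark_boosting(ds, gbm_control(max_trees = 10))
  expect_equal(lb$cold_start_margin[2],
               qlogis(mean(ds[[2]]$y)), tolerance = 1e-12)
  lb0 <- fit_landmark_boosting(ds, gbm_control(max_trees = 10),
                               cold_start = "zero")
  expect_identical(lb0$cold_start_margin, c(0, 0))
})

test_that("latest-value and stacked designs coincide at the first landmark", {
  s <- lm_setup(T_ = 2)
  ctl <- gbm_control(max_trees = 20, seed = 3)
  lv <- fit_comparator("latest_value", s$sim$events, s$coh, 2, s$feats,
                       ctl)
  st <- fit_comparator("stack_temporal", s$sim$events, s$coh, 2, s$feats,
                       ctl)
  pl <- predict_rolling(lv, s$sim$events, s$coh, 2, s$feats)
  ps <- predict_rolling(st, s$sim$events, s$coh, 2, s$feats)
  expect_equal(pl$probability[pl$landmark == 0],
               ps$probability[ps$landmark == 0], tolerance = 1e-12)
})

test_that("the discrete-survival representation trains exactly one model", {
  s <- lm_setup(T_ = 3)
  fit <- fit_comparator("discrete_survival", s$sim$events, s$coh, 3,
                        s$feats, gbm_control(max_trees = 20))
  expect_length(fit$models, 1L)
  p <- predict_rolling(fit, s$sim$events, s$coh, 3, s$feats)
  expect_setequal(unique(p$landmark), 0:2)
  expect_error(fit_comparator("nearest_neighbour", s$sim$events, s$coh,
                              3, s$feats), "arg")
})

test_that("rolling predictions cover exactly the eligible patients with percentiles", {
  s <- lm_setup(T_ = 3)
  ds <- build_landmark_datasets(s$sim$events, s$coh, 3, s$feats)
  lb <- fit_landmark_boosting(ds, gbm_control(max_trees = 15))
  pr <- predict_rolling(lb, s$sim$events, s$coh, 3, s$feats)
  for (t in 0:2) {
    sub <- pr[pr$landmark == t, ]
    expect_setequal(sub$patient_id, landboost:::.lb_eligible_ids(s$coh, t))
    expect_true(all(sub$percentile >= 0 & sub$percentile <= 100))
  }
  # constant scores tie at the midpoint percentile
  expect_equal(unique(landboost:::.lb_percentile(rep(0.4, 11))), 50)
  # trajectories have one entry per eligible landmark
  tr <- risk_trajectories(pr)
  lens <- vapply(tr, nrow, 0L)
  counts <- table(pr$patient_id)
  expect_identical(unname(lens[names(counts)]), unname(as.integer(counts)))
  full <- risk_trajectories(pr, complete_only = TRUE)
  expect_true(all(vapply(full, nrow, 0L) == 3L))
})

test_that("landmark training never sees events at or after its landmark day", {
  s <- lm_setup(T_ = 2, n = 150)
  ctl <- gbm_control(max_trees = 10, seed = 2)
  ds1 <- build_landmark_datasets(s$sim$events, s$coh, 2, s$feats)
  ev <- s$sim$events
  late <- ev$day >= 365
  ev$value[late & !is.na(ev$value)] <- ev$value[late & !is.na(ev$value)] * 3
  ds2 <- build_landmark_datasets(ev, s$coh, 2, s$feats)
  expect_identical(ds1[[2]]$X, ds2[[2]]$X)
  f1 <- fit_landmark_boosting(ds1[1:2], ctl)
  f2 <- fit_landmark_boosting(ds2[1:2], ctl)
  expect_identical(f1$models[[2]]$trees, f2$models[[2]]$trees)
})

test_that("adding landmark trees does not hurt the carried baseline's test log-loss", {
  # knowledge-transfer check on a well-specified time-constant scenario
  # stump updates: the cleanest reading of "correctly fit trees cannot
  # hurt" -- deeper updates buy ranking at a small probabilistic
  # overconfidence cost on cohorts this small
  logloss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
  deltas <- c()
  for (seed in 1:10) {
    sim <- small_sim(n = 800, T_ = 2, seed = seed,
                     beta = c(laboratory_f2 = 1.2, diagnoses_f2 = 1.0))
    coh <- apply_cohort_filters(sim$events, 2)
    sp <- split_cohort(coh$cohort$patient_id, 0.8, seed)
    trc <- landboost:::.lb_subset_cohort(coh, sp$train)
    tec <- landboost:::.lb_subset_cohort(coh, sp$test)
    feats <- filter_rare_features(sim$events, 0.01, sp$train)
    ds <- build_landmark_datasets(sim$events, trc, 2, feats)
    lb <- fit_landmark_boosting(ds, gbm_control(max_depth = 1,
                                                min_child_weight = 5,
                                                lambda = 5,
                                                max_trees = 100,
                                                early_stop_rounds = 25,
                                                seed = seed))
    pr <- predict_rolling(lb, sim$events, tec, 2, feats)
    p0 <- pr[pr$landmark == 0, ]
    p1 <- pr[pr$landmark == 1, ]
    both <- intersect(p0$patient_id, p1$patient_id)
    carried <- p0$probability[match(both, p0$patient_id)]
    updated <- p1$probability[match(both, p1$patient_id)]
    y1 <- p1$label[match(both, p1$patient_id)]
    deltas <- c(deltas, logloss(updated, y1) - logloss(carried, y1))
  }
  expect_lte(mean(deltas), 0.01)
})

test_that("predicted risk percentiles separate eventual cases from controls", {
  cfg <- preset_scenarios(n_patients = 1200, seed = 31)$time_varying
  sim <- generate_cohort(cfg)
  coh <- apply_cohort_filters(sim$events, 5)
  feats <- filter_rare_features(sim$events, 0.01)
  ds <- build_landmark_datasets(sim$events, coh, 5, feats)
  lb <- fit_landmark_boosting(ds, gbm_control(max_depth = 2,
                                              min_child_weight = 5,
                                              lambda = 5,
                                              max_trees = 100,
                                              early_stop_rounds = 25,
                                              seed = 31))
  pr <- predict_rolling(lb, sim$events, coh, 5, feats)
  last <- pr[pr$landmark == 4, ]
  expect_gt(mean(last$percentile[last$label == 1]),
            mean(last$percentile[last$label == 0]))
})
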