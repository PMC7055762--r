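#' Patient-level train/test split
#'
#' Randomly divides patients into a training and a test set at the patient
#' level, so all of a patient's landmark examples stay on one side of the
#' split (default 80/20).
#'
#' @param patient_ids Character vector of patient ids.
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return List with sorted character vectors `train` and `test`.
#' @export
split_cohort <- function(patient_ids, train_fraction = 0.8, seed = 1L) {
  stopifnot(length(patient_ids) >= 1L, train_fraction > 0,
            train_fraction < 1)
  set.seed(seed)
  n_train <- floor(train_fraction * length(patient_ids))
  train <- sort(sample(patient_ids, n_train))
  list(train = train, test = sort(setdiff(patient_ids, train)))
}

# restrict a phenotyped cohort object to a patient subset
.lb_subset_cohort <- function(cohort, ids) {
  list(cohort = cohort$cohort[cohort$cohort$patient_id %in% ids, ,
                              drop = FALSE],
       sequences = cohort$sequences[intersect(names(cohort$sequences),
                                              ids)],
       exclusions = cohort$exclusions,
       demographics = cohort$demographics[
         cohort$demographics$patient_id %in% ids, , drop = FALSE])
}

#' Evaluate rolling predictions per landmark
#'
#' Computes, for every landmark, AUROC, AUPRC, the top-40th-percentile
#' threshold metrics (sensitivity, specificity, PPV, NPV), the Pearson
#' correlation between predicted and actual outcomes, and the overall
#' observed-to-expected ratio, each with a 30-resample bootstrap
#' percentile interval, plus the 20-bin regional calibration table.
#'
#' @param predictions Output of [predict_rolling()].
#' @param n_boot Bootstrap resamples for the intervals.
#' @param seed Bootstrap seed.
#' @param top_fraction Flagging fraction for the threshold metrics.
#' @param n_bins Calibration bins.
#' @return List: `metrics` (landmark x metric rows with `value`, `lower`,
#'   `median`, `upper`, `n`, `prevalence`) and `calibration` (per
#'   landmark x bin).
#' @export
evaluate_predictions <- function(predictions, n_boot = 30L, seed = 1L,
                                 top_fraction = 0.40, n_bins = 20L) {
  thr_fn <- function(name) function(s, l)
    unname(suppressWarnings(threshold_metrics(s, l, top_fraction))[name])
  metric_fns <- list(
    auroc = auroc, auprc = auprc,
    sensitivity = thr_fn("sensitivity"),
    specificity = thr_fn("specificity"),
    ppv = thr_fn("ppv"), npv = thr_fn("npv"),
    pearson = pearson_pred_actual,
    oe_ratio = function(s, l) sum(l) / sum(s))
  mrows <- list()
  crows <- list()
  for (t in sort(unique(predictions$landmark))) {
    sub <- predictions[predictions$landmark == t, ]
    s <- sub$probability
    l <- sub$label
    for (mn in names(metric_fns)) {
      fn <- metric_fns[[mn]]
      val <- tryCatch(suppressWarnings(fn(s, l)),
                      error = function(e) NA_real_)
      ci <- if (is.na(val)) c(lower = NA_real_, median = NA_real_,
                              upper = NA_real_) else
        tryCatch(bootstrap_ci(fn, s, l, n_boot = n_boot, seed = seed),
                 error = function(e) c(lower = NA_real_,
                                       median = NA_real_,
                                       upper = NA_real_))
      mrows[[length(mrows) + 1L]] <- data.frame(
        landmark = t, metric = mn, value = val,
        lower = unname(ci["lower"]), median = unname(ci["median"]),
        upper = unname(ci["upper"]), n = length(l),
        prevalence = mean(l), stringsAsFactors = FALSE)
    }
    cb <- calibration_bins(s, l, n_bins = n_bins)
    cb <- cbind(landmark = t, cb)
    crows[[length(crows) + 1L]] <- cb
  }
  list(metrics = do.call(rbind, mrows),
       calibration = do.call(rbind, crows))
}

#' Case-mix table over landmark times
#'
#' Eligible count, event count and rate, mean age, and sex/race
#' proportions per landmark, optionally per split.
#'
#' @param cohort Cohort object from [apply_cohort_filters()].
#' @param horizon_T Number of landmarks.
#' @param label Optional split label column.
#' @return Data frame, one row per landmark.
#' @export
casemix_table <- function(cohort, horizon_T = 5L, label = NULL) {
  rows <- lapply(seq_len(horizon_T) - 1L, function(t) {
    ids <- .lb_eligible_ids(cohort, t)
    y <- .lb_labels(cohort, ids, t)
    d <- cohort$demographics[match(ids, cohort$demographics$patient_id), ,
                             drop = FALSE]
    data.frame(landmark = t, n_eligible = length(ids), n_events = sum(y),
               event_rate = if (length(y)) mean(y) else NA_real_,
               mean_age = if (nrow(d)) mean(d$age_at_onset + t) else
                 NA_real_,
               pct_male = if (nrow(d)) mean(d$sex == "male") else
                 NA_real_,
               pct_white = if (nrow(d)) mean(d$race == "white") else
                 NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(label)) out <- cbind(split = label, out)
  out
}

#' Configuration of an end-to-end experiment
#'
#' @param simulate A [scenario_config()] to generate the cohort, or
#'   `NULL` when reading from `file`.
#' @param file Path to an event-table CSV (used when `simulate` is
#'   `NULL`).
#' @param train_fraction Patient-level training fraction (default 0.80).
#' @param methods Subset of the four temporal methods to run.
#' @param horizon Number of yearly landmarks.
#' @param control A [gbm_control()].
#' @param tune_grid Optional tuning grid.
#' @param min_prevalence Rare-feature threshold.
#' @param n_boot Bootstrap resamples for evaluation.
#' @param seed Master seed (split, holdouts, bootstrap).
#' @param output_dir Directory for the report bundle (`NULL`: in-memory
#'   only).
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(simulate = NULL, file = NULL,
                              train_fraction = 0.8,
                              methods = c("landmark_boosting",
                                          "latest_value",
                                          "stack_temporal",
                                          "discrete_survival"),
                              horizon = 5L, control = gbm_control(),
                              tune_grid = NULL, min_prevalence = 0.01,
                              n_boot = 30L, seed = 1L,
                              output_dir = NULL) {
  if (is.null(simulate) && is.null(file))
    stop("either a simulation scenario or an input file is required")
  stopifnot(train_fraction > 0, train_fraction < 1, length(methods) >= 1L)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(simulate = simulate, file = file,
                 train_fraction = train_fraction, methods = methods,
                 horizon = as.integer(horizon), control = control,
                 tune_grid = tune_grid, min_prevalence = min_prevalence,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Run the full experimental pipeline
#'
#' Phenotype, featurise, train on the training split, and evaluate rolling
#' predictions on the held-out split, for each requested temporal method.
#' Reproduces the experimental design end to end: patient-level 80/20
#' split, per-landmark models, top-40%-threshold metrics with 30-sample
#' bootstrap intervals, 20-bin calibration, and case-mix tables per
#' landmark and split.  With `output_dir` set, writes a deterministic
#' report bundle (CSV tables plus a JSON manifest); identical
#' configuration and seeds give byte-identical outputs.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with the cohort, split, per-method fits,
#'   predictions, metrics, calibration, case-mix tables and manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  events <- if (!is.null(config$simulate)) {
    say("stage simulate: n_patients=", config$simulate$n_patients,
        " seed=", config$simulate$seed)
    generate_cohort(config$simulate)$events
  } else {
    say("stage load: ", config$file)
    read_event_table(config$file)
  }

  pheno <- apply_cohort_filters(events, config$horizon)
  say("stage phenotype: cohort=", nrow(pheno$cohort), " excluded=",
      paste(pheno$exclusions$n_excluded, collapse = "/"))
  if (nrow(pheno$cohort) == 0L) stop("stage phenotype: empty cohort")

  split <- split_cohort(pheno$cohort$patient_id, config$train_fraction,
                        config$seed)
  train_cohort <- .lb_subset_cohort(pheno, split$train)
  test_cohort <- .lb_subset_cohort(pheno, split$test)
  features <- filter_rare_features(events, config$min_prevalence,
                                   split$train)
  say("stage featurise: ", length(features), " features retained")

  fits <- list(); preds <- list(); metrics <- list(); calib <- list()
  lv_methods <- intersect(config$methods,
                          c("landmark_boosting", "latest_value"))
  ds_tr <- if (length(lv_methods))
    build_landmark_datasets(events, train_cohort, config$horizon,
                            features)
  ds_te <- if (length(lv_methods))
    build_landmark_datasets(events, test_cohort, config$horizon, features)
  for (method in config$methods) {
    shared <- method %in% lv_methods
    fit <- landmark_boost(events, cohort = train_cohort,
                          horizon = config$horizon, method = method,
                          control = config$control,
                          tune_grid = config$tune_grid,
                          features = features,
                          datasets = if (shared) ds_tr)
    p <- predict_rolling(fit$fit, events, test_cohort, config$horizon,
                         features, designs = if (shared) ds_te)
    ev <- evaluate_predictions(p, n_boot = config$n_boot,
                               seed = config$seed)
    fits[[method]] <- fit
    preds[[method]] <- p
    metrics[[method]] <- cbind(method = method, ev$metrics)
    calib[[method]] <- cbind(method = method, ev$calibration)
    say("stage train+evaluate: ", method, " done (",
        nrow(p), " predictions)")
  }
  metrics_all <- do.call(rbind, metrics)
  calib_all <- do.call(rbind, calib)
  casemix <- rbind(casemix_table(train_cohort, config$horizon, "train"),
                   casemix_table(test_cohort, config$horizon, "test"))

  manifest <- list(package_version =
                     as.character(utils::packageVersion("landboost")),
                   seed = config$seed,
                   train_fraction = config$train_fraction,
                   horizon = config$horizon, methods = config$methods,
                   n_features = length(features),
                   n_train = length(split$train),
                   n_test = length(split$test))

  bundle <- list(cohort = pheno, split = split, features = features,
                 fits = fits, predictions = preds,
                 metrics = metrics_all, calibration = calib_all,
                 casemix = casemix, manifest = manifest, log = log_lines)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name)
      utils::write.csv(df, file.path(config$output_dir, name),
                       row.names = FALSE)
    wr(pheno$cohort, "cohort.csv")
    wr(pheno$exclusions, "exclusions.csv")
    for (method in names(preds))
      wr(preds[[method]], paste0("predictions_", method, ".csv"))
    wr(metrics_all, "metrics.csv")
    wr(calib_all, "calibration.csv")
    wr(casemix, "casemix.csv")
    jsonlite::write_json(manifest,
                         file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  invisible(bundle)
}
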