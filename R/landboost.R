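#' Fit a dynamic landmark risk model on a clinical event table
#'
#' The main entry point of the package.  Given a long-format event table
#' (and optionally a pre-computed phenotyped cohort), it derives diabetes
#' onset, yearly kidney-outcome sequences and per-landmark eligibility,
#' builds the temporal design matrices, and fits the requested model:
#' `"landmark_boosting"` (boosted trees re-ensembled at each yearly
#' landmark with the previous landmark's predicted risk carried as a
#' baseline log-odds offset) or one of the comparator representations
#' (`"latest_value"`, `"stack_temporal"`, `"discrete_survival"`).
#'
#' @param events Event table (see [generate_cohort()] for the schema).
#' @param cohort Optional cohort object from [apply_cohort_filters()];
#'   computed from `events` when `NULL`.
#' @param horizon Number of yearly landmark times T.
#' @param method Temporal representation to fit.
#' @param control A [gbm_control()].
#' @param tune_grid Optional grid for per-landmark 10-fold CV tuning.
#' @param retune Re-tune at every landmark (otherwise reuse landmark 0's
#'   winner).
#' @param min_prevalence Rare-feature threshold: features observed in
#'   fewer than this fraction of the training patients are dropped.
#' @param features Optional explicit feature set (overrides
#'   `min_prevalence` filtering).
#' @param codes A [clinical_codes()] object for phenotyping.
#' @param cold_start Cold-start margin rule for landmark-boosting.
#' @param datasets Optional pre-built per-landmark training datasets in
#'   the representation `method` expects (a performance affordance when
#'   several methods share designs).
#' @return An object of class `"landboost"` with `print`, `summary`,
#'   `predict` and `plot` methods.
#' @examples
#' cfg <- scenario_config(n_patients = 120, n_landmarks = 2, seed = 42)
#' sim <- generate_cohort(cfg)
#' fit <- landmark_boost(sim$events, horizon = 2,
#'                       control = gbm_control(max_trees = 20))
#' fit
#' @export
landmark_boost <- function(events, cohort = NULL, horizon = 5L,
                           method = c("landmark_boosting", "latest_value",
                                      "stack_temporal",
                                      "discrete_survival"),
                           control = gbm_control(), tune_grid = NULL,
                           retune = TRUE, min_prevalence = 0.01,
                           features = NULL, codes = clinical_codes(),
                           cold_start = c("prevalence", "zero"),
                           datasets = NULL) {
  method <- match.arg(method)
  cold_start <- match.arg(cold_start)
  if (is.null(cohort))
    cohort <- apply_cohort_filters(events, horizon, codes)
  if (is.null(features))
    features <- filter_rare_features(events, min_prevalence,
                                     cohort$cohort$patient_id)
  fit <- if (method == "landmark_boosting") {
    if (is.null(datasets))
      datasets <- build_landmark_datasets(events, cohort, horizon,
                                          features)
    fit_landmark_boosting(datasets, control = control,
                          tune_grid = tune_grid, cold_start = cold_start,
                          retune = retune)
  } else {
    fit_comparator(method, events, cohort, horizon, features,
                   control = control, tune_grid = tune_grid,
                   retune = retune,
                   datasets = if (method != "discrete_survival")
                     datasets)
  }
  structure(list(method = method, fit = fit, features = features,
                 horizon = as.integer(horizon), cohort = cohort,
                 codes = codes, control = control,
                 call = match.call()),
            class = "landboost")
}

#' @export
print.landboost <- function(x, ...) {
  cat("Dynamic landmark risk model (", x$method, ")\n", sep = "")
  cat("  landmarks: 0 ..", x$horizon - 1L,
      "| training patients:", nrow(x$cohort$cohort),
      "| features:", length(x$features), "\n")
  if (inherits(x$fit, "landmark_ensemble")) {
    nt <- vapply(x$fit$models, function(m)
      if (is.null(m)) 0L else m$n_trees, 0L)
    cat("  trees per landmark:", paste(nt, collapse = ", "), "\n")
  } else {
    nt <- vapply(x$fit$models, function(m) m$n_trees, 0L)
    cat("  trees:", paste(nt, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.landboost <- function(object, ...) {
  coh <- object$cohort
  T_ <- object$horizon
  rows <- lapply(seq_len(T_) - 1L, function(t) {
    ids <- .lb_eligible_ids(coh, t)
    y <- .lb_labels(coh, ids, t)
    data.frame(landmark = t, n_eligible = length(ids),
               n_events = sum(y), prevalence = mean(y))
  })
  out <- do.call(rbind, rows)
  cat("Training case mix over landmark times\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Predict dynamic risks for new patients
#'
#' Rolling per-landmark predictions (see [predict_rolling()]) for a new
#' event table; the cohort is phenotyped with the codes stored in the
#' fitted model unless supplied.
#'
#' @param object A `"landboost"` fit.
#' @param events Event table of the patients to score.
#' @param cohort Optional pre-computed cohort object.
#' @param ... Unused.
#' @return Data frame: `patient_id`, `landmark`, `probability`,
#'   `percentile`, `label`.
#' @export
predict.landboost <- function(object, events, cohort = NULL, ...) {
  if (is.null(cohort))
    cohort <- apply_cohort_filters(events, object$horizon, object$codes)
  predict_rolling(object$fit, events, cohort, object$horizon,
                  object$features)
}

#' Plot risk-percentile trajectories
#'
#' Draws each patient's predicted-risk percentile against landmark time;
#' patients whose final observed status is an event are drawn in red,
#' event-free patients in green.
#'
#' @param x A `"landboost"` fit.
#' @param predictions Rolling-prediction table from [predict.landboost()].
#' @param complete_only Restrict to patients eligible at every landmark.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the list of trajectories.
#' @export
plot.landboost <- function(x, predictions, complete_only = TRUE, ...) {
  tr <- risk_trajectories(predictions, complete_only = complete_only)
  T_ <- x$horizon
  graphics::plot(NULL, xlim = c(0, T_ - 1), ylim = c(0, 100),
                 xlab = "Landmark time (years since DM onset)",
                 ylab = "Risk percentile", ...)
  for (d in tr) {
    is_case <- any(d$label == 1)
    graphics::lines(d$landmark, d$percentile,
                    col = if (is_case) "#c0392baa" else "#27ae6055")
  }
  invisible(tr)
}
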