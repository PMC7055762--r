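#' Build the per-landmark training datasets
#'
#' Latest-value designs (the predictor set used by the landmark-boosting
#' scheme: predictors updated as of each landmark) for `t = 0..T-1`,
#' restricted to the patients eligible at each landmark.
#'
#' @param events Event table.
#' @param cohort Cohort object from [apply_cohort_filters()].
#' @param horizon_T Number of yearly landmarks.
#' @param features Retained feature ids.
#' @param design `"latest_value"` or `"stack_temporal"`.
#' @return List of `"landmark_dataset"` objects.
#' @export
build_landmark_datasets <- function(events, cohort, horizon_T = 5L,
                                    features = NULL,
                                    design = c("latest_value",
                                               "stack_temporal")) {
  design <- match.arg(design)
  fn <- if (design == "latest_value") latest_value_design else
    stack_temporal_design
  ctx <- .lb_design_context(events, cohort)
  lapply(seq_len(horizon_T) - 1L, function(t)
    fn(events, cohort, t, features, .ctx = ctx))
}

#' Fit the landmark-boosting sequence of ensembles
#'
#' Sequential scheme for dynamic 1-year risk prediction: at landmark 0 an
#' ordinary boosted ensemble is fitted; at every later landmark `t` the
#' predicted probability of the previous landmark's model, on its own
#' predictors, is converted to log-odds and carried as a per-patient
#' baseline margin, and new trees are ensembled on top using the
#' predictors updated at `t`.  Patients eligible at `t` without a
#' prediction at `t - 1` (e.g. status `NA` at `t - 1`) receive a
#' cold-start margin, by default the log-odds of the training prevalence
#' at `t`.  Each landmark's fit is capped at `control$max_trees` trees
#' (default 1000) with early stopping on a stratified 20% holdout, and
#' hyperparameters can be re-tuned by 10-fold cross-validation at each
#' landmark.
#'
#' @param datasets List of `"landmark_dataset"` objects ordered by `t`
#'   (see [build_landmark_datasets()]).
#' @param control A [gbm_control()]; `control$seed + t` seeds the holdout
#'   at landmark `t`.
#' @param tune_grid Optional hyperparameter grid (see
#'   [default_tuning_grid()]); when supplied, tuning runs at each landmark
#'   unless `retune = FALSE`, in which case only landmark 0 is tuned and
#'   the winner is reused.
#' @param cold_start `"prevalence"` (log-odds of training prevalence at
#'   `t`) or `"zero"`.
#' @param retune Re-tune at every landmark (default `TRUE`).
#' @param cross_fit_folds Number of folds used to cross-fit the carried
#'   baselines of the \emph{training} patients.  A model's in-sample
#'   predictions partly memorise its own training labels -- and every
#'   patient eligible at `t` carried label 0 at `t - 1` -- so carrying
#'   them directly would hand landmark `t` systematically deflated,
#'   optimistic margins while new patients are scored with honest
#'   out-of-sample ones.  With cross-fitting (default 3 folds), each
#'   training patient's carried risk comes from a model that never saw
#'   that patient, matching the distribution of the margins used at
#'   prediction time.  Set to 1 to carry in-sample predictions.
#' @param carry `"latest"` (default): a patient whose status was missing
#'   at `t - 1` carries their most recent earlier prediction instead of
#'   falling back to the cold-start margin; `"previous_only"` carries
#'   strictly from `t - 1` and cold-starts everyone else.
#' @return Object of class `"landmark_ensemble"`: per-landmark `"lb_gbm"`
#'   models, tuned controls, cold-start margins, and the (cross-fitted)
#'   training predictions used as carried baselines.
#' @export
fit_landmark_boosting <- function(datasets, control = gbm_control(),
                                  tune_grid = NULL,
                                  cold_start = c("prevalence", "zero"),
                                  retune = TRUE, cross_fit_folds = 3L,
                                  carry = c("latest", "previous_only")) {
  cold_start <- match.arg(cold_start)
  carry <- match.arg(carry)
  T_ <- length(datasets)
  stopifnot(T_ >= 1L, cross_fit_folds >= 1L)
  models <- vector("list", T_)
  controls <- vector("list", T_)
  cold <- numeric(T_)
  preds <- vector("list", T_)   # named prob vectors per landmark

  prev_pred <- NULL   # carried risk per patient (latest available)
  tuned <- NULL
  for (t0 in seq_len(T_)) {
    t <- t0 - 1L
    d <- datasets[[t0]]
    if (is.null(d) || d$n == 0L) {
      warning("empty dataset at landmark ", t, "; carrying model forward")
      models[[t0]] <- models[[max(t0 - 1L, 1L)]]
      controls[[t0]] <- controls[[max(t0 - 1L, 1L)]]
      cold[t0] <- if (t0 > 1L) cold[t0 - 1L] else 0
      preds[[t0]] <- stats::setNames(numeric(0), character(0))
      next
    }
    prevalence <- .lb_clip(mean(d$y))
    cold[t0] <- if (cold_start == "prevalence") stats::qlogis(prevalence)
    else 0
    base_margin <- if (t == 0L) rep(0, d$n) else {
      carried <- prev_pred[d$patient_id]
      m <- stats::qlogis(.lb_clip(unname(carried)))
      m[is.na(carried)] <- cold[t0]
      m
    }
    ctl <- control
    if (!is.null(tune_grid) && (retune || is.null(tuned))) {
      tuned <- tune_by_cv(d$X, d$y, base_margin, tune_grid,
                          control = control, folds = control$cv_folds,
                          seed = control$seed + t)$best
    }
    if (!is.null(tuned)) ctl <- tuned
    ctl$seed <- control$seed + t
    holdout <- .lb_stratified_holdout(d$y, ctl$holdout_fraction, ctl$seed)
    models[[t0]] <- fit_gbm(d$X, d$y, base_margin, control = ctl,
                            holdout = if (length(holdout)) holdout else
                              NULL)
    controls[[t0]] <- ctl
    p_main <- predict(models[[t0]], d$X, base_margin = base_margin)
    p <- if (t0 < T_ && cross_fit_folds >= 2L) {
      p_cf <- .lb_cross_fit_predictions(d, base_margin, ctl,
                                        cross_fit_folds,
                                        models[[t0]]$n_trees)
      # anchor the cross-fitted carry to the deployed model's level: the
      # reduced-capacity fold models under-correct each landmark's
      # prevalence shift, and without this intercept alignment the small
      # bias compounds along the chain into systematic underprediction
      .lb_match_mean(p_cf, mean(p_main))
    } else {
      p_main
    }
    preds[[t0]] <- stats::setNames(p, d$patient_id)
    if (carry == "latest") {
      if (is.null(prev_pred)) prev_pred <- preds[[t0]] else
        prev_pred[d$patient_id] <- p
    } else {
      prev_pred <- preds[[t0]]
    }
  }
  structure(list(models = models, controls = controls,
                 cold_start_margin = cold, train_predictions = preds,
                 cold_start = cold_start, carry = carry,
                 feature_names = lapply(datasets, function(d)
                   colnames(d$X))),
            class = "landmark_ensemble")
}

# shift probabilities by a constant on the logit scale so their mean
# matches `target`; leaves the ranking untouched
.lb_match_mean <- function(p, target) {
  lo <- stats::qlogis(.lb_clip(p))
  f <- function(delta) mean(stats::plogis(lo + delta)) - target
  if (f(-4) > 0 || f(4) < 0) return(p)   # degenerate; leave unshifted
  delta <- stats::uniroot(f, c(-4, 4), tol = 1e-10)$root
  stats::plogis(lo + delta)
}

# out-of-fold predictions of a landmark model for its own training rows:
# each fold is scored by a model fitted on the remaining folds (with the
# same carried margins), so the carried baselines of training patients are
# not contaminated by their own labels.  Fold models run to exactly the
# deployed model's tree count (no separate early stopping), matching its
# capacity.
.lb_cross_fit_predictions <- function(d, base_margin, ctl, folds,
                                      n_trees) {
  fold <- .lb_stratified_folds(d$y, folds, ctl$seed + 7919L)
  ctl$max_trees <- max(n_trees, 1L)
  p <- rep(NA_real_, d$n)
  for (k in seq_len(folds)) {
    te <- which(fold == k)
    tr <- which(fold != k)
    if (length(unique(d$y[tr])) < 2L) {
      p[te] <- mean(d$y[tr])   # degenerate fold: carry the prevalence
      next
    }
    fit <- fit_gbm(d$X[tr, , drop = FALSE], d$y[tr], base_margin[tr],
                   control = ctl)
    p[te] <- predict(fit, d$X[te, , drop = FALSE],
                     base_margin = base_margin[te])
  }
  p
}

#' @export
print.landmark_ensemble <- function(x, ...) {
  cat("Landmark-boosting ensemble over", length(x$models),
      "landmark times\n")
  for (t0 in seq_along(x$models)) {
    m <- x$models[[t0]]
    cat("  t =", t0 - 1L, ":", if (is.null(m)) "none" else
      paste(m$n_trees, "trees"), "\n")
  }
  invisible(x)
}

#' Fit a comparator temporal model
#'
#' The three reference representations: `latest_value` and
#' `stack_temporal` fit an independent boosted ensemble per landmark on
#' their respective designs; `discrete_survival` fits one pooled ensemble
#' on the stacked pseudo-observations and applies it at every landmark.
#'
#' @param method One of `"latest_value"`, `"stack_temporal"`,
#'   `"discrete_survival"`.
#' @param events,cohort,horizon_T,features As in
#'   [build_landmark_datasets()].
#' @param control,tune_grid,retune As in [fit_landmark_boosting()].
#' @param datasets Optional pre-built per-landmark datasets matching
#'   `method` (avoids recomputing designs shared with another fit);
#'   ignored for `discrete_survival`.
#' @return Object of class `"comparator_models"`.
#' @export
fit_comparator <- function(method, events, cohort, horizon_T = 5L,
                           features = NULL, control = gbm_control(),
                           tune_grid = NULL, retune = TRUE,
                           datasets = NULL) {
  method <- match.arg(method, c("latest_value", "stack_temporal",
                                "discrete_survival"))
  if (method == "discrete_survival") {
    d <- discrete_survival_design(events, cohort, horizon_T, features)
    ctl <- control
    if (!is.null(tune_grid))
      ctl <- tune_by_cv(d$X, d$y, 0, tune_grid, control = control,
                        folds = control$cv_folds, seed = control$seed)$best
    holdout <- .lb_stratified_holdout(d$y, ctl$holdout_fraction, ctl$seed)
    fit <- fit_gbm(d$X, d$y, 0, control = ctl,
                   holdout = if (length(holdout)) holdout else NULL)
    return(structure(list(method = method, models = list(fit),
                          controls = list(ctl)),
                     class = "comparator_models"))
  }
  if (is.null(datasets))
    datasets <- build_landmark_datasets(events, cohort, horizon_T,
                                        features, design = method)
  models <- vector("list", length(datasets))
  controls <- vector("list", length(datasets))
  tuned <- NULL
  for (t0 in seq_along(datasets)) {
    d <- datasets[[t0]]
    ctl <- control
    if (!is.null(tune_grid) && (retune || is.null(tuned)))
      tuned <- tune_by_cv(d$X, d$y, 0, tune_grid, control = control,
                          folds = control$cv_folds,
                          seed = control$seed + d$t)$best
    if (!is.null(tuned)) ctl <- tuned
    ctl$seed <- control$seed + d$t
    holdout <- .lb_stratified_holdout(d$y, ctl$holdout_fraction, ctl$seed)
    models[[t0]] <- fit_gbm(d$X, d$y, 0, control = ctl,
                            holdout = if (length(holdout)) holdout else
                              NULL)
    controls[[t0]] <- ctl
  }
  structure(list(method = method, models = models, controls = controls),
            class = "comparator_models")
}

# risk percentiles with average-rank ties, scaled to [0, 100]
.lb_percentile <- function(p) {
  n <- length(p)
  if (n == 0L) return(numeric(0))
  100 * (rank(p, ties.method = "average") - 0.5) / n
}

#' Rolling per-landmark predictions on a phenotyped cohort
#'
#' Applies a fitted landmark-boosting or comparator model to a (test)
#' cohort, stepping through the landmark times: at each `t`, predictions
#' are made for exactly the patients eligible at `t`, and for
#' landmark-boosting the previous landmark's prediction is carried as the
#' baseline margin (cold-start margin when absent).  Risk percentiles are
#' computed within each landmark's concurrent population (average-rank
#' ties, scaled to \[0, 100\]).
#'
#' @param fit A `"landmark_ensemble"` or `"comparator_models"` object.
#' @param events Event table covering the cohort.
#' @param cohort Cohort object from [apply_cohort_filters()].
#' @param horizon_T Number of landmarks to predict.
#' @param features The retained feature set used at training time.
#' @param designs Optional list of pre-built per-landmark test datasets
#'   in the representation the fit expects (latest-value for
#'   landmark-boosting and the latest-value comparator, stacked for
#'   stack-temporal); built on the fly when `NULL`.
#' @return Data frame: `patient_id`, `landmark`, `probability`,
#'   `percentile`, `label`.
#' @export
predict_rolling <- function(fit, events, cohort, horizon_T = 5L,
                            features = NULL, designs = NULL) {
  out <- vector("list", horizon_T)
  prev_pred <- NULL
  ctx <- if (is.null(designs)) .lb_design_context(events, cohort)
  for (t0 in seq_len(horizon_T)) {
    t <- t0 - 1L
    if (inherits(fit, "landmark_ensemble")) {
      d <- if (!is.null(designs)) designs[[t0]] else
        latest_value_design(events, cohort, t, features, .ctx = ctx)
      model <- fit$models[[t0]]
      if (d$n == 0L) next
      if (t == 0L) bm <- rep(0, d$n) else {
        carried <- if (is.null(prev_pred)) rep(NA_real_, d$n) else
          prev_pred[d$patient_id]
        bm <- stats::qlogis(.lb_clip(unname(carried)))
        bm[is.na(carried)] <- fit$cold_start_margin[t0]
      }
      p <- predict(model, d$X, base_margin = bm)
      if (identical(fit$carry, "previous_only") || is.null(prev_pred)) {
        prev_pred <- stats::setNames(p, d$patient_id)
      } else {
        prev_pred[d$patient_id] <- p
      }
    } else if (fit$method == "discrete_survival") {
      d <- if (!is.null(designs)) designs[[t0]] else
        discrete_survival_rows(events, cohort, t, features, .ctx = ctx)
      if (d$n == 0L) next
      p <- predict(fit$models[[1L]], d$X)
    } else {
      d <- if (!is.null(designs)) designs[[t0]] else
        if (fit$method == "latest_value")
          latest_value_design(events, cohort, t, features, .ctx = ctx)
        else stack_temporal_design(events, cohort, t, features,
                                   .ctx = ctx)
      if (d$n == 0L) next
      p <- predict(fit$models[[t0]], d$X)
    }
    out[[t0]] <- data.frame(patient_id = d$patient_id, landmark = t,
                            probability = p,
                            percentile = .lb_percentile(p),
                            label = d$y, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-patient risk trajectories
#'
#' Reshapes a rolling-prediction table into one trajectory per patient:
#' the sequence of risk percentiles over the landmarks at which the
#' patient was eligible.  The subset of patients eligible at every
#' landmark (outcome sequences all-0 or 0...01) is the natural set for
#' trajectory plots.
#'
#' @param predictions Output of [predict_rolling()].
#' @param complete_only Keep only patients eligible at every landmark.
#' @return List of data frames, one per patient, each with `landmark`,
#'   `probability`, `percentile`, `label`.
#' @export
risk_trajectories <- function(predictions, complete_only = FALSE) {
  T_ <- length(unique(predictions$landmark))
  tr <- split(predictions[, c("landmark", "probability", "percentile",
                              "label")], predictions$patient_id)
  if (complete_only) tr <- tr[vapply(tr, nrow, 0L) == T_]
  lapply(tr, function(d) d[order(d$landmark), , drop = FALSE])
}
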