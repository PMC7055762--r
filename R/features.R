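#' Feature dictionary of an event table
#'
#' Enumerates the distinct clinical features of an event table.  Feature
#' identity is the concatenation `domain:feature_code[:modifier]`, so the
#' same code recorded under different modifiers (e.g. billing vs problem
#' list) yields distinct features.  A feature is numeric when it ever
#' carries a value; otherwise it is a presence-only (binary) indicator.
#' Demographics events are handled separately and are not part of the
#' dictionary.
#'
#' @param events Event table.
#' @return Data frame: `feature_id`, `domain`, `feature_code`, `modifier`,
#'   `numeric`.
#' @export
feature_dictionary <- function(events) {
  ev <- events[events$domain != "demographics", , drop = FALSE]
  fid <- .lb_feature_id(ev)
  first <- !duplicated(fid)
  has_val <- tapply(!is.na(ev$value), fid, any)
  out <- data.frame(feature_id = fid[first], domain = ev$domain[first],
                    feature_code = ev$feature_code[first],
                    modifier = ev$modifier[first],
                    stringsAsFactors = FALSE)
  out$numeric <- as.logical(has_val[out$feature_id])
  out[order(out$feature_id), , drop = FALSE]
}

.lb_feature_id <- function(ev) {
  ifelse(is.na(ev$modifier) | ev$modifier == "",
         paste(ev$domain, ev$feature_code, sep = ":"),
         paste(ev$domain, ev$feature_code, ev$modifier, sep = ":"))
}

#' Drop rarely observed features
#'
#' Retains the features observed (ever) in at least
#' `min_prevalence * n_patients` of the reference patients.  With the
#' default 1% threshold this reproduces the sparsity-reduction step that
#' removes features recorded for fewer than 1% of patients.  Prevalence
#' should be computed on the training split only; pass the training
#' patient ids as `patient_ids`.
#'
#' @param events Event table.
#' @param min_prevalence Fraction in \[0, 1\].
#' @param patient_ids Patients over which prevalence is computed (default:
#'   all patients in `events`).
#' @return Character vector of retained `feature_id`s.
#' @export
filter_rare_features <- function(events, min_prevalence = 0.01,
                                 patient_ids = NULL) {
  stopifnot(min_prevalence >= 0, min_prevalence <= 1)
  if (is.null(patient_ids)) patient_ids <- unique(events$patient_id)
  ev <- events[events$patient_id %in% patient_ids &
                 events$domain != "demographics", , drop = FALSE]
  fid <- .lb_feature_id(ev)
  key <- paste(fid, ev$patient_id)
  first <- !duplicated(key)
  n_pat <- tapply(rep(1L, sum(first)), fid[first], sum)
  prev <- as.numeric(n_pat) / length(patient_ids)
  sort(names(n_pat)[prev >= min_prevalence])
}

# relative-day event view restricted to a cohort; adds rel_day and
# feature_id columns
.lb_rel_events <- function(events, cohort) {
  onset <- stats::setNames(cohort$cohort$dm_onset_day,
                           cohort$cohort$patient_id)
  ev <- events[events$patient_id %in% names(onset) &
                 events$domain != "demographics", , drop = FALSE]
  ev$rel_day <- ev$day - onset[ev$patient_id]
  ev$feature_id <- .lb_feature_id(ev)
  ev
}

# shared per-cohort design context: the relative-day event view, the
# numeric-feature dictionary, and the first observation day of every
# (patient, feature) pair (for the history counts).  Building designs for
# several landmarks re-uses one context instead of re-deriving these from
# the full event table each time.
.lb_design_context <- function(events, cohort) {
  ev <- .lb_rel_events(events, cohort)
  dict <- feature_dictionary(
    events[events$patient_id %in% cohort$cohort$patient_id, ,
           drop = FALSE])
  ord <- order(ev$patient_id, ev$feature_id, ev$rel_day,
               method = "radix")
  sorted <- ev[ord, c("patient_id", "feature_id", "rel_day")]
  first <- !duplicated(paste(sorted$patient_id, sorted$feature_id,
                             sep = "\r"))
  list(rel = ev, numeric_ids = dict$feature_id[dict$numeric],
       first_obs = sorted[first, , drop = FALSE])
}

# history counts from the precomputed first-observation table
.lb_history_counts <- function(first_obs, patient_ids, t) {
  fo <- first_obs[first_obs$patient_id %in% patient_ids, , drop = FALSE]
  cnt_before <- function(cut) {
    sub <- fo[fo$rel_day < cut, , drop = FALSE]
    out <- stats::setNames(rep(0, length(patient_ids)), patient_ids)
    if (nrow(sub)) {
      v <- rowsum(rep(1, nrow(sub)), sub$patient_id)
      out[rownames(v)] <- v[, 1L]
    }
    out
  }
  cum <- cnt_before(365 * t)
  prev <- if (t >= 1L) cnt_before(365 * (t - 1)) else 0 * cum
  cbind(hist_cum = unname(cum), hist_inc = unname(cum - prev))
}

# aggregate one event subset into per-(patient, feature) cells:
# numeric -> mean of the values on the most recent day; binary -> presence
.lb_aggregate_cells <- function(ev, numeric_ids) {
  if (nrow(ev) == 0L)
    return(data.frame(patient_id = character(0), feature_id = character(0),
                      value = numeric(0)))
  is_num <- ev$feature_id %in% numeric_ids
  out <- list()
  sub <- ev[is_num & !is.na(ev$value), , drop = FALSE]
  if (nrow(sub)) {
    ord <- order(sub$patient_id, sub$feature_id, sub$rel_day,
                 method = "radix")
    sub <- sub[ord, , drop = FALSE]
    key <- paste(sub$patient_id, sub$feature_id, sep = "\r")
    grp <- cumsum(!duplicated(key))
    last_row <- !duplicated(key, fromLast = TRUE)
    at_last <- sub$rel_day == sub$rel_day[last_row][grp]
    sums <- rowsum(sub$value[at_last], grp[at_last], reorder = FALSE)
    cnts <- rowsum(rep(1, sum(at_last)), grp[at_last], reorder = FALSE)
    out$num <- data.frame(patient_id = sub$patient_id[last_row],
                          feature_id = sub$feature_id[last_row],
                          value = as.numeric(sums / cnts),
                          stringsAsFactors = FALSE)
  }
  if (any(!is_num)) {
    bin <- ev[!is_num, , drop = FALSE]
    first <- !duplicated(paste(bin$patient_id, bin$feature_id,
                               sep = "\r"))
    out$bin <- data.frame(patient_id = bin$patient_id[first],
                          feature_id = bin$feature_id[first],
                          value = 1, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# demographics columns at landmark t for the given patients
.lb_demo_matrix <- function(cohort, patient_ids, t) {
  d <- cohort$demographics
  idx <- match(patient_ids, d$patient_id)
  cbind(age_at_landmark = d$age_at_onset[idx] + t,
        sex_male = as.numeric(d$sex[idx] == "male"),
        race_white = as.numeric(d$race[idx] == "white"),
        race_black = as.numeric(d$race[idx] == "black"))
}

#' Engineered history-count features
#'
#' Per patient: the cumulative number of distinct clinical features
#' observed strictly before landmark `t`, and the increment relative to
#' landmark `t - 1` (at `t = 0` the increment equals the cumulative
#' count).
#'
#' @param events Event table.
#' @param cohort Cohort object from [apply_cohort_filters()].
#' @param t Zero-based landmark index.
#' @param patient_ids Patients to report (default: whole cohort).
#' @return Matrix with columns `hist_cum`, `hist_inc`.
#' @export
history_count_features <- function(events, cohort, t, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- cohort$cohort$patient_id
  ctx <- .lb_design_context(events, cohort)
  .lb_history_counts(ctx$first_obs, patient_ids, t)
}

# assemble a design matrix from aggregated cells
.lb_fill_matrix <- function(cells, patient_ids, feature_ids, numeric_ids) {
  X <- matrix(0, nrow = length(patient_ids), ncol = length(feature_ids),
              dimnames = list(NULL, feature_ids))
  if (length(feature_ids)) {
    num_cols <- feature_ids %in% numeric_ids
    X[, num_cols] <- NA_real_
    cells <- cells[cells$feature_id %in% feature_ids &
                     cells$patient_id %in% patient_ids, , drop = FALSE]
    if (nrow(cells))
      X[cbind(match(cells$patient_id, patient_ids),
              match(cells$feature_id, feature_ids))] <- cells$value
  }
  X
}

.lb_eligible_ids <- function(cohort, t) {
  el <- vapply(cohort$sequences, landmark_eligibility, logical(1), t = t)
  intersect(cohort$cohort$patient_id, names(el)[el])
}

.lb_labels <- function(cohort, patient_ids, t) {
  vapply(cohort$sequences[patient_ids],
         function(s) as.numeric(s[t + 1L]), numeric(1))
}

# construct a classed landmark dataset
.lb_dataset <- function(t, X, y, patient_ids, col_type) {
  structure(list(t = t, X = X, y = y, patient_id = patient_ids,
                 n = nrow(X), col_type = col_type),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset t =", x$t, ":", x$n, "patients x", ncol(x$X),
      "features;", sum(x$y), "events\n")
  invisible(x)
}

# column types (numeric/binary) for a design; demographics/history/window
# columns are numeric
.lb_col_types <- function(colnames_, base_numeric_ids) {
  base <- sub("@w[0-9]+$", "", colnames_)
  ifelse(colnames_ %in% c("age_at_landmark", "sex_male", "race_white",
                          "race_black", "hist_cum", "hist_inc",
                          "window_index") |
           base %in% base_numeric_ids, "numeric", "binary")
}

#' Latest-value design at a landmark
#'
#' One row per patient eligible at landmark `t` (outcome year
#' `[365 t, 365 (t+1))` from onset).  Each numeric cell holds the most
#' recent observed value strictly before day `365 t`, averaging same-day
#' duplicates; each binary cell holds 1 when the feature was ever observed
#' before the landmark.  No timestamp information is retained.
#' Demographics (age at landmark, sex, race indicators) and the engineered
#' history counts are appended.
#'
#' @param events Event table.
#' @param cohort Cohort object from [apply_cohort_filters()].
#' @param t Zero-based landmark index.
#' @param features Retained `feature_id`s (e.g. from
#'   [filter_rare_features()]); default: all features of the cohort's
#'   events.
#' @param patient_ids Override of the row set (default: the patients
#'   eligible at `t`); labels are `NA` for rows without a status at `t`.
#' @param .ctx Precomputed per-cohort design context (internal; lets
#'   multi-landmark builders share one pass over the event table).
#' @return A `"landmark_dataset"`: fields `t`, `X`, `y`, `patient_id`,
#'   `n`, `col_type`.
#' @export
latest_value_design <- function(events, cohort, t, features = NULL,
                                patient_ids = NULL, .ctx = NULL) {
  if (is.null(.ctx)) .ctx <- .lb_design_context(events, cohort)
  ev <- .ctx$rel
  if (is.null(features)) features <- sort(unique(ev$feature_id))
  numeric_ids <- .ctx$numeric_ids
  if (is.null(patient_ids)) patient_ids <- .lb_eligible_ids(cohort, t)
  ev <- ev[ev$patient_id %in% patient_ids & ev$rel_day < 365 * t, ,
           drop = FALSE]
  cells <- .lb_aggregate_cells(ev, numeric_ids)
  X <- .lb_fill_matrix(cells, patient_ids, features, numeric_ids)
  X <- cbind(X, .lb_demo_matrix(cohort, patient_ids, t),
             .lb_history_counts(.ctx$first_obs, patient_ids, t))
  y <- .lb_labels(cohort, patient_ids, t)
  .lb_dataset(t, X, y, patient_ids, .lb_col_types(colnames(X), numeric_ids))
}

#' Stacked-window design at a landmark
#'
#' Distinguishes when a feature was observed: at landmark `t` the history
#' splits into `t + 1` non-overlapping windows (window 0 is the pre-onset
#' history, window `w >= 1` covers days `[365 (w-1), 365 w)`), and every
#' base feature contributes one column per window holding that window's
#' aggregate (last value for numeric features, presence for binary).  The
#' base-feature column count therefore grows linearly, `p = features x
#' (t + 1)`.  Demographics and history counts are appended once.
#'
#' @inheritParams latest_value_design
#' @return A `"landmark_dataset"` with columns named `<feature_id>@w<w>`.
#' @export
stack_temporal_design <- function(events, cohort, t, features = NULL,
                                  patient_ids = NULL, .ctx = NULL) {
  if (is.null(.ctx)) .ctx <- .lb_design_context(events, cohort)
  ev <- .ctx$rel
  if (is.null(features)) features <- sort(unique(ev$feature_id))
  numeric_ids <- .ctx$numeric_ids
  if (is.null(patient_ids)) patient_ids <- .lb_eligible_ids(cohort, t)
  ev <- ev[ev$patient_id %in% patient_ids, , drop = FALSE]
  mats <- vector("list", t + 1L)
  for (w in 0:t) {
    lo <- if (w == 0L) -Inf else 365 * (w - 1)
    hi <- if (w == 0L) 0 else 365 * w
    sub <- ev[ev$rel_day >= lo & ev$rel_day < hi, , drop = FALSE]
    cells <- .lb_aggregate_cells(sub, numeric_ids)
    Xw <- .lb_fill_matrix(cells, patient_ids, features, numeric_ids)
    colnames(Xw) <- paste0(features, "@w", w)
    mats[[w + 1L]] <- Xw
  }
  X <- do.call(cbind, mats)
  X <- cbind(X, .lb_demo_matrix(cohort, patient_ids, t),
             .lb_history_counts(.ctx$first_obs, patient_ids, t))
  y <- .lb_labels(cohort, patient_ids, t)
  .lb_dataset(t, X, y, patient_ids, .lb_col_types(colnames(X), numeric_ids))
}

#' Pooled discrete-time survival design
#'
#' The discrete-survival representation stacks one pseudo-observation per
#' patient per eligible yearly window: the label is the status in window
#' `t` and the predictors are the aggregates of the window immediately
#' preceding landmark `t` (the pre-onset history for `t = 0`), plus a
#' `window_index` column equal to `t`.  Rows from the same patient are
#' treated as independent examples, which lets a single binary classifier
#' serve all windows.
#'
#' @inheritParams latest_value_design
#' @param horizon_T Number of yearly windows.
#' @return A `"landmark_dataset"` with `t = NA`; extra field `landmark`
#'   gives each row's window index.
#' @export
discrete_survival_design <- function(events, cohort, horizon_T = 5L,
                                     features = NULL) {
  ctx <- .lb_design_context(events, cohort)
  parts <- lapply(seq_len(horizon_T) - 1L, function(t)
    discrete_survival_rows(events, cohort, t, features, .ctx = ctx))
  X <- do.call(rbind, lapply(parts, function(p) p$X))
  y <- unlist(lapply(parts, function(p) p$y), use.names = FALSE)
  pid <- unlist(lapply(parts, function(p) p$patient_id),
                use.names = FALSE)
  lm <- unlist(lapply(parts, function(p) rep(p$t, p$n)), use.names = FALSE)
  d <- .lb_dataset(NA_integer_, X, y, pid, parts[[1L]]$col_type)
  d$landmark <- lm
  d
}

#' @rdname discrete_survival_design
#' @param t Zero-based landmark index for a single window's rows.
#' @export
discrete_survival_rows <- function(events, cohort, t, features = NULL,
                                   patient_ids = NULL, .ctx = NULL) {
  if (is.null(.ctx)) .ctx <- .lb_design_context(events, cohort)
  ev <- .ctx$rel
  if (is.null(features)) features <- sort(unique(ev$feature_id))
  numeric_ids <- .ctx$numeric_ids
  if (is.null(patient_ids)) patient_ids <- .lb_eligible_ids(cohort, t)
  lo <- if (t == 0L) -Inf else 365 * (t - 1)
  hi <- 365 * t
  ev <- ev[ev$patient_id %in% patient_ids & ev$rel_day >= lo &
             ev$rel_day < hi, , drop = FALSE]
  cells <- .lb_aggregate_cells(ev, numeric_ids)
  X <- .lb_fill_matrix(cells, patient_ids, features, numeric_ids)
  X <- cbind(X, window_index = rep(t, length(patient_ids)),
             .lb_demo_matrix(cohort, patient_ids, t),
             .lb_history_counts(.ctx$first_obs, patient_ids, t))
  y <- .lb_labels(cohort, patient_ids, t)
  .lb_dataset(t, X, y, patient_ids, .lb_col_types(colnames(X), numeric_ids))
}

#' Serialise / restore a landmark dataset
#'
#' Sparse triplet serialisation: `<prefix>_cells.csv` holds (row, column,
#' value) for every stored cell (numeric values at full precision, so the
#' round-trip is exact), `<prefix>_columns.csv` the column dictionary with
#' types, and `<prefix>_rows.csv` the patient ids and labels.  Absent
#' binary cells restore as 0, absent numeric cells as missing.
#'
#' @param dataset A `"landmark_dataset"`.
#' @param prefix File-path prefix.
#' @return `write_design` returns `prefix` invisibly; `read_design` the
#'   restored dataset.
#' @export
write_design <- function(dataset, prefix) {
  X <- dataset$X
  is_num <- dataset$col_type == "numeric"
  # numeric: every observed (non-NA) cell, including zeros;
  # binary: only the ones
  store <- !is.na(X) & (rep(is_num, each = nrow(X)) | X != 0)
  idx <- which(store, arr.ind = TRUE)
  cells <- data.frame(row = idx[, 1L], col = idx[, 2L],
                      value = sprintf("%.17g", X[idx]))
  utils::write.csv(cells, paste0(prefix, "_cells.csv"), row.names = FALSE,
                   quote = FALSE)
  cols <- data.frame(col = seq_len(ncol(X)), name = colnames(X),
                     type = dataset$col_type)
  utils::write.csv(cols, paste0(prefix, "_columns.csv"), row.names = FALSE)
  rows <- data.frame(row = seq_len(nrow(X)), patient_id =
                       dataset$patient_id, y = dataset$y,
                     landmark = if (is.null(dataset$landmark))
                       rep(dataset$t, nrow(X)) else dataset$landmark)
  utils::write.csv(rows, paste0(prefix, "_rows.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_design
#' @export
read_design <- function(prefix) {
  cells <- utils::read.csv(paste0(prefix, "_cells.csv"),
                           colClasses = c("integer", "integer",
                                          "character"))
  cols <- utils::read.csv(paste0(prefix, "_columns.csv"),
                          stringsAsFactors = FALSE)
  rows <- utils::read.csv(paste0(prefix, "_rows.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character"))
  X <- matrix(0, nrow = nrow(rows), ncol = nrow(cols),
              dimnames = list(NULL, cols$name))
  X[, cols$type == "numeric"] <- NA_real_
  X[cbind(cells$row, cells$col)] <- as.numeric(cells$value)
  t <- unique(rows$landmark)
  d <- .lb_dataset(if (length(t) == 1L) t else NA_integer_, X, rows$y,
                   rows$patient_id, cols$type)
  if (length(t) > 1L) d$landmark <- rows$landmark
  d
}
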