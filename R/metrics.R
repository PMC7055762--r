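#' Area under the ROC curve
#'
#' Mann--Whitney form: the probability that a uniformly drawn positive
#' outranks a uniformly drawn negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary outcomes in \{0, 1\}.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision--recall curve
#'
#' Step-curve definition without interpolation: thresholds sweep the
#' distinct score values in decreasing order and the area is
#' \eqn{\sum_k P_k \, (R_k - R_{k-1})} with precision \eqn{P_k} and recall
#' \eqn{R_k} at each step.  With constant scores the curve degenerates to a
#' single point and the area equals the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0L) stop("AUPRC undefined: no positive labels")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # block ends of tied-score groups
  ends <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[ends]
  k <- ends
  prec <- tp / k
  rec <- tp / P
  sum(prec * diff(c(0, rec)))
}

#' Threshold metrics at a top-fraction cut
#'
#' Flags the `ceil(top_fraction * n)` highest-scoring examples as predicted
#' positives (ties at the cut broken by stable score-then-index order) and
#' reports the standard 2x2 metrics.  By default the cut is the top 40th
#' percentile of predicted risk.
#'
#' @inheritParams auroc
#' @param top_fraction Fraction of examples flagged positive.
#' @return Named vector: `sensitivity`, `specificity`, `ppv`, `npv`, plus
#'   `n_flagged`.  Metrics with an empty denominator are `NA` with a
#'   warning.
#' @export
threshold_metrics <- function(scores, labels, top_fraction = 0.40) {
  labels <- as.numeric(labels)
  n <- length(scores)
  stopifnot(n >= 1L, length(labels) == n, all(labels %in% c(0, 1)),
            top_fraction >= 0, top_fraction <= 1)
  k <- ceiling(top_fraction * n)
  flagged <- logical(n)
  if (k > 0) flagged[order(-scores, seq_len(n))[seq_len(k)]] <- TRUE
  tp <- sum(flagged & labels == 1)
  fp <- sum(flagged & labels == 0)
  fn <- sum(!flagged & labels == 1)
  tn <- sum(!flagged & labels == 0)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (empty denominator)")
      return(NA_real_)
    }
    num / den
  }
  c(sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    ppv = safe(tp, tp + fp, "ppv"),
    npv = safe(tn, tn + fn, "npv"),
    n_flagged = k)
}

#' Bootstrap percentile interval for a metric
#'
#' Resamples (score, label) pairs with replacement `n_boot` times (default
#' 30) and reports the 2.5th, 50th and 97.5th percentiles of the metric
#' over the resamples.  Resamples on which the metric is not computable
#' (e.g. a single-class draw for AUROC) are redrawn, up to 100 attempts
#' each, then skipped with a warning.
#'
#' @param metric Function of `(scores, labels)` returning a scalar.
#' @inheritParams auroc
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Named vector `lower`, `median`, `upper`.
#' @export
bootstrap_ci <- function(metric, scores, labels, n_boot = 30L, seed = 1L) {
  n <- length(scores)
  stopifnot(length(labels) == n, n >= 1L)
  full <- tryCatch(suppressWarnings(metric(scores, labels)),
                   error = function(e) NA_real_)
  if (is.na(full)) stop("metric not computable on the full sample")
  set.seed(seed)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    for (attempt in seq_len(100L)) {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(suppressWarnings(metric(scores[idx], labels[idx])),
                    error = function(e) NA_real_)
      if (!is.na(v)) {
        vals[b] <- v
        break
      }
    }
  }
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " resample(s) skipped: metric not computable")
    vals <- vals[!is.na(vals)]
  }
  q <- stats::quantile(vals, c(0.025, 0.5, 0.975), names = FALSE)
  c(lower = q[1], median = q[2], upper = q[3])
}

#' Binned observed-to-expected calibration
#'
#' Groups predictions into `n_bins` equal-width bins on the probability
#' scale (default 20) and reports, per bin, the observed event count O, the
#' expected count E (sum of predicted probabilities), the O:E ratio and a
#' calibration flag.  A bin is flagged `"overpredicted"` when O is
#' significantly below E and `"underpredicted"` when significantly above
#' (two-sided exact binomial test of O against Binomial(n, E/n) at level
#' `alpha`; a Poisson test of O with mean E is available as an
#' alternative).
#'
#' @inheritParams auroc
#' @param n_bins Number of equal-width probability bins.
#' @param alpha Significance level for the flags.
#' @param test `"binomial"` (exact, default) or `"poisson"`.
#' @return Data frame with one row per bin: `bin`, `lower`, `upper`, `n`,
#'   `observed`, `expected`, `oe_ratio`, `p_value`, `flag`.
#' @export
calibration_bins <- function(scores, labels, n_bins = 20L, alpha = 0.05,
                             test = c("binomial", "poisson")) {
  test <- match.arg(test)
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)),
            all(scores >= 0), all(scores <= 1), n_bins >= 1)
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = (seq_len(n_bins) - 1) / n_bins,
                    upper = seq_len(n_bins) / n_bins,
                    n = 0L, observed = 0L, expected = 0,
                    oe_ratio = NA_real_, p_value = NA_real_,
                    flag = NA_character_)
  for (b in seq_len(n_bins)) {
    rows <- bin == b
    nb <- sum(rows)
    out$n[b] <- nb
    if (nb == 0L) next
    O <- sum(labels[rows])
    E <- sum(scores[rows])
    out$observed[b] <- O
    out$expected[b] <- E
    out$oe_ratio[b] <- if (E > 0) O / E else NA_real_
    if (E <= 0) next
    p <- if (test == "binomial") {
      stats::binom.test(O, nb, min(E / nb, 1))$p.value
    } else {
      stats::poisson.test(O, r = E)$p.value
    }
    out$p_value[b] <- p
    out$flag[b] <- if (p < alpha && O < E) "overpredicted" else
      if (p < alpha && O > E) "underpredicted" else "calibrated"
  }
  out
}

#' Pearson correlation between predicted probabilities and outcomes
#'
#' @inheritParams auroc
#' @return Correlation in \[-1, 1\].
#' @export
pearson_pred_actual <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  if (stats::var(scores) == 0 || stats::var(labels) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(scores, labels)
}

# dense rank with 1 = largest
.lb_dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Feature-importance rank drift across landmark models
#'
#' For a sequence of per-landmark ensembles, computes gain-based importance
#' per model, converts it to dense ranks (1 = most important; features
#' absent from a model's dictionary get rank `n_features + 1`), and reports
#' for each feature the Pearson correlation between its rank and the
#' landmark index.  A strongly negative correlation means the feature grew
#' more important over time.  Features whose rank never changes have an
#' undefined correlation and are reported as stable, with a missing `r`.
#'
#' @param models List of at least two `"lb_gbm"` fits ordered by landmark,
#'   or a fitted [landmark_boost()] object.
#' @return Data frame: `feature`, one `rank_t<k>` column per landmark,
#'   `r`, `stable`.
#' @export
importance_rank_drift <- function(models) {
  if (inherits(models, "landboost")) models <- models$models
  stopifnot(is.list(models))
  if (length(models) < 2L)
    stop("rank drift requires at least two landmark models")
  imps <- lapply(models, gbm_importance)
  feats <- sort(unique(unlist(lapply(imps, names))))
  nf <- length(feats)
  ranks <- matrix(nf + 1L, nrow = nf, ncol = length(models),
                  dimnames = list(feats, NULL))
  for (t in seq_along(imps)) {
    imp <- imps[[t]]
    ranks[names(imp), t] <- .lb_dense_rank_desc(unname(imp))
  }
  tt <- seq_along(models) - 1L
  r <- apply(ranks, 1L, function(rk) {
    if (stats::var(rk) == 0) NA_real_ else stats::cor(rk, tt)
  })
  out <- data.frame(feature = feats, ranks, r = r,
                    stable = is.na(r), row.names = NULL,
                    check.names = FALSE)
  names(out)[1L + seq_along(models)] <- paste0("rank_t", tt)
  out
}
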