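#' Control parameters for the boosted-tree learner
#'
#' Collects and validates the hyperparameters of the Newton-boosted tree
#' classifier.  The defaults mirror the tuning ranges used for the dynamic
#' risk models: tree depth 2--10, learning rate 0.01--0.1, minimal child
#' weight 1--10, up to 1000 trees per fit with early stopping after 100
#' stagnant rounds of holdout AUROC.
#'
#' @param max_depth Number of split levels per tree (1 = stump).
#' @param learning_rate Shrinkage applied to every leaf contribution.
#' @param min_child_weight Minimum hessian sum required in each child.
#' @param max_trees Maximum number of boosting rounds.
#' @param early_stop_rounds Stop when holdout AUROC has not improved for
#'   this many rounds (only active when a holdout is supplied).
#' @param lambda L2 regularisation on leaf weights.
#' @param holdout_fraction Fraction of training rows reserved for early
#'   stopping by the higher-level fitters.
#' @param cv_folds Number of cross-validation folds used by [tune_by_cv()].
#' @param seed Integer seed for any randomised step (holdout draw, folds).
#' @return A list of class `"gbm_control"`.
#' @export
gbm_control <- function(max_depth = 3L, learning_rate = 0.1,
                        min_child_weight = 1, max_trees = 1000L,
                        early_stop_rounds = 100L, lambda = 1,
                        holdout_fraction = 0.2, cv_folds = 10L, seed = 1L) {
  max_depth <- as.integer(max_depth)
  stopifnot(max_depth >= 1L, max_depth <= 10L,
            learning_rate > 0, learning_rate <= 1,
            min_child_weight >= 0, max_trees >= 0,
            early_stop_rounds >= 1, lambda >= 0,
            holdout_fraction >= 0, holdout_fraction < 1,
            cv_folds >= 2)
  structure(list(max_depth = max_depth, learning_rate = learning_rate,
                 min_child_weight = min_child_weight,
                 max_trees = as.integer(max_trees),
                 early_stop_rounds = as.integer(early_stop_rounds),
                 lambda = lambda, holdout_fraction = holdout_fraction,
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "gbm_control")
}

# probability clip used before any logit
.lb_clip <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

.lb_as_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix or data frame")
  X
}

# ascending order of present values per column (0-based, for the C++ core)
.lb_col_orders <- function(X) {
  lapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    idx <- which(!is.na(v))
    as.integer(idx[order(v[idx], method = "radix")] - 1L)
  })
}

#' Fit a gradient-boosted tree classifier with baseline margin support
#'
#' Stagewise second-order (Newton) boosting on the binomial log-loss.  Per
#' round, gradients `g = p - y` and hessians `h = p (1 - p)` are evaluated at
#' the current margin and a depth-limited regression tree is grown by exact
#' greedy search.  Missing values are handled adaptively: at every split
#' both routings of missing rows are scored and the gain-maximising one is
#' kept, and an explicit present-vs-missing split is also considered.
#'
#' A fixed per-row log-odds offset (`base_margin`) can be supplied; the
#' ensemble then learns additively on top of it, which is how the
#' landmark-boosting scheme carries the previous landmark's risk forward.
#'
#' @param X Numeric matrix (or data frame); `NA` encodes a missing value.
#' @param y Binary response in \{0, 1\}.
#' @param base_margin Per-row baseline log-odds (scalar or vector);
#'   default 0.
#' @param control A [gbm_control()] object.
#' @param holdout Optional integer vector of row indices reserved for early
#'   stopping on holdout AUROC; these rows are excluded from tree growth.
#'   When `NULL`, boosting runs to `max_trees`.
#' @return An object of class `"lb_gbm"`: the fitted trees, learning rate,
#'   feature dictionary, and the holdout AUROC trace when early stopping
#'   was active.
#' @seealso [predict.lb_gbm()], [tune_by_cv()], [gbm_save()]
#' @export
fit_gbm <- function(X, y, base_margin = 0, control = gbm_control(),
                    holdout = NULL) {
  X <- .lb_as_matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("X must have rows and columns")
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  base_margin <- rep_len(as.numeric(base_margin), nrow(X))

  fit <- list(trees = list(), learning_rate = control$learning_rate,
              intercept = 0, feature_names = colnames(X),
              control = control, n_trees = 0L, best_iteration = 0L,
              evals = numeric(0))
  class(fit) <- "lb_gbm"

  if (length(unique(y)) < 2L) {
    warning("single-class response: returning degenerate constant ensemble")
    fit$intercept <- stats::qlogis(.lb_clip(mean(y)))
    return(fit)
  }
  if (control$max_trees == 0L) return(fit)

  train <- seq_len(nrow(X))
  use_es <- !is.null(holdout) && length(holdout) > 0L
  if (use_es) {
    holdout <- as.integer(holdout)
    stopifnot(all(holdout >= 1L), all(holdout <= nrow(X)))
    train <- setdiff(train, holdout)
    if (length(unique(y[holdout])) < 2L) {
      warning("holdout has a single class; early stopping disabled")
      use_es <- FALSE
      train <- seq_len(nrow(X))
    }
  }

  Xtr <- X[train, , drop = FALSE]
  ytr <- y[train]
  orders <- .lb_col_orders(Xtr)
  margin_tr <- base_margin[train]
  margin_ho <- if (use_es) base_margin[holdout] else numeric(0)
  Xho <- if (use_es) X[holdout, , drop = FALSE] else NULL

  trees <- vector("list", control$max_trees)
  evals <- numeric(control$max_trees)
  best_auc <- -Inf
  best_iter <- 0L
  n_done <- 0L

  for (m in seq_len(control$max_trees)) {
    p <- stats::plogis(margin_tr)
    g <- p - ytr
    h <- p * (1 - p)
    tree <- lb_grow_tree(Xtr, orders, g, h, control$max_depth,
                         control$min_child_weight, control$lambda)
    trees[[m]] <- tree
    n_done <- m
    margin_tr <- margin_tr +
      control$learning_rate * lb_predict_tree(tree, Xtr)
    if (use_es) {
      margin_ho <- margin_ho +
        control$learning_rate * lb_predict_tree(tree, Xho)
      auc <- auroc(stats::plogis(margin_ho), y[holdout])
      evals[m] <- auc
      if (auc > best_auc) {
        best_auc <- auc
        best_iter <- m
      } else if (m - best_iter >= control$early_stop_rounds) {
        break
      }
    }
  }

  # boosting stops once the holdout AUROC has stagnated for
  # early_stop_rounds; all trees grown up to the stop are kept (the later
  # trees no longer change the ranking but keep refining the probability
  # scale), with the best round recorded for reference
  fit$trees <- trees[seq_len(n_done)]
  fit$best_iteration <- if (use_es) best_iter else n_done
  if (use_es) fit$evals <- evals[seq_len(n_done)]
  fit$n_trees <- n_done
  fit
}

# align a prediction matrix to the model's feature dictionary; columns the
# model knows but X lacks are filled with NA (treated as missing)
.lb_align <- function(object, X) {
  X <- .lb_as_matrix(X)
  fn <- object$feature_names
  if (is.null(fn) || is.null(colnames(X))) {
    if (!is.null(fn) && ncol(X) != length(fn))
      stop("X has no column names and its width does not match the model")
    return(X)
  }
  out <- matrix(NA_real_, nrow(X), length(fn), dimnames = list(NULL, fn))
  keep <- intersect(fn, colnames(X))
  out[, keep] <- X[, keep, drop = FALSE]
  out
}

#' Predict from a fitted boosted ensemble
#'
#' @param object An `"lb_gbm"` fit.
#' @param X Feature matrix; columns are matched by name against the model's
#'   feature dictionary, and columns the model expects but `X` lacks are
#'   treated as missing values.
#' @param base_margin Per-row baseline log-odds added before the trees.
#' @param type `"response"` for probabilities, `"link"` for log-odds.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lb_gbm <- function(object, X, base_margin = 0,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- .lb_align(object, X)
  bm <- rep_len(as.numeric(base_margin), nrow(X)) + object$intercept
  margin <- if (length(object$trees) == 0L) bm else
    lb_predict_ensemble(object$trees, X, bm, object$learning_rate)
  if (type == "link") margin else stats::plogis(margin)
}

#' Per-row log-odds of an ensemble given a baseline margin
#'
#' Convenience wrapper equivalent to
#' `predict(ensemble, X, base_margin, type = "link")`.
#'
#' @inheritParams predict.lb_gbm
#' @param ensemble An `"lb_gbm"` fit.
#' @return Numeric vector of log-odds.
#' @export
predict_margin <- function(ensemble, X, base_margin = 0) {
  predict(ensemble, X, base_margin = base_margin, type = "link")
}

#' @export
print.lb_gbm <- function(x, ...) {
  cat("Boosted tree ensemble:", x$n_trees, "trees,",
      "depth", x$control$max_depth,
      "| learning rate", x$control$learning_rate, "\n")
  if (x$intercept != 0) cat("Intercept (log-odds):", x$intercept, "\n")
  invisible(x)
}

#' Gain-based feature importance
#'
#' Total split gain accumulated per feature over all trees, normalised to
#' sum to one.  Features the ensemble never split on get importance 0.
#'
#' @param object An `"lb_gbm"` fit.
#' @return Named numeric vector over the model's feature dictionary.
#' @export
gbm_importance <- function(object) {
  stopifnot(inherits(object, "lb_gbm"))
  fn <- object$feature_names
  if (is.null(fn)) fn <- as.character(seq_len(0))
  imp <- stats::setNames(numeric(length(fn)), fn)
  for (tree in object$trees) {
    int <- tree$feature != 0L
    if (!any(int)) next
    f <- tree$feature[int]
    gsum <- tapply(tree$gain[int], f, sum)
    idx <- as.integer(names(gsum))
    imp[idx] <- imp[idx] + as.numeric(gsum)
  }
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  imp
}

# stratified draw of a holdout index set (used for early stopping)
.lb_stratified_holdout <- function(y, fraction, seed) {
  if (fraction <= 0) return(integer(0))
  set.seed(seed)
  idx <- integer(0)
  for (cls in sort(unique(y))) {
    rows <- which(y == cls)
    k <- max(1L, floor(fraction * length(rows)))
    idx <- c(idx, sort(sample(rows, k)))
  }
  sort(idx)
}

# stratified fold assignment for cross-validation
.lb_stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    rows <- which(y == cls)
    fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  fold
}

#' Tune boosting hyperparameters by stratified cross-validation
#'
#' Evaluates every row of a hyperparameter grid by mean out-of-fold AUROC
#' over stratified folds (default 10) and returns the winning
#' configuration.  Within each fold, the held-out fold serves as the early
#' stopping set.  Ties are broken in favour of the smaller depth, then the
#' smaller learning rate.
#'
#' @param X,y,base_margin As in [fit_gbm()].
#' @param grid Data frame of candidate values; recognised columns are
#'   `max_depth`, `learning_rate` and `min_child_weight`.  Missing columns
#'   fall back to the values in `control`.
#' @param control Baseline [gbm_control()] supplying all non-tuned
#'   parameters.
#' @param folds Number of folds (reduced with a warning when there are
#'   fewer rows than folds).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (a full [gbm_control()]) and `scores` (the grid
#'   with a `mean_auc` column).
#' @export
tune_by_cv <- function(X, y, base_margin = 0, grid, control = gbm_control(),
                       folds = 10L, seed = 1L) {
  X <- .lb_as_matrix(X)
  y <- as.numeric(y)
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) stop("grid must be non-empty")
  for (col in c("max_depth", "learning_rate", "min_child_weight"))
    if (is.null(grid[[col]])) grid[[col]] <- control[[col]]
  folds <- as.integer(folds)
  if (nrow(X) < folds) {
    warning("fewer rows than folds; reducing folds to ", nrow(X))
    folds <- nrow(X)
  }
  fold <- .lb_stratified_folds(y, folds, seed)
  base_margin <- rep_len(as.numeric(base_margin), nrow(X))

  grid$mean_auc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ctl <- control
    ctl$max_depth <- as.integer(grid$max_depth[i])
    ctl$learning_rate <- grid$learning_rate[i]
    ctl$min_child_weight <- grid$min_child_weight[i]
    aucs <- numeric(folds)
    for (k in seq_len(folds)) {
      te <- which(fold == k)
      fit <- fit_gbm(X, y, base_margin, control = ctl, holdout = te)
      p <- predict(fit, X[te, , drop = FALSE],
                   base_margin = base_margin[te])
      aucs[k] <- if (length(unique(y[te])) < 2L) NA_real_ else
        auroc(p, y[te])
    }
    grid$mean_auc[i] <- mean(aucs, na.rm = TRUE)
  }
  ord <- order(-grid$mean_auc, grid$max_depth, grid$learning_rate,
               grid$min_child_weight, seq_len(nrow(grid)))
  best_row <- grid[ord[1L], ]
  best <- control
  best$max_depth <- as.integer(best_row$max_depth)
  best$learning_rate <- best_row$learning_rate
  best$min_child_weight <- best_row$min_child_weight
  list(best = best, scores = grid)
}

#' Serialise / restore a boosted ensemble
#'
#' Writes the fitted trees (feature index, threshold, missing direction,
#' children, leaf weights), learning rate and feature dictionary to a JSON
#' dump that restores bit-exactly: numeric fields are stored at full
#' precision.
#'
#' @param object An `"lb_gbm"` fit.
#' @param path File path of the dump.
#' @return `gbm_save` returns `path` invisibly; `gbm_load` returns the
#'   restored `"lb_gbm"` object.
#' @export
gbm_save <- function(object, path) {
  stopifnot(inherits(object, "lb_gbm"))
  # numeric fields are written with %.17g so that every double restores
  # to the identical bit pattern
  jnum <- function(x) ifelse(is.na(x), "null", sprintf("%.17g", x))
  jint <- function(x) ifelse(is.na(x), "null", sprintf("%d", x))
  jbool <- function(x) ifelse(x, "true", "false")
  jstr <- function(x) paste0('"', gsub('"', '\\\\"',
                                       gsub("\\\\", "\\\\\\\\", x)), '"')
  jarr <- function(x) paste0("[", paste(x, collapse = ","), "]")
  jtree <- function(tr) paste0(
    '{"feature":', jarr(jint(tr$feature)),
    ',"threshold":', jarr(jnum(tr$threshold)),
    ',"presence":', jarr(jbool(tr$presence)),
    ',"missing_left":', jarr(jbool(tr$missing_left)),
    ',"left":', jarr(jint(tr$left)),
    ',"right":', jarr(jint(tr$right)),
    ',"value":', jarr(jnum(tr$value)),
    ',"gain":', jarr(jnum(tr$gain)),
    ',"cover":', jarr(jnum(tr$cover)),
    ',"count":', jarr(jint(tr$count)), "}")
  ctl <- object$control
  json <- paste0(
    '{"format":"landboost-gbm-1"',
    ',"learning_rate":', jnum(object$learning_rate),
    ',"intercept":', jnum(object$intercept),
    ',"feature_names":',
    if (is.null(object$feature_names)) "null" else
      jarr(jstr(object$feature_names)),
    ',"n_trees":', jint(object$n_trees),
    ',"best_iteration":', jint(object$best_iteration),
    ',"control":{',
    '"max_depth":', jint(ctl$max_depth),
    ',"learning_rate":', jnum(ctl$learning_rate),
    ',"min_child_weight":', jnum(ctl$min_child_weight),
    ',"max_trees":', jint(ctl$max_trees),
    ',"early_stop_rounds":', jint(ctl$early_stop_rounds),
    ',"lambda":', jnum(ctl$lambda),
    ',"holdout_fraction":', jnum(ctl$holdout_fraction),
    ',"cv_folds":', jint(ctl$cv_folds),
    ',"seed":', jint(ctl$seed), "}",
    ',"trees":', jarr(vapply(object$trees, jtree, "")), "}")
  writeLines(json, path)
  invisible(path)
}

#' @rdname gbm_save
#' @export
gbm_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(payload$format, "landboost-gbm-1"))
  ctl <- payload$control
  control <- gbm_control(max_depth = ctl$max_depth,
                         learning_rate = ctl$learning_rate,
                         min_child_weight = ctl$min_child_weight,
                         max_trees = ctl$max_trees,
                         early_stop_rounds = ctl$early_stop_rounds,
                         lambda = ctl$lambda,
                         holdout_fraction = ctl$holdout_fraction,
                         cv_folds = ctl$cv_folds, seed = ctl$seed)
  num <- function(x) vapply(as.list(x), function(e)
    if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
  int <- function(x) vapply(as.list(x), function(e)
    if (is.null(e)) NA_integer_ else as.integer(e), integer(1))
  lgl <- function(x) vapply(as.list(x), function(e)
    if (is.null(e)) NA else as.logical(e), logical(1))
  trees <- lapply(payload$trees, function(tr) {
    list(feature = int(tr$feature), threshold = num(tr$threshold),
         presence = lgl(tr$presence),
         missing_left = lgl(tr$missing_left),
         left = int(tr$left), right = int(tr$right),
         value = num(tr$value), gain = num(tr$gain),
         cover = num(tr$cover), count = int(tr$count))
  })
  fn <- payload$feature_names
  fit <- list(trees = trees, learning_rate = as.numeric(payload$learning_rate),
              intercept = as.numeric(payload$intercept),
              feature_names = if (is.null(fn)) NULL else
                as.character(unlist(fn)),
              control = control,
              n_trees = as.integer(payload$n_trees),
              best_iteration = as.integer(payload$best_iteration),
              evals = numeric(0))
  class(fit) <- "lb_gbm"
  fit
}

#' Default hyperparameter grid for the boosted learner
#'
#' A small grid spanning the documented tuning ranges (depth 2--10,
#' learning rate 0.01--0.1, minimal child weight 1--10).
#'
#' @param max_depth,learning_rate,min_child_weight Candidate values.
#' @return Data frame with one row per combination.
#' @export
default_tuning_grid <- function(max_depth = c(2L, 4L, 6L),
                                learning_rate = c(0.05, 0.1),
                                min_child_weight = c(1, 5)) {
  expand.grid(max_depth = max_depth, learning_rate = learning_rate,
              min_child_weight = min_child_weight,
              KEEP.OUT.ATTRS = FALSE)
}
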