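# The anchored single-regression occlusal-force estimator and its
# leave-one-run-out cross-validated evaluation.
#
# Per training run the slope of force on ear is the ordinary least-squares
# regression coefficient; the fold's slope is the arithmetic mean of the
# K - 1 training slopes. Prediction on the held-out run is anchored to that
# run's first (ear, force) sample instead of a fitted intercept:
#   f~_j = a_bar * (e_j - e0) + f0.
# Accuracy is RMSE against the measured force and NRMSE, the RMSE divided
# by the range of the *estimated* series.

#' Single-regression slope of force on ear
#'
#' The ordinary least-squares regression coefficient of f on e, written as
#' \deqn{a = (n \sum e_j f_j - \sum e_j \sum f_j) /
#'           (n \sum e_j^2 - (\sum e_j)^2),}
#' i.e. the slope of the intercept-including least-squares line. The
#' intercept itself is discarded by the anchored predictor.
#'
#' @param e,f numeric vectors of equal length >= 2; `e` must have nonzero
#'   variance.
#' @return the slope, AD-force units per AD-ear unit.
#' @export
slope <- function(e, f) {
  n <- length(e)
  if (length(f) != n) occl_range_error("'e' and 'f' must have equal length")
  if (n < 2L) occl_insufficient_data_error("need at least 2 samples")
  if (anyNA(e) || anyNA(f)) occl_degenerate_error("missing values in input")
  denom <- n * sum(e^2) - sum(e)^2
  if (denom == 0)
    occl_degenerate_error("constant ear series: slope undefined")
  (n * sum(e * f) - sum(e) * sum(f)) / denom
}

#' Fold-averaged slope over a training set
#'
#' @param runs list of [occl_run()] objects (the K - 1 training runs of a
#'   fold).
#' @return arithmetic mean of the per-run slopes.
#' @export
fold_mean_slope <- function(runs) {
  if (!is.list(runs) || length(runs) < 1L)
    occl_insufficient_data_error("training set is empty")
  slopes <- vapply(seq_along(runs), function(i)
    tryCatch(slope(runs[[i]]$ear, runs[[i]]$force),
             occl_error = function(e) occl_degenerate_error(sprintf(
               "training run %d: %s", attr(runs[[i]], "run_index") %||% i,
               conditionMessage(e)))),
    numeric(1))
  mean(slopes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anchored force prediction
#'
#' Evaluates f~_j = a_bar * (e_j - e0) + f0 elementwise: the estimate is
#' pinned to the anchor pair (e0, f0), normally the first sample of the
#' held-out run, rather than using a fitted intercept.
#'
#' @param e numeric vector of ear AD values.
#' @param a_bar fold-averaged slope.
#' @param e0,f0 anchor ear and force AD values.
#' @return estimated force series, same length as `e` (AD units, unclamped).
#' @export
predict_force <- function(e, a_bar, e0, f0) {
  if (length(e) < 1L) occl_range_error("'e' must be non-empty")
  a_bar * (e - e0) + f0
}

#' Root-mean-square error between measured and estimated series
#'
#' @param f measured force series.
#' @param f_tilde estimated force series of the same length.
#' @return sqrt of the mean squared difference.
#' @export
rmse <- function(f, f_tilde) {
  if (length(f) != length(f_tilde))
    occl_range_error("series lengths differ")
  if (length(f) < 1L) occl_range_error("empty series")
  sqrt(mean((f - f_tilde)^2))
}

#' Width of the estimated series
#'
#' The difference between the maximum and minimum estimated values within a
#' fold; used to normalize RMSE into NRMSE so folds with different
#' estimation ranges are comparable.
#'
#' @param f_tilde_max,f_tilde_min extremes of the estimate series.
#' @return `f_tilde_max - f_tilde_min`.
#' @export
estimated_width <- function(f_tilde_max, f_tilde_min) {
  if (f_tilde_max < f_tilde_min)
    occl_range_error("maximum below minimum")
  f_tilde_max - f_tilde_min
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the width of the estimated series,
#' NRMSE_k = RMSE_k / (f~_max - f~_min). Scale-free: rescaling both series
#' by a common positive factor leaves it unchanged.
#'
#' @param rmse_k RMSE of the fold.
#' @param f_tilde_max,f_tilde_min extremes of the estimate series;
#'   must differ.
#' @return the normalized error.
#' @export
nrmse <- function(rmse_k, f_tilde_max, f_tilde_min) {
  w <- estimated_width(f_tilde_max, f_tilde_min)
  if (w == 0)
    occl_degenerate_error("zero estimated width: NRMSE undefined")
  rmse_k / w
}

#' Fit the anchored single-regression force estimator
#'
#' Fits the estimator on a set of training runs: computes the
#' ordinary-least-squares slope of force on ear for each run and averages
#' them. The returned model predicts force from an ear series once given an
#' anchor pair (the initial ear and force values of the target trial), via
#' [predict.occl_fit()].
#'
#' @param session an [occl_session()].
#' @param exclude optional run index to hold out (the cross-validation
#'   fold); `NULL` trains on all runs.
#' @return an object of class `occl_fit` with fields `slopes` (per training
#'   run), `a_bar`, `subject_id`, `train_runs`, `exclude`.
#' @examples
#' s <- generate_session(subject_params(seed = 1))
#' fit <- occl_fit(s, exclude = 1)
#' coef(fit)
#' @export
occl_fit <- function(session, exclude = NULL) {
  stopifnot(inherits(session, "occl_session"))
  idx <- seq_len(session$K)
  if (!is.null(exclude)) {
    exclude <- as.integer(exclude)
    if (length(exclude) != 1L || is.na(exclude) || !exclude %in% idx)
      occl_range_error("'exclude' must be a single run index of the session")
    idx <- setdiff(idx, exclude)
  }
  runs <- session$runs[idx]
  slopes <- vapply(seq_along(runs), function(i)
    tryCatch(slope(runs[[i]]$ear, runs[[i]]$force),
             occl_error = function(e) occl_degenerate_error(sprintf(
               "subject %s, training run %d: %s", session$subject_id,
               idx[i], conditionMessage(e)))),
    numeric(1))
  structure(list(slopes = stats::setNames(slopes, idx),
                 a_bar = mean(slopes),
                 subject_id = session$subject_id,
                 train_runs = idx, exclude = exclude,
                 call = match.call()),
            class = "occl_fit")
}

#' @export
coef.occl_fit <- function(object, ...) c(a_bar = object$a_bar)

#' @export
print.occl_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Anchored single-regression force estimator (subject %s)\n",
              x$subject_id))
  cat(sprintf("  trained on runs %s%s\n",
              paste(x$train_runs, collapse = ", "),
              if (is.null(x$exclude)) ""
              else sprintf(" (run %d held out)", x$exclude)))
  cat(sprintf("  fold-averaged slope a_bar = %.*f AD-force per AD-ear\n",
              digits, x$a_bar))
  invisible(x)
}

#' Predict force from an ear series with an anchored fit
#'
#' @param object an [occl_fit()].
#' @param newdata either an [occl_run()] (anchors default to its first
#'   sample) or a numeric ear series.
#' @param e0,f0 anchor values; required when `newdata` is a bare series,
#'   defaulted to the first (ear, force) sample when it is a run.
#' @param ... unused.
#' @return estimated force series in AD units.
#' @export
predict.occl_fit <- function(object, newdata, e0 = NULL, f0 = NULL, ...) {
  if (inherits(newdata, "occl_run")) {
    e <- newdata$ear
    if (is.null(e0)) e0 <- newdata$ear[1L]
    if (is.null(f0)) f0 <- newdata$force[1L]
  } else {
    e <- as.numeric(newdata)
    if (is.null(e0) || is.null(f0))
      occl_range_error("anchors 'e0' and 'f0' required for a bare ear series")
  }
  predict_force(e, object$a_bar, e0, f0)
}

#' Leave-one-run-out cross-validation of the force estimator
#'
#' For each fold k = 1..K the estimator is trained on the other K - 1 runs
#' ([occl_fit()]), anchored on the first (ear, force) sample of the held-out
#' run, and evaluated against that run's measured force: RMSE_k, the
#' estimate extremes f~_max and f~_min, the estimated width, and
#' NRMSE_k = RMSE_k / width. The subject-level summary averages each fold
#' column independently (so the averaged NRMSE is not the ratio of the
#' averaged RMSE to the averaged width) and reports the mean of the K
#' fold-averaged slopes together with the square root of their unbiased
#' variance.
#'
#' @param session an [occl_session()] with K >= 2 runs.
#' @return an object of class `occl_cv`: `folds` (per-fold data frame with
#'   columns `k`, `a_bar`, `e0`, `f0`, `rmse`, `f_tilde_max`, `f_tilde_min`,
#'   `width`, `nrmse`), `estimates` (list of per-fold estimate series),
#'   `summary` (independent column means plus `a_bar_sd`), `subject_id`, `K`.
#' @examples
#' s <- generate_session(subject_params(seed = 1))
#' cv <- cross_validate(s)
#' summary(cv)
#' @export
cross_validate <- function(session) {
  stopifnot(inherits(session, "occl_session"))
  K <- session$K
  folds <- vector("list", K)
  estimates <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- tryCatch(occl_fit(session, exclude = k),
                    occl_degenerate_error = function(e)
                      occl_degenerate_error(sprintf(
                        "fold %d: %s", k, conditionMessage(e))))
    test <- session$runs[[k]]
    e0 <- test$ear[1L]
    f0 <- test$force[1L]
    f_tilde <- predict_force(test$ear, fit$a_bar, e0, f0)
    r <- rmse(test$force, f_tilde)
    fmax <- max(f_tilde)
    fmin <- min(f_tilde)
    w <- estimated_width(fmax, fmin)
    nr <- tryCatch(nrmse(r, fmax, fmin),
                   occl_degenerate_error = function(e)
                     occl_degenerate_error(sprintf(
                       "fold %d: %s", k, conditionMessage(e))))
    folds[[k]] <- data.frame(k = k, a_bar = fit$a_bar, e0 = e0, f0 = f0,
                             rmse = r, f_tilde_max = fmax, f_tilde_min = fmin,
                             width = w, nrmse = nr)
    estimates[[k]] <- f_tilde
  }
  folds <- do.call(rbind, folds)
  summ <- c(a_bar_mean = mean(folds$a_bar),
            a_bar_sd = stats::sd(folds$a_bar),
            rmse_mean = mean(folds$rmse),
            f_tilde_max_mean = mean(folds$f_tilde_max),
            f_tilde_min_mean = mean(folds$f_tilde_min),
            width_mean = mean(folds$width),
            nrmse_mean = mean(folds$nrmse))
  structure(list(folds = folds, estimates = estimates, summary = summ,
                 subject_id = session$subject_id, K = K, session = session),
            class = "occl_cv")
}

#' @export
print.occl_cv <- function(x, digits = 4, ...) {
  cat(sprintf("Leave-one-run-out cross-validation: subject %s, K = %d folds\n",
              x$subject_id, x$K))
  s <- x$summary
  cat(sprintf("  slope a_bar: %.*f (sqrt unbiased variance %.*f)\n",
              digits, s["a_bar_mean"], digits, s["a_bar_sd"]))
  cat(sprintf("  RMSE %.4f | width %.4f | NRMSE %.4f (fold averages)\n",
              s["rmse_mean"], s["width_mean"], s["nrmse_mean"]))
  invisible(x)
}

#' @export
summary.occl_cv <- function(object, ...) {
  out <- list(subject_id = object$subject_id, K = object$K,
              folds = object$folds, summary = object$summary)
  class(out) <- "summary.occl_cv"
  out
}

#' @export
print.summary.occl_cv <- function(x, digits = 4, ...) {
  cat(sprintf("Subject %s: %d-fold leave-one-run-out cross-validation\n\n",
              x$subject_id, x$K))
  df <- x$folds
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  print.data.frame(df, row.names = FALSE)
  cat("\nFold averages (each column averaged independently):\n")
  print(round(x$summary, digits))
  invisible(x)
}

#' @export
coef.occl_cv <- function(object, ...) {
  c(a_bar_mean = unname(object$summary["a_bar_mean"]))
}

#' @export
as.data.frame.occl_cv <- function(x, ...) x$folds

#' Residuals of the cross-validated estimates
#'
#' @param object an `occl_cv` object.
#' @param ... unused.
#' @return a samples-by-folds matrix of measured minus estimated force.
#' @export
residuals.occl_cv <- function(object, ...) {
  vapply(seq_len(object$K), function(k)
    object$session$runs[[k]]$force - object$estimates[[k]],
    numeric(length(object$estimates[[1L]])))
}

#' Plot measured versus estimated force per fold
#'
#' One panel per fold: the held-out run's measured force (solid) and the
#' anchored estimate (dashed) against time.
#'
#' @param x an `occl_cv` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.occl_cv <- function(x, ...) {
  K <- x$K
  old <- graphics::par(mfrow = grDevices::n2mfrow(K),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(K)) {
    run <- x$session$runs[[k]]
    graphics::matplot(run$t, cbind(run$force, x$estimates[[k]]),
                      type = "l", lty = c(1, 2), col = c(1, 2),
                      xlab = "time [s]", ylab = "force [AD]",
                      main = sprintf("fold %d (NRMSE %.3f)",
                                     k, x$folds$nrmse[k]), ...)
  }
  invisible(x)
}
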