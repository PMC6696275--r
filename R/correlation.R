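# Per-run Pearson and first-order partial correlations among the three
# channels, aggregated per subject as mean and square root of unbiased
# variance across runs.

#' Pearson product-moment correlation with degeneracy checks
#'
#' Thin wrapper around [stats::cor()] that rejects degenerate input (fewer
#' than two samples, or a zero-variance series) with a structured error
#' instead of silently returning NA, so that per-run coefficients entering
#' the subject summaries are always well defined.
#'
#' @param x,y numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return the correlation coefficient, in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    occl_range_error("'x' and 'y' must have equal length")
  if (length(x) < 2L)
    occl_insufficient_data_error("need at least 2 samples")
  if (anyNA(x) || anyNA(y))
    occl_degenerate_error("missing values in correlation input")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    occl_degenerate_error("zero-variance series in correlation input")
  stats::cor(x, y)
}

#' First-order partial correlation from pairwise coefficients
#'
#' Correlation between x and y after removing the linear influence of a
#' third variable z, computed by the standard first-order recursion
#' \deqn{r_{xy.z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}.}
#' Equivalent to the Pearson correlation of the residuals of x and y after
#' each is regressed on z.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson coefficients in [-1, 1];
#'   `|r_xz|` and `|r_yz|` must be strictly below 1.
#' @return the partial coefficient r_xy.z.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  r <- c(r_xy, r_xz, r_yz)
  if (!is.numeric(r) || length(r) != 3L || anyNA(r))
    occl_range_error("coefficients must be three non-missing numbers")
  if (any(abs(r) > 1 + 1e-12))
    occl_range_error("correlation coefficients must lie in [-1, 1]")
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1)
    occl_degenerate_error(
      "control variable perfectly correlated with x or y (|r| = 1)")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Mean and square root of unbiased variance over runs
#'
#' The study's dispersion measure: the arithmetic mean of a per-run series
#' of coefficients together with the square root of its unbiased
#' (n-1 denominator) variance.
#'
#' @param values numeric vector of at least 2 per-run values.
#' @return named numeric vector with elements `mean` and `sd`.
#' @export
summarize_runs <- function(values) {
  if (!is.numeric(values) || anyNA(values))
    occl_range_error("'values' must be numeric with no missing values")
  if (length(values) < 2L)
    occl_insufficient_data_error(
      "need at least 2 per-run values to summarize")
  c(mean = mean(values), sd = stats::sd(values))
}

channel_pairs <- function() {
  list(ear_force = c("ear", "force"),
       ear_emg = c("ear", "emg"),
       emg_force = c("emg", "force"))
}

run_correlations <- function(run, subject_id = "?", run_index = NA_integer_) {
  out <- numeric(3)
  names(out) <- names(channel_pairs())
  for (p in names(channel_pairs())) {
    ch <- channel_pairs()[[p]]
    out[p] <- tryCatch(
      pearson(run[[ch[1L]]], run[[ch[2L]]]),
      occl_error = function(e) occl_degenerate_error(sprintf(
        "subject %s, run %d, pair %s-%s: %s",
        subject_id, run_index, ch[1L], ch[2L], conditionMessage(e))))
  }
  out
}

#' Per-subject correlation summary table
#'
#' For every run, computes the three pairwise Pearson coefficients
#' (ear-force, ear-EMG, EMG-force) and the two partial coefficients the
#' study reports: ear-force controlling for the EMG envelope, and EMG-force
#' controlling for the ear sensor. Each of the five per-run series is then
#' summarized as its mean and the square root of its unbiased variance
#' across the K runs.
#'
#' Partial coefficients are computed per run from that run's own pairwise
#' coefficients and then averaged, not derived from run-averaged
#' coefficients.
#'
#' @param session an [occl_session()].
#' @return a data frame of class `occl_cortab` with columns `subject`,
#'   `statistic` (`"pearson"` or `"partial"`), `pair`, `mean_r`, `sd_r`,
#'   `n_runs`; the per-run coefficients are kept in the `"runs"` attribute.
#' @examples
#' s <- generate_session(subject_params(seed = 1))
#' correlation_table(s)
#' @export
correlation_table <- function(session) {
  stopifnot(inherits(session, "occl_session"))
  if (session$K < 2L)
    occl_insufficient_data_error("cannot summarize a single-run session")
  per_run <- t(vapply(seq_len(session$K), function(k)
    run_correlations(session$runs[[k]], session$subject_id, k),
    numeric(3)))
  partials <- cbind(
    ear_force = vapply(seq_len(session$K), function(k)
      partial_correlation(per_run[k, "ear_force"], per_run[k, "ear_emg"],
                          per_run[k, "emg_force"]), numeric(1)),
    emg_force = vapply(seq_len(session$K), function(k)
      partial_correlation(per_run[k, "emg_force"], per_run[k, "ear_emg"],
                          per_run[k, "ear_force"]), numeric(1)))
  rows <- rbind(
    data.frame(statistic = "pearson", pair = colnames(per_run),
               t(apply(per_run, 2, summarize_runs))),
    data.frame(statistic = "partial", pair = colnames(partials),
               t(apply(partials, 2, summarize_runs))))
  names(rows)[3:4] <- c("mean_r", "sd_r")
  out <- data.frame(subject = session$subject_id, rows,
                    n_runs = session$K, row.names = NULL)
  attr(out, "runs") <- list(pearson = per_run, partial = partials)
  class(out) <- c("occl_cortab", "data.frame")
  out
}

#' @export
print.occl_cortab <- function(x, digits = 4, ...) {
  cat("Per-run correlation summary (mean and sqrt of unbiased variance over runs)\n")
  df <- as.data.frame(x)
  df$mean_r <- sprintf(paste0("%.", digits, "f"), df$mean_r)
  df$sd_r <- sprintf(paste0("%.", digits, "f"), df$sd_r)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
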