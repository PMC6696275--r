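# Report rendering and pipeline front-end helpers: simulate sessions to
# disk, analyze sessions into correlation and cross-validation tables, and
# write them as CSV plus aligned text. AD-scale statistics are printed to 4
# decimal places; Newton-scale columns are rounded to integers.

#' Simulate a synthetic session and write it to disk
#'
#' Generates a session with [generate_session()] and writes the run CSV
#' files and manifest with [write_session()].
#'
#' @param params a [subject_params()] object.
#' @param dir output directory.
#' @param K number of runs.
#' @param subject_id subject identifier.
#' @return invisibly, the manifest path.
#' @export
simulate_session <- function(params, dir, K = 6L, subject_id = "synthetic") {
  session <- generate_session(params, K = K, subject_id = subject_id)
  write_session(session, dir)
}

#' Correlation report over several sessions
#'
#' Stacks the per-subject [correlation_table()] rows, one block per
#' session, in the shape of the study's correlation tables: per channel
#' pair, the mean and the square root of the unbiased variance of the
#' per-run coefficients.
#'
#' @param sessions list of [occl_session()] objects.
#' @return a data frame of class `occl_cortab`.
#' @export
correlation_report <- function(sessions) {
  tabs <- lapply(sessions, correlation_table)
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  class(out) <- c("occl_cortab", "data.frame")
  out
}

#' Cross-validation report over several sessions
#'
#' One row per subject: the fold-averaged slope with its sqrt unbiased
#' variance, and the independently fold-averaged RMSE, estimate extremes,
#' estimated width and NRMSE. With `newtons = TRUE` the estimate extremes
#' are also converted to Newtons through the AD calibration.
#'
#' @param sessions list of [occl_session()] objects.
#' @param newtons add Newton-scale columns for the estimate extremes.
#' @param calibration an [occl_calibration()] used when `newtons = TRUE`.
#' @return a data frame, one row per subject.
#' @export
evaluation_report <- function(sessions, newtons = FALSE,
                              calibration = occl_calibration()) {
  rows <- lapply(sessions, function(s) {
    cv <- cross_validate(s)
    sm <- cv$summary
    df <- data.frame(subject = s$subject_id,
                     a_bar = sm[["a_bar_mean"]],
                     a_bar_sd = sm[["a_bar_sd"]],
                     rmse = sm[["rmse_mean"]],
                     f_tilde_max = sm[["f_tilde_max_mean"]],
                     f_tilde_min = sm[["f_tilde_min_mean"]],
                     width = sm[["width_mean"]],
                     nrmse = sm[["nrmse_mean"]])
    if (newtons) {
      df$f_max_N <- round(calibrate_force(clamp01(df$f_tilde_max),
                                          calibration))
      df$f_min_N <- round(calibrate_force(clamp01(df$f_tilde_min),
                                          calibration))
    }
    df
  })
  do.call(rbind, rows)
}

format_aligned <- function(df, digits = 4) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(abs(v - round(v)) < .Machine$double.eps & abs(v) >= 100,
           sprintf("%d", as.integer(round(v))),
           sprintf(paste0("%.", digits, "f"), v)))
  utils::capture.output(print.data.frame(df, row.names = FALSE))
}

write_report <- function(df, stem, out_dir, digits = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(out_dir, paste0(stem, ".csv"))
  txt <- file.path(out_dir, paste0(stem, ".txt"))
  utils::write.csv(as.data.frame(df), csv, row.names = FALSE, quote = FALSE)
  writeLines(format_aligned(as.data.frame(df), digits), txt)
  invisible(c(csv = csv, txt = txt))
}

#' Analyze sessions and write correlation and evaluation reports
#'
#' Runs the full analysis over one or more sessions and writes four files
#' to `out_dir`: `correlations.{csv,txt}` (Pearson and partial correlation
#' summaries) and `crossval.{csv,txt}` (per-subject cross-validation
#' summary, optionally with Newton-scale columns).
#'
#' @param sessions list of [occl_session()] objects (or a single session).
#' @param out_dir output directory.
#' @param newtons add Newton-scale columns to the evaluation report.
#' @param calibration an [occl_calibration()].
#' @return invisibly, a list with the two report data frames and the
#'   written file paths.
#' @export
analyze_sessions <- function(sessions, out_dir, newtons = FALSE,
                             calibration = occl_calibration()) {
  if (inherits(sessions, "occl_session")) sessions <- list(sessions)
  cortab <- correlation_report(sessions)
  evtab <- evaluation_report(sessions, newtons = newtons,
                             calibration = calibration)
  files <- c(write_report(cortab, "correlations", out_dir),
             write_report(evtab, "crossval", out_dir))
  invisible(list(correlations = cortab, crossval = evtab, files = files))
}
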