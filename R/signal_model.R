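# Domain types and AD-scale conventions for multi-channel chew recordings.
#
# A run is one 2 s press-and-hold chew trial: 200 samples at 100 Hz of three
# simultaneously recorded channels (optical ear-canal sensor, masseter-EMG
# envelope, occlusal-force meter), each digitized at 12 bit and normalized so
# the 0-3.3 V input range maps onto [0, 1] ("AD units"). A session is one
# subject's ordered collection of K such runs.

#' Number of samples per run (2 s at 100 Hz)
#' @keywords internal
RUN_LENGTH <- 200L

#' Sampling frequency of the acquisition chain, Hz
#' @keywords internal
SAMPLING_HZ <- 100L

AD_STEPS <- 4095L  # 12-bit converter: 2^12 - 1 intervals over 0-3.3 V
AD_VMAX <- 3.3

#' Quantize a voltage to the normalized 12-bit AD scale
#'
#' Models the acquisition chain's analog-to-digital conversion: inputs from
#' 0 V to 3.3 V are digitized at 12-bit resolution and reported on a
#' normalized scale where 0 V maps to 0.0000 and 3.3 V to 1.0000.
#' Round-to-nearest over the 4095 steps, so the endpoints are exact and the
#' quantization error never exceeds half a step (1/8190 in AD units).
#'
#' @param voltage numeric vector of voltages in [0, 3.3].
#' @return numeric vector of AD unit values in [0, 1].
#' @examples
#' quantize_ad(c(0, 1.65, 3.3))
#' @export
quantize_ad <- function(voltage) {
  if (!is.numeric(voltage) || anyNA(voltage))
    occl_range_error("'voltage' must be numeric with no missing values")
  if (any(voltage < 0 | voltage > AD_VMAX))
    occl_range_error(sprintf("voltage outside [0, %.1f] V", AD_VMAX))
  pmin(pmax(round(voltage / AD_VMAX * AD_STEPS) / AD_STEPS, 0), 1)
}

#' Snap AD unit values to the 12-bit grid
#'
#' Same rounding convention as [quantize_ad()] but acting on values already
#' on the normalized [0, 1] scale; used by the synthetic generator to emulate
#' the physical AD path.
#'
#' @param ad numeric vector in [0, 1].
#' @return numeric vector on the 4095-step grid.
#' @export
snap_ad <- function(ad) {
  round(ad * AD_STEPS) / AD_STEPS
}

#' Calibration from AD force values to Newtons
#'
#' The occlusal force meter outputs a liquid-pressure voltage whose
#' AD-converted value is mapped to force in Newtons by an experimentally
#' determined affine relation, F = gain * v + offset, with default constants
#' gain = 1985.6 N per AD unit and offset = -75.066 N.
#'
#' @param gain Newtons per AD unit; must be positive.
#' @param offset intercept in Newtons.
#' @return an object of class `occl_calibration`.
#' @seealso [calibrate_force()]
#' @export
occl_calibration <- function(gain = 1985.6, offset = -75.066) {
  if (!is.numeric(gain) || length(gain) != 1L || !is.finite(gain) || gain <= 0)
    occl_range_error("'gain' must be a single positive number")
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset))
    occl_range_error("'offset' must be a single finite number")
  structure(list(gain = gain, offset = offset), class = "occl_calibration")
}

#' @export
print.occl_calibration <- function(x, ...) {
  cat(sprintf("AD-to-Newton calibration: F = %.4g * v %+.4g N\n",
              x$gain, x$offset))
  invisible(x)
}

#' Convert AD force values to Newtons
#'
#' Applies the affine calibration to normalized AD unit values. The relation
#' is unclamped: values just above zero AD map to slightly negative Newtons,
#' which is reported as-is (the zero-force crossing sits at about 0.0378 AD).
#'
#' @param ad_value numeric vector of AD unit values in [0, 1].
#' @param calibration an [occl_calibration()] object.
#' @return force in Newtons, same length as `ad_value`.
#' @examples
#' round(calibrate_force(c(0.6004, 0.0614)))  # 1117 N, 47 N
#' @export
calibrate_force <- function(ad_value, calibration = occl_calibration()) {
  if (!is.numeric(ad_value) || anyNA(ad_value))
    occl_range_error("'ad_value' must be numeric with no missing values")
  if (any(ad_value < 0 | ad_value > 1))
    occl_range_error("'ad_value' outside [0, 1]")
  stopifnot(inherits(calibration, "occl_calibration"))
  calibration$gain * ad_value + calibration$offset
}

#' Construct a single measurement run
#'
#' A run holds one 2 s chew trial: exactly 200 samples at 100 Hz of the
#' three AD-converted channels. Timestamps are seconds since run start and
#' must advance in constant 0.01 s steps.
#'
#' @param ear,emg,force numeric vectors of AD unit values in [0, 1],
#'   length 200.
#' @param run_index positive integer identifying the run within its session.
#' @param t optional timestamps in seconds; defaults to 0, 0.01, ..., 1.99.
#' @param sampling_hz sampling frequency; the acquisition chain uses 100.
#' @return a data frame of class `occl_run` with columns `t`, `ear`, `emg`,
#'   `force` and attributes `run_index` and `sampling_hz`.
#' @export
occl_run <- function(ear, emg, force, run_index = 1L, t = NULL,
                     sampling_hz = SAMPLING_HZ) {
  n <- length(force)
  if (n != RUN_LENGTH)
    occl_range_error(sprintf("a run must have exactly %d samples, got %d",
                             RUN_LENGTH, n))
  if (length(ear) != n || length(emg) != n)
    occl_range_error("channel lengths differ within run")
  if (is.null(t)) t <- (seq_len(n) - 1L) / sampling_hz
  run <- structure(
    data.frame(t = t, ear = ear, emg = emg, force = force),
    run_index = as.integer(run_index),
    sampling_hz = as.integer(sampling_hz),
    class = c("occl_run", "data.frame"))
  validate_run(run)
}

validate_run <- function(run, where = "run") {
  n <- nrow(run)
  if (n != RUN_LENGTH)
    occl_range_error(sprintf("%s: expected %d samples, got %d",
                             where, RUN_LENGTH, n))
  hz <- attr(run, "sampling_hz")
  for (ch in c("ear", "emg", "force")) {
    v <- run[[ch]]
    if (anyNA(v) || !is.numeric(v))
      occl_parse_error(sprintf("%s: channel '%s' has missing values",
                               where, ch))
    if (any(v < 0 | v > 1))
      occl_range_error(sprintf(
        "%s: channel '%s' outside the [0, 1] AD range", where, ch))
  }
  dt <- diff(run$t)
  if (any(run$t < 0) || any(dt <= 0) ||
      any(abs(dt - 1 / hz) > 1e-9))
    occl_parse_error(sprintf(
      "%s: timestamps must increase in constant 1/%d s steps", where, hz))
  run
}

#' @export
print.occl_run <- function(x, ...) {
  cat(sprintf("Chew run %d: %d samples at %d Hz (%.2f s)\n",
              attr(x, "run_index"), nrow(x), attr(x, "sampling_hz"),
              nrow(x) / attr(x, "sampling_hz")))
  cat(sprintf("  force AD range [%.4f, %.4f], ear AD range [%.4f, %.4f]\n",
              min(x$force), max(x$force), min(x$ear), max(x$ear)))
  invisible(x)
}

#' Construct a measurement session
#'
#' A session is one subject's ordered collection of K runs (the study
#' protocol records K = 6 press-and-hold trials per subject). At least two
#' runs are required so that leave-one-run-out cross-validation has at least
#' one training run per fold.
#'
#' @param subject_id character scalar identifying the subject.
#' @param runs list of [occl_run()] objects.
#' @param sampling_hz sampling frequency shared by all runs.
#' @return an object of class `occl_session` with fields `subject_id`,
#'   `runs`, `K`, `sampling_hz`.
#' @export
occl_session <- function(subject_id, runs, sampling_hz = SAMPLING_HZ) {
  if (!is.character(subject_id) || length(subject_id) != 1L)
    occl_parse_error("'subject_id' must be a single string")
  if (!is.list(runs) || length(runs) < 2L)
    occl_insufficient_data_error(
      "a session needs at least 2 runs (one training run per fold)")
  for (i in seq_along(runs)) {
    if (!inherits(runs[[i]], "occl_run"))
      occl_parse_error(sprintf("runs[[%d]] is not an 'occl_run'", i))
    validate_run(runs[[i]],
                 where = sprintf("subject %s run %d", subject_id, i))
  }
  structure(list(subject_id = subject_id, runs = runs,
                 K = length(runs), sampling_hz = as.integer(sampling_hz)),
            class = "occl_session")
}

#' @export
print.occl_session <- function(x, ...) {
  cat(sprintf("Measurement session: subject %s, K = %d runs of %d samples at %d Hz\n",
              x$subject_id, x$K, nrow(x$runs[[1L]]), x$sampling_hz))
  invisible(x)
}

#' Extract the 2 s press window from a longer recording
#'
#' The analysis consumes exactly the 200-sample press window; recordings that
#' include lead-in or the relax phase are windowed by locating the first
#' sample whose force channel reaches an onset threshold and taking the 200
#' samples from there.
#'
#' @param long_run data frame with columns `t`, `ear`, `emg`, `force`
#'   (any length >= 200).
#' @param onset_threshold force AD value that marks press onset.
#' @param run_index run index for the resulting [occl_run()].
#' @param sampling_hz sampling frequency.
#' @return an [occl_run()] of the 200 samples starting at the crossing,
#'   with timestamps rebased to start at 0.
#' @export
extract_window <- function(long_run, onset_threshold = 0.05, run_index = 1L,
                           sampling_hz = SAMPLING_HZ) {
  if (nrow(long_run) < RUN_LENGTH)
    occl_extraction_error(sprintf(
      "recording has %d samples; %d needed", nrow(long_run), RUN_LENGTH))
  hit <- which(long_run$force >= onset_threshold)
  if (length(hit) == 0L)
    occl_extraction_error(sprintf(
      "force never reaches the onset threshold %.4f", onset_threshold))
  start <- hit[1L]
  if (start + RUN_LENGTH - 1L > nrow(long_run))
    occl_extraction_error(sprintf(
      "only %d samples after onset at sample %d; %d needed",
      nrow(long_run) - start + 1L, start, RUN_LENGTH))
  idx <- start:(start + RUN_LENGTH - 1L)
  occl_run(ear = long_run$ear[idx], emg = long_run$emg[idx],
           force = long_run$force[idx], run_index = run_index,
           sampling_hz = sampling_hz)
}

# ---- file I/O ---------------------------------------------------------------
# Run CSV: header t_s,ear_ad,emg_ad,force_ad, one row per sample, UTF-8.
# Session manifest: YAML with subject_id, sampling_hz and the ordered run
# file paths (relative to the manifest's directory).

#' Write a session to run CSV files plus a manifest
#'
#' @param session an [occl_session()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest path.
#' @seealso [read_session()]
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "occl_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run_files <- sprintf("%s_run%02d.csv", session$subject_id,
                       seq_len(session$K))
  for (k in seq_len(session$K)) {
    run <- session$runs[[k]]
    df <- data.frame(t_s = run$t, ear_ad = run$ear, emg_ad = run$emg,
                     force_ad = run$force)
    utils::write.csv(df, file.path(dir, run_files[k]), row.names = FALSE,
                     quote = FALSE)
  }
  manifest <- file.path(dir, sprintf("%s_manifest.yml", session$subject_id))
  yaml::write_yaml(list(subject_id = session$subject_id,
                        sampling_hz = session$sampling_hz,
                        runs = as.list(run_files)),
                   manifest)
  invisible(manifest)
}

read_run_csv <- function(path, run_index, sampling_hz, window_extract = FALSE,
                         onset_threshold = 0.05) {
  if (!file.exists(path))
    occl_parse_error(sprintf("run file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) occl_parse_error(
      sprintf("%s: %s", path, conditionMessage(e))))
  need <- c("t_s", "ear_ad", "emg_ad", "force_ad")
  if (!all(need %in% names(df)))
    occl_parse_error(sprintf(
      "%s: header must contain %s", path, paste(need, collapse = ",")))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    occl_parse_error(sprintf("%s: non-numeric or missing value at data line %d",
                             path, bad[1L]))
  long <- data.frame(t = df$t_s, ear = df$ear_ad, emg = df$emg_ad,
                     force = df$force_ad)
  if (nrow(long) != RUN_LENGTH && !window_extract)
    occl_parse_error(sprintf(
      "%s: %d rows; a run must have exactly %d samples (set window_extract = TRUE to locate the press window)",
      path, nrow(long), RUN_LENGTH))
  out <- tryCatch({
    if (nrow(long) == RUN_LENGTH && !window_extract)
      occl_run(ear = long$ear, emg = long$emg, force = long$force,
               run_index = run_index, t = long$t, sampling_hz = sampling_hz)
    else
      extract_window(long, onset_threshold = onset_threshold,
                     run_index = run_index, sampling_hz = sampling_hz)
  }, occl_error = function(e) occl_parse_error(
    sprintf("%s: %s", path, conditionMessage(e))))
  out
}

#' Read a session from a manifest of run CSV files
#'
#' @param manifest path to a session manifest (YAML listing `subject_id`,
#'   `sampling_hz` and the ordered run files).
#' @param window_extract if TRUE, run files longer than 200 samples are
#'   windowed with [extract_window()]; otherwise they are rejected.
#' @param onset_threshold onset threshold passed to [extract_window()].
#' @return an [occl_session()].
#' @export
read_session <- function(manifest, window_extract = FALSE,
                         onset_threshold = 0.05) {
  if (!file.exists(manifest))
    occl_parse_error(sprintf("manifest not found: %s", manifest))
  meta <- tryCatch(yaml::read_yaml(manifest),
                   error = function(e) occl_parse_error(
                     sprintf("%s: %s", manifest, conditionMessage(e))))
  for (field in c("subject_id", "sampling_hz", "runs"))
    if (is.null(meta[[field]]))
      occl_parse_error(sprintf("%s: manifest missing '%s'", manifest, field))
  base <- dirname(manifest)
  runs <- vector("list", length(meta$runs))
  for (k in seq_along(meta$runs)) {
    runs[[k]] <- read_run_csv(file.path(base, meta$runs[[k]]),
                              run_index = k,
                              sampling_hz = as.integer(meta$sampling_hz),
                              window_extract = window_extract,
                              onset_threshold = onset_threshold)
  }
  occl_session(subject_id = as.character(meta$subject_id), runs = runs,
               sampling_hz = as.integer(meta$sampling_hz))
}
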