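# Seeded synthetic session generator.
#
# Emulates the press-and-hold chew protocol: per run, a latent occlusal-force
# signal ramps monotonically over 2 s from a baseline to a per-run peak. The
# ear channel is an affine function of the latent force with a
# subject-specific signed slope (the coupling sign differs between subjects
# because ear-canal geometry differs), a per-run offset drift (the run-to-run
# traces form near-parallel lines), and per-sample measurement noise. The
# EMG envelope is a noisy monotone (linear by default) function of the
# latent force. Recorded channels get independent Gaussian measurement
# noise, are clamped to the [0, 1] AD range and optionally snapped to the
# 12-bit grid, matching the physical AD path.

#' Parameters of a synthetic subject
#'
#' Defaults are modelled on the best-behaved subject of the study protocol:
#' a force ramp from about 0.06 to 0.60 AD (roughly 45 N to 1100 N), an
#' ear-force coupling slope of -16.1 AD-force per AD-ear, small per-run ear
#' offset drift, and per-sample noise scales chosen so the per-run channel
#' correlations are high but imperfect (|r| around 0.98-0.99).
#'
#' @param slope signed coupling df/de, AD-force per AD-ear; nonzero.
#' @param e_base baseline ear AD value at force baseline.
#' @param f_base,f_peak baseline and peak force AD values; `f_base < f_peak
#'   <= 1`.
#' @param drift_sd standard deviation of the per-run ear offset (AD units).
#' @param noise_ear_sd,noise_emg_sd,noise_force_sd per-sample measurement
#'   noise scales (AD units).
#' @param emg_gain EMG envelope AD units per force AD unit.
#' @param emg_base EMG envelope baseline AD value.
#' @param peak_jitter_sd relative standard deviation of the per-run peak
#'   (the per-run peak is `f_peak * (1 + jitter)`).
#' @param quantize snap generated channels to the 12-bit AD grid
#'   (default TRUE, matching the acquisition hardware).
#' @param seed integer master seed for [generate_session()].
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(slope = -16.1,
                           e_base = 0.55,
                           f_base = 0.06,
                           f_peak = 0.60,
                           drift_sd = 0.01,
                           noise_ear_sd = 0.0015,
                           noise_emg_sd = 0.06,
                           noise_force_sd = 0.005,
                           emg_gain = 1.2,
                           emg_base = 0.08,
                           peak_jitter_sd = 0.03,
                           quantize = TRUE,
                           seed = 1L) {
  p <- list(slope = slope, e_base = e_base, f_base = f_base, f_peak = f_peak,
            drift_sd = drift_sd, noise_ear_sd = noise_ear_sd,
            noise_emg_sd = noise_emg_sd, noise_force_sd = noise_force_sd,
            emg_gain = emg_gain, emg_base = emg_base,
            peak_jitter_sd = peak_jitter_sd, quantize = isTRUE(quantize),
            seed = as.integer(seed))
  validate_subject_params(p)
  structure(p, class = "subject_params")
}

validate_subject_params <- function(p) {
  num <- c("slope", "e_base", "f_base", "f_peak", "drift_sd", "noise_ear_sd",
           "noise_emg_sd", "noise_force_sd", "emg_gain", "emg_base",
           "peak_jitter_sd")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      occl_range_error(sprintf("'%s' must be a single finite number", f))
  if (p$slope == 0) occl_range_error("'slope' must be nonzero")
  if (!(p$f_base < p$f_peak && p$f_peak <= 1))
    occl_range_error("need f_base < f_peak <= 1")
  for (f in c("e_base", "f_base", "drift_sd", "noise_ear_sd", "noise_emg_sd",
              "noise_force_sd", "emg_base", "peak_jitter_sd"))
    if (p[[f]] < 0) occl_range_error(sprintf("'%s' must be >= 0", f))
  if (is.na(p$seed)) occl_range_error("'seed' must be an integer")
  invisible(p)
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("Synthetic subject: slope %.4g, force ramp %.3f -> %.3f AD, seed %d\n",
              x$slope, x$f_base, x$f_peak, x$seed))
  cat(sprintf("  drift sd %.4g | noise sd (ear %.4g, emg %.4g, force %.4g) | quantize %s\n",
              x$drift_sd, x$noise_ear_sd, x$noise_emg_sd, x$noise_force_sd,
              x$quantize))
  invisible(x)
}

# Run the body with the session RNG untouched from the caller's viewpoint
# is NOT wanted here: generators consume the ambient stream so that a single
# set.seed() at session level drives every run reproducibly.

smoothstep <- function(u) u * u * (3 - 2 * u)

#' Latent force profile of one press-and-hold run
#'
#' The noise-free monotone ramp a run's three channels are coupled to: a
#' smoothstep from `f_base` to a per-run peak `f_peak * (1 + jitter)`
#' (jitter drawn from the ambient RNG stream, clamped so the peak stays in
#' (f_base, 1]). Measurement noise is added later, per recorded channel, in
#' [generate_run()].
#'
#' @param params a [subject_params()] object.
#' @param n_samples number of samples (200 at 100 Hz over 2 s).
#' @return numeric vector: the latent force series in AD units.
#' @export
generate_force_profile <- function(params, n_samples = RUN_LENGTH) {
  stopifnot(inherits(params, "subject_params"))
  jitter <- if (params$peak_jitter_sd > 0)
    stats::rnorm(1L, 0, params$peak_jitter_sd) else 0
  peak <- min(params$f_peak * (1 + jitter), 1)
  peak <- max(peak, params$f_base + 1e-6)
  u <- (seq_len(n_samples) - 1L) / (n_samples - 1L)
  params$f_base + (peak - params$f_base) * smoothstep(u)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one synthetic run
#'
#' Draws the latent force ramp, couples the ear channel to it through the
#' subject's signed slope plus a per-run offset drift, couples the EMG
#' envelope linearly, then applies per-channel Gaussian measurement noise,
#' clamping to [0, 1] and (optionally) 12-bit quantization. Consumes the
#' ambient RNG stream; seed at session level via [generate_session()].
#'
#' A warning is issued when more than 5% of samples in any channel were
#' clamped, since heavy clamping distorts the affine coupling the analysis
#' assumes.
#'
#' @param params a [subject_params()] object.
#' @param run_index index of the run within its session.
#' @return an [occl_run()].
#' @export
generate_run <- function(params, run_index = 1L) {
  stopifnot(inherits(params, "subject_params"))
  n <- RUN_LENGTH
  latent <- generate_force_profile(params, n)
  delta_r <- if (params$drift_sd > 0)
    stats::rnorm(1L, 0, params$drift_sd) else 0
  ear_raw <- params$e_base + delta_r + (latent - params$f_base) / params$slope +
    noise_vec(n, params$noise_ear_sd)
  emg_raw <- params$emg_base + params$emg_gain * (latent - params$f_base) +
    noise_vec(n, params$noise_emg_sd)
  force_raw <- latent + noise_vec(n, params$noise_force_sd)
  chans <- list(ear = ear_raw, emg = emg_raw, force = force_raw)
  for (ch in names(chans)) {
    clamped <- mean(chans[[ch]] < 0 | chans[[ch]] > 1)
    if (clamped > 0.05)
      warning(sprintf(
        "run %d: %.0f%% of '%s' samples clamped to [0, 1]; parameters drive the channel out of range",
        run_index, 100 * clamped, ch), call. = FALSE)
    v <- clamp01(chans[[ch]])
    chans[[ch]] <- if (params$quantize) snap_ad(v) else v
  }
  occl_run(ear = chans$ear, emg = chans$emg, force = chans$force,
           run_index = run_index)
}

noise_vec <- function(n, sd) {
  if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
}

#' Generate a synthetic measurement session
#'
#' Produces K runs from the subject's master seed. Fully deterministic:
#' the same `(params, K)` yields bit-identical sessions. The caller's RNG
#' state is preserved.
#'
#' @param params a [subject_params()] object.
#' @param K number of runs (the study protocol uses 6).
#' @param subject_id subject identifier.
#' @return an [occl_session()].
#' @examples
#' s1 <- generate_session(subject_params(seed = 7))
#' s2 <- generate_session(subject_params(seed = 7))
#' identical(s1, s2)
#' @export
generate_session <- function(params, K = 6L, subject_id = "synthetic") {
  stopifnot(inherits(params, "subject_params"))
  K <- as.integer(K)
  if (is.na(K) || K < 2L)
    occl_range_error("'K' must be an integer >= 2")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed))
  set.seed(params$seed)
  runs <- lapply(seq_len(K), function(k) generate_run(params, k))
  occl_session(subject_id = subject_id, runs = runs)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Five preset synthetic subjects
#'
#' Analogues of the study's five subjects: three with negative and two with
#' positive ear-force coupling, with per-subject slopes and force ranges
#' matching the published per-subject estimates (slope magnitudes between
#' about 9 and 23, force ramps peaking between about 0.26 and 0.60 AD).
#'
#' @param seed base seed; subject s gets seed `seed + s`.
#' @param ... overrides passed to every [subject_params()] call
#'   (e.g. `quantize = FALSE`).
#' @return named list of five [subject_params()] objects (`A` to `E`).
#' @export
preset_subjects <- function(seed = 20L, ...) {
  presets <- list(
    A = list(slope = -16.1064, e_base = 0.55, f_base = 0.060, f_peak = 0.60),
    B = list(slope = -22.8559, e_base = 0.50, f_base = 0.045, f_peak = 0.44),
    C = list(slope = 12.0029, e_base = 0.35, f_base = 0.054, f_peak = 0.26),
    D = list(slope = -8.9634, e_base = 0.60, f_base = 0.054, f_peak = 0.27),
    E = list(slope = 18.7544, e_base = 0.30, f_base = 0.018, f_peak = 0.45))
  extra <- list(...)
  out <- vector("list", length(presets))
  names(out) <- names(presets)
  for (s in seq_along(presets)) {
    args <- c(presets[[s]], extra)
    args$seed <- as.integer(seed) + s
    out[[s]] <- do.call(subject_params, args)
  }
  out
}

#' Read subject parameters from a key-value file
#'
#' Reads a YAML file whose keys match the arguments of [subject_params()].
#'
#' @param path file path.
#' @return a [subject_params()] object.
#' @export
read_subject_params <- function(path) {
  if (!file.exists(path))
    occl_parse_error(sprintf("parameter file not found: %s", path))
  kv <- tryCatch(yaml::read_yaml(path),
                 error = function(e) occl_parse_error(
                   sprintf("%s: %s", path, conditionMessage(e))))
  known <- names(formals(subject_params))
  bad <- setdiff(names(kv), known)
  if (length(bad))
    occl_parse_error(sprintf("%s: unknown parameter(s): %s", path,
                             paste(bad, collapse = ", ")))
  do.call(subject_params, kv)
}
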