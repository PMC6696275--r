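# Independent oracles and fixture builders used across the suite.

# Dense grid search over (a, b) minimizing sum((f - a*e - b)^2), refined over
# several stages. Independent of the closed-form slope estimator: it only
# evaluates the objective (via its sufficient-statistic expansion) on a grid
# and picks the argmin. Returns the slope and the final grid step.
grid_ls_slope <- function(e, f, a_range = c(-60, 60), stages = 3L,
                          n_grid = 601L) {
  n <- length(e)
  Se <- sum(e); Sf <- sum(f); See <- sum(e^2); Sef <- sum(e * f)
  Sff <- sum(f^2)
  sse <- function(a, b) Sff - 2 * a * Sef - 2 * b * Sf + a^2 * See +
    2 * a * b * Se + n * b^2
  b_range <- range(f) + c(-1, 1) * max(abs(a_range)) * max(abs(e))
  best <- c(a = NA_real_, b = NA_real_)
  a_step <- NA_real_
  for (s in seq_len(stages)) {
    a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
    b_grid <- seq(b_range[1], b_range[2], length.out = n_grid)
    obj <- outer(a_grid, b_grid, sse)
    idx <- arrayInd(which.min(obj), dim(obj))
    best <- c(a = a_grid[idx[1]], b = b_grid[idx[2]])
    a_step <- diff(a_range) / (n_grid - 1)
    b_step <- diff(b_range) / (n_grid - 1)
    # the SSE surface is an elongated valley in (a, b); keep a wide window
    # around the coarse argmin so refinement cannot exclude the optimum
    a_range <- best["a"] + c(-4, 4) * a_step
    b_range <- best["b"] + c(-4, 4) * b_step
  }
  list(a = unname(best["a"]), step = a_step)
}

# Residual-regression oracle for the first-order partial correlation:
# correlation of the residuals of x and y after each is regressed on z.
partial_cor_residual_oracle <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# Random (x, y, z) triple with a valid, non-degenerate correlation matrix:
# linear mixtures of independent normals plus noise.
random_correlated_triple <- function(n = 50L) {
  base <- matrix(stats::rnorm(n * 3L), n, 3L)
  mix <- matrix(stats::runif(9L, -1, 1), 3L, 3L)
  diag(mix) <- diag(mix) + 2 * sign(diag(mix) + 1e-9)
  d <- base %*% mix + 0.2 * matrix(stats::rnorm(n * 3L), n, 3L)
  list(x = d[, 1L], y = d[, 2L], z = d[, 3L])
}

# Noise-free session whose channels are exact affine functions of a monotone
# latent ramp; built directly (not via the generator) so generator and
# estimator can be checked against each other.
affine_session <- function(a = -16, K = 3L, e_base = 0.55, f_base = 0.06,
                           f_peak = 0.6, emg_gain = 1.2, emg_base = 0.08,
                           subject_id = "affine") {
  u <- (0:199) / 199
  ramp <- f_base + (f_peak - f_base) * u^2 * (3 - 2 * u)
  runs <- lapply(seq_len(K), function(k)
    occl_run(ear = e_base + (ramp - f_base) / a,
             emg = emg_base + emg_gain * (ramp - f_base),
             force = ramp, run_index = k))
  occl_session(subject_id, runs)
}

# Rebuild a session with transformed channels (channel name -> function).
transform_session <- function(session, ...) {
  fns <- list(...)
  runs <- lapply(session$runs, function(run) {
    cols <- list(ear = run$ear, emg = run$emg, force = run$force)
    for (ch in names(fns)) cols[[ch]] <- fns[[ch]](cols[[ch]])
    occl_run(ear = cols$ear, emg = cols$emg, force = cols$force,
             run_index = attr(run, "run_index"))
  })
  occl_session(session$subject_id, runs)
}
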