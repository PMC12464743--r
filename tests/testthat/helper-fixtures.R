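# Programmatic fixtures shared across test files. Everything is generated in
# code; nothing is read from disk.

# Pulse train: one raised-cosine pulse per beat at `ibi` second spacing.
make_pulse_train <- function(duration = 60, ibi = 1, fs = 400, width = 0.3,
                             amplitude = 1) {
  tt <- seq(0, duration, by = 1 / fs)
  x <- numeric(length(tt))
  beats <- seq(width, duration - width, by = ibi)
  hw <- round(width / 2 * fs)
  for (bt in beats) {
    bi <- round(bt * fs) + 1
    lo <- max(1L, bi - hw)
    hi <- min(length(tt), bi + hw)
    x[lo:hi] <- x[lo:hi] +
      amplitude * 0.5 * (1 + cos(2 * pi * (tt[lo:hi] - tt[bi]) / width))
  }
  list(x = x, t = tt, beats = beats, fs = fs)
}

# Small deterministic ROI-by-time fixture with reproducible noise.
make_random_matrix <- function(R = 10, T_ = 100, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(R * T_), R, T_))
}

# Tiny simulated dataset for fast model tests.
make_tiny_dataset <- function(n_scans = 12, n_rois = 8, n_frames = 120,
                              noise_sd = 0.5, seed = 5) {
  simulate_dataset(sim_config(n_scans = n_scans, n_rois = n_rois,
                              n_frames = n_frames, noise_sd = noise_sd,
                              zero_frac = 0, seed = seed))
}

# Independent brute-force OLS residual used as an oracle in several files.
brute_ols_residual <- function(y, X) {
  A <- cbind(1, X)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  as.numeric(y - A %*% beta)
}
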