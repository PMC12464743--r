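# Shared zero-phase filtering and detrending helpers.
#
# All band-pass filtering in the package is a 2nd-order Butterworth design
# applied forward and backward (signal::filtfilt), i.e. zero phase, so the
# timing relationship between physiology and BOLD is preserved.

# Zero-phase Butterworth band-pass. `x` numeric, `dt` sampling step (s),
# `band` c(f_lo, f_hi) in Hz.
bp_filtfilt <- function(x, dt, band, order = 2L) {
  stopifnot(length(band) == 2L, dt > 0)
  fs <- 1 / dt
  nyq <- fs / 2
  if (!(band[1] < band[2])) stop("band must satisfy f_lo < f_hi")
  if (band[2] >= nyq) {
    stop(sprintf("upper band edge %.4g Hz is not below Nyquist %.4g Hz",
                 band[2], nyq))
  }
  flt <- signal::butter(order, band / nyq, type = "pass")
  min_len <- 3L * max(length(flt$b), length(flt$a))
  if (length(x) < min_len) stop("series too short to filter")
  as.numeric(signal::filtfilt(flt, x))
}

# Remove the OLS-best linear + quadratic trend from a series.
detrend_poly2 <- function(x) {
  n <- length(x)
  t1 <- seq_len(n) - (n + 1) / 2
  basis <- cbind(1, t1, t1^2)
  fit <- lm.fit(basis, x)
  as.numeric(fit$residuals)
}

# Keep frames 1, 1+factor, 1+2*factor, ... (deterministic phase).
decimate_keep <- function(x, factor) {
  stopifnot(factor >= 1, factor == as.integer(factor))
  x[seq(1L, length(x), by = as.integer(factor))]
}
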