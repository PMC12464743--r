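#' Respiration and cardiac response functions
#'
#' Canonical impulse responses mapping slow fluctuations in respiration
#' variation and heart rate to BOLD signal change. The respiration response
#' function (RRF) is the difference of two gamma-like terms
#' (Birn and colleagues' published form),
#' \deqn{RRF(t) = 0.6\,t^{2.1} e^{-t/1.6} - 0.0023\,t^{3.54} e^{-t/4.25},}
#' and the cardiac response function (CRF) is a gamma-like term minus a
#' Gaussian centered near 12 s (Chang and colleagues' published form),
#' \deqn{CRF(t) = 0.6\,t^{2.7} e^{-t/1.6} -
#'   \frac{16}{\sqrt{2\pi\cdot 9}} e^{-(t-12)^2/18}.}
#' Both kernels are causal and negligible beyond about 50 s.
#'
#' @param kind `"rrf"` or `"crf"`.
#' @param t Non-negative times (s).
#' @return Kernel values at `t`.
#' @export
response_function_eval <- function(kind = c("rrf", "crf"), t) {
  kind <- match.arg(kind)
  if (any(t < 0)) stop("response functions are causal: t must be >= 0")
  if (kind == "rrf") {
    0.6 * t^2.1 * exp(-t / 1.6) - 0.0023 * t^3.54 * exp(-t / 4.25)
  } else {
    0.6 * t^2.7 * exp(-t / 1.6) - (16 / sqrt(2 * pi * 9)) *
      exp(-(t - 12)^2 / 18)
  }
}

#' Sample a response function on a regular grid
#'
#' @param kind `"rrf"` or `"crf"`.
#' @param support Kernel duration (s). Both canonical kernels decay to under
#'   5\% of their peak magnitude well before the 60 s default.
#' @param dt Sampling step (s).
#' @return A `response_function` object with `times` and `values`.
#' @export
response_function <- function(kind = c("rrf", "crf"), support = 60, dt) {
  kind <- match.arg(kind)
  stopifnot(support > 0, dt > 0)
  times <- seq(0, support, by = dt)
  structure(list(kind = kind, support = support, dt = dt, times = times,
                 values = response_function_eval(kind, times)),
            class = "response_function")
}

#' Physiological regressors with time and dispersion derivatives
#'
#' Builds the three-column basis for one physiological signal: the causal
#' convolution with the canonical kernel, its temporal derivative (first
#' difference, leading 0), and a dispersion derivative (finite difference of
#' the convolution over a stretch of the kernel time axis by `1 + eps`,
#' divided by `eps`). The basis absorbs small deviations in response latency
#' and shape from the canonical model. All columns are mean-centered.
#'
#' @param signal Frame-aligned physiological series (typically z-scored).
#' @param dt Frame spacing (s).
#' @param kind `"rrf"` (for RV) or `"crf"` (for HR).
#' @param support Kernel support (s).
#' @param eps Dispersion stretch factor.
#' @return T x 3 matrix with columns `<kind>`, `<kind>_tderiv`,
#'   `<kind>_dderiv`.
#' @export
build_physio_regressors <- function(signal, dt, kind = c("rrf", "crf"),
                                    support = 60, eps = 0.1) {
  kind <- match.arg(kind)
  n <- length(signal)
  if (diff(range(signal)) == 0) {
    warning("degenerate regressors: input signal is constant")
  }
  if (n * dt < 3 * support) {
    warning("series spans fewer than 3 kernel supports; ",
            "regressors may be poorly conditioned")
  }
  times <- seq(0, support, by = dt)
  canonical <- causal_conv(signal, response_function_eval(kind, times), dt)
  stretched <- causal_conv(signal,
                           response_function_eval(kind, times / (1 + eps)),
                           dt)
  tderiv <- c(0, diff(canonical))
  dderiv <- (stretched - canonical) / eps
  out <- cbind(canonical, tderiv, dderiv)
  colnames(out) <- paste0(kind, c("", "_tderiv", "_dderiv"))
  if (any(apply(out, 2, function(x) diff(range(x)) == 0))) {
    warning("degenerate (constant) regressor column for kind ", kind)
  }
  sweep(out, 2, colMeans(out))
}

# Discrete causal convolution truncated to the signal length, scaled by dt
# so amplitudes approximate the continuous-time integral.
causal_conv <- function(x, kern, dt) {
  n <- length(x)
  full <- convolve(x, rev(kern), type = "open")
  full[seq_len(n)] * dt
}

#' Joint RV + HR regressor set
#'
#' The six-column basis used throughout the variance-explained and
#' connectivity analyses: RV convolved with the RRF and HR with the CRF,
#' each with temporal and dispersion derivatives.
#'
#' @param rv,hr Frame-aligned (typically z-scored) physiological series.
#' @param dt Frame spacing (s).
#' @param ... Passed to [build_physio_regressors()].
#' @return T x 6 mean-centered matrix.
#' @export
physio_regressor_set <- function(rv, hr, dt, ...) {
  stopifnot(length(rv) == length(hr))
  cbind(build_physio_regressors(rv, dt, "rrf", ...),
        build_physio_regressors(hr, dt, "crf", ...))
}

#' Percent of temporal variance explained by a regressor set
#'
#' The fraction by which a signal's temporal variance is reduced after
#' projecting out (via ordinary least squares, with an intercept) a linear
#' combination of the regressors, times 100. Negative values (possible on
#' held-out application) are clipped to 0. Linearly dependent regressor
#' columns are dropped with a warning.
#'
#' @param y Signal (non-constant numeric series).
#' @param X Regressor matrix (T x K).
#' @return Percent in \[0, 100\].
#' @export
percent_variance_explained <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  if (diff(range(y)) == 0) stop("y is constant: variance undefined")
  if (n <= ncol(X) + 1) stop("need more frames than regressors")
  res <- ols_residual(y, X)
  max(0, 100 * (1 - var(res) / var(y)))
}

# OLS residual of y on [1, X], dropping aliased columns.
ols_residual <- function(y, X) {
  A <- cbind(`(intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    drop_cols <- qrA$pivot[(qrA$rank + 1):ncol(A)]
    warning("dropping linearly dependent regressor column(s): ",
            paste(colnames(A)[drop_cols], collapse = ", "))
    A <- A[, qrA$pivot[seq_len(qrA$rank)], drop = FALSE]
    qrA <- qr(A)
  }
  as.numeric(qr.resid(qrA, y))
}

#' Per-ROI percent-variance-explained map
#'
#' Builds the joint six-column RV/HR regressor set and applies
#' [percent_variance_explained()] to every ROI row. Group-level maps are the
#' arithmetic mean of per-scan maps.
#'
#' @param ts A [roi_timeseries()] or plain R x T matrix.
#' @param rv,hr Frame-aligned physiological series (length T).
#' @param dt Frame spacing (s); taken from `ts` when it is a
#'   `roi_timeseries`.
#' @param ... Passed to [physio_regressor_set()].
#' @return Tibble with `roi_id` and `pct_var`.
#' @export
variance_explained_map <- function(ts, rv, hr, dt = NULL, ...) {
  if (inherits(ts, "roi_timeseries")) {
    dt <- dt %||% ts$dt
    ids <- ts$roi_ids
    mat <- ts$data
  } else {
    mat <- as.matrix(ts)
    ids <- seq_len(nrow(mat))
    if (is.null(dt)) stop("dt required for a plain matrix")
  }
  stopifnot(ncol(mat) == length(rv))
  X <- physio_regressor_set(rv, hr, dt, ...)
  const <- apply(mat, 1, function(x) diff(range(x)) == 0)
  if (any(const)) {
    warning("constant ROI rows scored as NA: ",
            paste(ids[const], collapse = ", "))
  }
  tibble(roi_id = ids,
         pct_var = vapply(seq_len(nrow(mat)), function(r) {
           if (const[r]) return(NA_real_)
           percent_variance_explained(mat[r, ], X)
         }, numeric(1)))
}
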