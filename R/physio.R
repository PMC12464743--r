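#' Raw physiological recording
#'
#' Container for the raw respiration-belt and pulse-oximetry (PPG) waveforms
#' acquired alongside an fMRI scan. Either channel may be missing; a missing
#' channel is a quality-control finding, not an error. Amplitudes are
#' arbitrary ADC units; the HCP dialect records integers saturating at 0 and
#' 4095, which is the default saturation range used by [qc_physio()].
#'
#' @param resp Numeric respiration waveform, or `NULL` if absent.
#' @param ppg Numeric pulse-oximetry waveform, or `NULL` if absent.
#' @param fs Sampling rate in Hz (HCP physiological recordings: 400 Hz).
#' @param adc_min,adc_max Saturation bounds of the digitizer.
#' @return An object of class `raw_physio`.
#' @export
raw_physio <- function(resp = NULL, ppg = NULL, fs, adc_min = 0,
                       adc_max = 4095) {
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!is.null(resp) && !is.null(ppg) && length(resp) != length(ppg)) {
    stop("resp and ppg must have equal length when both present")
  }
  if (is.null(resp) && is.null(ppg)) {
    warning("both physiological channels are missing")
  }
  structure(
    list(resp = resp, ppg = ppg, fs = fs,
         adc_min = adc_min, adc_max = adc_max),
    class = "raw_physio"
  )
}

#' @export
print.raw_physio <- function(x, ...) {
  n <- length(x$resp %||% x$ppg)
  cat(sprintf("<raw_physio> %.1f s at %g Hz; resp: %s, ppg: %s\n",
              n / x$fs, x$fs,
              if (is.null(x$resp)) "missing" else "present",
              if (is.null(x$ppg)) "missing" else "present"))
  invisible(x)
}

#' Detect cardiac beats in a pulse-oximetry waveform
#'
#' Local-maxima detection on a lightly smoothed waveform with an adaptive
#' amplitude threshold and a refractory period. The threshold is anchored at
#' the 60th percentile of the smoothed signal and raised by a fraction of the
#' remaining amplitude range above it, which rejects baseline noise maxima
#' while tracking per-recording gain. Within the refractory period the
#' larger peak wins.
#'
#' @param ppg Numeric pulse waveform.
#' @param fs Sampling rate (Hz).
#' @param refractory Minimum allowed inter-beat interval (s).
#' @param smooth_width Moving-average smoothing width (s).
#' @param base_quantile Quantile of the smoothed signal anchoring the
#'   threshold.
#' @param range_frac Fraction of (max - anchor) added on top of the anchor.
#' @return Numeric vector of strictly increasing beat times (s); sample `k`
#'   is at time `(k - 1) / fs`. A constant waveform yields an empty vector
#'   (callers flag it through QC).
#' @export
detect_beats <- function(ppg, fs, refractory = 0.25, smooth_width = 0.05,
                         base_quantile = 0.6, range_frac = 0.25) {
  stopifnot(fs > 0)
  if (length(ppg) < 2 * fs) stop("insufficient waveform")
  if (diff(range(ppg)) == 0) return(numeric(0))

  w <- max(1L, round(smooth_width * fs))
  if (w %% 2 == 0) w <- w + 1L
  kern <- rep(1 / w, w)
  sm <- as.numeric(stats::filter(ppg, kern, sides = 2))
  # moving average is undefined at the very edges; hold the nearest value
  sm <- zoo_na_fill(sm)

  anchor <- quantile(sm, base_quantile, names = FALSE)
  thr <- anchor + range_frac * (max(sm) - anchor)

  n <- length(sm)
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                 sm[2:(n - 1)] >= sm[3:n], FALSE) & sm >= thr
  idx <- which(is_peak)
  if (length(idx) == 0) return(numeric(0))

  times <- (idx - 1) / fs
  amps <- sm[idx]
  keep_t <- times[1]
  keep_a <- amps[1]
  if (length(idx) > 1) {
    for (i in 2:length(idx)) {
      last <- length(keep_t)
      if (times[i] - keep_t[last] < refractory) {
        if (amps[i] > keep_a[last]) {  # larger peak replaces the held one
          keep_t[last] <- times[i]
          keep_a[last] <- amps[i]
        }
      } else {
        keep_t <- c(keep_t, times[i])
        keep_a <- c(keep_a, amps[i])
      }
    }
  }
  keep_t
}

# nearest-value fill for leading/trailing NAs produced by symmetric filters
zoo_na_fill <- function(x) {
  ok <- which(!is.na(x))
  if (length(ok) == 0) return(x)
  x[seq_len(ok[1] - 1)] <- x[ok[1]]
  nlast <- ok[length(ok)]
  if (nlast < length(x)) x[(nlast + 1):length(x)] <- x[nlast]
  x
}

#' Heart rate from detected beats
#'
#' HR at each fMRI frame is the inverse of the mean inter-beat interval
#' (IBI), in beats per minute, over a sliding window centered at the frame.
#' An IBI belongs to a window when its midpoint falls inside it. Frames whose
#' window holds fewer than two beats are filled by linear interpolation from
#' the nearest valid frames (nearest value at the ends).
#'
#' @param beats Strictly increasing beat times (s), e.g. from
#'   [detect_beats()].
#' @param frame_times Centers of the fMRI frames (s).
#' @param window Window length (s).
#' @return Numeric HR series in bpm, one value per frame.
#' @export
extract_hr <- function(beats, frame_times, window = 6) {
  stopifnot(window > 0)
  if (length(beats) < 2) stop("cannot form inter-beat interval")
  if (is.unsorted(beats, strictly = TRUE)) stop("beat times must be strictly increasing")
  ibi <- diff(beats)
  mid <- (beats[-1] + beats[-length(beats)]) / 2
  half <- window / 2
  hr <- vapply(frame_times, function(t) {
    in_win <- beats >= t - half & beats <= t + half
    if (sum(in_win) < 2) return(NA_real_)
    sel <- mid >= t - half & mid <= t + half
    if (!any(sel)) return(NA_real_)
    60 / mean(ibi[sel])
  }, numeric(1))
  if (all(is.na(hr))) stop("no frame window holds two beats")
  if (anyNA(hr)) {
    ok <- which(!is.na(hr))
    hr <- approx(frame_times[ok], hr[ok], xout = frame_times, rule = 2)$y
  }
  hr
}

#' Respiration variation from the raw belt waveform
#'
#' RV at each fMRI frame is the temporal standard deviation (population
#' convention, divisor n) of the raw respiration waveform in a sliding
#' window centered at the frame. Windows at the series edges are truncated
#' to the available samples.
#'
#' @param resp Numeric respiration waveform.
#' @param fs Sampling rate (Hz); sample `k` is at time `(k - 1) / fs`.
#' @param frame_times Centers of the fMRI frames (s).
#' @param window Window length (s).
#' @return Non-negative numeric RV series, one value per frame.
#' @export
extract_rv <- function(resp, fs, frame_times, window = 6) {
  stopifnot(fs > 0, window > 0)
  if (window * fs < 2) stop("window must span at least 2 samples")
  n <- length(resp)
  half <- window / 2
  vapply(frame_times, function(t) {
    lo <- max(1L, ceiling((t - half) * fs) + 1L)
    hi <- min(n, floor((t + half) * fs) + 1L)
    if (lo > hi) stop("empty RV window after truncation at t = ", t)
    x <- resp[lo:hi]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
}

#' Zero-phase band-pass and resampling of a frame-aligned series
#'
#' Applies the package-standard zero-phase Butterworth band-pass and then
#' resamples. When the output step is an integer multiple of the input step
#' the series is decimated by keeping frames 1, 1 + factor, ... (so the
#' output length is `ceiling(T / factor)`); otherwise it is linearly
#' interpolated onto the new grid.
#'
#' @param x Numeric per-frame series.
#' @param dt_in Input frame spacing (s).
#' @param band `c(f_lo, f_hi)` pass band (Hz); defaults to the low-frequency
#'   physiological band.
#' @param dt_out Output frame spacing (s); `NULL` keeps `dt_in`.
#' @return Numeric series with attribute `dt` set to the output spacing.
#' @export
bandpass_resample <- function(x, dt_in, band = c(0.01, 0.15), dt_out = NULL) {
  y <- bp_filtfilt(x, dt_in, band)
  dt_out <- dt_out %||% dt_in
  if (dt_out < dt_in) stop("dt_out must be >= dt_in")
  ratio <- dt_out / dt_in
  if (abs(ratio - round(ratio)) < 1e-9) {
    y <- decimate_keep(y, round(ratio))
  } else {
    t_in <- (seq_along(y) - 1) * dt_in
    y <- approx(t_in, y, xout = seq(0, t_in[length(t_in)], by = dt_out))$y
  }
  attr(y, "dt") <- dt_out
  y
}

#' Z-normalize a series to zero mean and unit variance
#'
#' A constant series maps to all zeros with a warning rather than an error,
#' since constant physiological traces are a QC finding.
#'
#' @param x Numeric series.
#' @return Numeric series with mean 0 and (sample) SD 1.
#' @export
znormalize <- function(x) {
  if (length(x) == 0) stop("cannot normalize an empty series")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("constant series: returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Frame-aligned physiological series
#'
#' Bundles the RV and HR series sampled on the fMRI frame grid as a tibble
#' with one row per frame, carrying the frame spacing, the extraction window
#' and the normalization state as attributes.
#'
#' @param rv,hr Numeric series, one value per frame (`hr` in bpm unless
#'   `normalized`).
#' @param frame_times Frame centers (s).
#' @param dt Frame spacing (s).
#' @param window Extraction window (s).
#' @param normalized Have both series been z-normalized?
#' @return A `frame_physio` tibble with columns `time`, `rv`, `hr`.
#' @export
frame_physio <- function(rv, hr, frame_times, dt, window = 6,
                         normalized = FALSE) {
  stopifnot(length(rv) == length(hr), length(rv) == length(frame_times),
            dt > 0)
  out <- tibble(time = as.numeric(frame_times), rv = as.numeric(rv),
                hr = as.numeric(hr))
  class(out) <- c("frame_physio", class(out))
  attr(out, "dt") <- dt
  attr(out, "window") <- window
  attr(out, "normalized") <- normalized
  out
}

#' Extract frame-aligned RV and HR from a raw recording
#'
#' Convenience pipeline: beat detection and windowed HR from the PPG channel,
#' windowed RV from the respiration channel. Missing channels yield `NA`
#' columns (QC reports them).
#'
#' @param raw A [raw_physio()] object.
#' @param frame_times Frame centers (s).
#' @param dt Frame spacing (s).
#' @param window Extraction window (s).
#' @return A [frame_physio()] tibble (un-normalized; HR in bpm).
#' @export
extract_frame_physio <- function(raw, frame_times, dt, window = 6) {
  stopifnot(inherits(raw, "raw_physio"))
  rv <- if (is.null(raw$resp)) rep(NA_real_, length(frame_times)) else
    extract_rv(raw$resp, raw$fs, frame_times, window)
  hr <- if (is.null(raw$ppg)) rep(NA_real_, length(frame_times)) else {
    beats <- detect_beats(raw$ppg, raw$fs)
    if (length(beats) < 2) rep(NA_real_, length(frame_times)) else
      extract_hr(beats, frame_times, window)
  }
  frame_physio(rv, hr, frame_times, dt, window = window)
}

#' Automated physiological quality control
#'
#' Applies independent scan-level criteria to a raw recording and its derived
#' heart-rate series: waveform clipping at the digitizer saturation bounds
#' (flagged when the saturated fraction exceeds `clip_frac`), unrealistic
#' mean heart rate (below 30 or above 97 bpm), heart rate constant at 48 bpm
#' (a known failure mode of the acquisition chain, flagged when every frame
#' is within 0.5 bpm of 48), and missing channels. The verdict fails exactly
#' when any flag is set.
#'
#' @param raw A [raw_physio()] object.
#' @param hr HR series in physical units (bpm), or `NULL` when unavailable.
#' @param clip_frac Fraction of saturated samples that counts as clipping.
#' @return A one-row `qc_report` tibble.
#' @export
qc_physio <- function(raw, hr = NULL, clip_frac = 0.01) {
  stopifnot(inherits(raw, "raw_physio"))
  n_clipped <- 0L
  clipped <- FALSE
  for (ch in list(raw$resp, raw$ppg)) {
    if (is.null(ch)) next
    k <- sum(ch <= raw$adc_min | ch >= raw$adc_max)
    n_clipped <- n_clipped + k
    if (k / length(ch) > clip_frac) clipped <- TRUE
  }
  hr_ok <- !is.null(hr) && !all(is.na(hr))
  hr_out_of_range <- hr_ok && (mean(hr, na.rm = TRUE) < 30 ||
                                 mean(hr, na.rm = TRUE) > 97)
  hr_constant_48 <- hr_ok && all(abs(hr - 48) <= 0.5, na.rm = TRUE)
  missing_resp <- is.null(raw$resp)
  missing_ppg <- is.null(raw$ppg)
  flags <- c(clipped, hr_out_of_range, hr_constant_48, missing_resp,
             missing_ppg)
  out <- tibble(
    clipped = clipped, n_clipped = n_clipped,
    hr_out_of_range = hr_out_of_range, hr_constant_48 = hr_constant_48,
    missing_resp = missing_resp, missing_ppg = missing_ppg,
    verdict = if (any(flags)) "fail" else "pass"
  )
  class(out) <- c("qc_report", class(out))
  out
}

#' Read a columnar plain-text physiological recording
#'
#' Whitespace- or tab-separated columns with a configurable column map. The
#' default map is the HCP dialect: column 2 is the respiration belt, column
#' 3 the pulse oximeter, recorded at 400 Hz as integers in 0--4095.
#'
#' @param path File path.
#' @param fs Sampling rate (Hz).
#' @param columns Named integer vector mapping `resp` and/or `ppg` to column
#'   indices; drop a name to mark that channel missing.
#' @param adc_min,adc_max Digitizer saturation bounds.
#' @return A [raw_physio()] object.
#' @export
read_physio_txt <- function(path, fs = 400, columns = c(resp = 2, ppg = 3),
                            adc_min = 0, adc_max = 4095) {
  dat <- read.table(path, header = FALSE)
  pick <- function(nm) {
    if (!nm %in% names(columns)) return(NULL)
    j <- columns[[nm]]
    if (j > ncol(dat)) stop("column ", j, " for ", nm, " not present in file")
    as.numeric(dat[[j]])
  }
  raw_physio(resp = pick("resp"), ppg = pick("ppg"), fs = fs,
             adc_min = adc_min, adc_max = adc_max)
}

#' Write / read frame-aligned physiology as TSV + JSON sidecar
#'
#' The TSV holds the `rv` and `hr` columns (one row per frame); the sidecar
#' `<path>.json` records `dt`, `window`, `band` and `normalized` so the file
#' is self-describing.
#'
#' @param fp A [frame_physio()] tibble.
#' @param path Output TSV path.
#' @param band Pass band recorded in the sidecar (or `NULL`).
#' @return `path`, invisibly.
#' @export
write_frame_physio <- function(fp, path, band = NULL) {
  stopifnot(inherits(fp, "frame_physio"))
  write.table(fp[, c("rv", "hr")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(dt = attr(fp, "dt"), window = attr(fp, "window"),
               band = band, normalized = attr(fp, "normalized"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_frame_physio
#' @export
read_frame_physio <- function(path) {
  dat <- read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dt <- meta$dt
  frame_physio(dat$rv, dat$hr, frame_times = (seq_len(nrow(dat)) - 1) * dt,
               dt = dt, window = meta$window %||% 6,
               normalized = isTRUE(meta$normalized))
}

#' Serialize a QC report as JSON
#'
#' @param qc A `qc_report` tibble from [qc_physio()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_report"))
  jsonlite::write_json(as.list(qc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
#' @method autoplot frame_physio
autoplot.frame_physio <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("rv", "hr"),
                              names_to = "signal", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
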