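#' Simulator configuration
#'
#' Study conditions for the brain-body forward simulator. Defaults mirror
#' the acquisition and physiology this package targets: 1.44 s frame
#' spacing (0.72 s TR downsampled by 2), latents confined to the
#' 0.01--0.15 Hz band, an RV--HR coupling of 0.275 (the population mean
#' coupling between measured RV and HR), four scans per synthetic subject,
#' and additive AR(1) noise scaled so the six canonical physiological
#' regressors explain roughly a quarter of each loaded ROI's variance.
#'
#' @param n_scans Number of scans.
#' @param n_rois ROIs (input channels) per scan.
#' @param n_frames Frames per scan.
#' @param dt Frame spacing (s).
#' @param band Latent frequency band (Hz).
#' @param rho Target RV--HR correlation.
#' @param loading_rv,loading_hr Ranges from which per-ROI loadings are drawn
#'   uniformly.
#' @param zero_frac Fraction of ROIs with zero physiological loading.
#' @param noise_sd Marginal SD of the additive AR(1) noise (the latent
#'   contributions are unit-variance before loading).
#' @param ar_coeff AR(1) coefficient of the noise.
#' @param scans_per_subject Scans grouped under one synthetic subject.
#' @param seed RNG seed; all simulator randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_scans = 8, n_rois = 50, n_frames = 300, dt = 1.44,
                       band = c(0.01, 0.15), rho = 0.275,
                       loading_rv = c(0.5, 1.5), loading_hr = c(0.5, 1.5),
                       zero_frac = 0.1, noise_sd = 2.8, ar_coeff = 0.3,
                       scans_per_subject = 4, seed = 1) {
  stopifnot(abs(rho) < 1, noise_sd >= 0, ar_coeff >= 0, ar_coeff < 1,
            band[1] < band[2], dt > 0, n_frames >= 8)
  structure(list(n_scans = n_scans, n_rois = n_rois, n_frames = n_frames,
                 dt = dt, band = band, rho = rho, loading_rv = loading_rv,
                 loading_hr = loading_hr, zero_frac = zero_frac,
                 noise_sd = noise_sd, ar_coeff = ar_coeff,
                 scans_per_subject = scans_per_subject, seed = seed),
            class = "sim_config")
}

# Pre-emphasis compensating the sliding-window extraction: RV/HR derived
# from the synthesized waveforms are effectively the latents smoothed by a
# `window`-second boxcar (frequency response sinc(w f)). Dividing the latent
# spectrum by that response (gain capped for stability) makes the *derived*
# series, not the raw envelope, match the latent.
window_preemphasis <- function(x, dt, window = 6, min_gain = 0.25) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)
  g <- ifelse(freqs == 0, 1, sin(pi * window * freqs) / (pi * window * freqs))
  g <- pmax(g, min_gain)
  out <- Re(fft(fft(x) / g, inverse = TRUE)) / n
  # keep the input's scale; constants (DC only, unit gain) pass unchanged
  if (sd(out) > 0 && sd(x) > 0) out <- out * (sd(x) / sd(out))
  out
}

# Brick-wall band-limiting in the frequency domain: a zero-phase band-pass
# that guarantees exact spectral confinement of the simulated latents.
band_limit_fft <- function(x, dt, band) {
  n <- length(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  xf <- fft(x)
  xf[!keep] <- 0
  Re(fft(xf, inverse = TRUE)) / n
}

#' Simulate coupled band-limited RV and HR latents
#'
#' Two z-scored series produced by band-pass filtering correlated Gaussian
#' noise. Coupling uses shared-component mixing (`hr_raw = rho * rv_raw +
#' sqrt(1 - rho^2) * noise`) before filtering, so the target correlation is
#' analytic; band-limiting is exact (FFT brick wall), so at least 95\% -- in
#' fact all -- of each latent's periodogram power lies inside `band`.
#'
#' @param n_frames Series length.
#' @param dt Frame spacing (s). `n_frames * dt` of at least ~200 s is
#'   recommended to support the 0.01 Hz band edge.
#' @param rho Target correlation (|rho| < 1).
#' @param band Frequency band (Hz).
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return Tibble with `time`, `rv`, `hr`.
#' @export
simulate_latent_physio <- function(n_frames, dt = 1.44, rho = 0.275,
                                   band = c(0.01, 0.15), seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  gen <- function() {
    x <- rnorm(n_frames)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n_frames)
    rv <- znormalize(band_limit_fft(x, dt, band))
    hr <- znormalize(band_limit_fft(y, dt, band))
    tibble(time = (seq_len(n_frames) - 1) * dt, rv = rv, hr = hr)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthesize raw physiological waveforms consistent with given latents
#'
#' Inverts the RV/HR extraction definitions: the respiration channel is a
#' breathing-rate sinusoid whose instantaneous amplitude is proportional to
#' the (interpolated, positively shifted) RV latent, and the pulse channel
#' is a train of raised-cosine pulses whose instantaneous beat rate tracks
#' the HR latent (rescaled from z-units to bpm). Output is on the HCP ADC
#' scale (integers around 2048, bounded by 0 and 4095) so quality-control
#' logic can be exercised on simulator output. Extraction applied to the
#' result recovers the latents (correlation > 0.9 under defaults).
#'
#' @param rv,hr Z-scored latent series (e.g. [simulate_latent_physio()]
#'   columns), one value per fMRI frame.
#' @param dt Frame spacing (s).
#' @param fs Waveform sampling rate (Hz).
#' @param hr_mean,hr_sd Rescaling of the HR latent to bpm.
#' @param resp_rate Breathing rate (Hz); the default 1/3 Hz (20 breaths
#'   per minute) spans whole cycles within the 6 s extraction window.
#' @param rv_shift Positive shift added to the z-scored RV before use as an
#'   amplitude envelope (must leave the envelope positive).
#' @param window Extraction window (s) the consumer will use; with
#'   `preemphasis` the latents are deconvolved by the window's boxcar
#'   response (gain capped for stability) so that the windowed extraction,
#'   which smooths over `window` seconds, returns the latents themselves.
#' @param preemphasis Apply the window pre-emphasis (default `TRUE`).
#' @param seed Optional seed (reserved for noise options).
#' @param resp_noise_sd,ppg_noise_sd Additive Gaussian noise SD in ADC units.
#' @return A [raw_physio()] with attributes `beat_times` (ground truth) and
#'   `frame_times`.
#' @export
simulate_raw_waveforms <- function(rv, hr, dt = 1.44, fs = 400,
                                   hr_mean = 70, hr_sd = 5,
                                   resp_rate = 1 / 3, rv_shift = 3.5,
                                   window = 6, preemphasis = TRUE,
                                   seed = NULL, resp_noise_sd = 0,
                                   ppg_noise_sd = 0) {
  stopifnot(length(rv) == length(hr))
  run <- function() {
    n_frames <- length(rv)
    frame_times <- (seq_len(n_frames) - 1) * dt
    tt <- seq(0, frame_times[n_frames], by = 1 / fs)
    if (preemphasis) {
      rv <- window_preemphasis(rv, dt, window)
      hr <- window_preemphasis(hr, dt, window)
    }
    rv_i <- approx(frame_times, rv, tt, rule = 2)$y
    hr_i <- approx(frame_times, hr, tt, rule = 2)$y

    amp <- rv_i + rv_shift
    if (any(amp <= 0)) stop("non-positive respiration amplitude after shift")
    resp <- 2048 + 220 * amp * sin(2 * pi * resp_rate * tt)
    if (resp_noise_sd > 0) resp <- resp + rnorm(length(tt), 0, resp_noise_sd)

    rate_bpm <- hr_mean + hr_sd * hr_i
    if (any(rate_bpm <= 0)) stop("non-positive instantaneous heart rate")
    phase <- cumsum(rate_bpm / 60) / fs
    beat_idx <- which(diff(floor(c(0, phase))) > 0)
    beat_times <- tt[beat_idx]
    pulse <- numeric(length(tt))
    w <- 0.30  # pulse width (s), raised cosine
    hw <- round(w / 2 * fs)
    for (bi in beat_idx) {
      lo <- max(1L, bi - hw)
      hi <- min(length(tt), bi + hw)
      seg <- (tt[lo:hi] - tt[bi]) / w
      pulse[lo:hi] <- pulse[lo:hi] + 0.5 * (1 + cos(2 * pi * seg))
    }
    ppg <- 1200 + 1200 * pulse
    if (ppg_noise_sd > 0) ppg <- ppg + rnorm(length(tt), 0, ppg_noise_sd)

    out <- raw_physio(resp = round(pmin(pmax(resp, 0), 4095)),
                      ppg = round(pmin(pmax(ppg, 0), 4095)), fs = fs)
    attr(out, "beat_times") <- beat_times
    attr(out, "frame_times") <- frame_times
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate one ROI-by-time BOLD scan from latents
#'
#' Forward model: each ROI row is `loading_rv * znorm(rv (*) RRF) +
#' loading_hr * znorm(hr (*) CRF) + AR(1) noise`, then z-scored. Loadings
#' are drawn uniformly from the configured ranges with a configurable
#' fraction of zero-loading ROIs. With `noise_sd = 0` every loaded row is an
#' exact linear combination of the canonical regressor columns.
#'
#' @param latents Tibble from [simulate_latent_physio()] (columns `rv`,
#'   `hr`), or a list with those elements.
#' @param config A [sim_config()].
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return A `sim_scan`: list with `roi` ([roi_timeseries()]), `latents`
#'   and `loadings` (tibble `roi_id`, `loading_rv`, `loading_hr`).
#' @export
simulate_roi_scan <- function(latents, config = sim_config(), seed = NULL) {
  run <- function() {
    rv <- latents$rv
    hr <- latents$hr
    T_ <- length(rv)
    R <- config$n_rois
    c_rv <- znormalize(causal_conv(
      rv, response_function_eval("rrf", seq(0, 60, by = config$dt)),
      config$dt))
    c_hr <- znormalize(causal_conv(
      hr, response_function_eval("crf", seq(0, 60, by = config$dt)),
      config$dt))
    n_zero <- round(config$zero_frac * R)
    zero_rois <- if (n_zero > 0) sample.int(R, n_zero) else integer(0)
    a <- runif(R, config$loading_rv[1], config$loading_rv[2])
    b <- runif(R, config$loading_hr[1], config$loading_hr[2])
    a[zero_rois] <- 0
    b[zero_rois] <- 0
    innov_sd <- config$noise_sd * sqrt(1 - config$ar_coeff^2)
    data <- matrix(0, R, T_)
    for (r in seq_len(R)) {
      noise <- if (config$noise_sd > 0) {
        as.numeric(stats::filter(rnorm(T_, 0, innov_sd), config$ar_coeff,
                                 method = "recursive"))
      } else {
        numeric(T_)
      }
      row <- a[r] * c_rv + b[r] * c_hr + noise
      data[r, ] <- if (diff(range(row)) == 0) row else znormalize(row)
    }
    structure(list(
      roi = roi_timeseries(data, dt = config$dt, preprocessed = TRUE),
      latents = tibble(time = (seq_len(T_) - 1) * config$dt, rv = rv,
                       hr = hr),
      loadings = tibble(roi_id = seq_len(R), loading_rv = a, loading_hr = b)
    ), class = "sim_scan")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a multi-subject dataset
#'
#' Independent scans sharing the loading distribution but with independent
#' latents and noise, grouped into synthetic subjects
#' (`scans_per_subject` scans each, echoing four-run acquisitions). The
#' returned tibble feeds [train_recon()] directly; all randomness flows
#' from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` tibble with columns `scan_id`, `subject`, `run`,
#'   `x` (R x T matrices), `rv`, `hr` (latent targets) and `loadings`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  man <- scan_manifest(ceiling(config$n_scans / config$scans_per_subject),
                       config$scans_per_subject)[seq_len(config$n_scans), ]
  with_seed(config$seed, {
    scans <- purrr::map(seq_len(config$n_scans), function(i) {
      lat <- simulate_latent_physio(config$n_frames, config$dt, config$rho,
                                    config$band)
      simulate_roi_scan(lat, config)
    })
    out <- tibble(
      scan_id = man$scan_id, subject = man$subject, run = man$run,
      x = purrr::map(scans, function(s) s$roi$data),
      rv = purrr::map(scans, function(s) s$latents$rv),
      hr = purrr::map(scans, function(s) s$latents$hr),
      loadings = purrr::map(scans, "loadings")
    )
    class(out) <- c("sim_dataset", class(out))
    out
  })
}

#' Scan manifest for a multi-run cohort
#'
#' @param n_subjects Number of subjects.
#' @param scans_per_subject Runs per subject.
#' @return Tibble with `subject`, `run`, `scan_id` (one row per scan).
#' @export
scan_manifest <- function(n_subjects, scans_per_subject = 4) {
  tibble(
    subject = rep(sprintf("sub-%04d", seq_len(n_subjects)),
                  each = scans_per_subject),
    run = rep(seq_len(scans_per_subject), n_subjects)
  ) |>
    dplyr::mutate(scan_id = sprintf("%s_run-%d", .data$subject, .data$run))
}

#' Synthetic four-part atlas on a small grid
#'
#' Builds a desk-scale stand-in for the canonical four-atlas composition:
#' 400 cortical labels, a 72-region probabilistic white-matter part
#' (thresholded at 0.95), 16 subcortical and 9 ascending-arousal-network
#' labels, laid out deterministically on a small voxel grid. The part list
#' includes a few voxels claimed by two parts (to exercise precedence) and
#' a sub-threshold white-matter voxel (to exercise thresholding).
#'
#' @param dim Grid dimensions (needs at least 497 + a few voxels).
#' @return Named list of [atlas_part()]s (`cortical`, `wm`, `subcortical`,
#'   `aan`), composable with [compose_atlas()].
#' @export
simulate_atlas_parts <- function(dim = c(12, 12, 4)) {
  V <- prod(dim)
  n <- c(cortical = 400L, wm = 72L, subcortical = 16L, aan = 9L)
  stopifnot(V >= sum(n) + 4)
  offs <- cumsum(c(0, n[-4]))
  names(offs) <- names(n)

  vol <- function(part) {
    a <- array(0L, dim)
    a[offs[[part]] + seq_len(n[[part]])] <- seq_len(n[[part]])
    a
  }
  cortical <- vol("cortical")
  # second voxel for cortical region 1, so it survives either overlap
  # precedence in the composition tests
  cortical[sum(n) + 10L] <- 1L
  subcort <- vol("subcortical")
  aan <- vol("aan")

  # probabilistic WM part: each region claims its own voxel at p = 0.96
  wm <- array(0, c(dim, n[["wm"]]))
  for (l in seq_len(n[["wm"]])) {
    wm[offs[["wm"]] + l + (l - 1L) * V] <- 0.96
  }
  # overlap: WM region 1 also claims (confidently) a cortical voxel --
  # resolved to cortex by gray-matter-first precedence
  wm[1L] <- 0.97
  # sub-threshold claim on an otherwise unlabeled voxel: must be excluded
  wm[sum(n) + 1L + (2L - 1L) * V] <- 0.90

  list(
    cortical = atlas_part(cortical, "label", name = "cortical"),
    wm = atlas_part(wm, "probability", name = "wm", threshold = 0.95),
    subcortical = atlas_part(subcort, "label", name = "subcortical"),
    aan = atlas_part(aan, "label", name = "aan")
  )
}

#' Tiny 4D volume driven by physiological latents
#'
#' A desk-scale 4D image for seed-map and ROI-extraction tests: a block of
#' voxels carries the convolved RV/HR signal plus noise, the rest is pure
#' noise. Returns the array, a plausible 2 mm affine, and the loaded-voxel
#' mask.
#'
#' @param latents Tibble from [simulate_latent_physio()].
#' @param dim Spatial dimensions.
#' @param config A [sim_config()] (noise and dt settings are used).
#' @param seed Optional seed.
#' @return List with `img` (4D array), `affine`, `dt`, `loaded` (3D logical
#'   array).
#' @export
simulate_fmri_volume <- function(latents, dim = c(10, 10, 10),
                                 config = sim_config(), seed = NULL) {
  run <- function() {
    T_ <- nrow(latents)
    c_rv <- znormalize(causal_conv(
      latents$rv, response_function_eval("rrf", seq(0, 60, by = config$dt)),
      config$dt))
    c_hr <- znormalize(causal_conv(
      latents$hr, response_function_eval("crf", seq(0, 60, by = config$dt)),
      config$dt))
    V <- prod(dim)
    loaded <- array(FALSE, dim)
    loaded[1:floor(dim[1] / 2), 1:floor(dim[2] / 2), ] <- TRUE
    flat <- matrix(rnorm(V * T_, 0, config$noise_sd), V, T_)
    nl <- sum(loaded)
    flat[as.vector(loaded), ] <- flat[as.vector(loaded), ] +
      outer(runif(nl, 0.5, 1.5), c_rv) + outer(runif(nl, 0.5, 1.5), c_hr)
    affine <- rbind(cbind(diag(c(2, 2, 2)), c(-dim[1], -dim[2], -dim[3])),
                    c(0, 0, 0, 1))
    list(img = array(flat, c(dim, T_)), affine = affine, dt = config$dt,
         loaded = loaded)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
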