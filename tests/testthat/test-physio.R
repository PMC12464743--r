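# Waveform-to-frame extraction: beat detection, HR, RV, filtering, QC.

test_that("detect_beats recovers a periodic pulse train", {
  pt <- make_pulse_train(duration = 60, ibi = 1)
  beats <- detect_beats(pt$x, pt$fs)
  expect_equal(length(beats), length(pt$beats), tolerance = 0)
  expect_true(all(abs(beats - pt$beats) < 0.05))
  expect_true(all(diff(beats) >= 0.25))
})

test_that("detect_beats tolerates 10% additive noise", {
  pt <- make_pulse_train(duration = 60, ibi = 1)
  noisy <- pt$x + withr::with_seed(2, rnorm(length(pt$x), 0, 0.1))
  beats <- detect_beats(noisy, pt$fs)
  expect_true(abs(length(beats) - length(pt$beats)) <= 1)
})

test_that("detect_beats degenerate inputs", {
  expect_identical(detect_beats(rep(3, 2000), 400), numeric(0))
  expect_error(detect_beats(rnorm(100), 400), "insufficient waveform")
})

test_that("extract_hr computes windowed inverse mean IBI", {
  frames <- seq(5, 55, by = 1.44)
  expect_equal(extract_hr(seq(0, 60, by = 1), frames), rep(60, length(frames)))
  expect_equal(extract_hr(seq(0, 60, by = 0.5), frames),
               rep(120, length(frames)))
})

test_that("extract_hr mixed-IBI window matches the brute-force mean", {
  # window at t = 1 holds exactly the IBIs {0.5, 1.0}
  beats <- c(0.25, 0.75, 1.75)
  hr <- extract_hr(beats, frame_times = 1, window = 6)
  expect_equal(hr, 60 / mean(c(0.5, 1.0)))
  expect_equal(hr, 80)
})

test_that("extract_hr interpolates frames with too few beats", {
  # beats only in the first 10 s; later frames must take the nearest value
  beats <- seq(0, 10, by = 0.5)
  frames <- c(2, 5, 30, 60)
  hr <- extract_hr(beats, frames, window = 6)
  expect_equal(hr, rep(120, 4))
  expect_error(extract_hr(c(1), frames), "cannot form inter-beat interval")
})

test_that("extract_hr ignores waveform content outside every frame window", {
  frames <- seq(10, 20, by = 1.44)
  inside <- seq(6, 24, by = 1)
  padded <- c(seq(0.1, 5.3, by = 0.2), inside, seq(25, 40, by = 0.13))
  expect_equal(extract_hr(inside, frames), extract_hr(padded, frames))
})

test_that("extract_rv matches closed forms", {
  fs <- 50
  tt <- seq(0, 120, by = 1 / fs)
  frames <- seq(10, 110, by = 1.44)
  expect_equal(extract_rv(rep(7, length(tt)), fs, frames),
               rep(0, length(frames)))
  # sine of amplitude A over whole cycles: population sd -> A / sqrt(2)
  A <- 100
  sine <- A * sin(2 * pi * 0.5 * tt)  # 3 cycles per 6 s window
  rv <- extract_rv(sine, fs, frames, window = 6)
  expect_true(all(abs(rv - A / sqrt(2)) / (A / sqrt(2)) < 0.01))
})

test_that("extract_rv doubles after an amplitude-doubling step", {
  fs <- 50
  tt <- seq(0, 200, by = 1 / fs)
  amp <- ifelse(tt < 100, 1, 2)
  x <- amp * sin(2 * pi * 0.5 * tt)
  rv <- extract_rv(x, fs, c(50, 150), window = 6)
  expect_equal(rv[2] / rv[1], 2, tolerance = 1e-6)
})

test_that("extract_rv is non-negative for arbitrary waveforms", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(5000, sd = 100 * seed))
    rv <- extract_rv(x, 50, seq(5, 95, by = 7))
    expect_true(all(rv >= 0))
  }
})

test_that("bandpass_resample passes in-band and attenuates out-of-band", {
  dt <- 0.72
  tt <- (0:1199) * dt
  mid <- 300:900  # avoid filter edge transients when measuring gain
  in_band <- sin(2 * pi * 0.05 * tt)
  out_band <- sin(2 * pi * 0.3 * tt)
  y_in <- bandpass_resample(in_band, dt)
  y_out <- bandpass_resample(out_band, dt)
  gain_in <- max(abs(y_in[mid])) / 1
  gain_out <- max(abs(y_out[mid])) / 1
  expect_true(gain_in > 0.9 && gain_in < 1.1)
  expect_lt(gain_out, 0.1)
})

test_that("bandpass_resample decimates 0.72 s to 1.44 s", {
  x <- withr::with_seed(3, rnorm(1199))
  y <- bandpass_resample(x, 0.72, dt_out = 1.44)
  expect_equal(attr(y, "dt"), 1.44)
  expect_equal(length(y), ceiling(length(x) / 2))
})

test_that("bandpass_resample is approximately idempotent on band-limited input", {
  # content in the interior of the pass band, away from the filter edges
  x <- simulate_latent_physio(600, 1.44, band = c(0.03, 0.10), seed = 9)$rv
  y1 <- as.numeric(bandpass_resample(x, 1.44))
  y2 <- as.numeric(bandpass_resample(y1, 1.44))
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.05)
})

test_that("bandpass_resample rejects too-short series", {
  expect_error(bandpass_resample(rnorm(5), 0.72), "too short")
})

test_that("znormalize contract", {
  y <- znormalize(c(1, 2, 3))
  expect_equal(mean(y), 0, tolerance = 1e-6)
  expect_equal(sd(y), 1, tolerance = 1e-6)
  z <- withr::with_seed(4, rnorm(50, 3, 7))
  expect_equal(znormalize(znormalize(z)), znormalize(z), tolerance = 1e-6)
  expect_warning(out <- znormalize(c(5, 5, 5)), "constant")
  expect_equal(out, c(0, 0, 0))
  expect_error(znormalize(numeric(0)), "empty")
})

test_that("qc_physio flags each failure mode and verdict is the disjunction", {
  fs <- 400
  good_resp <- 2048 + 500 * sin(2 * pi * (1 / 3) * seq(0, 60, by = 1 / fs))
  pt <- make_pulse_train(60, ibi = 1, fs = fs)
  good_ppg <- 1000 + 1000 * pt$x
  hr_good <- rep(c(58, 62), 50)

  cases <- list(
    clean = list(raw = raw_physio(good_resp, good_ppg, fs), hr = hr_good,
                 flags = character(0)),
    clipped = list(
      raw = raw_physio(replace(good_resp, 1:1300, 4095), good_ppg, fs),
      hr = hr_good, flags = "clipped"),
    low_hr = list(raw = raw_physio(good_resp, good_ppg, fs),
                  hr = rep(25, 100), flags = "hr_out_of_range"),
    high_hr = list(raw = raw_physio(good_resp, good_ppg, fs),
                   hr = rep(99, 100), flags = "hr_out_of_range"),
    const48 = list(raw = raw_physio(good_resp, good_ppg, fs),
                   hr = rep(48.2, 100), flags = "hr_constant_48"),
    no_resp = list(raw = raw_physio(NULL, good_ppg, fs), hr = hr_good,
                   flags = "missing_resp"),
    no_ppg = list(raw = raw_physio(good_resp, NULL, fs), hr = NULL,
                  flags = "missing_ppg")
  )
  flag_cols <- c("clipped", "hr_out_of_range", "hr_constant_48",
                 "missing_resp", "missing_ppg")
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    qc <- qc_physio(cs$raw, cs$hr)
    got <- flag_cols[unlist(qc[1, flag_cols])]
    expect_identical(got, cs$flags, label = paste("case", nm))
    expect_identical(qc$verdict, if (length(cs$flags)) "fail" else "pass",
                     label = paste("verdict", nm))
  }
})

test_that("qc clipping threshold is a fraction, not a count", {
  fs <- 400
  x <- 2048 + 500 * sin(2 * pi * 0.3 * seq(0, 60, by = 1 / fs))
  few <- replace(x, 1:10, 4095)           # < 1% saturated: benign
  many <- replace(x, 1:500, 4095)         # > 1%: clipped
  expect_false(qc_physio(raw_physio(few, NULL, fs), rep(60, 10))$clipped)
  expect_true(qc_physio(raw_physio(many, NULL, fs), rep(60, 10))$clipped)
})

test_that("physio text reader honors the HCP column dialect", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  dat <- cbind(trig = 0, resp = 1:8 * 10, ppg = 1:8 * 100)
  write.table(dat, tmp, row.names = FALSE, col.names = FALSE)
  raw <- read_physio_txt(tmp, fs = 400)
  expect_equal(raw$resp, 1:8 * 10)
  expect_equal(raw$ppg, 1:8 * 100)
  raw2 <- read_physio_txt(tmp, fs = 400, columns = c(ppg = 3))
  expect_null(raw2$resp)
})

test_that("frame physio TSV + sidecar round-trips", {
  fp <- frame_physio(rv = sin(1:50), hr = cos(1:50),
                     frame_times = (0:49) * 1.44, dt = 1.44,
                     normalized = TRUE)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_frame_physio(fp, tmp, band = c(0.01, 0.15))
  back <- read_frame_physio(tmp)
  expect_equal(back$rv, fp$rv)
  expect_equal(back$hr, fp$hr)
  expect_equal(attr(back, "dt"), 1.44)
  expect_true(attr(back, "normalized"))
})
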