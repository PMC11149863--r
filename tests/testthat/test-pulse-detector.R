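# Generic pulse detector: filtering, spectra, triggering, merging, gates.

fs <- 200000

test_that("band-pass filter attenuates out-of-band tones and passes in-band ones", {
  t <- seq_len(fs / 10) / fs
  cfg <- detector_config(band_high = 95, calibration_offset = 154)
  low <- sin(2 * pi * 2000 * t)
  out_low <- bandpass(low, fs, cfg)
  expect_gt(20 * log10(sd(low) / sd(out_low)), 40)
  mid <- sin(2 * pi * 40000 * t)
  out_mid <- bandpass(mid, fs, cfg)
  expect_lt(abs(20 * log10(sd(mid) / sd(out_mid))), 1)
  expect_equal(bandpass(numeric(100), fs, cfg), numeric(100))
  expect_error(bandpass(numeric(0), fs, cfg), "empty")
  expect_warning(bandpass(mid, fs, detector_config(calibration_offset = 154)),
                 "Nyquist")
})

test_that("snippet spectra follow the 400-point Hann-weighted DFT convention", {
  cfg <- DET_CFG
  t <- seq_len(300) / fs
  tone <- sin(2 * pi * 40000 * t)
  spec <- snippet_spectrum(tone, cfg, fs)
  expect_length(spec, 201L)
  freq <- attr(spec, "freq_khz")
  expect_equal(freq[2] - freq[1], 0.5)   # 200 kHz / 400 points
  expect_equal(freq[which.max(spec)], 40)
  # zero padding does not move the peak by more than one bin
  short <- snippet_spectrum(tone[1:100], cfg, fs)
  expect_lte(abs(which.max(short) - which.max(spec)), 1L)
  # longer-than-DFT snippets are center-truncated, same shape
  long <- snippet_spectrum(sin(2 * pi * 40000 * seq_len(900) / fs), cfg, fs)
  expect_equal(attr(long, "freq_khz")[which.max(long)], 40)
  # silent snippet floors at the configured value
  expect_true(all(snippet_spectrum(numeric(128), cfg, fs) ==
                    cfg$spectrum_floor_db))
})

test_that("pulses below the received-level threshold are not detected", {
  sc <- scene_config(duration = 5, events = list(
    scene_event(TPL$Zc, 0.5, 5, 110)), noise_floor = 20, seed = 3)
  scene <- render_scene(sc)
  cfg <- detector_config(band_high = 95,
                         calibration_offset = scene$calibration_offset)
  det <- detect_pulses(bandpass(scene$waveform, fs, cfg), fs, cfg)
  expect_equal(n_detections(det), 0L)
})

test_that("pulses closer than the merge gap become one detection", {
  cfg <- detector_config(band_high = 95, calibration_offset = 154)
  burst <- sin(2 * pi * 40000 * seq_len(40) / fs)  # 200-us rectangular burst
  scale <- db_to_amp(130 - 154) / 2
  x <- numeric(fs %/% 20)
  i1 <- 3000L
  i2 <- i1 + 40L + round(50e-6 * fs)   # signals 50 us apart
  x[i1:(i1 + 39L)] <- burst * scale
  x[i2:(i2 + 39L)] <- burst * scale
  det <- detect_pulses(bandpass(x, fs, cfg), fs, cfg)
  expect_equal(n_detections(det), 1L)
  # the same pair 2 ms apart stays two detections
  i3 <- i1 + 40L + round(2000e-6 * fs)
  x2 <- numeric(fs %/% 20)
  x2[i1:(i1 + 39L)] <- burst * scale
  x2[i3:(i3 + 39L)] <- burst * scale
  det2 <- detect_pulses(bandpass(x2, fs, cfg), fs, cfg)
  expect_equal(n_detections(det2), 2L)
})

test_that("detector round-trip on a rendered scene meets the recall contract", {
  sc <- scene_config(duration = 16, events = list(
    scene_event(TPL$Zc, 0.5, 15, 130),
    scene_event(TPL$Me, 8.5, 15, 130)), noise_floor = 45, seed = 12)
  scene <- render_scene(sc)
  cfg <- detector_config(band_high = 95,
                         calibration_offset = scene$calibration_offset)
  det <- detect_pulses(bandpass(scene$waveform, fs, cfg), fs, cfg)
  err <- vapply(scene$truth$start_s,
                function(t0) min(abs(det$table$start_s - t0)), 0)
  expect_gte(mean(err < 200e-6), 0.95)
  # sorted, no two detections closer than the merge gap
  expect_false(is.unsorted(det$table$start_s))
  if (n_detections(det) > 1L)
    expect_true(all(det$table$start_s[-1] - head(det$table$end_s, -1) >=
                      cfg$merge_gap * 1e-6))
  # durations inside the configured gate
  dur <- (det$table$end_s - det$table$start_s) * 1e6
  expect_true(all(dur >= cfg$min_duration & dur <= cfg$max_duration))
  # received levels within a dB of the planted level
  expect_true(all(abs(det$table$rl_pp_db - 130) < 1.5))

  # threshold monotonicity: raising min_rl_pp never adds detections
  cfg_hi <- cfg
  cfg_hi$min_rl_pp <- 135
  det_hi <- detect_pulses(bandpass(scene$waveform, fs, cfg_hi), fs, cfg_hi)
  expect_lte(n_detections(det_hi), n_detections(det))
})

test_that("detection stores round-trip through disk", {
  det <- simulate_detections(list(scene_event(TPL$Mb, 0, 5, 128)), seed = 1)
  dir <- withr::local_tempdir()
  write_detections(det, file.path(dir, "d"))
  expect_true(file.exists(file.path(dir, "d.csv")))
  back <- read_detections(file.path(dir, "d"))
  expect_equal(back$table, det$table)
  expect_equal(back$snippets, det$snippets)
})
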