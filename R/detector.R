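# Generic band-limited pulse detector: band-pass filtering, amplitude
# triggering, merging, energy-bound timing and per-click spectra.

#' Pulse detector configuration
#'
#' Defaults follow the standard toothed-whale click detection settings for
#' 200-kHz archival recordings: a fifth-order Butterworth band-pass between
#' 5 and 100 kHz, a minimum received level of 118 dB peak-to-peak re 1 muPa,
#' durations between 30 and 1200 us, merging of pulses closer than 100 us,
#' signal boundaries at the 70th percentile of the high-energy event, and
#' 400-point spectra.
#'
#' @param band_low,band_high Band-pass corner frequencies, kHz. `band_high`
#'   is clipped to Nyquist (with a warning) when it reaches it.
#' @param filter_order Butterworth filter order.
#' @param min_rl_pp Minimum received level, dB peak-to-peak re 1 muPa.
#' @param min_duration,max_duration Duration gates, microseconds.
#' @param merge_gap Pulses closer than this are merged, microseconds.
#' @param energy_percentile Percentile of event energy defining signal
#'   start/end bounds.
#' @param fft_points DFT length for click spectra.
#' @param calibration_offset dB added to `20*log10(amplitude)` to convert
#'   recorder amplitude units to dB re 1 muPa.
#' @param spectrum_floor_db Floor applied to log-spectra of silent snippets.
#' @param energy_smooth Samples of moving-average smoothing applied to
#'   squared amplitude before boundary finding.
#' @return A `detector_config` list.
#' @export
detector_config <- function(band_low = 5, band_high = 100, filter_order = 5L,
                            min_rl_pp = 118, min_duration = 30,
                            max_duration = 1200, merge_gap = 100,
                            energy_percentile = 70, fft_points = 400L,
                            calibration_offset = NA_real_,
                            spectrum_floor_db = -120, energy_smooth = 5L) {
  stopifnot(band_low < band_high, min_duration < max_duration,
            energy_percentile > 0, energy_percentile < 100)
  structure(list(
    band_low = band_low, band_high = band_high, filter_order = filter_order,
    min_rl_pp = min_rl_pp, min_duration = min_duration,
    max_duration = max_duration, merge_gap = merge_gap,
    energy_percentile = energy_percentile, fft_points = as.integer(fft_points),
    calibration_offset = calibration_offset,
    spectrum_floor_db = spectrum_floor_db, energy_smooth = energy_smooth
  ), class = "detector_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering, so click timing is not biased
#' by group delay. When `band_high` reaches the Nyquist frequency the
#' filter degrades gracefully to a high-pass at `band_low`.
#'
#' @param waveform Numeric input signal.
#' @param sample_rate Sampling rate, Hz.
#' @param config A [detector_config()].
#' @return Filtered signal, same length as the input.
#' @export
bandpass <- function(waveform, sample_rate, config = detector_config()) {
  if (length(waveform) == 0L) stop("empty input waveform")
  nyq <- sample_rate / 2
  lo <- config$band_low * 1000 / nyq
  hi <- config$band_high * 1000 / nyq
  if (hi >= 1) {
    warning("band_high at or above Nyquist; using a high-pass at band_low")
    flt <- signal::butter(config$filter_order, lo, type = "high")
  } else {
    flt <- signal::butter(config$filter_order, c(lo, hi), type = "pass")
  }
  as.numeric(signal::filtfilt(flt, waveform))
}

#' Click spectrum from a waveform snippet
#'
#' The snippet is Hann-weighted and zero-padded to `fft_points` before a
#' `fft_points`-point DFT; the one-sided magnitude-squared spectrum is
#' returned in dB. Snippets longer than `fft_points` are center-truncated.
#' Bin spacing is always `sample_rate / fft_points`.
#'
#' @param snippet Numeric waveform snippet.
#' @param config A [detector_config()].
#' @param sample_rate Sampling rate, Hz (sets the frequency axis attribute).
#' @return Numeric vector of length `fft_points / 2 + 1` (dB), with
#'   attribute `freq_khz`.
#' @export
snippet_spectrum <- function(snippet, config = detector_config(),
                             sample_rate = 200000) {
  nfft <- config$fft_points
  n <- length(snippet)
  if (n == 0L) stop("empty snippet")
  if (n > nfft) {
    mid <- floor(n / 2)
    snippet <- snippet[(mid - nfft %/% 2L + 1L):(mid - nfft %/% 2L + nfft)]
    n <- nfft
  }
  seg <- c(snippet * hann_window(n), numeric(nfft - n))
  p <- Mod(stats::fft(seg))[1:(nfft %/% 2L + 1L)] ^ 2
  db <- 10 * log10(p)
  db[!is.finite(db)] <- config$spectrum_floor_db
  db <- pmax(db, config$spectrum_floor_db)
  attr(db, "freq_khz") <- seq(0, sample_rate / 2, by = sample_rate / nfft) / 1000
  db
}

# Assemble a click_detections container.
new_click_detections <- function(table, snippets, spectra, sample_rate, config) {
  structure(list(table = table, snippets = snippets, spectra = spectra,
                 sample_rate = sample_rate, config = config),
            class = "click_detections")
}

#' @export
print.click_detections <- function(x, ...) {
  cat(sprintf("<click_detections> %d detections, %.1f kHz sampling\n",
              nrow(x$table), x$sample_rate / 1000))
  if (nrow(x$table)) {
    cat(sprintf("  time span %.2f-%.2f s, RL pp %.1f-%.1f dB\n",
                min(x$table$start_s), max(x$table$end_s),
                min(x$table$rl_pp_db), max(x$table$rl_pp_db)))
  }
  invisible(x)
}

#' @export
`[.click_detections` <- function(x, i, ...) {
  idx <- seq_len(nrow(x$table))[i]
  tab <- x$table[idx, , drop = FALSE]
  rownames(tab) <- NULL
  spectra <- x$spectra[idx, , drop = FALSE]
  attr(spectra, "freq_khz") <- attr(x$spectra, "freq_khz")
  new_click_detections(tab, x$snippets[idx], spectra, x$sample_rate, x$config)
}

#' Number of detections in a container
#' @param x A `click_detections` object.
#' @return Integer count.
#' @export
n_detections <- function(x) nrow(x$table)

# Process one candidate region [a, b] (sample indices of the above-trigger
# run) into a detection record, or NULL if it fails the gates.
.process_region <- function(x, a, b, fs, config) {
  n <- length(x)
  pad <- 400L
  w0 <- max(1L, a - pad)
  w1 <- min(n, b + pad)
  seg <- x[w0:w1]
  e <- smooth_ma(analytic_envelope(seg) ^ 2, config$energy_smooth)
  run <- (a - w0 + 1L):(b - w0 + 1L)
  pk <- run[which.max(e[run])]
  thr <- stats::quantile(e[run], config$energy_percentile / 100, names = FALSE)
  above <- run[e[run] >= thr]
  s <- min(above)
  en <- max(above)
  dur_us <- (en - s + 1L) / fs * 1e6
  pp <- max(seg[run]) - min(seg[run])
  rl <- amp_to_db(pp) + config$calibration_offset
  if (rl < config$min_rl_pp) return(NULL)
  if (dur_us < config$min_duration || dur_us > config$max_duration) return(NULL)
  core_len <- en - s + 1L
  pad2 <- max(80L, round(2.5 * core_len))
  s0 <- max(1L, s - pad2)
  s1 <- min(length(seg), en + pad2)
  list(start_s = (w0 - 1L + s - 1L) / fs,
       end_s = (w0 - 1L + en) / fs,
       rl_pp_db = rl,
       snippet = seg[s0:s1],
       start_idx = s - s0 + 1L,
       end_idx = en - s0 + 1L,
       core = seg[s:en],
       a = w0 - 1L + s, b = w0 - 1L + en)
}

#' Detect pulses in a band-pass-filtered waveform
#'
#' Candidate pulses are samples whose absolute amplitude exceeds half the
#' minimum peak-to-peak threshold (after calibration); candidates closer
#' than `merge_gap` are merged into one high-energy event. Each event's
#' start and end are the first and last samples around the main energy peak
#' where smoothed squared amplitude exceeds the `energy_percentile`-th
#' percentile of the event energy. Events are kept if their received level
#' and duration pass the configured gates.
#'
#' @param filtered Band-pass-filtered waveform (amplitude units).
#' @param sample_rate Sampling rate, Hz.
#' @param config A [detector_config()]; `calibration_offset` must be set.
#' @return A `click_detections` object: a table of `click_id`, `start_s`,
#'   `end_s`, `rl_pp_db` plus per-click snippets and spectra.
#' @export
detect_pulses <- function(filtered, sample_rate, config = detector_config()) {
  if (!is.finite(config$calibration_offset))
    stop("config$calibration_offset must be supplied")
  fs <- sample_rate
  gap_samp <- max(1L, round(config$merge_gap * 1e-6 * fs))
  trigger <- db_to_amp(config$min_rl_pp - config$calibration_offset) / 2
  hot <- which(abs(filtered) >= trigger)
  regions <- list()
  if (length(hot)) {
    brk <- which(diff(hot) > gap_samp)
    starts <- hot[c(1L, brk + 1L)]
    ends <- hot[c(brk, length(hot))]
    regions <- Map(c, starts, ends)
  }
  dets <- list()
  for (r in regions) {
    d <- .process_region(filtered, r[1L], r[2L], fs, config)
    if (!is.null(d)) dets[[length(dets) + 1L]] <- d
  }
  # Energy bounds can extend events toward each other; merge any pair of
  # detections whose gap falls below merge_gap and re-process the union.
  repeat {
    if (length(dets) < 2L) break
    gaps <- vapply(seq_len(length(dets) - 1L), function(i)
      dets[[i + 1L]]$start_s - dets[[i]]$end_s, 0)
    bad <- which(gaps < config$merge_gap * 1e-6)
    if (!length(bad)) break
    i <- bad[1L]
    merged <- .process_region(filtered, dets[[i]]$a, dets[[i + 1L]]$b, fs, config)
    dets <- append(dets[-c(i, i + 1L)], list(merged)[!is.null(merged)], after = i - 1L)
    dets <- dets[order(vapply(dets, `[[`, 0, "start_s"))]
  }
  k <- length(dets)
  nbins <- config$fft_points %/% 2L + 1L
  spectra <- matrix(config$spectrum_floor_db, k, nbins)
  freq <- seq(0, fs / 2, by = fs / config$fft_points) / 1000
  snippets <- vector("list", k)
  tab <- data.frame(click_id = seq_len(k),
                    start_s = numeric(k), end_s = numeric(k),
                    rl_pp_db = numeric(k), start_idx = integer(k),
                    end_idx = integer(k))
  for (i in seq_len(k)) {
    d <- dets[[i]]
    tab$start_s[i] <- d$start_s; tab$end_s[i] <- d$end_s
    tab$rl_pp_db[i] <- d$rl_pp_db
    tab$start_idx[i] <- d$start_idx; tab$end_idx[i] <- d$end_idx
    snippets[[i]] <- d$snippet
    spectra[i, ] <- as.numeric(snippet_spectrum(d$core, config, fs))
  }
  attr(spectra, "freq_khz") <- freq
  new_click_detections(tab, snippets, spectra, fs, config)
}

#' Run the detector on raw audio
#'
#' Convenience wrapper: [bandpass()] then [detect_pulses()].
#'
#' @inheritParams detect_pulses
#' @param waveform Raw (unfiltered) waveform.
#' @return A `click_detections` object.
#' @export
detect_clicks <- function(waveform, sample_rate, config = detector_config()) {
  detect_pulses(bandpass(waveform, sample_rate, config), sample_rate, config)
}

#' Write / read a detection store
#'
#' The detection table is written as CSV; snippets and spectra are kept in
#' an RDS sidecar so a store round-trips exactly.
#'
#' @param detections A `click_detections` object.
#' @param path Base path (without extension).
#' @return `read_detections` returns a `click_detections` object.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections$table, paste0(path, ".csv"), row.names = FALSE)
  saveRDS(detections, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) readRDS(paste0(path, ".rds"))
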