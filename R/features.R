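# Per-click scalar metrics and per-cluster summary features: the three
# classification feature families (spectral shape, waveform envelope /
# duration, clicking rate).

ENV_WINDOW_S <- 0.002   # physical window for envelope summaries, seconds
ENV_POINTS <- 200L      # resampled envelope length
ICI_MAX_S <- 0.8        # ICI distributions limited to 0.8 s
ICI_BIN_S <- 0.01       # histogram bin width, seconds

# Smoothed magnitude of the analytic signal.
click_envelope <- function(snippet, smooth = 5L) {
  smooth_ma(analytic_envelope(snippet), smooth)
}

#' Scalar metrics for one detected click
#'
#' Computes peak frequency (spectral argmax), center frequency (spectral
#' centroid of linear power within the analysis band), duration (70th-
#' percentile energy bounds), sweep rate (least-squares slope of the
#' per-frame peak-frequency track over the click, 40-sample frames with
#' 75% overlap) and the smoothed Hilbert envelope.
#'
#' @param snippet Numeric waveform snippet containing one click.
#' @param sample_rate Sampling rate, Hz.
#' @param config A [detector_config()] (band limits, percentile, FFT size).
#' @param rl_pp_db Optional received level to carry through.
#' @return An object of class `click_metrics`: `peak_freq` and
#'   `center_freq` (kHz), `duration` (us), `sweep_rate` (kHz/ms, `NA` when
#'   the click is shorter than one analysis frame), `envelope` (aligned to
#'   the snippet), `start_idx`/`end_idx` (click bounds within the snippet)
#'   and `sample_rate`.
#' @export
click_metrics <- function(snippet, sample_rate, config = detector_config(),
                          rl_pp_db = NA_real_) {
  snippet <- as.numeric(snippet)
  if (length(snippet) < 8L) stop("snippet too short for click metrics")
  b <- energy_bounds(snippet, smooth = config$energy_smooth,
                     pctl = config$energy_percentile / 100)
  dur_us <- (b$end - b$start + 1L) / sample_rate * 1e6
  core <- snippet[b$start:b$end]
  spec <- snippet_spectrum(core, config, sample_rate)
  freq <- attr(spec, "freq_khz")
  in_band <- freq >= config$band_low & freq <= config$band_high
  peak <- freq[in_band][which.max(spec[in_band])]
  p_lin <- 10 ^ (spec[in_band] / 10)
  center <- sum(freq[in_band] * p_lin) / sum(p_lin)
  sweep <- .sweep_rate(core, sample_rate, config)
  structure(list(
    peak_freq = peak, center_freq = center, duration = dur_us,
    sweep_rate = sweep, envelope = click_envelope(snippet, config$energy_smooth),
    start_idx = b$start, end_idx = b$end, rl_pp = rl_pp_db,
    sample_rate = sample_rate, spectrum = spec
  ), class = "click_metrics")
}

# Least-squares slope (kHz/ms) of the per-frame spectral-argmax track.
.sweep_rate <- function(core, sample_rate, config,
                        frame = 40L, hop = 10L) {
  n <- length(core)
  if (n < frame + hop) return(NA_real_)
  starts <- seq(1L, n - frame + 1L, by = hop)
  if (length(starts) < 2L) return(NA_real_)
  nfft <- config$fft_points
  freq <- seq(0, sample_rate / 2, by = sample_rate / nfft) / 1000
  in_band <- freq >= config$band_low & freq <= config$band_high
  win <- hann_window(frame)
  track <- vapply(starts, function(s) {
    seg <- c(core[s:(s + frame - 1L)] * win, numeric(nfft - frame))
    p <- Mod(stats::fft(seg))[1:(nfft %/% 2L + 1L)] ^ 2
    freq[in_band][which.max(p[in_band])]
  }, 0)
  t_ms <- (starts + frame / 2) / sample_rate * 1000
  stats::coef(stats::lm(track ~ t_ms))[[2L]]
}

#' Per-click metric table for a detection container
#'
#' @param detections A `click_detections` object.
#' @return Data frame with one row per detection: `click_id`, `peak_khz`,
#'   `center_khz`, `duration_us`, `sweep_khz_ms`, `rl_pp_db`.
#' @export
click_metrics_table <- function(detections) {
  tab <- detections$table
  out <- data.frame(click_id = tab$click_id, peak_khz = NA_real_,
                    center_khz = NA_real_, duration_us = NA_real_,
                    sweep_khz_ms = NA_real_, rl_pp_db = tab$rl_pp_db)
  for (i in seq_len(nrow(tab))) {
    m <- click_metrics(detections$snippets[[i]], detections$sample_rate,
                       detections$config, rl_pp_db = tab$rl_pp_db[i])
    out$peak_khz[i] <- m$peak_freq
    out$center_khz[i] <- m$center_freq
    out$duration_us[i] <- m$duration
    out$sweep_khz_ms[i] <- m$sweep_rate
  }
  out
}

#' Inter-click-interval distribution and modal ICI
#'
#' Successive differences of the click times are computed; gaps above
#' 0.8 s (missed detections, pauses between click trains) are discarded,
#' and the remainder histogrammed over (0, 0.8\] s in 0.01-s bins. The
#' modal ICI is the center of the tallest bin.
#'
#' @param click_times Numeric vector of click start times, seconds,
#'   sorted ascending.
#' @return List with `hist` (normalized counts, all zero when fewer than
#'   two valid gaps), `breaks`, `mids`, `modal_ici` (s, `NA` when
#'   undefined) and `n_gaps`.
#' @export
ici_distribution <- function(click_times) {
  if (is.unsorted(click_times)) stop("click_times must be sorted ascending")
  breaks <- seq(0, ICI_MAX_S, by = ICI_BIN_S)
  mids <- breaks[-1L] - ICI_BIN_S / 2
  gaps <- diff(click_times)
  gaps <- gaps[gaps > 0 & gaps <= ICI_MAX_S]
  if (length(gaps) < 2L) {
    return(list(hist = numeric(length(mids)), breaks = breaks, mids = mids,
                modal_ici = NA_real_, n_gaps = length(gaps)))
  }
  counts <- tabulate(pmin(ceiling(gaps / ICI_BIN_S), length(mids)),
                     nbins = length(mids))
  list(hist = counts / sum(counts), breaks = breaks, mids = mids,
       modal_ici = mids[which.max(counts)], n_gaps = length(gaps))
}

#' Summary features for a cluster of clicks
#'
#' Each member's dB spectrum is min-max normalized to \[0, 1\] and the
#' normalized spectra averaged; envelopes are extracted over a fixed 2-ms
#' window centered on each click's energy peak, resampled to 200 points,
#' normalized and averaged; the ICI distribution and modal ICI come from
#' the member start times.
#'
#' @param members A `click_detections` object with at least one detection.
#' @return An object of class `cluster_summary`: `mean_spectrum` (\[0, 1\]),
#'   `freq_khz`, `mean_envelope` (\[0, 1\], length 200), `ici_hist`,
#'   `ici_mids`, `modal_ici`, `n_clicks`, and the member time span.
#' @export
cluster_summary <- function(members) {
  k <- n_detections(members)
  if (k < 1L) stop("cluster_summary needs at least one member click")
  spec_norm <- t(apply(members$spectra, 1L, minmax_norm))
  mean_spec <- colMeans(spec_norm)
  fs <- members$sample_rate
  win_n <- round(ENV_WINDOW_S * fs)
  envs <- matrix(0, k, ENV_POINTS)
  for (i in seq_len(k)) {
    env <- click_envelope(members$snippets[[i]])
    pk <- which.max(env)
    lo <- pk - win_n %/% 2L
    idx <- lo:(lo + win_n - 1L)
    vals <- numeric(win_n)
    ok <- idx >= 1L & idx <= length(env)
    vals[ok] <- env[idx[ok]]
    envs[i, ] <- minmax_norm(resample_series(vals, ENV_POINTS))
  }
  times <- sort(members$table$start_s)
  ici <- ici_distribution(times)
  structure(list(
    mean_spectrum = mean_spec,
    freq_khz = attr(members$spectra, "freq_khz"),
    mean_envelope = colMeans(envs),
    ici_hist = ici$hist, ici_mids = ici$mids, modal_ici = ici$modal_ici,
    n_clicks = k, t_start = min(times), t_end = max(times)
  ), class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  pk <- x$freq_khz[which.max(x$mean_spectrum)]
  cat(sprintf(
    "<cluster_summary> %d clicks, mean-spectrum peak %.1f kHz, modal ICI %s s\n",
    x$n_clicks, pk,
    if (is.na(x$modal_ici)) "NA" else sprintf("%.2f", x$modal_ici)))
  invisible(x)
}
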