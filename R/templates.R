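#' Construct a species click-type template
#'
#' A `species_template` parameterizes the synthetic click generator for one
#' click type: the frequency-modulated upsweep (onset and peak frequency,
#' sweep rate), any secondary spectral peaks, the click duration as measured
#' by the 70th-percentile energy-bound convention of [click_metrics()], and
#' the click-train rhythm (modal inter-click interval and its jitter).
#'
#' @param class_id Class label, e.g. `"Zc"`.
#' @param onset_freq Frequency onset of the upsweep, kHz.
#' @param peak_freq Central peak frequency, kHz (must exceed `onset_freq`,
#'   at most 100 kHz).
#' @param peak_range Length-2 allowed range for peak frequency, kHz.
#' @param secondary_peaks Numeric vector of secondary spectral peaks, kHz
#'   (possibly empty).
#' @param duration Central measured click duration, microseconds.
#' @param duration_range Length-2 allowed range for duration, microseconds.
#' @param sweep_rate Upsweep rate, kHz/ms; 0 for click types without a
#'   consistent upsweep.
#' @param modal_ici Modal inter-click interval, seconds.
#' @param ici_jitter_sd Standard deviation of Gaussian ICI jitter, seconds.
#' @param peak_jitter_sd Per-click peak-frequency variability, kHz
#'   (truncated to `peak_range`); large for spectrally diverse classes
#'   such as the multi-species delphinid group.
#' @param source_level_pp Length-2 typical peak-to-peak source level range,
#'   dB re 1 muPa.
#' @param group `"beaked"` for Ziphiidae click types, `"other"` otherwise.
#' @return An object of class `species_template`.
#' @seealso [builtin_templates()], [make_click()]
#' @export
species_template <- function(class_id, onset_freq, peak_freq,
                             peak_range = peak_freq + c(-2, 2),
                             secondary_peaks = numeric(0),
                             duration, duration_range = duration * c(0.8, 1.2),
                             sweep_rate = 0, modal_ici, ici_jitter_sd = 0.01,
                             peak_jitter_sd = 0.5,
                             source_level_pp = c(120, 140), group = "other") {
  stopifnot(is.character(class_id), length(class_id) == 1L)
  if (!(onset_freq < peak_freq && peak_freq <= 100))
    stop("template '", class_id, "': need onset_freq < peak_freq <= 100 kHz")
  if (duration <= 0) stop("template '", class_id, "': duration must be positive")
  if (modal_ici <= 0) stop("template '", class_id, "': modal_ici must be positive")
  if (sweep_rate < 0) stop("template '", class_id, "': sweep_rate must be >= 0")
  structure(list(
    class_id = class_id, onset_freq = onset_freq, peak_freq = peak_freq,
    peak_range = peak_range, secondary_peaks = secondary_peaks,
    duration = duration, duration_range = duration_range,
    sweep_rate = sweep_rate, modal_ici = modal_ici,
    ici_jitter_sd = ici_jitter_sd, peak_jitter_sd = peak_jitter_sd,
    source_level_pp = source_level_pp,
    group = group
  ), class = "species_template")
}

#' @export
print.species_template <- function(x, ...) {
  cat(sprintf(
    "<species_template %s> peak %.1f kHz, duration %.0f us, sweep %.0f kHz/ms, modal ICI %.2f s\n",
    x$class_id, x$peak_freq, x$duration, x$sweep_rate, x$modal_ici))
  invisible(x)
}

#' Built-in click-type templates
#'
#' Returns the library of 11 click-type templates used throughout the
#' package: the six North Atlantic beaked whale classes (Zc, Me, Mm, Mb,
#' Md, BWG) with their published peak frequencies, secondary peaks,
#' durations and modal inter-click intervals, plus five distractor classes
#' (unspecified delphinids, Risso's dolphin, Kogia-like narrowband
#' high-frequency clicks, low-frequency ship noise and sperm whale clicks,
#' and echosounder pings). The delphinid template deliberately has no
#' consistent upsweep, so it fails the sweep-rate rule of the hard
#' negative filter.
#'
#' @param include_variants If `TRUE`, regional variant templates are
#'   appended (currently `Md_GoM`, the short-duration Gulf of Mexico
#'   Blainville's beaked whale click, under 250 us).
#' @return Named list of [species_template()] objects.
#' @export
builtin_templates <- function(include_variants = FALSE) {
  tpl <- list(
    species_template("Zc", onset_freq = 26, peak_freq = 40,
                     peak_range = c(38, 42), secondary_peaks = c(19, 24, 70),
                     duration = 450, sweep_rate = 30, modal_ici = 0.51,
                     source_level_pp = c(121, 137), group = "beaked"),
    species_template("Mb", onset_freq = 50, peak_freq = 70,
                     peak_range = c(60, 80), secondary_peaks = numeric(0),
                     duration = 400, sweep_rate = 30, modal_ici = 0.13,
                     source_level_pp = c(121, 135), group = "beaked"),
    species_template("Md", onset_freq = 21.5, peak_freq = 33,
                     peak_range = c(29.5, 36.5), secondary_peaks = numeric(0),
                     duration = 400, sweep_rate = 27, modal_ici = 0.30,
                     source_level_pp = c(120, 134), group = "beaked"),
    species_template("Me", onset_freq = 30, peak_freq = 42,
                     peak_range = c(40, 44.5), secondary_peaks = 23.5,
                     duration = 400, sweep_rate = 30, modal_ici = 0.28,
                     source_level_pp = c(120, 135), group = "beaked"),
    species_template("Mm", onset_freq = 30, peak_freq = 47,
                     peak_range = c(45, 49), secondary_peaks = 24.5,
                     duration = 400, sweep_rate = 30, modal_ici = 0.19,
                     source_level_pp = c(120, 135), group = "beaked"),
    species_template("BWG", onset_freq = 23, peak_freq = 50,
                     peak_range = c(40, 60), secondary_peaks = 17,
                     duration = 550, sweep_rate = 28, modal_ici = 0.10,
                     source_level_pp = c(120, 134), group = "beaked"),
    # Distractors. The delphinid class covers many species: individual
    # clicks are short tonal pulses whose peak frequency varies widely
    # across the 30-70 kHz band (peak_jitter_sd 8), with no consistent
    # upsweep (sweep_rate 0) and a fast click rate.
    species_template("De spp", onset_freq = 40, peak_freq = 50,
                     peak_range = c(30, 70), secondary_peaks = numeric(0),
                     duration = 150, duration_range = c(100, 200),
                     sweep_rate = 0, modal_ici = 0.075, ici_jitter_sd = 0.012,
                     peak_jitter_sd = 8,
                     source_level_pp = c(120, 145), group = "other"),
    species_template("Gg", onset_freq = 25, peak_freq = 33,
                     peak_range = c(30, 36), secondary_peaks = c(23.5, 27),
                     duration = 180, duration_range = c(120, 240),
                     sweep_rate = 0, modal_ici = 0.15, ici_jitter_sd = 0.015,
                     peak_jitter_sd = 1,
                     source_level_pp = c(120, 142), group = "other"),
    species_template("Ko spp", onset_freq = 80, peak_freq = 90,
                     peak_range = c(86, 94), secondary_peaks = numeric(0),
                     duration = 120, duration_range = c(90, 160),
                     sweep_rate = 0, modal_ici = 0.08, ici_jitter_sd = 0.01,
                     source_level_pp = c(118, 135), group = "other"),
    species_template("Pm & Boat", onset_freq = 6, peak_freq = 12,
                     peak_range = c(8, 18), secondary_peaks = numeric(0),
                     duration = 600, duration_range = c(400, 900),
                     sweep_rate = 0, modal_ici = 0.70, ici_jitter_sd = 0.04,
                     source_level_pp = c(120, 150), group = "other"),
    species_template("ES ping", onset_freq = 40, peak_freq = 50.5,
                     peak_range = c(49.5, 51.5), secondary_peaks = numeric(0),
                     duration = 1000, duration_range = c(800, 1150),
                     sweep_rate = 0, modal_ici = 0.60, ici_jitter_sd = 0.002,
                     source_level_pp = c(125, 150), group = "other")
  )
  names(tpl) <- vapply(tpl, `[[`, "", "class_id")
  if (include_variants) {
    tpl[["Md_GoM"]] <- species_template(
      "Md_GoM", onset_freq = 21.5, peak_freq = 32, peak_range = c(31, 32.5),
      secondary_peaks = numeric(0), duration = 200, duration_range = c(150, 245),
      sweep_rate = 27, modal_ici = 0.30, source_level_pp = c(120, 134),
      group = "beaked")
  }
  tpl
}

#' Class labels of the built-in click-type library
#'
#' @return Character vector of the 11 class labels, beaked whale classes first.
#' @export
template_classes <- function() names(builtin_templates())

#' Beaked whale class labels
#'
#' @return Character vector of the six Ziphiidae class labels.
#' @export
beaked_whale_classes <- function() {
  tpl <- builtin_templates()
  names(tpl)[vapply(tpl, `[[`, "", "group") == "beaked"]
}
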