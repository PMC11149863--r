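# Fast simulation paths that produce detection records and labeled cluster
# summaries directly from click templates, without rendering and
# re-detecting full audio. Waveform snippets, spectra and timing follow the
# same conventions as the pulse detector, so downstream stages are
# exercised on equivalent inputs.

#' Simulate a detection record directly from click templates
#'
#' For each event a click train is generated, every click synthesized with
#' [make_click()], embedded in Gaussian noise at the configured noise
#' floor, scaled to its received level, and converted into the same
#' detection record [detect_pulses()] would produce (energy-bound times,
#' core spectrum, snippet with margins). The true class of each click is
#' kept in the table column `true_class`.
#'
#' @param events List of [scene_event()]s.
#' @param sample_rate Sampling rate, Hz.
#' @param noise_floor Background noise spectral density, dB re 1 muPa^2/Hz.
#' @param full_scale_pp Calibration: full-scale peak-to-peak level, dB.
#' @param rl_jitter_sd Per-click received-level jitter, dB.
#' @param seed Integer master seed.
#' @param config Optional [detector_config()] (calibration offset is set
#'   from the scene calibration).
#' @return A `click_detections` object.
#' @export
simulate_detections <- function(events, sample_rate = 200000,
                                noise_floor = 30, full_scale_pp = 160,
                                rl_jitter_sd = 2, seed = 1L,
                                config = detector_config()) {
  offset <- full_scale_pp - amp_to_db(2)
  config$calibration_offset <- offset
  gain <- db_to_amp(offset)
  noise_sd <- sqrt(10 ^ (noise_floor / 10) * sample_rate / 2) / gain
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      length(events)))
  recs <- list()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    ev_seeds <- with_seed(seeds[i],
                          sample.int(.Machine$integer.max - 1L, 2L * ev$n_clicks + 1L))
    times <- make_click_train(ev$template, ev$n_clicks, ev$start_time,
                              ev_seeds[1L])
    for (k in seq_len(ev$n_clicks)) {
      snip <- as.numeric(make_click(ev$template, sample_rate,
                                    seed = ev_seeds[1L + k]))
      rl <- ev$received_level_pp + with_seed(ev_seeds[1L + ev$n_clicks + k],
                                             stats::rnorm(1, 0, rl_jitter_sd))
      scale <- db_to_amp(rl - offset) / (max(snip) - min(snip))
      margin <- max(40L, round(length(snip) * 0.25))
      full <- c(numeric(margin), snip * scale, numeric(margin))
      noisy <- full + with_seed(ev_seeds[1L + ev$n_clicks + k],
                                stats::rnorm(length(full), 0, noise_sd))
      b <- energy_bounds(snip)
      s_idx <- margin + b$start
      e_idx <- margin + b$end
      recs[[length(recs) + 1L]] <- list(
        true_class = ev$template$class_id,
        start_s = times[k] + (b$start - 1L) / sample_rate,
        end_s = times[k] + b$end / sample_rate,
        rl_pp_db = rl, start_idx = s_idx, end_idx = e_idx,
        snippet = noisy, core = noisy[s_idx:e_idx])
    }
  }
  k <- length(recs)
  ord <- order(vapply(recs, `[[`, 0, "start_s"))
  recs <- recs[ord]
  nbins <- config$fft_points %/% 2L + 1L
  spectra <- matrix(config$spectrum_floor_db, k, nbins)
  snippets <- vector("list", k)
  tab <- data.frame(click_id = seq_len(k),
                    start_s = vapply(recs, `[[`, 0, "start_s"),
                    end_s = vapply(recs, `[[`, 0, "end_s"),
                    rl_pp_db = vapply(recs, `[[`, 0, "rl_pp_db"),
                    start_idx = vapply(recs, function(r) as.integer(r$start_idx), 0L),
                    end_idx = vapply(recs, function(r) as.integer(r$end_idx), 0L),
                    true_class = vapply(recs, `[[`, "", "true_class"))
  for (i in seq_len(k)) {
    snippets[[i]] <- recs[[i]]$snippet
    spectra[i, ] <- as.numeric(snippet_spectrum(recs[[i]]$core, config,
                                                sample_rate))
  }
  attr(spectra, "freq_khz") <- seq(0, sample_rate / 2,
                                   by = sample_rate / config$fft_points) / 1000
  new_click_detections(tab, snippets, spectra, sample_rate, config)
}

#' Simulate labeled cluster summaries for classifier development
#'
#' Generates, per template, `n_per_class` clusters of `clicks_per_cluster`
#' synthetic clicks each (via [simulate_detections()] and
#' [cluster_summary()]), organized into encounters on a rotating set of
#' sites so encounter-preserving splits can be exercised: clusters within
#' an encounter are 5 minutes apart; consecutive encounters are separated
#' by 60 minutes.
#'
#' @param templates List of [species_template()]s (defaults to the
#'   built-in library).
#' @param n_per_class Clusters per template.
#' @param clicks_per_cluster Clicks per cluster.
#' @param clusters_per_encounter Encounter length, clusters.
#' @param n_sites Number of sites to rotate encounters over.
#' @param received_level Mean received level, dB pp.
#' @param seed Integer master seed.
#' @return List with `clusters` (list of `click_cluster`), `labels`,
#'   `times_min`, `sites`.
#' @export
simulate_labeled_clusters <- function(templates = builtin_templates(),
                                      n_per_class = 50L,
                                      clicks_per_cluster = 12L,
                                      clusters_per_encounter = 10L,
                                      n_sites = 3L, received_level = 130,
                                      seed = 1L) {
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             length(templates) * n_per_class),
                                  length(templates), n_per_class))
  clusters <- list(); labels <- character(0)
  times_min <- numeric(0); sites <- integer(0)
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    for (ci in seq_len(n_per_class)) {
      det <- simulate_detections(
        list(scene_event(tpl, 0, clicks_per_cluster, received_level)),
        seed = seeds[ti, ci])
      cl <- new_click_cluster(bin_id = ci, member_ids = det$table$click_id,
                              summary = cluster_summary(det))
      cl$label <- tpl$class_id
      clusters[[length(clusters) + 1L]] <- cl
      labels <- c(labels, tpl$class_id)
      enc <- (ci - 1L) %/% clusters_per_encounter
      within <- (ci - 1L) %% clusters_per_encounter
      times_min <- c(times_min, enc * (clusters_per_encounter * 5 + 60) +
                       within * 5)
      sites <- c(sites, (enc %% n_sites) + 1L)
    }
  }
  list(clusters = clusters, labels = labels, times_min = times_min,
       sites = sites)
}
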