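# Taxonomic family delimitation: removal of non-beaked-whale detections
# before clustering, by a rule-based hard negative filter or a
# cluster-and-classify moderate negative filter.

#' Hard negative filter configuration
#'
#' The classical rule set for beaked whale click candidates: minimum
#' duration 355 us, peak frequency at least 32 kHz, center frequency at
#' least 25 kHz, a frequency-modulated upsweep of at least 23 kHz/ms, and
#' a waveform envelope that slopes positively over the first 0.1 ms of the
#' click and stays at or above 50% of its maximum for the following
#' 0.1 ms. Clicks are then screened in 75-s intervals, retained when an
#' interval has at least 7 candidate signals or at least 13% of its
#' signals meet all criteria.
#'
#' @param min_duration Minimum click duration, microseconds.
#' @param min_peak_freq,min_center_freq Frequency thresholds, kHz.
#' @param min_sweep_rate Minimum upsweep rate, kHz/ms.
#' @param envelope_rise Length of the initial positive-slope window, s.
#' @param envelope_sustain Length of the following sustain window, s.
#' @param sustain_level Fraction of the envelope maximum that must be
#'   sustained.
#' @param interval_length Screening interval, seconds.
#' @param min_candidates Candidate count retaining an interval.
#' @param min_fraction Candidate fraction retaining an interval (of all
#'   detections in the interval).
#' @return A `hard_filter_config` list.
#' @export
hard_filter_config <- function(min_duration = 355, min_peak_freq = 32,
                               min_center_freq = 25, min_sweep_rate = 23,
                               envelope_rise = 1e-4, envelope_sustain = 1e-4,
                               sustain_level = 0.5, interval_length = 75,
                               min_candidates = 7L, min_fraction = 0.13) {
  stopifnot(min_duration > 0, min_peak_freq > 0, min_center_freq > 0,
            min_sweep_rate > 0, min_fraction > 0, min_fraction < 1)
  structure(list(
    min_duration = min_duration, min_peak_freq = min_peak_freq,
    min_center_freq = min_center_freq, min_sweep_rate = min_sweep_rate,
    envelope_rise = envelope_rise, envelope_sustain = envelope_sustain,
    sustain_level = sustain_level, interval_length = interval_length,
    min_candidates = as.integer(min_candidates), min_fraction = min_fraction
  ), class = "hard_filter_config")
}

# Envelope rule: least-squares slope over the first `envelope_rise` seconds
# from the click start must be positive, and the envelope must stay at or
# above `sustain_level` of its maximum over the following window.
.envelope_rule <- function(envelope, start_idx, sample_rate, config) {
  rise_n <- max(2L, round(config$envelope_rise * sample_rate))
  sus_n <- max(1L, round(config$envelope_sustain * sample_rate))
  n <- length(envelope)
  w1 <- start_idx:min(n, start_idx + rise_n - 1L)
  if (length(w1) < 2L) return(FALSE)
  slope <- stats::coef(stats::lm(envelope[w1] ~ seq_along(w1)))[[2L]]
  if (!(slope > 0)) return(FALSE)
  w2 <- (max(w1) + 1L):min(n, max(w1) + sus_n)
  if (max(w1) >= n || length(w2) < 1L) return(FALSE)
  min(envelope[w2]) >= config$sustain_level * max(envelope)
}

#' Apply the per-click beaked whale candidate rules
#'
#' @param metrics A [click_metrics()] object (an undefined sweep rate
#'   fails the sweep rule).
#' @param config A [hard_filter_config()].
#' @return List with `pass` (all five rules hold) and `flags`, a named
#'   logical vector with the outcome of each rule (`duration`,
#'   `peak_freq`, `center_freq`, `sweep_rate`, `envelope`).
#' @export
click_passes_hard_rules <- function(metrics, config = hard_filter_config()) {
  stopifnot(inherits(metrics, "click_metrics"))
  flags <- c(
    duration = metrics$duration >= config$min_duration,
    peak_freq = metrics$peak_freq >= config$min_peak_freq,
    center_freq = metrics$center_freq >= config$min_center_freq,
    sweep_rate = !is.na(metrics$sweep_rate) &&
      metrics$sweep_rate >= config$min_sweep_rate,
    envelope = .envelope_rule(metrics$envelope, metrics$start_idx,
                              metrics$sample_rate, config)
  )
  list(pass = all(flags), flags = flags)
}

#' Hard negative filter over a detection record
#'
#' Evaluates the candidate rules per click, partitions the record into
#' consecutive 75-s intervals (half-open, anchored at recording start) and
#' retains every detection of each interval that holds at least
#' `min_candidates` rule-passing clicks or in which at least
#' `min_fraction` of all detections pass. The operation is idempotent.
#'
#' @param detections A time-sorted `click_detections` object.
#' @param config A [hard_filter_config()].
#' @param pass Optional precomputed logical vector of per-click rule
#'   outcomes (skips metric computation).
#' @return List with `detections` (the retained subset, original order),
#'   `pass` (per input click) and `report`, a data frame per interval:
#'   `interval`, `n_clicks`, `n_candidates`, `fraction`, `retained`.
#' @export
hard_negative_filter <- function(detections, config = hard_filter_config(),
                                 pass = NULL) {
  k <- n_detections(detections)
  if (is.null(pass)) {
    pass <- logical(k)
    for (i in seq_len(k)) {
      m <- click_metrics(detections$snippets[[i]], detections$sample_rate,
                         detections$config)
      pass[i] <- click_passes_hard_rules(m, config)$pass
    }
  }
  iv <- floor(detections$table$start_s / config$interval_length)
  ids <- sort(unique(iv))
  report <- data.frame(interval = ids, n_clicks = NA_integer_,
                       n_candidates = NA_integer_, fraction = NA_real_,
                       retained = NA)
  keep <- logical(k)
  for (r in seq_along(ids)) {
    in_iv <- iv == ids[r]
    n_tot <- sum(in_iv)
    n_cand <- sum(pass[in_iv])
    frac <- n_cand / n_tot
    ok <- n_cand >= config$min_candidates || frac >= config$min_fraction
    keep[in_iv] <- ok
    report$n_clicks[r] <- n_tot
    report$n_candidates[r] <- n_cand
    report$fraction[r] <- frac
    report$retained[r] <- ok
  }
  list(detections = detections[keep], pass = pass, report = report)
}

#' Moderate negative filter configuration
#'
#' @param pass1_min_cluster Minimum clicks per cluster in the first
#'   clustering pass (large clusters only).
#' @param pass1_prune Edge pruning level of the first pass, percent.
#' @param removal_min_clicks Minimum cluster size for removal.
#' @param beaked_classes Labels treated as beaked whale (never removed).
#' @return A `moderate_filter_config` list.
#' @export
moderate_filter_config <- function(pass1_min_cluster = 50L, pass1_prune = 95,
                                   removal_min_clicks = 50L,
                                   beaked_classes = beaked_whale_classes()) {
  structure(list(pass1_min_cluster = as.integer(pass1_min_cluster),
                 pass1_prune = pass1_prune,
                 removal_min_clicks = as.integer(removal_min_clicks),
                 beaked_classes = beaked_classes),
            class = "moderate_filter_config")
}

#' Moderate negative filter (first iteration)
#'
#' Clusters each 5-min bin with the large-cluster settings (minimum 50
#' clicks per cluster, 95% edge pruning), classifies the clusters with the
#' trained network, and deletes the member detections of every cluster
#' holding at least `removal_min_clicks` clicks and a non-beaked-whale
#' label. All other detections — including unclustered ones — survive.
#' The second iteration (re-clustering the survivors with standard
#' settings) is performed by the pipeline driver.
#'
#' @param detections A `click_detections` object.
#' @param model A trained network from [build_and_train()].
#' @param cluster_cfg Base [cluster_config()]; its `min_cluster` and
#'   `prune_threshold` are overridden by the pass-1 settings.
#' @param config A [moderate_filter_config()].
#' @param seed Integer seed for the clustering pass.
#' @return List with `detections` (survivors, original order) and
#'   `report`, one row per pass-1 cluster: `bin_id`, `n_clicks`, `label`,
#'   `score`, `removed`.
#' @export
moderate_negative_filter <- function(detections, model,
                                     cluster_cfg = cluster_config(),
                                     config = moderate_filter_config(),
                                     seed = 1L) {
  if (!all(config$beaked_classes %in% model$classes))
    stop("model class list does not cover the configured beaked whale classes")
  pass1_cfg <- cluster_cfg
  pass1_cfg$min_cluster <- config$pass1_min_cluster
  pass1_cfg$prune_threshold <- config$pass1_prune
  clusters <- cluster_bins(detections, pass1_cfg, seed = seed)
  drop_ids <- integer(0)
  report <- data.frame(bin_id = numeric(0), n_clicks = integer(0),
                       label = character(0), score = numeric(0),
                       removed = logical(0))
  if (length(clusters)) {
    pred <- predict(model, clusters)
    for (i in seq_along(clusters)) {
      cl <- clusters[[i]]
      removed <- cl$n_clicks >= config$removal_min_clicks &&
        !(pred$label[i] %in% config$beaked_classes)
      if (removed) drop_ids <- c(drop_ids, cl$member_ids)
      report <- rbind(report, data.frame(
        bin_id = cl$bin_id, n_clicks = cl$n_clicks, label = pred$label[i],
        score = pred$score[i], removed = removed))
    }
  }
  keep <- !(detections$table$click_id %in% drop_ids)
  list(detections = detections[keep], report = report)
}
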