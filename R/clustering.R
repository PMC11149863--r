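# Unsupervised identification of click types: graph construction from
# pairwise feature similarities, Chinese Whispers label propagation, and
# consensus partition selection by normalized mutual information.

#' Clustering configuration
#'
#' @param bin_length Time-bin length, seconds (default 300: 5-min bins).
#' @param prune_threshold Edge pruning level, percent. 80 in the standard
#'   pipeline; 95 when building training sets and in the moderate filter's
#'   first pass.
#' @param prune_mode `"percentile"` (the threshold is a percentile of the
#'   off-diagonal weights) or `"absolute"` (threshold/100 is a weight value).
#' @param max_iterations Chinese Whispers iteration cap.
#' @param max_network Maximum clicks per bin network; larger bins are
#'   subsampled (uniformly, seeded) before graph construction.
#' @param min_cluster Minimum clicks per retained cluster (10 standard;
#'   50 in the moderate filter's first pass).
#' @param n_partitions Repeated clustering runs compared by mean NMI.
#' @param spectrum_band Band (kHz) to which spectra are truncated for
#'   similarity computation.
#' @param min_bin_clusters_pass2 Minimum bin-level clusters per retained
#'   signal-type group in the across-bin pass.
#' @param use_envelope_pass2 Include mean envelopes in the across-bin
#'   similarity (disabled for long-duration, variable click types).
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(bin_length = 300, prune_threshold = 80,
                           prune_mode = c("percentile", "absolute"),
                           max_iterations = 25L, max_network = 40000L,
                           min_cluster = 10L, n_partitions = 5L,
                           spectrum_band = c(10, 90),
                           min_bin_clusters_pass2 = 5L,
                           use_envelope_pass2 = TRUE) {
  stopifnot(prune_threshold > 0, prune_threshold < 100, min_cluster >= 2L)
  structure(list(
    bin_length = bin_length, prune_threshold = prune_threshold,
    prune_mode = match.arg(prune_mode), max_iterations = as.integer(max_iterations),
    max_network = as.integer(max_network), min_cluster = as.integer(min_cluster),
    n_partitions = as.integer(n_partitions), spectrum_band = spectrum_band,
    min_bin_clusters_pass2 = as.integer(min_bin_clusters_pass2),
    use_envelope_pass2 = use_envelope_pass2
  ), class = "cluster_config")
}

# Truncate dB spectra to the analysis band and min-max normalize each row.
normalize_spectra <- function(spectra, freq_khz, band) {
  keep <- freq_khz >= band[1L] & freq_khz <= band[2L]
  t(apply(spectra[, keep, drop = FALSE], 1L, minmax_norm))
}

# Pearson similarity on rows, clipped to [0, 1]; degenerate rows get 0.
.cor_similarity <- function(mat) {
  s <- suppressWarnings(stats::cor(t(mat)))
  s[!is.finite(s)] <- 0
  diag(s) <- 1
  pmin(pmax(s, 0), 1)
}

#' Pairwise similarity matrix for clustering
#'
#' Spectral (and optionally envelope) similarity is one minus the Pearson
#' correlation distance, clipped to \[0, 1\]; modal-ICI similarity is
#' `exp(-d / 0.1)` of the Euclidean distance between modal ICIs in seconds.
#' When several feature families are supplied, the per-family similarities
#' are combined by arithmetic mean.
#'
#' @param spectra Matrix of dB spectra, one row per item.
#' @param freq_khz Frequency axis of the spectrum columns, kHz.
#' @param envelopes Optional matrix of envelopes, one row per item.
#' @param modal_icis Optional vector of modal ICIs, seconds (`NA` allowed;
#'   pairs involving `NA` get ICI similarity 0).
#' @param config A [cluster_config()] (band for spectral truncation).
#' @return Symmetric matrix of edge weights in \[0, 1\] with unit diagonal.
#' @export
similarity_matrix <- function(spectra, freq_khz = NULL, envelopes = NULL,
                              modal_icis = NULL, config = cluster_config()) {
  n <- nrow(spectra)
  if (is.null(n) || n < 2L) stop("need at least 2 items to compare")
  if (!is.null(freq_khz))
    spectra <- normalize_spectra(spectra, freq_khz, config$spectrum_band)
  sims <- list(.cor_similarity(spectra))
  if (!is.null(envelopes)) sims <- c(sims, list(.cor_similarity(envelopes)))
  if (!is.null(modal_icis)) {
    d <- abs(outer(modal_icis, modal_icis, "-"))
    s_ici <- exp(-d / 0.1)
    s_ici[!is.finite(s_ici)] <- 0
    diag(s_ici) <- 1
    sims <- c(sims, list(s_ici))
  }
  Reduce(`+`, sims) / length(sims)
}

#' Prune weak edges from a similarity matrix
#'
#' In percentile mode (the default) the cutoff is the
#' `prune_threshold`-th percentile of the off-diagonal weights; in
#' absolute mode the cutoff is `prune_threshold / 100` as a weight value.
#' Edges at or above the cutoff are retained.
#'
#' @param weights Symmetric weight matrix from [similarity_matrix()].
#' @param prune_threshold Pruning level, percent.
#' @param mode `"percentile"` or `"absolute"`.
#' @return A `click_graph`: edge list (`i`, `j`, `w` with `i < j`) plus
#'   node count `n`.
#' @export
prune_edges <- function(weights, prune_threshold = 80,
                        mode = c("percentile", "absolute")) {
  mode <- match.arg(mode)
  n <- nrow(weights)
  ut <- upper.tri(weights)
  w <- weights[ut]
  cutoff <- if (mode == "percentile")
    stats::quantile(w, prune_threshold / 100, names = FALSE)
  else prune_threshold / 100
  idx <- which(ut & weights >= cutoff, arr.ind = TRUE)
  structure(list(n = n, i = idx[, 1L], j = idx[, 2L],
                 w = weights[idx]), class = "click_graph")
}

#' @export
print.click_graph <- function(x, ...) {
  cat(sprintf("<click_graph> %d nodes, %d edges\n", x$n, length(x$w)))
  invisible(x)
}

#' Chinese Whispers graph clustering
#'
#' Iterative label propagation: starting from singleton labels, nodes are
#' visited in a seeded random order (re-randomized each iteration) and each
#' adopts the label with the maximum summed edge weight among its
#' neighbors, ties going to the lowest label id, until no label changes or
#' `max_iterations` is reached. Isolated nodes keep singleton labels.
#'
#' @param graph A `click_graph` from [prune_edges()].
#' @param max_iterations Iteration cap.
#' @param seed Integer seed controlling visit orders.
#' @return Integer vector of cluster labels (1, 2, ... in order of first
#'   appearance), one per node.
#' @export
chinese_whispers <- function(graph, max_iterations = 25L, seed = 1L) {
  stopifnot(inherits(graph, "click_graph"))
  n <- graph$n
  if (n == 1L) return(1L)
  orders <- with_seed(seed, t(vapply(seq_len(max_iterations),
                                     function(i) sample.int(n), integer(n))))
  lab <- cw_propagate(n, as.integer(graph$i), as.integer(graph$j),
                      as.numeric(graph$w), orders, seq_len(n))
  as.integer(factor(lab, levels = unique(lab)))
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the mean of the two partition
#' entropies (natural logarithms). When both partitions have zero entropy
#' the score is 1 if they are identical as partitions and 0 otherwise;
#' when exactly one entropy is zero the score is 0.
#'
#' @param a,b Label vectors over the same nodes.
#' @return NMI score in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must cover the same node set")
  n <- length(a)
  tab <- table(a, b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  max(0, min(1, mi / ((ha + hb) / 2)))
}

#' Consensus partition by repeated clustering
#'
#' Runs [chinese_whispers()] `n_partitions` times with distinct derived
#' seeds and returns the partition with the highest mean NMI against all
#' other runs (first such run on ties). Deterministic given `seed`.
#'
#' @param graph A `click_graph`.
#' @param config A [cluster_config()].
#' @param seed Integer seed.
#' @return Integer label vector of the selected partition.
#' @export
select_partition <- function(graph, config = cluster_config(), seed = 1L) {
  stopifnot(graph$n >= 1L)
  np <- config$n_partitions
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, np))
  parts <- lapply(seeds, function(s)
    chinese_whispers(graph, config$max_iterations, seed = s))
  if (np == 1L) return(parts[[1L]])
  score <- vapply(seq_len(np), function(i)
    mean(vapply(seq_len(np)[-i], function(j) nmi(parts[[i]], parts[[j]]), 0)), 0)
  parts[[which.max(score)]]
}

# One bin-level cluster record.
new_click_cluster <- function(bin_id, member_ids, summary, pseudo = FALSE) {
  structure(list(bin_id = bin_id, member_ids = member_ids, summary = summary,
                 n_clicks = summary$n_clicks, pseudo = pseudo,
                 label = NA_character_, score = NA_real_),
            class = "click_cluster")
}

#' @export
print.click_cluster <- function(x, ...) {
  cat(sprintf("<click_cluster> bin %s, %d clicks%s%s\n", x$bin_id, x$n_clicks,
              if (x$pseudo) " (pseudo-cluster)" else "",
              if (is.na(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Cluster the detections of one time bin into click types
#'
#' Builds the similarity network over the bin's spectra (truncated to the
#' analysis band and normalized), prunes weak edges, and partitions it by
#' consensus Chinese Whispers. Clusters with fewer than `min_cluster`
#' members are discarded (their clicks stay unlabeled). When the bin holds
#' fewer than `min_cluster` clicks no clustering is applied: all clicks are
#' averaged into a single pseudo-cluster so they remain classifiable. Bins
#' larger than `max_network` are subsampled before graph construction.
#'
#' @param detections `click_detections` falling inside one bin.
#' @param config A [cluster_config()].
#' @param bin_id Identifier carried into the output clusters.
#' @param seed Integer seed.
#' @return List of `click_cluster` objects (possibly empty).
#' @export
cluster_bin <- function(detections, config = cluster_config(), bin_id = 0L,
                        seed = 1L) {
  k <- n_detections(detections)
  if (k == 0L) return(list())
  if (k < config$min_cluster) {
    return(list(new_click_cluster(bin_id, detections$table$click_id,
                                  cluster_summary(detections), pseudo = TRUE)))
  }
  if (k > config$max_network) {
    keep <- with_seed(seed, sort(sample.int(k, config$max_network)))
    detections <- detections[keep]
    k <- config$max_network
  }
  freq <- attr(detections$spectra, "freq_khz")
  w <- similarity_matrix(detections$spectra, freq_khz = freq, config = config)
  g <- prune_edges(w, config$prune_threshold, config$prune_mode)
  part <- select_partition(g, config, seed = seed)
  out <- list()
  for (lab in unique(part)) {
    members <- which(part == lab)
    if (length(members) < config$min_cluster) next
    out[[length(out) + 1L]] <- new_click_cluster(
      bin_id, detections$table$click_id[members],
      cluster_summary(detections[members]))
  }
  out
}

#' Cluster a detection record into 5-min bins of click types
#'
#' Assigns detections to consecutive `bin_length` bins anchored at time 0
#' (half-open) and runs [cluster_bin()] in each.
#'
#' @param detections A `click_detections` object.
#' @param config A [cluster_config()].
#' @param seed Integer master seed (one seed is derived per bin).
#' @return List of `click_cluster` objects across all bins.
#' @export
cluster_bins <- function(detections, config = cluster_config(), seed = 1L) {
  if (n_detections(detections) == 0L) return(list())
  bin <- floor(detections$table$start_s / config$bin_length)
  ids <- sort(unique(bin))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, length(ids)))
  out <- list()
  for (i in seq_along(ids)) {
    cl <- cluster_bin(detections[bin == ids[i]], config,
                      bin_id = ids[i], seed = seeds[i])
    out <- c(out, cl)
  }
  out
}

#' Group bin-level clusters into signal types
#'
#' The across-bin pass: bin-level cluster summaries are compared by mean
#' spectral shape, mean envelope (optional) and modal-ICI similarity, the
#' per-family similarities averaged, and the same consensus Chinese
#' Whispers applied. Groups with fewer than `min_bin_clusters_pass2`
#' members are discarded.
#'
#' @param bin_clusters List of `click_cluster` objects (>= 2).
#' @param config A [cluster_config()].
#' @param seed Integer seed.
#' @return List of integer vectors, each the indices into `bin_clusters`
#'   of one retained signal-type group.
#' @export
cluster_types_across_bins <- function(bin_clusters, config = cluster_config(),
                                      seed = 1L) {
  if (length(bin_clusters) < 2L)
    stop("need at least 2 bin-level clusters")
  spectra <- t(vapply(bin_clusters, function(cl) cl$summary$mean_spectrum,
                      bin_clusters[[1L]]$summary$mean_spectrum))
  freq <- bin_clusters[[1L]]$summary$freq_khz
  envelopes <- if (config$use_envelope_pass2)
    t(vapply(bin_clusters, function(cl) cl$summary$mean_envelope,
             numeric(ENV_POINTS)))
  icis <- vapply(bin_clusters, function(cl) cl$summary$modal_ici, 0)
  w <- similarity_matrix(spectra, freq_khz = freq, envelopes = envelopes,
                         modal_icis = icis, config = config)
  g <- prune_edges(w, config$prune_threshold, config$prune_mode)
  part <- select_partition(g, config, seed = seed)
  groups <- list()
  for (lab in unique(part)) {
    members <- which(part == lab)
    if (length(members) < config$min_bin_clusters_pass2) next
    groups[[length(groups) + 1L]] <- members
  }
  groups
}
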