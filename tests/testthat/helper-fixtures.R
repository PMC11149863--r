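# Shared fixtures and independent oracles for the test suite.

TPL <- builtin_templates()
TPL_ALL <- builtin_templates(include_variants = TRUE)
DET_CFG <- detector_config(calibration_offset = 154)

# Independent brute-force NMI oracle: explicit contingency table built by
# double loop, entropies from first principles. Deliberately naive.
nmi_bruteforce <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  cont <- matrix(0, length(ua), length(ub))
  for (i in seq_len(n)) {
    cont[match(a[i], ua), match(b[i], ub)] <- cont[match(a[i], ua), match(b[i], ub)] + 1
  }
  pa <- rowSums(cont) / n
  pb <- colSums(cont) / n
  ha <- 0; for (p in pa) if (p > 0) ha <- ha - p * log(p)
  hb <- 0; for (p in pb) if (p > 0) hb <- hb - p * log(p)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub)) {
    pij <- cont[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (pa[i] * pb[j]))
  }
  mi / ((ha + hb) / 2)
}

# All set partitions of seq_len(n) as label vectors (restricted growth
# strings), used to enumerate partition pairs for the NMI oracle.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (l in seq_len(next_max + 1L)) {
      recurse(c(labels, l), max(next_max, l))
    }
  }
  recurse(integer(0), 0L)
  out
}

# A planted-partition weighted graph: two or three blocks with strong
# in-block and weak out-block similarities.
planted_graph <- function(sizes, seed, w_in = c(0.7, 1), w_out = c(0, 0.25)) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  with_seed(seed, {
    w <- matrix(stats::runif(n * n, w_out[1], w_out[2]), n, n)
    for (b in seq_along(sizes)) {
      idx <- which(block == b)
      w[idx, idx] <- stats::runif(length(idx) ^ 2, w_in[1], w_in[2])
    }
    w <- (w + t(w)) / 2
    diag(w) <- 1
    list(w = w, block = block)
  })
}

# A synthetic click_metrics object with a controllable envelope, for
# exercising the hard-filter rules without synthesizing audio.
fake_metrics <- function(duration = 400, peak = 40, center = 30, sweep = 30,
                         envelope_ok = TRUE, sample_rate = 200000) {
  n <- 400L
  t <- seq_len(n)
  env <- if (envelope_ok) {
    # rises over the first 0.1-ms window, then sustains near max
    pmin(1, t / 20) * exp(-pmax(0, t - 300) / 100)
  } else {
    # immediate decay: negative slope from the click start
    exp(-t / 30)
  }
  structure(list(peak_freq = peak, center_freq = center, duration = duration,
                 sweep_rate = sweep, envelope = env, start_idx = 1L,
                 end_idx = n, rl_pp = 125, sample_rate = sample_rate),
            class = "click_metrics")
}

# Memoized small 11-class network shared across tests that need a trained
# classifier (moderate filter, pipelines).
.fixture_env <- new.env(parent = emptyenv())
test_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  lab <- simulate_labeled_clusters(TPL, n_per_class = 40L,
                                   clicks_per_cluster = 12L, seed = 2024)
  layout <- feature_layout(lab$clusters[[1L]]$summary$freq_khz)
  x <- cluster_features(lab$clusters, layout)
  cfg <- train_config(examples_per_class = 100L, n_train_test = c(70L, 30L))
  bal <- balance_classes(x, lab$labels, cfg, seed = 7)
  .fixture_env$model <- build_and_train(bal, cfg, layout, seed = 7)
  .fixture_env$model_data <- list(bal = bal, layout = layout, lab = lab)
  .fixture_env$model
}
test_model_data <- function() {
  test_model()
  .fixture_env$model_data
}
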