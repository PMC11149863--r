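# Graph construction, Chinese Whispers, NMI and the two clustering passes.

test_that("similarity matrices are well-formed and family rules hold", {
  X <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(4, 3, 2, 1))
  w <- similarity_matrix(X)
  expect_equal(dim(w), c(3L, 3L))
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(1, 3))
  expect_equal(w[1, 2], 1)               # identical spectra
  expect_equal(w[1, 3], 0)               # anticorrelated, clipped to 0
  one_hot <- diag(4)[1:2, ]
  expect_equal(similarity_matrix(one_hot)[1, 2], 0)
  expect_error(similarity_matrix(X[1, , drop = FALSE]), "at least 2")
  # ICI similarity decreases with modal-ICI distance
  w2 <- similarity_matrix(rbind(X[1, ], X[1, ], X[1, ]),
                          modal_icis = c(0.1, 0.5, 0.1))
  expect_lt(w2[1, 2], w2[1, 3])
  expect_equal(w2[1, 3], 1)
})

test_that("edge pruning matches a direct percentile computation", {
  w <- with_seed(5, {
    m <- matrix(runif(100), 10, 10)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
  g <- prune_edges(w, 80)
  off <- w[upper.tri(w)]
  cutoff <- quantile(off, 0.8, names = FALSE)
  expected <- sum(off >= cutoff)
  expect_equal(length(g$w), expected)
  expect_true(all(g$w >= cutoff))
  # boundary thresholds
  expect_equal(length(prune_edges(w, 0)$w), length(off))
  g100 <- prune_edges(w, 100 - 1e-9)
  expect_true(all(g100$w >= max(off) - 1e-12))
  # absolute mode uses the raw weight value
  ga <- prune_edges(w, 50, mode = "absolute")
  expect_equal(length(ga$w), sum(off >= 0.5))
})

test_that("Chinese Whispers returns connected components on clique graphs for any seed", {
  w <- matrix(0, 12, 12)
  w[1:5, 1:5] <- 0.9
  w[6:12, 6:12] <- 0.8
  diag(w) <- 1
  g <- prune_edges(w, 50, mode = "absolute")
  for (s in 1:20) {
    lab <- chinese_whispers(g, seed = s)
    expect_equal(length(unique(lab)), 2L)
    expect_equal(length(unique(lab[1:5])), 1L)
    expect_equal(length(unique(lab[6:12])), 1L)
  }
  # single node
  g1 <- structure(list(n = 1L, i = integer(0), j = integer(0),
                       w = numeric(0)), class = "click_graph")
  expect_equal(chinese_whispers(g1), 1L)
})

test_that("Chinese Whispers recovers planted partitions on noisy graphs", {
  hits <- 0L
  n_seeds <- 60L
  for (s in seq_len(n_seeds)) {
    pg <- planted_graph(c(20, 15, 15), seed = s)
    g <- prune_edges(pg$w, 60)
    lab <- chinese_whispers(g, seed = s + 1000L)
    hits <- hits + (nmi(lab, pg$block) > 1 - 1e-9)
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("NMI matches the brute-force contingency oracle", {
  expect_equal(nmi(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_error(nmi(1:3, 1:4), "same node set")
  # all partition pairs on 5 nodes
  parts <- all_partitions(5L)
  for (i in seq_along(parts)) {
    for (j in seq_along(parts)) {
      expect_equal(nmi(parts[[i]], parts[[j]]),
                   nmi_bruteforce(parts[[i]], parts[[j]]), tolerance = 1e-12)
    }
  }
  # random label pairs on 8 nodes, plus symmetry and renaming invariance
  for (s in 1:50) {
    ab <- with_seed(s, list(sample(1:3, 8, TRUE), sample(1:4, 8, TRUE)))
    expect_equal(nmi(ab[[1]], ab[[2]]), nmi_bruteforce(ab[[1]], ab[[2]]),
                 tolerance = 1e-12)
    expect_equal(nmi(ab[[1]], ab[[2]]), nmi(ab[[2]], ab[[1]]))
    expect_equal(nmi(ab[[1]], ab[[2]]), nmi(ab[[1]] + 10, ab[[2]] * 3))
    expect_gte(nmi(ab[[1]], ab[[2]]), 0)
    expect_lte(nmi(ab[[1]], ab[[2]]), 1)
  }
  # degenerate conventions
  expect_equal(nmi(c(1, 1, 1), c(2, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 1), c(1, 2, 2)), 0)
})

test_that("NMI agrees with an independent library implementation", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    ab <- with_seed(s, list(sample(1:4, 12, TRUE), sample(1:3, 12, TRUE)))
    expect_equal(nmi(ab[[1]], ab[[2]]),
                 igraph::compare(ab[[1]], ab[[2]], method = "nmi"),
                 tolerance = 1e-10)
  }
})

test_that("partition selection maximizes mean NMI and is deterministic", {
  pg <- planted_graph(c(10, 10), seed = 3)
  g <- prune_edges(pg$w, 60)
  cfg1 <- cluster_config(n_partitions = 1L)
  expect_equal(select_partition(g, cfg1, seed = 2),
               chinese_whispers(g, seed = with_seed(2, sample.int(.Machine$integer.max - 1L, 1L))))
  p1 <- select_partition(g, cluster_config(), seed = 9)
  p2 <- select_partition(g, cluster_config(), seed = 9)
  expect_identical(p1, p2)
  expect_equal(nmi(p1, pg$block), 1)
})

test_that("bin clustering separates click types and respects the minimum size", {
  det <- simulate_detections(list(scene_event(TPL$Zc, 0, 30, 128),
                                  scene_event(TPL$Mb, 1, 30, 128)), seed = 7)
  cl <- cluster_bin(det, cluster_config(), bin_id = 0, seed = 3)
  expect_equal(length(cl), 2L)
  peaks <- sort(vapply(cl, function(c)
    c$summary$freq_khz[which.max(c$summary$mean_spectrum)], 0))
  expect_lt(abs(peaks[1] - 40), 2)
  expect_true(peaks[2] >= 50 && peaks[2] <= 90)
  # below min_cluster: one pseudo-cluster forwarding all clicks
  few <- simulate_detections(list(scene_event(TPL$Zc, 0, 9, 128)), seed = 8)
  pcl <- cluster_bin(few, cluster_config(), bin_id = 4, seed = 1)
  expect_equal(length(pcl), 1L)
  expect_true(pcl[[1]]$pseudo)
  expect_equal(pcl[[1]]$n_clicks, 9L)
  # empty bin
  expect_equal(cluster_bin(det[0], cluster_config()), list())
  # determinism of the full bin output
  cl2 <- cluster_bin(det, cluster_config(), bin_id = 0, seed = 3)
  expect_equal(cl, cl2)
  # raising min_cluster never increases the number of emitted clusters
  for (mc in c(10L, 20L, 31L)) {
    cfg <- cluster_config(min_cluster = mc)
    expect_lte(length(cluster_bin(det, cfg, bin_id = 0, seed = 3)), length(cl))
  }
})

test_that("across-bin clustering groups signal types and drops small groups", {
  mk <- function(tpl, n, seed0) {
    lapply(seq_len(n), function(i) {
      det <- simulate_detections(list(scene_event(tpl, 0, 12, 128)),
                                 seed = seed0 + i)
      bwclassify:::new_click_cluster(i, det$table$click_id,
                                     cluster_summary(det))
    })
  }
  cls <- c(mk(TPL$Zc, 10, 100), mk(TPL$Mb, 10, 200))
  groups <- cluster_types_across_bins(cls, cluster_config(), seed = 5)
  expect_equal(length(groups), 2L)
  types <- lapply(groups, function(g) unique(ifelse(g <= 10, "Zc", "Mb")))
  expect_true(all(lengths(types) == 1L))
  # envelope on/off gives the same grouping for well-separated types
  g2 <- cluster_types_across_bins(cls, cluster_config(use_envelope_pass2 = FALSE),
                                  seed = 5)
  expect_equal(length(g2), 2L)
  # fewer than min_bin_clusters_pass2 of a single type: nothing retained
  few <- mk(TPL$Zc, 4, 300)
  expect_equal(cluster_types_across_bins(few, cluster_config(), seed = 2),
               list())
  expect_error(cluster_types_across_bins(few[1]), "at least 2")
})
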