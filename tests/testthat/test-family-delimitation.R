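# Hard and moderate negative filters.

test_that("each hard-filter rule gates exactly at its threshold", {
  base <- list(duration = 400, peak = 40, center = 30, sweep = 30)
  ok <- click_passes_hard_rules(fake_metrics())
  expect_true(ok$pass)
  expect_true(all(ok$flags))
  cases <- list(
    list(duration = 354, flag = "duration"),
    list(duration = 300, flag = "duration"),
    list(peak = 31, flag = "peak_freq"),
    list(peak = 31.9, flag = "peak_freq"),
    list(center = 24.9, flag = "center_freq"),
    list(sweep = 22.9, flag = "sweep_rate"),
    list(sweep = NA_real_, flag = "sweep_rate")
  )
  for (cs in cases) {
    args <- utils::modifyList(base, cs[names(cs) != "flag"])
    m <- fake_metrics(duration = args$duration, peak = args$peak,
                      center = args$center, sweep = args$sweep)
    r <- click_passes_hard_rules(m)
    expect_false(r$pass)
    expect_false(r$flags[[cs$flag]])
    expect_true(all(r$flags[setdiff(names(r$flags), c(cs$flag, "envelope"))]))
  }
  # values just above every threshold pass
  m <- fake_metrics(duration = 356, peak = 32.1, center = 25.1, sweep = 23.1)
  expect_true(click_passes_hard_rules(m)$pass)
  # a decaying envelope fails only the envelope rule
  r <- click_passes_hard_rules(fake_metrics(envelope_ok = FALSE))
  expect_false(r$pass)
  expect_false(r$flags[["envelope"]])
  expect_true(all(r$flags[names(r$flags) != "envelope"]))
})

test_that("the 75-s interval retention rule matches direct counting", {
  det <- simulate_detections(list(scene_event(TPL$Zc, 0, 40, 128)), seed = 2)
  with_seed(99, {
    for (rep in 1:200) {
      n <- sample(1:100, 1)
      k <- sample(0:n, 1)
      pass <- sample(c(rep(TRUE, k), rep(FALSE, n - k)))
      sub <- det[rep_len(seq_len(n_detections(det)), n)]
      sub$table$start_s <- sort(runif(n, 0, 74.9))
      sub$table$click_id <- seq_len(n)
      res <- hard_negative_filter(sub, pass = pass)
      expected <- k >= 7 || (k / n) >= 0.13
      expect_equal(res$report$retained[1], expected)
      expect_equal(n_detections(res$detections), if (expected) n else 0L)
    }
  })
})

test_that("interval arithmetic follows the 7-candidate / 13% rule", {
  det <- simulate_detections(list(scene_event(TPL$Zc, 0, 10, 128)), seed = 2)
  # 6 passing of 100 -> dropped; 2 of 10 -> retained
  d100 <- det[rep_len(1:10, 100)]
  d100$table$start_s <- seq(0, 70, length.out = 100)
  d100$table$click_id <- 1:100
  r1 <- hard_negative_filter(d100, pass = c(rep(TRUE, 6), rep(FALSE, 94)))
  expect_equal(n_detections(r1$detections), 0L)
  r2 <- hard_negative_filter(det, pass = c(TRUE, TRUE, rep(FALSE, 8)))
  expect_equal(n_detections(r2$detections), 10L)
})

test_that("the hard filter is idempotent, order-preserving and monotone", {
  det <- simulate_detections(list(scene_event(TPL$Zc, 0, 25, 128),
                                  scene_event(TPL[["De spp"]], 80, 120, 132)),
                             seed = 6)
  once <- hard_negative_filter(det)
  twice <- hard_negative_filter(once$detections)
  expect_equal(twice$detections$table, once$detections$table)
  # subset property, order preserved
  expect_true(all(once$detections$table$click_id %in% det$table$click_id))
  expect_false(is.unsorted(once$detections$table$start_s))
  # raising a threshold never retains more clicks
  stricter <- hard_filter_config(min_peak_freq = 45)
  expect_lte(n_detections(hard_negative_filter(det, stricter)$detections),
             n_detections(once$detections))
})

test_that("a delphinid-only scene is almost entirely removed by the hard filter", {
  det <- simulate_detections(list(scene_event(TPL[["De spp"]], 0, 300, 132)),
                             seed = 14)
  res <- hard_negative_filter(det)
  expect_lte(n_detections(res$detections), 0.01 * 300)
})

test_that("the moderate filter removes dominant non-beaked clusters and keeps the rest", {
  model <- test_model()
  det <- simulate_detections(list(
    scene_event(TPL[["De spp"]], 0, 1000, 135),
    scene_event(TPL$Zc, 5, 15, 126)), seed = 19)
  res <- moderate_negative_filter(det, model, seed = 4)
  surv <- res$detections$table$true_class
  expect_equal(sum(surv == "Zc"), 15L)
  # the dominant train is mostly removed; stragglers outside the large
  # pass-1 clusters survive by design
  expect_lte(sum(surv == "De spp"), 0.3 * 1000)
  expect_true(all(res$report$removed == (res$report$n_clicks >= 50 &
                    !(res$report$label %in% beaked_whale_classes()))))
  # a bin with few clicks forms no removable cluster
  small <- simulate_detections(list(scene_event(TPL[["De spp"]], 0, 30, 132)),
                               seed = 3)
  res2 <- moderate_negative_filter(small, model, seed = 1)
  expect_equal(n_detections(res2$detections), 30L)
  # a model lacking the beaked classes is rejected
  bad <- model
  bad$classes <- c("a", "b")
  expect_error(moderate_negative_filter(det, bad), "class list")
})
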