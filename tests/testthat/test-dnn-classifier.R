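# Training-set assembly, the dense network, and prediction.

test_that("feature vectors are [0,1], fixed-length and deterministic", {
  det <- simulate_detections(list(scene_event(TPL$Zc, 0, 12, 128)), seed = 4)
  s <- cluster_summary(det)
  layout <- feature_layout(s$freq_khz)
  v <- feature_vector(s, layout)
  expect_length(v, layout$length)
  expect_equal(layout$length, layout$n_spec + 80L + 200L)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(v, feature_vector(s, layout))
  # degenerate constant segment maps to zeros
  s0 <- s
  s0$mean_spectrum[] <- 0.4
  v0 <- feature_vector(s0, layout)
  expect_true(all(v0[seq_len(layout$n_spec)] == 0))
  # layout mismatch
  bad <- feature_layout(seq(0, 50, by = 0.25))
  expect_error(feature_vector(s, bad), "layout")
})

test_that("encounters are built by the 15-min gap rule and never split across sets", {
  sp <- split_encounters(c(0, 10, 40), config = train_config(), seed = 1)
  expect_equal(sp$encounter, c(1L, 1L, 2L))
  # 10 equal encounters split 7/1/2
  times <- as.vector(vapply(0:9, function(e) e * 100 + (0:9) * 2, numeric(10)))
  sp10 <- split_encounters(times, seed = 3)
  enc_sets <- table(unique(data.frame(e = sp10$encounter, s = sp10$set))$s)
  expect_equal(as.vector(enc_sets[c("train", "validate", "test")]), c(7L, 1L, 2L))
  # no encounter leakage over many random seeds
  lab <- with_seed(11, {
    t <- cumsum(c(0, sample(c(2, 2, 2, 60), 199, TRUE)))
    s <- sample(1:3, 200, TRUE)
    list(t = t, s = rep(1L, 200))
  })
  for (seed in 1:100) {
    sp <- split_encounters(lab$t, lab$s, seed = seed)
    leak <- tapply(sp$set, sp$encounter, function(x) length(unique(x)))
    expect_true(all(leak == 1L))
  }
  expect_warning(split_encounters(c(0, 5, 10)), "single encounter")
})

test_that("class balancing yields the exact per-class counts and splits", {
  with_seed(21, {
    counts <- c(BWG = 29L, Mb = 1852L, Zc = 3000L)
    y <- rep(names(counts), counts)
    x <- matrix(runif(length(y) * 8), ncol = 8)
    bal <- balance_classes(x, y, train_config(), seed = 5)
    expect_equal(as.vector(table(bal$y)), rep(1500L, 3))
    expect_true(all(bal$x >= 0 & bal$x <= 1))
    split_tab <- table(bal$y, bal$split)
    expect_true(all(split_tab[, "train"] == 800L))
    expect_true(all(split_tab[, "validate"] == 200L))
    expect_true(all(split_tab[, "test"] == 500L))
    expect_error(balance_classes(x, factor(y, c(names(counts), "Gg")),
                                 train_config(), seed = 1), "Gg")
  })
})

test_that("training is seed-deterministic and the parameter count is structural", {
  md <- test_model_data()
  net1 <- build_and_train(md$bal, train_config(examples_per_class = 100L,
                                               n_train_test = c(70L, 30L)),
                          md$layout, seed = 7)
  net2 <- test_model()
  expect_identical(net1$weights, net2$weights)
  expect_identical(net1$history, net2$history)
  d <- md$layout$length
  h <- net2$config$hidden
  expected <- (d * h[1] + h[1]) + sum(h[-length(h)] * h[-1] + h[-1]) +
    (h[length(h)] * 11 + 11)
  expect_equal(n_params(net2), expected)
})

test_that("prediction propagates labels, scores and probabilities coherently", {
  model <- test_model()
  md <- test_model_data()
  # memorization sanity: training exemplars get their own class
  tr <- which(md$bal$split == "train")[1:50]
  pred <- predict(model, md$bal$x[tr, , drop = FALSE])
  expect_gte(mean(pred$label == md$bal$y[tr]), 0.95)
  P <- attr(pred, "prob")
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-9)
  expect_equal(pred$score, apply(P, 1, max))
  # batch prediction equals concatenated single predictions
  single <- do.call(rbind, lapply(tr[1:5], function(i)
    predict(model, md$bal$x[i, , drop = FALSE])))
  expect_equal(single$label, pred$label[1:5])
  expect_equal(single$score, pred$score[1:5])
  # layout mismatch errors
  expect_error(predict(model, md$bal$x[1:2, 1:10]), "layout")
})

test_that("held-out accuracy on synthetic classes is high and labels reach clicks", {
  model <- test_model()
  md <- test_model_data()
  te <- md$bal$split == "test"
  pred <- predict(model, md$bal$x[te, , drop = FALSE])
  expect_gte(mean(pred$label == md$bal$y[te]), 0.95)
  # cluster-level prediction propagates to member clicks via the pipeline
  det <- simulate_detections(list(scene_event(TPL$Mb, 0, 30, 128)), seed = 9)
  res <- run_pipeline(det, "generalized", model, seed = 2)
  expect_true(nrow(res$click_labels) > 0)
  expect_true(all(res$click_labels$label == "Mb"))
})

test_that("model serialization round-trips bit-exactly", {
  model <- test_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$classes, model$classes)
})
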