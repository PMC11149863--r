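# Synthetic click, train and scene generation.

test_that("built-in template library covers the 11 classes with the printed parameters", {
  expect_gte(length(TPL), 11L)
  expect_setequal(beaked_whale_classes(), c("BWG", "Mb", "Md", "Me", "Mm", "Zc"))
  zc <- TPL$Zc
  expect_equal(zc$peak_freq, 40)
  expect_setequal(zc$secondary_peaks, c(19, 24, 70))
  expect_equal(zc$modal_ici, 0.51)
  mb <- TPL$Mb
  expect_gte(mb$onset_freq, 50)
  expect_lte(2 * mb$peak_freq - mb$onset_freq, 90)
  expect_equal(mb$modal_ici, 0.13)
  bwg <- TPL$BWG
  expect_gt(bwg$duration, 500)
  expect_equal(bwg$modal_ici, 0.1, tolerance = 0.05)
  expect_equal(bwg$secondary_peaks, 17)
  expect_equal(TPL$Mm$modal_ici, 0.19)
  expect_equal(TPL$Me$modal_ici, 0.28)
})

test_that("template invariants are enforced", {
  expect_error(species_template("x", onset_freq = 50, peak_freq = 40,
                                duration = 300, modal_ici = 0.2),
               "onset_freq < peak_freq")
  expect_error(species_template("x", onset_freq = 10, peak_freq = 40,
                                duration = 0, modal_ici = 0.2), "duration")
  expect_error(species_template("x", onset_freq = 10, peak_freq = 40,
                                duration = 300, modal_ici = 0.2,
                                sweep_rate = -1), "sweep_rate")
})

test_that("synthesized clicks match their template's measured descriptors", {
  for (nm in c("Zc", "Mb", "Md", "Me", "Mm", "BWG")) {
    tpl <- TPL[[nm]]
    for (s in 1:5) {
      m <- click_metrics(as.numeric(make_click(tpl, 200000, seed = s)),
                         200000, DET_CFG)
      expect_lt(abs(m$duration / tpl$duration - 1), 0.2, label = nm)
      expect_lt(abs(m$peak_freq - tpl$peak_freq), 2, label = nm)
      expect_gte(m$sweep_rate, 0.85 * tpl$sweep_rate)
    }
  }
})

test_that("Zc clicks measure a peak frequency in [38, 42] kHz", {
  for (s in 1:10) {
    m <- click_metrics(as.numeric(make_click(TPL$Zc, 200000, seed = s)),
                       200000, DET_CFG)
    expect_gte(m$peak_freq, 38)
    expect_lte(m$peak_freq, 42)
  }
})

test_that("Gulf of Mexico Blainville's variant stays under 250 us", {
  for (s in 1:5) {
    m <- click_metrics(as.numeric(make_click(TPL_ALL$Md_GoM, 200000, seed = s)),
                       200000, DET_CFG)
    expect_lt(m$duration, 250)
  }
})

test_that("make_click rejects invalid templates and is seed-deterministic", {
  bad <- TPL$Zc
  bad$duration <- 0
  expect_error(make_click(bad, 200000), "duration")
  ko <- TPL[["Ko spp"]]
  expect_error(make_click(ko, 150000), "Nyquist")
  expect_identical(as.numeric(make_click(TPL$Zc, 200000, seed = 5)),
                   as.numeric(make_click(TPL$Zc, 200000, seed = 5)))
  expect_false(identical(as.numeric(make_click(TPL$Zc, 200000, seed = 5)),
                         as.numeric(make_click(TPL$Zc, 200000, seed = 6))))
})

test_that("click trains have the template rhythm", {
  tpl0 <- TPL$Zc
  tpl0$ici_jitter_sd <- 0
  expect_equal(make_click_train(tpl0, 2, start = 1), c(1, 1.51))
  expect_equal(make_click_train(TPL$Zc, 1, start = 3), 3)
  expect_error(make_click_train(TPL$Zc, 0), "at least 1")
  times <- make_click_train(TPL$Zc, 100, seed = 4)
  expect_true(all(diff(times) > 0))
  expect_lt(abs(ici_distribution(times)$modal_ici - 0.51), 0.011)
})

test_that("rendered scenes are calibrated, deterministic and fully book-kept", {
  empty <- render_scene(scene_config(duration = 0.5, seed = 1))
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(length(empty$waveform), 100000L)

  sc <- scene_config(duration = 12, events = list(
    scene_event(TPL$Zc, 0.5, 15, 125)), noise_floor = 40, seed = 9)
  scene <- render_scene(sc)
  expect_equal(nrow(scene$truth), 15L)
  expect_true(all(scene$truth$class_id == "Zc"))
  expect_true(all(diff(scene$truth$start_s) > 0))
  expect_true(all(scene$truth$start_s >= 0 & scene$truth$end_s < 12))
  # identical config + seed => bit-identical output
  scene2 <- render_scene(sc)
  expect_identical(scene$waveform, scene2$waveform)
  expect_identical(scene$truth, scene2$truth)
  # rendered peak-to-peak level matches the requested received level
  i0 <- round(scene$truth$start_s[1] * 200000)
  seg <- scene$waveform[(i0 - 200):(i0 + 400)]
  rl <- amp_to_db(max(seg) - min(seg)) + scene$calibration_offset
  expect_equal(rl, 125, tolerance = 0.5)
})

test_that("ephemeral scenario ground truth counts the planted classes", {
  det <- simulate_detections(list(
    scene_event(TPL[["De spp"]], 0, 200, 132),
    scene_event(TPL$Zc, 10, 15, 126)), seed = 5)
  expect_equal(sum(det$table$true_class == "De spp"), 200L)
  expect_equal(sum(det$table$true_class == "Zc"), 15L)
  expect_false(is.unsorted(det$table$start_s))
})

test_that("WAV and scene files round-trip", {
  dir <- withr::local_tempdir()
  x <- sin(2 * pi * 1000 * seq_len(4000) / 48000) * 0.5
  write_wav(x, 48000, file.path(dir, "t.wav"))
  back <- read_wav(file.path(dir, "t.wav"))
  expect_equal(back$sample_rate, 48000)
  expect_equal(back$waveform, x, tolerance = 1e-4)
  scene <- render_scene(scene_config(duration = 1, events = list(
    scene_event(TPL$Mb, 0.1, 3, 130)), seed = 2))
  paths <- write_scene(scene, dir)
  expect_true(all(file.exists(paths)))
  truth <- read.csv(paths["truth"])
  expect_equal(names(truth), c("click_id", "class_id", "start_s", "end_s",
                               "rl_pp_db"))
  expect_equal(nrow(truth), 3L)
})
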