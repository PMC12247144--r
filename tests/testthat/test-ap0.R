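rect_recording <- function(srate = 1024, dur = 10, nch = 4) {
  data <- matrix(0, nch, dur * srate)
  data[2, (5 * srate + 1):(5.5 * srate)] <- 500
  eeg_recording(data, srate, positions = dry_montage(nch)$positions)
}

test_that("the detector traces the amplitude rules on a rectangular excursion", {
  rec <- rect_recording()
  per <- detect_ap0(rec)
  expect_identical(nrow(per), 1L)
  expect_identical(per$channel_index, 2L)
  # onset 200 ms before the first crossing: 4.8 s at 1024 Hz
  expect_identical(per$start, 5L * 1024L - as.integer(round(0.2 * 1024)))
  # stabilizes immediately after the excursion ends at 5.5 s
  expect_identical(per$end, as.integer(round(5.5 * 1024)))
  expect_identical(per$peak_amplitude, 500)
})

test_that("signals inside the stable band yield no periods", {
  set.seed(1)
  rec <- eeg_recording(matrix(runif(4 * 4096, -79, 79), 4), 1024)
  expect_identical(nrow(detect_ap0(rec)), 0L)
})

test_that("two excursions 100 ms apart merge into a single period", {
  srate <- 1024
  data <- matrix(0, 2, 10 * srate)
  data[1, (2L * srate + 1):round(2.2 * srate)] <- 400
  data[1, (round(2.3 * srate) + 1):(round(2.5 * srate))] <- -400  # 100 ms later
  rec <- eeg_recording(data, srate)
  per <- detect_ap0(rec)
  expect_identical(nrow(per), 1L)
  expect_lte(per$start, 2L * srate - round(0.2 * srate) + 1L)
  expect_gte(per$end, round(2.5 * srate))
})

test_that("zeroing leaves an exact zero core with Hann half-ramps at half amplitude", {
  srate <- 1024
  rec <- eeg_recording(matrix(200, 2, 10 * srate), srate)
  per <- data.frame(channel = "E01", channel_index = 1L,
                    start = 4 * srate, end = 6 * srate,
                    peak_amplitude = 200, source = "manual")
  out <- apply_zeroing(rec, per, taper = 0.5)
  expect_true(all(out$data[1, (4 * srate + 1):(6 * srate)] == 0))
  # midpoint of the 0.25 s fade-out: 200 * 0.5
  half <- round(0.25 * srate)
  mid <- 4 * srate - half + half / 2 + 1
  expect_equal(unname(out$data[1, mid]), 100, tolerance = 1e-9)
  # samples clear of period and tapers are bit-identical; other channel untouched
  expect_identical(out$data[1, 1:(4 * srate - half)],
                   rec$data[1, 1:(4 * srate - half)])
  expect_identical(out$data[2, ], rec$data[2, ])
  # empty list is the identity
  set.seed(2)
  quiet <- eeg_recording(matrix(runif(2 * 1024, -50, 50), 2), srate)
  expect_identical(apply_zeroing(quiet, detect_ap0(quiet))$data, quiet$data)
})

test_that("taper zones at the recording bounds are truncated without error", {
  srate <- 512
  rec <- eeg_recording(matrix(300, 1, 2 * srate), srate)
  per <- data.frame(channel = "E01", channel_index = 1L, start = 0L,
                    end = 2L * srate, peak_amplitude = 300, source = "manual")
  out <- apply_zeroing(rec, per)
  expect_true(all(out$data == 0))
})

test_that("re-zeroing with the same periods is stable on the core and outside the tapers", {
  rec <- rect_recording()
  per <- detect_ap0(rec)
  once <- apply_zeroing(rec, per)
  twice <- apply_zeroing(once, per)
  half <- round(0.25 * rec$srate)
  core <- (per$start + 1):per$end
  expect_identical(twice$data[2, core], once$data[2, core])
  outside <- setdiff(seq_len(ncol(rec$data)),
                     (per$start - half + 1):(per$end + half))
  expect_identical(twice$data[, outside], once$data[, outside])
})

test_that("span interpolation reproduces constants and smooth backgrounds", {
  mt <- dry_montage(32)
  rec <- eeg_recording(matrix(20, 32, 2048), 1024, mt$names, mt$positions)
  per <- data.frame(channel = "E07", channel_index = 7L, start = 100L,
                    end = 1100L, peak_amplitude = 0, source = "manual")
  out <- interpolate_ap0_spans(rec, per)
  expect_lt(max(abs(out$data[7, 101:1100] - 20)), 1e-6)
  expect_identical(out$data[, c(1:100, 1101:2048)],
                   rec$data[, c(1:100, 1101:2048)])
  expect_identical(interpolate_ap0_spans(rec, detect_ap0(rec)), rec)
  # >= 1 s span of a smooth background is restored faithfully
  gen <- generate_recording(quiet_config(duration = 6, seed = 44))
  rec <- gen$recording
  span <- 2049:3584                                # 1.5 s
  orig <- rec$data[5, span]
  rec$data[5, span] <- 0
  per <- data.frame(channel = rec$channel_names[5], channel_index = 5L,
                    start = 2048L, end = 3584L, peak_amplitude = 0,
                    source = "manual")
  out <- interpolate_ap0_spans(rec, per)
  expect_gt(cor(out$data[5, span], orig), 0.9)
  bad <- per; bad$channel <- "nope"
  expect_error(interpolate_ap0_spans(rec, bad), "unknown channel")
})

test_that("detection recalls at least 95% of generator jumps", {
  gen <- generate_recording(synth_config(duration = 60, seed = 5))
  rec <- preprocess_phase_a(gen$recording)
  per <- detect_ap0(rec)
  gt <- gen$ground_truth$jump_periods
  hit <- mapply(function(ch, s, e) {
    d <- per[per$channel_index == ch, ]
    nrow(d) && any(d$start < e & d$end > s)
  }, gt$channel, gt$start, gt$end)
  expect_gte(mean(hit), 0.95)
})

test_that("zeroing before spatial filtering prevents smearing into mesh neighbours", {
  mt <- dry_montage(64)
  mesh <- sensor_mesh(mt$positions, mt$names)
  basis <- sphara_basis(mesh)
  nb <- mesh_neighbors(mesh)
  spec <- spatial_filter_spec()
  for (s in 1:10) {
    gen <- generate_recording(quiet_config(duration = 8, seed = 600 + s))
    inj <- inject_jump(gen$recording, channel = 5 + 3 * s, onset_s = 3,
                       amp = c(250, 400, 600)[s %% 3 + 1])
    rec <- inj$rec
    bg <- gen$ground_truth$clean
    per <- detect_ap0(rec)
    sph <- sphara_filter(basis, rec$data, spec)
    sph0 <- sphara_filter(basis, apply_zeroing(rec, per)$data, spec)
    cols <- (inj$start + 1):inj$end
    nbs <- nb[[inj$channel]]
    expect_lt(rms(sph0[nbs, cols] - bg[nbs, cols]),
              rms(sph[nbs, cols] - bg[nbs, cols]))
  }
})

test_that("annotation files round-trip period tables", {
  rec <- rect_recording()
  per <- detect_ap0(rec)
  tsv <- tempfile(fileext = ".tsv")
  write_ap0_annotations(per, tsv)
  back <- read_ap0_annotations(tsv)
  expect_identical(back$channel, per$channel)
  expect_identical(back$start, per$start)
  expect_identical(back$end, per$end)
  js <- tempfile(fileext = ".json")
  write_ap0_json(per, js)
  back2 <- read_ap0_json(js)
  expect_identical(back2$start, per$start)
})
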