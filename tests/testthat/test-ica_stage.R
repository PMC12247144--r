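test_that("back-projection of all components reproduces the rank-k PCA approximation", {
  gen <- generate_recording(synth_config(n_channels = 16, duration = 6,
                                         seed = 2))
  rec <- gen$recording
  dec <- suppressWarnings(eeg_decompose(rec, n_components = 10, seed = 1))
  recon <- dec$mixing %*% dec$sources + dec$center
  Xc <- rec$data - rowMeans(rec$data)
  sv <- svd(Xc, nu = 10, nv = 0)
  rank_k <- sv$u %*% crossprod(sv$u, Xc) + rowMeans(rec$data)
  expect_lt(max(abs(recon - rank_k)), 1e-6 * max(abs(rank_k)))
})

test_that("decomposition is bitwise deterministic given the seed", {
  gen <- generate_recording(synth_config(n_channels = 16, duration = 4,
                                         seed = 5))
  d1 <- suppressWarnings(eeg_decompose(gen$recording, 8, seed = 4))
  d2 <- suppressWarnings(eeg_decompose(gen$recording, 8, seed = 4))
  expect_identical(d1$mixing, d2$mixing)
  expect_identical(d1$sources, d2$sources)
})

test_that("two mixed sources are recovered up to sign/scale/permutation", {
  n <- 20000
  s1 <- sign(sin(2 * pi * 3 * (1:n) / 1024))
  set.seed(77)
  s2 <- runif(n, -1, 1)
  A <- matrix(c(1, .6, -.4, .2, .3, -1, .8, .5), 4, 2)
  rec <- eeg_recording(A %*% rbind(s1, s2), 1024)
  dec <- suppressWarnings(eeg_decompose(rec, n_components = 2, seed = 3))
  r <- abs(cor(t(dec$sources), cbind(s1, s2)))
  expect_gt(max(r[, 1]), 0.99)
  expect_gt(max(r[, 2]), 0.99)
})

test_that("component count is validated against channels and sample count", {
  rec <- eeg_recording(matrix(rnorm(4 * 300), 4), 256)
  expect_error(eeg_decompose(rec, n_components = 8), "channels")
  expect_warning(eeg_decompose(rec, n_components = 4, seed = 1),
                 "recommended")
})

test_that("an injected blink is labeled blink via its matching component", {
  gen <- generate_recording(synth_config(duration = 20, seed = 301,
                                         eye_movement_rate = 0,
                                         emg_burst_rate = 0, heart_rate = 0,
                                         jump_fraction = 0))
  rec <- gen$recording
  dec <- suppressWarnings(eeg_decompose(rec, 50, seed = 1))
  dec <- classify_components(dec, rec)
  blink_tc <- colSums(gen$ground_truth$artifact_components$blink)
  r <- abs(apply(dec$sources, 1, cor, y = blink_tc))
  expect_identical(dec$labels[which.max(r)], "blink")
})

test_that("an injected 60 bpm cardiac train is labeled cardiac", {
  gen <- generate_recording(synth_config(duration = 30, seed = 9,
                                         heart_rate = 60, blink_rate = 0,
                                         eye_movement_rate = 0,
                                         emg_burst_rate = 0,
                                         jump_fraction = 0))
  rec <- preprocess_phase_a(gen$recording)
  dec <- classify_components(suppressWarnings(eeg_decompose(rec, 50, seed = 1)))
  ct <- colSums(gen$ground_truth$artifact_components$cardiac)
  r <- abs(apply(dec$sources, 1, cor, y = ct))
  expect_identical(dec$labels[which.max(r)], "cardiac")
  # and its inter-peak periodicity sits near 1 s
  th <- classifier_thresholds()
  f <- dryclean:::component_features(dec$sources[which.max(r), ], rec$srate, th)
  expect_lt(abs(f$ipi_med - 1), 0.1)
})

test_that("pure-background recordings yield no blink labels across 10 seeded runs", {
  for (s in 1:10) {
    gen <- generate_recording(quiet_config(duration = 15, seed = 100 + s,
                                           sensor_noise_sd = 8))
    rec <- preprocess_phase_a(gen$recording)
    dec <- classify_components(suppressWarnings(eeg_decompose(rec, 50, seed = 1)))
    expect_identical(sum(dec$labels == "blink"), 0L)
  }
})

test_that("reprojection honours the drop set, including the degenerate ones", {
  gen <- generate_recording(synth_config(n_channels = 16, duration = 6,
                                         seed = 8))
  rec <- gen$recording
  dec <- suppressWarnings(eeg_decompose(rec, 10, seed = 1))
  dec <- classify_components(dec, rec)
  none <- remove_and_reproject(dec, rec, character())
  recon <- dec$mixing %*% dec$sources + dec$center
  expect_lt(max(abs(none$data - recon)), 1e-9 * max(abs(recon)))
  expect_warning(
    zero <- remove_and_reproject(dec, rec, unique(dec$labels)), "zero")
  expect_identical(unname(zero$data), matrix(0, 16, ncol(rec$data)))
})

test_that("removal is additive over disjoint label sets", {
  gen <- generate_recording(synth_config(duration = 20, seed = 302,
                                         jump_fraction = 0))
  rec <- gen$recording
  dec <- suppressWarnings(eeg_decompose(rec, 40, seed = 1))
  dec <- classify_components(dec, rec)
  A <- c("blink", "eye_movement"); B <- c("myogenic", "cardiac", "pulse")
  outA <- remove_and_reproject(dec, rec, A)$data
  outB <- remove_and_reproject(dec, rec, B)$data
  outAB <- remove_and_reproject(dec, rec, c(A, B))$data
  out0 <- remove_and_reproject(dec, rec, character())$data
  expect_lt(max(abs(outAB - (outA + outB - out0))), 1e-8 * max(abs(out0)))
})

test_that("energy accounting closes once cross-terms are included", {
  gen <- generate_recording(synth_config(duration = 10, seed = 13))
  rec <- gen$recording
  dec <- suppressWarnings(eeg_decompose(rec, 30, seed = 1))
  dec <- classify_components(dec, rec)
  drop <- dec$labels != "neural"
  if (!any(drop)) drop[1] <- TRUE
  kept_bp <- dec$mixing[, !drop, drop = FALSE] %*%
    dec$sources[!drop, , drop = FALSE]
  rem_bp <- dec$mixing[, drop, drop = FALSE] %*%
    dec$sources[drop, , drop = FALSE]
  total <- kept_bp + rem_bp
  cross <- sum(kept_bp * rem_bp)
  expect_lt(abs(sum(total^2) -
                  (sum(kept_bp^2) + sum(rem_bp^2) + 2 * cross)),
            1e-6 * sum(total^2))
})

test_that("removing the blink class halves the error against the clean background", {
  gen <- generate_recording(synth_config(duration = 20, seed = 301,
                                         eye_movement_rate = 0,
                                         emg_burst_rate = 0, heart_rate = 0,
                                         jump_fraction = 0,
                                         sensor_noise_sd = 0))
  rec <- gen$recording
  bg <- gen$ground_truth$clean
  dec <- classify_components(suppressWarnings(eeg_decompose(rec, 50, seed = 1)))
  cleaned <- remove_and_reproject(dec, rec)
  expect_lt(rms(cleaned$data - bg), 0.5 * rms(rec$data - bg))
  # the stage's power-ratio SNR against its input is positive
  expect_gt(mean(compute_snr(rec, cleaned)), 0)
})
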