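# Synthetic rPPG generator: waveform spectra, determinism, dataset layout.

test_that("noiseless pulse traces place their dominant frequency at hr/60", {
  for (hr in c(50, 75, 100, 150, 180)) {
    p <- subject_profile(hr_bpm = hr, noise_sd = 0)
    tr <- synth_ppg_trace(p, fps = 30, n_samples = 150)
    f <- dominant_frequency(tr$series, fps = 30)
    # bin resolution 30/150 = 0.2 Hz
    expect_lte(abs(f - hr / 60), 0.2 + 1e-9)
  }
})

test_that("modulation switched off leaves a constant DC series", {
  p <- subject_profile(pulse_amp = 1e-12, resp_amp = 0, noise_sd = 0,
                       skin_rgb = c(180, 120, 90))
  tr <- synth_ppg_trace(p, fps = 30, n_samples = 150)
  expect_equal(tr$series, rep(120, 150), tolerance = 1e-9)
})

test_that("cardiac frequencies beyond fps/2 raise a Nyquist violation", {
  # 200 BPM would be 3.33 Hz; profiles cap at 180 BPM, so drop the rate
  p <- subject_profile(hr_bpm = 180)
  expect_error(synth_ppg_trace(p, fps = 5, n_samples = 150), "Nyquist")
  expect_silent(invisible(synth_ppg_trace(p, fps = 6, n_samples = 150)))
})

test_that("trace generation is reproducible for a fixed seed", {
  p <- subject_profile(seed = 77, noise_sd = 2)
  a <- synth_ppg_trace(p, 30, 300)
  b <- synth_ppg_trace(p, 30, 300)
  expect_identical(a$series, b$series)
  expect_equal(nrow(a$gt), 2)  # 300 samples -> 2 full buffers
})

test_that("dominant_frequency resolves tones and flags constant traces", {
  t <- 0:149
  expect_equal(dominant_frequency(sin(2 * pi * 2 * t / 30), 30), 2.0)
  two_tone <- 2 * sin(2 * pi * 1 * t / 30) + sin(2 * pi * 3 * t / 30)
  expect_equal(dominant_frequency(two_tone, 30), 1.0)
  expect_error(dominant_frequency(rep(5, 150), 30), "non-DC")
})

test_that("synthetic video frames are deterministic and carry the pulse", {
  v1 <- quick_clip(seed = 9)
  v2 <- quick_clip(seed = 9)
  expect_identical(v1$frame(10), v2$frame(10))
  expect_identical(v1$frame(299), v2$frame(299))

  # noiseless patch: mean green over a cheek ROI oscillates in
  # skin green +/- pulse envelope
  p <- subject_profile(subject_id = "amp", hr_bpm = 75, spo2_pct = 100,
                       pulse_amp = 5, resp_amp = 0, noise_sd = 0,
                       skin_rgb = c(180, 120, 90))
  v <- synth_face_video(p, synthetic_clip_config(duration_s = 5.2,
                                                 image_h = 64, image_w = 80))
  rois <- select_rois(v$landmarks)
  greens <- vapply(seq(1, 150, by = 7), function(i) {
    mean_green(v$frame(i), rois$left_cheek)
  }, numeric(1))
  # envelope: pulse_amp 5 times the (1 + 0.1 sin) respiratory modulation
  expect_true(all(greens >= 120 - 5.5 - 1e-9 & greens <= 120 + 5.5 + 1e-9))
  expect_gt(diff(range(greens)), 1)  # actually oscillates
})

test_that("synth_dataset emits n_subjects x clips x 3 files with valid ranges", {
  d <- withr::local_tempdir()
  files <- synth_dataset(10, 2, d, seed = 4)
  expect_length(list.files(d, pattern = "\\.csv$"), 60)

  ds <- load_trace_files(d)
  expect_true(all(ds$hr_gt >= 47 & ds$hr_gt <= 180))
  expect_true(all(ds$br_gt >= 10 & ds$br_gt <= 27))
  expect_true(all(ds$spo2_gt >= 90 & ds$spo2_gt <= 100))
  expect_length(unique(ds$subject_id), 10)

  # constant sampler pins the ground truth
  d2 <- withr::local_tempdir()
  sampler <- function(n, seed) lapply(seq_len(n), function(i) {
    subject_profile(subject_id = sprintf("c%02d", i), hr_bpm = 75, seed = i)
  })
  synth_dataset(3, 1, d2, sampler = sampler)
  ds2 <- load_trace_files(d2)
  expect_true(all(ds2$hr_gt == 75))
})

test_that("profile validation mirrors the physiological ranges", {
  expect_error(subject_profile(hr_bpm = 200), "47, 180")
  expect_error(subject_profile(br_bpm = 9), "10, 27")
  expect_error(subject_profile(spo2_pct = 89), "90, 100")
  expect_error(subject_profile(pulse_amp = 0), "pulse_amp")
})
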