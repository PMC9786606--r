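# Video front end: detection, alignment, ROI geometry, averaging,
# AC removal, buffering.

test_that("detect_face finds the rendered patch and prefers the largest", {
  f1 <- patch_frame(120, 160, list(list(x = 30, y = 20, w = 60, h = 70,
                                        rgb = c(180, 120, 90))))
  box <- detect_face(f1, detector_blob())
  expect_gte(box_iou(box, face_box(30, 20, 60, 70)), 0.9)

  # uniform frame: nothing to detect
  expect_null(detect_face(patch_frame(60, 60), detector_blob()))

  # two faces: largest-area tie-break
  f2 <- patch_frame(200, 200, list(
    list(x = 10, y = 10, w = 80, h = 80, rgb = c(180, 120, 90)),
    list(x = 120, y = 120, w = 40, h = 40, rgb = c(170, 110, 80))))
  box2 <- detect_face(f2, detector_blob())
  expect_gte(box_iou(box2, face_box(10, 10, 80, 80)), 0.9)
})

test_that("fixture detector honours sidecar presence flags", {
  v <- quick_clip(face_absent_frames = c(2L))
  expect_s3_class(detect_face(v$frame(1), detector_fixture()), "face_box")
  expect_null(detect_face(v$frame(2), detector_fixture()))
})

test_that("align_and_landmark echoes fixture points and handles rotation", {
  v <- quick_clip()
  f <- v$frame(1)
  box <- detect_face(f, detector_fixture())
  pts <- align_and_landmark(f, box, landmarker_fixture())
  expect_equal(pts, v$landmarks, tolerance = 1e-12)

  # 15 degree in-plane rotation: output matches the rotated ground truth
  vr <- quick_clip(rotation_deg = 15)
  fr <- vr$frame(1)
  boxr <- detect_face(fr, detector_fixture())
  ptsr <- align_and_landmark(fr, boxr, landmarker_fixture(),
                             angle_threshold = 5)
  expect_equal(ptsr, vr$landmarks, tolerance = 1e-6)

  # degenerate box rejected at the precondition
  expect_error(face_box(10, 10, 0, 20), "w > 0")
})

test_that("select_rois yields three deterministic, equivariant regions", {
  pts <- face_landmark_template(face_box(10, 8, 50, 60))
  rois <- select_rois(pts)
  expect_named(rois, c("left_cheek", "right_cheek", "forehead"))
  expect_length(rois, 3)
  expect_identical(rois, select_rois(pts))

  # translation equivariance, checked pixel-wise on the rasterized masks
  shifted <- select_rois(pts + 10)
  for (rn in names(rois)) {
    m0 <- rppgtwin:::polygon_mask(rois[[rn]], 100, 100)
    m1 <- rppgtwin:::polygon_mask(shifted[[rn]], 110, 110)
    expect_identical(unname(which(m1, arr.ind = TRUE)),
                     unname(which(m0, arr.ind = TRUE) + 10L))
  }
})

test_that("mean_green equals a brute-force per-pixel loop", {
  withr::with_seed(5, {
    px <- array(runif(40 * 50 * 3, 0, 255), dim = c(40, 50, 3))
  })
  f <- frame_image(px)
  pts <- face_landmark_template(face_box(4, 2, 40, 36))
  rois <- select_rois(pts)
  for (rn in names(rois)) {
    mask <- rppgtwin:::polygon_mask(rois[[rn]], 40, 50)
    acc <- 0; cnt <- 0
    for (r in 1:40) for (c in 1:50) if (mask[r, c]) {
      acc <- acc + px[r, c, 2]; cnt <- cnt + 1
    }
    expect_gt(cnt, 0)
    expect_equal(mean_green(f, rois[[rn]]), acc / cnt, tolerance = 1e-12)
  }

  # hand-checkable means
  half <- patch_frame(10, 10, list(list(x = 0, y = 0, w = 10, h = 5,
                                        rgb = c(0, 100, 0)),
                                   list(x = 0, y = 5, w = 10, h = 5,
                                        rgb = c(0, 200, 0))))
  full_mask <- matrix(TRUE, 10, 10)
  expect_equal(mean_green(half, full_mask), 150)
  const <- patch_frame(8, 8, list(), background = c(0, 120, 0))
  expect_equal(mean_green(const, matrix(TRUE, 8, 8)), 120)
  expect_error(mean_green(const, matrix(FALSE, 8, 8)), "empty ROI")
})

test_that("ac_component removes the mean, exactly and idempotently", {
  expect_equal(ac_component(rep(100, 150)), rep(0, 150))
  t <- 0:149
  wave <- sin(2 * pi * 3 * t / 150)  # integer cycles: analytically mean-free
  out <- ac_component(100 + wave)
  expect_lt(max(abs(out - wave)), 1e-9)
  withr::with_seed(3, x <- runif(150, 50, 200))
  expect_lt(abs(sum(ac_component(x))), 1e-9)
  expect_equal(ac_component(ac_component(x)), ac_component(x))
  expect_error(ac_component(runif(149)), "not full")
})

test_that("extract_traces fills non-overlapping buffers and skips gaps", {
  v <- quick_clip(hr = 90, seed = 21)        # 300 frames at 30 FPS
  ds <- extract_traces(v)
  expect_equal(nrow(ds), 6)                  # 2 buffers x 3 ROIs
  expect_setequal(unique(ds$roi), c("left_cheek", "right_cheek", "forehead"))
  expect_true(all(table(ds$roi) == 2))
  expect_true(all(ds$hr_gt == 90))
  expect_lt(max(abs(rowMeans(trace_matrix(ds)))), 1e-9)

  # dominant frequency of every trace within one FFT bin of the truth
  freqs <- apply(trace_matrix(ds), 1, dominant_frequency, fps = 30)
  expect_true(all(abs(freqs - 90 / 60) <= 0.2 + 1e-9))

  # 149-frame source: buffer never fills
  frames149 <- lapply(1:149, v$frame)
  expect_equal(nrow(extract_traces(frames149, fps = 30)), 0)

  # a detection gap flushes the partial buffer: 300 frames with a gap at
  # frame 100 leaves only one post-gap full buffer (frames 101..250)
  vgap <- quick_clip(face_absent_frames = 100L, seed = 22)
  dsgap <- extract_traces(vgap)
  expect_equal(nrow(dsgap), 3)

  # determinism: identical source + config -> identical output
  expect_identical(extract_traces(quick_clip(seed = 21, hr = 90)),
                   extract_traces(quick_clip(seed = 21, hr = 90)))
})

test_that("extract_traces round-trips through an on-disk frame directory", {
  v <- quick_clip(hr = 72, duration_s = 5.2, noise_sd = 0)
  d <- withr::local_tempdir()
  write_video(v, d)
  ds_disk <- extract_traces(d)
  ds_mem <- extract_traces(v)
  expect_equal(nrow(ds_disk), nrow(ds_mem))
  # PPM rounds to 8-bit: each AC sample can shift by the 0.5 quantization
  # step plus the induced shift of the window mean
  expect_lt(max(abs(trace_matrix(ds_disk) - trace_matrix(ds_mem))), 1.0)
  expect_equal(ds_disk$hr_gt, ds_mem$hr_gt)
})

test_that("fps below the Nyquist minimum warns but proceeds", {
  v <- quick_clip(hr = 47, duration_s = 31, fps = 5)
  expect_warning(ds <- extract_traces(v), "Nyquist")
  expect_equal(nrow(ds), 3)
})

test_that("nyquist policy and buffer arithmetic are exact", {
  pol <- nyquist_policy(180)
  expect_identical(pol$max_hr_hz, 3)
  expect_identical(pol$min_fps, 6)
  expect_identical(buffer_fill_time(150, 30), 5)
})
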