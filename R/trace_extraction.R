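# Video -> per-ROI 150-sample green-channel AC traces.

#' Nyquist sampling policy
#'
#' The maximum detectable heart rate fixes the minimum usable frame rate:
#' the cardiac fundamental must stay at or below half the sampling rate.
#' At the 180 BPM ceiling the cardiac frequency is 3 Hz, so the minimum
#' frame rate is 6 FPS.
#'
#' @param max_hr_bpm Maximum heart rate the system is designed to detect.
#' @return A list with `max_hr_bpm`, `max_hr_hz` and `min_fps`.
#' @export
nyquist_policy <- function(max_hr_bpm = 180) {
  stopifnot(max_hr_bpm > 0)
  structure(list(max_hr_bpm = max_hr_bpm,
                 max_hr_hz = max_hr_bpm / 60,
                 min_fps = 2 * max_hr_bpm / 60),
            class = "nyquist_policy")
}

#' Buffer fill time in seconds
#'
#' Time to fill one trace buffer: capacity / fps (5 s for 150 samples at
#' 30 FPS).
#'
#' @param capacity Buffer capacity in samples.
#' @param fps Frame rate.
#' @return Seconds.
#' @export
buffer_fill_time <- function(capacity = 150, fps = 30) capacity / fps

#' Expected number of trace files for a clip collection
#'
#' One trace file is emitted per clip per region of interest, so a corpus
#' of `n_clips` clips yields `n_clips * n_rois` files.
#'
#' @param n_clips Number of video clips.
#' @param n_rois Regions of interest per clip (3).
#' @return Integer file count.
#' @export
expected_trace_files <- function(n_clips, n_rois = 3L) {
  as.integer(n_clips) * as.integer(n_rois)
}

#' Detect a face in a frame
#'
#' Runs the pluggable detector and validates the returned box. With
#' multiple candidate faces a detector must return the largest-area box
#' (single-subject assumption); both shipped detectors do.
#'
#' @param frame A [frame_image()].
#' @param detector A detector object (see [detector_fixture()],
#'   [detector_blob()]).
#' @return A [face_box()], or `NULL` when no face is present.
#' @export
detect_face <- function(frame, detector = detector_fixture()) {
  if (!inherits(frame, "frame_image")) {
    stop("frame must be a frame_image", call. = FALSE)
  }
  if (!inherits(detector, "face_detector")) {
    stop("detector backend is not a face_detector", call. = FALSE)
  }
  box <- detector$detect(frame)
  if (is.null(box)) return(NULL)
  validate_box_in_frame(box, frame)
  box
}

#' Locate 68 facial landmarks, aligning the face upright first if needed
#'
#' Runs the pluggable landmarker on the detected face. If the inter-ocular
#' axis is rotated beyond `angle_threshold` degrees, the frame is rotated
#' upright about the box centre, the landmarker is re-run on the aligned
#' image, and the points are mapped back to original frame coordinates
#' (minimizing the effect of in-plane head pose on landmark placement).
#' Points are clamped to frame bounds.
#'
#' @param frame A [frame_image()].
#' @param box The [face_box()] from [detect_face()] on the same frame.
#' @param landmarker A landmarker object (see [landmarker_fixture()],
#'   [landmarker_template()]).
#' @param angle_threshold Degrees of in-plane rotation tolerated before
#'   alignment kicks in.
#' @return A 68 x 2 landmark matrix, or `NULL` as a detection-failure
#'   signal when every landmark falls outside the box.
#' @export
align_and_landmark <- function(frame, box, landmarker = landmarker_fixture(),
                               angle_threshold = 5) {
  if (!inherits(box, "face_box") || box$w <= 0 || box$h <= 0) {
    stop("invalid face box", call. = FALSE)
  }
  validate_box_in_frame(box, frame)
  if (!inherits(landmarker, "face_landmarker")) {
    stop("landmarker backend is not a face_landmarker", call. = FALSE)
  }
  pts <- landmarker$landmark(frame, box)
  check_landmarks(pts)
  angle <- interocular_angle(pts)
  if (is.finite(angle) && abs(angle) > angle_threshold) {
    cx <- box$x + box$w / 2
    cy <- box$y + box$h / 2
    aligned <- rotate_frame(frame, -angle, cx, cy)
    pts <- landmarker$landmark(aligned, box)
    check_landmarks(pts)
    pts <- rotate_points(pts, angle, cx, cy)
  }
  inside <- pts[, 1] >= box$x & pts[, 1] <= box$x + box$w &
    pts[, 2] >= box$y & pts[, 2] <= box$y + box$h
  if (!any(inside)) return(NULL)   # detection failure: skip frame
  d <- frame_dims(frame)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), d$w - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), d$h - 1)
  pts
}

check_landmarks <- function(pts) {
  if (!is.matrix(pts) || nrow(pts) != 68 || ncol(pts) != 2) {
    stop("landmarker must return a 68 x 2 point matrix", call. = FALSE)
  }
  invisible(pts)
}

# In-plane rotation of the inter-ocular axis, degrees (0 = upright).
interocular_angle <- function(pts) {
  right_eye <- colMeans(pts[37:42, , drop = FALSE])
  left_eye <- colMeans(pts[43:48, , drop = FALSE])
  atan2(left_eye[2] - right_eye[2], left_eye[1] - right_eye[1]) * 180 / pi
}

#' Mean green-channel intensity over a region of interest
#'
#' The green channel carries the strongest blood-volume signal-to-noise of
#' the RGB channels and is the only channel used. The mean is the plain
#' arithmetic average of green values at pixels inside the region.
#'
#' @param frame A [frame_image()].
#' @param roi A polygon (k x 2 vertex matrix), an element of a
#'   [select_rois()] result, or a logical H x W mask.
#' @return Scalar mean green intensity (0--255 scale).
#' @export
mean_green <- function(frame, roi) {
  d <- frame_dims(frame)
  mask <- if (is.logical(roi) && is.matrix(roi)) roi else polygon_mask(roi, d$h, d$w)
  if (!any(mask)) stop("empty ROI: no pixels inside region", call. = FALSE)
  g <- frame[, , 2]
  mean(g[mask])
}

#' AC component of a full trace buffer
#'
#' Removes the DC baseline by subtracting the per-buffer mean, leaving the
#' zero-mean pulsatile component. Idempotent; the output always sums to
#' zero within float tolerance.
#'
#' @param samples Numeric vector holding a full buffer.
#' @param capacity Required buffer length (default 150).
#' @return Zero-mean numeric vector of length `capacity`.
#' @export
ac_component <- function(samples, capacity = 150L) {
  if (length(samples) != capacity) {
    stop("buffer not full: have ", length(samples), " of ", capacity,
         " samples", call. = FALSE)
  }
  samples - mean(samples)
}

#' Extract per-ROI trace records from a video source
#'
#' The end-to-end front end: for each frame, detect and align the face,
#' place the three regions of interest from the 68 landmarks, average the
#' green channel per region, and push one sample per region into three
#' parallel buffers. When the buffers reach capacity (150 samples), one
#' zero-mean AC trace record per region is emitted, synchronized with the
#' clip's ground truth, and the buffers restart empty (0% overlap between
#' adjacent windows). Frames with no detectable face are skipped and -- to
#' avoid stitching a window across a tracking gap -- any partially filled
#' buffer is flushed when the face is lost. The trailing partial buffer is
#' discarded.
#'
#' @param source A video source: a synthetic clip from
#'   [synth_face_video()], a frame-directory created by [write_video()],
#'   or a plain list of [frame_image()] objects.
#' @param detector,landmarker Pluggable backends; default to the fixture
#'   implementations driven by sidecar metadata.
#' @param policy [nyquist_policy()]; a warning is issued (and extraction
#'   proceeds) when the source frame rate is below `policy$min_fps`.
#' @param buffer_capacity Samples per window (default 150).
#' @param fps Explicit frame-rate override, required if the source carries
#'   no rate metadata.
#' @param constants [roi_constants()] for region placement.
#' @return A tibble in the interchange trace schema: columns
#'   `subject_id`, `roi`, `hr_gt`, `br_gt`, `spo2_gt`, `s0` ... `s149`,
#'   one row per region per full buffer.
#' @export
extract_traces <- function(source,
                           detector = detector_fixture(),
                           landmarker = landmarker_fixture(),
                           policy = nyquist_policy(),
                           buffer_capacity = 150L,
                           fps = NULL,
                           constants = roi_constants()) {
  src <- as_video_source(source, fps = fps)
  if (is.null(src$fps)) {
    stop("source carries no frame-rate metadata; supply fps explicitly",
         call. = FALSE)
  }
  if (src$fps < policy$min_fps) {
    warning("source frame rate ", src$fps, " FPS is below the Nyquist ",
            "minimum ", policy$min_fps, " FPS for ", policy$max_hr_bpm,
            " BPM detection", call. = FALSE)
  }
  roi_names <- c("left_cheek", "right_cheek", "forehead")
  buffers <- setNames(vector("list", 3), roi_names)
  for (rn in roi_names) buffers[[rn]] <- numeric(0)
  records <- list()
  n_emitted <- 0L
  mask_cache <- NULL
  mask_key <- NULL

  flush <- function() for (rn in roi_names) buffers[[rn]] <<- numeric(0)

  for (i in seq_len(src$n_frames)) {
    frame <- src$frame(i)
    box <- detect_face(frame, detector)
    if (is.null(box)) { flush(); next }
    pts <- align_and_landmark(frame, box, landmarker)
    if (is.null(pts)) { flush(); next }
    key <- c(pts)
    if (is.null(mask_key) || length(mask_key) != length(key) ||
        any(mask_key != key)) {
      rois <- select_rois(pts, constants)
      d <- frame_dims(frame)
      mask_cache <- lapply(rois, polygon_mask, h = d$h, w = d$w)
      mask_key <- key
    }
    for (rn in roi_names) {
      buffers[[rn]] <- c(buffers[[rn]], mean_green(frame, mask_cache[[rn]]))
    }
    if (length(buffers[[roi_names[1]]]) == buffer_capacity) {
      n_emitted <- n_emitted + 1L
      gt <- buffer_gt(src, n_emitted)
      for (rn in roi_names) {
        trace <- ac_component(buffers[[rn]], buffer_capacity)
        rec <- c(list(subject_id = src$subject_id, roi = rn,
                      hr_gt = gt$hr, br_gt = gt$br, spo2_gt = gt$spo2),
                 as.list(setNames(trace, trace_cols(buffer_capacity))))
        records[[length(records) + 1L]] <- tibble::as_tibble(rec)
      }
      flush()
    }
  }
  if (length(records) == 0L) {
    return(empty_trace_dataset(buffer_capacity))
  }
  dplyr::bind_rows(records)
}

empty_trace_dataset <- function(buffer_capacity = 150L) {
  cols <- c(list(subject_id = character(0), roi = character(0),
                 hr_gt = numeric(0), br_gt = numeric(0), spo2_gt = numeric(0)),
            setNames(rep(list(numeric(0)), buffer_capacity),
                     trace_cols(buffer_capacity)))
  tibble::as_tibble(cols)
}

buffer_gt <- function(src, buffer_index) {
  gt <- src$gt
  if (!is.null(gt) && buffer_index <= nrow(gt)) {
    list(hr = gt$hr_gt[buffer_index], br = gt$br_gt[buffer_index],
         spo2 = gt$spo2_gt[buffer_index])
  } else if (!is.null(gt) && nrow(gt) > 0) {
    # ground truth constant over the clip: reuse the last synchronized value
    n <- nrow(gt)
    list(hr = gt$hr_gt[n], br = gt$br_gt[n], spo2 = gt$spo2_gt[n])
  } else {
    list(hr = NA_real_, br = NA_real_, spo2 = NA_real_)
  }
}

#' Write trace records to per-clip per-ROI CSV files
#'
#' Emits the interchange schema consumed by the data-engineering stage:
#' header `subject_id,roi,hr_gt,br_gt,spo2_gt,s0,...,s149`, one row per
#' full buffer, one file per (subject, clip label, ROI). Missing ground
#' truth is written as an empty field.
#'
#' @param ds Trace dataset tibble (e.g. from [extract_traces()]).
#' @param dir Output directory.
#' @param clip_label Label distinguishing clips of the same subject.
#' @return Invisibly, the paths written.
#' @export
write_trace_files <- function(ds, dir, clip_label = "clip01") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (grp in split(ds, list(ds$subject_id, ds$roi), drop = TRUE)) {
    path <- file.path(dir, sprintf("%s_%s_%s.csv",
                                   grp$subject_id[1], clip_label, grp$roi[1]))
    write.csv(grp, path, row.names = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}
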