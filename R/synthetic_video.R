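# Synthetic face-patch clips with sidecar ground truth: the test double
# for real camera input. Frames are rendered lazily and deterministically
# from the profile, so identical seeds give byte-identical frames without
# materializing whole clips in memory.

#' Configuration of a synthetic clip
#'
#' @param fps Frame rate (default 30).
#' @param duration_s Clip duration in seconds; `fps * duration_s` must be
#'   at least 150 so one full buffer can be extracted.
#' @param image_h,image_w Frame dimensions in pixels.
#' @param face_x,face_y,face_w,face_h Face-patch geometry (0-based pixels);
#'   defaults centre a patch covering ~60% of the frame.
#' @param rotation_deg In-plane face rotation about the patch centre.
#' @param face_absent_frames 1-based frame indices rendered without a face
#'   (simulating detection gaps).
#' @param background_rgb Static background colour.
#' @return A `synthetic_clip_config` list.
#' @export
synthetic_clip_config <- function(fps = 30, duration_s = 10,
                                  image_h = 72, image_w = 96,
                                  face_x = NULL, face_y = NULL,
                                  face_w = NULL, face_h = NULL,
                                  rotation_deg = 0,
                                  face_absent_frames = integer(0),
                                  background_rgb = c(60, 60, 60)) {
  n_frames <- floor(fps * duration_s)
  if (n_frames < 150) {
    stop("fps * duration_s must be >= 150 for at least one full buffer",
         call. = FALSE)
  }
  face_w <- face_w %||% round(0.55 * image_w)
  face_h <- face_h %||% round(0.75 * image_h)
  face_x <- face_x %||% round((image_w - face_w) / 2)
  face_y <- face_y %||% round((image_h - face_h) / 2)
  stopifnot(face_x >= 0, face_y >= 0,
            face_x + face_w <= image_w, face_y + face_h <= image_h)
  structure(list(fps = fps, duration_s = duration_s, n_frames = n_frames,
                 image_h = image_h, image_w = image_w,
                 face_x = face_x, face_y = face_y,
                 face_w = face_w, face_h = face_h,
                 rotation_deg = rotation_deg,
                 face_absent_frames = as.integer(face_absent_frames),
                 background_rgb = background_rgb),
            class = "synthetic_clip_config")
}

#' Generate a synthetic face video with sidecar ground truth
#'
#' Renders a rectangular skin patch on a static background. The patch's
#' green channel follows the pulse-intensity series of
#' [synth_ppg_trace()] uniformly across the patch, so the mean green over
#' any region inside the face reproduces the generating waveform exactly.
#' Sidecar metadata (face box, 68 template landmarks, per-buffer ground
#' truth) drives the fixture detector and landmarker.
#'
#' @param profile A [subject_profile()].
#' @param config A [synthetic_clip_config()].
#' @return An object of class `synthetic_video` with fields `n_frames`,
#'   `fps`, `subject_id`, `gt` (per-buffer ground-truth tibble), `box`,
#'   `landmarks`, and a `frame(i)` accessor returning [frame_image()] `i`
#'   (1-based).
#' @export
synth_face_video <- function(profile, config = synthetic_clip_config()) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "synthetic_clip_config"))
  tr <- synth_ppg_trace(profile, fps = config$fps, n_samples = config$n_frames)
  box <- face_box(config$face_x, config$face_y, config$face_w, config$face_h)
  landmarks <- face_landmark_template(box)
  if (config$rotation_deg != 0) {
    landmarks <- rotate_points(landmarks, config$rotation_deg,
                               box$x + box$w / 2, box$y + box$h / 2)
  }
  h <- config$image_h; w <- config$image_w
  bg <- config$background_rgb
  base <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) base[, , ch] <- bg[ch]
  patch_idx <- face_patch_index(config)

  render <- function(i) {
    present <- !(i %in% config$face_absent_frames)
    px <- base
    if (present) {
      g <- min(max(tr$series[i], 0), 255)
      plane <- px[, , 1]; plane[patch_idx] <- profile$skin_rgb[1]
      px[, , 1] <- plane
      plane <- px[, , 2]; plane[patch_idx] <- g
      px[, , 2] <- plane
      plane <- px[, , 3]; plane[patch_idx] <- profile$skin_rgb[3]
      px[, , 3] <- plane
    }
    meta <- list(face_present = present, face_box = box,
                 landmarks = landmarks)
    frame_image(px, index = i - 1L, timestamp_s = (i - 1) / config$fps,
                meta = meta)
  }

  structure(list(n_frames = config$n_frames, fps = config$fps,
                 subject_id = profile$subject_id,
                 gt = tr$gt, box = box, landmarks = landmarks,
                 series = tr$series, profile = profile, config = config,
                 frame = render),
            class = "synthetic_video")
}

# Linear indices (into an h x w plane) of the pixels covered by the face
# patch, honouring in-plane rotation about the patch centre.
face_patch_index <- function(config) {
  h <- config$image_h; w <- config$image_w
  xs <- rep(seq_len(w) - 1, each = h)
  ys <- rep(seq_len(h) - 1, times = w)
  if (config$rotation_deg == 0) {
    inside <- xs >= config$face_x & xs <= config$face_x + config$face_w - 1 &
      ys >= config$face_y & ys <= config$face_y + config$face_h - 1
  } else {
    cx <- config$face_x + config$face_w / 2
    cy <- config$face_y + config$face_h / 2
    p <- rotate_points(cbind(xs, ys), -config$rotation_deg, cx, cy)
    inside <- p[, 1] >= config$face_x & p[, 1] <= config$face_x + config$face_w - 1 &
      p[, 2] >= config$face_y & p[, 2] <= config$face_y + config$face_h - 1
  }
  which(matrix(inside, h, w))
}

# --- video source abstraction -------------------------------------------

as_video_source <- function(source, fps = NULL) {
  if (inherits(source, "synthetic_video")) {
    return(list(n_frames = source$n_frames, fps = fps %||% source$fps,
                subject_id = source$subject_id, gt = source$gt,
                frame = source$frame))
  }
  if (is.character(source) && length(source) == 1L && dir.exists(source)) {
    return(frame_dir_source(source, fps = fps))
  }
  if (is.list(source) && length(source) > 0L &&
      inherits(source[[1]], "frame_image")) {
    return(list(n_frames = length(source), fps = fps,
                subject_id = "unknown", gt = NULL,
                frame = function(i) source[[i]]))
  }
  stop("unreadable video source: expected a synthetic_video, a frame ",
       "directory, or a list of frame_image objects", call. = FALSE)
}

#' Export a video to a frame directory (plain-text PPM + JSON sidecar)
#'
#' Writes each frame as an ASCII PPM (P3) image plus a `sidecar.json`
#' carrying frame rate, subject id, face geometry, landmarks and the
#' per-buffer ground truth. The directory round-trips through
#' [extract_traces()] as an offline video source. Pixel values are rounded
#' to the nearest integer on write (8-bit sensor quantization).
#'
#' @param video A video source (e.g. [synth_face_video()]).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_video <- function(video, dir) {
  src <- as_video_source(video)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(src$n_frames)) {
    write_ppm(src$frame(i), file.path(dir, sprintf("frame%05d.ppm", i)))
  }
  meta <- list(fps = src$fps, n_frames = src$n_frames,
               subject_id = src$subject_id)
  f1 <- src$frame(1)
  m <- attr(f1, "meta")
  if (!is.null(m)) {
    meta$face_box <- m$face_box[c("x", "y", "w", "h")]
    meta$landmarks <- unname(as.matrix(m$landmarks))
    meta$face_absent_frames <-
      if (inherits(video, "synthetic_video")) video$config$face_absent_frames
      else integer(0)
  }
  if (!is.null(src$gt)) meta$gt <- src$gt
  jsonlite::write_json(meta, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

frame_dir_source <- function(dir, fps = NULL) {
  files <- sort(list.files(dir, pattern = "^frame\\d+\\.ppm$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no frame files found in ", dir, call. = FALSE)
  }
  sidecar_path <- file.path(dir, "sidecar.json")
  meta <- NULL
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  gt <- if (!is.null(meta$gt)) tibble::as_tibble(meta$gt) else NULL
  landmarks <- if (!is.null(meta$landmarks)) as.matrix(meta$landmarks) else NULL
  fb <- if (!is.null(meta$face_box)) {
    face_box(meta$face_box$x, meta$face_box$y, meta$face_box$w, meta$face_box$h)
  } else NULL
  absent <- as.integer(meta$face_absent_frames %||% integer(0))
  list(
    n_frames = length(files),
    fps = fps %||% meta$fps,
    subject_id = meta$subject_id %||% "unknown",
    gt = gt,
    frame = function(i) {
      px <- read_ppm(files[i])
      fmeta <- if (!is.null(fb)) {
        list(face_present = !(i %in% absent), face_box = fb,
             landmarks = landmarks)
      } else NULL
      frame_image(px, index = i - 1L,
                  timestamp_s = if (!is.null(fps %||% meta$fps)) {
                    (i - 1) / (fps %||% meta$fps)
                  } else NA_real_,
                  meta = fmeta)
    }
  )
}

# --- minimal ASCII PPM (P3) I/O -----------------------------------------
# No installed R package reads PPM; the format is three header tokens and
# whitespace-separated integers, written here directly.

write_ppm <- function(frame, path) {
  d <- frame_dims(frame)
  vals <- integer(d$h * d$w * 3L)
  # PPM is row-major, RGB interleaved
  r <- t(round(frame[, , 1])); g <- t(round(frame[, , 2])); b <- t(round(frame[, , 3]))
  vals[seq(1L, length(vals), 3L)] <- as.integer(r)
  vals[seq(2L, length(vals), 3L)] <- as.integer(g)
  vals[seq(3L, length(vals), 3L)] <- as.integer(b)
  vals <- pmin(pmax(vals, 0L), 255L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d$w, d$h), "255"), con)
  writeLines(paste(vals, collapse = " "), con)
}

read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop("not an ASCII PPM (P3) file: ", path, call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  stopifnot(length(vals) == h * w * 3L)
  px <- array(0, dim = c(h, w, 3))
  r <- vals[seq(1L, length(vals), 3L)]
  g <- vals[seq(2L, length(vals), 3L)]
  b <- vals[seq(3L, length(vals), 3L)]
  px[, , 1] <- matrix(r, h, w, byrow = TRUE)
  px[, , 2] <- matrix(g, h, w, byrow = TRUE)
  px[, , 3] <- matrix(b, h, w, byrow = TRUE)
  px
}
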