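#' Construct a video frame image
#'
#' Frames are H x W x 3 numeric arrays on the 0--255 intensity scale with
#' channel order fixed as RGB (decoders that are BGR-native must swap at the
#' boundary). Coordinates are 0-based and pixel-centered: x indexes columns
#' (0 .. W-1), y indexes rows (0 .. H-1).
#'
#' @param pixels H x W x 3 numeric array, values in `[0, 255]`.
#' @param index 0-based frame ordinal.
#' @param timestamp_s Seconds from stream start.
#' @param meta Optional sidecar metadata list (used by the fixture
#'   detector/landmarker); typically carries `face_box`, `landmarks`,
#'   `face_present`.
#' @return An object of class `frame_image`.
#' @export
frame_image <- function(pixels, index = 0L, timestamp_s = 0, meta = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("frame must have H >= 1 and W >= 1", call. = FALSE)
  }
  structure(pixels,
            index = as.integer(index), timestamp_s = timestamp_s,
            meta = meta, class = "frame_image")
}

frame_dims <- function(frame) {
  d <- dim(frame)
  list(h = d[1], w = d[2])
}

#' Create a face box
#'
#' @param x,y Top-left corner in 0-based pixel coordinates.
#' @param w,h Width and height in pixels (> 0).
#' @return A `face_box` list.
#' @export
face_box <- function(x, y, w, h) {
  if (w <= 0 || h <= 0) stop("face box must have w > 0 and h > 0", call. = FALSE)
  structure(list(x = x, y = y, w = w, h = h), class = "face_box")
}

validate_box_in_frame <- function(box, frame) {
  d <- frame_dims(frame)
  if (box$x < 0 || box$y < 0 || box$x + box$w > d$w || box$y + box$h > d$h) {
    stop("face box extends outside the frame bounds", call. = FALSE)
  }
  invisible(box)
}

# Intersection-over-union of two face boxes (test/diagnostic utility).
#' @export
box_iou <- function(a, b) {
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (a$w * a$h + b$w * b$h - inter)
}

#' Render a frame with rectangular colour patches
#'
#' Utility for building deterministic detector fixtures: a uniform
#' background with zero or more axis-aligned rectangular patches.
#'
#' @param h,w Frame dimensions.
#' @param patches List of lists, each with `x`, `y`, `w`, `h` (0-based
#'   pixel geometry) and `rgb` (length-3 colour).
#' @param background Length-3 background colour (default mid gray).
#' @return A [frame_image()].
#' @export
patch_frame <- function(h, w, patches = list(), background = c(128, 128, 128)) {
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- background[ch]
  for (p in patches) {
    rows <- (p$y + 1):(p$y + p$h)
    cols <- (p$x + 1):(p$x + p$w)
    for (ch in 1:3) px[rows, cols, ch] <- p$rgb[ch]
  }
  frame_image(px)
}

# Rotate a frame in-plane by angle_deg about (cx, cy), nearest-neighbour
# resampling, same canvas size; sidecar landmark metadata is transformed
# with the exact affine map so fixture landmarkers stay consistent.
rotate_frame <- function(frame, angle_deg, cx, cy) {
  d <- frame_dims(frame)
  th <- angle_deg * pi / 180
  # inverse map: for each destination pixel, sample the source
  xs <- rep(seq_len(d$w) - 1, each = d$h)
  ys <- rep(seq_len(d$h) - 1, times = d$w)
  sx <- cx + cos(-th) * (xs - cx) - sin(-th) * (ys - cy)
  sy <- cy + sin(-th) * (xs - cx) + cos(-th) * (ys - cy)
  si <- round(sy) + 1
  sj <- round(sx) + 1
  ok <- si >= 1 & si <= d$h & sj >= 1 & sj <= d$w
  out <- array(0, dim = dim(frame))
  for (ch in 1:3) {
    plane <- matrix(0, d$h, d$w)
    src <- frame[, , ch]
    plane[cbind(ys + 1, xs + 1)[ok, , drop = FALSE]] <-
      src[cbind(si, sj)[ok, , drop = FALSE]]
    out[, , ch] <- plane
  }
  meta <- attr(frame, "meta")
  if (!is.null(meta) && !is.null(meta$landmarks)) {
    meta$landmarks <- rotate_points(meta$landmarks, angle_deg, cx, cy)
  }
  frame_image(out, index = attr(frame, "index"),
              timestamp_s = attr(frame, "timestamp_s"), meta = meta)
}

# Rotate an n x 2 matrix of (x, y) points by angle_deg about (cx, cy).
rotate_points <- function(pts, angle_deg, cx, cy) {
  th <- angle_deg * pi / 180
  x <- pts[, 1] - cx
  y <- pts[, 2] - cy
  cbind(cx + cos(th) * x - sin(th) * y,
        cy + sin(th) * x + cos(th) * y)
}
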