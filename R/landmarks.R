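# 68-point facial landmark geometry and region-of-interest selection.
#
# Landmark ordering follows the standard 68-point annotation (1-based):
# jawline 1-17, right brow 18-22, left brow 23-27, nose bridge 28-31,
# nostrils 32-36, right eye 37-42, left eye 43-48, mouth 49-68 (outer lip
# 49-60, inner lip 61-68). "Right"/"left" are the subject's right/left,
# i.e. image-left/image-right.

#' Deterministic 68-point landmark template for a face box
#'
#' Places a parametric 68-point layout inside a face box: a half-elliptical
#' jawline, arched brows, hexagonal eyes, nose bridge and nostril line, and
#' elliptical outer/inner lips. The synthetic clip generator and the
#' geometric landmarker share this template, so fixture tests have exact
#' ground truth.
#'
#' @param box A [face_box()].
#' @return A 68 x 2 matrix of (x, y) coordinates, 0-based pixel units.
#' @export
face_landmark_template <- function(box) {
  w <- box$w; h <- box$h
  px <- function(fx, fy) c(box$x + fx * (w - 1), box$y + fy * (h - 1))
  pts <- matrix(0, 68, 2)
  # jawline: half ellipse from left temple through chin to right temple
  th <- pi + pi * (0:16) / 16
  pts[1:17, 1] <- box$x + (0.5 + 0.45 * cos(th)) * (w - 1)
  pts[1:17, 2] <- box$y + (0.45 - 0.5 * sin(th)) * (h - 1)
  # brows, slight arch
  t5 <- (0:4) / 4
  pts[18:22, 1] <- box$x + (0.18 + 0.24 * t5) * (w - 1)
  pts[18:22, 2] <- box$y + (0.26 - 0.02 * sin(pi * t5)) * (h - 1)
  pts[23:27, 1] <- box$x + (0.58 + 0.24 * t5) * (w - 1)
  pts[23:27, 2] <- box$y + (0.26 - 0.02 * sin(pi * t5)) * (h - 1)
  # nose bridge and nostril line
  t4 <- (0:3) / 3
  pts[28:31, 1] <- box$x + 0.5 * (w - 1)
  pts[28:31, 2] <- box$y + (0.30 + 0.18 * t4) * (h - 1)
  pts[32:36, 1] <- box$x + (0.40 + 0.20 * (0:4) / 4) * (w - 1)
  pts[32:36, 2] <- box$y + 0.52 * (h - 1)
  # eyes: hexagons
  eye <- function(cxf, cyf, first) {
    ang <- pi + 2 * pi * (0:5) / 6
    pts[first:(first + 5), 1] <<- box$x + (cxf + 0.07 * cos(ang)) * (w - 1)
    pts[first:(first + 5), 2] <<- box$y + (cyf - 0.025 * sin(ang)) * (h - 1)
  }
  eye(0.30, 0.33, 37)
  eye(0.70, 0.33, 43)
  # mouth: outer lip 12 points, inner lip 8 points
  ang12 <- pi + 2 * pi * (0:11) / 12
  pts[49:60, 1] <- box$x + (0.5 + 0.18 * cos(ang12)) * (w - 1)
  pts[49:60, 2] <- box$y + (0.72 - 0.06 * sin(ang12)) * (h - 1)
  ang8 <- pi + 2 * pi * (0:7) / 8
  pts[61:68, 1] <- box$x + (0.5 + 0.12 * cos(ang8)) * (w - 1)
  pts[61:68, 2] <- box$y + (0.72 - 0.03 * sin(ang8)) * (h - 1)
  pts
}

#' ROI landmark-index constants
#'
#' The standard 68-point annotation does not prescribe which landmarks
#' delimit the cheeks and forehead, so these are configurable package
#' constants shared with the synthetic generator. Cheek regions are convex
#' polygons over jawline, nose-flank and mouth-corner landmarks; the
#' forehead is a rectangle above the brows with height
#' `forehead_height_frac` times the brow-to-eye distance.
#'
#' @param right_cheek_idx,left_cheek_idx Landmark indices (1-based) whose
#'   convex hull forms each cheek polygon.
#' @param forehead_height_frac Forehead band height as a fraction of the
#'   eyebrow-to-eye vertical distance.
#' @return A list of constants, class `roi_constants`.
#' @export
roi_constants <- function(right_cheek_idx = c(2:6, 49, 32),
                          left_cheek_idx = c(12:16, 55, 36),
                          forehead_height_frac = 0.6) {
  structure(list(right_cheek_idx = right_cheek_idx,
                 left_cheek_idx = left_cheek_idx,
                 forehead_height_frac = forehead_height_frac),
            class = "roi_constants")
}

#' Select the three facial regions of interest from landmarks
#'
#' Derives the left-cheek, right-cheek and forehead regions used for
#' green-channel averaging: the cheeks carry the strongest blood-volume
#' signal-to-noise and the forehead adds a third stable skin patch; eyes
#' and mouth are excluded by construction. Deterministic for a fixed
#' landmark set and translation-equivariant.
#'
#' @param landmarks 68 x 2 matrix of (x, y) landmark coordinates.
#' @param constants [roi_constants()].
#' @return An object of class `roi_set`: a named list with polygon
#'   matrices `left_cheek`, `right_cheek`, `forehead` (each k x 2,
#'   vertices in order).
#' @export
select_rois <- function(landmarks, constants = roi_constants()) {
  if (!is.matrix(landmarks) || nrow(landmarks) != 68 || ncol(landmarks) != 2) {
    stop("landmarks must be a 68 x 2 matrix", call. = FALSE)
  }
  hull_poly <- function(idx) {
    p <- landmarks[idx, , drop = FALSE]
    p[grDevices::chull(p[, 1], p[, 2]), , drop = FALSE]
  }
  right_cheek <- hull_poly(constants$right_cheek_idx)
  left_cheek <- hull_poly(constants$left_cheek_idx)
  brow <- landmarks[18:27, , drop = FALSE]
  eyes <- landmarks[37:48, , drop = FALSE]
  d <- mean(eyes[, 2]) - mean(brow[, 2])
  if (d <= 0) stop("degenerate landmark geometry: eyes not below brows",
                   call. = FALSE)
  hband <- constants$forehead_height_frac * d
  top <- min(brow[, 2]) - hband
  bottom <- min(brow[, 2])
  forehead <- cbind(c(min(brow[, 1]), max(brow[, 1]), max(brow[, 1]), min(brow[, 1])),
                    c(top, top, bottom, bottom))
  for (poly in list(right_cheek, left_cheek, forehead)) {
    if (abs(polygon_area(poly)) < 1e-9) {
      stop("degenerate landmark geometry: zero-area ROI polygon", call. = FALSE)
    }
  }
  structure(list(left_cheek = left_cheek, right_cheek = right_cheek,
                 forehead = forehead),
            class = "roi_set")
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# Rasterize a polygon to a logical pixel mask (h x w). Pixel (row, col)
# has center (x = col-1, y = row-1); membership by even-odd rule with a
# tiny deterministic offset so edge-on-center ties resolve consistently.
polygon_mask <- function(poly, h, w) {
  mask <- matrix(FALSE, h, w)
  xmin <- max(1L, floor(min(poly[, 1])) + 1L)
  xmax <- min(w, ceiling(max(poly[, 1])) + 1L)
  ymin <- max(1L, floor(min(poly[, 2])) + 1L)
  ymax <- min(h, ceiling(max(poly[, 2])) + 1L)
  if (xmin > xmax || ymin > ymax) return(mask)
  cols <- xmin:xmax
  rows <- ymin:ymax
  px <- rep(cols - 1, each = length(rows)) + 1e-7
  py <- rep(rows - 1, times = length(cols)) + 1e-7
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask[cbind(rep(rows, times = length(cols)), rep(cols, each = length(rows)))] <- inside
  mask
}
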