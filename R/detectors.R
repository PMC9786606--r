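# Pluggable face-detector and landmarker backends. Two of each ship with
# the package: fixture implementations that read the sidecar metadata
# emitted by the synthetic clip generator (tests run without any model
# download), and image-driven geometric implementations for frames that
# carry no metadata. Pretrained cascade/regressor weights are deliberately
# not bundled; the detector interface accepts any user-supplied backend.

#' Fixture face detector
#'
#' Reads the ground-truth face box from the frame's sidecar metadata
#' (attached by the synthetic video source). Frames without metadata, or
#' whose metadata marks the face absent, yield no detection.
#'
#' @return A detector object usable with [detect_face()].
#' @export
detector_fixture <- function() {
  structure(list(
    name = "fixture",
    detect = function(frame) {
      meta <- attr(frame, "meta")
      if (is.null(meta) || !isTRUE(meta$face_present)) return(NULL)
      meta$face_box
    }
  ), class = "face_detector")
}

#' Blob face detector
#'
#' Model-free detector for synthetic and simple scenes: pixels deviating
#' from the modal (background) colour are grouped into 4-connected
#' components and the largest component's bounding box is returned.
#' Single-subject assumption: when multiple components exist, the largest
#' area wins.
#'
#' @param min_area Minimum component pixel count to count as a face.
#' @return A detector object usable with [detect_face()].
#' @export
detector_blob <- function(min_area = 16L) {
  structure(list(
    name = "blob",
    detect = function(frame) {
      d <- frame_dims(frame)
      # background = modal rounded colour
      key <- round(frame[, , 1]) * 256^2 + round(frame[, , 2]) * 256 +
        round(frame[, , 3])
      tab <- table(key)
      bg <- as.numeric(names(tab)[which.max(tab)])
      fg <- matrix(key != bg, d$h, d$w)
      if (!any(fg)) return(NULL)
      lab <- label_components(fg)
      sizes <- tabulate(lab[lab > 0])
      best <- which.max(sizes)
      if (sizes[best] < min_area) return(NULL)
      idx <- which(lab == best, arr.ind = TRUE)
      face_box(x = min(idx[, 2]) - 1L, y = min(idx[, 1]) - 1L,
               w = diff(range(idx[, 2])) + 1L, h = diff(range(idx[, 1])) + 1L)
    }
  ), class = "face_detector")
}

# 4-connected component labelling by iterative flood fill.
label_components <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  current <- 0L
  todo <- which(fg & lab == 0L)
  while (length(todo) > 0L) {
    current <- current + 1L
    stack <- todo[1L]
    lab[stack] <- current
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (i - 1L) %% h + 1L
      c <- (i - 1L) %/% h + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (nb[1] >= 1L && nb[1] <= h && nb[2] >= 1L && nb[2] <= w) {
          j <- (nb[2] - 1L) * h + nb[1]
          if (fg[j] && lab[j] == 0L) {
            lab[j] <- current
            stack <- c(stack, j)
          }
        }
      }
    }
    todo <- which(fg & lab == 0L)
  }
  lab
}

#' Fixture landmarker
#'
#' Echoes the 68 ground-truth landmark points stored in the frame's
#' sidecar metadata. Raises a configuration error on frames without
#' metadata.
#'
#' @return A landmarker object usable with [align_and_landmark()].
#' @export
landmarker_fixture <- function() {
  structure(list(
    name = "fixture",
    landmark = function(frame, box) {
      meta <- attr(frame, "meta")
      if (is.null(meta) || is.null(meta$landmarks)) {
        stop("fixture landmarker: frame carries no landmark metadata",
             call. = FALSE)
      }
      meta$landmarks
    }
  ), class = "face_landmarker")
}

#' Geometric template landmarker
#'
#' Places the deterministic 68-point template ([face_landmark_template()])
#' inside the detected box. A geometry-only stand-in for a pretrained
#' landmark regressor; adequate for upright synthetic faces.
#'
#' @return A landmarker object usable with [align_and_landmark()].
#' @export
landmarker_template <- function() {
  structure(list(
    name = "template",
    landmark = function(frame, box) face_landmark_template(box)
  ), class = "face_landmarker")
}
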