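# The deployed loop: consume a video source, maintain per-ROI sample
# windows, and publish fused HR/BR/SpO2 readings every `update_interval`
# frames. Batch extraction uses non-overlapping windows; at runtime the
# most recent 150 valid samples form a sliding window advanced by the
# update interval, reconciling second-by-second readings with the
# 5-second window the models were trained on.

#' Run the fused vital-sign reading loop on a video source
#'
#' Emits one reading event every `update_interval` frames. Until the
#' first 150 valid samples have accumulated, events are flagged
#' `"warming_up"` with no predictions; afterwards each event carries
#' HR, BR and SpO2 predicted from the AC component of the most recent 150
#' valid samples of each region of interest, averaged across the three
#' regions. In offline mode the clip's sidecar ground truth is joined
#' onto each event and the exit summary aggregates the four evaluation
#' metrics over all prediction events.
#'
#' Event `wall_time` is media time (`frame_index / fps`), so repeated
#' offline runs on one clip are bitwise identical.
#'
#' @param source A video source (see [extract_traces()]).
#' @param models Named list with elements `hr`, `br`, `spo2`: trained
#'   `twin_model` objects or paths to [save_model()] bundles.
#' @param mode `"offline"` (join sidecar ground truth) or `"realtime"`.
#' @param update_interval Frames between readings (default 30; one
#'   reading per second at 30 FPS).
#' @param buffer_capacity Sliding-window length in samples (default 150).
#' @param detector,landmarker Pluggable extraction backends.
#' @param fps Frame-rate override for sources without rate metadata.
#' @param jsonl Optional path; when given, each event is appended as one
#'   JSON object per line.
#' @return An object of class `twin_run`: list with `events` (tibble:
#'   `frame_index`, `status`, `hr`, `br`, `spo2`, `hr_gt`, `br_gt`,
#'   `spo2_gt`, `wall_time`) and `summary` (named list of
#'   [compute_metrics()] reports for signals with ground truth, or
#'   `NULL` when no prediction was made).
#' @export
run_twin <- function(source, models,
                     mode = c("offline", "realtime"),
                     update_interval = 30L,
                     buffer_capacity = 150L,
                     detector = detector_fixture(),
                     landmarker = landmarker_fixture(),
                     fps = NULL,
                     jsonl = NULL) {
  mode <- match.arg(mode)
  if (update_interval < 1L) {
    stop("update_interval must be >= 1", call. = FALSE)
  }
  models <- lapply(models, function(m) {
    if (inherits(m, "twin_model")) m
    else if (is.character(m) && dir.exists(m)) load_model(m)
    else stop("configuration error: model bundle missing or unreadable",
              call. = FALSE)
  })
  for (sig in c("hr", "br", "spo2")) {
    if (is.null(models[[sig]])) {
      stop("configuration error: no model supplied for signal '", sig, "'",
           call. = FALSE)
    }
  }
  src <- as_video_source(source, fps = fps)
  if (is.null(src$fps)) {
    stop("source carries no frame-rate metadata; supply fps explicitly",
         call. = FALSE)
  }
  gt <- if (mode == "offline" && !is.null(src$gt) && nrow(src$gt) > 0) {
    list(hr = src$gt$hr_gt[1], br = src$gt$br_gt[1], spo2 = src$gt$spo2_gt[1])
  } else {
    list(hr = NA_real_, br = NA_real_, spo2 = NA_real_)
  }

  roi_names <- c("left_cheek", "right_cheek", "forehead")
  windows <- setNames(lapply(roi_names, function(x) numeric(0)), roi_names)
  mask_cache <- NULL
  mask_key <- NULL
  events <- list()
  con <- if (!is.null(jsonl)) file(jsonl, "w") else NULL
  if (!is.null(con)) on.exit(close(con), add = TRUE)

  for (i in seq_len(src$n_frames)) {
    frame <- src$frame(i)
    box <- detect_face(frame, detector)
    pts <- if (!is.null(box)) align_and_landmark(frame, box, landmarker) else NULL
    if (!is.null(pts)) {
      key <- c(pts)
      if (is.null(mask_key) || length(mask_key) != length(key) ||
          any(mask_key != key)) {
        rois <- select_rois(pts)
        d <- frame_dims(frame)
        mask_cache <- lapply(rois, polygon_mask, h = d$h, w = d$w)
        mask_key <- key
      }
      for (rn in roi_names) {
        wnd <- c(windows[[rn]], mean_green(frame, mask_cache[[rn]]))
        if (length(wnd) > buffer_capacity) {
          wnd <- wnd[(length(wnd) - buffer_capacity + 1L):length(wnd)]
        }
        windows[[rn]] <- wnd
      }
    }
    if (i %% update_interval == 0L) {
      warm <- length(windows[[roi_names[1]]]) >= buffer_capacity
      ev <- if (warm) {
        traces <- vapply(roi_names, function(rn) {
          ac_component(windows[[rn]], buffer_capacity)
        }, numeric(buffer_capacity))
        X <- t(traces)   # one row per ROI
        preds <- vapply(c("hr", "br", "spo2"), function(sig) {
          mean(predict(models[[sig]], X))
        }, numeric(1))
        tibble::tibble(frame_index = i, status = "reading",
                       hr = preds[["hr"]], br = preds[["br"]],
                       spo2 = preds[["spo2"]],
                       hr_gt = gt$hr, br_gt = gt$br, spo2_gt = gt$spo2,
                       wall_time = i / src$fps)
      } else {
        tibble::tibble(frame_index = i, status = "warming_up",
                       hr = NA_real_, br = NA_real_, spo2 = NA_real_,
                       hr_gt = gt$hr, br_gt = gt$br, spo2_gt = gt$spo2,
                       wall_time = i / src$fps)
      }
      events[[length(events) + 1L]] <- ev
      if (!is.null(con)) {
        writeLines(as.character(jsonlite::toJSON(as.list(ev),
                                                 auto_unbox = TRUE,
                                                 digits = NA, na = "null")),
                   con)
      }
    }
  }
  events <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(frame_index = integer(0), status = character(0),
                   hr = numeric(0), br = numeric(0), spo2 = numeric(0),
                   hr_gt = numeric(0), br_gt = numeric(0),
                   spo2_gt = numeric(0), wall_time = numeric(0))
  readings <- events[events$status == "reading", , drop = FALSE]
  if (nrow(readings) == 0L) {
    warning("source ended before the first full buffer; no readings emitted",
            call. = FALSE)
  }
  summary <- NULL
  if (nrow(readings) >= 2L) {
    summary <- list()
    for (sig in c("hr", "br", "spo2")) {
      y_true <- readings[[paste0(sig, "_gt")]]
      if (all(is.finite(y_true))) {
        summary[[sig]] <- suppressWarnings(
          compute_metrics(y_true, readings[[sig]]))
      }
    }
    if (length(summary) == 0L) summary <- NULL
  }
  structure(list(events = events, summary = summary, mode = mode,
                 update_interval = update_interval),
            class = "twin_run")
}

#' @export
print.twin_run <- function(x, ...) {
  n_read <- sum(x$events$status == "reading")
  cat(sprintf("twin run (%s): %d events, %d readings\n",
              x$mode, nrow(x$events), n_read))
  if (n_read > 0) {
    last <- tail(x$events[x$events$status == "reading", ], 1)
    cat(sprintf("last reading @ frame %d: HR %.1f BPM, BR %.1f breaths/min, SpO2 %.1f%%\n",
                last$frame_index, last$hr, last$br, last$spo2))
  }
  if (!is.null(x$summary)) {
    for (sig in names(x$summary)) {
      cat(sprintf("%s vs ground truth: ", toupper(sig)))
      print(x$summary[[sig]])
    }
  }
  invisible(x)
}
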