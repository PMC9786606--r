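# Shared fixture builders. All fixtures are generated in code at test
# time; seeds are fixed so every run sees identical data.

# Build an in-memory trace dataset: one row per (subject, record), traces
# are zero-mean noise unless `trace` is supplied.
make_trace_ds <- function(records_per_subject, hr = NULL, br = NULL,
                          spo2 = NULL, seed = 1, trace = NULL) {
  n_subj <- length(records_per_subject)
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subj)) {
      for (k in seq_len(records_per_subject[s])) {
        tr <- if (is.null(trace)) {
          x <- rnorm(150)
          x - mean(x)
        } else {
          trace
        }
        rows[[length(rows) + 1L]] <- tibble::as_tibble(c(
          list(subject_id = sprintf("s%03d", s),
               roi = sample(c("left_cheek", "right_cheek", "forehead"), 1),
               hr_gt = if (is.null(hr)) runif(1, 50, 170) else hr,
               br_gt = if (is.null(br)) runif(1, 11, 26) else br,
               spo2_gt = if (is.null(spo2)) runif(1, 91, 99) else spo2),
          stats::setNames(as.list(tr), paste0("s", 0:149))))
      }
    }
    dplyr::bind_rows(rows)
  })
}

# A small synthetic clip that extracts quickly (64 x 80 frames).
quick_clip <- function(hr = 80, br = 14, spo2 = 96, noise_sd = 0.5,
                       duration_s = 10, seed = 1, ...) {
  synth_face_video(
    subject_profile(subject_id = "fix", hr_bpm = hr, br_bpm = br,
                    spo2_pct = spo2, noise_sd = noise_sd, seed = seed),
    synthetic_clip_config(duration_s = duration_s, image_h = 64,
                          image_w = 80, ...))
}

# Train a small boosted-tree model quickly (few rounds) for tests whose
# subject is not model accuracy.
quick_model <- function(ds_split, signal, n_estimators = 40) {
  train_model(xgb_spec(signal, n_estimators = n_estimators),
              ds_split$train, ds_split$val, signal = signal)
}
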