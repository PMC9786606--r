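#' Subject profile for the synthetic rPPG generator
#'
#' Bundles the physiological and photometric parameters that drive the
#' synthetic pulse-signal generator: heart rate, breathing rate, blood-oxygen
#' saturation, base skin colour, modulation amplitudes and sensor noise.
#' Valid ranges mirror the cleaning intervals used downstream
#' (HR 47--180 beats/min, BR 10--27 breaths/min, SpO2 90--100%).
#'
#' @param subject_id Opaque subject identifier (character scalar).
#' @param hr_bpm Heart rate in beats per minute, in `[47, 180]`.
#' @param br_bpm Breathing rate in breaths per minute, in `[10, 27]`.
#' @param spo2_pct Blood-oxygen saturation in percent, in `[90, 100]`.
#' @param skin_rgb Base skin colour as an RGB triple on the 0--255 scale;
#'   the green component is the DC level of the pulse trace.
#' @param pulse_amp Green-intensity modulation amplitude of the cardiac
#'   pulse, in intensity counts (must be > 0).
#' @param resp_amp Amplitude of the respiratory baseline wander, counts.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise.
#' @param seed Integer seed making the subject's noise reproducible.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "s01",
                            hr_bpm = 75,
                            br_bpm = 15,
                            spo2_pct = 97,
                            skin_rgb = c(180, 120, 90),
                            pulse_amp = 5,
                            resp_amp = 2,
                            noise_sd = 1,
                            seed = 1L) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (hr_bpm < 47 || hr_bpm > 180) {
    stop("hr_bpm must lie in [47, 180], got ", hr_bpm, call. = FALSE)
  }
  if (br_bpm < 10 || br_bpm > 27) {
    stop("br_bpm must lie in [10, 27], got ", br_bpm, call. = FALSE)
  }
  if (spo2_pct < 90 || spo2_pct > 100) {
    stop("spo2_pct must lie in [90, 100], got ", spo2_pct, call. = FALSE)
  }
  if (pulse_amp <= 0) stop("pulse_amp must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(length(skin_rgb) == 3L, all(skin_rgb >= 0), all(skin_rgb <= 255))
  structure(
    list(subject_id = subject_id, hr_bpm = hr_bpm, br_bpm = br_bpm,
         spo2_pct = spo2_pct, skin_rgb = as.numeric(skin_rgb),
         pulse_amp = pulse_amp, resp_amp = resp_amp, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "subject_profile"
  )
}

# Monotone coupling between SpO2 and the effective pulse amplitude.
# Green-channel video carries no physical SpO2 signal; the generator encodes
# SpO2 as a documented amplitude gain so the regression path is testable:
# gain rises linearly from 0.4 at 90% to 1.0 at 100%.
spo2_gain <- function(spo2_pct) 0.4 + 0.06 * (spo2_pct - 90)

#' Generate a raw synthetic pulse-intensity series
#'
#' Simulates the green-channel intensity of facial skin under cardiac and
#' respiratory modulation:
#' \deqn{s_t = DC + A\,\sin(2\pi f_{hr} t/\mathrm{fps})\,
#'   (1 + 0.1 \sin(2\pi f_{br} t/\mathrm{fps}))
#'   + R\,\sin(2\pi f_{br} t/\mathrm{fps}) + \epsilon_t}
#' where \eqn{f_{hr} = } `hr_bpm`/60 Hz, \eqn{f_{br} = } `br_bpm`/60 Hz,
#' \eqn{A = } `pulse_amp` scaled by a monotone gain in SpO2, \eqn{R = }
#' `resp_amp`, and \eqn{\epsilon_t \sim N(0, \mathrm{noise\_sd}^2)}.
#' The DC level is the green component of `skin_rgb`.
#'
#' @param profile A [subject_profile()].
#' @param fps Sampling rate (video frame rate), frames per second.
#' @param n_samples Number of samples to generate (>= 1).
#'
#' @return A list with `series` (numeric vector of raw intensities),
#'   `fps`, and `gt`, a tibble with one row per complete 150-sample buffer
#'   carrying the synchronized `hr_gt`, `br_gt`, `spo2_gt` ground truths.
#' @export
#' @examples
#' tr <- synth_ppg_trace(subject_profile(hr_bpm = 60, noise_sd = 0), 30, 150)
#' dominant_frequency(tr$series - mean(tr$series), 30)  # 1 Hz
synth_ppg_trace <- function(profile, fps, n_samples) {
  stopifnot(inherits(profile, "subject_profile"), fps > 0, n_samples >= 1)
  f_hr <- profile$hr_bpm / 60
  f_br <- profile$br_bpm / 60
  if (f_hr > fps / 2) {
    stop("Nyquist violation: cardiac frequency ", round(f_hr, 3),
         " Hz exceeds fps/2 = ", fps / 2, " Hz", call. = FALSE)
  }
  t <- seq_len(n_samples) - 1
  amp <- profile$pulse_amp * spo2_gain(profile$spo2_pct)
  cardiac <- amp * sin(2 * pi * f_hr * t / fps) *
    (1 + 0.1 * sin(2 * pi * f_br * t / fps))
  resp <- profile$resp_amp * sin(2 * pi * f_br * t / fps)
  noise <- if (profile$noise_sd > 0) {
    withr::with_seed(profile$seed, rnorm(n_samples, 0, profile$noise_sd))
  } else {
    numeric(n_samples)
  }
  series <- profile$skin_rgb[2] + cardiac + resp + noise
  n_buffers <- floor(n_samples / 150)
  gt <- tibble::tibble(
    buffer = seq_len(n_buffers),
    hr_gt = rep(profile$hr_bpm, n_buffers),
    br_gt = rep(profile$br_bpm, n_buffers),
    spo2_gt = rep(profile$spo2_pct, n_buffers)
  )
  list(series = series, fps = fps, gt = gt)
}

#' Dominant non-DC frequency of a trace
#'
#' Brute-force spectral oracle: returns the frequency of the maximum-
#' magnitude non-DC FFT bin. Bin resolution is `fps / length(trace)`
#' (0.2 Hz for 150 samples at 30 FPS).
#'
#' @param trace Numeric vector, length >= 2.
#' @param fps Sampling rate in Hz.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(trace, fps) {
  stopifnot(length(trace) >= 2, fps > 0)
  n <- length(trace)
  spec <- Mod(fft(trace - mean(trace)))
  half <- 2:(floor(n / 2) + 1)   # positive non-DC frequencies
  if (max(spec[half]) < 1e-9 * max(1, max(abs(trace)))) {
    stop("dominant_frequency undefined: trace has no non-DC energy",
         call. = FALSE)
  }
  k <- half[which.max(spec[half])]
  (k - 1) * fps / n
}

#' Draw random subject profiles over the valid physiological ranges
#'
#' The default sampler draws HR, BR and SpO2 uniformly over the full valid
#' intervals (HR 47--180, BR 10--27, SpO2 90--100) rather than the narrow
#' clinical mode, so models are exercised across the whole detection range.
#' Skin tone varies across subjects; amplitudes and noise are fixed at the
#' generator defaults.
#'
#' @param n_subjects Number of profiles.
#' @param seed Integer seed.
#' @param hr_range,br_range,spo2_range Length-2 numeric ranges to sample
#'   uniformly from.
#' @param noise_sd Sensor noise passed to every profile.
#' @return List of [subject_profile()] objects with unique ids.
#' @export
sample_profiles <- function(n_subjects, seed = 1L,
                            hr_range = c(47, 180),
                            br_range = c(10, 27),
                            spo2_range = c(90, 100),
                            noise_sd = 1) {
  stopifnot(n_subjects >= 1)
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      subject_profile(
        subject_id = sprintf("subj%04d", i),
        hr_bpm = runif(1, hr_range[1], hr_range[2]),
        br_bpm = runif(1, br_range[1], br_range[2]),
        spo2_pct = runif(1, spo2_range[1], spo2_range[2]),
        skin_rgb = c(runif(1, 140, 220), runif(1, 100, 160), runif(1, 70, 120)),
        noise_sd = noise_sd,
        seed = sample.int(2^31 - 1, 1)
      )
    })
  })
}

#' Generate a directory of synthetic trace files
#'
#' Writes one CSV trace file per clip per region of interest in the
#' interchange schema (`subject_id,roi,hr_gt,br_gt,spo2_gt,s0,...,s149`),
#' emulating the structure of an engineered rPPG dataset: each clip yields
#' three region traces sharing the same ground truth. Traces are stored as
#' zero-mean AC components, one row per complete 150-sample buffer.
#'
#' @param n_subjects Number of subjects.
#' @param clips_per_subject Clips (hence 3x trace files) per subject.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed for the profile sampler and per-clip noise.
#' @param buffers_per_clip Complete 150-sample buffers per clip (default 1).
#' @param fps Sampling rate of the simulated clips (default 30).
#' @param sampler A function `(n_subjects, seed)` returning profiles;
#'   defaults to [sample_profiles()].
#' @param noise_sd Sensor noise handed to the default sampler.
#' @return Invisibly, a character vector of the files written
#'   (`n_subjects * clips_per_subject * 3` paths).
#' @export
synth_dataset <- function(n_subjects, clips_per_subject, dir,
                          seed = 1L, buffers_per_clip = 1L, fps = 30,
                          sampler = NULL, noise_sd = 1) {
  stopifnot(n_subjects >= 1, clips_per_subject >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  profiles <- if (is.null(sampler)) {
    sample_profiles(n_subjects, seed = seed, noise_sd = noise_sd)
  } else {
    sampler(n_subjects, seed)
  }
  n_samples <- 150L * buffers_per_clip
  rois <- c("left_cheek", "right_cheek", "forehead")
  files <- character(0)
  for (p in profiles) {
    for (clip in seq_len(clips_per_subject)) {
      # distinct noise per clip and ROI, still fully seed-determined
      for (ri in seq_along(rois)) {
        pr <- p
        pr$seed <- as.integer((p$seed + 7919L * clip + 104729L * ri) %% (2^31 - 1))
        tr <- synth_ppg_trace(pr, fps = fps, n_samples = n_samples)
        rows <- lapply(seq_len(buffers_per_clip), function(b) {
          seg <- tr$series[((b - 1L) * 150L + 1L):(b * 150L)]
          as.list(setNames(seg - mean(seg), trace_cols()))
        })
        df <- tibble::tibble(
          subject_id = p$subject_id, roi = rois[ri],
          hr_gt = p$hr_bpm, br_gt = p$br_bpm, spo2_gt = p$spo2_pct
        )[rep(1L, buffers_per_clip), ]
        df <- dplyr::bind_cols(df, dplyr::bind_rows(rows))
        path <- file.path(dir, sprintf("%s_clip%02d_%s.csv",
                                       p$subject_id, clip, rois[ri]))
        write.csv(df, path, row.names = FALSE)
        files <- c(files, path)
      }
    }
  }
  invisible(files)
}
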