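# Aggregation, cleaning, subject-disjoint splitting, summaries.

test_that("load_trace_files aggregates, skips empties, rejects bad rows", {
  d <- withr::local_tempdir()
  ds0 <- make_trace_ds(rep(2, 5), seed = 2)
  for (s in unique(ds0$subject_id)) {
    write.csv(ds0[ds0$subject_id == s, ],
              file.path(d, paste0(s, ".csv")), row.names = FALSE)
  }
  ds <- load_trace_files(d)
  expect_equal(nrow(ds), 10)

  # zero-byte file (no face ever detected) is skipped, not fatal
  file.create(file.path(d, "empty_clip.csv"))
  ds2 <- load_trace_files(d)
  expect_equal(nrow(ds2), 10)
  expect_equal(attr(ds2, "load_report")$files_skipped_empty, 1)

  # a row with 149 samples is rejected with a diagnostic naming the row
  short <- ds0[1, ]
  line <- paste(unlist(short[1, 1:154]), collapse = ",")  # drops s149
  writeLines(c(paste(names(short)[1:155], collapse = ","), line),
             file.path(d, "short_row.csv"))
  ds3 <- load_trace_files(d)
  expect_equal(nrow(ds3), 10)
  rep3 <- attr(ds3, "load_report")
  expect_equal(rep3$rows_rejected, 1)
  expect_true(any(grepl("short_row.csv row 1", rep3$diagnostics)))

  expect_error(load_trace_files(withr::local_tempdir()), "no readable")
})

test_that("cleaning removes exactly the out-of-range and zero records", {
  good <- make_trace_ds(rep(2, 4), hr = 80, br = 15, spo2 = 97, seed = 3)
  bad_hr <- make_trace_ds(1, hr = 255, br = 15, spo2 = 97, seed = 4)
  bad_spo2 <- make_trace_ds(1, hr = 80, br = 15, spo2 = 127, seed = 5)
  bad_br_lo <- make_trace_ds(1, hr = 80, br = 5, spo2 = 97, seed = 6)
  bad_br_hi <- make_trace_ds(1, hr = 80, br = 30, spo2 = 97, seed = 7)
  zero_gt <- make_trace_ds(1, hr = 0, br = 15, spo2 = 97, seed = 8)
  zero_trace <- make_trace_ds(1, hr = 80, br = 15, spo2 = 97, seed = 9,
                              trace = rep(0, 150))
  ds <- dplyr::bind_rows(good, bad_hr, bad_spo2, bad_br_lo, bad_br_hi,
                         zero_gt, zero_trace)
  res <- clean_traces(ds)
  expect_equal(res$report$input, 14)
  expect_equal(res$report$hr_out_of_range, 1)
  expect_equal(res$report$spo2_out_of_range, 1)
  expect_equal(res$report$br_out_of_range, 2)
  expect_equal(res$report$zero_row, 2)
  expect_equal(res$report$retained, 8)
  # conservation
  expect_equal(res$report$retained + res$report$zero_row +
                 res$report$hr_out_of_range + res$report$br_out_of_range +
                 res$report$spo2_out_of_range, res$report$input)
  # only the good records survive
  expect_true(all(res$data$hr_gt == 80))
  # idempotence
  res2 <- clean_traces(res$data)
  expect_identical(res2$data, res$data)
  expect_equal(res2$report$retained, res2$report$input)
})

test_that("absent ground truth is not grounds for removal", {
  ds <- make_trace_ds(c(1, 1), hr = 80, br = 15, spo2 = 97, seed = 11)
  ds$br_gt <- NA_real_   # e.g. a source without breathing-rate truth
  res <- clean_traces(ds)
  expect_equal(res$report$retained, 2)
})

test_that("subject-wise split is disjoint, exhaustive and deterministic", {
  ds <- make_trace_ds(rep(3, 10), seed = 13)
  sp <- split_subjectwise(ds, seed = 42)
  subj <- lapply(sp, function(x) unique(x$subject_id))
  expect_length(intersect(subj$train, subj$val), 0)
  expect_length(intersect(subj$train, subj$test), 0)
  expect_length(intersect(subj$val, subj$test), 0)
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(ds))
  fr <- sapply(sp, nrow) / nrow(ds)
  expect_true(all(abs(fr - c(0.6, 0.2, 0.2)) <= 0.1))
  expect_identical(attr(split_subjectwise(ds, seed = 42), "assignment"),
                   attr(sp, "assignment"))
  expect_error(split_subjectwise(make_trace_ds(c(2, 2)), seed = 1),
               "at least 3 subjects")
})

test_that("greedy assignment is near-optimal under skewed record counts", {
  # brute-force oracle: minimal achievable max fraction deviation over
  # all 3^n subject assignments
  brute_best <- function(counts, fractions = c(0.6, 0.2, 0.2)) {
    n <- length(counts)
    total <- sum(counts)
    best <- Inf
    for (code in 0:(3^n - 1)) {
      x <- code
      fill <- c(0, 0, 0)
      for (i in seq_len(n)) {
        fill[x %% 3 + 1] <- fill[x %% 3 + 1] + counts[i]
        x <- x %/% 3
      }
      best <- min(best, max(abs(fill / total - fractions)))
    }
    best
  }
  cases <- list(c(20, 4, 4, 4, 4, 4),    # one subject holds 50% of records
                c(5, 5, 5, 5, 5, 5, 5, 5),
                c(9, 7, 5, 3, 2, 1))
  for (counts in cases) {
    ds <- make_trace_ds(counts, seed = 17)
    sp <- suppressWarnings(split_subjectwise(ds, seed = 3))
    dev <- max(abs(sapply(sp, nrow) / nrow(ds) - c(0.6, 0.2, 0.2)))
    expect_lte(dev, brute_best(counts) + 0.051)
  }
})

test_that("summaries match an independent quantile computation", {
  ds <- make_trace_ds(rep(2, 6), seed = 19)
  s <- summarize_traces(ds)
  expect_equal(s$signal, c("hr", "br", "spo2"))
  expect_true(all(s$min <= s$q25 & s$q25 <= s$median &
                    s$median <= s$q75 & s$q75 <= s$max))
  # independent oracle: manual linear interpolation between order stats
  manual_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  hr <- ds$hr_gt
  expect_equal(s$q25[s$signal == "hr"], manual_q(hr, 0.25), tolerance = 1e-12)
  expect_equal(s$median[s$signal == "hr"], manual_q(hr, 0.5), tolerance = 1e-12)
  expect_equal(s$q75[s$signal == "hr"], manual_q(hr, 0.75), tolerance = 1e-12)

  # hand-checkable example
  ds3 <- make_trace_ds(c(1, 1, 1), seed = 23)
  ds3$hr_gt <- c(60, 70, 80)
  s3 <- summarize_traces(ds3)
  expect_equal(s3$mean[s3$signal == "hr"], 70)
  expect_equal(s3$min[s3$signal == "hr"], 60)
  expect_equal(s3$max[s3$signal == "hr"], 80)
  expect_equal(s3$median[s3$signal == "hr"], 70)

  # degenerate n = 1: std reported as zero with a warning
  ds1 <- make_trace_ds(1, seed = 29)
  w <- testthat::capture_warnings(s1 <- summarize_traces(ds1))
  expect_length(grep("std reported as 0", w), 3)  # one per bio-signal
  expect_equal(s1$std, rep(0, 3))
  expect_error(summarize_traces(ds1[0, ]), "empty")
})
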