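# Aggregation, validation, cleaning, subject-disjoint splitting and EDA
# summaries of trace datasets.

#' Load a directory of trace CSV files
#'
#' Aggregates all trace files in the interchange schema into one dataset.
#' Empty (zero-byte) files -- the footprint of clips where no face was
#' ever detected -- are skipped and counted; malformed rows (wrong sample
#' count, unparseable fields) are rejected with row-level diagnostics;
#' records with every ground-truth field absent are dropped.
#'
#' @param dir Directory containing `*.csv` trace files.
#' @param provenance Optional source label stored on the result.
#' @return A tibble in the trace schema with attributes `provenance` and
#'   `load_report` (list: `files_read`, `files_skipped_empty`,
#'   `rows_rejected`, `diagnostics`).
#' @export
load_trace_files <- function(dir, provenance = basename(dir)) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no readable trace files in ", dir, call. = FALSE)
  }
  empty <- file.size(files) == 0L
  skipped <- sum(empty)
  files <- files[!empty]
  if (length(files) == 0L) {
    stop("all trace files in ", dir, " are empty", call. = FALSE)
  }
  needed <- c("subject_id", "roi", "hr_gt", "br_gt", "spo2_gt", trace_cols())
  diags <- character(0)
  rejected <- 0L
  parts <- list()
  for (f in files) {
    df <- tryCatch(
      read.csv(f, stringsAsFactors = FALSE, fill = TRUE),
      error = function(e) NULL)
    if (is.null(df) || !all(c("subject_id", "roi") %in% names(df))) {
      diags <- c(diags, paste0(basename(f), ": unreadable or missing header"))
      next
    }
    for (col in needed[-(1:2)]) {
      if (!col %in% names(df)) df[[col]] <- NA_real_
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    }
    df <- df[, needed]
    bad_trace <- apply(is.na(df[, trace_cols()]), 1, any)
    all_gt_absent <- is.na(df$hr_gt) & is.na(df$br_gt) & is.na(df$spo2_gt)
    bad <- bad_trace | all_gt_absent
    if (any(bad)) {
      rejected <- rejected + sum(bad)
      why <- ifelse(bad_trace[bad], "incomplete trace (expected 150 samples)",
                    "all ground-truth fields absent")
      diags <- c(diags, paste0(basename(f), " row ", which(bad), ": ", why))
    }
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) > 0L) parts[[length(parts) + 1L]] <- df
  }
  if (length(parts) == 0L) {
    stop("no valid trace rows found in ", dir, call. = FALSE)
  }
  ds <- tibble::as_tibble(dplyr::bind_rows(parts))
  attr(ds, "provenance") <- provenance
  attr(ds, "load_report") <- list(
    files_read = length(files) - sum(!vapply(parts, is.data.frame, TRUE)),
    files_skipped_empty = skipped,
    rows_rejected = rejected,
    diagnostics = diags
  )
  ds
}

#' Validity intervals for bio-signal ground truth
#'
#' The cleaning thresholds: heart rate above 180 beats/min is an outlier;
#' breathing rate outside 10--27 breaths/min and SpO2 outside 90--100% are
#' anomalies; rows with zero values (a zero ground truth or an all-zero
#' trace, both footprints of extraction failure) are dropped.
#'
#' @param hr_max,br_min,br_max,spo2_min,spo2_max Interval bounds.
#' @param drop_zero_rows Drop records with zero values.
#' @return A `cleaning_rules` list.
#' @export
cleaning_rules <- function(hr_max = 180, br_min = 10, br_max = 27,
                           spo2_min = 90, spo2_max = 100,
                           drop_zero_rows = TRUE) {
  stopifnot(br_min < br_max, spo2_min < spo2_max)
  structure(list(hr_max = hr_max, br_min = br_min, br_max = br_max,
                 spo2_min = spo2_min, spo2_max = spo2_max,
                 drop_zero_rows = drop_zero_rows),
            class = "cleaning_rules")
}

#' Clean a trace dataset against the validity intervals
#'
#' Removes records whose present ground-truth values violate the rules.
#' A rule only applies when the relevant ground truth is present: a record
#' legitimately lacking breathing-rate truth is not removed by the
#' breathing-rate rule. Each removed record is attributed to the first
#' rule it violates, in the order zero-row, heart-rate, breathing-rate,
#' SpO2, so removal counts plus survivors always equal the input count.
#'
#' @param ds Trace dataset tibble.
#' @param rules A [cleaning_rules()].
#' @return A list with `data` (the surviving records) and `report`
#'   (named removal counts: `zero_row`, `hr_out_of_range`,
#'   `br_out_of_range`, `spo2_out_of_range`, `retained`, `input`).
#' @export
clean_traces <- function(ds, rules = cleaning_rules()) {
  n <- nrow(ds)
  tr <- trace_matrix(ds)
  zero_row <- if (rules$drop_zero_rows) {
    gt_zero <- (!is.na(ds$hr_gt) & ds$hr_gt == 0) |
      (!is.na(ds$br_gt) & ds$br_gt == 0) |
      (!is.na(ds$spo2_gt) & ds$spo2_gt == 0)
    trace_zero <- rowSums(tr != 0) == 0L
    gt_zero | trace_zero
  } else rep(FALSE, n)
  hr_bad <- !is.na(ds$hr_gt) & ds$hr_gt > rules$hr_max & !zero_row
  br_bad <- !is.na(ds$br_gt) &
    (ds$br_gt < rules$br_min | ds$br_gt > rules$br_max) &
    !zero_row & !hr_bad
  spo2_bad <- !is.na(ds$spo2_gt) &
    (ds$spo2_gt < rules$spo2_min | ds$spo2_gt > rules$spo2_max) &
    !zero_row & !hr_bad & !br_bad
  keep <- !(zero_row | hr_bad | br_bad | spo2_bad)
  out <- ds[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("cleaning removed every record", call. = FALSE)
  }
  list(
    data = out,
    report = list(zero_row = sum(zero_row),
                  hr_out_of_range = sum(hr_bad),
                  br_out_of_range = sum(br_bad),
                  spo2_out_of_range = sum(spo2_bad),
                  retained = nrow(out),
                  input = n)
  )
}

#' Subject-disjoint train/validation/test split
#'
#' Partitions a trace dataset so that all records of one subject land in
#' exactly one partition (no identity leakage) while the realized *sample*
#' fractions approach the 60/20/20 targets. Because subjects contribute
#' unequal record counts, exact fractions are a packing problem; subjects
#' are assigned largest-first to the currently most-underfilled partition,
#' which is deterministic for a fixed seed (the seed only shuffles ties).
#'
#' @param ds Trace dataset tibble.
#' @param fractions Target sample fractions, named `train`, `val`, `test`,
#'   summing to 1.
#' @param seed Integer seed (tie shuffling).
#' @param tolerance Warn when a realized fraction deviates from its target
#'   by more than this.
#' @return A named list of tibbles `train`, `val`, `test` with attribute
#'   `assignment` (named character vector subject -> partition).
#' @export
split_subjectwise <- function(ds, fractions = c(train = 0.6, val = 0.2, test = 0.2),
                              seed = 1L, tolerance = 0.1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9,
            all(c("train", "val", "test") %in% names(fractions)))
  counts <- table(ds$subject_id)
  if (length(counts) < 3L) {
    stop("subject-disjoint 3-way split needs at least 3 subjects, have ",
         length(counts), call. = FALSE)
  }
  subjects <- names(counts)
  # largest-first; ties broken by a seeded shuffle for unbiased assignment
  ord <- withr::with_seed(seed, {
    jitter_rank <- sample.int(length(counts))
    order(-as.integer(counts), jitter_rank)
  })
  total <- sum(counts)
  filled <- c(train = 0, val = 0, test = 0)
  assignment <- setNames(character(length(subjects)), subjects)
  for (s in subjects[ord]) {
    deficit <- fractions - filled / total
    part <- names(deficit)[which.max(deficit)]  # ties: train > val > test
    assignment[s] <- part
    filled[part] <- filled[part] + counts[[s]]
  }
  realized <- filled / total
  dev <- abs(realized - fractions)
  if (any(dev > tolerance)) {
    warning("realized sample fractions (",
            paste(sprintf("%s=%.2f", names(realized), realized), collapse = ", "),
            ") deviate from targets by more than ", tolerance, call. = FALSE)
  }
  out <- lapply(c(train = "train", val = "val", test = "test"), function(p) {
    ds[ds$subject_id %in% names(assignment)[assignment == p], , drop = FALSE]
  })
  attr(out, "assignment") <- assignment
  attr(out, "realized_fractions") <- realized
  out
}

#' Statistical profile of the ground-truth bio-signals
#'
#' Produces the EDA summary used to spot outliers before cleaning: count,
#' mean, standard deviation and the five-number summary per bio-signal,
#' with quantiles by linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param ds Trace dataset tibble.
#' @param by Optional grouping column name (e.g. a provenance column).
#' @return A tibble with one row per bio-signal (and group), columns
#'   `signal`, `count`, `mean`, `std`, `min`, `q25`, `median`, `q75`, `max`.
#' @export
summarize_traces <- function(ds, by = NULL) {
  if (nrow(ds) == 0L) stop("cannot summarize an empty dataset", call. = FALSE)
  one <- function(sub, label) {
    rows <- lapply(c(hr = "hr_gt", br = "br_gt", spo2 = "spo2_gt"), function(col) {
      x <- sub[[col]]
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(NULL)
      if (length(x) == 1L) {
        warning("single observation for ", col,
                ": std reported as 0", call. = FALSE)
      }
      q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      tibble::tibble(count = length(x), mean = mean(x),
                     std = if (length(x) > 1L) sd(x) else 0,
                     min = min(x), q25 = q[1], median = q[2], q75 = q[3],
                     max = max(x))
    })
    keep <- !vapply(rows, is.null, TRUE)
    res <- dplyr::bind_rows(rows[keep])
    res <- dplyr::bind_cols(tibble::tibble(signal = names(rows)[keep]), res)
    if (!is.null(label)) res <- dplyr::bind_cols(tibble::tibble(source = label), res)
    res
  }
  if (is.null(by)) {
    one(ds, NULL)
  } else {
    dplyr::bind_rows(lapply(split(ds, ds[[by]]), function(sub) {
      one(sub, sub[[by]][1])
    }))
  }
}
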