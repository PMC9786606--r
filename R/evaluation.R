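# Formula-defined regression metrics and model comparison reports.

#' Compute the four evaluation metrics
#'
#' Given ground-truth values \eqn{y_g} and predictions \eqn{y_p}:
#' \deqn{MAE = \frac{1}{n}\sum_i |y_{ig} - y_{ip}|}
#' \deqn{MAPE = \frac{1}{n}\sum_i \frac{|y_{ig} - y_{ip}|}{y_{ig}} \times 100}
#' \deqn{RMSE = \sqrt{\frac{1}{n}\sum_i (y_{ig} - y_{ip})^2}}
#' \deqn{r = \frac{\frac{1}{n-1}\sum_i (y_{ig}-\bar y_g)(y_{ip}-\bar y_p)}
#'   {STD(y_g)\,STD(y_p)}}
#' with STD the sample standard deviation (n-1 denominator). MAPE is on
#' the percent scale. A zero ground-truth value leaves MAPE undefined
#' (reported `NA` with a warning -- cleaning should have removed zero
#' rows; evaluation never mutates its inputs). A constant series leaves
#' the Pearson correlation undefined (`NA` with a warning).
#'
#' @param y_true Ground-truth values (length >= 2).
#' @param y_pred Predicted values, same length.
#' @return An object of class `metrics_report`: list with `mae`, `mape`,
#'   `rmse`, `pearson_r`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  n <- length(y_true)
  if (n < 2L) stop("metrics need at least 2 observations", call. = FALSE)
  if (any(!is.finite(y_true)) || any(!is.finite(y_pred))) {
    stop("metrics require finite inputs", call. = FALSE)
  }
  err <- y_true - y_pred
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  mape <- if (any(y_true == 0)) {
    warning("MAPE undefined: y_true contains zero; reporting NA",
            call. = FALSE)
    NA_real_
  } else {
    mean(abs(err) / abs(y_true)) * 100
  }
  pearson_r <- if (sd(y_true) == 0 || sd(y_pred) == 0) {
    warning("Pearson correlation undefined for a constant series; ",
            "reporting NA", call. = FALSE)
    NA_real_
  } else {
    sum((y_true - mean(y_true)) * (y_pred - mean(y_pred))) /
      ((n - 1) * sd(y_true) * sd(y_pred))
  }
  structure(list(mae = mae, mape = mape, rmse = rmse,
                 pearson_r = pearson_r, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE %.4g | RMSE %.4g | MAPE %.4g%% | Pearson r %.4g (n = %d)\n",
              x$mae, x$rmse, x$mape, x$pearson_r, x$n))
  invisible(x)
}

#' Rank candidate models and designate the best per bio-signal
#'
#' Ranking key: lowest MAPE, ties broken by higher Pearson correlation.
#' The rendered table follows the column order MAE, RMSE, MAPE %, Pearson
#' Correlation.
#'
#' @param reports A nested named list: `reports[[signal]][[model]]` is a
#'   [compute_metrics()] result.
#' @return An object of class `model_selection`: list with `table`
#'   (tibble: `signal`, `model`, `mae`, `rmse`, `mape_pct`, `pearson_r`,
#'   `selected`) and `best` (named character vector signal -> model).
#' @export
model_selection_report <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  rows <- list()
  best <- character(0)
  for (signal in names(reports)) {
    fam <- reports[[signal]]
    if (length(fam) < 1L) stop("no reports for signal ", signal, call. = FALSE)
    tab <- dplyr::bind_rows(lapply(names(fam), function(m) {
      r <- fam[[m]]
      tibble::tibble(signal = signal, model = m, mae = r$mae, rmse = r$rmse,
                     mape_pct = r$mape, pearson_r = r$pearson_r)
    }))
    ord <- order(tab$mape_pct, -tab$pearson_r)
    tab <- tab[ord, ]
    tab$selected <- seq_len(nrow(tab)) == 1L
    best[signal] <- tab$model[1]
    rows[[signal]] <- tab
  }
  structure(list(table = dplyr::bind_rows(rows), best = best),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  for (signal in unique(x$table$signal)) {
    tab <- x$table[x$table$signal == signal, ]
    cat(sprintf("%s model\tMAE\tRMSE\tMAPE %%\tPearson Correlation\n",
                toupper(signal)))
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("%s%s\t%.3g\t%.3g\t%.3g\t%.3g\n",
                  tab$model[i], if (tab$selected[i]) " *" else "",
                  tab$mae[i], tab$rmse[i], tab$mape_pct[i], tab$pearson_r[i]))
    }
  }
  invisible(x)
}
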