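# Model specs, the shared training/prediction surface, and bundle
# serialization for the three regressor families. Each trained model maps
# one 150-sample AC trace to one bio-signal value; the fused system runs
# one model per bio-signal on the shared trace (nine models across the
# three families).

#' Gradient-boosted tree regressor specification
#'
#' Per-bio-signal defaults follow the tuned design parameters of the
#' reference system: HR learning rate 0.05 / 350 estimators / depth 4 /
#' 50 early-stopping rounds; BR 0.05 / 300 / 5 / 200; SpO2 0.01 / 100 /
#' 6 / 5; random state 99 and MAE as the evaluation metric throughout.
#'
#' @param signal Optional bio-signal (`"hr"`, `"br"`, `"spo2"`) selecting
#'   the tuned defaults; individual arguments override.
#' @param learning_rate Shrinkage per boosting round (> 0).
#' @param n_estimators Maximum number of trees (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param random_state Recorded random state (the learner itself is
#'   deterministic; exact-greedy splits with fixed tie-breaking).
#' @param early_stopping_rounds Stop when validation MAE has not improved
#'   for this many rounds.
#' @param eval_metric Early-stopping metric; `"mae"`.
#' @param lambda L2 regularization on leaf weights.
#' @param gamma Minimum split gain.
#' @param min_child_weight Minimum hessian sum per child.
#' @return An object of class `c("xgb_spec", "model_spec")`.
#' @export
xgb_spec <- function(signal = NULL, learning_rate = NULL, n_estimators = NULL,
                     max_depth = NULL, random_state = 99L,
                     early_stopping_rounds = NULL, eval_metric = "mae",
                     lambda = 1, gamma = 0, min_child_weight = 1) {
  defaults <- list(
    hr = list(learning_rate = 0.05, n_estimators = 350L, max_depth = 4L,
              early_stopping_rounds = 50L),
    br = list(learning_rate = 0.05, n_estimators = 300L, max_depth = 5L,
              early_stopping_rounds = 200L),
    spo2 = list(learning_rate = 0.01, n_estimators = 100L, max_depth = 6L,
                early_stopping_rounds = 5L)
  )
  d <- if (!is.null(signal)) defaults[[match.arg(signal, names(defaults))]]
       else list(learning_rate = 0.05, n_estimators = 300L, max_depth = 4L,
                 early_stopping_rounds = 50L)
  spec <- list(
    learning_rate = learning_rate %||% d$learning_rate,
    n_estimators = n_estimators %||% d$n_estimators,
    max_depth = max_depth %||% d$max_depth,
    random_state = as.integer(random_state),
    early_stopping_rounds = early_stopping_rounds %||% d$early_stopping_rounds,
    eval_metric = match.arg(eval_metric, "mae"),
    lambda = lambda, gamma = gamma, min_child_weight = min_child_weight
  )
  if (spec$learning_rate <= 0) {
    stop("configuration error: learning_rate must be > 0", call. = FALSE)
  }
  if (spec$n_estimators < 1) {
    stop("configuration error: n_estimators must be >= 1", call. = FALSE)
  }
  if (spec$max_depth < 1) {
    stop("configuration error: max_depth must be >= 1", call. = FALSE)
  }
  structure(spec, class = c("xgb_spec", "model_spec"))
}

#' Multilayer-perceptron regressor specification
#'
#' Architecture: input of width 150, batch normalization fitted right
#' after the input (replacing manual feature scaling), then dense hidden
#' layers with ReLU activation and dropout regularization after each, and
#' one linear output neuron. Weights use He (variance-scaling)
#' initialization, standard for ReLU-family activations.
#'
#' @param input_width Trace length consumed (150).
#' @param hidden_widths Sizes of the dense hidden layers (>= 1 layer).
#' @param dropout_rate Dropout rate per hidden layer, in `[0, 1)`.
#' @param use_batch_norm_after_input Keep the post-input batch-norm layer.
#' @return An object of class `c("mlp_spec", "model_spec")`.
#' @export
mlp_spec <- function(input_width = 150L, hidden_widths = c(128L, 64L, 32L),
                     dropout_rate = 0.2, use_batch_norm_after_input = TRUE) {
  if (length(hidden_widths) < 1L || any(hidden_widths < 1L)) {
    stop("configuration error: need at least one hidden layer of width >= 1",
         call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("configuration error: dropout_rate must be in [0, 1)", call. = FALSE)
  }
  structure(list(input_width = as.integer(input_width),
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate,
                 use_batch_norm_after_input = isTRUE(use_batch_norm_after_input)),
            class = c("mlp_spec", "model_spec"))
}

#' LSTM regressor specification
#'
#' Architecture: one LSTM layer over the 150-step trace (scalar input per
#' step), batch normalization right after the recurrent layer, a cascade
#' of dense layers each followed by LeakyReLU activation and dropout, and
#' one linear output unit.
#'
#' @param lstm_units Recurrent state width (>= 1).
#' @param dense_widths Dense cascade sizes after the recurrent layer.
#' @param recurrent_dropout Variational dropout on the recurrent state
#'   during training, in `[0, 1)`.
#' @param dense_dropout Dropout after each dense layer, in `[0, 1)`.
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.01).
#' @param input_width Trace length consumed (150).
#' @return An object of class `c("lstm_spec", "model_spec")`.
#' @export
lstm_spec <- function(lstm_units = 64L, dense_widths = c(64L, 32L),
                      recurrent_dropout = 0, dense_dropout = 0.2,
                      leaky_slope = 0.01, input_width = 150L) {
  if (lstm_units < 1L) {
    stop("configuration error: lstm_units must be >= 1", call. = FALSE)
  }
  if (recurrent_dropout < 0 || recurrent_dropout >= 1 ||
      dense_dropout < 0 || dense_dropout >= 1) {
    stop("configuration error: dropout rates must be in [0, 1)", call. = FALSE)
  }
  structure(list(lstm_units = as.integer(lstm_units),
                 dense_widths = as.integer(dense_widths),
                 recurrent_dropout = recurrent_dropout,
                 dense_dropout = dense_dropout,
                 leaky_slope = leaky_slope,
                 input_width = as.integer(input_width)),
            class = c("lstm_spec", "model_spec"))
}

#' Training configuration for the neural families
#'
#' Neural models train with Adam on MAE loss (matching the evaluation
#' metric), early stopping on validation loss with a configurable
#' patience, mini-batches of 64, and at most 500 epochs by default.
#'
#' @param learning_rate Adam step size.
#' @param loss `"mae"` or `"mse"`.
#' @param max_epochs Upper bound on epochs.
#' @param patience Epochs without validation improvement before stopping
#'   (>= 1).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, loss = c("mae", "mse"),
                         max_epochs = 500L, patience = 20L, batch_size = 64L,
                         seed = 1L, verbose = FALSE) {
  if (patience < 1L) stop("configuration error: patience must be >= 1",
                          call. = FALSE)
  structure(list(learning_rate = learning_rate, loss = match.arg(loss),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build an untrained model from a specification
#'
#' Validates the specification and seeds parameter initialization for the
#' neural families (boosted trees initialize from data at fit time).
#'
#' @param spec An [xgb_spec()], [mlp_spec()] or [lstm_spec()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `twin_untrained`.
#' @export
build_model <- function(spec, seed = 1L) {
  if (!inherits(spec, "model_spec")) {
    stop("configuration error: spec must be a model_spec", call. = FALSE)
  }
  family <- sub("_spec$", "", class(spec)[1])
  params <- switch(family,
    mlp = init_mlp_params(spec, seed),
    lstm = init_lstm_params(spec, seed),
    xgb = NULL)
  structure(list(family = family, spec = spec, params = params,
                 seed = as.integer(seed)),
            class = "twin_untrained")
}

#' Train a regressor on a trace dataset
#'
#' Fits one model of the given family mapping the 150-sample AC trace to
#' the chosen bio-signal. Training stops at the configured maximum or
#' when the validation loss stops improving for the configured patience
#' (neural families) / early-stopping rounds (boosted trees). Train and
#' validation sets must be subject-disjoint for honest validation -- use
#' [split_subjectwise()].
#'
#' @param x A model spec or a [build_model()] result.
#' @param train,val Trace dataset tibbles (`val` optional but required
#'   for early stopping).
#' @param signal Target bio-signal: `"hr"`, `"br"` or `"spo2"`.
#' @param cfg A [train_config()] (used by the neural families).
#' @return An object of class `twin_model` with elements `family`,
#'   `spec`, `signal`, `params`, `meta` (seed, stopping point, dataset
#'   fingerprint, target range) and `curves` (per-epoch/round train and
#'   validation loss).
#' @export
train_model <- function(x, train, val = NULL, signal = c("hr", "br", "spo2"),
                        cfg = train_config()) {
  signal <- match.arg(signal)
  model <- if (inherits(x, "twin_untrained")) x else build_model(x, seed = cfg$seed)
  xy <- prep_xy(train, signal)
  xyv <- if (!is.null(val)) prep_xy(val, signal) else NULL
  fitted <- switch(model$family,
    xgb = train_xgb(model$spec, xy, xyv),
    mlp = train_mlp(model, xy, xyv, cfg),
    lstm = train_lstm(model, xy, xyv, cfg),
    stop("unknown model family: ", model$family, call. = FALSE))
  fitted$signal <- signal
  fitted$meta$data_fingerprint <- dataset_fingerprint(xy$X, xy$y)
  fitted$meta$n_train <- length(xy$y)
  fitted$meta$target_range <- range(xy$y)
  structure(fitted, class = "twin_model")
}

prep_xy <- function(ds, signal) {
  if (is.null(ds) || nrow(ds) == 0L) {
    stop("empty training set", call. = FALSE)
  }
  col <- gt_col(signal)
  y <- ds[[col]]
  keep <- !is.na(y)
  if (!any(keep)) {
    stop("target '", col, "' is absent from every record", call. = FALSE)
  }
  list(X = trace_matrix(ds[keep, , drop = FALSE]), y = y[keep])
}

dataset_fingerprint <- function(X, y) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(sprintf("%.10g", c(dim(X), sum(X), sum(X^2), sum(y), sum(y^2))),
             tmp)
  unname(tools::md5sum(tmp))
}

# --- boosted-tree training ----------------------------------------------

train_xgb <- function(spec, xy, xyv) {
  n <- length(xy$y)
  base_score <- mean(xy$y)
  pred <- rep(base_score, n)
  pred_val <- if (!is.null(xyv)) rep(base_score, length(xyv$y)) else NULL
  trees <- list()
  curve_train <- numeric(0)
  curve_val <- numeric(0)
  best_val <- Inf
  best_round <- 0L
  for (r in seq_len(spec$n_estimators)) {
    grad <- pred - xy$y       # squared-error loss: g = pred - y, h = 1
    hess <- rep(1, n)
    tree <- fit_tree_cpp(xy$X, grad, hess, spec$max_depth, spec$lambda,
                         spec$gamma, spec$min_child_weight)
    trees[[r]] <- tree
    pred <- pred + spec$learning_rate *
      predict_forest_cpp(xy$X, list(tree), 0, 1, -1L)
    curve_train[r] <- mean(abs(xy$y - pred))
    if (!is.null(xyv)) {
      pred_val <- pred_val + spec$learning_rate *
        predict_forest_cpp(xyv$X, list(tree), 0, 1, -1L)
      curve_val[r] <- mean(abs(xyv$y - pred_val))
      if (curve_val[r] < best_val - 1e-12) {
        best_val <- curve_val[r]
        best_round <- r
      } else if (r - best_round >= spec$early_stopping_rounds) {
        break
      }
    }
  }
  n_used <- if (!is.null(xyv)) max(best_round, 1L) else length(trees)
  curves <- tibble::tibble(step = seq_along(curve_train),
                           train_loss = curve_train,
                           val_loss = if (!is.null(xyv)) curve_val else NA_real_)
  list(family = "xgb", spec = spec,
       params = list(base_score = base_score, trees = trees[seq_len(length(trees))],
                     n_trees_used = n_used),
       meta = list(seed = spec$random_state, stopped_at = n_used,
                   rounds_run = length(trees),
                   best_val_loss = if (!is.null(xyv)) best_val else NA_real_),
       curves = curves)
}

# --- prediction ----------------------------------------------------------

as_trace_input <- function(newdata, input_width = 150L) {
  if (is.data.frame(newdata)) {
    X <- trace_matrix(newdata, input_width)
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    X <- matrix(newdata, nrow = 1)
  } else if (is.matrix(newdata)) {
    X <- newdata
  } else {
    stop("newdata must be a trace dataset, matrix or numeric vector",
         call. = FALSE)
  }
  if (ncol(X) != input_width) {
    stop("trace length must be ", input_width, ", got ", ncol(X),
         call. = FALSE)
  }
  X
}

#' Predict bio-signal values from traces
#'
#' @param object A trained `twin_model`.
#' @param newdata Trace input: a trace dataset tibble, an n x 150 matrix,
#'   or a single length-150 numeric trace.
#' @param ... Unused.
#' @return Numeric vector, one prediction per trace. Batch prediction is
#'   identical to per-record prediction.
#' @export
predict.twin_model <- function(object, newdata, ...) {
  width <- object$spec$input_width %||% 150L
  X <- as_trace_input(newdata, width)
  switch(object$family,
    xgb = predict_forest_cpp(X, object$params$trees,
                             object$params$base_score,
                             object$spec$learning_rate,
                             object$params$n_trees_used),
    mlp = predict_mlp(object, X),
    lstm = predict_lstm(object, X),
    stop("unknown model family: ", object$family, call. = FALSE))
}

# --- bundle serialization ("tuple format": parameters + metadata) --------

# Learned parameters are serialized as C99 hexadecimal floating-point
# strings ("%a"), the only plain-text encoding that round-trips IEEE-754
# doubles exactly, so save/load changes no prediction bit.
encode_params <- function(params) {
  rapply(params, function(x) {
    if (is.matrix(x)) {
      list(dim = dim(x), data = sprintf("%a", as.vector(x)))
    } else {
      list(data = sprintf("%a", as.numeric(x)))
    }
  }, classes = c("matrix", "array", "numeric", "integer"), how = "replace")
}

#' Save a trained model bundle
#'
#' Writes a self-describing directory bundle: `spec.json` (family, spec,
#' signal), `params.json` (all learned parameters at full numeric
#' precision) and `meta.json` (seed, stopping point, dataset fingerprint,
#' and an MD5 checksum of the parameter file for integrity verification).
#' Predictions round-trip bit-identically through save/load.
#'
#' @param model A trained `twin_model`.
#' @param path Bundle directory (created if needed).
#' @return Invisibly, `path`; the serialized parameter size in bytes is
#'   recorded in `meta.json` as `bundle_bytes`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "twin_model"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  jsonlite::write_json(
    list(family = model$family, signal = model$signal,
         spec = unclass(model$spec), spec_class = class(model$spec)),
    file.path(path, "spec.json"), auto_unbox = TRUE, digits = NA)
  params_path <- file.path(path, "params.json")
  jsonlite::write_json(encode_params(model$params), params_path,
                       auto_unbox = FALSE, digits = NA)
  meta <- model$meta
  meta$checksum <- unname(tools::md5sum(params_path))
  meta$bundle_bytes <- file.size(params_path)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$curves)) {
    write.csv(model$curves, file.path(path, "curves.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Load a trained model bundle
#'
#' Verifies the parameter checksum before reconstructing the model; a
#' tampered or corrupt bundle raises an integrity error naming the
#' expected and observed checksums.
#'
#' @param path Bundle directory written by [save_model()].
#' @return A `twin_model`.
#' @export
load_model <- function(path) {
  spec_info <- jsonlite::read_json(file.path(path, "spec.json"),
                                   simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  params_path <- file.path(path, "params.json")
  observed <- unname(tools::md5sum(params_path))
  if (!is.null(meta$checksum) && !identical(observed, meta$checksum)) {
    stop("integrity error: parameter checksum mismatch (expected ",
         meta$checksum, ", observed ", observed, ")", call. = FALSE)
  }
  raw <- jsonlite::read_json(params_path, simplifyVector = FALSE)
  params <- decode_params(raw, spec_info$family)
  spec <- structure(as.list(spec_info$spec), class = spec_info$spec_class)
  structure(list(family = spec_info$family, spec = spec,
                 signal = spec_info$signal, params = params,
                 meta = meta, curves = NULL),
            class = "twin_model")
}

decode_params <- function(raw, family) {
  decode_one <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      vals <- as.numeric(unlist(x$data))
      if (!is.null(x$dim)) {
        matrix(vals, as.integer(x$dim[[1]]), as.integer(x$dim[[2]]))
      } else {
        vals
      }
    } else if (is.list(x)) {
      lapply(x, decode_one)
    } else {
      as.numeric(unlist(x))
    }
  }
  params <- decode_one(raw)
  if (family == "xgb") {
    params$trees <- lapply(params$trees, function(m) {
      colnames(m) <- c("feature", "threshold", "left", "right", "value")
      m
    })
    params$n_trees_used <- as.integer(params$n_trees_used)
  }
  params
}
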