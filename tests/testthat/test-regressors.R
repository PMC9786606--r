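# The three regressor families: spec validation, training behaviour,
# prediction contracts, serialization.

make_split <- function(n_subjects = 24, seed = 11) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  synth_dataset(n_subjects, 1, d, seed = seed)
  split_subjectwise(load_trace_files(d), seed = seed)
}

test_that("specs carry the tuned per-signal defaults and validate input", {
  hr <- xgb_spec("hr")
  expect_equal(hr$learning_rate, 0.05)
  expect_equal(hr$n_estimators, 350L)
  expect_equal(hr$max_depth, 4L)
  expect_equal(hr$early_stopping_rounds, 50L)
  expect_equal(hr$random_state, 99L)
  expect_equal(hr$eval_metric, "mae")
  br <- xgb_spec("br")
  expect_equal(c(br$learning_rate, br$n_estimators, br$max_depth,
                 br$early_stopping_rounds), c(0.05, 300, 5, 200))
  spo2 <- xgb_spec("spo2")
  expect_equal(c(spo2$learning_rate, spo2$n_estimators, spo2$max_depth,
                 spo2$early_stopping_rounds), c(0.01, 100, 6, 5))

  expect_error(xgb_spec(learning_rate = 0), "learning_rate")
  expect_error(xgb_spec(n_estimators = 0), "n_estimators")
  expect_error(mlp_spec(hidden_widths = integer(0)), "hidden layer")
  expect_error(mlp_spec(dropout_rate = 1), "dropout_rate")
  expect_error(lstm_spec(lstm_units = 0), "lstm_units")
  expect_error(build_model(list(a = 1)), "model_spec")
})

test_that("MLP and LSTM architectures end in one linear output unit", {
  mp <- rppgtwin:::init_mlp_params(mlp_spec(hidden_widths = c(16, 8)), 1)
  expect_equal(dim(mp$W3), c(8, 1))          # final dense: 1 unit
  expect_equal(length(mp$b3), 1)
  lp <- rppgtwin:::init_lstm_params(lstm_spec(lstm_units = 6,
                                              dense_widths = 4), 1)
  expect_equal(dim(lp$Wx), c(1, 24))         # 4 gates x 6 units
  expect_equal(dim(lp$W2), c(4, 1))
})

test_that("constant-target training degenerates to the constant", {
  ds <- make_trace_ds(rep(2, 6), hr = 75, seed = 41)
  sp <- suppressWarnings(split_subjectwise(ds, seed = 1))
  for (spec in list(xgb_spec("hr", n_estimators = 10),
                    mlp_spec(hidden_widths = 8),
                    lstm_spec(lstm_units = 4, dense_widths = 4))) {
    m <- train_model(spec, sp$train, sp$val, "hr",
                     train_config(max_epochs = 3, patience = 2, seed = 5))
    expect_true(all(abs(predict(m, sp$test) - 75) <= 1.0))
  }
})

test_that("validation plateau triggers early stopping before the cap", {
  # tiny training set overfits immediately; validation stops improving
  sp <- make_split(12, seed = 43)
  m <- train_model(xgb_spec("hr", n_estimators = 300,
                            early_stopping_rounds = 10),
                   sp$train, sp$val, "hr")
  expect_lt(m$meta$rounds_run, 300)
  expect_lte(m$meta$stopped_at, m$meta$rounds_run)
  expect_equal(nrow(m$curves), m$meta$rounds_run)
  expect_true(all(c("train_loss", "val_loss") %in% names(m$curves)))
})

test_that("training MAE is non-increasing in rounds on noiseless data", {
  d <- withr::local_tempdir()
  synth_dataset(12, 1, d, seed = 47, noise_sd = 0)
  ds <- load_trace_files(d)
  m <- train_model(xgb_spec("hr", n_estimators = 40), ds, NULL, "hr")
  expect_true(all(diff(m$curves$train_loss) <= 1e-9))
})

test_that("fixed seed and data give identical boosted-tree fits", {
  sp <- make_split(10, seed = 51)
  m1 <- train_model(xgb_spec("hr", n_estimators = 25), sp$train, sp$val, "hr")
  m2 <- train_model(xgb_spec("hr", n_estimators = 25), sp$train, sp$val, "hr")
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("neural training is reproducible under a fixed seed", {
  sp <- make_split(10, seed = 53)
  cfg <- train_config(max_epochs = 4, patience = 3, seed = 7)
  m1 <- train_model(mlp_spec(hidden_widths = c(16, 8)), sp$train, sp$val,
                    "hr", cfg)
  m2 <- train_model(mlp_spec(hidden_widths = c(16, 8)), sp$train, sp$val,
                    "hr", cfg)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("prediction contracts: batching, length check, target hull", {
  sp <- make_split(16, seed = 57)
  m <- quick_model(sp, "hr")
  X <- trace_matrix(sp$test)
  batch <- predict(m, X)
  single <- vapply(seq_len(nrow(X)), function(i) predict(m, X[i, ]),
                   numeric(1))
  expect_identical(batch, single)
  expect_true(all(is.finite(batch)))
  hull <- m$meta$target_range
  expect_true(all(batch >= hull[1] - 1e-9 & batch <= hull[2] + 1e-9))
  expect_error(predict(m, runif(149)), "150")
  expect_error(train_model(xgb_spec("hr"), sp$train[0, ], NULL, "hr"),
               "empty")
  no_target <- sp$train
  no_target$hr_gt <- NA_real_
  expect_error(train_model(xgb_spec("hr"), no_target, NULL, "hr"), "absent")
})

test_that("bundles round-trip bit-identically and detect tampering", {
  sp <- make_split(10, seed = 61)
  cfg <- train_config(max_epochs = 3, patience = 2, seed = 3)
  specs <- list(xgb = xgb_spec("hr", n_estimators = 15),
                mlp = mlp_spec(hidden_widths = c(12, 6)),
                lstm = lstm_spec(lstm_units = 5, dense_widths = 5))
  for (fam in names(specs)) {
    m <- train_model(specs[[fam]], sp$train, sp$val, "hr", cfg)
    pred <- predict(m, sp$test)
    b <- withr::local_tempdir()
    save_model(m, b)
    m2 <- load_model(b)
    expect_identical(predict(m2, sp$test), pred)
    meta <- jsonlite::read_json(file.path(b, "meta.json"))
    expect_true(meta$bundle_bytes > 0)
    # flip one byte of the parameter blob
    pf <- file.path(b, "params.json")
    txt <- readLines(pf, warn = FALSE)
    txt[1] <- sub("0x1", "0x2", txt[1])
    writeLines(txt, pf)
    expect_error(load_model(b), "integrity")
  }
})

test_that("hand-derived gradients match numerical differentiation", {
  eps <- 1e-6
  rel_err <- function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b))
  withr::with_seed(67, {
    # MLP with smooth loss (MAE kinks would confound the check)
    spec <- mlp_spec(input_width = 10, hidden_widths = c(7, 5),
                     dropout_rate = 0)
    params <- rppgtwin:::init_mlp_params(spec, 1)
    X <- matrix(rnorm(40), 4, 10)
    y <- rnorm(4) + 5
    bn <- list(mean = rep(0, 10), var = rep(1, 10))
    loss_at <- function(p) {
      fw <- rppgtwin:::mlp_forward(p, spec, X, TRUE, bn)
      mean((fw$yhat - y)^2)
    }
    fw <- rppgtwin:::mlp_forward(params, spec, X, TRUE, bn)
    lg <- rppgtwin:::loss_grad(fw$yhat, y, "mse")
    gr <- rppgtwin:::mlp_backward(params, spec, X, lg$dyhat, fw$cache)
    for (nm in names(gr)) {
      for (k in sample(length(gr[[nm]]), min(4, length(gr[[nm]])))) {
        pp <- params; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- params; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_lt(rel_err(num, gr[[nm]][k]), 1e-4)
      }
    }
    # LSTM through time
    ls <- lstm_spec(lstm_units = 4, dense_widths = 4, dense_dropout = 0,
                    input_width = 12)
    lp <- rppgtwin:::init_lstm_params(ls, 2)
    Xl <- matrix(rnorm(36), 3, 12)
    yl <- rnorm(3) + 5
    bns <- list(mean = rep(0, 4), var = rep(1, 4))
    loss_l <- function(p) {
      fw <- rppgtwin:::lstm_forward(p, ls, Xl, TRUE, bns)
      mean((fw$yhat - yl)^2)
    }
    fwl <- rppgtwin:::lstm_forward(lp, ls, Xl, TRUE, bns)
    lgl <- rppgtwin:::loss_grad(fwl$yhat, yl, "mse")
    grl <- rppgtwin:::lstm_backward(lp, ls, Xl, lgl$dyhat, fwl$cache)
    for (nm in c("Wx", "Wh", "b", "bn_gamma", "W1", "W2")) {
      for (k in sample(length(grl[[nm]]), min(4, length(grl[[nm]])))) {
        pp <- lp; pp[[nm]][k] <- pp[[nm]][k] + eps
        pm <- lp; pm[[nm]][k] <- pm[[nm]][k] - eps
        num <- (loss_l(pp) - loss_l(pm)) / (2 * eps)
        expect_lt(rel_err(num, grl[[nm]][k]), 1e-4)
      }
    }
  })
})
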