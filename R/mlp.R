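# Multilayer perceptron: input -> batch norm -> [dense + ReLU + dropout]*
# -> linear output unit. Targets are standardized internally (mean/sd of
# the training targets) and restored at prediction time.

init_mlp_params <- function(spec, seed) {
  withr::with_seed(seed, {
    widths <- c(spec$input_width, spec$hidden_widths, 1L)
    params <- list()
    if (spec$use_batch_norm_after_input) {
      params$bn_gamma <- rep(1, spec$input_width)
      params$bn_beta <- rep(0, spec$input_width)
    }
    n_layers <- length(widths) - 1L
    for (i in seq_len(n_layers)) {
      params[[paste0("W", i)]] <- he_init(widths[i], widths[i + 1])
      params[[paste0("b", i)]] <- rep(0, widths[i + 1])
    }
    # zero-init the linear output head: the initial prediction is the
    # (standardized) target mean, which stabilizes early training
    params[[paste0("W", n_layers)]][] <- 0
    params
  })
}

mlp_forward <- function(params, spec, X, training, bn_state) {
  cache <- list()
  A <- X
  if (spec$use_batch_norm_after_input) {
    bn <- bn_forward(X, params$bn_gamma, params$bn_beta,
                     bn_state$mean, bn_state$var, training)
    cache$bn <- bn
    A <- bn$out
  }
  n_layers <- length(spec$hidden_widths) + 1L
  cache$A <- vector("list", n_layers)
  cache$Z <- vector("list", n_layers)
  cache$mask <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    cache$A[[i]] <- A
    Z <- sweep(A %*% params[[paste0("W", i)]], 2, params[[paste0("b", i)]], `+`)
    cache$Z[[i]] <- Z
    if (i < n_layers) {
      A <- pmax(Z, 0)
      if (training && spec$dropout_rate > 0) {
        mask <- matrix(runif(length(A)) >= spec$dropout_rate,
                       nrow(A), ncol(A)) / (1 - spec$dropout_rate)
        cache$mask[[i]] <- mask
        A <- A * mask
      }
    } else {
      A <- Z
    }
  }
  list(yhat = A[, 1], cache = cache)
}

mlp_backward <- function(params, spec, X, dyhat, cache) {
  n_layers <- length(spec$hidden_widths) + 1L
  grads <- list()
  dA <- matrix(dyhat, ncol = 1)
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) {
      if (!is.null(cache$mask[[i]])) dA <- dA * cache$mask[[i]]
      dA <- dA * (cache$Z[[i]] > 0)
    }
    grads[[paste0("W", i)]] <- t(cache$A[[i]]) %*% dA
    grads[[paste0("b", i)]] <- colSums(dA)
    dA <- dA %*% t(params[[paste0("W", i)]])
  }
  if (spec$use_batch_norm_after_input) {
    bnb <- bn_backward(dA, cache$bn, params$bn_gamma)
    grads$bn_gamma <- bnb$dgamma
    grads$bn_beta <- bnb$dbeta
  }
  grads
}

train_mlp <- function(model, xy, xyv, cfg) {
  spec <- model$spec
  params <- model$params
  std <- standardize_targets(xy$y)
  yv <- if (!is.null(xyv)) (xyv$y - std$mu) / std$sd else NULL
  bn_state <- list(mean = rep(0, spec$input_width),
                   var = rep(1, spec$input_width))

  fwdbwd <- function(params, Xb, yb) {
    fw <- mlp_forward(params, spec, Xb, training = TRUE, bn_state)
    if (spec$use_batch_norm_after_input) {
      bn_state$mean <<- fw$cache$bn$run_mean
      bn_state$var <<- fw$cache$bn$run_var
    }
    lg <- loss_grad(fw$yhat, yb, cfg$loss)
    grads <- mlp_backward(params, spec, Xb, lg$dyhat, fw$cache)
    list(loss = lg$loss, grads = grads)
  }
  evaluate <- function(params, Xv, yv) {
    fw <- mlp_forward(params, spec, Xv, training = FALSE, bn_state)
    loss_grad(fw$yhat, yv, cfg$loss)$loss
  }
  res <- train_loop(params, xy$X, std$y,
                    if (!is.null(xyv)) xyv$X else NULL, yv,
                    cfg, fwdbwd, evaluate, std$sd)
  params <- res$params
  params$bn_run_mean <- bn_state$mean
  params$bn_run_var <- bn_state$var
  params$y_mu <- std$mu
  params$y_sd <- std$sd
  list(family = "mlp", spec = spec, params = params,
       meta = list(seed = cfg$seed, stopped_at = res$stopped_at,
                   best_val_loss = res$best_loss),
       curves = res$curves)
}

predict_mlp <- function(model, X) {
  spec <- model$spec
  bn_state <- list(mean = model$params$bn_run_mean,
                   var = model$params$bn_run_var)
  fw <- mlp_forward(model$params, spec, X, training = FALSE, bn_state)
  fw$yhat * model$params$y_sd + model$params$y_mu
}
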