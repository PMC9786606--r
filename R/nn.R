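# Minimal neural-network primitives: He initialization, Adam, batch
# normalization, and the shared mini-batch training loop with early
# stopping. No compiled-graph framework is available in this stack, so
# forward and backward passes are hand-derived matrix code; parameters
# live in flat named lists of matrices/vectors.

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Batch-norm forward over features (columns). Training mode uses batch
# statistics (biased variance, as is conventional) and updates running
# statistics with momentum; eval mode uses the running statistics so
# predictions are row-independent.
bn_forward <- function(X, gamma, beta, run_mean, run_var,
                       training, momentum = 0.99, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    centered <- sweep(X, 2, mu)
    v <- colMeans(centered^2)
    run_mean <- momentum * run_mean + (1 - momentum) * mu
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean
    v <- run_var
    centered <- sweep(X, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(centered, 2, inv_sd, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, xhat = xhat, centered = centered, inv_sd = inv_sd,
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dout, cache, gamma) {
  B <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, gamma, `*`)
  # standard batch-norm gradient w.r.t. the input
  t1 <- dxhat
  t2 <- matrix(colMeans(dxhat), B, ncol(dout), byrow = TRUE)
  t3 <- cache$xhat * matrix(colMeans(dxhat * cache$xhat), B, ncol(dout),
                            byrow = TRUE)
  dX <- sweep(t1 - t2 - t3, 2, cache$inv_sd, `*`)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

loss_grad <- function(yhat, y, loss) {
  d <- yhat - y
  if (loss == "mae") {
    list(loss = mean(abs(d)), dyhat = sign(d) / length(y))
  } else {
    list(loss = mean(d^2), dyhat = 2 * d / length(y))
  }
}

# Shared mini-batch loop: fwdbwd(params, X, y, training) returns
# list(loss, grads) in training mode; evaluate(params, X, y) returns the
# loss in eval mode. Targets are standardized by the caller; losses in
# the curves are reported on the original target scale.
train_loop <- function(params, X, y, Xval, yval, cfg, fwdbwd, evaluate,
                       y_sd) {
  n <- nrow(X)
  state <- adam_init(params)
  best <- list(params = params, loss = Inf, epoch = 0L)
  curve_train <- numeric(0)
  curve_val <- numeric(0)
  withr::with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        if (length(idx) < 2L) next   # batch norm needs >= 2 rows
        res <- fwdbwd(params, X[idx, , drop = FALSE], y[idx])
        params <- res$params %||% params
        upd <- adam_step(params, res$grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + res$loss
        nb <- nb + 1L
      }
      curve_train[epoch] <- epoch_loss / max(nb, 1L) * y_sd
      monitor <- if (!is.null(Xval)) {
        curve_val[epoch] <- evaluate(params, Xval, yval) * y_sd
        curve_val[epoch]
      } else {
        curve_train[epoch]
      }
      if (cfg$verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        curve_train[epoch],
                        if (!is.null(Xval)) curve_val[epoch] else NA))
      }
      if (monitor < best$loss - 1e-10) {
        best <- list(params = params, loss = monitor, epoch = epoch)
      } else if (epoch - best$epoch >= cfg$patience) {
        break
      }
    }
  })
  curves <- tibble::tibble(step = seq_along(curve_train),
                           train_loss = curve_train,
                           val_loss = if (!is.null(Xval)) curve_val else NA_real_)
  list(params = best$params, stopped_at = best$epoch,
       best_loss = best$loss, curves = curves)
}

standardize_targets <- function(y) {
  mu <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  list(mu = mu, sd = s, y = (y - mu) / s)
}
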