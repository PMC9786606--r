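# LSTM regressor: a single recurrent layer consumes the 150-step trace
# (one scalar per step), batch normalization follows the recurrent layer,
# then a dense cascade with LeakyReLU and dropout, and a linear output
# unit. Backpropagation through time is hand-derived; gate order in the
# packed weight matrices is [input, forget, cell, output].

sigmoid <- function(x) 1 / (1 + exp(-x))

init_lstm_params <- function(spec, seed) {
  withr::with_seed(seed, {
    U <- spec$lstm_units
    params <- list(
      Wx = he_init(1L, 4L * U),
      Wh = he_init(U, 4L * U) / sqrt(2),  # orthogonal-ish scale for recurrence
      b = c(rep(0, U), rep(1, U), rep(0, 2L * U))  # forget-gate bias 1
    )
    params$bn_gamma <- rep(1, U)
    params$bn_beta <- rep(0, U)
    widths <- c(U, spec$dense_widths, 1L)
    n_dense <- length(widths) - 1L
    for (i in seq_len(n_dense)) {
      params[[paste0("W", i)]] <- he_init(widths[i], widths[i + 1])
      params[[paste0("b", i)]] <- rep(0, widths[i + 1])
    }
    # zero-init the output head (see init_mlp_params)
    params[[paste0("W", n_dense)]][] <- 0
    params
  })
}

lstm_recurrent_forward <- function(params, X, U, rec_mask = NULL) {
  B <- nrow(X); Tn <- ncol(X)
  H <- matrix(0, B, U); C <- matrix(0, B, U)
  steps <- vector("list", Tn)
  ii <- 1:U; ff <- (U + 1):(2 * U); gg <- (2 * U + 1):(3 * U)
  oo <- (3 * U + 1):(4 * U)
  for (t in seq_len(Tn)) {
    Hd <- if (is.null(rec_mask)) H else H * rec_mask
    Z <- outer(X[, t], params$Wx[1, ]) + Hd %*% params$Wh +
      matrix(params$b, B, 4 * U, byrow = TRUE)
    i_g <- sigmoid(Z[, ii, drop = FALSE])
    f_g <- sigmoid(Z[, ff, drop = FALSE])
    g_g <- tanh(Z[, gg, drop = FALSE])
    o_g <- sigmoid(Z[, oo, drop = FALSE])
    C_prev <- C
    C <- f_g * C_prev + i_g * g_g
    tC <- tanh(C)
    Hn <- o_g * tC
    steps[[t]] <- list(Hd = Hd, i = i_g, f = f_g, g = g_g, o = o_g,
                       C_prev = C_prev, tC = tC)
    H <- Hn
  }
  list(H = H, steps = steps)
}

lstm_forward <- function(params, spec, X, training, bn_state, rec_mask = NULL) {
  U <- spec$lstm_units
  rec <- lstm_recurrent_forward(params, X, U,
                                if (training) rec_mask else NULL)
  bn <- bn_forward(rec$H, params$bn_gamma, params$bn_beta,
                   bn_state$mean, bn_state$var, training)
  A <- bn$out
  n_dense <- length(spec$dense_widths) + 1L
  cache <- list(rec = rec, bn = bn, A = vector("list", n_dense),
                Z = vector("list", n_dense), mask = vector("list", n_dense))
  for (i in seq_len(n_dense)) {
    cache$A[[i]] <- A
    Z <- sweep(A %*% params[[paste0("W", i)]], 2, params[[paste0("b", i)]], `+`)
    cache$Z[[i]] <- Z
    if (i < n_dense) {
      A <- ifelse(Z > 0, Z, spec$leaky_slope * Z)
      if (training && spec$dense_dropout > 0) {
        mask <- matrix(runif(length(A)) >= spec$dense_dropout,
                       nrow(A), ncol(A)) / (1 - spec$dense_dropout)
        cache$mask[[i]] <- mask
        A <- A * mask
      }
    } else {
      A <- Z
    }
  }
  list(yhat = A[, 1], cache = cache)
}

lstm_backward <- function(params, spec, X, dyhat, cache, rec_mask = NULL) {
  U <- spec$lstm_units
  B <- nrow(X); Tn <- ncol(X)
  n_dense <- length(spec$dense_widths) + 1L
  grads <- list()
  dA <- matrix(dyhat, ncol = 1)
  for (i in rev(seq_len(n_dense))) {
    if (i < n_dense) {
      if (!is.null(cache$mask[[i]])) dA <- dA * cache$mask[[i]]
      dA <- dA * ifelse(cache$Z[[i]] > 0, 1, spec$leaky_slope)
    }
    grads[[paste0("W", i)]] <- t(cache$A[[i]]) %*% dA
    grads[[paste0("b", i)]] <- colSums(dA)
    dA <- dA %*% t(params[[paste0("W", i)]])
  }
  bnb <- bn_backward(dA, cache$bn, params$bn_gamma)
  grads$bn_gamma <- bnb$dgamma
  grads$bn_beta <- bnb$dbeta

  dH <- bnb$dX
  dC <- matrix(0, B, U)
  dWx <- matrix(0, 1, 4 * U)
  dWh <- matrix(0, U, 4 * U)
  db <- rep(0, 4 * U)
  ii <- 1:U; ff <- (U + 1):(2 * U); gg <- (2 * U + 1):(3 * U)
  oo <- (3 * U + 1):(4 * U)
  for (t in rev(seq_len(Tn))) {
    st <- cache$rec$steps[[t]]
    do <- dH * st$tC
    dC <- dC + dH * st$o * (1 - st$tC^2)
    di <- dC * st$g
    dg <- dC * st$i
    df <- dC * st$C_prev
    dC_prev <- dC * st$f
    dZ <- matrix(0, B, 4 * U)
    dZ[, ii] <- di * st$i * (1 - st$i)
    dZ[, ff] <- df * st$f * (1 - st$f)
    dZ[, gg] <- dg * (1 - st$g^2)
    dZ[, oo] <- do * st$o * (1 - st$o)
    dWx <- dWx + matrix(colSums(dZ * X[, t]), 1)
    dWh <- dWh + t(st$Hd) %*% dZ
    db <- db + colSums(dZ)
    dHprev <- dZ %*% t(params$Wh)
    if (!is.null(rec_mask)) dHprev <- dHprev * rec_mask
    dH <- dHprev
    dC <- dC_prev
  }
  grads$Wx <- dWx
  grads$Wh <- dWh
  grads$b <- db
  grads
}

train_lstm <- function(model, xy, xyv, cfg) {
  spec <- model$spec
  params <- model$params
  std <- standardize_targets(xy$y)
  yv <- if (!is.null(xyv)) (xyv$y - std$mu) / std$sd else NULL
  bn_state <- list(mean = rep(0, spec$lstm_units),
                   var = rep(1, spec$lstm_units))

  fwdbwd <- function(params, Xb, yb) {
    rec_mask <- if (spec$recurrent_dropout > 0) {
      matrix(runif(nrow(Xb) * spec$lstm_units) >= spec$recurrent_dropout,
             nrow(Xb), spec$lstm_units) / (1 - spec$recurrent_dropout)
    } else NULL
    fw <- lstm_forward(params, spec, Xb, training = TRUE, bn_state, rec_mask)
    bn_state$mean <<- fw$cache$bn$run_mean
    bn_state$var <<- fw$cache$bn$run_var
    lg <- loss_grad(fw$yhat, yb, cfg$loss)
    grads <- lstm_backward(params, spec, Xb, lg$dyhat, fw$cache, rec_mask)
    list(loss = lg$loss, grads = grads)
  }
  evaluate <- function(params, Xv, yv) {
    fw <- lstm_forward(params, spec, Xv, training = FALSE, bn_state)
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
  list(family = "lstm", spec = spec, params = params,
       meta = list(seed = cfg$seed, stopped_at = res$stopped_at,
                   best_val_loss = res$best_loss),
       curves = res$curves)
}

predict_lstm <- function(model, X) {
  spec <- model$spec
  bn_state <- list(mean = model$params$bn_run_mean,
                   var = model$params$bn_run_var)
  fw <- lstm_forward(model$params, spec, X, training = FALSE, bn_state)
  fw$yhat * model$params$y_sd + model$params$y_mu
}
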