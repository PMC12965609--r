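#' Two-branch recurrent downscaler specification
#'
#' Architecture of the temporal-fusion yield model: a satellite-band branch
#' (`T1 x F1` time series into a recurrent cell) and a weather branch
#' (`T2 x F2`), each followed by a 16-unit ReLU dense layer; their outputs are
#' concatenated with the static features into a merged vector fed through a
#' 128-64-32 ReLU head (dropout after each head layer) and a Softplus output
#' that keeps predicted yields non-negative.
#'
#' @param cell `"lstm"` or `"gru"` (double-bias, reset-after GRU formulation).
#' @param bands_dim `c(T1, F1)` time steps and features of the band branch.
#' @param weather_dim `c(T2, F2)` for the weather branch.
#' @param static_dim number of static features (crop indicator by default).
#' @param rnn_units recurrent hidden units per branch.
#' @param branch_dense width of the per-branch dense layer.
#' @param head widths of the fully connected head.
#' @param dropout dropout rate applied after each head layer during training.
#' @return Object of class `recurrent_spec`.
#' @export
recurrent_spec <- function(cell = c("lstm", "gru"), bands_dim = c(3, 7),
                           weather_dim = c(5, 6), static_dim = 1,
                           rnn_units = 32, branch_dense = 16,
                           head = c(128, 64, 32), dropout = 0.1) {
  cell <- match.arg(cell)
  stopifnot(all(bands_dim >= 1), all(weather_dim >= 1), static_dim >= 0,
            rnn_units >= 1, branch_dense >= 1, length(head) >= 1,
            dropout >= 0, dropout < 1)
  structure(list(cell = cell, bands_dim = as.integer(bands_dim),
                 weather_dim = as.integer(weather_dim),
                 static_dim = as.integer(static_dim),
                 rnn_units = as.integer(rnn_units),
                 branch_dense = as.integer(branch_dense),
                 head = as.integer(head), dropout = dropout),
            class = "recurrent_spec")
}

#' Closed-form trainable parameter count
#'
#' LSTM cell: `4 * (d + h + 1) * h`. GRU cell (double-bias convention, input
#' and recurrent kernels each with their own bias): `3 * (d*h + h^2 + 2h)`.
#' Dense layer: `(in + 1) * out`. Summed over both branches, both branch
#' dense layers, the head and the output unit.
#'
#' @param spec a [recurrent_spec()].
#' @return Integer parameter total.
#' @export
count_trainable_parameters <- function(spec) {
  h <- spec$rnn_units
  cellp <- function(d) switch(spec$cell,
                              lstm = 4 * (d + h + 1) * h,
                              gru = 3 * (d * h + h * h + 2 * h))
  dense <- function(i, o) (i + 1) * o
  merged <- 2 * spec$branch_dense + spec$static_dim
  widths <- c(merged, spec$head)
  headp <- sum(vapply(seq_along(spec$head),
                      function(i) dense(widths[i], widths[i + 1]), 0))
  as.integer(cellp(spec$bands_dim[2]) + cellp(spec$weather_dim[2]) +
               2 * dense(h, spec$branch_dense) + headp +
               dense(spec$head[length(spec$head)], 1))
}

# ---- parameter initialization ----------------------------------------------

glorot <- function(fan_in, fan_out, nr = fan_in, nc = fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_cell <- function(cell, d, h) {
  if (cell == "lstm") {
    b <- rep(0, 4 * h)
    b[(h + 1):(2 * h)] <- 1  # forget-gate bias
    list(W = glorot(d, 4 * h), U = glorot(h, 4 * h), b = b)
  } else {
    list(W = glorot(d, 3 * h), U = glorot(h, 3 * h),
         b_in = rep(0, 3 * h), b_rec = rep(0, 3 * h))
  }
}

init_params <- function(spec, y_mean = 0) {
  h <- spec$rnn_units
  hd <- spec$head
  merged <- 2 * spec$branch_dense + spec$static_dim
  widths <- c(merged, hd)
  params <- list(
    bands = init_cell(spec$cell, spec$bands_dim[2], h),
    weather = init_cell(spec$cell, spec$weather_dim[2], h),
    bdense = list(W = glorot(h, spec$branch_dense), b = rep(0, spec$branch_dense)),
    wdense = list(W = glorot(h, spec$branch_dense), b = rep(0, spec$branch_dense)),
    head = lapply(seq_along(hd), function(i)
      list(W = glorot(widths[i], widths[i + 1]), b = rep(0, widths[i + 1]))),
    out = list(W = glorot(hd[length(hd)], 1), b = y_mean)
  )
  params
}

sigmoid <- function(x) 1 / (1 + exp(-x))
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

addb <- function(M, b) sweep(M, 2, b, "+")

# ---- recurrent forward / backward ------------------------------------------

lstm_forward <- function(X, p, h) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- X[, t, , drop = FALSE]; dim(Xt) <- c(n, dim(X)[3])
    Z <- addb(Xt %*% p$W + H %*% p$U, p$b)
    i <- sigmoid(Z[, 1:h, drop = FALSE])
    f <- sigmoid(Z[, (h + 1):(2 * h), drop = FALSE])
    g <- tanh(Z[, (2 * h + 1):(3 * h), drop = FALSE])
    o <- sigmoid(Z[, (3 * h + 1):(4 * h), drop = FALSE])
    Cp <- C
    C <- f * Cp + i * g
    Hp <- H
    H <- o * tanh(C)
    cache[[t]] <- list(Xt = Xt, Hp = Hp, Cp = Cp, i = i, f = f, g = g, o = o,
                       C = C)
  }
  list(H = H, cache = cache)
}

lstm_backward <- function(dH, p, cache, h) {
  Tn <- length(cache)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dC <- dH * 0
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    tC <- tanh(cc$C)
    do <- dH * tC
    dC <- dC + dH * cc$o * (1 - tC^2)
    di <- dC * cc$g
    df <- dC * cc$Cp
    dg <- dC * cc$i
    dZ <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cc$Xt, dZ)
    dU <- dU + crossprod(cc$Hp, dZ)
    db <- db + colSums(dZ)
    dH <- dZ %*% t(p$U)
    dC <- dC * cc$f
  }
  list(W = dW, U = dU, b = db)
}

gru_forward <- function(X, p, h) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  H <- matrix(0, n, h)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    Xt <- X[, t, , drop = FALSE]; dim(Xt) <- c(n, dim(X)[3])
    Xm <- addb(Xt %*% p$W, p$b_in)
    Rm <- addb(H %*% p$U, p$b_rec)
    z <- sigmoid(Xm[, 1:h, drop = FALSE] + Rm[, 1:h, drop = FALSE])
    r <- sigmoid(Xm[, (h + 1):(2 * h), drop = FALSE] +
                   Rm[, (h + 1):(2 * h), drop = FALSE])
    rn <- Rm[, (2 * h + 1):(3 * h), drop = FALSE]
    nn <- tanh(Xm[, (2 * h + 1):(3 * h), drop = FALSE] + r * rn)
    Hp <- H
    H <- z * Hp + (1 - z) * nn
    cache[[t]] <- list(Xt = Xt, Hp = Hp, z = z, r = r, rn = rn, nn = nn)
  }
  list(H = H, cache = cache)
}

gru_backward <- function(dH, p, cache, h) {
  Tn <- length(cache)
  dW <- p$W * 0; dU <- p$U * 0
  db_in <- p$b_in * 0; db_rec <- p$b_rec * 0
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dz <- dH * (cc$Hp - cc$nn)
    dnn <- dH * (1 - cc$z)
    dHp <- dH * cc$z
    dnn_pre <- dnn * (1 - cc$nn^2)
    dr <- dnn_pre * cc$rn
    drn <- dnn_pre * cc$r
    dz_pre <- dz * cc$z * (1 - cc$z)
    dr_pre <- dr * cc$r * (1 - cc$r)
    dXm <- cbind(dz_pre, dr_pre, dnn_pre)
    dRm <- cbind(dz_pre, dr_pre, drn)
    dW <- dW + crossprod(cc$Xt, dXm)
    db_in <- db_in + colSums(dXm)
    dU <- dU + crossprod(cc$Hp, dRm)
    db_rec <- db_rec + colSums(dRm)
    dH <- dHp + dRm %*% t(p$U)
  }
  list(W = dW, U = dU, b_in = db_in, b_rec = db_rec)
}

# ---- full network forward / backward ---------------------------------------

net_forward <- function(inputs, params, spec, dropout_masks = NULL) {
  h <- spec$rnn_units
  fwd <- if (spec$cell == "lstm") lstm_forward else gru_forward
  br_b <- fwd(inputs$bands, params$bands, h)
  br_w <- fwd(inputs$weather, params$weather, h)
  hb_pre <- addb(br_b$H %*% params$bdense$W, params$bdense$b)
  hb <- pmax(hb_pre, 0)
  hw_pre <- addb(br_w$H %*% params$wdense$W, params$wdense$b)
  hw <- pmax(hw_pre, 0)
  merged <- cbind(hb, hw, inputs$static)
  acts <- list(); x <- merged
  for (i in seq_along(params$head)) {
    pre <- addb(x %*% params$head[[i]]$W, params$head[[i]]$b)
    a <- pmax(pre, 0)
    if (!is.null(dropout_masks)) a <- a * dropout_masks[[i]]
    acts[[i]] <- list(input = x, pre = pre, act = a)
    x <- a
  }
  u <- addb(x %*% params$out$W, params$out$b)
  yhat <- softplus(u)
  list(yhat = as.vector(yhat), u = u, acts = acts, merged = merged,
       hb_pre = hb_pre, hw_pre = hw_pre, br_b = br_b, br_w = br_w)
}

net_backward <- function(dy, fw, inputs, params, spec, dropout_masks = NULL) {
  h <- spec$rnn_units
  du <- dy * sigmoid(fw$u)
  g <- list()
  last <- fw$acts[[length(fw$acts)]]$act
  g$out <- list(W = crossprod(last, du), b = sum(du))
  dx <- du %*% t(params$out$W)
  g$head <- vector("list", length(params$head))
  for (i in rev(seq_along(params$head))) {
    a <- fw$acts[[i]]
    if (!is.null(dropout_masks)) dx <- dx * dropout_masks[[i]]
    dpre <- dx * (a$pre > 0)
    g$head[[i]] <- list(W = crossprod(a$input, dpre), b = colSums(dpre))
    dx <- dpre %*% t(params$head[[i]]$W)
  }
  nb <- spec$branch_dense
  dhb <- dx[, 1:nb, drop = FALSE]
  dhw <- dx[, (nb + 1):(2 * nb), drop = FALSE]
  dhb_pre <- dhb * (fw$hb_pre > 0)
  dhw_pre <- dhw * (fw$hw_pre > 0)
  g$bdense <- list(W = crossprod(fw$br_b$H, dhb_pre), b = colSums(dhb_pre))
  g$wdense <- list(W = crossprod(fw$br_w$H, dhw_pre), b = colSums(dhw_pre))
  dHb <- dhb_pre %*% t(params$bdense$W)
  dHw <- dhw_pre %*% t(params$wdense$W)
  bwd <- if (spec$cell == "lstm") lstm_backward else gru_backward
  g$bands <- bwd(dHb, params$bands, fw$br_b$cache, h)
  g$weather <- bwd(dHw, params$weather, fw$br_w$cache, h)
  g
}

# ---- flat parameter bookkeeping for Adam -----------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_params <- function(v, skeleton) stats::setNames(
  utils::relist(v, skeleton), names(skeleton))

adam_step <- function(theta, grad, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mhat <- state$m / (1 - b1^state$t)
  vhat <- state$v / (1 - b2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Training configuration for the recurrent downscaler
#'
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without improvement of the
#'   monitored validation quantity); `Inf` disables early stopping.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param monitor `"val_loss"` (MSE) or `"val_mae"`.
#' @param seed integer seed for weight init, shuffling and dropout.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return list of class `train_config`.
#' @export
train_config <- function(max_epochs = 500, patience = 25, batch_size = 32,
                         lr = 1e-3, monitor = c("val_loss", "val_mae"),
                         seed = 42L, verbose = 0) {
  monitor <- match.arg(monitor)
  stopifnot(patience >= 1, max_epochs >= 1, is.infinite(patience) ||
              patience < max_epochs)
  structure(list(max_epochs = max_epochs, patience = patience,
                 batch_size = batch_size, lr = lr, monitor = monitor,
                 seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

standardize_branch <- function(arr, st) {
  d <- dim(arr)
  flat <- matrix(arr, d[1], d[2] * d[3])
  flat <- sweep(sweep(flat, 2, st$mu), 2, st$sd, "/")
  array(flat, d)
}

standardize_inputs <- function(inputs, stats) {
  list(bands = standardize_branch(inputs$bands, stats$bands),
       weather = standardize_branch(inputs$weather, stats$weather),
       static = sweep(sweep(inputs$static, 2, stats$static$mu), 2,
                      stats$static$sd, "/"))
}

#' Train the two-branch recurrent downscaler
#'
#' Minibatch Adam on the mean-squared-error loss with mean-absolute-error
#' monitoring, early stopping on the validation monitor with best-weight
#' restoration. Inputs are standardized per time-feature column with training
#' statistics that are stored on the model. Fully deterministic under
#' `config$seed`.
#'
#' @param spec a [recurrent_spec()].
#' @param train list `(bands, weather, static)` arrays plus `y` — as produced
#'   by [branch_arrays()].
#' @param val validation set in the same layout (disjoint from `train`).
#' @param config a [train_config()].
#' @return Object of class `recurrent_model`: parameters, spec, input
#'   statistics and per-epoch `history`.
#' @export
train_recurrent <- function(spec, train, val, config = train_config()) {
  set.seed(config$seed)
  n <- length(train$y)
  stats <- list(bands = standardize_fit(matrix(train$bands, nrow = n)),
                weather = standardize_fit(matrix(train$weather, nrow = n)),
                static = standardize_fit(train$static))
  tr <- standardize_inputs(train, stats)
  vl <- standardize_inputs(val, stats)
  params <- init_params(spec, y_mean = mean(train$y))
  skel <- params
  theta <- flatten_params(params)
  adam <- list(t = 0, m = theta * 0, v = theta * 0)
  best <- list(metric = Inf, theta = theta, epoch = 0)
  hist <- data.frame()
  n_head <- length(spec$head)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (bi in batches) {
      binp <- list(bands = tr$bands[bi, , , drop = FALSE],
                   weather = tr$weather[bi, , , drop = FALSE],
                   static = tr$static[bi, , drop = FALSE])
      masks <- NULL
      if (spec$dropout > 0)
        masks <- lapply(seq_len(n_head), function(i)
          matrix(stats::rbinom(length(bi) * spec$head[i], 1,
                               1 - spec$dropout) / (1 - spec$dropout),
                 length(bi), spec$head[i]))
      fw <- net_forward(binp, params, spec, masks)
      err <- fw$yhat - train$y[bi]
      if (any(!is.finite(err)))
        stop("NaN/Inf loss at epoch ", epoch,
             "; try a lower learning rate or check input scaling")
      dy <- matrix(2 * err / length(bi), ncol = 1)
      g <- net_backward(dy, fw, binp, params, spec, masks)
      g <- g[names(params)]  # gradient flattening must mirror parameter order
      upd <- adam_step(theta, flatten_params(g), adam, lr = config$lr)
      theta <- upd$theta
      adam <- upd$state
      params <- relist_params(theta, skel)
    }
    fw_tr <- net_forward(tr, params, spec)
    fw_vl <- net_forward(vl, params, spec)
    row <- data.frame(epoch = epoch,
                      loss = mean((fw_tr$yhat - train$y)^2),
                      mae = mean(abs(fw_tr$yhat - train$y)),
                      val_loss = mean((fw_vl$yhat - val$y)^2),
                      val_mae = mean(abs(fw_vl$yhat - val$y)))
    hist <- rbind(hist, row)
    metric <- row[[config$monitor]]
    if (metric < best$metric - 1e-12) {
      best <- list(metric = metric, theta = theta, epoch = epoch)
    } else if (is.finite(config$patience) &&
               epoch - best$epoch >= config$patience) {
      break
    }
    if (config$verbose > 0 && epoch %% config$verbose == 0)
      cat(sprintf("epoch %d: loss %.4f val_loss %.4f val_mae %.4f\n",
                  epoch, row$loss, row$val_loss, row$val_mae))
  }
  params <- relist_params(best$theta, skel)
  structure(list(params = params, spec = spec, stats = stats,
                 history = hist, best_epoch = best$epoch,
                 monitor = config$monitor, config = config),
            class = "recurrent_model")
}

#' Predict with a trained recurrent model
#'
#' @param model a `recurrent_model`.
#' @param inputs list `(bands, weather, static)` in the training layout.
#' @return Numeric vector of non-negative yield predictions.
#' @export
predict_recurrent <- function(model, inputs) {
  if (!identical(dim(inputs$bands)[-1],
                 c(model$spec$bands_dim[1], model$spec$bands_dim[2])) ||
      ncol(inputs$static) != model$spec$static_dim)
    stop("input layout does not match the trained specification")
  std <- standardize_inputs(inputs, model$stats)
  net_forward(std, model$params, model$spec)$yhat
}
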