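test_that("closed-form parameter counts match the architecture", {
  expect_identical(count_trainable_parameters(recurrent_spec("lstm")), 25889L)
  expect_identical(count_trainable_parameters(recurrent_spec("gru")), 23553L)
  # minimal LSTM cell: d = 1, h = 1 -> 4 * (1 + 1 + 1) * 1 = 12 for the cell
  tiny <- recurrent_spec("lstm", bands_dim = c(2, 1), weather_dim = c(2, 1),
                         rnn_units = 1, branch_dense = 1, head = 1)
  # 2 cells (12 each) + 2 branch dense (2 each) + head (3+1)*1 + out (1+1)*1
  expect_identical(count_trainable_parameters(tiny), 12L + 12L + 4L + 4L + 2L)
  # count equals the number of weights actually allocated
  for (cell in c("lstm", "gru")) {
    spec <- recurrent_spec(cell)
    set.seed(1)
    p <- yieldkrige:::init_params(spec)
    expect_identical(length(yieldkrige:::flatten_params(p)),
                     count_trainable_parameters(spec))
  }
})

test_that("forward pass merges branches to width 33 and stays non-negative", {
  spec <- recurrent_spec("gru")
  set.seed(2)
  p <- yieldkrige:::init_params(spec)
  n <- 64
  inputs <- list(bands = array(rnorm(n * 3 * 7, sd = 10), c(n, 3, 7)),
                 weather = array(rnorm(n * 5 * 6, sd = 10), c(n, 5, 6)),
                 static = matrix(rnorm(n, sd = 10), n, 1))
  fw <- yieldkrige:::net_forward(inputs, p, spec)
  expect_identical(ncol(fw$merged), 16L + 16L + 1L)
  expect_true(all(fw$yhat >= 0))
  # extreme random probes cannot break the Softplus floor
  for (i in 1:20) {
    xin <- list(bands = array(rnorm(3 * 7, sd = 1e3), c(1, 3, 7)),
                weather = array(rnorm(5 * 6, sd = 1e3), c(1, 5, 6)),
                static = matrix(rnorm(1, sd = 1e3), 1, 1))
    expect_gte(yieldkrige:::net_forward(xin, p, spec)$yhat, 0)
  }
  # zeroed network emits Softplus(0) = log 2
  pz <- utils::relist(yieldkrige:::flatten_params(p) * 0, p)
  expect_equal(yieldkrige:::net_forward(inputs, pz, spec)$yhat,
               rep(log(2), n))
})

test_that("analytic gradients agree with finite differences", {
  for (cell in c("lstm", "gru")) {
    spec <- recurrent_spec(cell, bands_dim = c(3, 2), weather_dim = c(2, 2),
                           static_dim = 1, rnn_units = 3, branch_dense = 2,
                           head = c(4, 3), dropout = 0)
    set.seed(7)
    params <- yieldkrige:::init_params(spec, y_mean = 0.5)
    n <- 4
    inputs <- list(bands = array(rnorm(n * 3 * 2), c(n, 3, 2)),
                   weather = array(rnorm(n * 2 * 2), c(n, 2, 2)),
                   static = matrix(rnorm(n), n, 1))
    y <- rnorm(n)
    theta <- yieldkrige:::flatten_params(params)
    loss <- function(th) {
      fw <- yieldkrige:::net_forward(inputs, utils::relist(th, params), spec)
      mean((fw$yhat - y)^2)
    }
    fw <- yieldkrige:::net_forward(inputs, params, spec)
    g <- yieldkrige:::net_backward(matrix(2 * (fw$yhat - y) / n, ncol = 1),
                                  fw, inputs, params, spec)
    ga <- yieldkrige:::flatten_params(g[names(params)])
    eps <- 1e-6
    gn <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (loss(tp) - loss(tm)) / (2 * eps)
    }, 0)
    expect_lt(max(abs(ga - gn)), 1e-7)
  }
})

test_that("a noiseless fixture is memorized and training is deterministic", {
  set.seed(5)
  n <- 20
  tr <- list(bands = array(rnorm(n * 3 * 7), c(n, 3, 7)),
             weather = array(rnorm(n * 5 * 6), c(n, 5, 6)),
             static = matrix(1, n, 1))
  tr$y <- 45 + 3 * tr$bands[, 2, 4] - 2 * tr$weather[, 3, 1]
  spec <- recurrent_spec("gru", dropout = 0)
  cfg <- train_config(max_epochs = 500, patience = Inf, lr = 5e-3, seed = 1)
  m <- train_recurrent(spec, tr, tr, cfg)
  expect_lt(min(m$history$loss), 1e-2)
  m2 <- train_recurrent(spec, tr, tr, cfg)
  expect_identical(m$history$val_mae, m2$history$val_mae)
})

test_that("early stopping halts within patience of the best epoch", {
  set.seed(6)
  n <- 24
  mk <- function(n) list(bands = array(rnorm(n * 3 * 7), c(n, 3, 7)),
                         weather = array(rnorm(n * 5 * 6), c(n, 5, 6)),
                         static = matrix(1, n, 1))
  tr <- mk(n); tr$y <- rnorm(n, 40, 3)      # pure noise: little to learn
  vl <- mk(12); vl$y <- rnorm(12, 40, 3)
  cfg <- train_config(max_epochs = 400, patience = 10, seed = 2)
  m <- train_recurrent(recurrent_spec("gru"), tr, vl, cfg)
  ran <- nrow(m$history)
  expect_lte(ran - m$best_epoch, 10)
  expect_lt(ran, 400)
  # best weights restored: reported best epoch has the minimum monitor value
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss))
})

test_that("pixel prediction respects the mask and aggregation round-trips", {
  sc <- tiny_scene()
  feats <- extract_features(sc$stack, sc$zones, sc$mask,
                            sc$villages$village_id)
  smp <- assemble_samples(sc$villages, feats, "band-weather", seed = 4)
  m <- fit_yield_model(smp, "gru",
                       config = train_config(max_epochs = 30, patience = 10,
                                             seed = 3))
  surf <- predict_pixel_yield(m, sc$stack, sc$mask)
  expect_true(all(is.na(surf[sc$mask == 0])))
  expect_true(all(surf[sc$mask > 0] >= 0))
  # village mean of pixel predictions equals the admin aggregation output
  agg <- aggregate_to_admin(surf, sc$zones, sc$mask, sc$villages$village_id)
  k <- 7
  sel <- sc$zones == k & sc$mask > 0
  expect_equal(agg$mean[k], mean(surf[sel]))
  # constant feature vector across pixels -> constant surface
  stk2 <- sc$stack
  for (j in seq_len(dim(stk2$values)[3]))
    stk2$values[, , j] <- stk2$values[5, 5, j]
  surf2 <- predict_pixel_yield(m, stk2, sc$mask)
  expect_lt(diff(range(surf2[sc$mask > 0])), 1e-10)
  # aggregation is linear in the surface
  agg2 <- aggregate_to_admin(2 * surf, sc$zones, sc$mask,
                             sc$villages$village_id)
  expect_equal(agg2$mean, 2 * agg$mean)
})
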