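# beta = (X'X + lambda I)^-1 X'y on centred, z-scored features; the intercept
# is the training mean and carries no penalty
ridge_solve <- function(Xs, y, lambda) {
  p <- ncol(Xs)
  beta <- solve(crossprod(Xs) + diag(lambda, p), crossprod(Xs, y - mean(y)))
  list(beta = as.vector(beta), intercept = mean(y), lambda = lambda)
}

ridge_cv_lambda <- function(Xs, y, grid = 10^seq(-3, 3, length.out = 25),
                            nfolds = 10, seed = 42L) {
  set.seed(seed)
  n <- length(y)
  fold <- sample(rep_len(seq_len(nfolds), n))
  err <- sapply(grid, function(l) {
    se <- 0
    for (k in seq_len(nfolds)) {
      hold <- fold == k
      f <- ridge_solve(Xs[!hold, , drop = FALSE], y[!hold], l)
      se <- se + sum((y[hold] - f$intercept -
                        Xs[hold, , drop = FALSE] %*% f$beta)^2)
    }
    se
  })
  grid[which.min(err)]
}

#' Fit a village-level yield model
#'
#' One fitting front-end for every downscaling model family: ordinary least
#' squares (`"linear"`), L2/L1-regularized regression (`"ridge"`, `"lasso"`,
#' fitted on z-scored features), bagged trees (`"rf"`), two gradient-boosted
#' tree configurations (`"gb"`: depth-3 trees with full subsampling in the
#' classical boosting style; `"xgb"`: regularized boosting defaults), and the
#' two-branch recurrent downscalers (`"lstm"`, `"gru"`). Tree ensembles use
#' 100 trees, learning rate 0.1 where applicable and seed 42; recurrent
#' models follow [train_config()] (Adam/MSE, batch 32, early-stopping
#' patience 25, at most 500 epochs).
#'
#' Models are trained on the `train` rows of `samples`; the `val` rows drive
#' early stopping for the recurrent family and are otherwise held out.
#'
#' @param samples a `village_samples` object from [assemble_samples()].
#' @param method model family, see above.
#' @param lambda regularization strength for ridge/lasso (default via
#'   internal 10-fold CV on the training split, seeded).
#' @param config a [train_config()] for the recurrent family.
#' @param spec optional [recurrent_spec()] override; defaults to the branch
#'   dimensions found in `samples` with `static_dim` equal to the assembled
#'   static block (crop indicator plus any soil features).
#' @param seed seed for tree ensembles and regularization CV.
#' @param ... unused.
#' @return Object of class `yield_model`.
#' @export
fit_yield_model <- function(samples, method = c("linear", "ridge", "lasso",
                                                "rf", "gb", "xgb", "lstm",
                                                "gru"),
                            lambda = NULL, config = train_config(),
                            spec = NULL, seed = 42L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(samples, "village_samples"))
  tr <- sample_split(samples, "train")
  vl <- sample_split(samples, "val")
  fit <- NULL; scaler <- NULL
  if (method %in% c("lstm", "gru")) {
    if (!length(samples$groups$bands) || !length(samples$groups$weather))
      stop("recurrent models need both band and weather features; ",
           "combination '", samples$combination, "' lacks one")
    atr <- branch_arrays(tr$X, tr$layers, tr$groups); atr$y <- tr$y
    avl <- branch_arrays(vl$X, vl$layers, vl$groups); avl$y <- vl$y
    if (is.null(spec))
      spec <- recurrent_spec(cell = method,
                             bands_dim = dim(atr$bands)[2:3],
                             weather_dim = dim(atr$weather)[2:3],
                             static_dim = ncol(atr$static))
    fit <- train_recurrent(spec, atr, avl, config)
  } else if (method == "linear") {
    df <- data.frame(y = tr$y, tr$X, check.names = TRUE)
    fit <- stats::lm(y ~ ., data = df)
    if (anyNA(stats::coef(fit)))
      warning("singular design: ", sum(is.na(stats::coef(fit))),
              " coefficients not estimable (dropped)")
  } else if (method == "ridge") {
    # exact normal-equations minimizer of the L2-penalized least squares
    # objective (penalty excludes the intercept; features z-scored)
    scaler <- standardize_fit(tr$X)
    Xs <- scale(tr$X, scaler$mu, scaler$sd)
    if (is.null(lambda)) lambda <- ridge_cv_lambda(Xs, tr$y, seed = seed)
    fit <- ridge_solve(Xs, tr$y, lambda)
  } else if (method == "lasso") {
    scaler <- standardize_fit(tr$X)
    Xs <- scale(tr$X, scaler$mu, scaler$sd)
    set.seed(seed)
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(Xs, tr$y, alpha = 1, standardize = FALSE)
      lambda <- cv$lambda.min
    }
    fit <- glmnet::glmnet(Xs, tr$y, alpha = 1, lambda = lambda,
                          standardize = FALSE, thresh = 1e-12)
  } else if (method == "rf") {
    set.seed(seed)
    fit <- randomForest::randomForest(tr$X, tr$y, ntree = 100)
  } else {
    prm <- if (method == "gb") {
      list(eta = 0.1, max_depth = 3, subsample = 1, colsample_bytree = 1,
           lambda = 0, objective = "reg:squarederror", nthread = 1)
    } else {
      list(eta = 0.1, objective = "reg:squarederror", nthread = 1)
    }
    set.seed(seed)
    fit <- xgboost::xgb.train(params = prm,
                              data = xgboost::xgb.DMatrix(tr$X, label = tr$y),
                              nrounds = 100)
  }
  structure(list(method = method, fit = fit, scaler = scaler,
                 layers = samples$layers, groups = samples$groups,
                 combination = samples$combination,
                 n_train = length(tr$y), n_features = ncol(samples$X),
                 seed = seed,
                 call = match.call()),
            class = "yield_model")
}

#' @export
#' @method print yield_model
print.yield_model <- function(x, ...) {
  cat(sprintf("yield_model: %s on combination '%s' (%d features, %d training villages)\n",
              x$method, x$combination, x$n_features, x$n_train))
  if (inherits(x$fit, "recurrent_model"))
    cat(sprintf("  %s, %d trainable parameters, best epoch %d (%s)\n",
                toupper(x$fit$spec$cell),
                count_trainable_parameters(x$fit$spec),
                x$fit$best_epoch, x$fit$monitor))
  invisible(x)
}

#' @export
#' @method summary yield_model
summary.yield_model <- function(object, samples = NULL, ...) {
  cat(sprintf("Yield downscaling model (%s)\n", object$method))
  print(object)
  if (!is.null(samples)) {
    for (sp in c("train", "val")) {
      ss <- sample_split(samples, sp)
      m <- regression_metrics(ss$y, predict(object, ss),
                              p = object$n_features)
      cat(sprintf("  %s: R2 %.4f  RMSE %.3f  MAE %.3f  MAPE %.2f%%\n",
                  sp, m$r2, m$rmse, m$mae, m$mape))
    }
  }
  invisible(object)
}

#' Predict village or pixel yields from a fitted model
#'
#' @param object a `yield_model`.
#' @param newdata a `village_samples` object or a feature matrix whose
#'   columns match the training layer layout.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.yield_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "village_samples")) newdata$X else as.matrix(newdata)
  if (ncol(X) != nrow(object$layers))
    stop("feature layout mismatch: expected ", nrow(object$layers),
         " columns, got ", ncol(X))
  if (nrow(X) == 0) return(numeric(0))
  if (object$method %in% c("lstm", "gru")) {
    inp <- branch_arrays(X, object$layers, object$groups)
    predict_recurrent(object$fit, inp)
  } else if (object$method == "linear") {
    df <- as.data.frame(X)
    names(df) <- make.names(colnames(X))
    unname(stats::predict(object$fit, df))
  } else if (object$method == "ridge") {
    Xs <- scale(X, object$scaler$mu, object$scaler$sd)
    as.vector(object$fit$intercept + Xs %*% object$fit$beta)
  } else if (object$method == "lasso") {
    Xs <- scale(X, object$scaler$mu, object$scaler$sd)
    as.vector(stats::predict(object$fit, Xs))
  } else if (object$method == "rf") {
    unname(stats::predict(object$fit, X))
  } else {
    stats::predict(object$fit, xgboost::xgb.DMatrix(X))
  }
}

#' @export
residuals.yield_model <- function(object, samples, which = "val", ...) {
  ss <- sample_split(samples, which)
  ss$y - predict(object, ss)
}

#' Pixel-level yield prediction over a raster stack
#'
#' Builds the per-pixel feature matrix in the training layout from the
#' covariate stack, predicts masked pixels in chunks and returns a yield
#' raster (`NA` outside the mask). Recurrent models apply Softplus, so the
#' surface is non-negative.
#'
#' @param model a `yield_model`.
#' @param stack a [raster_stack()] containing every training layer.
#' @param mask crop mask matrix (pixels with mask > 0 are predicted).
#' @param chunk pixels per prediction chunk.
#' @return Yield matrix aligned to the stack grid.
#' @export
predict_pixel_yield <- function(model, stack, mask = NULL, chunk = 20000L) {
  nms <- layer_names(model$layers)
  have <- layer_names(stack$layers)
  idx <- match(nms, have)
  if (anyNA(idx)) stop("stack lacks training layers: ",
                       paste(nms[is.na(idx)], collapse = ", "))
  nr <- stack$geom$nrow; nc <- stack$geom$ncol
  keep <- if (is.null(mask)) rep(TRUE, nr * nc) else as.vector(!is.na(mask) & mask > 0)
  X <- matrix(stack$values[, , idx], nr * nc, length(idx))
  colnames(X) <- nms
  valid <- keep & rowSums(is.na(X)) == 0
  out <- rep(NA_real_, nr * nc)
  vi <- which(valid)
  for (s in seq(1, length(vi), by = chunk)) {
    ii <- vi[s:min(s + chunk - 1L, length(vi))]
    out[ii] <- predict(model, X[ii, , drop = FALSE])
  }
  matrix(out, nr, nc)
}

#' Aggregate a predicted yield raster to administrative units
#'
#' Masked zonal means per village (or block) — the aggregation that produces
#' the predicted means entering the residual computation.
#'
#' @param values predicted yield matrix.
#' @param zones integer zone matrix.
#' @param mask optional crop mask.
#' @param unit_id zone labels.
#' @return data.frame `(village_id, mean, pixel_count)`.
#' @export
aggregate_to_admin <- function(values, zones, mask = NULL, unit_id = NULL) {
  zonal_aggregate(values, zones, mask, village_id = unit_id)
}
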