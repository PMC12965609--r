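#' Semivariogram model functions
#'
#' Closed-form semivariance `gamma(h)` for the four supported models. By
#' definition `gamma(0) = 0`; the nugget is the limit from the right, so
#' `variogram_gamma()` returns `nugget + structure(h)` for `h >= 0` (value
#' `nugget` at `h = 0`), and the kriging solver zeroes the matrix diagonal
#' itself. Range conventions: `spherical` reaches its sill exactly at
#' `range`; `exponential` and `gaussian` use the correlation-length
#' parameterization `1 - exp(-h/range)` and `1 - exp(-(h/range)^2)`
#' (practical ranges about `3*range` and `sqrt(3)*range`). The `linear` model
#' is `nugget + slope * h` (no sill; pass the slope via `psill`).
#'
#' @param h distances (any numeric shape).
#' @param type `"linear"`, `"spherical"`, `"gaussian"` or `"exponential"`.
#' @param nugget non-negative nugget.
#' @param psill partial sill (slope for `"linear"`).
#' @param range range parameter (> 0); unused for `"linear"`.
#' @return Semivariances, same shape as `h`.
#' @export
variogram_gamma <- function(h, type, nugget, psill, range = NULL) {
  s <- switch(type,
    linear = psill * h,
    spherical = ifelse(h < range,
                       psill * (1.5 * h / range - 0.5 * (h / range)^3),
                       psill),
    gaussian = psill * (1 - exp(-(h / range)^2)),
    exponential = psill * (1 - exp(-h / range)),
    stop("unknown variogram type: ", type))
  nugget + s
}

#' Fitted semivariogram model
#'
#' @param type model type (see [variogram_gamma()]).
#' @param nugget non-negative nugget.
#' @param psill partial sill (slope for linear).
#' @param range range parameter; `NA` for linear.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(type, nugget, psill, range = NA_real_) {
  type <- match.arg(type, c("linear", "spherical", "gaussian", "exponential"))
  stopifnot(nugget >= 0, psill >= 0, type == "linear" || range > 0)
  structure(list(type = type, nugget = nugget, psill = psill, range = range),
            class = "variogram_model")
}

#' @export
#' @method print variogram_model
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s (nugget %.4g, %s %.4g%s)\n", x$type,
              x$nugget, if (x$type == "linear") "slope" else "partial sill",
              x$psill,
              if (x$type == "linear") "" else sprintf(", range %.4g", x$range)))
  invisible(x)
}

#' Village residuals at centroids
#'
#' `e_i = y_i - yhat_i` matched by village id, located at the village
#' centroid; the input to semivariogram estimation and residual kriging.
#'
#' @param observed data.frame `(village_id, yield)` or a [village_map()].
#' @param predicted data.frame `(village_id, mean)` of aggregated predictions.
#' @param coords two-column centroid matrix aligned with `observed`; taken
#'   from the village map when omitted.
#' @return Object of class `residual_field`: `coords`, `residual`, `village_id`.
#' @export
compute_residuals <- function(observed, predicted, coords = NULL) {
  if (inherits(observed, "village_map")) {
    if (is.null(coords)) coords <- cbind(observed$cx, observed$cy)
    observed <- data.frame(village_id = observed$village_id,
                           yield = observed$yield)
  }
  idx <- match(observed$village_id, predicted$village_id)
  if (anyNA(idx)) stop("unmatched village ids: ",
                       paste(observed$village_id[is.na(idx)], collapse = ", "))
  pcol <- intersect(c("mean", "yield", "predicted"), names(predicted))[1]
  e <- observed$yield - predicted[[pcol]][idx]
  if (any(!is.finite(e))) stop("non-finite residuals")
  structure(list(coords = coords, residual = e,
                 village_id = observed$village_id),
            class = "residual_field")
}

#' Empirical semivariogram
#'
#' Method-of-moments estimator: half the mean squared difference of the field
#' over point pairs binned by separation distance.
#'
#' @param field a `residual_field` (or list with `coords` and `residual`).
#' @param n_lags number of equal-width distance bins.
#' @param max_dist largest pair distance considered; default half the maximum
#'   pairwise distance.
#' @return data.frame `(lag, gamma, n_pairs)` of non-empty bins, with
#'   `max_dist` attached as an attribute.
#' @export
empirical_semivariogram <- function(field, n_lags = 15, max_dist = NULL) {
  d <- as.vector(stats::dist(field$coords))
  if (all(d == 0)) stop("all points coincident")
  sq <- 0.5 * as.vector(stats::dist(field$residual))^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  keep <- d <= max_dist & d > 0
  bins <- cut(d[keep], breaks = seq(0, max_dist, length.out = n_lags + 1),
              include.lowest = TRUE)
  gamma <- tapply(sq[keep], bins, mean)
  cnt <- tapply(rep(1, sum(keep)), bins, sum)
  centre <- (seq_len(n_lags) - 0.5) * max_dist / n_lags
  ok <- !is.na(gamma)
  out <- data.frame(lag = centre[ok], gamma = as.numeric(gamma[ok]),
                    n_pairs = as.numeric(cnt[ok]))
  attr(out, "max_dist") <- max_dist
  out
}

#' Fit a semivariogram model to an empirical semivariogram
#'
#' Weighted least squares with pair counts as weights. Nonlinear models are
#' fitted by bounded quasi-Newton from several deterministic starts
#' (sill initialized at the empirical plateau, range at 1/3 of the maximum
#' lag); the linear model is a weighted regression with the nugget floored at
#' zero. Non-convergence falls back to the linear model with a warning.
#'
#' @param emp output of [empirical_semivariogram()].
#' @param type model type.
#' @return A [variogram_model()]; attribute `wss` holds the weighted residual
#'   sum of squares of the fit.
#' @export
fit_variogram <- function(emp, type = c("exponential", "spherical",
                                        "gaussian", "linear")) {
  type <- match.arg(type)
  if (nrow(emp) < 3) stop("need at least 3 non-empty lag bins")
  w <- emp$n_pairs
  if (type == "linear") {
    fit <- stats::lm(gamma ~ lag, data = emp, weights = w)
    nug <- max(stats::coef(fit)[1], 0)
    slope <- max(stats::coef(fit)[2], 0)
    vm <- variogram_model("linear", nug, slope)
    attr(vm, "wss") <- sum(w * (variogram_gamma(emp$lag, "linear", nug, slope) -
                                  emp$gamma)^2)
    return(vm)
  }
  obj <- function(p) {
    g <- variogram_gamma(emp$lag, type, p[1], p[2], p[3])
    sum(w * (g - emp$gamma)^2)
  }
  s0 <- max(mean(emp$gamma[emp$lag > stats::median(emp$lag)]), 1e-10)
  maxlag <- max(emp$lag)
  starts <- list(c(0, s0, maxlag / 3), c(s0 / 2, s0 / 2, maxlag / 3),
                 c(0, s0, maxlag), c(0, s0, maxlag / 10))
  best <- NULL
  for (p0 in starts) {
    res <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                            lower = c(0, 1e-12, maxlag * 1e-3),
                            upper = c(Inf, Inf, maxlag * 10)), silent = TRUE)
    if (!inherits(res, "try-error") &&
        (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    warning("variogram fit failed to converge; falling back to linear")
    return(fit_variogram(emp, "linear"))
  }
  vm <- variogram_model(type, best$par[1], best$par[2], best$par[3])
  attr(vm, "wss") <- best$value
  vm
}

# Ordinary kriging system: augmented matrix [[Gamma, 1], [1', 0]] with a
# zero diagonal (gamma(0) = 0 by definition) so predictions are exact at data
# points iff the nugget is zero; the RHS uses gamma(h) = nugget + structure(h),
# which at a data point equals the nugget and produces the usual smoothing.
ok_matrix <- function(coords, vm) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  G <- variogram_gamma(D, vm$type, vm$nugget, vm$psill, vm$range)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

ok_solve <- function(A, values, rhs) {
  sol <- try(solve(A, rhs), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular kriging system (duplicate or degenerate point configuration)")
  lambda <- sol[seq_along(values), , drop = FALSE]
  list(pred = as.vector(crossprod(lambda, values)),
       lambda_sum = colSums(lambda),
       mu = sol[length(values) + 1, ])
}

#' Ordinary kriging prediction at arbitrary points
#'
#' Solves the ordinary-kriging system (weights constrained to sum to one via
#' a Lagrange multiplier) under a fitted semivariogram model, for every
#' target location at once.
#'
#' @param coords observation coordinates (two-column matrix).
#' @param values observed values.
#' @param targets prediction coordinates (two-column matrix).
#' @param vm a [variogram_model()].
#' @return list: `pred` (predictions), `lambda_sum` (per-target weight sums,
#'   an unbiasedness audit), `mu` (Lagrange multipliers).
#' @export
krige_points <- function(coords, values, targets, vm) {
  if (nrow(coords) < 2) stop("need at least 2 observations")
  if (anyDuplicated(coords)) stop("duplicate observation locations")
  A <- ok_matrix(coords, vm)
  n <- nrow(coords)
  m <- nrow(targets)
  out_pred <- numeric(m); out_lsum <- numeric(m); out_mu <- numeric(m)
  chunk <- 4000L
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(s + chunk - 1L, m)
    dx <- outer(coords[, 1], targets[idx, 1], "-")
    dy <- outer(coords[, 2], targets[idx, 2], "-")
    g0 <- variogram_gamma(sqrt(dx^2 + dy^2), vm$type, vm$nugget, vm$psill,
                          vm$range)
    rhs <- rbind(g0, 1)
    sol <- ok_solve(A, values, rhs)
    out_pred[idx] <- sol$pred
    out_lsum[idx] <- sol$lambda_sum
    out_mu[idx] <- sol$mu
  }
  list(pred = out_pred, lambda_sum = out_lsum, mu = out_mu)
}

#' Leave-one-out cross-validated variogram selection
#'
#' For each candidate type, fits the model to the empirical semivariogram and
#' predicts every point by ordinary kriging from all remaining points; the
#' type with the lowest LOO-CV RMSE wins, ties broken in the order linear <
#' spherical < gaussian < exponential. Candidates whose kriging system is
#' singular are disqualified.
#'
#' @param field a `residual_field`.
#' @param types candidate variogram types.
#' @param n_lags,max_dist passed to [empirical_semivariogram()].
#' @return list: `selected` type, `cv_rmse` (named vector), `models`
#'   (fitted [variogram_model()]s).
#' @export
select_variogram_cv <- function(field,
                                types = c("linear", "spherical", "gaussian",
                                          "exponential"),
                                n_lags = 15, max_dist = NULL) {
  n <- length(field$residual)
  if (n < 10) stop("need at least 10 points for cross-validated selection")
  emp <- empirical_semivariogram(field, n_lags, max_dist)
  order_pref <- c("linear", "spherical", "gaussian", "exponential")
  types <- order_pref[order_pref %in% types]
  rmse <- stats::setNames(rep(NA_real_, length(types)), types)
  models <- stats::setNames(vector("list", length(types)), types)
  for (ty in types) {
    vm <- try(fit_variogram(emp, ty), silent = TRUE)
    if (inherits(vm, "try-error")) next
    models[[ty]] <- vm
    pred <- rep(NA_real_, n)
    ok <- TRUE
    for (i in seq_len(n)) {
      kr <- try(krige_points(field$coords[-i, , drop = FALSE],
                             field$residual[-i],
                             field$coords[i, , drop = FALSE], vm),
                silent = TRUE)
      if (inherits(kr, "try-error")) { ok <- FALSE; break }
      pred[i] <- kr$pred
    }
    if (ok) rmse[ty] <- sqrt(mean((pred - field$residual)^2))
  }
  if (all(is.na(rmse))) stop("no candidate variogram produced a solvable system")
  selected <- types[which.min(rmse)]  # which.min takes the first minimum: tie order
  list(selected = selected, cv_rmse = rmse, models = models)
}

#' Krige a residual surface onto a grid
#'
#' Ordinary kriging of the residual field to every (optionally masked) pixel
#' centre of the target grid.
#'
#' @param field a `residual_field`.
#' @param vm a [variogram_model()].
#' @param geom target [grid_geom()].
#' @param mask optional crop mask; unmasked pixels become `NA`.
#' @return Matrix of kriged residuals; attribute `max_lambda_dev` records the
#'   worst absolute deviation of the weight sums from one.
#' @export
krige_residual_surface <- function(field, vm, geom, mask = NULL) {
  xy <- pixel_coords(geom)
  keep <- rep(TRUE, nrow(xy))
  if (!is.null(mask)) keep <- as.vector(!is.na(mask) & mask > 0)
  kr <- krige_points(field$coords, field$residual, xy[keep, , drop = FALSE], vm)
  out <- rep(NA_real_, nrow(xy))
  out[keep] <- kr$pred
  m <- matrix(out, geom$nrow, geom$ncol)
  attr(m, "max_lambda_dev") <- max(abs(kr$lambda_sum - 1))
  m
}

#' Add a kriged residual surface back to a predicted yield surface
#'
#' `y*(s) = yhat(s) + e_krig(s)`, with nodata propagated. Negative corrected
#' values are kept by default (`floor_zero = TRUE` clips them).
#'
#' @param predicted predicted yield raster (matrix).
#' @param residual kriged residual raster (matrix).
#' @param floor_zero clip negative corrected yields to zero.
#' @return Corrected yield matrix.
#' @export
correct_yield_surface <- function(predicted, residual, floor_zero = FALSE) {
  if (!identical(dim(predicted), dim(residual))) stop("misaligned grids")
  out <- predicted + residual
  if (floor_zero) out[out < 0] <- 0
  out
}
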