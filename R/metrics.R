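#' Regression evaluation metrics
#'
#' R-squared, adjusted R-squared, RMSE, MAE and MAPE (in percent). MAPE
#' excludes zero-valued observations rather than failing; the number excluded
#' is reported. A per-unit difference table is attached for auditing.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param p number of predictors entering the adjusted R-squared penalty.
#' @return list of class `metric_report`: `r2`, `adj_r2`, `rmse`, `mae`,
#'   `mape`, `n`, `p`, `mape_excluded`, `diffs`.
#' @export
regression_metrics <- function(observed, predicted, p = 1) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ok <- is.finite(observed) & is.finite(predicted)
  y <- observed[ok]; yh <- predicted[ok]
  n <- length(y)
  ss_res <- sum((y - yh)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (n - 1) / (n - p - 1) * (1 - r2)
  nz <- y != 0
  mape <- 100 * mean(abs((y[nz] - yh[nz]) / y[nz]))
  if (any(!nz)) warning(sum(!nz), " zero observations excluded from MAPE")
  structure(list(r2 = r2, adj_r2 = adj, rmse = sqrt(ss_res / n),
                 mae = mean(abs(y - yh)), mape = mape, n = n, p = p,
                 mape_excluded = sum(!nz),
                 diffs = data.frame(observed = y, predicted = yh,
                                    diff = y - yh)),
            class = "metric_report")
}

#' @export
#' @method print metric_report
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d, p = %d\nR2 %.4f  adj.R2 %.4f  RMSE %.4f  MAE %.4f  MAPE %.2f%%\n",
              x$n, x$p, x$r2, x$adj_r2, x$rmse, x$mae, x$mape))
  invisible(x)
}

#' Friedman rank test across blocks
#'
#' Average-rank form of the Friedman chi-square statistic: scores are ranked
#' within each block (mid-ranks on ties), and
#' `chi2_F = 12N / (k(k+1)) * (sum(Rbar_j^2) - k(k+1)^2 / 4)` with `N` blocks
#' and `k` treatments, referred to a chi-square distribution with `k - 1`
#' degrees of freedom.
#'
#' @param scores `N x k` matrix (blocks x treatments/models).
#' @param lower_is_better rank direction: `TRUE` for error metrics (rank 1 =
#'   best = smallest), `FALSE` for R-squared-like scores.
#' @return list of class `rank_test`: `statistic`, `p_value`, `df`,
#'   `avg_ranks`, `ranks`, `N`, `k`.
#' @export
friedman_test <- function(scores, lower_is_better = TRUE) {
  scores <- as.matrix(scores)
  N <- nrow(scores); k <- ncol(scores)
  stopifnot(N >= 2, k >= 2)
  ranks <- t(apply(if (lower_is_better) scores else -scores, 1, rank,
                   ties.method = "average"))
  rbar <- colMeans(ranks)
  stat <- 12 * N / (k * (k + 1)) * (sum(rbar^2) - k * (k + 1)^2 / 4)
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
                 df = k - 1, avg_ranks = rbar, ranks = ranks, N = N, k = k),
            class = "rank_test")
}

#' @export
#' @method print rank_test
print.rank_test <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4f, df = %d, p = %.4g (N = %d blocks, k = %d)\n",
              x$statistic, x$df, x$p_value, x$N, x$k))
  cat("average ranks:", paste(sprintf("%.2f", x$avg_ranks), collapse = " "), "\n")
  invisible(x)
}

# Nemenyi constants q_alpha = q_{alpha, k, inf} / sqrt(2): the infinite-df
# studentized range quantile divided by sqrt(2), k = 2..20.
.nemenyi_q <- list(
  "0.05" = c(1.959964, 2.343701, 2.569032, 2.727774, 2.849705, 2.948320,
             3.030879, 3.101730, 3.163684, 3.218654, 3.268004, 3.312739,
             3.353618, 3.391230, 3.426041, 3.458425, 3.488685, 3.517073,
             3.543799),
  "0.1"  = c(1.644854, 2.052293, 2.291341, 2.459516, 2.588521, 2.692732,
             2.779884, 2.854606, 2.919889, 2.977768, 3.029694, 3.076733,
             3.119693, 3.159199, 3.195743, 3.229723, 3.261461, 3.291224,
             3.319233))

#' Nemenyi critical difference
#'
#' Post-hoc critical difference for pairwise average-rank comparisons after a
#' Friedman test: `CD = q_alpha * sqrt(k(k+1) / (6N))`. Two treatments whose
#' average ranks differ by more than CD are significantly different.
#'
#' @param k number of treatments (2 to 20).
#' @param N number of blocks.
#' @param alpha significance level, 0.05 or 0.10.
#' @return The critical difference (average-rank units).
#' @export
nemenyi_cd <- function(k, N, alpha = 0.05) {
  key <- as.character(alpha)
  if (!key %in% names(.nemenyi_q)) stop("alpha must be 0.05 or 0.1")
  if (k < 2 || k > 20) stop("k outside tabulated range 2..20")
  stopifnot(N >= 1)
  q <- .nemenyi_q[[key]][k - 1]
  q * sqrt(k * (k + 1) / (6 * N))
}

#' k-nearest-neighbour spatial weights
#'
#' Binary kNN adjacency symmetrized by `max(W, t(W))` (i is a neighbour of j
#' if either is among the other's k nearest), no self-neighbours.
#'
#' @param coords two-column coordinate matrix.
#' @param k neighbours per point.
#' @return `n x n` 0/1 weight matrix of class `spatial_weights` (attribute
#'   `k`).
#' @export
knn_weights <- function(coords, k = 8) {
  n <- nrow(coords)
  if (n <= k) stop("need more points than neighbours (n > k)")
  D <- as.matrix(stats::dist(coords))
  diag(D) <- Inf
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, order(D[i, ])[seq_len(k)]] <- 1
  W <- pmax(W, t(W))
  structure(W, k = k, class = c("spatial_weights", "matrix", "array"))
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation `I = (n / S0) * (z' W z) / (z' z)` with
#' `z` the centred values and `S0` the total weight. The expectation under
#' spatial randomness is `-1/(n-1)`. The p-value is from a random-labelling
#' permutation test with floor `1 / (n_permutations + 1)`.
#'
#' @param values numeric vector at point locations.
#' @param weights a [knn_weights()] matrix (or any non-negative weight matrix
#'   with zero diagonal).
#' @param n_permutations random relabellings (default 999).
#' @param alternative `"greater"` tests clustering (positive autocorrelation),
#'   `"two.sided"` tests any departure.
#' @param seed integer seed for the permutations.
#' @return list: `I`, `expected`, `p_value`, `n`, `n_permutations`.
#' @export
morans_i <- function(values, weights, n_permutations = 999,
                     alternative = c("greater", "two.sided"), seed = 1L) {
  alternative <- match.arg(alternative)
  n <- length(values)
  stopifnot(nrow(weights) == n)
  if (stats::var(values) == 0) stop("constant field: Moran's I undefined")
  s0 <- sum(weights)
  stat <- function(v) {
    z <- v - mean(v)
    (n / s0) * sum(weights * outer(z, z)) / sum(z^2)
  }
  I <- stat(values)
  expected <- -1 / (n - 1)
  set.seed(seed)
  perm <- replicate(n_permutations, stat(sample(values)))
  p <- if (alternative == "greater") {
    (1 + sum(perm >= I)) / (n_permutations + 1)
  } else {
    (1 + sum(abs(perm - expected) >= abs(I - expected))) / (n_permutations + 1)
  }
  list(I = I, expected = expected, p_value = p, n = n,
       n_permutations = n_permutations)
}

#' Village- and block-level validation report
#'
#' Aggregates each method's pixel surface to villages and blocks and compares
#' with reported yields: village-level R2, adjusted R2, RMSE, MAE, MAPE and
#' block-level RMSE, MAE, MAPE (block-level R2 is not reported — with few
#' blocks relative to predictors it is unstable and non-interpretable).
#'
#' @param surfaces named list of pixel yield matrices (one per method).
#' @param villages a [village_map()] with observed yields.
#' @param zones integer village zone matrix.
#' @param mask optional crop mask.
#' @param block_yield optional data.frame `(block_id, yield)` of reported
#'   block yields; defaults to pixel-count-weighted means of village yields.
#' @param p predictor count for adjusted R-squared.
#' @return list of class `validation_report` with data.frames `village` and
#'   `block` (method x metric).
#' @export
validation_report <- function(surfaces, villages, zones, mask = NULL,
                              block_yield = NULL, p = 1) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1)
  vrows <- list(); brows <- list()
  for (m in names(surfaces)) {
    agg <- zonal_aggregate(surfaces[[m]], zones, mask,
                           village_id = villages$village_id)
    idx <- match(villages$village_id, agg$village_id)
    pred <- agg$mean[idx]
    ok <- !is.na(pred) & !is.na(villages$yield)
    if (sum(ok) < 2) stop("too few villages with predictions for method ", m)
    mv <- regression_metrics(villages$yield[ok], pred[ok], p = p)
    vrows[[m]] <- data.frame(method = m, r2 = mv$r2, adj_r2 = mv$adj_r2,
                             rmse = mv$rmse, mae = mv$mae, mape = mv$mape)
    cnt <- agg$pixel_count[idx]
    bw <- rowsum(cbind(pred[ok] * cnt[ok], villages$yield[ok] * cnt[ok],
                       cnt[ok]), villages$block_id[ok])
    bpred <- bw[, 1] / bw[, 3]
    bobs <- if (is.null(block_yield)) bw[, 2] / bw[, 3] else
      block_yield$yield[match(rownames(bw), block_yield$block_id)]
    mb <- regression_metrics(bobs, bpred, p = p)
    brows[[m]] <- data.frame(method = m, rmse = mb$rmse, mae = mb$mae,
                             mape = mb$mape)
  }
  structure(list(village = do.call(rbind, c(vrows, make.row.names = FALSE)),
                 block = do.call(rbind, c(brows, make.row.names = FALSE))),
            class = "validation_report")
}

#' @export
#' @method print validation_report
print.validation_report <- function(x, ...) {
  cat("Village-level performance:\n")
  print(x$village, row.names = FALSE, digits = 4)
  cat("Block-level performance:\n")
  print(x$block, row.names = FALSE, digits = 4)
  invisible(x)
}
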