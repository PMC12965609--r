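test_that("regression metrics follow their printed formulas", {
  m <- regression_metrics(c(10, 20), c(9, 22), p = 1)
  expect_equal(m$mae, 1.5)
  expect_equal(m$mape, 10)
  expect_equal(m$rmse, sqrt(5 / 2))
  perfect <- regression_metrics(1:5, 1:5, p = 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape, 0)
  # adjusted R2 penalty: 1 - (n-1)/(n-p-1) * (1 - R2)
  mm <- regression_metrics(c(1, 2, 3), c(1.1, 1.9, 3.05), p = 1)
  expect_equal(mm$adj_r2, 1 - (3 - 1) / (3 - 1 - 1) * (1 - mm$r2))
  expect_warning(regression_metrics(c(0, 1, 2), c(1, 1, 2)), "zero observations")
})

test_that("RMSE dominates MAE with equality only for equal absolute errors", {
  set.seed(20)
  for (i in 1:20) {
    y <- rnorm(15); yh <- y + rnorm(15)
    m <- regression_metrics(y, yh)
    expect_gte(m$rmse + 1e-12, m$mae)
  }
  eq <- suppressWarnings(regression_metrics(c(0, 0, 0, 0), c(1, -1, 1, -1)))
  expect_equal(eq$rmse, eq$mae)
})

test_that("Friedman statistic agrees with a brute-force rank-sum oracle", {
  # perfectly consistent orderings: chi2 = N * (k - 1)
  consistent <- matrix(rep(c(1, 2, 3), 3), 3, 3, byrow = TRUE)
  ft <- friedman_test(consistent)
  expect_equal(ft$statistic, 3 * (3 - 1))
  # fully tied matrix -> 0
  expect_equal(friedman_test(matrix(5, 4, 3))$statistic, 0)
  # random matrices vs. explicit rank-sum computation
  set.seed(21)
  for (i in 1:100) {
    M <- matrix(rnorm(20), 5, 4)
    ft <- friedman_test(M)
    R <- t(apply(M, 1, rank))
    Rbar <- colSums(R) / 5
    stat <- 12 * 5 / (4 * 5) * (sum(Rbar^2) - 4 * 25 / 4)
    expect_equal(ft$statistic, stat)
  }
  # agreement with the reference implementation in stats
  M <- matrix(rnorm(24), 6, 4)
  expect_equal(friedman_test(M)$statistic,
               unname(stats::friedman.test(M)$statistic))
  expect_equal(friedman_test(M)$p_value,
               unname(stats::friedman.test(M)$p.value))
  # invariance to within-block monotone transformation
  expect_equal(friedman_test(exp(M))$statistic, friedman_test(M)$statistic)
  # direction flag flips rankings
  expect_equal(friedman_test(-M, lower_is_better = FALSE)$statistic,
               friedman_test(M)$statistic)
})

test_that("Nemenyi critical difference behaves per its closed form", {
  expect_equal(nemenyi_cd(7, 6, 0.05), 3.6772, tolerance = 1e-4)
  # CD strictly decreases as N grows
  cds <- sapply(c(2, 4, 8, 16, 32), function(N) nemenyi_cd(5, N, 0.05))
  expect_true(all(diff(cds) < 0))
  # k = 2 row reduces to q * sqrt(k(k+1)/6N)
  expect_equal(nemenyi_cd(2, 1, 0.05), 1.959964 * sqrt(2 * 3 / 6))
  expect_error(nemenyi_cd(25, 5), "outside")
  expect_error(nemenyi_cd(5, 5, alpha = 0.01), "alpha")
})

test_that("kNN weights have k neighbours, no self-links, and symmetry", {
  set.seed(22)
  pts <- cbind(runif(30), runif(30))
  W <- knn_weights(pts, 8)
  expect_true(all(diag(W) == 0))
  expect_true(all(rowSums(W) >= 8))      # symmetrization can only add links
  expect_identical(unclass(W), t(unclass(W)))
  expect_error(knn_weights(pts[1:5, ], 8), "n > k")
})

test_that("Moran's I detects gradients, ignores noise, centres at -1/(n-1)", {
  g <- expand.grid(x = 1:15, y = 1:15)
  W <- knn_weights(as.matrix(g), 8)
  grad <- morans_i(g$x + g$y, W, 999, seed = 1)
  expect_gt(grad$I, 0.3)
  expect_equal(grad$p_value, 0.001)      # permutation floor at 999 draws
  # affine invariance
  expect_equal(morans_i(5 * (g$x + g$y) - 3, W, 99, seed = 1)$I, grad$I)
  # i.i.d. noise is rarely significant
  pvals <- sapply(1:20, function(s) {
    set.seed(s + 500)
    morans_i(rnorm(225), W, 199, seed = s)$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.9)
  # permutation-null mean of the statistic approximates -1/(n-1)
  set.seed(30)
  pts <- cbind(runif(50), runif(50))
  Wp <- knn_weights(pts, 8)
  vals <- rnorm(50)^2
  Is <- vapply(1:400, function(i) {
    set.seed(i)
    morans_i(sample(vals), Wp, n_permutations = 1, seed = i)$I
  }, 0)
  expect_lt(abs(mean(Is) - (-1 / 49)), 0.02)
  expect_error(morans_i(rep(1, 50), Wp), "constant")
})

test_that("printed block tables reproduce their summary cells", {
  wheat <- read.csv(system.file("extdata", "block_yields_wheat.csv",
                                package = "yieldkrige"))
  mustard <- read.csv(system.file("extdata", "block_yields_mustard.csv",
                                  package = "yieldkrige"))
  tol <- 0.015   # one unit in the last printed digit
  m_wb <- regression_metrics(wheat$actual, wheat$weight_based)
  expect_equal(m_wb$rmse, 3.33, tolerance = tol / 3.33)
  expect_equal(m_wb$mae, 2.74, tolerance = tol / 2.74)
  m_lk <- regression_metrics(wheat$actual, wheat$lstm_kriging)
  expect_equal(m_lk$rmse, 1.79, tolerance = tol / 1.79)
  expect_equal(m_lk$mae, 1.44, tolerance = tol / 1.44)
  expect_equal(regression_metrics(mustard$actual, mustard$gru_kriging)$rmse,
               1.81, tolerance = tol / 1.81)
  expect_equal(regression_metrics(mustard$actual, mustard$lstm_kriging)$rmse,
               2.12, tolerance = tol / 2.12)
})

test_that("validation report is exact for identical surfaces", {
  sc <- tiny_scene()
  tr <- aggregate_truth(sc)
  exact <- sc$villages
  exact$yield <- tr$village$true_mean     # observations equal aggregated truth
  rep <- validation_report(list(perfect = sc$truth), exact, sc$zones, sc$mask)
  expect_equal(rep$village$rmse, 0, tolerance = 1e-10)
  expect_equal(rep$village$mae, 0, tolerance = 1e-10)
  expect_equal(rep$village$r2, 1)
  expect_equal(rep$block$rmse, 0, tolerance = 1e-10)
  expect_false("r2" %in% names(rep$block))   # block-level R2 deliberately absent
})
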