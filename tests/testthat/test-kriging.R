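test_that("residual computation subtracts matched predictions", {
  obs <- data.frame(village_id = c("a", "b"), yield = c(40, 50))
  pred <- data.frame(village_id = c("b", "a"), mean = c(47, 42))
  f <- compute_residuals(obs, pred, coords = cbind(1:2, 1:2))
  expect_equal(f$residual, c(-2, 3))
  expect_equal(mean(f$residual), mean(obs$yield) - mean(pred$mean))
  expect_error(compute_residuals(data.frame(village_id = "zz", yield = 1),
                                 pred, cbind(1, 1)), "unmatched")
})

test_that("empirical semivariogram matches its definition", {
  # two points, values 0 and 2 at distance d: gamma(d) = (0-2)^2 / (2*1) = 2
  f2 <- residual_field(cbind(c(0, 3), c(0, 4)), c(0, 2))
  emp2 <- empirical_semivariogram(f2, n_lags = 1, max_dist = 10)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$n_pairs, 1)
  # constant residuals -> flat zero
  set.seed(8)
  pts <- cbind(runif(10), runif(10))
  expect_true(all(empirical_semivariogram(residual_field(pts, rep(3, 10)),
                                          max_dist = 2)$gamma == 0))
  # all n(n-1)/2 pairs counted when max_dist spans the field
  emp <- empirical_semivariogram(residual_field(pts, rnorm(10)), max_dist = 2)
  expect_equal(sum(emp$n_pairs), 45)
  expect_error(empirical_semivariogram(residual_field(matrix(1, 4, 2),
                                                      rnorm(4))), "coincident")
})

test_that("variogram fitting recovers exact models and scales with the data", {
  lag <- seq(5, 150, by = 10)
  truth <- variogram_gamma(lag, "spherical", nugget = 0.5, psill = 4, range = 90)
  emp <- data.frame(lag = lag, gamma = truth, n_pairs = rep(20, length(lag)))
  fit <- fit_variogram(emp, "spherical")
  expect_lt(abs(fit$psill - 4) / 4, 0.01)
  expect_lt(abs(fit$range - 90) / 90, 0.01)
  # flat empirical variogram -> pure nugget
  flat <- data.frame(lag = lag, gamma = rep(2, length(lag)), n_pairs = 20)
  ffit <- fit_variogram(flat, "exponential")
  expect_lt(ffit$psill * (1 - exp(-max(lag) / ffit$range)), 0.2)
  expect_equal(ffit$nugget + ffit$psill * (1 - exp(-lag[8] / ffit$range)), 2,
               tolerance = 0.05)
  # scaling residuals by a scales the fitted sill by a^2
  set.seed(11)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  z <- rnorm(40)
  e1 <- empirical_semivariogram(residual_field(pts, z))
  e3 <- empirical_semivariogram(residual_field(pts, 3 * z))
  f1 <- fit_variogram(e1, "linear")
  f3 <- fit_variogram(e3, "linear")
  expect_equal(f3$psill, 9 * f1$psill, tolerance = 1e-6)
  expect_equal(f3$nugget, 9 * f1$nugget, tolerance = 1e-6)
})

test_that("ordinary kriging matches the brute-force dense oracle", {
  set.seed(13)
  for (vm in list(variogram_model("linear", 0.2, 0.05),
                  variogram_model("exponential", 0.1, 2, 30),
                  variogram_model("spherical", 0, 1.5, 60),
                  variogram_model("gaussian", 0.3, 1, 40))) {
    n <- sample(4:10, 1)
    coords <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    vals <- rnorm(n, 10)
    targets <- cbind(runif(25, 0, 100), runif(25, 0, 100))
    kr <- krige_points(coords, vals, targets, vm)
    for (j in seq_len(25)) {
      bf <- brute_krige(coords, vals, targets[j, ], vm)
      expect_lt(abs(kr$pred[j] - bf$pred), 1e-6)
    }
    expect_lt(max(abs(kr$lambda_sum - 1)), 1e-8)
  }
})

test_that("kriging is exact at data points iff the nugget is zero", {
  set.seed(14)
  coords <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  vals <- rnorm(6, 20, 4)
  exact <- krige_points(coords, vals,coords,
                        variogram_model("exponential", 0, 2, 15))
  expect_equal(exact$pred, vals, tolerance = 1e-8)
  smooth <- krige_points(coords, vals, coords,
                         variogram_model("exponential", 0.8, 2, 15))
  expect_gt(min(abs(smooth$pred - vals)), 1e-6)
  expect_error(krige_points(coords[c(1, 1), ], vals[1:2],
                            coords[1, , drop = FALSE],
                            variogram_model("linear", 0, 1)), "duplicate")
})

test_that("cross-validated selection is deterministic and sane on noise", {
  set.seed(15)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  white <- rnorm(40, sd = 2)
  f <- residual_field(pts, white)
  s1 <- select_variogram_cv(f)
  s2 <- select_variogram_cv(f)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$cv_rmse, s2$cv_rmse)
  # white noise: every candidate's CV-RMSE is near the residual sd
  expect_true(all(abs(s1$cv_rmse - sd(white)) < sd(white)))
  expect_error(select_variogram_cv(residual_field(pts[1:5, ], white[1:5])),
               "at least 10")
})

test_that("surface correction adds residuals and shifts village means", {
  sc <- tiny_scene()
  pred <- matrix(40, sc$geom$nrow, sc$geom$ncol)
  zero <- matrix(0, sc$geom$nrow, sc$geom$ncol)
  expect_identical(correct_yield_surface(pred, zero), pred)
  shift <- correct_yield_surface(pred, zero + 1.5)
  agg0 <- zonal_aggregate(pred, sc$zones, sc$mask)
  agg1 <- zonal_aggregate(shift, sc$zones, sc$mask)
  expect_equal(agg1$mean, agg0$mean + 1.5)
  expect_error(correct_yield_surface(pred, matrix(0, 2, 2)), "misaligned")
  neg <- correct_yield_surface(pred, zero - 100, floor_zero = TRUE)
  expect_true(all(neg == 0))
})

test_that("kriging correction removes an injected smooth regional bias", {
  sc <- generate_scene(scene_config(dim = c(50, 50), n_villages = 30,
                                    trend = c(3, 2), weather_block = 10,
                                    seed = 33))
  # a covariate model blind to the trend: fit on band features only
  feats <- extract_features(sc$stack, sc$zones, sc$mask,
                            sc$villages$village_id)
  smp <- assemble_samples(sc$villages, feats, "band-only", seed = 3)
  m <- fit_yield_model(smp, "rf")
  surf <- predict_pixel_yield(m, sc$stack, sc$mask)
  agg <- aggregate_to_admin(surf, sc$zones, sc$mask, sc$villages$village_id)
  field <- compute_residuals(sc$villages, agg)
  mi <- morans_i(field$residual, knn_weights(field$coords, 8), 999, seed = 1)
  expect_gt(mi$I, 0)
  expect_lte(mi$p_value, 0.01)
  sel <- select_variogram_cv(field)
  ek <- krige_residual_surface(field, sel$models[[sel$selected]], sc$geom,
                               sc$mask)
  expect_lt(attr(ek, "max_lambda_dev"), 1e-8)
  corrected <- correct_yield_surface(surf, ek)
  rep <- validation_report(list(un = surf, co = corrected), sc$villages,
                           sc$zones, sc$mask)
  expect_lt(rep$village$rmse[2], rep$village$rmse[1])
})
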