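#' Synthetic landscape configuration
#'
#' Defaults describe the study conditions the simulator emulates: a 10 km x
#' 10 km scene at 100 m resolution, 60 irregular villages grouped into a 2 x 2
#' grid of blocks, yields on a winter-wheat scale (~45 quintal/ha), covariates
#' driven by two smooth latent fields (fertility, moisture), weather surfaces
#' piecewise-constant on coarse 25-pixel blocks (mirroring reanalysis-grade
#' coarseness where many villages share identical weather values), and a
#' spatially autocorrelated yield component that no covariate explains — the
#' structured bias that residual kriging exists to remove.
#'
#' @param dim grid `c(nrow, ncol)` in pixels.
#' @param res pixel size, metres.
#' @param n_villages number of Voronoi villages.
#' @param variogram list `(type, sill, range, nugget)` for the unexplained
#'   spatially structured yield component (range in metres; for exponential /
#'   gaussian types this is the correlation-length parameter).
#' @param loadings named vector: yield response (quintal/ha per unit driver)
#'   to the fertility and moisture fields.
#' @param intercept mean yield, quintal/ha.
#' @param trend planar bias `c(per_km_x, per_km_y)` in quintal/ha added to the
#'   truth but invisible to every covariate (an injectable smooth regional bias).
#' @param weather_block side of the square weather block, pixels.
#' @param mask_coverage Bernoulli crop-mask coverage fraction in (0, 1].
#' @param noise_sd observation noise sd on village yields, quintal/ha.
#' @param covariate_noise_sd feature noise sd on each covariate layer.
#' @param n_soil number of static soil layers.
#' @param band_times,weather_times time steps for the band and weather series.
#' @param block_grid blocks as a `c(rows, cols)` partition of the scene.
#' @param seed integer; fixes all randomness in the scene.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(dim = c(100, 100), res = 100, n_villages = 60,
                         variogram = list(type = "exponential", sill = 4,
                                          range = 2000, nugget = 0),
                         loadings = c(fertility = 4, moisture = 2),
                         intercept = 45, trend = c(0, 0),
                         weather_block = 25, mask_coverage = 0.85,
                         noise_sd = 0.5, covariate_noise_sd = 0.15,
                         n_soil = 10,
                         band_times = 1:3, weather_times = 1:5,
                         block_grid = c(2, 2), seed = 1L) {
  stopifnot(variogram$range > 0, mask_coverage > 0, mask_coverage <= 1,
            n_villages >= 1, n_villages <= prod(dim))
  structure(list(dim = as.integer(dim), res = res, n_villages = n_villages,
                 variogram = variogram, loadings = loadings,
                 intercept = intercept, trend = trend,
                 weather_block = weather_block, mask_coverage = mask_coverage,
                 noise_sd = noise_sd, covariate_noise_sd = covariate_noise_sd,
                 n_soil = n_soil, band_times = band_times,
                 weather_times = weather_times, block_grid = as.integer(block_grid),
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate a Gaussian random field on a grid
#'
#' Zero-mean stationary field with the covariance implied by a bounded
#' variogram model, `C(h) = sill - gamma_structured(h)`, simulated by
#' circulant embedding on a doubled torus (FFT); any residual negative
#' eigenvalues of the embedding are clipped, which for these covariances and
#' grid sizes perturbs the target covariance negligibly. An unbounded
#' (linear) variogram has no finite-variance field and is rejected. Nugget, if
#' any, is added as white noise.
#'
#' @param dim grid `c(nrow, ncol)`.
#' @param variogram list `(type, sill, range, nugget)`; `range` in the same
#'   units as `res`.
#' @param res pixel size (distance unit of `range`).
#' @param seed integer seed.
#' @return Matrix `[nrow, ncol]`.
#' @export
gaussian_random_field <- function(dim, variogram, res = 1, seed = 1L) {
  type <- match.arg(variogram$type, c("exponential", "gaussian", "spherical"))
  sill <- variogram$sill
  nug <- if (is.null(variogram$nugget)) 0 else variogram$nugget
  nr <- dim[1]; nc <- dim[2]
  set.seed(seed)
  if (sill < 0 || nug < 0) stop("sill and nugget must be non-negative")
  white <- if (nug > 0) matrix(stats::rnorm(nr * nc, sd = sqrt(nug)), nr, nc) else 0
  if (sill == 0) return(matrix(0, nr, nc) + white)
  m <- 2 * nr; n <- 2 * nc
  di <- pmin(0:(m - 1), m - (0:(m - 1)))
  dj <- pmin(0:(n - 1), n - (0:(n - 1)))
  h <- sqrt(outer(di^2, dj^2, "+")) * res
  cov <- sill - variogram_gamma(h, type = type, nugget = 0, psill = sill,
                                range = variogram$range)
  lambda <- Re(stats::fft(cov))
  lambda[lambda < 0] <- 0
  z <- matrix(stats::rnorm(m * n), m, n) + 1i * matrix(stats::rnorm(m * n), m, n)
  f <- stats::fft(sqrt(lambda / (m * n)) * z, inverse = FALSE)
  Re(f)[seq_len(nr), seq_len(nc)] + white
}

#' Discrete Voronoi partition of a grid
#'
#' Assigns every pixel to its nearest seed point (Euclidean, pixel centres),
#' producing irregular contiguous cells that stand in for administrative
#' village polygons.
#'
#' @param geom a [grid_geom()].
#' @param seeds two-column matrix of seed coordinates.
#' @return Integer matrix of cell memberships.
#' @export
voronoi_zones <- function(geom, seeds) {
  xy <- pixel_coords(geom)
  n <- nrow(xy)
  best <- rep(1L, n)
  bestd <- (xy[, 1] - seeds[1, 1])^2 + (xy[, 2] - seeds[1, 2])^2
  for (i in seq_len(nrow(seeds))[-1]) {
    d <- (xy[, 1] - seeds[i, 1])^2 + (xy[, 2] - seeds[i, 2])^2
    upd <- d < bestd
    best[upd] <- i
    bestd[upd] <- d[upd]
  }
  matrix(best, geom$nrow, geom$ncol)
}

#' Generate a synthetic landscape with known pixel truth
#'
#' Builds the full data structure downstream stages consume: a latent yield
#' truth raster (`intercept + loadings * drivers + structured residual +
#' trend`), a covariate stack (optical/radar time series loaded on the
#' drivers, block-constant weather layers, static soil layers, each with
#' independent feature noise), a Bernoulli crop mask, a Voronoi village map
#' whose observed yields are masked zonal means of the truth plus observation
#' noise, and the village-to-block assignment.
#'
#' @param config a [scene_config()].
#' @return Object of class `synthetic_scene` with elements `truth`, `stack`,
#'   `mask`, `zones`, `villages`, `geom`, `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  geom <- grid_geom(config$dim, config$res)
  nr <- geom$nrow; nc <- geom$ncol
  base_seed <- config$seed
  smooth_vg <- function(sill) list(type = "exponential", sill = sill,
                                   range = config$variogram$range, nugget = 0)
  fert <- gaussian_random_field(c(nr, nc), smooth_vg(1), res = config$res,
                                seed = base_seed + 11L)
  moist <- gaussian_random_field(c(nr, nc), smooth_vg(1), res = config$res,
                                 seed = base_seed + 12L)
  resid <- gaussian_random_field(c(nr, nc), config$variogram, res = config$res,
                                 seed = base_seed + 13L)
  xy <- pixel_coords(geom)
  trend <- matrix(config$trend[1] * xy[, 1] / 1000 +
                    config$trend[2] * xy[, 2] / 1000, nr, nc)
  truth <- config$intercept + config$loadings[["fertility"]] * fert +
    config$loadings[["moisture"]] * moist + resid + trend

  set.seed(base_seed + 20L)
  csd <- config$covariate_noise_sd
  noise <- function() matrix(stats::rnorm(nr * nc, sd = csd), nr, nc)
  season <- function(t, times) 0.8 + 0.2 * sin(pi * t / (max(times) + 1))

  # optical: NIR tracks fertility, Red anti-tracks it; others mild mixes
  opt_feats <- c(B2 = 0.1, B3 = 0.2, B4 = -0.5, B8 = 0.8, B11 = -0.2)
  opt_base <- c(B2 = 0.1, B3 = 0.15, B4 = 0.35, B8 = 0.55, B11 = 0.3)
  rad_feats <- c(VV = 0.6, VH = 0.4)
  layers <- list(); vals <- list()
  for (t in config$band_times) {
    s <- season(t, config$band_times)
    for (f in names(opt_feats)) {
      vals[[length(vals) + 1]] <- opt_base[[f]] + s * opt_feats[[f]] * 0.2 * fert +
        0.02 * moist + noise() * 0.05
      layers[[length(layers) + 1]] <- data.frame(source = "optical", feature = f, time = t)
    }
    for (f in names(rad_feats)) {
      vals[[length(vals) + 1]] <- -12 + s * rad_feats[[f]] * 2 * moist +
        0.3 * fert + noise() * 2
      layers[[length(layers) + 1]] <- data.frame(source = "radar", feature = f, time = t)
    }
  }

  # weather: block-averaged drivers, identical value across each coarse block
  blockify <- function(m, b) {
    ri <- (seq_len(nr) - 1L) %/% b
    ci <- (seq_len(nc) - 1L) %/% b
    means <- tapply(as.vector(m),
                    list(ri[row(m)], ci[col(m)]), mean)
    matrix(means[cbind(as.character(ri[row(m)]), as.character(ci[col(m)]))], nr, nc)
  }
  wb <- config$weather_block
  moist_b <- blockify(moist, wb)
  fert_b <- blockify(fert, wb)
  w_feats <- c(t2m = 1, soil_temp = 0.8, radiation = -0.5, evap = 0.6,
               precip = 0.9, lai = 0.7)
  w_base <- c(t2m = 18, soil_temp = 16, radiation = 180, evap = 2.5,
              precip = 15, lai = 1.8)
  for (t in config$weather_times) {
    for (f in names(w_feats)) {
      bn <- blockify(noise(), wb)
      vals[[length(vals) + 1]] <- w_base[[f]] + w_feats[[f]] *
        (1 + 0.1 * t) * moist_b + 0.2 * fert_b + bn
      layers[[length(layers) + 1]] <- data.frame(source = "weather", feature = f, time = t)
    }
  }

  # static soil layers loaded on fertility
  for (k in seq_len(config$n_soil)) {
    coef <- 0.5 * cos(k)  # varied, fixed loadings across soil properties
    vals[[length(vals) + 1]] <- 10 + k + coef * fert + noise() * 2
    layers[[length(layers) + 1]] <- data.frame(source = "soil",
                                               feature = paste0("prop", k),
                                               time = NA_integer_)
  }

  stack <- raster_stack(array(unlist(vals), c(nr, nc, length(vals))), geom,
                        do.call(rbind, layers))

  set.seed(base_seed + 30L)
  mask <- matrix(stats::rbinom(nr * nc, 1, config$mask_coverage), nr, nc)

  set.seed(base_seed + 40L)
  seeds <- cbind(stats::runif(config$n_villages, 0, nc * config$res),
                 stats::runif(config$n_villages, 0, nr * config$res))
  zones <- voronoi_zones(geom, seeds)
  # guarantee every village keeps at least one masked pixel
  for (i in seq_len(config$n_villages)) {
    inz <- which(zones == i)
    if (!any(mask[inz] > 0)) mask[inz[1]] <- 1L
  }

  vxy <- pixel_coords(geom)
  cent <- cbind(tapply(vxy[, 1], as.vector(zones), mean),
                tapply(vxy[, 2], as.vector(zones), mean))
  bg <- config$block_grid
  bx <- pmin(floor(cent[, 1] / (nc * config$res / bg[2])), bg[2] - 1)
  by <- pmin(floor(cent[, 2] / (nr * config$res / bg[1])), bg[1] - 1)
  block_id <- sprintf("B%d%d", by + 1, bx + 1)

  zt <- zonal_aggregate(truth, zones, mask)
  set.seed(base_seed + 50L)
  obs <- zt$mean + stats::rnorm(config$n_villages, sd = config$noise_sd)
  vmap <- village_map(sprintf("V%03d", seq_len(config$n_villages)), block_id,
                      cent, obs,
                      area_ha = tabulate(zones, config$n_villages) *
                        (config$res / 100)^2)
  structure(list(truth = truth, stack = stack, mask = mask, zones = zones,
                 villages = vmap, geom = geom, config = config),
            class = "synthetic_scene")
}

#' @export
#' @method print synthetic_scene
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d x %d pixels, %d villages, %d covariate layers\n",
              x$geom$nrow, x$geom$ncol, nrow(x$villages), nrow(x$stack$layers)))
  invisible(x)
}

#' True village and block mean yields of a scene
#'
#' Exact masked means of the latent truth raster at both administrative
#' supports; the oracle against which recovery is judged.
#'
#' @param scene a [generate_scene()] result.
#' @return list of data.frames `village` (village_id, true_mean, pixel_count)
#'   and `block` (block_id, true_mean, pixel_count).
#' @export
aggregate_truth <- function(scene) {
  v <- zonal_aggregate(scene$truth, scene$zones, scene$mask,
                       village_id = scene$villages$village_id)
  names(v)[2] <- "true_mean"
  blk <- scene$villages$block_id[match(v$village_id, scene$villages$village_id)]
  bsum <- rowsum(cbind(v$true_mean * v$pixel_count, v$pixel_count), blk)
  b <- data.frame(block_id = rownames(bsum),
                  true_mean = bsum[, 1] / bsum[, 2],
                  pixel_count = bsum[, 2], row.names = NULL,
                  stringsAsFactors = FALSE)
  list(village = v, block = b)
}
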