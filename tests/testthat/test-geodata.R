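test_that("monthly composites average scenes and honour nodata", {
  a <- matrix(c(2, NA, 4, 8), 2, 2)
  b <- matrix(c(4, 5, NA, 10), 2, 2)
  cmp <- monthly_composite(list(a, b))
  expect_equal(cmp[1, 1], 3)            # mean of 2 and 4
  expect_equal(cmp[2, 1], 5)            # nodata in one scene ignored
  expect_equal(cmp[1, 2], 4)
  expect_equal(attr(cmp, "n_valid")[2, 1], 1)
  expect_identical(monthly_composite(list(a))[2, 2], a[2, 2])
  cmp_all_na <- monthly_composite(list(matrix(NA_real_, 1, 1),
                                       matrix(NA_real_, 1, 1)))
  expect_true(is.na(cmp_all_na[1, 1]))
  expect_error(monthly_composite(list()), "at least one")
  expect_error(monthly_composite(list(a, matrix(0, 3, 3))), "mismatched")
})

test_that("zonal aggregation matches brute-force enumeration and is linear", {
  set.seed(42)
  v <- matrix(rnorm(64, 10), 8, 8)
  zones <- matrix(rep(1:2, each = 32), 8, 8)
  mask <- matrix((row(v) + col(v)) %% 2L, 8, 8)    # checkerboard
  z <- zonal_aggregate(v, zones, mask)
  for (k in 1:2) {
    sel <- zones == k & mask == 1
    expect_equal(z$mean[k], mean(v[sel]))
    expect_equal(z$pixel_count[k], sum(sel))
  }
  expect_equal(sum(z$pixel_count), 32)
  z3 <- zonal_aggregate(3 * v, zones, mask)
  expect_equal(z3$mean, 3 * z$mean)     # linearity
  # simple cases
  z1 <- zonal_aggregate(matrix(c(10, 20, 99, 99), 1, 4),
                        matrix(c(1, 1, 2, 2), 1, 4))
  expect_equal(z1$mean, c(15, 99))
  zempty <- zonal_aggregate(v, zones, mask * 0)
  expect_true(all(is.na(zempty$mean)))
  expect_identical(attr(zempty, "empty_villages"), c("1", "2"))
})

test_that("pixel-centre polygon inclusion is deterministic and consistent", {
  geom <- grid_geom(c(4, 4), res = 1)
  square <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))   # covers 2x2 lower-left cells
  xy <- pixel_coords(geom)
  inside <- point_in_polygon(xy[, 1], xy[, 2], square)
  expect_equal(sum(inside), 4)
  expect_true(all(xy[inside, 1] < 2 & xy[inside, 2] < 2))
  vm <- village_map("V1", "B1", matrix(c(1, 1), 1), 40,
                    polygons = list(square))
  zones <- rasterize_villages(vm, geom)
  expect_equal(sum(zones == 1, na.rm = TRUE), 4)
})

test_that("sample assembly reproduces the documented split and imputation", {
  n <- 1116
  set.seed(9)
  vm <- village_map(sprintf("V%04d", 1:n), sprintf("B%02d", rep(1:20, length.out = n)),
                    cbind(runif(n), runif(n)), rnorm(n, 40, 5))
  layers <- data.frame(source = "soil", feature = "prop1", time = NA_integer_)
  feats <- data.frame(village_id = vm$village_id, soil.prop1 = rnorm(n))
  attr(feats, "layers") <- layers
  smp <- assemble_samples(vm, feats, "soil-only", split_fraction = 0.8, seed = 1)
  expect_equal(sum(smp$split == "train"), 892)
  expect_equal(sum(smp$split == "val"), 224)
  expect_equal(length(smp$y), 1116)
  # determinism and partition
  smp2 <- assemble_samples(vm, feats, "soil-only", split_fraction = 0.8, seed = 1)
  expect_identical(smp$split, smp2$split)
  smp3 <- assemble_samples(vm, feats, "soil-only", split_fraction = 0.8, seed = 2)
  expect_false(identical(smp$split, smp3$split))
  expect_equal(sort(unique(as.character(smp$split))), c("train", "val"))
})

test_that("block-mean imputation fills gaps and drops empty blocks", {
  vm <- village_map(paste0("V", 1:5), c("B1", "B1", "B1", "B2", "B2"),
                    cbind(1:5, 1:5), c(40, 44, NA, NA, NA))
  out <- impute_block_yields(vm)
  expect_equal(out$yield[out$village_id == "V3"], 42)
  expect_identical(attr(out, "dropped"), c("V4", "V5"))
  expect_equal(nrow(out), 3)
})

test_that("feature counts per combination follow the source dimensions", {
  sc <- tiny_scene()
  feats <- extract_features(sc$stack, sc$zones, sc$mask,
                            sc$villages$village_id)
  counts <- list("band-weather" = c(21, 30, 0), "all-features" = c(21, 30, 10),
                 "band-only" = c(21, 0, 0), "weather-only" = c(0, 30, 0),
                 "soil-only" = c(0, 0, 10), "soil-weather" = c(0, 30, 10),
                 "band-soil" = c(21, 0, 10))
  for (cmb in names(counts)) {
    smp <- assemble_samples(sc$villages, feats, cmb, seed = 1)
    got <- c(length(smp$groups$bands), length(smp$groups$weather),
             length(smp$groups$static))
    expect_equal(got, counts[[cmb]], info = cmb)
  }
  expect_error(assemble_samples(sc$villages, feats, "nope"), "unknown combination")
})

test_that("raster and vector round-trips preserve data", {
  sc <- tiny_scene()
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "truth.asc")
  v <- sc$truth
  v[1, 1] <- NA
  write_ascii_grid(v, sc$geom, f)
  rt <- read_ascii_grid(f)
  expect_equal(rt$values, v, tolerance = 1e-6)
  expect_equal(rt$geom$res, sc$geom$res)
  # stack manifest round trip on a 2-layer subset
  sub <- raster_stack(sc$stack$values[, , 1:2], sc$geom, sc$stack$layers[1:2, ])
  write_stack(sub, file.path(tmp, "cov"))
  rt2 <- read_stack(file.path(tmp, "cov_manifest.json"))
  expect_equal(rt2$values, sub$values, tolerance = 1e-6,
               ignore_attr = "dimnames")
  expect_equal(rt2$layers$feature, sub$layers$feature)
  # village GeoJSON + CSV
  g <- file.path(tmp, "v.geojson")
  write_village_geojson(sc$villages, g)
  back <- read_village_geojson(g)
  expect_equal(back$village_id, sc$villages$village_id)
  expect_equal(back$yield, sc$villages$yield)
  csv <- file.path(tmp, "y.csv")
  write_yield_csv(sc$villages, csv)
  expect_equal(read_yield_csv(csv)$yield_q_ha, sc$villages$yield)
})
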