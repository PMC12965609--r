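#' Grid geometry of a raster
#'
#' A raster grid is described by its dimensions, the pixel size in projected
#' metres and the projected coordinate of the lower-left corner. Row 1 is the
#' northernmost row; values are stored `[row, col]`. The cell with index
#' `(r, c)` covers the half-open square `[x, x + res) x [y, y + res)` and its
#' centre is the point used for all pixel-in-polygon and distance computations.
#'
#' @param dim integer vector `c(nrow, ncol)`.
#' @param res pixel size in metres.
#' @param origin projected `c(xmin, ymin)` of the grid's lower-left corner.
#' @return An object of class `grid_geom`.
#' @export
grid_geom <- function(dim, res = 100, origin = c(0, 0)) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 2, all(dim >= 1), res > 0, length(origin) == 2)
  structure(list(nrow = dim[1], ncol = dim[2], res = res,
                 origin = as.numeric(origin)),
            class = "grid_geom")
}

#' @export
#' @method print grid_geom
print.grid_geom <- function(x, ...) {
  cat(sprintf("grid_geom: %d x %d pixels, %g m resolution, origin (%g, %g)\n",
              x$nrow, x$ncol, x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Projected coordinates of all pixel centres
#'
#' @param geom a [grid_geom()].
#' @return A two-column matrix `(x, y)` with one row per pixel in column-major
#'   order (matching `as.vector()` on a value matrix).
#' @export
pixel_coords <- function(geom) {
  stopifnot(inherits(geom, "grid_geom"))
  rows <- rep(seq_len(geom$nrow), times = geom$ncol)
  cols <- rep(seq_len(geom$ncol), each = geom$nrow)
  cbind(x = geom$origin[1] + (cols - 0.5) * geom$res,
        y = geom$origin[2] + (geom$nrow - rows + 0.5) * geom$res)
}

#' Multi-layer raster stack
#'
#' Container for aligned covariate layers sharing one grid geometry. Nodata is
#' represented by `NA` and never silently treated as zero. The layer index
#' records, for each layer, its source (`optical`, `radar`, `weather`, `soil`
#' or `mask`), feature name and time step; time steps within a source must be
#' non-decreasing in the layer order.
#'
#' @param values numeric array `[row, col, layer]`.
#' @param geom a [grid_geom()] matching the first two dimensions.
#' @param layers data frame with columns `source`, `feature`, `time` (use
#'   `NA` time for static layers), one row per layer.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(values, geom, layers) {
  if (length(dim(values)) == 2) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3,
            inherits(geom, "grid_geom"),
            dim(values)[1] == geom$nrow, dim(values)[2] == geom$ncol,
            is.data.frame(layers), nrow(layers) == dim(values)[3],
            all(c("source", "feature", "time") %in% names(layers)))
  for (key in unique(paste(layers$source, layers$feature))) {
    tt <- layers$time[paste(layers$source, layers$feature) == key]
    tt <- tt[!is.na(tt)]
    if (length(tt) > 1 && is.unsorted(tt, strictly = TRUE))
      stop("time steps for '", key, "' must be strictly ordered")
  }
  dimnames(values)[[3]] <- layer_names(layers)
  structure(list(values = values, geom = geom, layers = layers),
            class = "raster_stack")
}

layer_names <- function(layers) {
  ifelse(is.na(layers$time),
         paste(layers$source, layers$feature, sep = "."),
         paste0(layers$source, ".", layers$feature, ".t", layers$time))
}

#' @export
#' @method print raster_stack
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d x %d pixels, %d layers (%s)\n",
              x$geom$nrow, x$geom$ncol, nrow(x$layers),
              paste(sprintf("%s:%d", names(table(x$layers$source)),
                            as.integer(table(x$layers$source))),
                    collapse = ", ")))
  print(x$geom)
  invisible(x)
}

#' Extract one layer of a stack as a matrix
#'
#' @param stack a [raster_stack()].
#' @param layer layer index or layer name (`source.feature.tN`).
#' @return Numeric matrix `[row, col]`.
#' @export
get_layer <- function(stack, layer) {
  stopifnot(inherits(stack, "raster_stack"))
  stack$values[, , layer]
}

#' Average scenes into a monthly composite
#'
#' Per-pixel mean over all scenes, ignoring nodata; a composite pixel is nodata
#' only where every scene is nodata. The number of valid scenes per pixel is
#' attached as attribute `n_valid` so masking effects stay auditable.
#'
#' @param scenes list of aligned value matrices (one per acquisition).
#' @return Matrix of per-pixel means with attribute `n_valid`.
#' @export
monthly_composite <- function(scenes) {
  if (!is.list(scenes) || length(scenes) == 0)
    stop("need at least one scene")
  d <- dim(scenes[[1]])
  for (s in scenes) if (!identical(dim(s), d)) stop("mismatched grids")
  acc <- matrix(0, d[1], d[2])
  n <- matrix(0L, d[1], d[2])
  for (s in scenes) {
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    n <- n + ok
  }
  out <- acc / n
  out[n == 0L] <- NA_real_
  attr(out, "n_valid") <- n
  out
}

#' Point-in-polygon test (ray casting)
#'
#' Even-odd rule against a single (optionally closed) ring; vertices on an
#' edge follow the half-open convention implied by the crossing test, so a
#' point set laid on a regular lattice is partitioned deterministically.
#'
#' @param px,py point coordinates.
#' @param poly two-column matrix of ring vertices.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  if (all(poly[1, ] == poly[nv, ])) { poly <- poly[-nv, , drop = FALSE]; nv <- nv - 1L }
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize village polygons to a zone matrix
#'
#' Assigns each pixel whose centre falls inside a village polygon the index of
#' that village (first match wins for overlapping rings).
#'
#' @param villages a [village_map()] carrying polygons.
#' @param geom a [grid_geom()].
#' @return Integer matrix of village indices (`NA` outside all polygons).
#' @export
rasterize_villages <- function(villages, geom) {
  polys <- attr(villages, "polygons")
  if (is.null(polys)) stop("village map carries no polygons; supply a zone matrix instead")
  xy <- pixel_coords(geom)
  zone <- rep(NA_integer_, nrow(xy))
  for (i in seq_along(polys)) {
    cand <- which(is.na(zone))
    if (!length(cand)) break
    hit <- point_in_polygon(xy[cand, 1], xy[cand, 2], polys[[i]])
    zone[cand[hit]] <- i
  }
  matrix(zone, geom$nrow, geom$ncol)
}

#' Zonal aggregation of a raster layer over villages
#'
#' Mean of masked, non-nodata pixels per village. Villages with zero eligible
#' pixels are flagged (mean `NA`, `pixel_count` 0) rather than silently zeroed.
#'
#' @param values value matrix (one layer).
#' @param zones integer matrix of village indices (same shape), or a
#'   [village_map()] with polygons together with `geom`.
#' @param mask optional logical/0-1 crop-mask matrix; `NULL` keeps all pixels.
#' @param village_id character vector naming each zone index.
#' @param geom required only when `zones` is a village map.
#' @return data.frame `(village_id, mean, pixel_count)`.
#' @export
zonal_aggregate <- function(values, zones, mask = NULL, village_id = NULL,
                            geom = NULL) {
  if (inherits(zones, "village_map")) {
    if (is.null(geom)) stop("geom required to rasterize polygons")
    village_id <- zones$village_id
    zones <- rasterize_villages(zones, geom)
  }
  stopifnot(identical(dim(values), dim(zones)))
  nz <- max(zones, na.rm = TRUE)
  if (is.null(village_id)) village_id <- as.character(seq_len(nz))
  keep <- !is.na(zones) & !is.na(values)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(values)))
    keep <- keep & !is.na(mask) & mask > 0
  }
  z <- zones[keep]
  v <- values[keep]
  cnt <- tabulate(z, nbins = nz)
  sums <- rep(0, nz)
  if (length(z)) {
    agg <- rowsum(v, group = z)
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  m <- ifelse(cnt > 0, sums / cnt, NA_real_)
  out <- data.frame(village_id = village_id[seq_len(nz)], mean = m,
                    pixel_count = cnt, stringsAsFactors = FALSE)
  if (any(cnt == 0))
    attr(out, "empty_villages") <- out$village_id[cnt == 0]
  out
}

#' Zonal means of every layer in a stack
#'
#' Convenience wrapper over [zonal_aggregate()] building the per-village
#' covariate feature table used for sample assembly.
#'
#' @param stack a [raster_stack()].
#' @param zones integer zone matrix.
#' @param mask optional crop mask matrix.
#' @param village_id zone labels.
#' @return data.frame: `village_id` plus one column per layer.
#' @export
extract_features <- function(stack, zones, mask = NULL, village_id = NULL) {
  nms <- layer_names(stack$layers)
  cols <- lapply(seq_len(nrow(stack$layers)), function(i)
    zonal_aggregate(stack$values[, , i], zones, mask, village_id)$mean)
  base <- zonal_aggregate(stack$values[, , 1], zones, mask, village_id)
  out <- data.frame(village_id = base$village_id, stringsAsFactors = FALSE)
  out[nms] <- cols
  attr(out, "layers") <- stack$layers
  attr(out, "pixel_count") <- base$pixel_count
  out
}
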