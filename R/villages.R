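#' Village map
#'
#' Tabular representation of the administrative layer: one row per village
#' with its block membership, centroid in projected metres, observed yield in
#' quintal/ha (`NA` when unreported) and area in hectares. Polygon rings, when
#' available, are carried in the `polygons` attribute (list of two-column
#' matrices, one ring per village).
#'
#' @param village_id unique village identifiers.
#' @param block_id block (supervisory unit) identifier per village.
#' @param centroid two-column matrix of projected `(x, y)` centroids.
#' @param yield observed yield, quintal/ha; `NA` allowed.
#' @param area_ha village area in hectares.
#' @param polygons optional list of polygon rings.
#' @return data.frame of class `village_map`.
#' @export
village_map <- function(village_id, block_id, centroid, yield = NA_real_,
                        area_ha = NA_real_, polygons = NULL) {
  village_id <- as.character(village_id)
  if (anyDuplicated(village_id)) stop("village_id values must be unique")
  stopifnot(is.matrix(centroid), nrow(centroid) == length(village_id))
  out <- data.frame(village_id = village_id,
                    block_id = rep_len(as.character(block_id),
                                       length(village_id)),
                    cx = centroid[, 1], cy = centroid[, 2],
                    yield = rep_len(as.numeric(yield), length(village_id)),
                    area_ha = rep_len(as.numeric(area_ha), length(village_id)),
                    stringsAsFactors = FALSE)
  if (!is.null(polygons)) {
    stopifnot(length(polygons) == nrow(out))
    for (i in seq_along(polygons)) {
      p <- polygons[[i]]
      bb <- apply(p, 2, range)
      if (out$cx[i] < bb[1, 1] || out$cx[i] > bb[2, 1] ||
          out$cy[i] < bb[1, 2] || out$cy[i] > bb[2, 2])
        stop("centroid of village ", out$village_id[i],
             " falls outside its polygon bounding box")
    }
    attr(out, "polygons") <- polygons
  }
  class(out) <- c("village_map", "data.frame")
  out
}

#' @export
#' @method print village_map
print.village_map <- function(x, ...) {
  cat(sprintf("village_map: %d villages in %d blocks, %d with observed yield\n",
              nrow(x), length(unique(x$block_id)), sum(!is.na(x$yield))))
  NextMethod()
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param values value matrix (row 1 = north).
#' @param geom a [grid_geom()].
#' @param path output `.asc` file.
#' @param nodata sentinel written for `NA` cells.
#' @export
write_ascii_grid <- function(values, geom, path, nodata = -9999) {
  stopifnot(identical(dim(values), c(geom$nrow, geom$ncol)))
  hdr <- c(sprintf("ncols %d", geom$ncol),
           sprintf("nrows %d", geom$nrow),
           sprintf("xllcorner %.10g", geom$origin[1]),
           sprintf("yllcorner %.10g", geom$origin[2]),
           sprintf("cellsize %.10g", geom$res),
           sprintf("NODATA_value %g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file written by [write_ascii_grid()] or any conformant tool.
#' @return list with `values` matrix and `geom`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  list(values = v,
       geom = grid_geom(c(val[["nrows"]], val[["ncols"]]), val[["cellsize"]],
                        c(val[["xllcorner"]], val[["yllcorner"]])))
}

#' Write a raster stack as ASCII grids plus a JSON sidecar manifest
#'
#' One `.asc` file per layer plus `<stem>_manifest.json` documenting the band
#' order (source, feature, time) and grid geometry.
#'
#' @param stack a [raster_stack()].
#' @param stem path stem; files become `<stem>_<layer>.asc`.
#' @export
write_stack <- function(stack, stem) {
  nms <- layer_names(stack$layers)
  files <- character(length(nms))
  for (i in seq_along(nms)) {
    files[i] <- paste0(stem, "_", gsub("[^A-Za-z0-9_.-]", "_", nms[i]), ".asc")
    write_ascii_grid(stack$values[, , i], stack$geom, files[i])
  }
  manifest <- list(layers = cbind(stack$layers, file = basename(files)),
                   geom = stack$geom[c("nrow", "ncol", "res", "origin")])
  jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}

#' Read a raster stack from an ASCII-grid manifest
#'
#' @param manifest_path path to the `<stem>_manifest.json` written by [write_stack()].
#' @return A [raster_stack()].
#' @export
read_stack <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  lay <- man$layers
  grids <- lapply(file.path(dir, lay$file), read_ascii_grid)
  geom <- grids[[1]]$geom
  vals <- array(NA_real_, c(geom$nrow, geom$ncol, nrow(lay)))
  for (i in seq_along(grids)) vals[, , i] <- grids[[i]]$values
  raster_stack(vals, geom, lay[c("source", "feature", "time")])
}

# ---- vector & table I/O -----------------------------------------------------

#' Write a village map to GeoJSON
#'
#' Polygon features (or Point features from centroids when no polygons are
#' attached) with properties `village_id`, `block_id`, `yield_q_ha`.
#'
#' @param villages a [village_map()].
#' @param path output `.geojson` file.
#' @export
write_village_geojson <- function(villages, path) {
  polys <- attr(villages, "polygons")
  feats <- lapply(seq_len(nrow(villages)), function(i) {
    geometry <- if (is.null(polys)) {
      list(type = "Point", coordinates = c(villages$cx[i], villages$cy[i]))
    } else {
      ring <- polys[[i]]
      if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      list(type = "Polygon", coordinates = list(unname(split(ring, row(ring)[, 1]))))
    }
    list(type = "Feature",
         properties = list(village_id = villages$village_id[i],
                           block_id = villages$block_id[i],
                           yield_q_ha = villages$yield[i]),
         geometry = geometry)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a village map from GeoJSON
#'
#' @param path `.geojson` FeatureCollection with `village_id`, `block_id`,
#'   `yield_q_ha` properties; Polygon or Point geometries.
#' @return A [village_map()].
#' @export
read_village_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  n <- length(feats)
  vid <- character(n); bid <- character(n); yld <- rep(NA_real_, n)
  cent <- matrix(NA_real_, n, 2)
  polys <- vector("list", n)
  has_poly <- FALSE
  for (i in seq_len(n)) {
    f <- feats[[i]]
    vid[i] <- as.character(f$properties$village_id)
    bid[i] <- as.character(f$properties$block_id)
    y <- f$properties$yield_q_ha
    yld[i] <- if (is.null(y)) NA_real_ else as.numeric(y)
    g <- f$geometry
    if (identical(g$type, "Point")) {
      cent[i, ] <- unlist(g$coordinates)
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], unlist))
      polys[[i]] <- ring
      has_poly <- TRUE
      cent[i, ] <- colMeans(ring[-nrow(ring), , drop = FALSE])
    } else stop("unsupported geometry type: ", g$type)
  }
  village_map(vid, bid, cent, yld,
              polygons = if (has_poly) polys else NULL)
}

#' Write / read the village yield table (CSV)
#'
#' Fixed headers `village_id, block_id, yield_q_ha`.
#'
#' @param villages a [village_map()].
#' @param path CSV path.
#' @export
write_yield_csv <- function(villages, path) {
  utils::write.csv(data.frame(village_id = villages$village_id,
                              block_id = villages$block_id,
                              yield_q_ha = villages$yield),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_yield_csv
#' @export
read_yield_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("village_id", "block_id", "yield_q_ha")
  if (!all(need %in% names(df))) stop("yield CSV must have headers: ",
                                      paste(need, collapse = ", "))
  df$village_id <- as.character(df$village_id)
  df
}
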