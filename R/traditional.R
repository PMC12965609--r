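#' Normalized difference vegetation index
#'
#' `(NIR - Red) / (NIR + Red)`, nodata where the denominator is zero.
#'
#' @param nir,red aligned reflectance matrices.
#' @return NDVI matrix in `[-1, 1]`.
#' @export
ndvi_map <- function(nir, red) {
  if (!identical(dim(nir), dim(red))) stop("mismatched grids")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Seasonal NDVI from a covariate stack
#'
#' NDVI computed from the temporally aggregated NIR and Red optical layers —
#' the mean composite across time steps by default, or the per-pixel peak.
#'
#' @param stack a [raster_stack()] with optical `B8` (NIR) and `B4` (Red) layers.
#' @param fun `"mean"` or `"peak"` temporal aggregation.
#' @return NDVI matrix.
#' @export
seasonal_ndvi <- function(stack, fun = c("mean", "peak")) {
  fun <- match.arg(fun)
  pick <- function(feat) {
    sel <- which(stack$layers$source == "optical" & stack$layers$feature == feat)
    if (!length(sel)) stop("stack lacks optical layer ", feat)
    arr <- stack$values[, , sel, drop = FALSE]
    if (fun == "mean") apply(arr, c(1, 2), mean) else apply(arr, c(1, 2), max)
  }
  ndvi_map(pick("B8"), pick("B4"))
}

#' NDVI weight-based production allocation
#'
#' Distributes the administrative unit's reported production over its pixels
#' proportionally to NDVI: `alloc_p = NDVI_p / sum(NDVI) * P`. Allocations
#' sum to `P` exactly (mass conservation). Units whose NDVI sum is zero or
#' negative are flagged and left nodata — no silent uniform fallback.
#'
#' @param ndvi NDVI matrix.
#' @param production named vector of production `P` per unit (quintal).
#' @param zones integer zone matrix over the same grid.
#' @param mask optional crop mask.
#' @param unit_id zone labels matching `names(production)`.
#' @return Allocation matrix; attribute `flagged` lists degenerate units.
#' @export
weight_based_disagg <- function(ndvi, production, zones, mask = NULL,
                                unit_id = NULL) {
  nz <- max(zones, na.rm = TRUE)
  if (is.null(unit_id)) unit_id <- as.character(seq_len(nz))
  p <- production[unit_id]
  keep <- !is.na(zones) & !is.na(ndvi)
  if (!is.null(mask)) keep <- keep & !is.na(mask) & mask > 0
  out <- matrix(NA_real_, nrow(ndvi), ncol(ndvi))
  flagged <- character(0)
  for (i in seq_len(nz)) {
    sel <- keep & zones == i
    s <- sum(ndvi[sel])
    if (!is.finite(s) || s <= 0) { flagged <- c(flagged, unit_id[i]); next }
    out[sel] <- ndvi[sel] / s * p[i]
  }
  attr(out, "flagged") <- flagged
  out
}

#' Percentile-based yield scaling
#'
#' Linear rescaling of pixel NDVI by the unit's yield and NDVI spread:
#' `yield_p = (Maxyield - Minyield) / (MaxNDVI95 - MinNDVI5) * NDVI_p`,
#' with the 95th/5th NDVI percentiles taken from the unit's own masked NDVI
#' distribution. The formula is a pure slope (no intercept term): NDVI of
#' zero maps to zero yield, so the output range is not anchored at
#' `Minyield` — a property of the published scaling kept deliberately.
#'
#' @param ndvi NDVI matrix.
#' @param max_yield,min_yield yield bounds for the unit, quintal/ha.
#' @param zones optional zone matrix to apply per unit (with per-unit
#'   percentiles); `NULL` treats the whole masked grid as one unit.
#' @param mask optional crop mask.
#' @return Pixel yield matrix.
#' @export
percentile_based_disagg <- function(ndvi, max_yield, min_yield, zones = NULL,
                                    mask = NULL) {
  keep <- !is.na(ndvi)
  if (!is.null(mask)) keep <- keep & !is.na(mask) & mask > 0
  out <- matrix(NA_real_, nrow(ndvi), ncol(ndvi))
  apply_unit <- function(sel, mx, mn) {
    q <- stats::quantile(ndvi[sel], c(0.05, 0.95), names = FALSE)
    if (q[2] <= q[1]) stop("degenerate NDVI distribution (MaxNDVI95 <= MinNDVI5)")
    out[sel] <<- (mx - mn) / (q[2] - q[1]) * ndvi[sel]
  }
  if (is.null(zones)) {
    apply_unit(keep, max_yield, min_yield)
  } else {
    nz <- max(zones, na.rm = TRUE)
    mx <- rep_len(max_yield, nz); mn <- rep_len(min_yield, nz)
    for (i in seq_len(nz)) {
      sel <- keep & !is.na(zones) & zones == i
      if (any(sel)) apply_unit(sel, mx[i], mn[i])
    }
  }
  out
}

#' Area-to-point kriging surrogate
#'
#' Disaggregates village yields to pixels without covariates: ordinary
#' kriging of the village yields from their centroids to pixel centres, the
#' centroid surrogate for area-to-point kriging. Exact at centroids when the
#' variogram nugget is zero.
#'
#' @param villages a [village_map()] with observed yields.
#' @param geom target [grid_geom()].
#' @param vm optional [variogram_model()]; fitted to the village yields by
#'   cross-validated selection when omitted.
#' @param mask optional crop mask.
#' @return Yield matrix; the variogram used is attached as attribute `vm`.
#' @export
atpk_disagg <- function(villages, geom, vm = NULL, mask = NULL) {
  ok <- !is.na(villages$yield)
  if (sum(ok) < 3) stop("need at least 3 villages with yields")
  field <- structure(list(coords = cbind(villages$cx, villages$cy)[ok, ],
                          residual = villages$yield[ok]),
                     class = "residual_field")
  if (is.null(vm)) {
    vm <- if (sum(ok) >= 10) {
      sel <- select_variogram_cv(field)
      sel$models[[sel$selected]]
    } else {
      fit_variogram(empirical_semivariogram(field, n_lags = 8), "linear")
    }
  }
  out <- krige_residual_surface(field, vm, geom, mask)
  attr(out, "vm") <- vm
  out
}
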