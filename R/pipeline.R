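#' Hybrid village-to-pixel downscaling with residual kriging
#'
#' The end-to-end workflow on one landscape: assemble village samples from
#' zonal covariate means, fit the chosen downscaling model, predict pixel
#' yields, aggregate back to villages, krige the village residuals under a
#' cross-validation-selected semivariogram and add the kriged surface back.
#' Returns every intermediate needed for validation and diagnosis.
#'
#' @param scene a `synthetic_scene`, or a list with elements `stack`
#'   ([raster_stack()]), `zones` (integer matrix), `mask`, `villages`
#'   ([village_map()]) and `geom`.
#' @param method model family passed to [fit_yield_model()].
#' @param combination dataset combination id.
#' @param config a [train_config()] for recurrent methods.
#' @param variogram_types candidate types for residual-kriging selection.
#' @param kriging set `FALSE` to stop after the uncorrected surface.
#' @param split_fraction,seed sample-assembly controls.
#' @param morans_k,morans_perms Moran's I neighbours and permutations for the
#'   residual diagnostics.
#' @return Object of class `hybrid_downscale` with the fitted `model`,
#'   rasters (`predicted`, `residual_surface`, `corrected`), the residual
#'   field, variogram CV table, Moran diagnostics and a
#'   [validation_report()] comparing the uncorrected and corrected surfaces.
#' @export
hybrid_downscale <- function(scene, method = "gru",
                             combination = "band-weather",
                             config = train_config(),
                             variogram_types = c("linear", "spherical",
                                                 "gaussian", "exponential"),
                             kriging = TRUE, split_fraction = 0.8, seed = 1L,
                             morans_k = 8, morans_perms = 999) {
  stopifnot(!is.null(scene$stack), !is.null(scene$zones),
            !is.null(scene$villages), !is.null(scene$geom))
  features <- extract_features(scene$stack, scene$zones, scene$mask,
                               village_id = scene$villages$village_id)
  samples <- assemble_samples(scene$villages, features, combination,
                              split_fraction, seed)
  model <- fit_yield_model(samples, method, config = config, seed = seed)
  predicted <- predict_pixel_yield(model, scene$stack, scene$mask)
  agg <- aggregate_to_admin(predicted, scene$zones, scene$mask,
                            unit_id = scene$villages$village_id)
  field <- compute_residuals(scene$villages, agg)
  moran_before <- morans_i(field$residual, knn_weights(field$coords, morans_k),
                           n_permutations = morans_perms, seed = seed)
  out <- list(model = model, samples = samples, predicted = predicted,
              aggregated = agg, residual_field = field,
              moran_before = moran_before, geom = scene$geom,
              zones = scene$zones, mask = scene$mask,
              villages = scene$villages, seed = seed)
  if (kriging) {
    sel <- select_variogram_cv(field, types = variogram_types)
    vm <- sel$models[[sel$selected]]
    residual_surface <- krige_residual_surface(field, vm, scene$geom,
                                               scene$mask)
    corrected <- correct_yield_surface(predicted, residual_surface)
    agg_c <- aggregate_to_admin(corrected, scene$zones, scene$mask,
                                unit_id = scene$villages$village_id)
    field_c <- compute_residuals(scene$villages, agg_c)
    moran_after <- morans_i(field_c$residual,
                            knn_weights(field_c$coords, morans_k),
                            n_permutations = morans_perms, seed = seed)
    out <- c(out, list(variogram_cv = sel, variogram = vm,
                       residual_surface = residual_surface,
                       corrected = corrected,
                       residual_field_corrected = field_c,
                       moran_after = moran_after))
    surfaces <- list(uncorrected = predicted, corrected = corrected)
  } else {
    surfaces <- list(uncorrected = predicted)
  }
  out$report <- validation_report(surfaces, scene$villages, scene$zones,
                                  scene$mask, p = ncol(samples$X))
  class(out) <- "hybrid_downscale"
  out
}

#' @export
#' @method print hybrid_downscale
print.hybrid_downscale <- function(x, ...) {
  cat(sprintf("hybrid_downscale: %s on '%s'%s\n", x$model$method,
              x$model$combination,
              if (!is.null(x$corrected))
                sprintf(" + residual kriging (%s variogram)", x$variogram$type)
              else " (no kriging)"))
  cat(sprintf("  residual Moran's I %.3f (p = %.3g)%s\n",
              x$moran_before$I, x$moran_before$p_value,
              if (!is.null(x$moran_after))
                sprintf(" -> %.3f (p = %.3g) after correction",
                        x$moran_after$I, x$moran_after$p_value) else ""))
  print(x$report)
  invisible(x)
}

#' @export
#' @method summary hybrid_downscale
summary.hybrid_downscale <- function(object, ...) {
  print(object)
  if (!is.null(object$variogram_cv)) {
    cat("Variogram LOO-CV RMSE (quintal/ha):\n")
    print(round(object$variogram_cv$cv_rmse, 4))
  }
  invisible(object)
}

#' @export
plot.hybrid_downscale <- function(x, which = c("corrected", "predicted",
                                               "residual_surface"), ...) {
  which <- match.arg(which)
  m <- x[[which]]
  if (is.null(m)) stop("surface '", which, "' not available")
  graphics::image(t(m[nrow(m):1, ]), axes = FALSE, main = which,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Run the full pipeline and write its artifact bundle
#'
#' Orchestrates simulate -> assemble -> fit -> predict -> aggregate ->
#' residual kriging -> validate and writes every product (ASCII-grid rasters,
#' CSV tables, JSON run manifest) under `out_dir`. Re-running with the same
#' configuration and seed reproduces the same files.
#'
#' @param scene_cfg a [scene_config()] describing the landscape to simulate
#'   (or an already generated `synthetic_scene`).
#' @param out_dir output directory (created if needed).
#' @param method,combination,kriging,seed forwarded to [hybrid_downscale()].
#' @param config a [train_config()].
#' @param quiet suppress stage logging.
#' @return The [hybrid_downscale()] result, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(scene_cfg, out_dir, method = "gru",
                         combination = "band-weather",
                         config = train_config(), kriging = TRUE,
                         seed = 1L, quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- if (inherits(scene_cfg, "synthetic_scene")) scene_cfg else
    generate_scene(scene_cfg)
  log_stage("scene: %d x %d pixels, %d villages",
            scene$geom$nrow, scene$geom$ncol, nrow(scene$villages))
  hd <- hybrid_downscale(scene, method = method, combination = combination,
                         config = config, kriging = kriging, seed = seed)
  log_stage("model: %s, %d train / %d val villages", method,
            sum(hd$samples$split == "train"), sum(hd$samples$split == "val"))
  write_ascii_grid(hd$predicted, scene$geom,
                   file.path(out_dir, "predicted_yield.asc"))
  if (kriging) {
    write_ascii_grid(hd$residual_surface, scene$geom,
                     file.path(out_dir, "residual_surface.asc"))
    write_ascii_grid(hd$corrected, scene$geom,
                     file.path(out_dir, "corrected_yield.asc"))
    utils::write.csv(data.frame(type = names(hd$variogram_cv$cv_rmse),
                                cv_rmse = as.numeric(hd$variogram_cv$cv_rmse),
                                selected = names(hd$variogram_cv$cv_rmse) ==
                                  hd$variogram_cv$selected),
                     file.path(out_dir, "variogram_cv.csv"), row.names = FALSE)
    log_stage("kriging: %s variogram selected", hd$variogram_cv$selected)
  }
  write_yield_csv(scene$villages, file.path(out_dir, "village_yields.csv"))
  utils::write.csv(hd$report$village, file.path(out_dir, "validation_village.csv"),
                   row.names = FALSE)
  utils::write.csv(hd$report$block, file.path(out_dir, "validation_block.csv"),
                   row.names = FALSE)
  manifest <- list(method = method, combination = combination, seed = seed,
                   kriging = kriging,
                   n_villages = nrow(scene$villages),
                   grid = c(scene$geom$nrow, scene$geom$ncol),
                   scene_config = if (inherits(scene_cfg, "scene_config"))
                     unclass(scene_cfg) else unclass(scene$config),
                   train = unclass(config),
                   moran_before = hd$moran_before[c("I", "p_value")],
                   moran_after = if (kriging) hd$moran_after[c("I", "p_value")])
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage("artifacts written to %s", out_dir)
  invisible(hd)
}
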