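#' Dataset combinations
#'
#' The covariate sources included under each screening combination. Band
#' features are the optical plus radar time series; weather and soil enter as
#' their own groups.
#'
#' @return Named list mapping combination id to included sources.
#' @export
dataset_combinations <- function() {
  list("all-features" = c("optical", "radar", "weather", "soil"),
       "band-weather" = c("optical", "radar", "weather"),
       "band-soil"    = c("optical", "radar", "soil"),
       "soil-weather" = c("weather", "soil"),
       "band-only"    = c("optical", "radar"),
       "weather-only" = "weather",
       "soil-only"    = "soil")
}

#' Impute missing village yields from block averages
#'
#' Missing yields are replaced by the mean of reported yields in the same
#' block; villages in blocks where no yield is reported at all are dropped.
#'
#' @param villages a [village_map()].
#' @return The village map with yields imputed, attribute `n_imputed` /
#'   `dropped` recording what happened.
#' @export
impute_block_yields <- function(villages) {
  blk_mean <- tapply(villages$yield, villages$block_id,
                     function(v) mean(v, na.rm = TRUE))
  miss <- is.na(villages$yield)
  fill <- blk_mean[villages$block_id[miss]]
  villages$yield[miss] <- as.numeric(fill)
  dropped <- villages$village_id[is.na(villages$yield)]
  out <- villages[!is.na(villages$yield), , drop = FALSE]
  attr(out, "polygons") <- attr(villages, "polygons")[!is.na(villages$yield)]
  attr(out, "n_imputed") <- sum(miss) - length(dropped)
  attr(out, "dropped") <- dropped
  out
}

#' Assemble village-level model samples
#'
#' Joins the per-village covariate feature table to observed yields, imputes
#' missing yields from block means (before splitting), restricts features to
#' the requested dataset combination and draws a seed-reproducible random
#' train/validation split with `floor(split_fraction * n)` training samples.
#'
#' @param villages a [village_map()] (yields may contain `NA`).
#' @param features feature table from [extract_features()] (or any data.frame
#'   with a `village_id` column and a `layers` attribute describing columns).
#' @param combination one of the ids in [dataset_combinations()].
#' @param split_fraction fraction assigned to training (default 0.8).
#' @param seed integer seed controlling the split.
#' @return Object of class `village_samples`: feature matrix `X`, grouped
#'   column indices (`bands`, `weather`, `static`), response `y`, ids, blocks,
#'   centroids and the split factor.
#' @export
assemble_samples <- function(villages, features, combination = "band-weather",
                             split_fraction = 0.8, seed = 1L) {
  combos <- dataset_combinations()
  if (!combination %in% names(combos))
    stop("unknown combination '", combination, "'; expected one of: ",
         paste(names(combos), collapse = ", "))
  sources <- combos[[combination]]
  villages <- impute_block_yields(villages)
  idx <- match(villages$village_id, features$village_id)
  if (anyNA(idx)) stop("villages missing from feature table: ",
                       paste(villages$village_id[is.na(idx)], collapse = ", "))
  layers <- attr(features, "layers")
  if (is.null(layers)) stop("feature table lacks a 'layers' attribute")
  fmat <- as.matrix(features[idx, layer_names(layers), drop = FALSE])
  keep <- layers$source %in% sources
  layers <- layers[keep, , drop = FALSE]
  fmat <- fmat[, keep, drop = FALSE]
  if (anyNA(fmat)) {
    bad <- villages$village_id[rowSums(is.na(fmat)) > 0]
    stop("missing feature values after assembly for villages: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  n <- nrow(fmat)
  set.seed(seed)
  n_train <- floor(split_fraction * n)
  train_idx <- sample.int(n, n_train)
  split <- factor(rep("val", n), levels = c("train", "val"))
  split[train_idx] <- "train"
  grp <- list(bands = which(layers$source %in% c("optical", "radar")),
              weather = which(layers$source == "weather"),
              static = which(layers$source == "soil"))
  structure(list(X = fmat, layers = layers, groups = grp,
                 y = villages$yield,
                 village_id = villages$village_id,
                 block_id = villages$block_id,
                 centroid = cbind(villages$cx, villages$cy),
                 split = split, combination = combination,
                 split_fraction = split_fraction, seed = seed),
            class = "village_samples")
}

#' @export
#' @method print village_samples
print.village_samples <- function(x, ...) {
  cat(sprintf(paste0("village_samples: %d villages (%d train / %d val), ",
                     "combination '%s'\n  features: %d bands + %d weather + %d soil\n"),
              length(x$y), sum(x$split == "train"), sum(x$split == "val"),
              x$combination, length(x$groups$bands), length(x$groups$weather),
              length(x$groups$static)))
  invisible(x)
}

#' Subset samples by split
#'
#' @param samples a `village_samples` object.
#' @param which `"train"`, `"val"` or `"all"`.
#' @return A `village_samples` object restricted to the requested rows.
#' @export
sample_split <- function(samples, which = c("train", "val", "all")) {
  which <- match.arg(which)
  if (which == "all") return(samples)
  keep <- samples$split == which
  out <- samples
  out$X <- samples$X[keep, , drop = FALSE]
  out$y <- samples$y[keep]
  out$village_id <- samples$village_id[keep]
  out$block_id <- samples$block_id[keep]
  out$centroid <- samples$centroid[keep, , drop = FALSE]
  out$split <- samples$split[keep]
  out
}

#' Reshape grouped features into recurrent-branch arrays
#'
#' Bands and weather columns are rearranged into `[n, T, F]` arrays keyed by
#' the layer index's time and feature labels; static columns stay a matrix.
#' A leading crop-indicator column (all ones) is prepended to the static
#' block so the static branch always carries at least one feature.
#'
#' @param X feature matrix with columns described by `layers`.
#' @param layers layer index data.frame (`source`, `feature`, `time`).
#' @param groups grouped column indices as in `village_samples`.
#' @return list `bands` (array), `weather` (array), `static` (matrix).
#' @export
branch_arrays <- function(X, layers, groups) {
  to_array <- function(cols) {
    if (!length(cols)) return(NULL)
    sub <- layers[cols, , drop = FALSE]
    times <- sort(unique(sub$time))
    feats <- unique(sub$feature)
    arr <- array(NA_real_, c(nrow(X), length(times), length(feats)),
                 dimnames = list(NULL, paste0("t", times), feats))
    for (j in seq_along(cols)) {
      ti <- match(sub$time[j], times); fi <- match(sub$feature[j], feats)
      arr[, ti, fi] <- X[, cols[j]]
    }
    if (anyNA(arr)) stop("incomplete time x feature grid in branch")
    arr
  }
  static <- cbind(crop = rep(1, nrow(X)),
                  X[, groups$static, drop = FALSE])
  list(bands = to_array(groups$bands),
       weather = to_array(groups$weather),
       static = static)
}
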