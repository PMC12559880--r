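#' Per-site magnitude of SOC stock change
#'
#' For each site with applicability-screened changes in all four mineral
#' strata, the sum of absolute stock changes over the strata — the target of
#' the post-hoc driver model. Records of both directions of a land-use pair
#' are pooled by passing their row-bound `deltas` tables.
#'
#' @param deltas A `delta_records` data.frame (rows of one or both directions
#'   of a pair).
#' @return data.frame `site_id, direction, magnitude` (Mg C ha-1); sites
#'   missing any mineral stratum are dropped.
#' @export
magnitude_target <- function(deltas) {
  d <- deltas[deltas$in_aoa & deltas$stratum %in% .mineral_strata(), ,
              drop = FALSE]
  key <- paste(d$site_id, d$direction)
  n_strata <- tapply(d$stratum, key, function(s) length(unique(s)))
  mag <- tapply(abs(d$delta), key, sum)
  ok <- names(n_strata)[n_strata == length(.mineral_strata())]
  first <- d[!duplicated(key), , drop = FALSE]
  rownames(first) <- paste(first$site_id, first$direction)
  out <- data.frame(site_id = first[ok, "site_id"],
                    direction = first[ok, "direction"],
                    magnitude = as.numeric(mag[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble the driver-model frame for a land-use pair
#'
#' Joins the pooled change magnitudes with the mechanistic site predictors:
#' profile-level texture (fine-soil-stock-weighted mean clay and silt over
#' the harmonized increments), coarse fraction, climate, groundwater, NDVI,
#' terrain and the WRB reference soil group.
#'
#' @param magnitudes Output of [magnitude_target()].
#' @param inv The harmonized `soc_inventory` the magnitudes came from.
#' @return data.frame with `target` (the magnitude) and the driver
#'   predictors, plus coordinates for spatial blocking.
#' @export
driver_frame <- function(magnitudes, inv) {
  s <- inv$sites[match(magnitudes$site_id, inv$sites$site_id), , drop = FALSE]
  inc <- inv$increments
  w <- inc$bd_fine * (1 - inc$rff) * (inc$bottom_cm - inc$top_cm)
  prof_mean <- function(col) {
    num <- tapply(inc[[col]] * w, inc$site_id, sum)
    den <- tapply(w, inc$site_id, sum)
    as.numeric((num / den)[as.character(magnitudes$site_id)])
  }
  out <- data.frame(
    site_id = magnitudes$site_id, target = magnitudes$magnitude,
    direction = magnitudes$direction,
    x = s$x, y = s$y,
    clay_pct = prof_mean("clay_pct"), silt_pct = prof_mean("silt_pct"),
    coarse_frac = s$coarse_frac, map_mm = s$map_mm, mat_c = s$mat_c,
    drought_index = s$drought_index, ndvi = s$ndvi,
    slope_deg = s$slope_deg, elevation_m = s$elevation_m,
    wrb_group = s$wrb_group, groundwater_class = s$groundwater_class,
    stringsAsFactors = FALSE
  )
  out
}

#' Fit the post-hoc driver model of SOC-change magnitude
#'
#' The same stacked-ensemble machinery as the counterfactual models, with the
#' predictor set restricted to variables with established mechanistic links
#' to SOC change. Its permutation importances and accumulated local effects
#' are the interpretive output.
#'
#' @param frame A [driver_frame()] (or any frame with `target`, coordinates
#'   and the driver predictors).
#' @param control A [direction_control()] supplying the fold-plan and
#'   ensemble settings.
#' @param seed RNG seed.
#' @return A `soc_ensemble`.
#' @export
fit_driver_model <- function(frame, control = direction_control(), seed = 1L) {
  plan <- assign_spatial_folds(frame$x, frame$y, cell_size = control$cell_size,
                               k = control$k, repeats = control$repeats,
                               seed = seed)
  soc_ensemble(frame, predictor_spec("driver"), plan,
               control = control$ensemble, seed = seed + 1L)
}

.model_predict <- function(object, data, predict_fun = NULL) {
  if (!is.null(predict_fun)) return(as.numeric(predict_fun(object, data)))
  if (inherits(object, "soc_ensemble")) return(predict(object, data)$pred)
  as.numeric(predict(object, data))
}

#' Accumulated local effects of a numeric predictor
#'
#' Quantile-binned first-order ALE: within each bin the model is evaluated at
#' the bin's upper and lower edge (all other predictors held at their
#' observed values), local differences are averaged per bin, accumulated over
#' bins, and centred so that the count-weighted mean effect over the data is
#' zero.
#'
#' @param object A fitted model (a `soc_ensemble`, or anything `predict`able;
#'   override with `predict_fun(object, data)`).
#' @param data Data to evaluate on (must carry the feature).
#' @param feature Feature name.
#' @param n_bins Number of quantile bins (default 20).
#' @param predict_fun Optional prediction function.
#' @return An `ale_curve`: data.frame `edge, effect, centered, count` (the
#'   count is the number of points in the bin below each edge; 0 for the
#'   first edge).
#' @export
ale_numeric <- function(object, data, feature, n_bins = 20,
                        predict_fun = NULL) {
  x <- as.numeric(data[[feature]])
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7, names = FALSE))
  if (length(edges) < 2) {
    warning("ale_numeric: constant feature '", feature, "'; flat curve",
            call. = FALSE)
    curve <- data.frame(edge = edges, effect = 0, centered = 0, count = 0)
    return(structure(list(feature = feature, kind = "numeric", curve = curve),
                     class = "ale_curve"))
  }
  k <- findInterval(x, edges, all.inside = TRUE)   # bin 1..K
  K <- length(edges) - 1
  delta <- numeric(K); count <- numeric(K)
  for (b in seq_len(K)) {
    idx <- which(k == b)
    count[b] <- length(idx)
    if (!length(idx)) next
    hi <- data[idx, , drop = FALSE]; hi[[feature]] <- edges[b + 1]
    lo <- data[idx, , drop = FALSE]; lo[[feature]] <- edges[b]
    delta[b] <- mean(.model_predict(object, hi, predict_fun) -
                       .model_predict(object, lo, predict_fun))
  }
  acc <- c(0, cumsum(delta))                       # effect at each edge
  center <- sum(count * acc[-1]) / sum(count)      # points sit at upper edges
  curve <- data.frame(edge = edges, effect = acc, centered = acc - center,
                      count = c(0, count))
  structure(list(feature = feature, kind = "numeric", curve = curve),
            class = "ale_curve")
}

#' Accumulated local effects of a categorical predictor
#'
#' Categories are ordered by their within-category target mean (model
#' predictions unless an observed target is supplied); adjacent-category
#' local differences are averaged over the points of the two categories,
#' accumulated along the order, and centred by the count-weighted mean.
#'
#' @param object Fitted model (see [ale_numeric()]).
#' @param data Data to evaluate on.
#' @param feature Categorical feature name.
#' @param target Optional observed target used for ordering.
#' @param predict_fun Optional prediction function.
#' @return An `ale_curve` with `curve`: `category, centered, count`.
#' @export
ale_categorical <- function(object, data, feature, target = NULL,
                            predict_fun = NULL) {
  v <- as.character(data[[feature]])
  ord_by <- if (is.null(target)) .model_predict(object, data, predict_fun)
  else as.numeric(target)
  cat_means <- tapply(ord_by, v, mean)
  cats <- names(sort(cat_means))
  count <- as.numeric(table(v)[cats])
  if (length(cats) < 2) {
    curve <- data.frame(category = cats, centered = 0, count = count)
    return(structure(list(feature = feature, kind = "categorical",
                          curve = curve), class = "ale_curve"))
  }
  delta <- numeric(length(cats) - 1)
  for (j in seq_along(delta)) {
    idx <- which(v %in% cats[c(j, j + 1)])
    hi <- data[idx, , drop = FALSE]; hi[[feature]] <- cats[j + 1]
    lo <- data[idx, , drop = FALSE]; lo[[feature]] <- cats[j]
    delta[j] <- mean(.model_predict(object, hi, predict_fun) -
                       .model_predict(object, lo, predict_fun))
  }
  acc <- c(0, cumsum(delta))
  centered <- acc - sum(count * acc) / sum(count)
  curve <- data.frame(category = cats, centered = centered, count = count,
                      stringsAsFactors = FALSE)
  structure(list(feature = feature, kind = "categorical", curve = curve),
            class = "ale_curve")
}

#' @export
print.ale_curve <- function(x, ...) {
  cat("ALE curve for", x$kind, "feature '", x$feature, "'\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}
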