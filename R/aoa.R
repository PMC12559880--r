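#' Build an area-of-applicability model
#'
#' Represents each training site as a point in importance-weighted,
#' standardised predictor space: numeric predictors are z-scored by training
#' mean/SD (zero-variance predictors are dropped with a warning), categorical
#' predictors are one-hot encoded, and every coordinate is multiplied by its
#' predictor's weight — the max-normalised, zero-clipped permutation
#' importance. The dissimilarity index (DI) of a point is its Euclidean
#' distance to the nearest training point divided by the mean pairwise
#' training distance. The applicability threshold is derived from the
#' cross-validated training DI distribution (each training site's nearest
#' neighbour excludes sites of its own CV fold): by default its 0.95 quantile
#' (type 7); alternatively the Tukey upper whisker.
#'
#' @param data Training data (the alternate-land-use group's model frame).
#' @param spec The model's [predictor_spec()].
#' @param importances Named importance vector (raw or normalised) over the
#'   spec's predictors.
#' @param fold Optional integer fold id per training row for the
#'   leave-own-fold-out training DI; `NULL` excludes only the point itself.
#' @param threshold One of `"quantile"` (0.95 quantile) or `"whisker"`
#'   (Tukey upper whisker `Q3 + 1.5 IQR`).
#' @return An `aoa_model` with the weighted training matrix, scaling
#'   parameters, mean pairwise distance `d_bar`, training DI distribution and
#'   threshold `tau`.
#' @export
build_aoa <- function(data, spec, importances, fold = NULL,
                      threshold = c("quantile", "whisker")) {
  threshold <- match.arg(threshold)
  if (nrow(data) < 2) stop("build_aoa: need at least 2 training sites", call. = FALSE)
  num <- spec$numeric
  sds <- vapply(num, function(p) sd(data[[p]], na.rm = TRUE), numeric(1))
  drop <- num[is.na(sds) | sds == 0]
  if (length(drop)) {
    warning("build_aoa: dropping zero-variance predictor(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
    num <- setdiff(num, drop)
  }
  w_all <- pmax(importances[c(num, spec$categorical)], 0)
  w_all[is.na(w_all)] <- 0
  if (max(w_all) > 0) w_all <- w_all / max(w_all)
  means <- vapply(num, function(p) mean(data[[p]], na.rm = TRUE), numeric(1))
  sds <- vapply(num, function(p) sd(data[[p]], na.rm = TRUE), numeric(1))
  cat_lv <- lapply(spec$categorical, function(p)
    sort(unique(as.character(data[[p]]))))
  names(cat_lv) <- spec$categorical
  model <- structure(list(
    numeric = num, categorical = spec$categorical,
    means = means, sds = sds, levels = cat_lv, w = w_all,
    threshold_method = threshold
  ), class = "aoa_model")
  M <- aoa_encode(model, data)
  d2 <- as.matrix(dist(M))^2
  d <- sqrt(d2)
  model$train <- M
  model$d_bar <- mean(d[upper.tri(d)])
  if (model$d_bar == 0) model$d_bar <- 1   # all training points identical
  diag(d) <- Inf
  if (!is.null(fold)) {
    same <- outer(fold, fold, "==")
    d[same] <- Inf
  }
  model$train_di <- unname(apply(d, 1, min)) / model$d_bar
  model$train_di[!is.finite(model$train_di)] <- NA
  di <- model$train_di[is.finite(model$train_di)]
  model$tau <- if (threshold == "quantile") {
    quantile(di, 0.95, type = 7, names = FALSE)
  } else {
    quantile(di, 0.75, type = 7, names = FALSE) + 1.5 * IQR(di, type = 7)
  }
  model
}

aoa_encode <- function(model, data) {
  cols <- list()
  for (p in model$numeric) {
    v <- (as.numeric(data[[p]]) - model$means[[p]]) / model$sds[[p]]
    v[is.na(v)] <- 0
    cols[[p]] <- v * model$w[[p]]
  }
  for (p in model$categorical) {
    v <- as.character(data[[p]])
    for (l in model$levels[[p]]) {
      cols[[paste0(p, "=", l)]] <- as.numeric(!is.na(v) & v == l) * model$w[[p]]
    }
  }
  do.call(cbind, cols)
}

#' @export
print.aoa_model <- function(x, ...) {
  cat("Area-of-applicability model: ", nrow(x$train), " training points, ",
      length(x$numeric) + length(x$categorical), " predictors\n",
      "  mean pairwise distance d_bar = ", signif(x$d_bar, 4),
      ", threshold tau = ", signif(x$tau, 4), " (", x$threshold_method, ")\n",
      sep = "")
  invisible(x)
}

#' Dissimilarity index of new sites
#'
#' Distance of each new point to its nearest training point in the weighted
#' standardised predictor space, divided by the mean pairwise training
#' distance. `DI = 0` iff the point coincides with a training point.
#'
#' @param model An [build_aoa()] model.
#' @param newdata Data carrying the model's predictors.
#' @return Numeric DI per row of `newdata`.
#' @export
di_of <- function(model, newdata) {
  N <- aoa_encode(model, newdata)
  Tr <- model$train
  # squared cross-distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  d2 <- outer(rowSums(N^2), rowSums(Tr^2), "+") - 2 * tcrossprod(N, Tr)
  sqrt(pmax(apply(d2, 1, min), 0)) / model$d_bar
}

#' Mask new sites by area of applicability
#'
#' @param model An `aoa_model`.
#' @param newdata Data carrying the model's predictors.
#' @param tau Threshold override (e.g. `Inf` to retain everything).
#' @return List with `in_aoa` (logical), `di`, `n_in`, `n_out`.
#' @export
aoa_mask <- function(model, newdata, tau = model$tau) {
  di <- di_of(model, newdata)
  keep <- di <= tau
  list(in_aoa = keep, di = di, n_in = sum(keep), n_out = sum(!keep))
}
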