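#' Percentile bootstrap confidence interval of a mean
#'
#' Resamples the values with replacement `n_boot` times and returns the
#' percentile interval (type-7 quantiles) of the resampled means.
#' Deterministic given the seed.
#'
#' @param values Numeric vector, length >= 2.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return Named vector `c(mean, low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 10000, level = 0.95, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("bootstrap_ci: need at least 2 values", call. = FALSE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  means <- rowMeans(matrix(values[idx], nrow = n_boot))
  a <- (1 - level) / 2
  q <- quantile(means, c(a, 1 - a), type = 7, names = FALSE)
  c(mean = mean(values), low = q[1], high = q[2])
}

# totals arithmetic shared by the full summariser and the printed-means check
.mineral_strata <- function() stratum_labels(litter = FALSE)

totals_from_means <- function(means) {
  mineral <- .mineral_strata()
  stopifnot(all(mineral %in% names(means)))
  mineral_total <- sum(unlist(means[mineral]))
  litter <- if ("litter" %in% names(means) && !is.na(means[["litter"]]))
    means[["litter"]] else 0
  top <- means[["0-10 cm"]] + means[["10-30 cm"]]
  sub <- means[["30-60 cm"]] + means[["60-90 cm"]]
  share <- if (abs(sub) + abs(top) > 0)
    abs(sub) / (abs(sub) + abs(top)) * 100 else NA_real_
  list(mineral_total = mineral_total,
       overall_total = mineral_total + litter,
       subsoil_share_pct = share)
}

#' Direction summary from printed stratum means
#'
#' Applies the summary-table arithmetic — mineral total as the sum of the
#' four mineral stratum means, overall total adding the signed litter mean,
#' subsoil share of the absolute change — to a set of per-stratum mean stock
#' changes (e.g. a published summary row).
#'
#' @param means Named numeric: `"0-10 cm"`, `"10-30 cm"`, `"30-60 cm"`,
#'   `"60-90 cm"`, optionally `"litter"`.
#' @param direction Direction label.
#' @return A `direction_summary` (confidence bounds `NA`).
#' @export
summarize_from_means <- function(means, direction = "") {
  means <- as.list(means)
  tot <- totals_from_means(means)
  labs <- c(if ("litter" %in% names(means)) "litter", .mineral_strata())
  strata <- data.frame(stratum = labs, n = NA_integer_,
                       mean_delta = unlist(means[labs]),
                       ci_low = NA_real_, ci_high = NA_real_,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(direction = direction, strata = strata,
                 mineral_total = tot$mineral_total,
                 overall_total = tot$overall_total,
                 topsoil_pct = NA_real_, subsoil_pct = NA_real_,
                 subsoil_share_pct = tot$subsoil_share_pct,
                 subsoil_share_ci = c(NA_real_, NA_real_)),
            class = "direction_summary")
}

#' Summarise the stock-change records of one direction
#'
#' Per-stratum means with percentile-bootstrap confidence intervals over the
#' in-applicability sites, the mineral and overall totals, topsoil (0-30 cm)
#' and subsoil (30-90 cm) change relative to the pre-conversion stocks, and
#' the subsoil share of the absolute change with a site-level bootstrap CI of
#' the ratio.
#'
#' @param deltas A `delta_records` data.frame (see [run_direction()]).
#' @param pre_stocks data.frame `site_id, stratum, stock` of observed
#'   (pre-conversion) stocks for the same sites.
#' @param n_boot,level,seed Bootstrap settings.
#' @return A `direction_summary`.
#' @export
summarize_direction <- function(deltas, pre_stocks, n_boot = 10000,
                                level = 0.95, seed = 1L) {
  d <- deltas[deltas$in_aoa, , drop = FALSE]
  direction <- if (nrow(d)) d$direction[1] else ""
  labs <- intersect(c("litter", .mineral_strata()), unique(d$stratum))
  rows <- lapply(seq_along(labs), function(i) {
    v <- d$delta[d$stratum == labs[i]]
    ci <- if (length(v) >= 2) bootstrap_ci(v, n_boot, level, seed + i) else
      c(mean = mean(v), low = NA_real_, high = NA_real_)
    data.frame(stratum = labs[i], n = length(v), mean_delta = ci[["mean"]],
               ci_low = ci[["low"]], ci_high = ci[["high"]],
               stringsAsFactors = FALSE)
  })
  strata <- do.call(rbind, rows)
  means <- setNames(as.list(strata$mean_delta), strata$stratum)
  miss <- setdiff(.mineral_strata(), names(means))
  if (length(miss)) stop("summarize_direction: missing stratum ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tot <- totals_from_means(means)

  # relative change uses the mean pre-conversion stock over the same sites
  rel <- function(strata_set) {
    dd <- d[d$stratum %in% strata_set, , drop = FALSE]
    ps <- pre_stocks[pre_stocks$stratum %in% strata_set &
                       pre_stocks$site_id %in% dd$site_id, , drop = FALSE]
    pre <- sum(ps$stock) / length(unique(ps$site_id))
    if (!is.finite(pre) || pre == 0) return(NA_real_)
    (sum(dd$delta) / length(unique(dd$site_id))) / pre * 100
  }
  topsoil_pct <- rel(c("0-10 cm", "10-30 cm"))
  subsoil_pct <- rel(c("30-60 cm", "60-90 cm"))

  # subsoil share CI: site-level bootstrap of the ratio over sites with all
  # four mineral strata
  wide <- tapply(d$delta, list(d$site_id, d$stratum), mean)
  keep <- rowSums(is.na(wide[, .mineral_strata(), drop = FALSE])) == 0
  wide <- wide[keep, , drop = FALSE]
  share_ci <- c(NA_real_, NA_real_)
  if (nrow(wide) >= 2) {
    top <- wide[, "0-10 cm"] + wide[, "10-30 cm"]
    sub <- wide[, "30-60 cm"] + wide[, "60-90 cm"]
    set.seed(seed)
    shares <- vapply(seq_len(n_boot), function(b) {
      j <- sample.int(nrow(wide), replace = TRUE)
      ms <- mean(sub[j]); mt <- mean(top[j])
      if (abs(ms) + abs(mt) == 0) NA_real_ else
        abs(ms) / (abs(ms) + abs(mt)) * 100
    }, numeric(1))
    a <- (1 - level) / 2
    share_ci <- quantile(shares, c(a, 1 - a), type = 7, names = FALSE,
                         na.rm = TRUE)
  }
  structure(list(direction = direction, strata = strata,
                 mineral_total = tot$mineral_total,
                 overall_total = tot$overall_total,
                 topsoil_pct = topsoil_pct, subsoil_pct = subsoil_pct,
                 subsoil_share_pct = tot$subsoil_share_pct,
                 subsoil_share_ci = share_ci),
            class = "direction_summary")
}

#' @export
print.direction_summary <- function(x, ...) {
  cat("Direction:", x$direction, "\n")
  st <- x$strata
  st$mean_delta <- round(st$mean_delta, 2)
  st$ci_low <- round(st$ci_low, 2); st$ci_high <- round(st$ci_high, 2)
  print(st, row.names = FALSE)
  cat("mineral total:", round(x$mineral_total, 2),
      " overall total:", round(x$overall_total, 2), "Mg C ha-1\n")
  if (!is.na(x$topsoil_pct))
    cat("relative change topsoil:", round(x$topsoil_pct, 1),
        "% subsoil:", round(x$subsoil_pct, 1), "%\n")
  if (!is.na(x$subsoil_share_pct))
    cat("subsoil share of |change|:", round(x$subsoil_share_pct, 1), "%\n")
  invisible(x)
}

#' Direction analysis settings
#'
#' @param repeats,k,cell_size Spatial CV plan (repeats x k folds over blocks
#'   of `cell_size` metres).
#' @param ensemble An [ensemble_control()].
#' @param n_boot,level Bootstrap settings for the summary.
#' @param aoa_threshold `"quantile"` or `"whisker"` (see [build_aoa()]).
#' @param tau Optional AOA threshold override.
#' @param keep_models Store the fitted per-stratum ensembles on the result?
#' @return A `direction_control` list.
#' @export
direction_control <- function(repeats = 10, k = 5, cell_size = 100e3,
                              ensemble = ensemble_control(),
                              n_boot = 10000, level = 0.95,
                              aoa_threshold = "quantile", tau = NULL,
                              keep_models = FALSE) {
  structure(as.list(environment()), class = "direction_control")
}

#' Run the reciprocal-modelling pipeline for one land-use-change direction
#'
#' For each mineral stratum: trains the stacked ensemble on the filtered
#' alternate-land-use group, screens the current-land-use sites by area of
#' applicability (importance-weighted), predicts the counterfactual stock for
#' the retained sites, and records the per-site change
#' `delta = predicted - observed`. Directions involving forest additionally
#' carry a litter stratum: converting to forest predicts a litter stock with
#' the restricted litter model (`delta = predicted - 0`); converting away
#' from forest removes the observed litter (`delta = 0 - observed`).
#'
#' @param inv A `soc_inventory` (harmonized, or harmonizable — see
#'   [harmonize_inventory()]).
#' @param current_lu,alternate_lu The direction `current -> alternate`.
#' @param control A [direction_control()].
#' @param seed Master seed for fold plans, fits and bootstrap.
#' @param predict_fn Optional oracle override: `function(frame, stratum)`
#'   returning counterfactual predictions for every row of the current
#'   group's model frame (bypasses fitting and applicability screening; used
#'   for validation).
#' @return A `luc_direction` object: `deltas` (per site x stratum records),
#'   `summary` (a `direction_summary`), `report` (filter report), `fit_info`
#'   (per-stratum out-of-fold metrics, importances, applicability counts) and
#'   optionally `models`.
#' @export
run_direction <- function(inv, current_lu, alternate_lu,
                          control = direction_control(), seed = 1L,
                          predict_fn = NULL) {
  if (inv$depth_scheme != "harmonized") inv <- harmonize_inventory(inv)
  g <- split_groups(inv, current_lu, alternate_lu)
  spec <- direction_spec(current_lu, alternate_lu)
  direction <- paste(current_lu, "to", alternate_lu)
  strata <- .mineral_strata()
  has_litter <- "forest" %in% c(current_lu, alternate_lu)
  delta_rows <- list()
  pre_rows <- list()
  fit_info <- list()
  models <- list()
  for (si in seq_along(strata)) {
    stratum <- strata[si]
    frame_alt <- model_frame(g$alternate, stratum)
    frame_cur <- model_frame(g$current, stratum)
    pre_rows[[stratum]] <- data.frame(site_id = frame_cur$site_id,
                                      stratum = stratum,
                                      stock = frame_cur$target)
    if (!is.null(predict_fn)) {
      pred <- predict_fn(frame_cur, stratum)
      keep <- rep(TRUE, nrow(frame_cur))
      iqr <- rep(0, nrow(frame_cur))
      di <- rep(0, nrow(frame_cur))
    } else {
      plan <- assign_spatial_folds(frame_alt$x, frame_alt$y,
                                   cell_size = control$cell_size,
                                   k = control$k, repeats = control$repeats,
                                   seed = seed + 97L * si)
      fit <- soc_ensemble(frame_alt, spec, plan, control = control$ensemble,
                          seed = seed + 131L * si)
      aoa <- build_aoa(frame_alt, spec, fit$importance$raw,
                       fold = plan$folds[, 1],
                       threshold = control$aoa_threshold)
      msk <- aoa_mask(aoa, frame_cur,
                      tau = if (is.null(control$tau)) aoa$tau else control$tau)
      keep <- msk$in_aoa
      di <- msk$di
      if (!any(keep)) {
        stop("run_direction: no sites inside the area of applicability for ",
             direction, ", ", stratum, call. = FALSE)
      }
      pr <- predict(fit, frame_cur[keep, , drop = FALSE])
      pred <- rep(NA_real_, nrow(frame_cur)); pred[keep] <- pr$pred
      iqr <- rep(NA_real_, nrow(frame_cur)); iqr[keep] <- pr$pred_iqr
      fit_info[[stratum]] <- list(metrics = fit$metrics,
                                  importance = fit$importance,
                                  aoa = list(tau = aoa$tau, n_in = msk$n_in,
                                             n_out = msk$n_out))
      if (control$keep_models) models[[stratum]] <- list(fit = fit, aoa = aoa)
    }
    delta_rows[[stratum]] <- data.frame(
      site_id = frame_cur$site_id, direction = direction, stratum = stratum,
      observed_stock = frame_cur$target, predicted_stock = pred,
      delta = pred - frame_cur$target, in_aoa = keep, di = di,
      pred_iqr = iqr, stringsAsFactors = FALSE
    )
  }
  if (has_litter) {
    if (alternate_lu == "forest") {
      lspec <- predictor_spec("litter")
      frame_lit <- model_frame(g$alternate, "litter")
      frame_cur <- g$current$sites
      if (!is.null(predict_fn)) {
        pred <- predict_fn(frame_cur, "litter")
        keep <- rep(TRUE, nrow(frame_cur)); iqr <- di <- rep(0, nrow(frame_cur))
      } else {
        plan <- assign_spatial_folds(frame_lit$x, frame_lit$y,
                                     cell_size = control$cell_size,
                                     k = control$k, repeats = control$repeats,
                                     seed = seed + 997L)
        fit <- soc_ensemble(frame_lit, lspec, plan, control = control$ensemble,
                            seed = seed + 1031L)
        aoa <- build_aoa(frame_lit, lspec, fit$importance$raw,
                         fold = plan$folds[, 1],
                         threshold = control$aoa_threshold)
        msk <- aoa_mask(aoa, frame_cur,
                        tau = if (is.null(control$tau)) aoa$tau else control$tau)
        keep <- msk$in_aoa; di <- msk$di
        pr <- predict(fit, frame_cur[keep, , drop = FALSE])
        pred <- rep(NA_real_, nrow(frame_cur)); pred[keep] <- pr$pred
        iqr <- rep(NA_real_, nrow(frame_cur)); iqr[keep] <- pr$pred_iqr
        fit_info[["litter"]] <- list(metrics = fit$metrics,
                                     importance = fit$importance,
                                     aoa = list(tau = aoa$tau, n_in = msk$n_in,
                                                n_out = msk$n_out))
        if (control$keep_models) models[["litter"]] <- list(fit = fit, aoa = aoa)
      }
      delta_rows[["litter"]] <- data.frame(
        site_id = frame_cur$site_id, direction = direction, stratum = "litter",
        observed_stock = 0, predicted_stock = pred, delta = pred - 0,
        in_aoa = keep, di = di, pred_iqr = iqr, stringsAsFactors = FALSE
      )
    } else {
      s <- g$current$sites
      s <- s[!is.na(s$litter_c_stock), , drop = FALSE]
      delta_rows[["litter"]] <- data.frame(
        site_id = s$site_id, direction = direction, stratum = "litter",
        observed_stock = s$litter_c_stock, predicted_stock = 0,
        delta = 0 - s$litter_c_stock, in_aoa = TRUE, di = 0,
        pred_iqr = 0, stringsAsFactors = FALSE
      )
    }
  }
  deltas <- do.call(rbind, c(delta_rows, list(make.row.names = FALSE)))
  pre_stocks <- do.call(rbind, c(pre_rows, list(make.row.names = FALSE)))
  summary <- summarize_direction(deltas, pre_stocks, n_boot = control$n_boot,
                                 level = control$level, seed = seed + 7L)
  structure(list(direction = direction, deltas = deltas,
                 pre_stocks = pre_stocks, summary = summary,
                 report = g$report, fit_info = fit_info,
                 models = if (control$keep_models) models,
                 control = control, seed = seed),
            class = "luc_direction")
}

#' @export
print.luc_direction <- function(x, ...) {
  cat("Reciprocal modelling result —", x$direction, "\n")
  print(x$summary)
  invisible(x)
}

#' @export
summary.luc_direction <- function(object, ...) object$summary
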