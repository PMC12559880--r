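#' Soil organic carbon stock of a depth increment
#'
#' Stock (Mg C ha-1) = SOC concentration (% of fine soil) x fine-soil bulk
#' density (g cm-3) x (1 - volumetric rock-fragment fraction) x increment
#' thickness (cm). The unit identity % x g cm-3 x cm = Mg ha-1 makes the
#' product come out directly in Mg C ha-1. Vectorized over all arguments.
#'
#' @param soc_pct SOC concentration of the fine soil, mass %.
#' @param bd_fine Fine-soil bulk density, g cm-3.
#' @param rff Volumetric rock-fragment fraction, 0-1.
#' @param thickness_cm Increment thickness, cm.
#' @return Stock in Mg C ha-1.
#' @examples
#' soc_stock(2.0, 1.3, 0.10, 10) # 23.4 Mg C ha-1
#' @export
soc_stock <- function(soc_pct, bd_fine, rff, thickness_cm) {
  if (any(soc_pct < 0, na.rm = TRUE) || any(bd_fine < 0, na.rm = TRUE) ||
      any(rff < 0 | rff > 1, na.rm = TRUE) || any(thickness_cm < 0, na.rm = TRUE)) {
    stop("soc_stock: inputs out of domain (negative value or rff outside [0,1])",
         call. = FALSE)
  }
  soc_pct * bd_fine * (1 - rff) * thickness_cm
}

.slice_props <- c("soc_pct", "bd_fine", "rff", "clay_pct", "silt_pct",
                  "ph", "cn_ratio", "n_pct")

#' Downscale depth increments to 1-cm slices
#'
#' Each 1-cm slice inherits its source increment's values (constant within the
#' increment). When a horizon boundary splits an increment and a per-horizon
#' SOC allocation is supplied, the SOC concentration is re-apportioned between
#' the sub-layers so that the increment's total stock is conserved exactly;
#' bulk density and all other properties stay constant.
#'
#' @param increments data.frame of increments for one site, contiguous from
#'   0 cm, with the columns of the inventory increment table.
#' @param horizon_alloc Optional data.frame `(boundary_cm, share_above)`:
#'   for each horizon boundary strictly inside an increment, the share of that
#'   increment's SOC stock assigned above the boundary.
#' @return A `sliced_profile`: data.frame with one row per 1-cm slice
#'   (`top_cm`, the properties, and `origin` = source increment index).
#' @export
downscale <- function(increments, horizon_alloc = NULL) {
  inc <- increments[order(increments$top_cm), , drop = FALSE]
  if (inc$top_cm[1] != 0) stop("downscale: increments must start at 0 cm", call. = FALSE)
  if (nrow(inc) > 1L &&
      any(abs(inc$top_cm[-1] - inc$bottom_cm[-nrow(inc)]) > 1e-9)) {
    stop("downscale: gap or overlap between increments", call. = FALSE)
  }
  if (any(round(inc$top_cm) != inc$top_cm) || any(round(inc$bottom_cm) != inc$bottom_cm)) {
    stop("downscale: increment bounds must be whole centimetres", call. = FALSE)
  }
  depth <- inc$bottom_cm[nrow(inc)]
  origin <- rep(seq_len(nrow(inc)), times = inc$bottom_cm - inc$top_cm)
  out <- data.frame(top_cm = seq_len(depth) - 1L, origin = origin)
  for (p in .slice_props) {
    out[[p]] <- if (p %in% names(inc)) inc[[p]][origin] else NA_real_
  }
  if (!is.null(horizon_alloc) && nrow(horizon_alloc)) {
    for (j in seq_len(nrow(horizon_alloc))) {
      b <- horizon_alloc$boundary_cm[j]
      k <- which(inc$top_cm < b & inc$bottom_cm > b)
      if (length(k) != 1L) next   # boundary coincides with an increment bound
      share <- horizon_alloc$share_above[j]
      t_above <- b - inc$top_cm[k]
      t_below <- inc$bottom_cm[k] - b
      thick <- inc$bottom_cm[k] - inc$top_cm[k]
      # constant bd/rff within the increment: conserving stock is equivalent
      # to conserving mean concentration over the increment
      above <- out$origin == k & out$top_cm < b
      below <- out$origin == k & out$top_cm >= b
      out$soc_pct[above] <- inc$soc_pct[k] * share * thick / t_above
      out$soc_pct[below] <- inc$soc_pct[k] * (1 - share) * thick / t_below
    }
  }
  class(out) <- c("sliced_profile", "data.frame")
  out
}

#' Aggregate a 1-cm sliced profile onto target depth increments
#'
#' Weighted means per the harmonization scheme: bulk density and rock-fragment
#' fraction use increment-thickness weights (a plain mean over slices); SOC
#' concentration, clay, silt, total N and pH use fine-soil-stock weights,
#' where the fine-soil stock of a slice is `bd_fine * (1 - rff) * 1 cm`. The
#' organic-carbon stock of each target increment is defined as the sum of its
#' slices' stocks, which conserves stock exactly through any re-slicing.
#'
#' @param profile A `sliced_profile` from [downscale()].
#' @param targets Two-column matrix or data.frame of `(top, bottom)` in cm.
#' @return data.frame of target increments with the aggregated properties and
#'   an `oc_stock` column (Mg C ha-1).
#' @export
aggregate_slices <- function(profile, targets) {
  targets <- as.matrix(targets)
  depth <- max(profile$top_cm) + 1L
  if (any(targets[, 2] > depth + 1e-9)) {
    stop("aggregate_slices: target deeper than profile (no extrapolation below ",
         depth, " cm)", call. = FALSE)
  }
  fs_weighted <- c("soc_pct", "clay_pct", "silt_pct", "ph", "cn_ratio", "n_pct")
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    sl <- profile[profile$top_cm >= targets[i, 1] & profile$top_cm < targets[i, 2], ]
    w_fs <- sl$bd_fine * (1 - sl$rff)           # fine-soil mass per 1-cm slice
    wmean <- function(v, w) if (all(is.na(v))) NA_real_ else sum(v * w) / sum(w)
    out <- data.frame(top_cm = targets[i, 1], bottom_cm = targets[i, 2])
    out$bd_fine <- mean(sl$bd_fine)
    out$rff <- mean(sl$rff)
    for (p in fs_weighted) out[[p]] <- wmean(sl[[p]], w_fs)
    out$oc_stock <- sum(soc_stock(sl$soc_pct, sl$bd_fine, sl$rff, 1))
    out
  })
  do.call(rbind, rows)
}

#' Merge the forest 0-5 and 5-10 cm increments into 0-10 cm
#'
#' Uses the same weighting scheme as [aggregate_slices()]: thickness weights
#' for bulk density and rock fragments, fine-soil-stock weights for the
#' concentration-like properties. Stocks are additive by construction.
#'
#' @param increments Increment table of one forest site on the forest scheme.
#' @return Increment table with the merged 0-10 cm layer first.
#' @export
merge_forest_topsoil <- function(increments) {
  inc <- increments[order(increments$top_cm), , drop = FALSE]
  i1 <- which(inc$top_cm == 0 & inc$bottom_cm == 5)
  i2 <- which(inc$top_cm == 5 & inc$bottom_cm == 10)
  if (length(i1) != 1L || length(i2) != 1L) {
    stop("merge_forest_topsoil: 0-5 and 5-10 cm increments required", call. = FALSE)
  }
  agg <- aggregate_slices(downscale(inc[c(i1, i2), , drop = FALSE]),
                          cbind(0, 10))
  merged <- inc[i1, , drop = FALSE]
  merged$top_cm <- 0; merged$bottom_cm <- 10
  for (p in intersect(.slice_props, names(inc))) merged[[p]] <- agg[[p]]
  out <- rbind(merged, inc[-c(i1, i2), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Harmonize an inventory onto the four target depth strata
#'
#' Downscales every site's increments to 1-cm slices and re-aggregates them to
#' 0-10, 10-30, 30-60 and 60-90 cm. Agricultural profiles sampled to 100 cm
#' contribute only their 0-90 cm slices; forest 0-5/5-10 cm layers are merged.
#' SOC stock is conserved exactly within every target stratum.
#'
#' @param inv A `soc_inventory` on any supported depth scheme.
#' @param horizon_alloc Optional named list (by site_id) of horizon allocation
#'   tables passed to [downscale()].
#' @return A `soc_inventory` on the harmonized scheme; increments gain an
#'   `oc_stock` column.
#' @export
harmonize_inventory <- function(inv, horizon_alloc = NULL) {
  targets <- target_strata()
  ids <- inv$sites$site_id
  # fast path: with constant values inside increments (no horizon table),
  # aggregation onto the targets is a fixed linear map per sampling scheme —
  # identical to the slice route, computed site-parallel
  if (is.null(horizon_alloc)) {
    fast <- .harmonize_fixed_schemes(inv)
    if (!is.null(fast)) {
      return(soc_inventory(inv$sites, fast, depth_scheme = "harmonized",
                           provenance = inv$provenance, validate = FALSE))
    }
  }
  inc_by_site <- split(inv$increments, inv$increments$site_id)
  rows <- lapply(ids, function(id) {
    prof <- downscale(inc_by_site[[as.character(id)]],
                      horizon_alloc = horizon_alloc[[as.character(id)]])
    if (max(prof$top_cm) + 1L < 90) {
      stop("harmonize_inventory: site ", id, " sampled shallower than 90 cm",
           call. = FALSE)
    }
    agg <- aggregate_slices(prof, targets)
    cbind(site_id = id, agg)
  })
  increments <- do.call(rbind, rows)
  soc_inventory(inv$sites, increments, depth_scheme = "harmonized",
                provenance = inv$provenance, validate = FALSE)
}

# overlap (cm) of each source increment with each target stratum
.scheme_overlap <- function(scheme) {
  targets <- target_strata()
  t(vapply(seq_len(nrow(targets)), function(i) {
    pmax(pmin(scheme[, "bottom"], targets[i, "bottom"]) -
           pmax(scheme[, "top"], targets[i, "top"]), 0)
  }, numeric(nrow(scheme))))
}

.harmonize_fixed_schemes <- function(inv) {
  inc <- inv$increments
  sites <- inv$sites
  out <- vector("list", 2L)
  for (g in 1:2) {
    scheme_name <- c("agricultural", "forest")[g]
    ids <- sites$site_id[if (g == 1) sites$land_use != "forest" else
      sites$land_use == "forest"]
    if (!length(ids)) next
    d <- inc[inc$site_id %in% ids, , drop = FALSE]
    d <- d[order(match(d$site_id, ids), d$top_cm), , drop = FALSE]
    sch <- .depth_schemes[[scheme_name]]
    n_inc <- nrow(sch)
    if (nrow(d) != length(ids) * n_inc) return(NULL)
    if (any(d$top_cm != rep(sch[, "top"], times = length(ids))) ||
        any(d$bottom_cm != rep(sch[, "bottom"], times = length(ids)))) {
      return(NULL)
    }
    getm <- function(col) matrix(d[[col]], nrow = n_inc)   # inc x site
    O <- .scheme_overlap(sch)                               # target x inc
    B <- getm("bd_fine"); R <- getm("rff")
    W <- B * (1 - R)                                        # fine-soil mass/cm
    thick <- target_strata()[, "bottom"] - target_strata()[, "top"]
    res <- data.frame(
      site_id = rep(ids, each = nrow(O)),
      top_cm = rep(target_strata()[, "top"], times = length(ids)),
      bottom_cm = rep(target_strata()[, "bottom"], times = length(ids))
    )
    res$bd_fine <- as.vector((O %*% B) / thick)
    res$rff <- as.vector((O %*% R) / thick)
    WW <- O %*% W
    for (p in c("soc_pct", "clay_pct", "silt_pct", "ph", "cn_ratio", "n_pct")) {
      if (p %in% names(d)) res[[p]] <- as.vector((O %*% (getm(p) * W)) / WW)
      else res[[p]] <- NA_real_
    }
    res$oc_stock <- as.vector(O %*% (getm("soc_pct") * W))
    out[[g]] <- res
  }
  res <- do.call(rbind, out)
  cols <- c("site_id", "top_cm", "bottom_cm", "bd_fine", "rff", "soc_pct",
            "clay_pct", "silt_pct", "ph", "cn_ratio", "n_pct", "oc_stock")
  res[, cols]
}
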