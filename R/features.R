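# Predictor specifications. Land uses expected not to be altered by the land
# use itself enter every model; pH and C:N are excluded from any model that
# involves forest (they are shaped by forest-specific biotic processes), and
# the litter model is restricted to soil group, climate and terrain.

#' Predictor specification for a model family
#'
#' @param kind `"agricultural"` (cropland/grassland only: full set incl. pH
#'   and C:N), `"forest"` (forest-involving: pH and C:N excluded),
#'   `"litter"` (soil group, climate, elevation, slope only) or `"driver"`
#'   (mechanistic set for the change-magnitude model).
#' @return List with `numeric` and `categorical` predictor names.
#' @export
predictor_spec <- function(kind = c("agricultural", "forest", "litter", "driver")) {
  kind <- match.arg(kind)
  base_num <- c("clay_pct", "silt_pct", "coarse_frac", "slope_deg",
                "elevation_m", "drought_index", "map_mm", "mat_c")
  base_cat <- c("wrb_group", "parent_material", "groundwater_class")
  spec <- switch(kind,
    agricultural = list(numeric = c(base_num, "ph", "cn_ratio"),
                        categorical = base_cat),
    forest = list(numeric = base_num, categorical = base_cat),
    litter = list(numeric = c("map_mm", "mat_c", "drought_index",
                              "elevation_m", "slope_deg"),
                  categorical = "wrb_group"),
    driver = list(numeric = c("clay_pct", "silt_pct", "coarse_frac",
                              "map_mm", "mat_c", "drought_index", "ndvi",
                              "slope_deg", "elevation_m"),
                  categorical = c("wrb_group", "groundwater_class"))
  )
  structure(c(spec, list(kind = kind)), class = "predictor_spec")
}

#' Predictor spec for a land-use-change direction
#' @param current_lu,alternate_lu The two land uses of the direction.
#' @return A [predictor_spec()]: `"forest"` if either land use is forest,
#'   else `"agricultural"`.
#' @export
direction_spec <- function(current_lu, alternate_lu) {
  if ("forest" %in% c(current_lu, alternate_lu)) predictor_spec("forest")
  else predictor_spec("agricultural")
}

#' Assemble the model frame for one depth stratum
#'
#' Joins the site-level predictors with the stratum's increment-level soil
#' properties (clay, silt, pH, C:N — as harmonized for that stratum) and the
#' stratum SOC stock as target.
#'
#' @param inv A harmonized `soc_inventory` (increments carry `oc_stock`).
#' @param stratum Stratum label, e.g. `"0-10 cm"`, or `"litter"`.
#' @return data.frame with `site_id`, `target` and all predictor columns.
#' @export
model_frame <- function(inv, stratum) {
  s <- inv$sites
  if (identical(stratum, "litter")) {
    out <- s
    out$target <- s$litter_c_stock
    return(out[!is.na(out$target), , drop = FALSE])
  }
  tb <- strsplit(sub(" cm$", "", stratum), "-")[[1]]
  d <- inv$increments[inv$increments$top_cm == as.numeric(tb[1]) &
                        inv$increments$bottom_cm == as.numeric(tb[2]), ,
                      drop = FALSE]
  if (nrow(d) == 0L) stop("model_frame: no increments for stratum ", stratum,
                          call. = FALSE)
  m <- match(s$site_id, d$site_id)
  out <- s
  for (p in c("clay_pct", "silt_pct", "ph", "cn_ratio")) {
    out[[p]] <- d[[p]][m]     # stratum-level soil properties override
  }
  out$target <- if ("oc_stock" %in% names(d)) d$oc_stock[m] else
    soc_stock(d$soc_pct[m], d$bd_fine[m], d$rff[m], d$bottom_cm[m] - d$top_cm[m])
  out[!is.na(out$target), , drop = FALSE]
}

# ---- encoding ---------------------------------------------------------------

# One-hot encoder with stored levels; unseen levels at prediction time encode
# to an all-zero block (logged via warning by the caller's option).
make_encoder <- function(data, spec) {
  num <- spec$numeric
  cat_lv <- lapply(spec$categorical, function(p) sort(unique(as.character(data[[p]]))))
  names(cat_lv) <- spec$categorical
  medians <- vapply(num, function(p) median(data[[p]], na.rm = TRUE), numeric(1))
  list(numeric = num, levels = cat_lv, medians = medians)
}

encode_features <- function(data, enc, warn_unseen = FALSE) {
  cols <- list()
  for (p in enc$numeric) {
    v <- as.numeric(data[[p]])
    v[is.na(v)] <- enc$medians[[p]]        # training-median imputation
    cols[[p]] <- v
  }
  for (p in names(enc$levels)) {
    v <- as.character(data[[p]])
    lv <- enc$levels[[p]]
    if (warn_unseen && any(!v %in% lv & !is.na(v))) {
      warning("unseen level(s) in '", p, "': ",
              paste(unique(setdiff(v, lv)), collapse = ", "),
              " encoded as all-zero", call. = FALSE)
    }
    for (l in lv) cols[[paste0(p, "=", l)]] <- as.numeric(!is.na(v) & v == l)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

# map each encoded column back to its source predictor
encoded_groups <- function(enc) {
  c(setNames(enc$numeric, enc$numeric),
    unlist(lapply(names(enc$levels), function(p) {
      setNames(rep(p, length(enc$levels[[p]])),
               paste0(p, "=", enc$levels[[p]]))
    })))
}
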