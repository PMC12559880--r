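#' @importFrom stats predict quantile median sd var cor setNames IQR dist
#'   rnorm runif rlnorm rgamma qnorm pnorm qlnorm plnorm
#' @importFrom utils read.csv write.csv head
NULL

# Canonical column sets for the long-format inventory CSV. Site-level columns
# are repeated on every increment row of a site; increment columns vary by row.
.site_cols <- c(
  "site_id", "x", "y", "land_use", "years_under_lu", "had_luc_in_record",
  "ley_rotation", "wrb_group", "is_histosol", "litter_c_stock",
  "map_mm", "mat_c", "drought_index", "elevation_m", "slope_deg",
  "groundwater_class", "ndvi", "parent_material", "coarse_frac"
)
.increment_cols <- c(
  "site_id", "top_cm", "bottom_cm", "soc_pct", "bd_fine", "rff",
  "clay_pct", "silt_pct", "ph", "cn_ratio", "n_pct"
)

.land_uses <- c("cropland", "grassland", "forest")

# Fixed sampling-depth schemes (cm). The agricultural inventory samples five
# increments to 100 cm; the forest inventory five to 90 cm plus a litter layer.
.depth_schemes <- list(
  agricultural = cbind(top = c(0, 10, 30, 50, 70), bottom = c(10, 30, 50, 70, 100)),
  forest       = cbind(top = c(0, 5, 10, 30, 60), bottom = c(5, 10, 30, 60, 90)),
  harmonized   = cbind(top = c(0, 10, 30, 60), bottom = c(10, 30, 60, 90))
)

#' Target depth strata of the harmonized profile
#'
#' The four mineral-soil increments all analyses are expressed on, 0-10,
#' 10-30, 30-60 and 60-90 cm. The litter layer is a separate stratum, never a
#' mineral increment.
#' @return A two-column matrix of top/bottom depths in cm.
#' @export
target_strata <- function() .depth_schemes$harmonized

#' Stratum labels used in results tables
#' @param litter Include the litter stratum first?
#' @return Character vector of stratum labels.
#' @export
stratum_labels <- function(litter = FALSE) {
  m <- target_strata()
  lab <- paste0(m[, "top"], "-", m[, "bottom"], " cm")
  if (litter) c("litter", lab) else lab
}

#' Construct a soil inventory object
#'
#' An inventory couples a per-site attribute table with a long table of depth
#' increments (one row per site x increment). Increments are half-open
#' \[top_cm, bottom_cm) measured downward from the mineral-soil surface; the
#' forest litter layer is carried as a per-site stock, not an increment.
#'
#' @param sites data.frame with columns `site_id, x, y, land_use,
#'   years_under_lu, had_luc_in_record, ley_rotation, wrb_group, is_histosol,
#'   litter_c_stock` plus the model predictors (`map_mm, mat_c, drought_index,
#'   elevation_m, slope_deg, groundwater_class, ndvi, parent_material,
#'   coarse_frac`).
#' @param increments data.frame with columns `site_id, top_cm, bottom_cm,
#'   soc_pct, bd_fine, rff, clay_pct, silt_pct, ph, cn_ratio, n_pct`.
#' @param depth_scheme One of `"agricultural"`, `"forest"`, `"harmonized"`,
#'   `"mixed"` (agricultural sites on the agricultural scheme, forest sites on
#'   the forest scheme), or `NULL` to infer from the increment bounds.
#' @param provenance Free-text origin note.
#' @param validate Run [validate_inventory()]?
#' @return An object of class `soc_inventory`.
#' @export
soc_inventory <- function(sites, increments, depth_scheme = NULL,
                          provenance = "", validate = TRUE) {
  sites <- as.data.frame(sites)
  increments <- as.data.frame(increments)
  o <- order(increments$site_id, increments$top_cm)
  increments <- increments[o, , drop = FALSE]
  rownames(increments) <- NULL
  rownames(sites) <- NULL
  if (is.null(depth_scheme)) depth_scheme <- infer_depth_scheme(sites, increments)
  inv <- structure(
    list(sites = sites, increments = increments,
         depth_scheme = depth_scheme, provenance = provenance),
    class = "soc_inventory"
  )
  if (validate) validate_inventory(inv)
  inv
}

infer_depth_scheme <- function(sites, increments) {
  match_scheme <- function(ids, scheme) {
    m <- .depth_schemes[[scheme]]
    all(vapply(ids, function(id) {
      b <- increments[increments$site_id == id, c("top_cm", "bottom_cm")]
      nrow(b) == nrow(m) && all(b$top_cm == m[, "top"]) && all(b$bottom_cm == m[, "bottom"])
    }, logical(1)))
  }
  ag_ids <- sites$site_id[sites$land_use != "forest"]
  fo_ids <- sites$site_id[sites$land_use == "forest"]
  if (match_scheme(sites$site_id, "harmonized")) return("harmonized")
  if (length(fo_ids) == 0L && match_scheme(ag_ids, "agricultural")) return("agricultural")
  if (length(ag_ids) == 0L && match_scheme(fo_ids, "forest")) return("forest")
  if (match_scheme(ag_ids, "agricultural") && match_scheme(fo_ids, "forest")) return("mixed")
  "irregular"
}

#' Validate a soil inventory
#'
#' Checks every structural invariant of the data model: unique site ids,
#' per-site increments sorted and non-overlapping, `rff` within \[0, 1\],
#' non-negative SOC, `bottom_cm > top_cm`, `clay + silt <= 100`, known land
#' uses, and litter stocks present only (and non-negative) under forest.
#' Violations raise an error naming the offending sites/rows.
#'
#' @param inv A `soc_inventory`.
#' @return Invisibly `TRUE` on success.
#' @export
validate_inventory <- function(inv) {
  s <- inv$sites; d <- inv$increments
  miss_s <- setdiff(c("site_id", "land_use"), names(s))
  miss_d <- setdiff(c("site_id", "top_cm", "bottom_cm", "soc_pct", "bd_fine", "rff"),
                    names(d))
  if (length(miss_s) || length(miss_d)) {
    stop("inventory schema error: missing mandatory column(s): ",
         paste(c(miss_s, miss_d), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(s$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(s$site_id[duplicated(s$site_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_lu <- setdiff(unique(s$land_use), .land_uses)
  if (length(bad_lu)) {
    stop("unknown land_use value(s): ", paste(bad_lu, collapse = ", "), call. = FALSE)
  }
  fail <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      i <- which(cond)
      stop("validation error: ", what, " on row(s) ",
           paste(head(i, 10L), collapse = ", "), " (site ",
           paste(head(unique(d$site_id[i]), 10L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  fail(d$rff < 0 | d$rff > 1, "rock-fragment fraction outside [0,1]")
  fail(d$soc_pct < 0, "negative SOC concentration")
  fail(d$bottom_cm <= d$top_cm, "bottom_cm not greater than top_cm")
  fail(d$bd_fine < 0, "negative bulk density")
  if (all(c("clay_pct", "silt_pct") %in% names(d))) {
    fail(d$clay_pct + d$silt_pct > 100 + 1e-9, "clay + silt exceeds 100%")
  }
  # non-overlap within site (increments already sorted by top_cm)
  by_site <- split(seq_len(nrow(d)), d$site_id)
  for (idx in by_site) {
    if (length(idx) > 1L) {
      tops <- d$top_cm[idx]; bots <- d$bottom_cm[idx]
      if (any(tops[-1] < bots[-length(bots)] - 1e-9)) {
        stop("validation error: overlapping increments at site ",
             d$site_id[idx[1]], call. = FALSE)
      }
    }
  }
  if ("litter_c_stock" %in% names(s)) {
    has_litter <- !is.na(s$litter_c_stock)
    if (any(has_litter & s$land_use != "forest")) {
      stop("validation error: litter_c_stock present on non-forest site(s): ",
           paste(head(s$site_id[has_litter & s$land_use != "forest"], 10L),
                 collapse = ", "), call. = FALSE)
    }
    if (any(s$litter_c_stock < 0, na.rm = TRUE)) {
      stop("validation error: negative litter_c_stock", call. = FALSE)
    }
  }
  orphans <- setdiff(unique(d$site_id), s$site_id)
  if (length(orphans)) {
    stop("validation error: increments for unknown site(s): ",
         paste(head(orphans, 10L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.soc_inventory <- function(x, ...) {
  tab <- table(factor(x$sites$land_use, levels = .land_uses))
  cat("Soil inventory: ", nrow(x$sites), " sites (",
      paste(names(tab), tab, sep = " ", collapse = ", "), "), ",
      nrow(x$increments), " increments, depth scheme '", x$depth_scheme, "'\n",
      sep = "")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a long-format soil inventory from CSV
#'
#' Expects comma-delimited UTF-8 text with one row per site x depth increment;
#' per-site attributes are repeated on each of the site's rows. A column
#' mapping (YAML file or named list `file_column: canonical_name`) adapts
#' foreign headers. Missing optional columns are filled with `NA`, never
#' imputed.
#'
#' @param path CSV file path.
#' @param schema Optional YAML path or named character vector mapping file
#'   column names to canonical names.
#' @param provenance Provenance note stored on the result (defaults to the
#'   path).
#' @return A validated [soc_inventory()].
#' @export
read_inventory <- function(path, schema = NULL, provenance = path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    map <- if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
      unlist(yaml::read_yaml(schema))
    } else unlist(schema)
    hit <- names(df) %in% names(map)
    names(df)[hit] <- unname(map[names(df)[hit]])
  }
  mandatory <- c("site_id", "land_use", "top_cm", "bottom_cm",
                 "soc_pct", "bd_fine", "rff")
  miss <- setdiff(mandatory, names(df))
  if (length(miss)) {
    stop("inventory schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(union(.site_cols, .increment_cols), names(df))) df[[col]] <- NA
  num_cols <- c("x", "y", "litter_c_stock", "map_mm", "mat_c", "drought_index",
                "elevation_m", "slope_deg", "ndvi", "coarse_frac", "top_cm",
                "bottom_cm", "soc_pct", "bd_fine", "rff", "clay_pct",
                "silt_pct", "ph", "cn_ratio", "n_pct")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  sites <- df[!duplicated(df$site_id), intersect(.site_cols, names(df)), drop = FALSE]
  increments <- df[, intersect(.increment_cols, names(df)), drop = FALSE]
  soc_inventory(sites, increments, provenance = provenance)
}

#' Write a soil inventory to long-format CSV
#'
#' Inverse of [read_inventory()]: merges the site attributes onto each
#' increment row and writes comma-delimited UTF-8 text. Reading the file back
#' reproduces every field.
#'
#' @param inv A `soc_inventory`.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_inventory <- function(inv, path) {
  long <- merge(inv$increments, inv$sites, by = "site_id", sort = FALSE)
  long <- long[order(long$site_id, long$top_cm),
               c(.site_cols[.site_cols %in% names(long)],
                 setdiff(.increment_cols, "site_id"))]
  write.csv(long, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write direction summaries to CSV
#'
#' One row per land-use-change direction x depth stratum with the site count,
#' mean stock change and bootstrap confidence bounds, plus the per-direction
#' totals repeated on each row. Output is bit-stable for fixed inputs.
#'
#' @param summaries A list of `direction_summary` objects (possibly empty).
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_results <- function(summaries, path) {
  cols <- c("direction", "stratum", "n", "mean_delta", "ci_low", "ci_high",
            "mineral_total", "overall_total", "topsoil_pct", "subsoil_pct",
            "subsoil_share_pct")
  rows <- lapply(summaries, function(s) {
    st <- s$strata
    data.frame(
      direction = s$direction, stratum = st$stratum, n = st$n,
      mean_delta = st$mean_delta, ci_low = st$ci_low, ci_high = st$ci_high,
      mineral_total = s$mineral_total, overall_total = s$overall_total,
      topsoil_pct = s$topsoil_pct, subsoil_pct = s$subsoil_pct,
      subsoil_share_pct = s$subsoil_share_pct,
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  write.csv(out[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path CSV path.
#' @return data.frame with one row per direction x stratum.
#' @export
read_results <- function(path) read.csv(path, stringsAsFactors = FALSE)
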