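# Permanency thresholds (years of continuous use after a recorded land-use
# change) beyond which SOC is taken to have re-equilibrated.
.equilibrium_years <- c(cropland = 151, grassland = 79)
.organic_soc_threshold <- 10  # % SOC in any increment

#' Flag organic soils
#'
#' A site is treated as organic — and excluded from mineral-soil analyses —
#' if SOC concentration exceeds 10% in any depth increment or the site is a
#' Histosol.
#'
#' @param soc_pct Numeric vector of the site's increment SOC concentrations.
#' @param is_histosol Logical.
#' @return `TRUE` if the site is organic.
#' @export
flag_organic <- function(soc_pct, is_histosol = FALSE) {
  isTRUE(is_histosol) || any(soc_pct > .organic_soc_threshold, na.rm = TRUE)
}

#' Is a site at SOC equilibrium with regard to land-use change?
#'
#' A site qualifies if it has no land-use change anywhere in its compiled
#' history, or has been under its current use long enough that historic
#' change no longer drives SOC (>= 151 years continuous cropland, >= 79 years
#' continuous grassland). Forest sites are taken to be at equilibrium.
#' Cropland in ley rotation is never at equilibrium (constant flux).
#'
#' @param land_use `"cropland"`, `"grassland"` or `"forest"`.
#' @param years_under_lu Years under the current land use.
#' @param had_luc_in_record Was a land-use change recorded in the site
#'   history? `FALSE` means an unbroken record.
#' @param ley_rotation Is the site under ley rotation?
#' @return `TRUE` if at equilibrium.
#' @export
is_equilibrium <- function(land_use, years_under_lu, had_luc_in_record,
                           ley_rotation = FALSE) {
  if (isTRUE(ley_rotation)) return(FALSE)
  if (land_use == "forest") return(TRUE)
  if (!isTRUE(had_luc_in_record)) return(TRUE)
  thr <- .equilibrium_years[[land_use]]
  !is.na(years_under_lu) && years_under_lu >= thr
}

filter_flags <- function(sites, increments) {
  ids <- sites$site_id
  soc_by_site <- split(increments$soc_pct, increments$site_id)
  organic <- vapply(seq_along(ids), function(i) {
    flag_organic(soc_by_site[[as.character(ids[i])]],
                 isTRUE(sites$is_histosol[i]))
  }, logical(1))
  ley <- vapply(seq_along(ids), function(i) isTRUE(sites$ley_rotation[i]), logical(1))
  equil <- vapply(seq_along(ids), function(i) {
    is_equilibrium(sites$land_use[i], sites$years_under_lu[i],
                   isTRUE(sites$had_luc_in_record[i]),
                   isTRUE(sites$ley_rotation[i]))
  }, logical(1))
  # first triggered reason wins, in the fixed order organic -> ley -> equilibrium
  reason <- rep(NA_character_, length(ids))
  reason[!equil] <- "nonequilibrium"
  reason[ley] <- "ley"
  reason[organic] <- "organic"
  reason
}

#' Apply the inclusion filters to an inventory
#'
#' Removes organic soils, ley-rotation croplands and sites not at SOC
#' equilibrium with regard to land-use change. Each excluded site is assigned
#' its first triggered reason in the fixed order organic, ley, equilibrium, so
#' reason counts are additive.
#'
#' @param inv A `soc_inventory`.
#' @return List with `inventory` (the retained sites) and `report` (a
#'   `filter_report` with counts and per-site reason codes).
#' @export
filter_sites <- function(inv) {
  reason <- filter_flags(inv$sites, inv$increments)
  keep <- is.na(reason)
  report <- structure(list(
    n_input = nrow(inv$sites),
    n_organic_excluded = sum(reason == "organic", na.rm = TRUE),
    n_ley_excluded = sum(reason == "ley", na.rm = TRUE),
    n_nonequilibrium_excluded = sum(reason == "nonequilibrium", na.rm = TRUE),
    n_retained = sum(keep),
    reasons = data.frame(site_id = inv$sites$site_id, reason = reason,
                         stringsAsFactors = FALSE)
  ), class = "filter_report")
  kept <- soc_inventory(
    inv$sites[keep, , drop = FALSE],
    inv$increments[inv$increments$site_id %in% inv$sites$site_id[keep], , drop = FALSE],
    depth_scheme = inv$depth_scheme, provenance = inv$provenance, validate = FALSE
  )
  list(inventory = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Site filter report:\n",
      "  input:          ", x$n_input, "\n",
      "  organic:        -", x$n_organic_excluded, "\n",
      "  ley rotation:   -", x$n_ley_excluded, "\n",
      "  non-equilibrium:-", x$n_nonequilibrium_excluded, "\n",
      "  retained:       ", x$n_retained, "\n", sep = "")
  invisible(x)
}

#' Split an inventory into current and alternate land-use groups
#'
#' Applies [filter_sites()] and returns the two disjoint groups needed for one
#' reciprocal-modelling direction: sites under the current land use (to be
#' predicted) and sites under the alternate land use (to train on).
#'
#' @param inv A `soc_inventory`.
#' @param current_lu,alternate_lu Land uses of the direction
#'   `current_lu -> alternate_lu`.
#' @return List `current`, `alternate` (both `soc_inventory`) and `report`.
#' @export
split_groups <- function(inv, current_lu, alternate_lu) {
  stopifnot(current_lu %in% .land_uses, alternate_lu %in% .land_uses,
            current_lu != alternate_lu)
  f <- filter_sites(inv)
  take <- function(lu) {
    s <- f$inventory$sites[f$inventory$sites$land_use == lu, , drop = FALSE]
    if (nrow(s) == 0L) {
      stop("split_groups: no ", lu, " sites retained for direction ",
           current_lu, " -> ", alternate_lu, call. = FALSE)
    }
    soc_inventory(
      s,
      f$inventory$increments[f$inventory$increments$site_id %in% s$site_id, ,
                             drop = FALSE],
      depth_scheme = f$inventory$depth_scheme,
      provenance = f$inventory$provenance, validate = FALSE
    )
  }
  list(current = take(current_lu), alternate = take(alternate_lu),
       report = f$report)
}
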