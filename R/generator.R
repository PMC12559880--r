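#' Configuration for the synthetic soil-inventory generator
#'
#' Defaults mirror the structure of the German agricultural and forest soil
#' inventories: land-use frequencies 0.45/0.17/0.38 (2234 cropland, 820
#' grassland, 1900 forest sites), WRB reference-soil-group frequencies led by
#' Cambisol (39%), Luvisol (13%) and Stagnosol (13%), mean annual
#' precipitation averaging 803 mm over 491-2144 mm, mean annual temperature
#' averaging 8.9 C over 4.6-11.3 C, and mean coarse-fragment volume of 6.8%
#' under forest, 1.4% under grassland and 3% under cropland. Depth profiles
#' decay exponentially with land-use-specific surface concentration and decay
#' rate; cropland is plow-homogenized over 0-30 cm. The WRB group multiplies
#' both the SOC level and the land-use contrast, making it the dominant driver
#' of change magnitude.
#'
#' @param n_sites Number of sites.
#' @param land_use_weights Probabilities over cropland/grassland/forest.
#' @param wrb_weights Named probabilities over WRB groups (must sum to 1).
#' @param map_range,map_mean Precipitation range (mm) and target mean.
#' @param mat_range,mat_mean Temperature range (C) and target mean.
#' @param coarse_mean_by_lu Mean volumetric coarse fraction per land use.
#' @param lu_effect Per land use, surface SOC concentration `A` (% at 0 cm)
#'   and depth-decay rate `k` (1/cm).
#' @param wrb_level Per-group multiplier on SOC concentration.
#' @param wrb_contrast Per-group exponent on the land-use profile term; groups
#'   above 1 show amplified land-use contrasts.
#' @param noise_sd Lognormal SD of the site-level SOC noise (mean 1).
#' @param obs_noise_sd Lognormal SD of per-increment measurement noise on SOC
#'   concentration.
#' @param p_nonequilibrium Fraction of agricultural sites planted to fail the
#'   equilibrium screen (recent land-use change or ley rotation).
#' @param litter_mean Mean forest litter C stock (Mg C ha-1) at the average
#'   0-10 cm mineral stock.
#' @param litter_slope Strength of the inverse litter / 0-10 cm relationship.
#' @param litter_noise_sd Lognormal SD of litter noise.
#' @param extent_m Plane extent `c(x, y)` in metres; large enough for >= 50
#'   blocks of 100 km.
#' @param seed RNG seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_sites = 1500,
    land_use_weights = c(cropland = 0.45, grassland = 0.17, forest = 0.38),
    wrb_weights = c(Cambisol = 0.39, Luvisol = 0.13, Stagnosol = 0.13,
                    Gleysol = 0.08, Fluvisol = 0.05, Podzol = 0.04,
                    Regosol = 0.04, Chernozem = 0.04, Vertisol = 0.04,
                    Anthrosol = 0.04, Histosol = 0.02),
    map_range = c(491, 2144), map_mean = 803,
    mat_range = c(4.6, 11.3), mat_mean = 8.9,
    coarse_mean_by_lu = c(cropland = 0.03, grassland = 0.014, forest = 0.068),
    lu_effect = list(cropland = c(A = 2.2, k = 0.035),
                     grassland = c(A = 4.0, k = 0.040),
                     forest = c(A = 4.8, k = 0.042)),
    wrb_level = c(Cambisol = 1.00, Luvisol = 0.75, Stagnosol = 1.10,
                  Gleysol = 1.60, Fluvisol = 1.50, Podzol = 1.20,
                  Regosol = 0.90, Chernozem = 1.30, Vertisol = 0.80,
                  Anthrosol = 1.05, Histosol = 5.00),
    wrb_contrast = c(Cambisol = 1.00, Luvisol = 0.85, Stagnosol = 1.05,
                     Gleysol = 1.15, Fluvisol = 1.10, Podzol = 1.00,
                     Regosol = 1.05, Chernozem = 0.95, Vertisol = 0.90,
                     Anthrosol = 1.00, Histosol = 1.00),
    noise_sd = 0.25, obs_noise_sd = 0.05,
    p_nonequilibrium = 0.15,
    litter_mean = 20, litter_slope = 0.6, litter_noise_sd = 0.25,
    extent_m = c(800e3, 700e3),
    seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(land_use_weights) - 1) < 1e-8,
            abs(sum(wrb_weights) - 1) < 1e-8,
            map_range[1] < map_range[2], mat_range[1] < mat_range[2],
            all(vapply(lu_effect, function(e) e[["k"]] > 0, logical(1))),
            noise_sd >= 0, obs_noise_sd >= 0)
  if (n_sites < 10 * length(wrb_weights)) {
    stop("generator_config: n_sites must be at least 10 x the number of WRB ",
         "groups (", 10 * length(wrb_weights), ") for stratified modelling",
         call. = FALSE)
  }
  class(cfg) <- "generator_config"
  cfg
}

# truncated draws via inverse CDF so the configured range is exact
.rtrunc_lnorm <- function(n, meanlog, sdlog, upper) {
  if (sdlog == 0) return(rep(exp(meanlog), n))
  qlnorm(runif(n) * plnorm(upper, meanlog, sdlog), meanlog, sdlog)
}
.rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(lower, mean, sd); hi <- pnorm(upper, mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

#' True equilibrium SOC concentration profile of a site under a land use
#'
#' Concentration at depth z is `A_LU * exp(-k_LU * z)`, raised to the site's
#' WRB contrast exponent, then multiplied by the WRB level, a clay term, a
#' precipitation term and the site's lognormal noise. Under cropland the
#' profile is replaced over 0-30 cm by its 0-30 cm mean (plow homogenization).
#'
#' @param factors List/row with `wrb_group, clay_pct, map_mm, eps` (site noise
#'   multiplier).
#' @param land_use Land use to evaluate.
#' @param config A [generator_config()].
#' @param depth_cm Profile depth (number of 1-cm slices).
#' @return Numeric vector of SOC concentration (%) per 1-cm slice.
#' @export
true_soc_profile <- function(factors, land_use, config, depth_cm = 90) {
  e <- config$lu_effect[[land_use]]
  z <- seq_len(depth_cm) - 0.5           # slice mid-depths
  s <- config$wrb_contrast[[factors$wrb_group]]
  m <- config$wrb_level[[factors$wrb_group]]
  g <- 0.75 + 0.01 * factors$clay_pct
  h <- (factors$map_mm / config$map_mean)^0.25
  conc <- (e[["A"]] * exp(-e[["k"]] * z))^s * m * g * h * factors$eps
  if (land_use == "cropland") {
    plow <- z < 30
    conc[plow] <- mean(conc[plow])
  }
  conc
}

#' True forest litter C stock of a site
#'
#' Lognormal draw whose location decreases with the site's true 0-10 cm
#' mineral SOC stock, producing the inverse litter/topsoil relationship seen
#' in forest inventories. With zero noise the litter stock is a strictly
#' decreasing function of the 0-10 cm stock.
#'
#' @param stock_0_10 True 0-10 cm mineral SOC stock (Mg C ha-1).
#' @param config A [generator_config()].
#' @param ref_stock Reference 0-10 cm stock at which the mean litter stock
#'   equals `litter_mean`.
#' @param noise Lognormal noise multiplier (mean 1), drawn by the caller.
#' @return Litter C stock, Mg C ha-1.
#' @export
true_litter <- function(stock_0_10, config, ref_stock = 35, noise = 1) {
  config$litter_mean * exp(-config$litter_slope *
                             (stock_0_10 - ref_stock) / ref_stock) * noise
}

.bd_profile <- function(z_mid, bd_factor) {
  pmin(pmax((0.95 + 0.45 * (1 - exp(-0.05 * z_mid))) * bd_factor, 0.5), 1.9)
}

#' Generate a synthetic soil inventory with known ground truth
#'
#' Emits agricultural sites on the agricultural depth scheme (0-10/10-30/
#' 30-50/50-70/70-100 cm) and forest sites on the forest scheme (0-5/5-10/
#' 10-30/30-60/60-90 cm plus litter), with predictor distributions, land-use
#' and soil-group frequencies per the configuration, and records the true
#' equilibrium SOC stock per 1-cm slice under every land use — hence the true
#' counterfactual stock change for all six land-use-change directions.
#' Generation is reproducible bit-for-bit given the seed.
#'
#' @param config A [generator_config()].
#' @return List with `inventory` (a `soc_inventory`, depth scheme `"mixed"`)
#'   and `truth` (a `soc_ground_truth`: slice stock array, litter, and helper
#'   accessors via [true_delta()]).
#' @export
generate_inventory <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_sites
  lus <- sample(.land_uses, n, replace = TRUE, prob = config$land_use_weights)
  wrb <- sample(names(config$wrb_weights), n, replace = TRUE,
                prob = config$wrb_weights)
  x <- runif(n, 0, config$extent_m[1])
  y <- runif(n, 0, config$extent_m[2])

  # climate: shifted truncated lognormal MAP, truncated normal MAT
  excess_mean <- config$map_mean - config$map_range[1]
  sdlog <- 0.65
  map <- config$map_range[1] +
    .rtrunc_lnorm(n, log(excess_mean) - sdlog^2 / 2, sdlog,
                  config$map_range[2] - config$map_range[1])
  mat <- .rtrunc_norm(n, config$mat_mean, 1.1,
                      config$mat_range[1], config$mat_range[2])
  drought <- map / (mat + 10) * exp(rnorm(n, 0, 0.05))   # de-Martonne-like
  elevation <- pmin(exp(rnorm(n, log(180), 0.7)), 1500)
  slope <- rgamma(n, shape = 1.5, scale = 1.5)
  ndvi <- pmin(pmax(0.55 + 0.1 * (map - config$map_mean) / 500 +
                      rnorm(n, 0, 0.08), 0.1), 0.95)
  groundwater <- sample(1:6, n, replace = TRUE,
                        prob = c(0.05, 0.1, 0.15, 0.2, 0.25, 0.25))
  parent_material <- sample(c("loess", "till", "alluvium", "bedrock", "sand"),
                            n, replace = TRUE,
                            prob = c(0.3, 0.25, 0.15, 0.15, 0.15))

  # texture: Dirichlet clay/silt/sand clipped to observed extremes
  a <- cbind(rgamma(n, 2.2), rgamma(n, 3.5), rgamma(n, 4.3))
  tex <- a / rowSums(a) * 100
  tex[, 1] <- pmin(tex[, 1], 76)
  tex[, 3] <- pmin(tex[, 3], 96)
  tex <- tex / rowSums(tex) * 100
  clay <- tex[, 1]; silt <- tex[, 2]

  coarse <- pmin(config$coarse_mean_by_lu[lus] *
                   exp(rnorm(n, -0.18, 0.6)), 0.8)  # lognormal, mean ~ target
  bd_factor <- exp(rnorm(n, 0, 0.05))
  eps <- if (config$noise_sd > 0) {
    rlnorm(n, -config$noise_sd^2 / 2, config$noise_sd)
  } else rep(1, n)

  # site histories: ~p_nonequilibrium of agricultural sites fail the screen
  is_ag <- lus != "forest"
  u <- runif(n)
  noneq <- is_ag & u < config$p_nonequilibrium
  ley <- noneq & lus == "cropland" & runif(n) < 0.5
  recent <- noneq & !ley
  unbroken <- is_ag & !noneq & runif(n) < 0.7
  had_luc <- rep(FALSE, n)
  had_luc[recent] <- TRUE
  had_luc[is_ag & !noneq & !unbroken] <- TRUE
  thr <- ifelse(lus == "cropland", 151, 79)
  years <- integer(n)
  years[is_ag] <- ifelse(recent[is_ag],
                         sample(5:70, sum(is_ag), replace = TRUE),
                         thr[is_ag] + sample(0:150, sum(is_ag), replace = TRUE))
  years[!is_ag] <- sample(80:300, sum(!is_ag), replace = TRUE)

  # true stock per 1-cm slice under each land use (0-90 cm; cropland/grassland
  # profiles are evaluated to 100 cm for the agricultural sampling scheme)
  # two renderings of the truth: exact 1-cm slice stocks, and the same
  # profiles as recorded through the native fixed-depth sampling scheme of
  # the inventory that measures each land use (constant values within
  # sampled increments) — the latter is the estimand the harmonized
  # pipeline can actually recover
  # site-parallel profile computation: conc[i, z] per land use, with the
  # WRB contrast exponent applied in log space
  z_mid <- seq_len(100) - 0.5
  s_site <- config$wrb_contrast[wrb]
  mod_site <- config$wrb_level[wrb] * (0.75 + 0.01 * clay) *
    (map / config$map_mean)^0.25 * eps
  bd_mat <- pmin(pmax(outer(bd_factor,
                            0.95 + 0.45 * (1 - exp(-0.05 * z_mid))),
                      0.5), 1.9)                 # n x 100
  slice_stock <- array(NA_real_, dim = c(n, 100, 3),
                       dimnames = list(NULL, NULL, .land_uses))
  scheme_stock <- array(NA_real_, dim = c(n, 100, 3),
                        dimnames = list(NULL, NULL, .land_uses))
  conc_all <- slice_stock
  w_mat <- bd_mat * (1 - coarse)                 # fine-soil mass per slice
  for (lu in .land_uses) {
    e <- config$lu_effect[[lu]]
    conc <- exp(outer(s_site, log(e[["A"]] * exp(-e[["k"]] * z_mid)))) * mod_site
    if (lu == "cropland") conc[, 1:30] <- rowMeans(conc[, 1:30])
    conc_all[, , lu] <- conc
    slice_stock[, , lu] <- conc * bd_mat * (1 - coarse)
    sch <- .depth_schemes[[if (lu == "forest") "forest" else "agricultural"]]
    flat <- conc
    for (j in seq_len(nrow(sch))) {
      sl <- (sch[j, "top"] + 1):sch[j, "bottom"]
      flat[, sl] <- rowSums(conc[, sl, drop = FALSE] * w_mat[, sl, drop = FALSE]) /
        rowSums(w_mat[, sl, drop = FALSE])
    }
    scheme_stock[, , lu] <- flat * bd_mat * (1 - coarse)
  }
  # pH and C:N are site properties, independent of land use within the
  # agricultural contrast (they enter cropland/grassland models as predictors);
  # forest sites are acidified and litter-widened, but forest-involving models
  # exclude both.
  ph_site <- 5.9 + 0.012 * clay + rnorm(n, 0, 0.25) - ifelse(lus == "forest", 1.6, 0)
  cn_site <- ifelse(lus == "forest", 20, 10.5) * exp(rnorm(n, 0, 0.06))
  litter_noise <- if (config$litter_noise_sd > 0) {
    rlnorm(n, -config$litter_noise_sd^2 / 2, config$litter_noise_sd)
  } else rep(1, n)
  true_litter_all <- true_litter(rowSums(slice_stock[, 1:10, "forest", drop = FALSE]),
                                 config, noise = litter_noise)

  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(n)), x = x, y = y, land_use = lus,
    years_under_lu = years, had_luc_in_record = had_luc, ley_rotation = ley,
    wrb_group = wrb, is_histosol = wrb == "Histosol",
    litter_c_stock = ifelse(lus == "forest", true_litter_all, NA_real_),
    map_mm = map, mat_c = mat, drought_index = drought,
    elevation_m = elevation, slope_deg = slope,
    groundwater_class = groundwater, ndvi = ndvi,
    parent_material = parent_material, coarse_frac = coarse,
    stringsAsFactors = FALSE
  )

  # observed increments on the native sampling scheme of each land use;
  # measurement noise multiplies the increment SOC concentration
  obs_mult <- matrix(if (config$obs_noise_sd > 0) {
    rlnorm(n * 5, -config$obs_noise_sd^2 / 2, config$obs_noise_sd)
  } else 1, nrow = n, ncol = 5)
  cn_jitter <- matrix(exp(rnorm(n * 5, 0, 0.05)), nrow = n)
  ph_jitter <- matrix(rnorm(n * 5, 0, 0.1), nrow = n)
  inc_parts <- vector("list", 2L)
  for (g in 1:2) {
    scheme <- .depth_schemes[[c("agricultural", "forest")[g]]]
    idx <- which(if (g == 1) lus != "forest" else lus == "forest")
    if (!length(idx)) next
    n_inc <- nrow(scheme)
    conc_own <- matrix(NA_real_, length(idx), 100L)
    for (lu in unique(lus[idx])) {
      pick <- lus[idx] == lu
      conc_own[pick, ] <- conc_all[idx[pick], , lu]
    }
    soc_obs <- bd_obs <- matrix(NA_real_, length(idx), n_inc)
    for (j in seq_len(n_inc)) {
      sl <- (scheme[j, "top"] + 1):scheme[j, "bottom"]
      wsl <- w_mat[idx, sl, drop = FALSE]
      cm <- rowSums(conc_own[, sl, drop = FALSE] * wsl) / rowSums(wsl)
      soc_obs[, j] <- cm * obs_mult[idx, j]
      bd_obs[, j] <- rowMeans(bd_mat[idx, sl, drop = FALSE])
    }
    cn_obs <- cn_site[idx] * cn_jitter[idx, seq_len(n_inc)]
    inc_parts[[g]] <- data.frame(
      site_id = rep(sites$site_id[idx], times = n_inc),
      top_cm = rep(scheme[, "top"], each = length(idx)),
      bottom_cm = rep(scheme[, "bottom"], each = length(idx)),
      soc_pct = as.vector(soc_obs), bd_fine = as.vector(bd_obs),
      rff = rep(coarse[idx], times = n_inc),
      clay_pct = rep(clay[idx], times = n_inc),
      silt_pct = rep(silt[idx], times = n_inc),
      ph = rep(ph_site[idx], times = n_inc) +
        0.2 * log1p(rep(scheme[, "top"], each = length(idx)) / 10) +
        as.vector(ph_jitter[idx, seq_len(n_inc)]),
      cn_ratio = as.vector(cn_obs),
      n_pct = as.vector(soc_obs / cn_obs),
      stringsAsFactors = FALSE
    )
  }
  increments <- do.call(rbind, inc_parts)
  inv <- soc_inventory(sites, increments, depth_scheme = "mixed",
                       provenance = sprintf("synthetic (seed %d)", config$seed))

  truth <- structure(list(
    site_id = sites$site_id,
    slice_stock = slice_stock[, 1:90, , drop = FALSE],
    scheme_stock = scheme_stock[, 1:90, , drop = FALSE],
    litter = true_litter_all,
    config = config
  ), class = "soc_ground_truth")
  list(inventory = inv, truth = truth)
}

#' True counterfactual stock change for a land-use-change direction
#'
#' For each site, the ground-truth equilibrium change in SOC stock per target
#' stratum when converting from `from_lu` to `to_lu`: the difference of true
#' slice-stock sums (mineral strata), and the signed true litter stock for the
#' litter stratum (+ when converting to forest, - when converting away).
#' Antisymmetric by construction: `true_delta(A, B) = -true_delta(B, A)`.
#'
#' Two renderings are available. `scheme = "slice"` sums the exact 1-cm
#' truth. `scheme = "inventory"` (default) first passes each land use's true
#' profile through the fixed-depth sampling scheme of the inventory that
#' measures it (constant values within sampled increments) — the estimand a
#' pipeline working from the harmonized increment data can actually recover;
#' the difference between the two quantifies the depth-harmonization
#' distortion where increment bounds do not align with the target strata.
#'
#' @param truth A `soc_ground_truth`.
#' @param from_lu,to_lu Land uses.
#' @param site_ids Optional subset of sites.
#' @param scheme `"inventory"` or `"slice"` (see above).
#' @return data.frame site_id x stratum of true deltas (Mg C ha-1), mineral
#'   strata only plus a `litter` column when forest is involved (else NA).
#' @export
true_delta <- function(truth, from_lu, to_lu, site_ids = NULL,
                       scheme = c("inventory", "slice")) {
  scheme <- match.arg(scheme)
  stock <- if (scheme == "inventory") truth$scheme_stock else truth$slice_stock
  idx <- if (is.null(site_ids)) seq_along(truth$site_id) else
    match(site_ids, truth$site_id)
  strata <- target_strata()
  out <- data.frame(site_id = truth$site_id[idx], stringsAsFactors = FALSE)
  for (j in seq_len(nrow(strata))) {
    sl <- (strata[j, "top"] + 1):strata[j, "bottom"]
    d <- rowSums(stock[idx, sl, to_lu, drop = FALSE]) -
      rowSums(stock[idx, sl, from_lu, drop = FALSE])
    out[[paste0(strata[j, "top"], "-", strata[j, "bottom"], " cm")]] <- d
  }
  out$litter <- if (to_lu == "forest") truth$litter[idx]
  else if (from_lu == "forest") -truth$litter[idx]
  else NA_real_
  out
}
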