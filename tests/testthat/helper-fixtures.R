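# Shared fixture builders. Everything is generated in code; no binary data.

# a tiny two-site agricultural inventory with hand-set values
toy_inventory <- function() {
  sites <- data.frame(
    site_id = c("A1", "A2"), x = c(1e3, 2e5), y = c(5e3, 3e5),
    land_use = c("cropland", "grassland"),
    years_under_lu = c(200L, 120L), had_luc_in_record = c(FALSE, TRUE),
    ley_rotation = c(FALSE, FALSE),
    wrb_group = c("Cambisol", "Luvisol"), is_histosol = c(FALSE, FALSE),
    litter_c_stock = c(NA_real_, NA_real_),
    map_mm = c(700, 900), mat_c = c(8.5, 9.2), drought_index = c(38, 47),
    elevation_m = c(120, 340), slope_deg = c(1.2, 3.4),
    groundwater_class = c(3L, 5L), ndvi = c(0.62, 0.71),
    parent_material = c("loess", "till"), coarse_frac = c(0.05, 0.01),
    stringsAsFactors = FALSE
  )
  scheme <- cbind(top = c(0, 10, 30, 50, 70), bottom = c(10, 30, 50, 70, 100))
  inc <- do.call(rbind, lapply(1:2, function(i) {
    data.frame(
      site_id = sites$site_id[i],
      top_cm = scheme[, "top"], bottom_cm = scheme[, "bottom"],
      soc_pct = c(2.1, 1.6, 0.8, 0.4, 0.2) * i,
      bd_fine = c(1.2, 1.3, 1.4, 1.5, 1.55),
      rff = sites$coarse_frac[i],
      clay_pct = 22 + i, silt_pct = 40 - i,
      ph = c(6.4, 6.5, 6.6, 6.7, 6.8),
      cn_ratio = 10 + i, n_pct = 0.1,
      stringsAsFactors = FALSE
    )
  }))
  soc_inventory(sites, inc)
}

# a profile of random increments on the agricultural scheme
random_ag_increments <- function() {
  scheme <- cbind(top = c(0, 10, 30, 50, 70), bottom = c(10, 30, 50, 70, 100))
  data.frame(
    site_id = "R", top_cm = scheme[, "top"], bottom_cm = scheme[, "bottom"],
    soc_pct = runif(5, 0.1, 4), bd_fine = runif(5, 0.9, 1.7),
    rff = runif(5, 0, 0.5), clay_pct = runif(5, 5, 50),
    silt_pct = runif(5, 10, 45), ph = runif(5, 4.5, 7.5),
    cn_ratio = runif(5, 8, 25), n_pct = runif(5, 0.01, 0.3),
    stringsAsFactors = FALSE
  )
}

# small synthetic generation cached per test run
small_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_inventory(generator_config(n_sites = 400, seed = 101))
    }
    cache
  }
})

# a frame + fold plan with a planted linear signal for ensemble tests
linear_frame <- function(n = 120, noise_sd = 0, seed = 7) {
  set.seed(seed)
  d <- data.frame(
    site_id = sprintf("L%04d", seq_len(n)),
    x = runif(n, 0, 800e3), y = runif(n, 0, 700e3),
    clay_pct = runif(n, 5, 60), silt_pct = runif(n, 10, 50),
    coarse_frac = runif(n, 0, 0.2), slope_deg = runif(n, 0, 8),
    elevation_m = runif(n, 20, 800), drought_index = runif(n, 25, 60),
    map_mm = runif(n, 500, 1500), mat_c = runif(n, 5, 11),
    ph = runif(n, 4.5, 7.5), cn_ratio = runif(n, 8, 25),
    wrb_group = sample(c("Cambisol", "Luvisol", "Gleysol"), n, replace = TRUE),
    parent_material = sample(c("loess", "till"), n, replace = TRUE),
    groundwater_class = sample(1:4, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  d$target <- 2 * d$clay_pct + rnorm(n, 0, noise_sd)
  d
}

# an analytic stand-in model: predictions are a deterministic function of the
# data frame (used with an explicit predict_fun), so ALE has a closed form
oracle_model <- function(f) structure(list(f = f), class = "ale_oracle")

lean_control <- function(...) {
  args <- utils::modifyList(
    list(n_iter = 2, inner_k = 3, n_perm = 2, num_trees = 60,
         gbt_rounds = c(40, 120)),
    list(...))
  do.call(ensemble_control, args)
}
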