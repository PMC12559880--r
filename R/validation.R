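#' Settings of the scaled-down validation study
#'
#' The fixed design used to validate parameter recovery on synthetic
#' inventories: 1500 sites, the grassland-to-cropland direction (its
#' counterfactual model trains on the largest land-use group, which keeps
#' model error small relative to the bootstrap interval over the ~200
#' predicted sites), two repeats of the spatial 5-fold plan, and reduced
#' learner budgets sized for a single CPU.
#'
#' @return List with `n_sites`, `direction` and a [direction_control()].
#' @export
validation_settings <- function() {
  list(
    n_sites = 1500,
    direction = c("grassland", "cropland"),
    control = direction_control(
      repeats = 2, k = 5,
      ensemble = ensemble_control(n_iter = 2, inner_k = 2, n_perm = 1,
                                  num_trees = 60, gbt_rounds = c(40, 100),
                                  svr_cost_log10 = c(-1, 2)),
      n_boot = 10000
    )
  )
}

#' Parameter-recovery experiment on one synthetic inventory
#'
#' Generates an inventory with known counterfactual ground truth, runs the
#' full reciprocal pipeline for the validation direction, and checks per
#' stratum whether the 95% bootstrap interval of the estimated mean stock
#' change covers the generator's ground-truth mean over the same
#' applicability-retained sites (ground truth rendered through the
#' inventories' sampling schemes, the estimand the harmonized data carry).
#'
#' @param seed Seed for generation, fitting and bootstrap.
#' @param settings A [validation_settings()] list.
#' @return data.frame per stratum: estimate, CI bounds, ground-truth mean,
#'   `covered`.
#' @export
recovery_experiment <- function(seed, settings = validation_settings()) {
  gen <- generate_inventory(generator_config(n_sites = settings$n_sites,
                                             seed = seed))
  h <- harmonize_inventory(gen$inventory)
  res <- run_direction(h, settings$direction[1], settings$direction[2],
                       control = settings$control, seed = seed)
  st <- res$summary$strata
  rows <- lapply(seq_len(nrow(st)), function(i) {
    keep <- res$deltas$site_id[res$deltas$in_aoa &
                                 res$deltas$stratum == st$stratum[i]]
    tm <- mean(true_delta(gen$truth, settings$direction[1],
                          settings$direction[2],
                          site_ids = keep)[[st$stratum[i]]])
    data.frame(seed = seed, stratum = st$stratum[i], n = st$n[i],
               estimate = st$mean_delta[i], ci_low = st$ci_low[i],
               ci_high = st$ci_high[i], truth = tm,
               covered = tm >= st$ci_low[i] & tm <= st$ci_high[i])
  })
  do.call(rbind, rows)
}

#' Driver-recovery experiment on one synthetic inventory
#'
#' Generates an inventory whose WRB soil group multiplies the land-use
#' contrast, computes the ground-truth change magnitudes for the
#' cropland/grassland pair, fits the driver model, and reports the
#' permutation-importance rank of the WRB group.
#'
#' @param seed Seed.
#' @param n_sites Inventory size.
#' @return List with `rank_wrb` (1 = most important) and the importance
#'   vector.
#' @export
driver_recovery_experiment <- function(seed, n_sites = 1000) {
  gen <- generate_inventory(generator_config(n_sites = n_sites, seed = seed))
  h <- harmonize_inventory(gen$inventory)
  s <- filter_sites(h)$inventory
  ag <- s$sites$site_id[s$sites$land_use != "forest"]
  mk <- function(from, to, ids) {
    td <- true_delta(gen$truth, from, to, site_ids = ids)
    data.frame(site_id = td$site_id, direction = paste(from, "to", to),
               magnitude = rowSums(abs(as.matrix(td[stratum_labels()]))))
  }
  crop <- s$sites$site_id[s$sites$land_use == "cropland"]
  grass <- s$sites$site_id[s$sites$land_use == "grassland"]
  mags <- rbind(mk("cropland", "grassland", crop),
                mk("grassland", "cropland", grass))
  frame <- driver_frame(mags, s)
  dm <- fit_driver_model(
    frame,
    control = direction_control(repeats = 1, k = 5,
                                ensemble = ensemble_control(
                                  n_iter = 2, inner_k = 2, n_perm = 2,
                                  num_trees = 60, gbt_rounds = c(40, 100),
                                  svr_cost_log10 = c(-1, 2))),
    seed = seed)
  imp <- sort(dm$importance$raw, decreasing = TRUE)
  list(rank_wrb = which(names(imp) == "wrb_group"), importance = imp)
}
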