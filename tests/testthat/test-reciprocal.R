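test_that("bootstrap interval matches the binomial closed form", {
  v <- rep(c(0, 1), 500)
  ci <- bootstrap_ci(v, n_boot = 10000, seed = 3)
  expect_equal(ci[["mean"]], 0.5)
  # closed form: 0.5 +- 1.96 * sqrt(0.25/1000) = (0.469, 0.531)
  expect_equal(ci[["low"]], 0.469, tolerance = 0.01)
  expect_equal(ci[["high"]], 0.531, tolerance = 0.01)
  expect_true(ci[["low"]] < 0.5 && ci[["high"]] > 0.5)
  # constant vector: degenerate interval
  expect_equal(bootstrap_ci(rep(2.5, 10), n_boot = 100, seed = 1),
               c(mean = 2.5, low = 2.5, high = 2.5))
  expect_error(bootstrap_ci(1), "at least 2")
  # deterministic given seed
  set.seed(1); w <- rnorm(50)
  expect_identical(bootstrap_ci(w, seed = 9), bootstrap_ci(w, seed = 9))
  expect_false(identical(bootstrap_ci(w, seed = 9)[["low"]],
                         bootstrap_ci(w, seed = 10)[["low"]]))
})

test_that("more bootstrap replicates move bounds less than Monte-Carlo error", {
  set.seed(5)
  v <- rnorm(200, 10, 4)
  ci1 <- bootstrap_ci(v, n_boot = 1000, seed = 7)
  ci2 <- bootstrap_ci(v, n_boot = 10000, seed = 7)
  # MC standard error of a 2.5% quantile estimate at B=1000 for a mean with
  # SE sigma/sqrt(n); allow 3 x
  mc_se <- 3 * (sd(v) / sqrt(length(v))) * sqrt(0.025 * 0.975 / 1000) /
    dnorm(qnorm(0.025))
  expect_lt(abs(ci1[["low"]] - ci2[["low"]]), mc_se)
  expect_lt(abs(ci1[["high"]] - ci2[["high"]]), mc_se)
})

test_that("summary-table arithmetic reproduces published aggregation rows", {
  # means as printed for cropland -> grassland
  s <- summarize_from_means(c("0-10 cm" = 21.5, "10-30 cm" = 10.9,
                              "30-60 cm" = 7.7, "60-90 cm" = 4.5))
  expect_equal(s$mineral_total, 44.6)
  expect_equal(s$overall_total, 44.6)
  # cropland -> forest with litter
  s2 <- summarize_from_means(c("litter" = 19.7, "0-10 cm" = 19.1,
                               "10-30 cm" = -5.2, "30-60 cm" = 3.9,
                               "60-90 cm" = 2.9))
  expect_equal(s2$mineral_total, 20.7, tolerance = 1e-12)
  expect_equal(s2$overall_total, 40.4, tolerance = 1e-12)
  # all-zero deltas: zero totals, undefined share
  s3 <- summarize_from_means(c("0-10 cm" = 0, "10-30 cm" = 0,
                               "30-60 cm" = 0, "60-90 cm" = 0))
  expect_equal(s3$mineral_total, 0)
  expect_true(is.na(s3$subsoil_share_pct))
})

test_that("oracle model injection yields zero deltas and degenerate CIs", {
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  res <- run_direction(h, "cropland", "grassland",
                       control = direction_control(n_boot = 200),
                       seed = 4,
                       predict_fn = function(frame, stratum) frame$target)
  d <- res$deltas
  expect_true(all(d$delta == 0))
  expect_true(all(d$in_aoa))
  st <- res$summary$strata
  expect_equal(st$mean_delta, rep(0, 4))
  expect_equal(st$ci_low, rep(0, 4))
  expect_equal(st$ci_high, rep(0, 4))
  expect_equal(res$summary$mineral_total, 0)
  # Eq.-2 identity on every record
  expect_equal(d$delta, d$predicted_stock - d$observed_stock)
  # bookkeeping: per-stratum site count equals the retained group size
  expect_true(all(table(d$stratum) <= nrow(res$pre_stocks) / 4 + 1e-9))
})

test_that("direction summary identities hold on a fitted run", {
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  res <- run_direction(h, "grassland", "cropland",
    control = direction_control(repeats = 2, k = 4, cell_size = 200e3,
                                ensemble = lean_control(),
                                n_boot = 500), seed = 21)
  s <- res$summary
  st <- s$strata
  expect_equal(s$mineral_total, sum(st$mean_delta[st$stratum != "litter"]),
               tolerance = 1e-12)
  expect_equal(s$overall_total, s$mineral_total, tolerance = 1e-12) # no litter
  expect_true(all(st$ci_low <= st$mean_delta & st$mean_delta <= st$ci_high))
  # per-record identity, where populated
  ok <- res$deltas$in_aoa
  expect_equal(res$deltas$delta[ok],
               res$deltas$predicted_stock[ok] - res$deltas$observed_stock[ok])
  expect_true(all(is.na(res$deltas$delta[!ok])))
})

test_that("forest-involving directions carry a signed litter stratum", {
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  # away from forest: litter removed, delta = -observed, no model involved
  res <- run_direction(h, "forest", "cropland",
    control = direction_control(repeats = 1, k = 4, cell_size = 200e3,
                                ensemble = lean_control(), n_boot = 300),
    seed = 31)
  lit <- res$deltas[res$deltas$stratum == "litter", ]
  expect_true(all(lit$delta <= 0))
  expect_equal(lit$delta, -lit$observed_stock)
  s <- res$summary
  litter_mean <- s$strata$mean_delta[s$strata$stratum == "litter"]
  expect_equal(s$overall_total, s$mineral_total + litter_mean,
               tolerance = 1e-12)
  expect_lt(litter_mean, 0)
})

test_that("reciprocal oracle runs are antisymmetric on symmetric groups", {
  # with truth-injected predictions the two directions of a pair are exact
  # mirrors up to group composition
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  truth <- gen$truth
  mk_fn <- function(to_lu) function(frame, stratum) {
    sl <- list("0-10 cm" = 1:10, "10-30 cm" = 11:30,
               "30-60 cm" = 31:60, "60-90 cm" = 61:90)[[stratum]]
    idx <- match(frame$site_id, truth$site_id)
    rowSums(truth$scheme_stock[idx, sl, to_lu, drop = FALSE])
  }
  ab <- run_direction(h, "cropland", "grassland",
                      control = direction_control(n_boot = 200), seed = 1,
                      predict_fn = mk_fn("grassland"))
  ba <- run_direction(h, "grassland", "cropland",
                      control = direction_control(n_boot = 200), seed = 1,
                      predict_fn = mk_fn("cropland"))
  # totals have opposite signs and similar magnitude (site noise only)
  expect_gt(ab$summary$mineral_total, 0)
  expect_lt(ba$summary$mineral_total, 0)
})
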