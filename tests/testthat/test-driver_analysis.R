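test_that("change magnitude is the sum of absolute stratum deltas", {
  mk <- function(site, deltas, in_aoa = TRUE) {
    data.frame(site_id = site, direction = "cropland to grassland",
               stratum = stratum_labels(), observed_stock = 0,
               predicted_stock = deltas, delta = deltas, in_aoa = in_aoa,
               di = 0, pred_iqr = 0, stringsAsFactors = FALSE)
  }
  d <- rbind(mk("S1", c(21.5, 10.9, 7.7, 4.5)),
             mk("S2", c(19.1, -5.2, 3.9, 2.9)),
             mk("S3", c(0, 0, 0, 0)))
  m <- magnitude_target(d)
  expect_equal(m$magnitude[m$site_id == "S1"], 44.6)
  expect_equal(m$magnitude[m$site_id == "S2"], 31.1)
  expect_equal(m$magnitude[m$site_id == "S3"], 0)
  # a site missing one stratum is dropped
  d4 <- rbind(d, mk("S4", c(1, 2, 3, 4))[-2, ])
  expect_false("S4" %in% magnitude_target(d4)$site_id)
  # out-of-applicability strata do not count
  d5 <- mk("S5", c(1, 2, 3, 4)); d5$in_aoa[1] <- FALSE
  expect_false("S5" %in% magnitude_target(d5)$site_id)
})

test_that("centered ALE of a linear oracle recovers the slope", {
  set.seed(10)
  d <- data.frame(x1 = runif(400, -2, 5), x2 = rnorm(400))
  m <- oracle_model(function(nd) 3 * nd$x1)
  a <- ale_numeric(m, d, "x1", n_bins = 15,
                   predict_fun = function(o, nd) o$f(nd))
  cv <- a$curve
  slopes <- diff(cv$centered) / diff(cv$edge)
  expect_lt(max(abs(slopes - 3)), 1e-9)
  # centering: count-weighted mean of the per-edge effects is zero
  expect_lt(abs(sum(cv$count * cv$centered) / sum(cv$count)), 1e-10)
  # unused feature: identically zero
  a2 <- ale_numeric(m, d, "x2", n_bins = 15,
                    predict_fun = function(o, nd) o$f(nd))
  expect_true(all(abs(a2$curve$centered) < 1e-12))
})

test_that("ALE of an additive model recovers each component up to a constant", {
  set.seed(11)
  d <- data.frame(x1 = runif(500, 0, 1), x2 = runif(500, -1, 1))
  f <- function(nd) 2 * nd$x1^2 - 1.5 * nd$x2
  a1 <- ale_numeric(oracle_model(f), d, "x1", n_bins = 20,
                    predict_fun = function(o, nd) o$f(nd))
  cv <- a1$curve
  shape <- 2 * cv$edge^2
  expect_lt(max(abs((cv$centered - mean(cv$centered)) -
                      (shape - mean(shape)))), 0.02)
})

test_that("first-order ALE cancels pure interactions with symmetric partners", {
  set.seed(12)
  d <- data.frame(x1 = runif(2000, 0, 1), x2 = rnorm(2000))  # x2 symmetric at 0
  f <- function(nd) nd$x1 * nd$x2
  a <- ale_numeric(oracle_model(f), d, "x1", n_bins = 10,
                   predict_fun = function(o, nd) o$f(nd))
  # bin-wise E[x2] ~ 0, so accumulated effects are ~0 up to MC error
  expect_lt(max(abs(a$curve$centered)), 4 / sqrt(2000 / 10))
})

test_that("constant feature yields a flat zero curve with a warning", {
  d <- data.frame(x1 = rep(2, 50), x2 = rnorm(50))
  expect_warning(a <- ale_numeric(oracle_model(function(nd) nd$x2), d, "x1",
                                  predict_fun = function(o, nd) o$f(nd)),
                 "constant feature")
  expect_true(all(a$curve$centered == 0))
})

test_that("categorical ALE isolates a planted category effect", {
  set.seed(13)
  d <- data.frame(g = sample(c("a", "b", "c", "d"), 400, replace = TRUE),
                  z = rnorm(400), stringsAsFactors = FALSE)
  f <- function(nd) ifelse(nd$g == "c", 10, 0)
  a <- ale_categorical(oracle_model(f), d, "g",
                       predict_fun = function(o, nd) o$f(nd))
  cv <- a$curve
  expect_equal(cv$category[which.max(cv$centered)], "c")
  others <- cv$centered[cv$category != "c"]
  expect_lt(max(others) - min(others), 1e-9)
  expect_equal(max(cv$centered) - max(others), 10, tolerance = 1e-9)
  expect_lt(abs(sum(cv$count * cv$centered) / sum(cv$count)), 1e-10)
  # feature ignored by the model: all effects zero
  a0 <- ale_categorical(oracle_model(function(nd) nd$z), d, "g",
                        predict_fun = function(o, nd) o$f(nd))
  expect_true(all(abs(a0$curve$centered) < 1e-9))
  # ordering invariant to input row order
  o <- sample(nrow(d))
  a2 <- ale_categorical(oracle_model(f), d[o, ], "g",
                        predict_fun = function(o_, nd) o_$f(nd))
  expect_equal(a2$curve$category, a$curve$category)
})

test_that("ALE through a fitted ensemble centers and responds to signal", {
  d <- linear_frame(n = 120, noise_sd = 1)
  plan <- assign_spatial_folds(d$x, d$y, cell_size = 200e3, k = 4,
                               repeats = 1, seed = 2)
  fit <- soc_ensemble(d, predictor_spec("agricultural"), plan,
                      control = lean_control(), seed = 3)
  a <- ale_numeric(fit, d, "clay_pct", n_bins = 8)
  cv <- a$curve
  expect_lt(abs(sum(cv$count * cv$centered) / sum(cv$count)), 1e-10)
  # monotone increasing signal overall (target = 2 * clay)
  expect_gt(cv$centered[nrow(cv)] - cv$centered[1], 0)
})

test_that("driver model recovers a soil-group-multiplied planted effect", {
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  f <- filter_sites(h)
  s <- f$inventory$sites
  keep <- s$land_use != "forest"
  td_ab <- true_delta(gen$truth, "cropland", "grassland",
                      site_ids = s$site_id[keep])
  mags <- data.frame(site_id = td_ab$site_id,
                     direction = "cropland to grassland",
                     magnitude = rowSums(abs(as.matrix(
                       td_ab[stratum_labels()]))))
  frame <- driver_frame(mags, f$inventory)
  dm <- fit_driver_model(frame,
                         control = direction_control(repeats = 1, k = 5,
                                                     ensemble = lean_control(n_perm = 3)),
                         seed = 17)
  rank_wrb <- which(names(sort(dm$importance$raw, decreasing = TRUE)) ==
                      "wrb_group")
  expect_lte(rank_wrb, 3)
  expect_true(all(dm$importance$raw >= 0))
  # deterministic given seed
  dm2 <- fit_driver_model(frame,
                          control = direction_control(repeats = 1, k = 5,
                                                      ensemble = lean_control(n_perm = 3)),
                          seed = 17)
  expect_identical(dm$importance, dm2$importance)
})
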