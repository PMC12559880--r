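test_that("stock computation matches the unit-conversion oracle", {
  # 2% of 1.3 g cm-3 fine soil, 10% rock, 10 cm: 0.234 g cm-2 = 23.4 Mg ha-1
  expect_equal(soc_stock(2.0, 1.3, 0.10, 10), 23.4)
  expect_equal(soc_stock(0, 1.3, 0.1, 10), 0)
  expect_equal(soc_stock(3.7, 1.1, 1.0, 25), 0)   # all-rock layer
  expect_equal(soc_stock(c(2, 0), c(1.3, 1), c(0.1, 0), c(10, 5)), c(23.4, 0))
  expect_error(soc_stock(-1, 1.3, 0.1, 10), "domain")
  expect_error(soc_stock(2, 1.3, 1.4, 10), "domain")
})

test_that("downscaling inherits increment values and checks structure", {
  inc <- random_ag_increments()
  prof <- downscale(inc)
  expect_equal(nrow(prof), 100L)
  expect_equal(prof$soc_pct[1:10], rep(inc$soc_pct[1], 10))
  expect_equal(prof$origin, rep(1:5, times = c(10, 20, 20, 20, 30)))
  gap <- inc; gap$top_cm[3] <- 32
  expect_error(downscale(gap), "gap or overlap")
  shifted <- inc; shifted$top_cm[1] <- 2
  expect_error(downscale(shifted), "start at 0")
})

test_that("downscale then aggregate conserves every stock", {
  set.seed(9)
  targets <- target_strata()
  ag <- cbind(top = c(0, 10, 30, 50, 70), bottom = c(10, 30, 50, 70, 100))
  for (i in 1:200) {
    inc <- random_ag_increments()
    prof <- downscale(inc)
    # back to the original scheme: every increment's stock is reproduced
    back <- aggregate_slices(prof, ag)
    expect_equal(back$oc_stock,
                 soc_stock(inc$soc_pct, inc$bd_fine, inc$rff,
                           inc$bottom_cm - inc$top_cm),
                 tolerance = 1e-9)
    # total 0-90 stock is invariant to the target split
    agg <- aggregate_slices(prof, targets)
    expect_equal(sum(agg$oc_stock),
                 sum(soc_stock(prof$soc_pct, prof$bd_fine, prof$rff,
                               1)[1:90]),
                 tolerance = 1e-9)
  }
})

test_that("aggregation weighting follows the harmonization scheme", {
  inc <- random_ag_increments()
  prof <- downscale(inc)
  # 30-60 cm target: bd is a thickness-weighted mean of the 30-50 and 50-70
  # source increments with weights 20:10
  agg <- aggregate_slices(prof, cbind(30, 60))
  expect_equal(agg$bd_fine, (20 * inc$bd_fine[3] + 10 * inc$bd_fine[4]) / 30)
  expect_equal(agg$rff, (20 * inc$rff[3] + 10 * inc$rff[4]) / 30)
  # concentration-like properties use fine-soil-stock weights
  w <- c(20 * inc$bd_fine[3] * (1 - inc$rff[3]),
         10 * inc$bd_fine[4] * (1 - inc$rff[4]))
  expect_equal(agg$soc_pct, sum(c(inc$soc_pct[3], inc$soc_pct[4]) * w) / sum(w))
  expect_equal(agg$ph, sum(c(inc$ph[3], inc$ph[4]) * w) / sum(w))
  # uniform profile: any split returns the same values
  u <- inc; for (p in c("soc_pct", "bd_fine", "rff", "ph")) u[[p]] <- u[[p]][1]
  ua <- aggregate_slices(downscale(u), target_strata())
  expect_equal(ua$soc_pct, rep(u$soc_pct[1], 4))
  expect_equal(ua$bd_fine, rep(u$bd_fine[1], 4))
  # order independence: 0-30 directly vs combining 0-10 and 10-30 stocks
  a030 <- aggregate_slices(prof, cbind(0, 30))
  asplit <- aggregate_slices(prof, rbind(c(0, 10), c(10, 30)))
  expect_equal(a030$oc_stock, sum(asplit$oc_stock), tolerance = 1e-12)
  expect_error(aggregate_slices(prof, cbind(60, 120)), "no extrapolation")
})

test_that("horizon-boundary adjustment re-apportions SOC under conservation", {
  inc <- random_ag_increments()
  # boundary at 25 cm inside the 10-30 cm increment, 70% of stock above
  prof <- downscale(inc, horizon_alloc = data.frame(boundary_cm = 25,
                                                    share_above = 0.7))
  above <- prof$soc_pct[prof$top_cm >= 10 & prof$top_cm < 25]
  below <- prof$soc_pct[prof$top_cm >= 25 & prof$top_cm < 30]
  # the 10-24 cm slice block carries 70% of the increment's SOC
  expect_equal(sum(above) / (sum(above) + sum(below)), 0.7, tolerance = 1e-12)
  expect_equal(unique(above), inc$soc_pct[2] * 0.7 * 20 / 15)
  expect_equal(unique(below), inc$soc_pct[2] * 0.3 * 20 / 5)
  # increment stock conserved exactly
  agg <- aggregate_slices(prof, cbind(10, 30))
  expect_equal(agg$oc_stock,
               soc_stock(inc$soc_pct[2], inc$bd_fine[2], inc$rff[2], 20),
               tolerance = 1e-12)
})

test_that("forest topsoil merge is stock-additive with scheme weights", {
  scheme <- cbind(top = c(0, 5, 10, 30, 60), bottom = c(5, 10, 30, 60, 90))
  inc <- data.frame(
    site_id = "F", top_cm = scheme[, "top"], bottom_cm = scheme[, "bottom"],
    soc_pct = c(4.2, 2.8, 1.5, 0.6, 0.3), bd_fine = c(0.9, 1.1, 1.3, 1.5, 1.6),
    rff = 0.07, clay_pct = 18, silt_pct = 35, ph = 4.4, cn_ratio = 21,
    n_pct = 0.2, stringsAsFactors = FALSE
  )
  m <- merge_forest_topsoil(inc)
  expect_equal(m$top_cm[1], 0); expect_equal(m$bottom_cm[1], 10)
  s1 <- soc_stock(inc$soc_pct[1], inc$bd_fine[1], inc$rff[1], 5)
  s2 <- soc_stock(inc$soc_pct[2], inc$bd_fine[2], inc$rff[2], 5)
  merged_stock <- soc_stock(m$soc_pct[1], m$bd_fine[1], m$rff[1], 10)
  expect_equal(merged_stock, s1 + s2, tolerance = 1e-12)
  expect_equal(m$bd_fine[1], (inc$bd_fine[1] + inc$bd_fine[2]) / 2)
  # equal layers merge to either value
  eq <- inc; eq$soc_pct[2] <- eq$soc_pct[1]; eq$bd_fine[2] <- eq$bd_fine[1]
  expect_equal(merge_forest_topsoil(eq)$soc_pct[1], eq$soc_pct[1])
  expect_error(merge_forest_topsoil(inc[-1, ]), "0-5 and 5-10")
})

test_that("agricultural 70-100 cm data contribute only slices 70-89", {
  inc <- random_ag_increments()
  prof <- downscale(inc)
  agg <- aggregate_slices(prof, cbind(60, 90))
  # 10 slices from 50-70 increment + 20 slices from 70-100 increment
  manual <- soc_stock(inc$soc_pct[4], inc$bd_fine[4], inc$rff[4], 10) +
    soc_stock(inc$soc_pct[5], inc$bd_fine[5], inc$rff[5], 20)
  expect_equal(agg$oc_stock, manual, tolerance = 1e-12)
})

test_that("harmonization puts mixed inventories on the target strata", {
  gen <- small_gen()
  h <- harmonize_inventory(gen$inventory)
  expect_equal(h$depth_scheme, "harmonized")
  expect_equal(sort(unique(h$increments$top_cm)), c(0, 10, 30, 60))
  expect_equal(nrow(h$increments), 4L * nrow(h$sites))
  # forest sites (aligned bounds): stock equals the direct increment stocks
  fid <- h$sites$site_id[h$sites$land_use == "forest"][1]
  raw <- gen$inventory$increments[gen$inventory$increments$site_id == fid, ]
  harm <- h$increments[h$increments$site_id == fid, ]
  raw_stock <- sum(soc_stock(raw$soc_pct, raw$bd_fine, raw$rff,
                             raw$bottom_cm - raw$top_cm))
  expect_equal(sum(harm$oc_stock), raw_stock, tolerance = 1e-9)
})
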