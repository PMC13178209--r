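# a fitted two-term model on simple data, used as a scoring device
score_fixture <- function(seed = 70, n = 120) {
  set.seed(seed)
  d <- data.frame(point_id = sprintf("P%04d", seq_len(n)),
                  zone = sample(c("za", "zb"), n, TRUE),
                  land_use = "arable",
                  manure = runif(n), ley = runif(n))
  d$stock <- 40 + 20 * d$manure + 30 * d$ley + rnorm(n, 0, 2)
  # the fixture has no real zone effect, so a boundary (zero-variance) fit
  # is expected
  fit <- suppressWarnings(fit_soc_lmm(d, "stock", c("manure", "ley")))
  list(data = d, fit = fit)
}

test_that("optimality score is the management fixed-effect predictor", {
  fx <- score_fixture()
  sc <- rank_by_optimality(fx$data, fx$fit)
  b <- lme4::fixef(fx$fit$model)
  manual <- b[["(Intercept)"]] + b[["manure"]] * fx$data$manure +
    b[["ley"]] * fx$data$ley
  expect_equal(sc$score, unname(manual))
  # single positive term: ordering equals the covariate ordering
  fit1 <- suppressWarnings(fit_soc_lmm(fx$data, "stock", "manure"))
  sc1 <- rank_by_optimality(fx$data, fit1)
  expect_equal(order(sc1$score), order(fx$data$manure))
  # missing management excluded with a message
  d2 <- fx$data
  d2$manure[3] <- NA
  expect_message(sc2 <- rank_by_optimality(d2, fx$fit), "1 point")
  expect_true(is.na(sc2$score[3]))
})

test_that("decile effect: flat stocks give zero, halves are hand-checkable", {
  d <- data.frame(point_id = sprintf("P%02d", 1:30), zone = "z",
                  land_use = "arable", stock = 50, score = runif(30))
  eff <- zone_management_effect(d)
  expect_equal(eff$effect, 0)
  expect_equal(eff$n_decile, 3L)

  d10 <- data.frame(point_id = sprintf("P%02d", 1:10), zone = "z",
                    land_use = "arable", stock = 1:10, score = 1:10)
  eff <- zone_management_effect(d10, q = 0.49, min_n = 10)
  # q = 0.49 on 10 points: top and bottom 5 by score
  expect_equal(eff$top_mean, mean(6:10))
  expect_equal(eff$bottom_mean, mean(1:5))
  expect_equal(eff$effect, 5)
  expect_equal(eff$se_effect, sqrt(2) * sd(1:5) / sqrt(5))

  expect_message(
    zone_management_effect(rbind(d, transform(d10, zone = "small")),
                           min_n = 20),
    "skipped")
  expect_error(zone_management_effect(d10, min_n = 20), "no stratum")
  expect_error(zone_management_effect(d10, q = 0.6), "q")
})

test_that("tied scores break deterministically by point id", {
  d <- data.frame(point_id = sprintf("P%02d", 20:1), zone = "z",
                  land_use = "arable", stock = 1:20, score = 1)
  eff1 <- zone_management_effect(d, min_n = 20)
  eff2 <- zone_management_effect(d[sample(20), ], min_n = 20)
  expect_equal(eff1$top_mean, eff2$top_mean)
  expect_equal(eff1$bottom_mean, eff2$bottom_mean)
})

test_that("decile effect recovers a known management contrast", {
  fx <- score_fixture(seed = 71, n = 300)
  d <- fx$data
  d$score <- rank_by_optimality(d, fx$fit)$score
  eff <- zone_management_effect(d, zone_col = "zone")
  # expected stocks rise with the score, so the decile contrast is positive
  # and roughly the spread of the generative predictor
  for (i in seq_len(nrow(eff))) {
    expect_gt(eff$effect[i], 0)
  }
})

test_that("management variability is the mean within-zone SD of normalized indicators", {
  # identical management everywhere: zero variability
  d <- data.frame(zone = rep(c("a", "b"), each = 10), land_use = "arable",
                  i1 = 5, i2 = 1)
  d$i1[d$zone == "b"] <- 9  # variation between zones only
  mv <- management_variability(d, c("i1", "i2"))
  expect_equal(mv$variability, c(0, 0))

  # a uniform full-range indicator contributes about 1/sqrt(12)
  set.seed(72)
  d2 <- data.frame(zone = "a", land_use = "arable", u = runif(3000))
  mv2 <- management_variability(d2, "u")
  expect_lt(abs(mv2$variability - 1 / sqrt(12)), 0.01)

  # indicator missing in the zone is excluded from the mean
  d3 <- data.frame(zone = "a", land_use = "arable",
                   u = runif(50), v = NA_real_)
  expect_equal(management_variability(d3, c("u", "v"))$variability,
               management_variability(d3, "u")$variability)
})

test_that("option space aggregates stratum deltas with the variance formula", {
  one <- data.frame(zone = "z1", land_use = "arable", n_points = 100L,
                    n_decile = 10L, top_mean = 60, bottom_mean = 45,
                    stratum_mean = 50, se_top = 1, se_bottom = 2, se_mean = 0.5,
                    effect = 15, se_effect = sqrt(5))
  areas <- data.frame(zone = "z1", land_use = "arable", area_ha = 1e8)
  os <- option_space(one, areas)
  # 10 Mg C/ha more than the stratum mean over 1e8 ha = 1 Pg C
  expect_equal(os$totals$best[os$totals$land_use == "all"], 1.0)
  expect_equal(os$totals$worst[os$totals$land_use == "all"], -0.5)
  expect_equal(os$totals$se_best[1], sqrt(1 + 0.25) * 1e8 * 1e-9)
  expect_equal(os$totals$best_high[1] - os$totals$best[1],
               1.96 * os$totals$se_best[1])

  # zero effects: both scenarios zero
  zero <- transform(one, top_mean = 50, bottom_mean = 50)
  os0 <- option_space(zero, areas)
  expect_equal(os0$totals$best, c(0, 0))
  expect_equal(os0$totals$worst, c(0, 0))

  # two strata: totals are the hand-computed sums
  two <- rbind(one, transform(one, zone = "z2", top_mean = 55,
                              bottom_mean = 48, effect = 7))
  areas2 <- rbind(areas, data.frame(zone = "z2", land_use = "arable",
                                    area_ha = 2e8))
  os2 <- option_space(two, areas2)
  expect_equal(os2$totals$best[os2$totals$land_use == "all"],
               (10 * 1e8 + 5 * 2e8) * 1e-9)
  # option space identity: best - worst = sum(area x effect)
  tot <- os2$totals[os2$totals$land_use == "all", ]
  expect_equal(tot$best - tot$worst, sum(two$effect * areas2$area_ha) * 1e-9)
  # halving areas halves totals and their standard errors
  os_half <- option_space(two, transform(areas2, area_ha = area_ha / 2))
  expect_equal(os_half$totals$best, os2$totals$best / 2)
  expect_equal(os_half$totals$se_best, os2$totals$se_best / 2)

  # stratum without an area is excluded with a message
  expect_message(os_part <- option_space(two, areas), "excluded")
  expect_equal(os_part$totals$best[os_part$totals$land_use == "all"], 1.0)
})
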