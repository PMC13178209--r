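test_that("stock equation: fixed-depth, coarse-fragment-corrected", {
  expect_equal(soc_stock(1.0, 10, 1), 0)    # all-stone soil
  expect_equal(soc_stock(1.0, 10, 0), 20)
  expect_equal(soc_stock(1.3, 15, 0.1), 35.1)
  # linear in OC and in (1 - coarse fragments), increasing in bulk density
  expect_equal(soc_stock(1.2, 30, 0.2), 3 * soc_stock(1.2, 10, 0.2))
  expect_equal(soc_stock(1.2, 10, 0.5), 0.5 * soc_stock(1.2, 10, 0))
  expect_gt(soc_stock(1.5, 10, 0.1), soc_stock(1.1, 10, 0.1))
  expect_error(soc_stock(1, 10, 1.4), "coarse_frag")
  expect_error(soc_stock(1, -2, 0), "oc")
})

test_that("benchmark ratio and yearly change follow their definitions", {
  expect_equal(benchmark_ratio(40, 40), 1.0)
  expect_equal(benchmark_ratio(60, 40), 1.5)
  expect_error(benchmark_ratio(60, 0), "typical_stock")
  expect_equal(delta_soc(15, 15, 2009, 2018), 0)
  expect_equal(delta_soc(15, 24, 2009, 2018), 1.0)
  expect_equal(delta_soc(20, 11, 2009, 2018), -1.0)
  expect_error(delta_soc(15, 24, 2018, 2018), "year_t1")
})

test_that("AIC search recovers a noiseless generative bulk-density model", {
  set.seed(30)
  n <- 80
  d <- data.frame(land_use = "arable",
                  sand = runif(n, 15, 80), clay = runif(n, 5, 40),
                  ph = runif(n, 4.5, 8), total_n = runif(n, 1, 4),
                  map_mm = runif(n, 500, 1200))
  d$bd_measured <- 1.6 - 0.03 * d$ph - 0.10 * d$total_n +
    4e-5 * d$sand * d$clay
  models <- fit_bd_models(d)
  m <- models[["arable"]]
  expect_setequal(m$terms, c("sand", "clay", "total_n", "ph", "sand:clay"))
  expect_equal(unname(m$coefficients[c("(Intercept)", "ph", "total_n", "sand:clay")]),
               c(1.6, -0.03, -0.10, 4e-5), tolerance = 1e-6)
  expect_equal(unname(m$coefficients[c("sand", "clay")]), c(0, 0),
               tolerance = 1e-6)
  # prediction reproduces the generative density
  expect_equal(predict_bd_ref(d, models), d$bd_measured,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("identical-RSS candidates resolve to the smaller model", {
  set.seed(31)
  n <- 60
  d <- data.frame(land_use = "arable",
                  sand = runif(n, 15, 80), clay = runif(n, 5, 40),
                  ph = runif(n, 4.5, 8), total_n = runif(n, 1, 4),
                  map_mm = runif(n, 500, 1200))
  d$bd_measured <- 1.8 - 0.05 * d$ph  # depends on pH only
  m <- fit_bd_models(d)[["arable"]]
  expect_identical(m$terms, "ph")
})

test_that("OC is rejected as a bulk-density predictor", {
  d <- data.frame(land_use = "arable", bd_measured = 1, oc_t1 = 10,
                  sand = 1, clay = 1, ph = 7, total_n = 2, map_mm = 800)
  expect_error(fit_bd_models(d, predictors = c("oc_t1", "ph")), "OC")
  expect_error(fit_bd_models(d), "arable")       # one point: too few
  expect_error(fit_bd_models(d[0, ]), "no usable")
})

test_that("reference bulk density is clipped to the plausible range", {
  set.seed(32)
  n <- 40
  d <- data.frame(land_use = "grassland", ph = runif(n, 4.5, 8),
                  sand = 50, clay = 20, total_n = 2, map_mm = 800)
  d$bd_measured <- 0.02 * (d$ph - 4.5) + 0.01  # below 0.1 over most of range
  models <- fit_bd_models(d, min_points = 30)
  pr <- predict_bd_ref(d, models)
  expect_true(all(pr >= 0.1 & pr <= 2.2))
  expect_gt(attr(pr, "clipped"), 0)
})

test_that("zone imputation: separable, permuted and single-class cases", {
  set.seed(33)
  n <- 300
  d <- data.frame(sand = runif(n, 0, 100))
  d$zone_true <- ifelse(d$sand > 50, "sandy", "loamy")
  d$zone <- d$zone_true
  miss <- sample(n, 60)
  d$zone[miss] <- NA
  zi <- impute_zone(d, predictors = "sand", seed = 1)
  expect_equal(zi$zone[miss], d$zone_true[miss])   # perfectly separable
  expect_equal(zi$n_imputed, 60L)
  expect_lt(zi$oob_error, 0.05)

  # permuted labels: out-of-bag error near the null-classifier rate
  d2 <- d
  d2$zone[-miss] <- sample(d2$zone[-miss])
  zi2 <- impute_zone(d2, predictors = "sand", seed = 1)
  null_rate <- 1 - max(table(d2$zone[-miss])) / (n - 60)
  expect_lt(abs(zi2$oob_error - null_rate), 0.12)

  # all training points one class: every prediction is that class
  d3 <- d
  d3$zone[!is.na(d3$zone)] <- "only"
  zi3 <- suppressWarnings(impute_zone(d3, predictors = "sand", seed = 1))
  expect_true(all(zi3$zone == "only"))
})

test_that("zone imputation refuses unseen factor levels", {
  d <- data.frame(region = rep(c("R1", "R2"), each = 20),
                  zone = rep(c("a", "b"), each = 20),
                  stringsAsFactors = FALSE)
  d2 <- rbind(d, data.frame(region = "R9", zone = NA))
  expect_error(impute_zone(d2, predictors = "region", seed = 1), "unseen")
})

test_that("cleaning filters use the stated thresholds with strict inequalities", {
  base <- data.frame(year_t0 = 2009, year_t1 = 2018,
                     land_use = "arable", land_use_t0 = "arable")
  d <- rbind(
    cbind(base, oc_t0 = 150, oc_t1 = 160),   # at the organic threshold: kept
    cbind(base, oc_t0 = 150, oc_t1 = 160.1), # above: removed
    cbind(base, oc_t0 = 10, oc_t1 = 21),     # 110% relative change: removed
    cbind(base, oc_t0 = 10, oc_t1 = 19),     # 90% relative change: kept
    cbind(base, oc_t0 = 30, oc_t1 = 57),     # 3 g/kg/yr exactly: kept
    cbind(base, oc_t0 = 30, oc_t1 = 58))     # above 3 g/kg/yr: removed
  d$land_use_t0[4] <- "grassland"            # land-use change: removed
  cl <- clean_records(d)
  expect_equal(cl$data$keep_stock, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(cl$data$keep_delta, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(cl$report$n_kept, c(5L, 5L, 2L))
  # idempotent: cleaning the cleaned table changes nothing
  cl2 <- clean_records(cl$data[, names(d)])
  expect_equal(cl2$data$keep_delta, cl$data$keep_delta)
  expect_equal(cl2$report, cl$report)
})

test_that("benchmark ratios centre on 1 when typical stocks equal zone means", {
  cfg <- noiseless_config(seed = 35L, n_regions = 2L, n_farms_per_region = 150L,
                          n_points = 400L,
                          true_effects = c(manure_share_n = 0),
                          noise_sd_stock = 5)
  farms <- generate_farms(cfg)
  out <- suppressMessages(generate_soil_points(cfg, farms))
  gt <- out$ground_truth
  for (z in unique(gt$zone)) {
    stocks <- gt$stock[gt$zone == z]
    ratio <- benchmark_ratio(stocks, mean(stocks))
    gm <- exp(mean(log(ratio)))
    expect_lt(abs(gm - 1), 3 / sqrt(length(stocks)))
  }
})

test_that("metric pipeline assembles stocks, ratios and change per point", {
  cfg <- noiseless_config(seed = 36L, n_regions = 2L, n_farms_per_region = 150L,
                          n_points = 300L)
  farms <- generate_farms(cfg)
  out <- suppressMessages(generate_soil_points(cfg, farms))
  bm <- generate_benchmarks(cfg)
  sm <- suppressMessages(compute_soc_metrics(out$points, bm,
                                             bd_min_points = 15L))
  expect_equal(sm$metrics$stock, out$ground_truth$expected_stock,
               tolerance = 1e-6)
  expect_equal(sm$metrics$delta_soc,
               (out$points$oc_t1 - out$points$oc_t0) / 9)
  typ <- bm$typical_stock[match(paste(sm$metrics$zone, sm$metrics$land_use),
                                paste(bm$zone, bm$land_use))]
  expect_equal(sm$metrics$benchmark_ratio, sm$metrics$stock / typ)
})
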