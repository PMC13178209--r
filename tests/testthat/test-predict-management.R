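test_that("farm weights follow the specialization x representativeness form", {
  expect_equal(farm_weight(10, 10, 10), 1.0)
  expect_equal(farm_weight(10, 10, 40), 0.5)
  expect_equal(farm_weight(5, 10, 20), sqrt(0.5 * 0.25))
  expect_error(farm_weight(0, 10, 10), "positive")
  expect_error(farm_weight(5, 0, 10), "positive")
  expect_error(farm_weight(12, 10, 20), "exceeds")
})

test_that("weighted median reduces to the lower median under equal weights", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    x <- round(runif(n, 0, 10), 1)
    lower_median <- sort(x)[ceiling(n / 2)]
    expect_equal(weighted_median(x, rep(1, n)), lower_median)
  }
})

test_that("weighted median minimizes the weighted absolute deviation", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 10)), 3)
  expect_equal(weighted_median(7, 2), 7)
  set.seed(11)
  for (i in 1:150) {
    n <- sample(1:8, 1)
    x <- sample(0:5, n, replace = TRUE) # integer ties on purpose
    w <- runif(n, 0.1, 3)
    expect_equal(weighted_median(x, w), brute_force_weighted_median(x, w))
  }
})

test_that("weighted SD is the population form and handles missing values", {
  expect_equal(weighted_sd(5, 1), 0)
  x <- c(1, 2, 3, 4)
  w <- c(1, 2, 3, 4)
  m <- sum(w * x) / sum(w)
  expect_equal(weighted_sd(x, w), sqrt(sum(w * (x - m)^2) / sum(w)))
  expect_equal(weighted_median(c(1, NA, 3), c(1, 1, 1)), 1)
  expect_true(is.na(weighted_sd(NA_real_, 1)))
})

test_that("matching walks the tier fallback chain at the group-size cut-off", {
  ind_of <- function(farms) compute_farm_indicators(farms)
  pt <- make_point()
  # exactly 15 farms in (region, altitude, crop): tier 1
  g15 <- make_farm_group(15)
  m <- match_point(pt, g15, ind_of(g15))
  expect_equal(m$tier, "1")
  expect_equal(m$n_farms, 15L)
  # 14 farms at the point's altitude plus 6 at another altitude: tier 2
  g14 <- rbind(make_farm_group(14),
               make_farm_group(6, altitude_class = ">600m"))
  g14$farm_id <- sprintf("F%06d", seq_len(nrow(g14)))
  m <- match_point(pt, g14, ind_of(g14))
  expect_equal(m$tier, "2")
  expect_equal(m$n_farms, 20L)
  # no farm grows the point's crop: nearest same-land-use farms, tier 3
  pt_barley <- make_point(land_cover = "barley")
  m <- match_point(pt_barley, g15, ind_of(g15))
  expect_equal(m$tier, "3")
  # no farm shares the land-use class at all: unmatched
  pt_tree <- make_point(land_cover = "olive", land_use = "tree")
  m <- match_point(pt_tree, g15, ind_of(g15))
  expect_equal(m$tier, "unmatched")
})

test_that("predictions at points reproduce a homogeneous group exactly", {
  farms <- make_farm_group(20, areas = c(wheat = 8, ley = 2), uaa = 10,
                           livestock_units = 5, mineral_n = 300)
  ind <- compute_farm_indicators(farms)
  pts <- rbind(make_point("P1"), make_point("P2", land_cover = "olive",
                                            land_use = "tree"))
  pred <- suppressMessages(predict_at_points(pts, farms, ind))
  expect_equal(pred$tier, c("1", "unmatched"))
  # identical farms: median equals the common value, SD zero
  expect_equal(pred$n_input_med[1], 300 / 10 + 135 * 5 / 10)
  expect_equal(pred$n_input_sd[1], 0)
  expect_equal(pred$ley_share_med[1], 0.2)
  # unmatched point: all indicators missing
  med_cols <- grep("_med$", names(pred), value = TRUE)
  expect_true(all(is.na(pred[2, med_cols])))
})

test_that("organic probability is the organic area share of the group", {
  farms <- make_farm_group(20, areas = c(wheat = 10))
  farms$organic[1:5] <- TRUE         # 5 of 20 equal-area farms organic
  ind <- compute_farm_indicators(farms)
  pred <- suppressMessages(predict_at_points(make_point(), farms, ind))
  expect_equal(pred$organic_probability, 0.25)
})

test_that("raising the group-size cut-off never adds tier-1 matches", {
  cfg <- tiny_config(seed = 21L)
  farms <- generate_farms(cfg)
  ind <- compute_farm_indicators(farms, generate_tillage_table(cfg, farms))
  pts <- suppressMessages(generate_soil_points(cfg, farms))$points
  n_tier1 <- vapply(c(5L, 15L, 40L), function(mgs) {
    pred <- suppressMessages(predict_at_points(pts, farms, ind,
                                               min_group_size = mgs))
    sum(pred$tier == "1")
  }, integer(1))
  expect_true(all(diff(n_tier1) <= 0))
})

test_that("tier-1 predictions beat region means at tracking true management", {
  # strong between-crop differences within each region
  cfg <- tiny_config(seed = 22L, n_points = 250L, fert_sdlog = 0.8)
  farms <- generate_farms(cfg)
  ind <- compute_farm_indicators(farms, generate_tillage_table(cfg, farms))
  out <- suppressMessages(generate_soil_points(cfg, farms))
  pred <- suppressMessages(predict_at_points(out$points, farms, ind))
  truth <- out$ground_truth$true_manure_share_n
  grouped <- pred$manure_share_n_med
  region_mean <- ave(grouped, out$points$region)
  expect_gt(cor(grouped, truth, use = "complete.obs"),
            cor(region_mean, truth, use = "complete.obs"))
})

test_that("Kruskal-Wallis check flags differentiated groups and not flat ones", {
  # identical values everywhere: no significance
  flat <- data.frame(region = "R1", g = rep(c("a", "b"), each = 5), v = 1)
  res <- within_region_kw_test(flat, "v", "g")
  expect_equal(res$p_value, 1)
  # strongly shifted groups: significant
  shifted <- data.frame(region = "R1", g = rep(c("a", "b"), each = 10),
                        v = c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1)))
  res <- within_region_kw_test(shifted, "v", "g")
  expect_lt(res$p_value, 0.05)
  expect_equal(attr(res, "pct_significant"), 100)
  # hand-computed statistic for {1,2,3} vs {10,11,12}: ranks 1..6,
  # H = 12/(6*7) * 3 * ((2-3.5)^2 + (5-3.5)^2) = 27/7
  two <- data.frame(region = "R1", g = rep(c("a", "b"), each = 3),
                    v = c(1, 2, 3, 10, 11, 12))
  res <- within_region_kw_test(two, "v", "g")
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  # degenerate region is excluded with a message
  deg <- rbind(shifted, data.frame(region = "R2", g = "a", v = 1))
  expect_message(res <- within_region_kw_test(deg, "v", "g"), "degenerate")
  expect_equal(nrow(res), 1L)
})
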