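#' Configuration for the synthetic survey generator
#'
#' Bundles every knob of the synthetic farm-survey / soil-monitoring world:
#' sample sizes, the crop catalogue, altitude thresholds, the ground-truth
#' management-to-SOC slopes, zone baseline stocks, noise levels and the
#' generative bulk-density model. All downstream stages are exercised against
#' data from this generator, whose ground truth makes parameter-recovery
#' testing possible.
#'
#' @param seed Integer seed; the farm, point, benchmark and tillage tables use
#'   `seed`, `seed + 1`, `seed + 2`, `seed + 3` respectively so each artifact
#'   is independently reproducible.
#' @param n_regions,n_farms_per_region,n_points Sizes of the synthetic world.
#' @param crop_list Crop catalogue as [default_crop_list()].
#' @param altitude_breaks_m Two strictly increasing altitude thresholds (m)
#'   defining the three altitude classes.
#' @param true_effects Named vector: slope of expected SOC stock
#'   (Mg C ha^-1 per unit indicator) for each management indicator that
#'   drives the ground truth. Names must be predicted-indicator names
#'   (e.g. `manure_share_n`, `ley_share`, `organic_probability`).
#' @param zone_baselines Named vector of mean stocks (Mg C ha^-1) per
#'   pedoclimatic zone; the names define the zone set.
#' @param noise_sd_stock SD (Mg C ha^-1) of point-level stock noise.
#' @param bd_model_coefficients Named vector `intercept`, `ph`, `total_n`,
#'   `sand`, `clay`, `sand_clay`: the generative linear model for fine-earth
#'   bulk density (g cm^-3).
#' @param bd_noise_sd SD (g cm^-3) of bulk-density noise around the
#'   generative model.
#' @param measurement_sd_oc SD (g C kg^-1) of the earlier-date OC
#'   measurement noise.
#' @param organic_fraction Mean Bernoulli probability that a farm is organic
#'   (modulated by a region-specific factor).
#' @param fert_rates_kg_ha Named vector `n`, `p`, `k`: median mineral
#'   fertilizer application rates (kg ha^-1) of non-organic farms.
#' @param fert_sdlog,livestock_sdlog Log-scale SDs of the log-normal
#'   fertilizer-rate and livestock draws; these set the within-group
#'   management spread, which real surveys do not publish.
#' @param bd_measured_fraction Fraction of points carrying a measured bulk
#'   density.
#' @param zone_missing_fraction Fraction of points whose zone label is masked
#'   (to be recovered by [impute_zone()]).
#' @param landuse_change_fraction Fraction of points whose earlier-survey land
#'   use differs from the later one.
#' @param organic_soil_fraction Fraction of points turned into organic soils
#'   (OC far above the mineral-soil cleaning threshold).
#' @param delta_mean,delta_sd Mean and SD (g kg^-1 yr^-1) of the true yearly
#'   change in SOC concentration.
#' @param years Length-2 integer vector: earlier and later survey years.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_regions = 4L,
                         n_farms_per_region = 300L,
                         n_points = 1200L,
                         crop_list = default_crop_list(),
                         altitude_breaks_m = c(300, 600),
                         true_effects = c(manure_share_n = 25,
                                          ley_share = 30,
                                          organic_probability = 10),
                         zone_baselines = c(alpine_boreal = 80,
                                            atlantic_central = 60,
                                            continental = 50,
                                            mediterranean = 35),
                         noise_sd_stock = 8,
                         bd_model_coefficients = c(intercept = 1.6,
                                                   ph = -0.03,
                                                   total_n = -0.10,
                                                   sand = 0,
                                                   clay = 0,
                                                   sand_clay = 4e-5),
                         bd_noise_sd = 0.05,
                         measurement_sd_oc = 0.5,
                         organic_fraction = 0.08,
                         fert_rates_kg_ha = c(n = 90, p = 15, k = 40),
                         fert_sdlog = 0.5,
                         livestock_sdlog = 0.4,
                         bd_measured_fraction = 1 / 3,
                         zone_missing_fraction = 0.19,
                         landuse_change_fraction = 0.03,
                         organic_soil_fraction = 0.02,
                         delta_mean = 0.05,
                         delta_sd = 0.08,
                         years = c(2009L, 2018L)) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param config Object to validate.
#' @export
validate_synth_config <- function(config) {
  fail <- function(field, why) {
    stop("invalid synth_config field '", field, "': ", why, call. = FALSE)
  }
  with(config, {
    if (!is.numeric(seed) || length(seed) != 1L) fail("seed", "must be a single integer")
    for (f in c("n_regions", "n_farms_per_region", "n_points")) {
      v <- config[[f]]
      if (!is.numeric(v) || length(v) != 1L || v < 1) fail(f, "must be a positive integer")
    }
    if (!is.data.frame(crop_list) || nrow(crop_list) == 0L) {
      fail("crop_list", "must be a non-empty data.frame")
    }
    if (!all(c("crop", "land_use") %in% names(crop_list))) {
      fail("crop_list", "needs columns 'crop' and 'land_use'")
    }
    if (length(altitude_breaks_m) != 2L || diff(altitude_breaks_m) <= 0) {
      fail("altitude_breaks_m", "must be two strictly increasing thresholds")
    }
    if (length(true_effects) > 0L && is.null(names(true_effects))) {
      fail("true_effects", "must be a named vector")
    }
    if (length(zone_baselines) == 0L || is.null(names(zone_baselines)) ||
        any(zone_baselines <= 0)) {
      fail("zone_baselines", "must be named with positive baselines")
    }
    for (f in c("noise_sd_stock", "bd_noise_sd", "measurement_sd_oc",
                "delta_sd", "fert_sdlog", "livestock_sdlog")) {
      if (config[[f]] < 0) fail(f, "must be >= 0")
    }
    need <- c("intercept", "ph", "total_n", "sand", "clay", "sand_clay")
    if (!all(need %in% names(bd_model_coefficients))) {
      fail("bd_model_coefficients",
           paste("must name", paste(need, collapse = ", ")))
    }
    for (f in c("organic_fraction", "bd_measured_fraction", "zone_missing_fraction",
                "landuse_change_fraction", "organic_soil_fraction")) {
      v <- config[[f]]
      if (v < 0 || v > 1) fail(f, "must be in [0, 1]")
    }
    if (length(years) != 2L || years[2] <= years[1]) {
      fail("years", "must be two increasing survey years")
    }
  })
  config
}

#' Altitude class from altitude
#' @param altitude_m Altitude (m).
#' @param breaks Two increasing thresholds (m).
#' @return Character class, e.g. `"<300m"`, `"300-600m"`, `">600m"`.
#' @export
altitude_class_of <- function(altitude_m, breaks = c(300, 600)) {
  labs <- c(paste0("<", breaks[1], "m"),
            paste0(breaks[1], "-", breaks[2], "m"),
            paste0(">", breaks[2], "m"))
  labs[findInterval(altitude_m, breaks) + 1L]
}

region_ids <- function(config) sprintf("R%02d", seq_len(config$n_regions))

# fixed grid of region centroids (WGS84) used for farms and points alike
region_centroids <- function(config) {
  r <- seq_len(config$n_regions)
  data.frame(region = region_ids(config),
             lon = 4 + 5 * ((r - 1L) %% 3L),
             lat = 42 + 4 * ((r - 1L) %/% 3L))
}

#' Generate a synthetic farm-survey table
#'
#' One row per farm-year with region, altitude class, farm type, size class,
#' utilized agricultural area, organic flag, livestock units, mineral N/P/K
#' and per-crop areas (`area_<crop>` columns, summing to the UAA). Crop areas
#' are Dirichlet over the farm's crop set, livestock and fertilizer rates are
#' log-normal, and the organic flag is Bernoulli with a region-specific
#' probability — positive, right-skewed draws matching survey character.
#'
#' @param config A [synth_config()].
#' @return `data.frame` of farms; byte-identical under the same config.
#' @export
generate_farms <- function(config) {
  config <- validate_synth_config(config)
  set.seed(config$seed)
  cl <- config$crop_list
  n <- config$n_regions * config$n_farms_per_region
  regions <- region_ids(config)
  region <- rep(regions, each = config$n_farms_per_region)
  ri <- match(region, regions)

  region_alt <- seq(120, 850, length.out = config$n_regions)
  altitude_m <- pmax(0, rnorm(n, region_alt[ri], 260))
  altitude_class <- altitude_class_of(altitude_m, config$altitude_breaks_m)

  classes <- intersect(c("arable", "grassland", "tree"), unique(cl$land_use))
  probs <- c(arable = 0.55, grassland = 0.30, tree = 0.15)[classes]
  orientation <- sample(classes, n, replace = TRUE, prob = probs / sum(probs))
  farm_type <- c(arable = "field_crops", grassland = "grazing_livestock",
                 tree = "permanent_crops")[orientation]

  uaa <- rlnorm(n, log(25), 1)
  size_class <- as.character(cut(uaa, c(0, 20, 100, Inf),
                                 labels = c("small", "medium", "large")))

  arable_crops <- cl$crop[cl$land_use == "arable"]
  grass_crops <- cl$crop[cl$land_use == "grassland"]
  tree_crops <- cl$crop[cl$land_use == "tree"]
  # region-specific arable crop mix (Dirichlet)
  wmat <- matrix(rgamma(config$n_regions * length(arable_crops), 1.2),
                 nrow = config$n_regions)
  wmat <- wmat / pmax(rowSums(wmat), 1e-12)

  pick_crops <- function(i) {
    o <- orientation[i]
    if (o == "arable" || length(grass_crops) + length(tree_crops) == 0L) {
      k <- min(1L + rbinom(1L, 3L, 0.55), length(arable_crops))
      sample(arable_crops, k, prob = wmat[ri[i], ])
    } else if (o == "grassland") {
      cr <- sample(grass_crops, 1L)
      if (length(arable_crops) > 0L && runif(1) < 0.35) {
        cr <- c(cr, sample(arable_crops, 1L, prob = wmat[ri[i], ]))
      }
      cr
    } else {
      sample(tree_crops, min(1L + rbinom(1L, 1L, 0.3), length(tree_crops)))
    }
  }
  crops_per_farm <- lapply(seq_len(n), pick_crops)

  amat <- matrix(0, nrow = n, ncol = nrow(cl),
                 dimnames = list(NULL, cl$crop))
  for (i in seq_len(n)) {
    cr <- crops_per_farm[[i]]
    w <- rgamma(length(cr), 1.5)
    amat[i, cr] <- uaa[i] * w / sum(w)
  }

  lu_density <- numeric(n)
  gr <- orientation == "grassland"
  lu_density[gr] <- rlnorm(sum(gr), log(0.9), config$livestock_sdlog)
  ar <- orientation == "arable"
  has_lu <- ar & runif(n) < 0.30
  lu_density[has_lu] <- rlnorm(sum(has_lu), log(0.25), config$livestock_sdlog)
  livestock_units <- lu_density * uaa

  reg_org_factor <- exp(rnorm(config$n_regions, 0, 0.5))
  p_org <- pmin(0.95, config$organic_fraction * reg_org_factor[ri])
  organic <- runif(n) < p_org

  rate <- function(nm) {
    r <- rlnorm(n, log(config$fert_rates_kg_ha[[nm]]), config$fert_sdlog)
    r[organic] <- 0
    r
  }
  mineral_n_kg <- rate("n") * uaa
  mineral_p_kg <- rate("p") * uaa
  mineral_k_kg <- rate("k") * uaa

  farms <- data.frame(
    farm_id = sprintf("F%06d", seq_len(n)),
    year = sample(2018:2020, n, replace = TRUE),
    country = "EU",
    region = region,
    altitude_m = round(altitude_m, 1),
    altitude_class = altitude_class,
    farm_type = farm_type,
    size_class = size_class,
    uaa_ha = uaa,
    organic = organic,
    livestock_units = livestock_units,
    mineral_n_kg = mineral_n_kg,
    mineral_p_kg = mineral_p_kg,
    mineral_k_kg = mineral_k_kg,
    stringsAsFactors = FALSE
  )
  acols <- as.data.frame(amat)
  names(acols) <- paste0("area_", colnames(amat))
  cbind(farms, acols)
}

#' Generate a synthetic tillage-practice area table
#'
#' Areas under conventional, conservation and zero tillage per
#' (region, size class, farm type) cell; every combination present in `farms`
#' is covered. Conservation/zero propensities vary by region.
#'
#' @param config A [synth_config()].
#' @param farms Farms table; defines the cells and their total area.
#' @return `data.frame` with columns `region`, `size_class`, `farm_type`,
#'   `area_conventional`, `area_conservation`, `area_zero`.
#' @export
generate_tillage_table <- function(config, farms) {
  config <- validate_synth_config(config)
  set.seed(config$seed + 3L)
  cells <- unique(farms[, c("region", "size_class", "farm_type")])
  cells <- cells[order(cells$region, cells$size_class, cells$farm_type), ]
  rownames(cells) <- NULL
  tot <- aggregate(uaa_ha ~ region + size_class + farm_type, farms, sum)
  key <- function(d) paste(d$region, d$size_class, d$farm_type, sep = "|")
  cells$total_ha <- tot$uaa_ha[match(key(cells), key(tot))]

  regions <- region_ids(config)
  cons_p <- runif(config$n_regions, 0.05, 0.45)
  zero_p <- runif(config$n_regions, 0.02, 0.20)
  ri <- match(cells$region, regions)
  alpha <- cbind(pmax(1 - cons_p[ri] - zero_p[ri], 0.01), cons_p[ri], zero_p[ri]) * 8
  g <- matrix(rgamma(length(alpha), shape = alpha), ncol = 3L)
  shares <- g / rowSums(g)
  cells$area_conventional <- cells$total_ha * shares[, 1]
  cells$area_conservation <- cells$total_ha * shares[, 2]
  cells$area_zero <- cells$total_ha * shares[, 3]
  cells$total_ha <- NULL
  cells
}

#' Generate a pedoclimatic benchmark table
#'
#' Typical SOC stock and mapped agricultural area per zone and land-use
#' stratum. Typical stocks are the zone baselines scaled by a land-use
#' multiplier (grassland above, arable below the zone mean).
#'
#' @param config A [synth_config()].
#' @return `data.frame` with columns `zone`, `land_use`, `typical_stock`
#'   (Mg C ha^-1) and `area_ha`.
#' @export
generate_benchmarks <- function(config) {
  config <- validate_synth_config(config)
  set.seed(config$seed + 2L)
  zones <- names(config$zone_baselines)
  lus <- intersect(c("arable", "grassland", "tree"),
                   unique(config$crop_list$land_use))
  g <- expand.grid(zone = zones, land_use = lus, stringsAsFactors = FALSE)
  mult <- c(arable = 0.9, grassland = 1.25, tree = 1.0)
  g$typical_stock <- unname(config$zone_baselines[g$zone] * mult[g$land_use])
  g$area_ha <- 10^runif(nrow(g), 6, 7.5)
  g
}

#' Generate synthetic soil-monitoring points with known ground truth
#'
#' Builds one row per monitoring point (region, coordinates, altitude, crop
#' cover, edaphic covariates, two-date OC, optional measured bulk density)
#' plus a ground-truth table. The true expected stock is
#' `zone baseline + sum(true_effects * indicator)` where the point-level true
#' indicators are the tier-matched weighted-median management predictions
#' computed from `farms`; realized stock adds Gaussian noise. Bulk density
#' follows the generative linear model on pH, total N, sand, clay and
#' sand x clay; the later-date OC is back-computed so that the fixed-depth
#' stock equation applied to the generated bulk density reproduces the
#' realized stock exactly, and the earlier-date OC subtracts the accumulated
#' true yearly change plus measurement noise.
#'
#' @param config A [synth_config()].
#' @param farms Farms table from [generate_farms()] under the same config.
#' @param tillage Optional tillage table; generated from the config if `NULL`.
#' @return List with elements `points` (the monitoring table, zone partially
#'   masked) and `ground_truth` (true zone, tier, true indicators, expected
#'   and realized stock, true yearly change, generated bulk density, flags).
#' @export
generate_soil_points <- function(config, farms, tillage = NULL) {
  config <- validate_synth_config(config)
  if (!all(unique(farms$region) %in% region_ids(config))) {
    stop("generate_soil_points: farm regions do not match the config regions")
  }
  if (is.null(tillage)) tillage <- generate_tillage_table(config, farms)
  find <- compute_farm_indicators(farms, tillage, crop_list = config$crop_list)

  set.seed(config$seed + 1L)
  n <- config$n_points
  regions <- region_ids(config)
  region <- sample(regions, n, replace = TRUE)
  ri <- match(region, regions)
  region_alt <- seq(120, 850, length.out = config$n_regions)
  altitude_m <- pmax(0, rnorm(n, region_alt[ri], 260))

  # crop drawn from each region's realized crop-area mix
  amat <- crop_area_matrix(farms)
  crop <- character(n)
  for (r in regions) {
    idx <- which(region == r)
    if (length(idx) == 0L) next
    atot <- colSums(amat[farms$region == r, , drop = FALSE])
    crop[idx] <- sample(colnames(amat), length(idx), replace = TRUE,
                        prob = atot + 1e-12)
  }
  cl <- config$crop_list
  land_use <- cl$land_use[match(crop, cl$crop)]

  zones <- names(config$zone_baselines)
  nz <- length(zones)
  zone_true <- character(n)
  for (k in seq_len(config$n_regions)) {
    idx <- which(ri == k)
    if (length(idx) == 0L) next
    p <- rep(if (nz > 1L) 0.3 / (nz - 1L) else 0, nz)
    p[(k - 1L) %% nz + 1L] <- if (nz > 1L) 0.7 else 1
    zone_true[idx] <- sample(zones, length(idx), replace = TRUE, prob = p)
  }

  cent <- region_centroids(config)
  lon <- cent$lon[ri] + runif(n, -1.2, 1.2)
  lat <- cent$lat[ri] + runif(n, -1.2, 1.2)

  ph <- runif(n, 4.5, 8.0)
  total_n <- pmin(rlnorm(n, log(2), 0.3), 6)
  sand <- runif(n, 15, 80)
  clay <- runif(n, 5, pmin(60, 95 - sand))
  region_map <- runif(config$n_regions, 500, 1200)
  map_mm <- pmax(250, rnorm(n, region_map[ri], 120))
  coarse_frag <- runif(n, 0, 0.3)

  b <- config$bd_model_coefficients
  bd <- b[["intercept"]] + b[["ph"]] * ph + b[["total_n"]] * total_n +
    b[["sand"]] * sand + b[["clay"]] * clay + b[["sand_clay"]] * sand * clay +
    rnorm(n, 0, config$bd_noise_sd)

  pts0 <- data.frame(
    point_id = sprintf("P%05d", seq_len(n)),
    lon = lon, lat = lat,
    country = "EU",
    region = region,
    altitude_m = round(altitude_m, 1),
    altitude_class = altitude_class_of(altitude_m, config$altitude_breaks_m),
    land_cover = crop,
    land_use = land_use,
    stringsAsFactors = FALSE
  )

  pred <- predict_at_points(pts0, farms, find, min_group_size = 15L)
  eff <- config$true_effects
  true_ind <- matrix(NA_real_, nrow = n, ncol = length(eff),
                     dimnames = list(NULL, names(eff)))
  for (e in names(eff)) {
    col <- if (e == "organic_probability") e else paste0(e, "_med")
    if (!col %in% names(pred)) {
      stop("generate_soil_points: true_effects names an unknown indicator '",
           e, "'")
    }
    true_ind[, e] <- pred[[col]]
  }
  contrib <- sweep(true_ind, 2L, eff, `*`)
  expected_stock <- unname(config$zone_baselines[zone_true]) +
    rowSums(contrib, na.rm = TRUE)
  stock <- pmax(expected_stock + rnorm(n, 0, config$noise_sd_stock), 0.01)

  true_delta <- rnorm(n, config$delta_mean, config$delta_sd)
  nyears <- diff(config$years)
  oc_t1 <- stock / (bd * 2 * (1 - coarse_frag))
  oc_t0 <- pmax(oc_t1 - nyears * true_delta +
                  rnorm(n, 0, config$measurement_sd_oc), 0.01)

  organic_soil <- runif(n) < config$organic_soil_fraction
  if (any(organic_soil)) {
    oc_t1[organic_soil] <- runif(sum(organic_soil), 170, 350)
    oc_t0[organic_soil] <- oc_t1[organic_soil] +
      rnorm(sum(organic_soil), 0, 10)
  }

  land_use_t0 <- land_use
  chg <- which(runif(n) < config$landuse_change_fraction)
  lus <- unique(cl$land_use)
  if (length(lus) > 1L) {
    for (i in chg) land_use_t0[i] <- sample(setdiff(lus, land_use[i]), 1L)
  }

  bd_measured <- ifelse(runif(n) < config$bd_measured_fraction, bd, NA_real_)
  zone_obs <- zone_true
  zone_obs[runif(n) < config$zone_missing_fraction] <- NA_character_

  points <- cbind(pts0, data.frame(
    land_use_t0 = land_use_t0,
    year_t0 = config$years[1], year_t1 = config$years[2],
    oc_t0 = oc_t0, oc_t1 = oc_t1,
    bd_measured = bd_measured,
    coarse_frag = coarse_frag,
    sand = sand, clay = clay, ph = ph, total_n = total_n,
    map_mm = map_mm,
    zone = zone_obs,
    stringsAsFactors = FALSE
  ))

  gt <- data.frame(point_id = pts0$point_id,
                   zone = zone_true,
                   tier = pred$tier,
                   stringsAsFactors = FALSE)
  for (e in names(eff)) gt[[paste0("true_", e)]] <- true_ind[, e]
  gt$expected_stock <- expected_stock
  gt$stock <- stock
  gt$true_delta <- true_delta
  gt$bd <- bd
  gt$organic_soil <- organic_soil
  list(points = points, ground_truth = gt)
}
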