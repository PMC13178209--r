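# Small configurations and hand-built tables used across the test files.

tiny_config <- function(seed = 42L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_regions = 2L, n_farms_per_region = 80L,
                   n_points = 150L)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# every noise source off, all points carry measured bulk density and a zone
noiseless_config <- function(seed = 42L, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_regions = 4L, n_farms_per_region = 200L,
                   n_points = 800L, noise_sd_stock = 0, bd_noise_sd = 0,
                   measurement_sd_oc = 0, organic_soil_fraction = 0,
                   landuse_change_fraction = 0, bd_measured_fraction = 1,
                   zone_missing_fraction = 0)
  do.call(synth_config, utils::modifyList(defaults, args))
}

# one farm row in the survey schema; crop areas given as a named vector
make_farm <- function(areas = c(wheat = 10), uaa = sum(areas),
                      livestock_units = 0, mineral_n = 0, mineral_p = 0,
                      mineral_k = 0, organic = FALSE, region = "R01",
                      altitude_class = "<300m", farm_type = "field_crops",
                      size_class = "small", farm_id = "F000001",
                      country = "EU") {
  f <- data.frame(farm_id = farm_id, year = 2018L, country = country,
                  region = region, altitude_class = altitude_class,
                  farm_type = farm_type, size_class = size_class,
                  uaa_ha = uaa, organic = organic,
                  livestock_units = livestock_units,
                  mineral_n_kg = mineral_n, mineral_p_kg = mineral_p,
                  mineral_k_kg = mineral_k, stringsAsFactors = FALSE)
  for (crop in default_crop_list()$crop) {
    f[[paste0("area_", crop)]] <- if (crop %in% names(areas)) areas[[crop]] else 0
  }
  f
}

# n copies of make_farm with distinct ids
make_farm_group <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    make_farm(farm_id = sprintf("F%06d", i), ...)
  }))
}

# one soil point matching the make_farm defaults
make_point <- function(point_id = "P00001", region = "R01",
                       altitude_class = "<300m", land_cover = "wheat",
                       land_use = "arable", lon = 5, lat = 45,
                       country = "EU") {
  data.frame(point_id = point_id, lon = lon, lat = lat, country = country,
             region = region, altitude_m = 100, altitude_class = altitude_class,
             land_cover = land_cover, land_use = land_use,
             stringsAsFactors = FALSE)
}

# independent lower-weighted-median oracle: the smallest candidate value
# minimizing the weighted absolute deviation
brute_force_weighted_median <- function(x, w) {
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  cand <- sort(unique(x))
  loss <- vapply(cand, function(m) sum(w * abs(x - m)), numeric(1))
  cand[which(loss <= min(loss) + 1e-12)][1L]
}
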