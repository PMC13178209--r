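# Long farm x crop table: one row per farm and crop with positive area,
# carrying the crop area, farm UAA, organic flag and all farm indicators.
farm_crop_long <- function(farms, indicators, crop_list = default_crop_list()) {
  m <- crop_area_matrix(farms)
  ind_cols <- indicator_columns(indicators)
  ind <- indicators[match(farms$farm_id, indicators$farm_id), ind_cols,
                    drop = FALSE]
  pieces <- lapply(colnames(m), function(cr) {
    has <- which(m[, cr] > 0)
    if (length(has) == 0L) return(NULL)
    cbind(
      data.frame(
        farm_id = farms$farm_id[has],
        country = if ("country" %in% names(farms)) farms$country[has] else "",
        region = farms$region[has],
        altitude_class = farms$altitude_class[has],
        crop = cr,
        crop_land_use = crop_list$land_use[match(cr, crop_list$crop)],
        area = m[has, cr],
        uaa = farms$uaa_ha[has],
        organic = farms$organic[has],
        stringsAsFactors = FALSE
      ),
      ind[has, , drop = FALSE]
    )
  })
  do.call(rbind, pieces)
}

# Weighted-median/SD summary of one matching group (rows of the long table),
# as a named numeric vector (fast to assemble across many groups).
group_summary <- function(rows, ind_cols) {
  w <- farm_weight(rows$area, rows$uaa, sum(rows$area))
  out <- numeric(2L * length(ind_cols) + 2L)
  names(out) <- group_summary_names(ind_cols)
  out[["n_farms"]] <- length(unique(rows$farm_id))
  for (ic in ind_cols) {
    out[[paste0(ic, "_med")]] <- weighted_median(rows[[ic]], w)
    out[[paste0(ic, "_sd")]] <- weighted_sd(rows[[ic]], w)
  }
  out[["organic_probability"]] <- sum(rows$area[rows$organic]) / sum(rows$area)
  out
}

group_summary_names <- function(ind_cols) {
  c("n_farms",
    as.vector(rbind(paste0(ind_cols, "_med"), paste0(ind_cols, "_sd"))),
    "organic_probability")
}

#' Match one soil point to a farm group
#'
#' Three-tier fallback: (1) farms growing the point's crop in the same region
#' and altitude class, if at least `min_group_size` of them exist; (2) same
#' region and crop ignoring altitude; (3) farms of the same land-use class in
#' the same country, accumulated group-by-group in order of great-circle
#' distance between the point and the group's region centroid until the
#' threshold is met. Points that still cannot be matched are `"unmatched"`.
#'
#' @param point One-row data.frame with `region`, `altitude_class`,
#'   `land_cover`, `land_use`, `country`, `lon`, `lat`.
#' @param farms Farms table.
#' @param indicators Farm indicators from [compute_farm_indicators()].
#' @param min_group_size Minimum farms per group (anonymity cut-off).
#' @param crop_list Crop catalogue.
#' @return List with `tier` (`"1"`, `"2"`, `"3"` or `"unmatched"`),
#'   `farm_ids`, `n_farms` and the Eq.-style `weights`.
#' @export
match_point <- function(point, farms, indicators, min_group_size = 15L,
                        crop_list = default_crop_list()) {
  long <- farm_crop_long(farms, indicators, crop_list)
  cents <- point_region_centroids(point)
  rows <- match_rows(point, long, min_group_size, cents)
  if (is.null(rows$rows)) {
    return(list(tier = "unmatched", farm_ids = character(), n_farms = 0L,
                weights = numeric()))
  }
  r <- rows$rows
  list(tier = rows$tier,
       farm_ids = unique(r$farm_id),
       n_farms = length(unique(r$farm_id)),
       weights = farm_weight(r$area, r$uaa, sum(r$area)))
}

# centroids of the regions represented in a points table (farms carry no
# coordinates, so tier-3 distance works at region-centroid resolution)
point_region_centroids <- function(points) {
  agg <- aggregate(cbind(lon, lat) ~ region, points, mean)
  agg
}

match_rows <- function(point, long, min_group_size, centroids) {
  t1 <- long$region == point$region &
    long$altitude_class == point$altitude_class &
    long$crop == point$land_cover
  if (sum(t1) >= min_group_size) {
    return(list(tier = "1", rows = long[t1, , drop = FALSE]))
  }
  t2 <- long$region == point$region & long$crop == point$land_cover
  if (sum(t2) >= min_group_size) {
    return(list(tier = "2", rows = long[t2, , drop = FALSE]))
  }
  t3 <- long$crop_land_use == point$land_use & long$country == point$country
  cand <- long[t3, , drop = FALSE]
  if (nrow(cand) == 0L) return(list(tier = "unmatched", rows = NULL))
  ord <- order(match(cand$region, tier3_region_order(point, centroids)),
               cand$region, cand$crop, cand$farm_id)
  cand <- cand[ord, , drop = FALSE]
  # accumulate whole (region, crop) groups by distance until enough farms
  grp <- paste(cand$region, cand$crop, sep = "|")
  ug <- unique(grp)
  n_cum <- 0L
  take <- character()
  for (g in ug) {
    take <- c(take, g)
    n_cum <- length(unique(cand$farm_id[grp %in% take]))
    if (n_cum >= min_group_size) break
  }
  if (n_cum < min_group_size) return(list(tier = "unmatched", rows = NULL))
  list(tier = "3", rows = cand[grp %in% take, , drop = FALSE])
}

tier3_region_order <- function(point, centroids) {
  d <- geosphere::distHaversine(cbind(point$lon, point$lat),
                                cbind(centroids$lon, centroids$lat))
  centroids$region[order(d, centroids$region)]
}

#' Predict management indicators at soil points
#'
#' For every point, matches a farm group ([match_point()] tiers), computes
#' the area-based weights and returns the weighted median and weighted SD of
#' every farm indicator plus the organic probability (organic crop area over
#' total crop area in the group). Unmatched points carry all-missing
#' indicators.
#'
#' @param points Soil-point table with `point_id`, `region`,
#'   `altitude_class`, `land_cover`, `land_use`, `country`, `lon`, `lat`.
#' @param farms Farms table.
#' @param indicators Farm indicators from [compute_farm_indicators()].
#' @param min_group_size Minimum farms per group.
#' @param crop_list Crop catalogue.
#' @return `data.frame`, one row per point: `point_id`, `tier`, `n_farms`,
#'   `<indicator>_med` / `<indicator>_sd` columns and `organic_probability`.
#'   The tier distribution is reported via `message()`.
#' @export
predict_at_points <- function(points, farms, indicators, min_group_size = 15L,
                              crop_list = default_crop_list()) {
  long <- farm_crop_long(farms, indicators, crop_list)
  ind_cols <- indicator_columns(indicators)
  cents <- point_region_centroids(points)

  long$t1key <- paste(long$region, long$altitude_class, long$crop, sep = "|")
  long$t2key <- paste(long$region, long$crop, sep = "|")
  t1n <- table(long$t1key)
  t2n <- table(long$t2key)

  p1 <- paste(points$region, points$altitude_class, points$land_cover, sep = "|")
  p2 <- paste(points$region, points$land_cover, sep = "|")
  tier <- unname(ifelse(!is.na(t1n[p1]) & t1n[p1] >= min_group_size, "1",
                        ifelse(!is.na(t2n[p2]) & t2n[p2] >= min_group_size,
                               "2", "3")))

  # summaries computed once per matching group actually used
  stat_names <- group_summary_names(ind_cols)
  stats <- matrix(NA_real_, nrow = nrow(points), ncol = length(stat_names),
                  dimnames = list(NULL, stat_names))
  idx1 <- split(seq_len(nrow(long)), long$t1key)
  idx2 <- split(seq_len(nrow(long)), long$t2key)

  fill_from_keys <- function(which_tier, pkey, idx) {
    sel <- which(tier == which_tier)
    if (length(sel) == 0L) return()
    uk <- unique(pkey[sel])
    summ <- vapply(uk, function(k) {
      group_summary(long[idx[[k]], , drop = FALSE], ind_cols)
    }, numeric(length(stat_names)))
    stats[sel, ] <<- t(summ)[match(pkey[sel], uk), , drop = FALSE]
  }
  fill_from_keys("1", p1, idx1)
  fill_from_keys("2", p2, idx2)

  for (i in which(tier == "3")) {
    m <- match_rows(points[i, , drop = FALSE], long, min_group_size, cents)
    if (is.null(m$rows)) {
      tier[i] <- "unmatched"
      stats[i, "n_farms"] <- 0
    } else {
      stats[i, ] <- group_summary(m$rows, ind_cols)
    }
  }
  out <- cbind(
    data.frame(point_id = points$point_id, tier = tier,
               stringsAsFactors = FALSE),
    as.data.frame(stats)
  )
  rownames(out) <- NULL
  tt <- table(factor(tier, levels = c("1", "2", "3", "unmatched")))
  message("management prediction tiers: ",
          paste(sprintf("%s: %d (%.1f%%)", names(tt), tt,
                        100 * tt / nrow(points)), collapse = ", "))
  out
}

#' Within-region Kruskal-Wallis check of management differentiation
#'
#' Tests, per region, whether a management indicator differs between matching
#' groups (e.g. crop x altitude combinations). A high share of significant
#' regions means group-level predictions add information over regional
#' averages. Regions with fewer than two groups of at least two observations
#' are excluded with a message.
#'
#' @param data Table with one row per observation.
#' @param value_col Name of the indicator column.
#' @param group_col Name of the grouping column.
#' @param region_col Name of the region column.
#' @param alpha Significance level for the summary percentage.
#' @return `data.frame` with `region`, `statistic` (chi-squared), `df`,
#'   `p_value`, `n_groups`; attribute `"pct_significant"` holds the
#'   percentage of regions with `p < alpha`.
#' @export
within_region_kw_test <- function(data, value_col, group_col,
                                  region_col = "region", alpha = 0.05) {
  res <- lapply(split(data, data[[region_col]]), function(d) {
    d <- d[!is.na(d[[value_col]]) & !is.na(d[[group_col]]), , drop = FALSE]
    sizes <- table(d[[group_col]])
    keep <- names(sizes)[sizes >= 2L]
    d <- d[d[[group_col]] %in% keep, , drop = FALSE]
    if (length(keep) < 2L) return(NULL)
    x <- d[[value_col]]
    g <- factor(d[[group_col]])
    if (sd(x) == 0) {
      stat <- 0; p <- 1
    } else {
      kt <- kruskal.test(x, g)
      stat <- unname(kt$statistic); p <- kt$p.value
    }
    data.frame(region = d[[region_col]][1L], statistic = stat,
               df = length(keep) - 1L, p_value = p, n_groups = length(keep),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped > 0L) {
    message("within_region_kw_test: ", dropped,
            " degenerate region(s) excluded")
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(region = character(), statistic = numeric(),
                      df = integer(), p_value = numeric(),
                      n_groups = integer())
  }
  rownames(out) <- NULL
  attr(out, "pct_significant") <-
    if (nrow(out) > 0L) 100 * mean(out$p_value < alpha) else NA_real_
  out
}
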