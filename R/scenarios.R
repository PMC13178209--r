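#' Rank points by management optimality under a fitted model
#'
#' Scores every point with the management part of the fixed-effect linear
#' predictor (random zone intercepts excluded, so the ordering reflects
#' management, not pedoclimate). Higher score means higher expected SOC on
#' the model's transformed scale. Points with missing management covariates
#' get `NA` and are reported.
#'
#' @param data Point table carrying the model covariates and `point_id`.
#' @param fit A `soc_lmm` (typically the eliminated practice model).
#' @param id_col Identifier column used for deterministic tie-breaking
#'   downstream.
#' @return `data.frame` with `point_id` and `score`.
#' @export
rank_by_optimality <- function(data, fit, id_col = "point_id") {
  X <- fixed_effect_matrix(fit, data)
  score <- as.numeric(X %*% lme4::fixef(fit$model))
  n_na <- sum(is.na(score))
  if (n_na > 0L) {
    message("rank_by_optimality: ", n_na,
            " point(s) with missing management excluded from ranking")
  }
  data.frame(point_id = data[[id_col]], score = score,
             stringsAsFactors = FALSE)
}

#' Decile management effect per zone and land-use stratum
#'
#' The difference in mean observed SOC stock between the 10% most optimally
#' and 10% least optimally managed points of each stratum (deciles by count,
#' `ceiling(q n)`, ties broken by point id). Standard errors of the decile
#' means are combined assuming independence. Strata with fewer than `min_n`
#' usable points are skipped with a message.
#'
#' @param data Point table with `point_id`, the stratum columns, a stock
#'   column and a `score` column from [rank_by_optimality()].
#' @param q Decile fraction, in `(0, 0.5)`.
#' @param min_n Minimum points per stratum.
#' @param zone_col,land_use_col,stock_col Column names.
#' @return `data.frame`, one row per stratum: `zone`, `land_use`,
#'   `n_points`, `n_decile`, `top_mean`, `bottom_mean`, `stratum_mean`,
#'   `se_top`, `se_bottom`, `se_mean`, `effect` (top minus bottom,
#'   Mg C ha^-1) and `se_effect`.
#' @export
zone_management_effect <- function(data, q = 0.10, min_n = 20L,
                                   zone_col = "zone",
                                   land_use_col = "land_use",
                                   stock_col = "stock") {
  if (q <= 0 || q >= 0.5) stop("zone_management_effect: 'q' must be in (0, 0.5)")
  d <- data[!is.na(data$score) & !is.na(data[[stock_col]]) &
              !is.na(data[[zone_col]]), , drop = FALSE]
  strata <- split(d, list(d[[zone_col]], d[[land_use_col]]), drop = TRUE)
  rows <- list()
  for (s in strata) {
    n <- nrow(s)
    if (n < min_n) {
      message("zone_management_effect: stratum ", s[[zone_col]][1L], " / ",
              s[[land_use_col]][1L], " skipped (n = ", n, " < ", min_n, ")")
      next
    }
    o <- order(-s$score, s$point_id)
    s <- s[o, , drop = FALSE]
    k <- ceiling(q * n)
    top <- s[[stock_col]][seq_len(k)]
    bottom <- s[[stock_col]][seq.int(n - k + 1L, n)]
    se <- function(x) sd(x) / sqrt(length(x))
    rows[[length(rows) + 1L]] <- data.frame(
      zone = s[[zone_col]][1L], land_use = s[[land_use_col]][1L],
      n_points = n, n_decile = k,
      top_mean = mean(top), bottom_mean = mean(bottom),
      stratum_mean = mean(s[[stock_col]]),
      se_top = se(top), se_bottom = se(bottom),
      se_mean = se(s[[stock_col]]),
      effect = mean(top) - mean(bottom),
      se_effect = sqrt(se(top)^2 + se(bottom)^2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("zone_management_effect: no stratum with enough points")
  rownames(out) <- NULL
  out
}

minmax01 <- function(x) {
  if (all(is.na(x))) return(rep(NA_real_, length(x)))
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) return(rep(NA_real_, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Within-zone management variability
#'
#' Each indicator is min-max normalized across the whole dataset; the
#' variability of a stratum is the mean, over indicators with at least two
#' non-missing values in the stratum, of the within-stratum standard
#' deviation of the normalized indicator. Zones where even small management
#' shifts produce significant stock effects despite low variability flag
#' particularly management-sensitive soils.
#'
#' @param data Point table.
#' @param indicators Indicator column names.
#' @param zone_col,land_use_col Stratum columns (`land_use_col = NULL` for
#'   zone-only strata).
#' @return `data.frame` with the stratum columns and `variability`.
#' @export
management_variability <- function(data, indicators, zone_col = "zone",
                                   land_use_col = "land_use") {
  norm <- lapply(indicators, function(v) minmax01(data[[v]]))
  names(norm) <- indicators
  key <- if (is.null(land_use_col)) list(data[[zone_col]]) else
    list(data[[zone_col]], data[[land_use_col]])
  idx <- split(seq_len(nrow(data)), key, drop = TRUE)
  rows <- lapply(idx, function(i) {
    sds <- vapply(norm, function(v) {
      x <- v[i]
      if (sum(!is.na(x)) < 2L) NA_real_ else sd(x, na.rm = TRUE)
    }, numeric(1))
    data.frame(zone = data[[zone_col]][i[1L]],
               land_use = if (is.null(land_use_col)) NA_character_ else
                 data[[land_use_col]][i[1L]],
               variability = mean(sds, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upscale decile management effects to a continental option space
#'
#' For each zone x land-use stratum the best scenario assumes all its area
#' reaches the top-decile mean stock and the worst scenario the bottom-decile
#' mean; deltas are relative to the stratum mean stock (so best and worst
#' need not be symmetric) or, with `baseline = "decile"`, to the opposite
#' decile. Per-stratum deltas are area-weighted to land-use and overall
#' totals in Pg C; the SE of a total is
#' \eqn{\sqrt{\sum_s (area_s \times se_s)^2}} (independent component errors)
#' and the 95% CI is `estimate +/- 1.96 SE`.
#'
#' @param effects Output of [zone_management_effect()].
#' @param areas Table with `zone`, `land_use`, `area_ha`.
#' @param baseline `"stratum_mean"` or `"decile"`.
#' @return List: `strata` (per-stratum deltas and SEs, Pg C) and `totals`
#'   (per land use plus `"all"`: `best`, `worst`, SEs and 95% CI bounds,
#'   Pg C).
#' @export
option_space <- function(effects, areas, baseline = c("stratum_mean", "decile")) {
  baseline <- match.arg(baseline)
  key <- function(d) paste(d$zone, d$land_use)
  e <- effects
  e$area_ha <- areas$area_ha[match(key(e), key(areas))]
  if (anyNA(e$area_ha)) {
    message("option_space: stratum(s) without area excluded: ",
            paste(key(e)[is.na(e$area_ha)], collapse = "; "))
    e <- e[!is.na(e$area_ha), , drop = FALSE]
  }
  if (nrow(e) == 0L) stop("option_space: no stratum with an area")
  if (baseline == "stratum_mean") {
    e$best_pg <- (e$top_mean - e$stratum_mean) * e$area_ha * 1e-9
    e$worst_pg <- (e$bottom_mean - e$stratum_mean) * e$area_ha * 1e-9
    e$se_best_pg <- sqrt(e$se_top^2 + e$se_mean^2) * e$area_ha * 1e-9
    e$se_worst_pg <- sqrt(e$se_bottom^2 + e$se_mean^2) * e$area_ha * 1e-9
  } else {
    e$best_pg <- e$effect * e$area_ha * 1e-9
    e$worst_pg <- -e$effect * e$area_ha * 1e-9
    e$se_best_pg <- e$se_effect * e$area_ha * 1e-9
    e$se_worst_pg <- e$se_effect * e$area_ha * 1e-9
  }
  total_row <- function(d, label) {
    se_b <- sqrt(sum(d$se_best_pg^2))
    se_w <- sqrt(sum(d$se_worst_pg^2))
    data.frame(land_use = label,
               best = sum(d$best_pg), se_best = se_b,
               best_low = sum(d$best_pg) - 1.96 * se_b,
               best_high = sum(d$best_pg) + 1.96 * se_b,
               worst = sum(d$worst_pg), se_worst = se_w,
               worst_low = sum(d$worst_pg) - 1.96 * se_w,
               worst_high = sum(d$worst_pg) + 1.96 * se_w,
               stringsAsFactors = FALSE)
  }
  totals <- do.call(rbind, c(
    lapply(split(e, e$land_use), function(d) total_row(d, d$land_use[1L])),
    list(total_row(e, "all"))))
  rownames(totals) <- NULL
  list(strata = e, totals = totals)
}
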