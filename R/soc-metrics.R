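#' Fit land-use-specific bulk-density models by exhaustive AIC search
#'
#' Ordinary least squares of measured fine-earth bulk density on
#' hierarchy-respecting subsets of `{sand, clay, sand:clay, total_n, ph,
#' map_mm}` — the sand x clay interaction is only offered together with both
#' main effects, giving 48 candidate models per land use. The minimum-AIC
#' model is selected. Organic-carbon variables are never admitted as
#' predictors: predicted bulk density multiplies OC in the stock equation, so
#' admitting OC would count it twice.
#'
#' When a candidate fits perfectly (mean squared residual below a numerical
#' floor) the Gaussian log-likelihood diverges and AIC comparisons degenerate;
#' the selection then prefers the smallest perfectly-fitting model, which is
#' also the AIC-penalty ordering for candidates of identical residual sum of
#' squares.
#'
#' @param points Soil-point table; rows with non-missing `bd_measured` and
#'   complete covariates are used.
#' @param predictors Candidate main-effect predictors; must not include OC.
#' @param min_points Minimum usable points per land use.
#' @return Named list (per land use) of `bd_model` objects: `land_use`,
#'   `terms`, `coefficients`, `aic`, `n`, `sigma` and the underlying `lm`
#'   fit.
#' @export
fit_bd_models <- function(points,
                          predictors = c("sand", "clay", "total_n", "ph", "map_mm"),
                          min_points = 30L) {
  if (any(grepl("^oc(_|$)|^oc_t", predictors))) {
    stop("fit_bd_models: OC must not be used to predict bulk density")
  }
  missing_cols <- setdiff(c("bd_measured", "land_use", predictors), names(points))
  if (length(missing_cols) > 0L) {
    stop("fit_bd_models: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  use <- points[!is.na(points$bd_measured) &
                  complete.cases(points[, predictors, drop = FALSE]), ,
                drop = FALSE]
  if (nrow(points) == 0L) {
    stop("fit_bd_models: no usable points with measured bulk density")
  }
  models <- list()
  for (lu in sort(unique(points$land_use))) {
    d <- use[use$land_use == lu, , drop = FALSE]
    if (nrow(d) < min_points) {
      stop("fit_bd_models: only ", nrow(d), " usable points for land use '",
           lu, "' (need >= ", min_points, ")")
    }
    cands <- bd_candidate_sets(predictors)
    fits <- lapply(cands, function(tt) {
      f <- if (length(tt) == 0L) bd_measured ~ 1 else
        as.formula(paste("bd_measured ~", paste(tt, collapse = " + ")))
      lm(f, data = d)
    })
    aic <- vapply(fits, AIC, numeric(1))
    msr <- vapply(fits, function(m) mean(m$residuals^2), numeric(1))
    k <- vapply(fits, function(m) length(coef(m)), numeric(1))
    perfect <- msr < 1e-20
    best <- if (any(perfect)) {
      cand_i <- which(perfect)
      cand_i[order(k[cand_i], aic[cand_i])][1L]
    } else {
      which.min(aic)
    }
    fit <- fits[[best]]
    models[[lu]] <- structure(
      list(land_use = lu, terms = cands[[best]], coefficients = coef(fit),
           aic = aic[best], n = nrow(d),
           sigma = sqrt(mean(fit$residuals^2)), fit = fit),
      class = "bd_model")
  }
  models
}

# hierarchy-respecting candidate term sets: all subsets of the main effects,
# each optionally extended with sand:clay when both mains are present
bd_candidate_sets <- function(predictors) {
  n <- length(predictors)
  sets <- list()
  for (mask in 0:(2^n - 1L)) {
    tt <- predictors[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    sets[[length(sets) + 1L]] <- tt
    if (all(c("sand", "clay") %in% tt)) {
      sets[[length(sets) + 1L]] <- c(tt, "sand:clay")
    }
  }
  sets
}

#' Predict reference bulk density at all points
#'
#' Applies the land-use-specific selected model to every point — including
#' points with a measured bulk density, so that stocks are mass-standardized
#' across land uses. Predictions are clipped to the physically plausible
#' fine-earth range \[0.1, 2.2\] g cm^-3.
#'
#' @param points Soil-point table.
#' @param models Output of [fit_bd_models()].
#' @return Numeric vector of reference bulk densities (g cm^-3); `NA` (with
#'   a message) where covariates are missing or no model exists for the land
#'   use. Attribute `"clipped"` counts clipped predictions.
#' @export
predict_bd_ref <- function(points, models) {
  out <- rep(NA_real_, nrow(points))
  clipped <- 0L
  for (lu in unique(points$land_use)) {
    idx <- which(points$land_use == lu)
    m <- models[[lu]]
    if (is.null(m)) next
    pr <- rep(NA_real_, length(idx))
    ok <- complete.cases(points[idx, all.vars(stats::formula(m$fit))[-1],
                                drop = FALSE])
    if (any(ok)) {
      pr[ok] <- predict(m$fit, newdata = points[idx[ok], , drop = FALSE])
    }
    clipped <- clipped + sum(pr < 0.1 | pr > 2.2, na.rm = TRUE)
    out[idx] <- pmin(pmax(pr, 0.1), 2.2)
  }
  n_na <- sum(is.na(out))
  if (n_na > 0L) {
    message("predict_bd_ref: ", n_na, " point(s) without a prediction")
  }
  attr(out, "clipped") <- clipped
  out
}

#' Fixed-depth SOC stock
#'
#' 0-20 cm stock from reference bulk density, organic-carbon concentration
#' and the volume fraction of coarse fragments:
#' \deqn{stock = B_{d,ref} \times OC \times 20 \times 0.1 \times (1 - C_f)}
#' with bulk density in g cm^-3, OC in g C kg^-1 and the result in
#' Mg C ha^-1.
#'
#' @param bd_ref Reference bulk density (g cm^-3).
#' @param oc OC concentration (g C kg^-1).
#' @param coarse_frag Coarse-fragment volume fraction in `[0, 1]`.
#' @return Stock in Mg C ha^-1; vectorized.
#' @export
soc_stock <- function(bd_ref, oc, coarse_frag) {
  if (any(coarse_frag < 0 | coarse_frag > 1, na.rm = TRUE)) {
    stop("soc_stock: 'coarse_frag' must be in [0, 1]")
  }
  if (any(oc < 0, na.rm = TRUE)) stop("soc_stock: 'oc' must be >= 0")
  bd_ref * oc * 20 * 0.1 * (1 - coarse_frag)
}

#' Benchmark ratio of a stock against the pedoclimatic typical stock
#'
#' @param stock Observed stock (Mg C ha^-1).
#' @param typical_stock Typical stock of the zone/land-use stratum, `> 0`.
#' @return Dimensionless ratio; 1 means at benchmark.
#' @export
benchmark_ratio <- function(stock, typical_stock) {
  if (any(typical_stock <= 0, na.rm = TRUE)) {
    stop("benchmark_ratio: 'typical_stock' must be > 0")
  }
  stock / typical_stock
}

#' Yearly change in SOC concentration
#'
#' @param oc_t0,oc_t1 OC concentration (g C kg^-1) at the earlier and later
#'   survey.
#' @param year_t0,year_t1 Survey years, `year_t1 > year_t0`.
#' @return Change in g C kg^-1 yr^-1.
#' @export
delta_soc <- function(oc_t0, oc_t1, year_t0, year_t1) {
  if (any(year_t1 <= year_t0, na.rm = TRUE)) {
    stop("delta_soc: 'year_t1' must be after 'year_t0'")
  }
  (oc_t1 - oc_t0) / (year_t1 - year_t0)
}

#' Impute missing pedoclimatic zones with a random-forest classifier
#'
#' Trains on points with a known zone (500 trees, minimum node size 1,
#' mtry 3 by default) and predicts the missing labels; the out-of-bag error
#' is reported.
#'
#' @param points Soil-point table with a partially missing `zone` column.
#' @param predictors Predictor columns (defaults to OC, region, land cover
#'   and the edaphic/climatic covariates present).
#' @param num_trees,min_node_size,mtry Forest parameters.
#' @param seed Seed forwarded to the forest.
#' @return List: `zone` (completed vector), `oob_error`, `n_imputed`,
#'   `model`.
#' @export
impute_zone <- function(points,
                        predictors = intersect(
                          c("oc_t1", "region", "land_cover", "sand", "clay",
                            "ph", "total_n", "map_mm"), names(points)),
                        num_trees = 500L, min_node_size = 1L, mtry = 3L,
                        seed = 1L) {
  train <- points[!is.na(points$zone), , drop = FALSE]
  if (nrow(train) == 0L) stop("impute_zone: no training points with a zone")
  small <- table(train$zone)
  if (any(small < 10L)) {
    warning("impute_zone: class(es) with < 10 training points: ",
            paste(names(small)[small < 10L], collapse = ", "))
  }
  d_train <- train[, predictors, drop = FALSE]
  for (cc in names(d_train)) {
    if (is.character(d_train[[cc]])) d_train[[cc]] <- factor(d_train[[cc]])
  }
  d_train$zone <- factor(train$zone)
  rf <- ranger::ranger(zone ~ ., data = d_train,
                       num.trees = num_trees, min.node.size = min_node_size,
                       mtry = min(mtry, length(predictors)), seed = seed)
  zone <- points$zone
  miss <- which(is.na(zone))
  if (length(miss) > 0L) {
    d_new <- points[miss, predictors, drop = FALSE]
    for (cc in names(d_new)) {
      if (is.character(d_new[[cc]])) {
        lev <- levels(d_train[[cc]])
        unseen <- setdiff(unique(d_new[[cc]]), lev)
        if (length(unseen) > 0L) {
          stop("impute_zone: unseen level(s) in '", cc, "': ",
               paste(unseen, collapse = ", "))
        }
        d_new[[cc]] <- factor(d_new[[cc]], levels = lev)
      }
    }
    zone[miss] <- as.character(predict(rf, data = d_new)$predictions)
  }
  list(zone = zone, oob_error = rf$prediction.error,
       n_imputed = length(miss), model = rf)
}

#' Cleaning filters for the SOC metric analysis sets
#'
#' Flags organic soils (OC above 160 g C kg^-1, strict inequality, at either
#' survey date), land-use-inconsistent points, and implausible changes
#' (absolute relative change in OC above 100% over the period, or above
#' 3 g kg^-1 yr^-1). The stock and benchmark sets drop later-date organic
#' soils; the change set additionally drops earlier-date organic soils,
#' land-use changes and change outliers.
#'
#' @param metrics Table with `oc_t0`, `oc_t1`, `year_t0`, `year_t1`,
#'   `land_use`, `land_use_t0` (and any metric columns to carry through).
#' @return List: `data` (input plus flag columns `flag_organic_t1`,
#'   `flag_organic_t0`, `flag_landuse_change`, `flag_delta_outlier` and
#'   logical `keep_stock`, `keep_benchmark`, `keep_delta`) and `report`
#'   (per-metric sample sizes and removal counts).
#' @export
clean_records <- function(metrics) {
  d <- metrics
  d$flag_organic_t1 <- d$oc_t1 > 160
  d$flag_organic_t0 <- d$oc_t0 > 160
  d$flag_landuse_change <- d$land_use != d$land_use_t0
  dd <- d$oc_t1 - d$oc_t0
  rate <- dd / (d$year_t1 - d$year_t0)
  rel <- abs(dd) / d$oc_t0
  d$flag_delta_outlier <- rel > 1 | abs(rate) > 3
  d$keep_stock <- !d$flag_organic_t1
  d$keep_benchmark <- !d$flag_organic_t1
  d$keep_delta <- !d$flag_organic_t1 & !d$flag_organic_t0 &
    !d$flag_landuse_change & !d$flag_delta_outlier
  report <- data.frame(
    metric = c("stock", "benchmark", "delta"),
    n_in = nrow(d),
    n_kept = c(sum(d$keep_stock), sum(d$keep_benchmark), sum(d$keep_delta)),
    n_removed_organic = c(sum(d$flag_organic_t1), sum(d$flag_organic_t1),
                          sum(d$flag_organic_t1 | d$flag_organic_t0)),
    n_removed_landuse = c(0L, 0L, sum(d$flag_landuse_change)),
    n_removed_outlier = c(0L, 0L, sum(d$flag_delta_outlier))
  )
  list(data = d, report = report)
}

#' Compute the three SOC metrics for a soil-point table
#'
#' Chains bulk-density model fitting ([fit_bd_models()]), reference
#' bulk-density prediction, the fixed-depth stock equation, zone imputation
#' when zones are partially missing, the benchmark ratio against the
#' zone/land-use typical stock, yearly change in OC concentration, and the
#' cleaning filters.
#'
#' @param points Soil-point table.
#' @param benchmarks Benchmark table (`zone`, `land_use`, `typical_stock`,
#'   `area_ha`).
#' @param bd_models Optional pre-fitted [fit_bd_models()] output.
#' @param impute_missing_zones Impute missing zone labels before
#'   benchmarking.
#' @param bd_min_points Minimum usable bulk-density points per land use.
#' @param seed Seed for the zone classifier.
#' @return List: `metrics` (per-point table with `bd_ref`, `stock`,
#'   `benchmark_ratio`, `delta_soc`, `zone`, flags and keep columns),
#'   `bd_models`, `zone_imputation` (or `NULL`) and the cleaning `report`.
#' @export
compute_soc_metrics <- function(points, benchmarks, bd_models = NULL,
                                impute_missing_zones = TRUE,
                                bd_min_points = 30L, seed = 1L) {
  if (is.null(bd_models)) {
    bd_models <- fit_bd_models(points, min_points = bd_min_points)
  }
  bd_ref <- predict_bd_ref(points, bd_models)
  out <- points
  out$bd_ref <- as.numeric(bd_ref)
  out$stock <- soc_stock(out$bd_ref, out$oc_t1, out$coarse_frag)
  zi <- NULL
  if (impute_missing_zones && anyNA(out$zone)) {
    zi <- impute_zone(out, seed = seed)
    out$zone <- zi$zone
  }
  bm <- benchmarks$typical_stock[
    match(paste(out$zone, out$land_use),
          paste(benchmarks$zone, benchmarks$land_use))]
  out$typical_stock <- bm
  out$benchmark_ratio <- ifelse(!is.na(bm), benchmark_ratio(out$stock, bm),
                                NA_real_)
  out$delta_soc <- delta_soc(out$oc_t0, out$oc_t1, out$year_t0, out$year_t1)
  cl <- clean_records(out)
  list(metrics = cl$data, bd_models = bd_models, zone_imputation = zi,
       report = cl$report)
}
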