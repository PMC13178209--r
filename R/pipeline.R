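#' Read and write pipeline tables
#'
#' CSV dialect used throughout: UTF-8, comma separator, `.` decimal, header
#' row mandatory, missing values as empty fields.
#'
#' @param path File path.
#' @return `read_table()` returns a `data.frame`.
#' @export
read_table <- function(path) {
  read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE)
}

#' @rdname read_table
#' @param x Table to write.
#' @export
write_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write soil points as GeoJSON
#'
#' WGS84 point features with `[lon, lat]` coordinates and all non-coordinate
#' columns as properties.
#'
#' @param points Soil-point table with `lon` and `lat`.
#' @param path Output path.
#' @export
write_points_geojson <- function(points, path) {
  props <- points[, setdiff(names(points), c("lon", "lat")), drop = FALSE]
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$lon[i], points$lat[i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

pipeline_schemas <- function() {
  num <- function(min = -Inf, max = Inf) list(type = "numeric", min = min, max = max)
  chr <- list(type = "character")
  lgl <- list(type = "logical")
  list(
    farms = list(
      columns = list(farm_id = chr, year = num(), country = chr, region = chr,
                     altitude_class = chr, farm_type = chr, size_class = chr,
                     uaa_ha = num(min = 1e-12), organic = lgl,
                     livestock_units = num(min = 0),
                     mineral_n_kg = num(min = 0), mineral_p_kg = num(min = 0),
                     mineral_k_kg = num(min = 0)),
      extra_ok = "^(area_|altitude_m$)"),
    tillage = list(
      columns = list(region = chr, size_class = chr, farm_type = chr,
                     area_conventional = num(min = 0),
                     area_conservation = num(min = 0),
                     area_zero = num(min = 0)),
      extra_ok = "^$"),
    points = list(
      columns = list(point_id = chr, lon = num(-180, 180), lat = num(-90, 90),
                     country = chr, region = chr, altitude_m = num(),
                     altitude_class = chr, land_cover = chr, land_use = chr,
                     land_use_t0 = chr, year_t0 = num(), year_t1 = num(),
                     oc_t0 = num(min = 0), oc_t1 = num(min = 0),
                     bd_measured = num(min = 0),
                     coarse_frag = num(min = 0, max = 1),
                     sand = num(0, 100), clay = num(0, 100), ph = num(0, 14),
                     total_n = num(min = 0), map_mm = num(min = 0),
                     zone = chr),
      extra_ok = "^$"),
    benchmarks = list(
      columns = list(zone = chr, land_use = chr,
                     typical_stock = num(min = 1e-12),
                     area_ha = num(min = 0)),
      extra_ok = "^$")
  )
}

#' Validate a pipeline table against its registered schema
#'
#' Checks required columns, their types and value ranges. Missing or
#' ill-typed columns and out-of-range values are errors listing the columns;
#' unknown extra columns only raise a warning.
#'
#' @param x Table to validate.
#' @param schema_name One of `"farms"`, `"tillage"`, `"points"`,
#'   `"benchmarks"`.
#' @return `invisible(TRUE)` on success.
#' @export
validate_schema <- function(x, schema_name) {
  schemas <- pipeline_schemas()
  if (!schema_name %in% names(schemas)) {
    stop("validate_schema: unknown schema '", schema_name, "'")
  }
  sc <- schemas[[schema_name]]
  missing_cols <- setdiff(names(sc$columns), names(x))
  if (length(missing_cols) > 0L) {
    stop("schema '", schema_name, "': missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  problems <- character()
  for (cn in names(sc$columns)) {
    spec <- sc$columns[[cn]]
    v <- x[[cn]]
    if (spec$type == "numeric" && !is.numeric(v)) {
      problems <- c(problems, paste0(cn, ": not numeric"))
    } else if (spec$type == "logical" && !is.logical(v)) {
      problems <- c(problems, paste0(cn, ": not logical"))
    } else if (spec$type == "numeric") {
      n_bad <- sum(v < spec$min | v > spec$max, na.rm = TRUE)
      if (n_bad > 0L) {
        problems <- c(problems,
                      sprintf("%s: %d value(s) outside [%g, %g]", cn, n_bad,
                              spec$min, spec$max))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("schema '", schema_name, "': ", paste(problems, collapse = "; "))
  }
  extra <- setdiff(names(x), names(sc$columns))
  extra <- extra[!grepl(sc$extra_ok, extra)]
  if (length(extra) > 0L) {
    warning("schema '", schema_name, "': unknown column(s): ",
            paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic experiment end-to-end
#'
#' Generates the synthetic world, computes farm indicators, predicts
#' management at all soil points, derives the SOC metrics, builds the
#' intensity composite, fits the three mixed-model families (intensity model,
#' all-land-use practice model, arable-only practice model) with backward
#' elimination and likelihood-ratio tests, computes zone-level decile
#' management effects and variability, and upscales best/worst scenarios to
#' Pg C totals. All stage outputs are written as CSV into `out_dir` together
#' with a JSON manifest (seed, per-stage row counts, file checksums).
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param min_group_size Matching threshold for management prediction.
#' @param alpha Backward-elimination retention threshold.
#' @param q Decile fraction for the scenarios.
#' @param response Metric modelled and upscaled (`"stock"` by default).
#' @param transform Response transformation for the mixed models.
#' @param geojson Also write the points as GeoJSON.
#' @return Invisible list with every stage result and the manifest.
#' @export
run_all <- function(config = synth_config(), out_dir = tempfile("farmsoc_run_"),
                    min_group_size = 15L, alpha = 0.05, q = 0.10,
                    response = "stock", transform = "log1p",
                    geojson = FALSE) {
  stopifnot(q > 0, q < 0.5, alpha > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outfile <- function(name) file.path(out_dir, name)

  sim <- run_stage("simulate", {
    farms <- generate_farms(config)
    tillage <- generate_tillage_table(config, farms)
    benchmarks <- generate_benchmarks(config)
    pts <- generate_soil_points(config, farms, tillage)
    validate_schema(farms, "farms")
    validate_schema(tillage, "tillage")
    validate_schema(pts$points, "points")
    validate_schema(benchmarks, "benchmarks")
    write_table(farms, outfile("farms.csv"))
    write_table(tillage, outfile("tillage.csv"))
    write_table(benchmarks, outfile("benchmarks.csv"))
    write_table(pts$points, outfile("points.csv"))
    write_table(pts$ground_truth, outfile("ground_truth.csv"))
    if (geojson) write_points_geojson(pts$points, outfile("points.geojson"))
    list(farms = farms, tillage = tillage, benchmarks = benchmarks,
         points = pts$points, ground_truth = pts$ground_truth)
  })
  counts$farms <- nrow(sim$farms)
  counts$points <- nrow(sim$points)

  indicators <- run_stage("indicators", {
    ind <- compute_farm_indicators(sim$farms, sim$tillage,
                                   crop_list = config$crop_list)
    write_table(ind, outfile("farm_indicators.csv"))
    ind
  })
  counts$farm_indicators <- nrow(indicators)

  predicted <- run_stage("predict", {
    pm <- predict_at_points(sim$points, sim$farms, indicators,
                            min_group_size = min_group_size,
                            crop_list = config$crop_list)
    write_table(pm, outfile("predicted_management.csv"))
    pm
  })
  counts$predicted_management <- nrow(predicted)

  metrics <- run_stage("metrics", {
    sm <- compute_soc_metrics(sim$points, sim$benchmarks,
                              seed = config$seed)
    write_table(sm$metrics, outfile("soc_metrics.csv"))
    write_table(sm$report, outfile("cleaning_report.csv"))
    sm
  })
  counts$soc_metrics_stock <- sum(metrics$metrics$keep_stock)
  counts$soc_metrics_delta <- sum(metrics$metrics$keep_delta)

  intensity <- run_stage("intensity", {
    it <- management_intensity(predicted)
    write_table(it, outfile("intensity.csv"))
    it
  })

  analysis <- run_stage("assemble", {
    a <- merge(metrics$metrics, predicted, by = "point_id")
    merge(a, intensity[, c("point_id", "intensity")], by = "point_id")
  })

  fits <- run_stage("fit", {
    a <- analysis[analysis$keep_stock, , drop = FALSE]
    # N input in 100 kg ha^-1 so the quadratic term is on a comparable scale
    a$n_input_100 <- a$n_input_med / 100
    multi_lu <- length(unique(a$land_use)) > 1L
    spec_list <- list(
      intensity = if (multi_lu) "intensity * land_use" else "intensity",
      practices = c(
        if (multi_lu) c("manure_share_n_med * land_use",
                        "organic_probability * land_use")
        else c("manure_share_n_med", "organic_probability"),
        "n_input_100", "I(n_input_100^2)"))
    fits <- lapply(names(spec_list), function(nm) {
      f0 <- fit_soc_lmm(a, response, spec_list[[nm]], transform = transform)
      fr <- backward_eliminate(f0, alpha = alpha)
      list(name = nm, fit = fr, lrt = lrt_vs_null(fr))
    })
    names(fits) <- names(spec_list)
    ar <- a[a$land_use == "arable", , drop = FALSE]
    if (nrow(ar) > 50L && length(unique(ar$zone)) > 1L) {
      f0 <- fit_soc_lmm(ar, response,
                        c("manure_share_n_med", "organic_probability",
                          "n_input_100", "I(n_input_100^2)",
                          "rotation_diversity_med", "ley_fodder_share_med",
                          "tillage_intensity_med"),
                        transform = transform)
      fr <- backward_eliminate(f0, alpha = alpha)
      fits$practices_arable <- list(name = "practices_arable", fit = fr,
                                    lrt = lrt_vs_null(fr))
    }
    summ <- do.call(rbind, lapply(fits, function(x) {
      data.frame(model = x$name,
                 terms = paste(x$fit$fixed_terms, collapse = " + "),
                 n = nrow(x$fit$data), chisq = x$lrt$chisq, df = x$lrt$df,
                 p_value = x$lrt$p_value, stringsAsFactors = FALSE)
    }))
    write_table(summ, outfile("fit_summaries.csv"))
    fits
  })

  scen <- run_stage("scenarios", {
    a <- analysis[analysis$keep_stock, , drop = FALSE]
    a$n_input_100 <- a$n_input_med / 100
    sc <- rank_by_optimality(a, fits$practices$fit)
    a$score <- sc$score[match(a$point_id, sc$point_id)]
    eff <- zone_management_effect(a, q = q)
    vb <- management_variability(
      a, c(grep("_med$", names(predicted), value = TRUE), "organic_probability"))
    eff$variability <- vb$variability[match(paste(eff$zone, eff$land_use),
                                            paste(vb$zone, vb$land_use))]
    os <- option_space(eff, sim$benchmarks)
    write_table(eff, outfile("zone_effects.csv"))
    write_table(os$strata, outfile("scenario_strata.csv"))
    write_table(os$totals, outfile("scenarios.csv"))
    list(effects = eff, option_space = os)
  })
  counts$zone_effects <- nrow(scen$effects)

  manifest <- run_stage("manifest", {
    files <- sort(list.files(out_dir, pattern = "\\.(csv|geojson)$"))
    m <- list(package = "farmsoc",
              version = as.character(packageVersion("farmsoc")),
              seed = config$seed,
              row_counts = counts,
              checksums = as.list(tools::md5sum(file.path(out_dir, files))))
    names(m$checksums) <- files
    jsonlite::write_json(m, outfile("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    m
  })

  invisible(list(config = config, out_dir = out_dir, simulate = sim,
                 indicators = indicators, predicted = predicted,
                 metrics = metrics, intensity = intensity, fits = fits,
                 scenarios = scen, manifest = manifest))
}
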