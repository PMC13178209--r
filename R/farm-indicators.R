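#' Default livestock excretion coefficients
#'
#' Annual nutrient excretion per standard livestock unit (LU). One dairy cow
#' equals one LU; the dairy-cow values are applied to all livestock, which
#' overstates excretion for lighter animal categories — the table is exposed so
#' users can substitute livestock-specific values.
#'
#' @return Named numeric vector with elements `n_kg`, `p_kg`, `k_kg`
#'   (kg LU^-1 yr^-1).
#' @export
default_excretion_table <- function() {
  c(n_kg = 135, p_kg = 19, k_kg = 139)
}

#' Default crop catalogue for the synthetic survey
#'
#' @return `data.frame` with columns `crop`, `land_use` (one of `"arable"`,
#'   `"grassland"`, `"tree"`) and `category` (rotation-composition category for
#'   arable crops, `NA` otherwise).
#' @export
default_crop_list <- function() {
  data.frame(
    crop = c("wheat", "barley", "maize", "potato", "sugar_beet", "rapeseed",
             "sunflower", "field_pea", "vegetables", "ley", "fodder_legume",
             "perm_grassland", "olive", "vineyard"),
    land_use = c(rep("arable", 11L), "grassland", "tree", "tree"),
    category = c("cereals", "cereals", "maize", "roots_tubers", "roots_tubers",
                 "rapeseed", "sunflower", "dry_pulses", "vegetables", "leys",
                 "fodder_legumes", NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Rotation-composition categories
#' @return Character vector of the ten crop categories used for composition
#'   shares.
#' @export
crop_categories <- function() {
  c("cereals", "roots_tubers", "dry_pulses", "sunflower", "rapeseed",
    "other_industrial", "fodder_legumes", "maize", "vegetables", "leys")
}

area_cols <- function(farms) grep("^area_", names(farms), value = TRUE)

crop_area_matrix <- function(farms) {
  cols <- area_cols(farms)
  if (length(cols) == 0L) stop("farms table has no 'area_<crop>' columns")
  m <- as.matrix(farms[, cols, drop = FALSE])
  colnames(m) <- sub("^area_", "", cols)
  m[is.na(m)] <- 0
  m
}

#' Per-hectare nutrient input
#'
#' Mineral fertilizer plus animal-based fertilizer per hectare of utilized
#' agricultural area. Animal-based input is livestock density (LU ha^-1)
#' times the annual excretion per LU.
#'
#' @param farms Farms table with columns `uaa_ha`, `livestock_units`,
#'   `mineral_n_kg`, `mineral_p_kg`, `mineral_k_kg`.
#' @param excretion Named vector as [default_excretion_table()].
#' @return `data.frame` with columns `n_input`, `p_input`, `k_input`
#'   (kg ha^-1) and the animal-based components `animal_n`, `animal_p`,
#'   `animal_k` (kg ha^-1).
#' @export
nutrient_input <- function(farms, excretion = default_excretion_table()) {
  if (any(excretion < 0)) stop("nutrient_input: excretion coefficients must be >= 0")
  if (any(!is.finite(farms$uaa_ha)) || any(farms$uaa_ha <= 0)) {
    stop("nutrient_input: 'uaa_ha' must be positive")
  }
  dens <- farms$livestock_units / farms$uaa_ha
  out <- data.frame(
    animal_n = dens * excretion[["n_kg"]],
    animal_p = dens * excretion[["p_kg"]],
    animal_k = dens * excretion[["k_kg"]]
  )
  out$n_input <- farms$mineral_n_kg / farms$uaa_ha + out$animal_n
  out$p_input <- farms$mineral_p_kg / farms$uaa_ha + out$animal_p
  out$k_input <- farms$mineral_k_kg / farms$uaa_ha + out$animal_k
  out[, c("n_input", "p_input", "k_input", "animal_n", "animal_p", "animal_k")]
}

#' Share of manure in the fertilizer mix
#'
#' Animal-based input divided by total (animal + mineral) input, per nutrient.
#' `NA` where the total input is zero.
#'
#' @inheritParams nutrient_input
#' @return `data.frame` with `manure_share_n`, `manure_share_p`,
#'   `manure_share_k`, each in `[0, 1]` or `NA`.
#' @export
manure_share <- function(farms, excretion = default_excretion_table()) {
  ni <- nutrient_input(farms, excretion)
  shr <- function(animal, total) ifelse(total > 0, animal / total, NA_real_)
  data.frame(
    manure_share_n = shr(ni$animal_n, ni$n_input),
    manure_share_p = shr(ni$animal_p, ni$p_input),
    manure_share_k = shr(ni$animal_k, ni$k_input)
  )
}

#' Gini-Simpson diversity of crop areas
#'
#' \eqn{1 - \sum_i p_i^2} with \eqn{p_i} the area shares. Bounded by
#' \eqn{1 - 1/k} for `k` crops; `NA` when the total area is zero.
#'
#' @param areas Numeric vector of areas, or a matrix with one row per farm.
#' @return Scalar (or per-row vector) in `[0, 1)`.
#' @export
gini_simpson <- function(areas) {
  if (is.matrix(areas)) {
    tot <- rowSums(areas)
    p2 <- rowSums((areas / ifelse(tot > 0, tot, NA))^2)
    return(ifelse(tot > 0, 1 - p2, NA_real_))
  }
  tot <- sum(areas)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  1 - sum((areas / tot)^2)
}

#' Rotation diversity of a farms table
#'
#' Gini-Simpson index over the arable crop areas of each farm.
#'
#' @param farms Farms table with `area_<crop>` columns.
#' @param crop_list Crop catalogue mapping crops to land-use classes.
#' @return Numeric vector, `NA` for farms without arable area.
#' @export
rotation_diversity <- function(farms, crop_list = default_crop_list()) {
  m <- crop_area_matrix(farms)
  arable <- intersect(colnames(m), crop_list$crop[crop_list$land_use == "arable"])
  gini_simpson(m[, arable, drop = FALSE])
}

#' Rotation composition shares
#'
#' Share of each crop category in the farm's arable area, plus crop richness
#' (number of arable crops with positive area) and the combined ley and
#' fodder-legume share. Shares sum to 1 where any arable area exists and are
#' `NA` otherwise.
#'
#' @param farms Farms table with `area_<crop>` columns.
#' @param crop_list Crop catalogue; its `category` column must cover every
#'   arable crop present.
#' @return `data.frame` with `share_<category>` columns, `crop_richness`,
#'   `ley_share`, `fodder_legume_share` and `ley_fodder_share`.
#' @export
crop_composition <- function(farms, crop_list = default_crop_list()) {
  m <- crop_area_matrix(farms)
  arable_crops <- crop_list$crop[crop_list$land_use == "arable"]
  arable_here <- intersect(colnames(m), arable_crops)
  unmapped <- setdiff(colnames(m), crop_list$crop)
  if (length(unmapped) > 0L) {
    stop("crop_composition: unmapped crop code(s): ", paste(unmapped, collapse = ", "))
  }
  am <- m[, arable_here, drop = FALSE]
  cat_of <- crop_list$category[match(arable_here, crop_list$crop)]
  if (anyNA(cat_of)) {
    stop("crop_composition: arable crop(s) without category: ",
         paste(arable_here[is.na(cat_of)], collapse = ", "))
  }
  tot <- rowSums(am)
  out <- data.frame(row.names = seq_len(nrow(farms)))
  for (cc in crop_categories()) {
    sub <- am[, cat_of == cc, drop = FALSE]
    out[[paste0("share_", cc)]] <- ifelse(tot > 0, rowSums(sub) / tot, NA_real_)
  }
  out$crop_richness <- rowSums(am > 0)
  out$crop_richness[tot <= 0] <- NA_real_
  out$ley_share <- out$share_leys
  out$fodder_legume_share <- out$share_fodder_legumes
  out$ley_fodder_share <- out$share_leys + out$share_fodder_legumes
  out
}

#' Tillage intensity of a tillage cell
#'
#' Fraction of area under conventional tillage weighted 1, conservation
#' tillage weighted 0.2, zero tillage weighted 0.
#'
#' @param conventional,conservation,zero Areas (ha) under each practice;
#'   vectorized.
#' @return Intensity in `[0, 1]`; `NA` where the cell total is zero.
#' @export
tillage_intensity <- function(conventional, conservation, zero) {
  if (any(c(conventional, conservation, zero) < 0, na.rm = TRUE)) {
    stop("tillage_intensity: areas must be >= 0")
  }
  tot <- conventional + conservation + zero
  ifelse(tot > 0, (conventional + 0.2 * conservation) / tot, NA_real_)
}

#' Compute all per-farm management indicators
#'
#' Runs [nutrient_input()], [manure_share()], [rotation_diversity()],
#' [crop_composition()] and joins tillage intensity by
#' (`region`, `size_class`, `farm_type`); farms without a matching tillage
#' cell get `NA`.
#'
#' @param farms Farms table (see [generate_farms()] for the schema).
#' @param tillage Optional tillage table with columns `region`, `size_class`,
#'   `farm_type`, `area_conventional`, `area_conservation`, `area_zero`.
#' @param excretion Excretion coefficients per LU.
#' @param crop_list Crop catalogue.
#' @return `data.frame`, one row per farm: identifiers plus all indicator
#'   columns.
#' @export
compute_farm_indicators <- function(farms, tillage = NULL,
                                    excretion = default_excretion_table(),
                                    crop_list = default_crop_list()) {
  out <- farms[, intersect(c("farm_id", "year", "country", "region",
                             "altitude_class", "farm_type", "size_class",
                             "uaa_ha", "organic"), names(farms))]
  ni <- nutrient_input(farms, excretion)
  out$n_input <- ni$n_input
  out$p_input <- ni$p_input
  out$k_input <- ni$k_input
  out <- cbind(out, manure_share(farms, excretion))
  out$rotation_diversity <- rotation_diversity(farms, crop_list)
  out <- cbind(out, crop_composition(farms, crop_list))
  if (!is.null(tillage)) {
    ti <- tillage_intensity(tillage$area_conventional, tillage$area_conservation,
                            tillage$area_zero)
    key <- function(d) paste(d$region, d$size_class, d$farm_type, sep = "|")
    out$tillage_intensity <- ti[match(key(farms), key(tillage))]
  } else {
    out$tillage_intensity <- NA_real_
  }
  out
}

#' Names of the numeric management-indicator columns
#' @param x A farm-indicators or predicted-management table.
#' @return Character vector of indicator column names present in `x`.
#' @export
indicator_columns <- function(x) {
  base <- c("n_input", "p_input", "k_input",
            "manure_share_n", "manure_share_p", "manure_share_k",
            "rotation_diversity", "crop_richness",
            paste0("share_", crop_categories()),
            "ley_share", "fodder_legume_share", "ley_fodder_share",
            "tillage_intensity")
  intersect(base, names(x))
}
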