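#' Rank-normalize a variable to \[0, 1\]
#'
#' Average-ties ranking across the non-missing values (descending when
#' `reverse`), followed by min-max scaling of the ranks to \[0, 1\]. Missing
#' values are preserved; a constant variable maps to 0.5 everywhere (the
#' midpoint avoids spurious extremes in the composite).
#'
#' @param x Numeric values.
#' @param reverse Rank descending (for practices that reduce intensity).
#' @return Numeric vector in `[0, 1]` with the missingness of `x`.
#' @export
rank_normalize <- function(x, reverse = FALSE) {
  r <- rank(if (reverse) -x else x, ties.method = "average", na.last = "keep")
  if (all(is.na(r))) return(rep(NA_real_, length(x)))
  rng <- range(r, na.rm = TRUE)
  if (rng[1] == rng[2]) return(ifelse(is.na(x), NA_real_, 0.5))
  (r - rng[1]) / (rng[2] - rng[1])
}

#' Default grouping of the management-intensity composite
#'
#' Each management function contributes unit weight, split equally over its
#' constituent indicators: nutrient input (N, P, K), manure share (N, P, K),
#' crop diversity (Gini-Simpson and richness), organic probability, combined
#' ley and fodder-legume share, and tillage intensity. Reverse-ranked groups
#' are practices expected to *reduce* intensity.
#'
#' @return List of groups, each a list with `name`, `vars`, `reverse`.
#' @export
default_intensity_spec <- function() {
  list(
    list(name = "nutrient_input",
         vars = c("n_input_med", "p_input_med", "k_input_med"),
         reverse = FALSE),
    list(name = "manure_share",
         vars = c("manure_share_n_med", "manure_share_p_med", "manure_share_k_med"),
         reverse = TRUE),
    list(name = "crop_diversity",
         vars = c("rotation_diversity_med", "crop_richness_med"),
         reverse = TRUE),
    list(name = "organic", vars = "organic_probability", reverse = TRUE),
    list(name = "ley_fodder", vars = "ley_fodder_share_med", reverse = TRUE),
    list(name = "tillage", vars = "tillage_intensity_med", reverse = FALSE)
  )
}

#' Rank-based management-intensity composite
#'
#' Every constituent variable is rank-normalized across the whole dataset
#' ([rank_normalize()], reversed for extensifying practices), constituents
#' are averaged within their function group, and the intensity is the
#' unweighted mean of the group scores over the groups with any non-missing
#' constituent. Result in \[0, 1\]; missing only when every variable is
#' missing.
#'
#' @param data Table of predicted management (one row per point or farm).
#' @param spec Grouping as [default_intensity_spec()]; variables absent from
#'   `data` are skipped.
#' @param id_col Optional identifier column copied to the output.
#' @return `data.frame` with the identifier (if any), one normalized-score
#'   column per group, and `intensity`.
#' @export
management_intensity <- function(data, spec = default_intensity_spec(),
                                 id_col = "point_id") {
  out <- if (id_col %in% names(data)) data[, id_col, drop = FALSE] else
    data.frame(row.names = seq_len(nrow(data)))
  gscores <- list()
  for (g in spec) {
    vars <- intersect(g$vars, names(data))
    if (length(vars) == 0L) next
    norm <- vapply(vars, function(v) rank_normalize(data[[v]], g$reverse),
                   numeric(nrow(data)))
    norm <- matrix(norm, nrow = nrow(data))
    score <- rowMeans(norm, na.rm = TRUE)
    score[rowSums(!is.na(norm)) == 0L] <- NA_real_
    gscores[[g$name]] <- score
    out[[paste0("rank_", g$name)]] <- score
  }
  if (length(gscores) == 0L) stop("management_intensity: no spec variable found in data")
  gm <- do.call(cbind, gscores)
  intensity <- rowMeans(gm, na.rm = TRUE)
  intensity[rowSums(!is.na(gm)) == 0L] <- NA_real_
  out$intensity <- intensity
  out
}
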