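#' Farm weight for crop-specific aggregation
#'
#' Weight given to a farm when aggregating management for one crop within a
#' matching group: the geometric mean of the farm's specialization in the crop
#' (crop area over the farm's utilized agricultural area) and its
#' representativeness for the group (crop area over the group's total area of
#' that crop),
#' \deqn{w_i = \sqrt{\frac{area_i}{UAA_i} \times \frac{area_i}{\sum_j area_j}}.}
#'
#' @param area_i Crop area on the farm (ha), `> 0`.
#' @param uaa_i Utilized agricultural area of the farm (ha), `>= area_i`.
#' @param total_area Total area of the crop across the group (ha),
#'   `>= area_i`.
#' @return Numeric weight in `(0, 1]`. Vectorized over all arguments.
#' @examples
#' farm_weight(10, 10, 40) # fully specialized farm holding a quarter: 0.5
#' @export
farm_weight <- function(area_i, uaa_i, total_area) {
  if (any(!is.finite(area_i)) || any(area_i <= 0)) {
    stop("farm_weight: 'area_i' must be positive and finite")
  }
  if (any(uaa_i <= 0) || any(total_area <= 0)) {
    stop("farm_weight: 'uaa_i' and 'total_area' must be positive")
  }
  if (any(area_i > uaa_i * (1 + 1e-9))) {
    stop("farm_weight: crop area exceeds farm UAA")
  }
  sqrt((area_i / uaa_i) * (area_i / total_area))
}

#' Lower weighted median
#'
#' The smallest value whose cumulative weight reaches half the total weight.
#' With equal weights this is the ordinary lower median; it minimizes
#' \eqn{\sum_i w_i |x_i - m|}, ties resolved to the smaller value. Missing
#' values are dropped pairwise with their weights.
#'
#' @param x Numeric values.
#' @param w Positive weights, same length as `x`.
#' @return Scalar median, or `NA` if nothing remains after missing removal.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  if (length(x) != length(w)) stop("weighted_median: lengths differ")
  keep <- !is.na(x) & !is.na(w)
  x <- as.numeric(x[keep]); w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  if (any(w <= 0)) stop("weighted_median: weights must be positive")
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1L]]
}

#' Weighted standard deviation
#'
#' Population (frequency-weight) form
#' \eqn{\sqrt{\sum_i w_i (x_i - \bar x_w)^2 / \sum_i w_i}} with
#' \eqn{\bar x_w} the weighted mean. Missing values dropped pairwise.
#'
#' @inheritParams weighted_median
#' @return Scalar SD (`0` for a single value), `NA` if empty.
#' @export
weighted_sd <- function(x, w = rep(1, length(x))) {
  if (length(x) != length(w)) stop("weighted_sd: lengths differ")
  keep <- !is.na(x) & !is.na(w)
  x <- as.numeric(x[keep]); w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  if (any(w <= 0)) stop("weighted_sd: weights must be positive")
  m <- sum(w * x) / sum(w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}
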