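#' Response transformations for the SOC mixed models
#'
#' Stocks are `log1p`-transformed, benchmark ratios `log`-transformed and
#' yearly SOC change `asinh`-transformed to better meet normality; `identity`
#' is available for simulation work where effects are generated on the
#' response scale.
#'
#' @param x Numeric values.
#' @param kind One of `"identity"`, `"log1p"`, `"log"`, `"asinh"`.
#' @return Transformed values.
#' @export
transform_response <- function(x, kind = c("identity", "log1p", "log", "asinh")) {
  kind <- match.arg(kind)
  bad <- switch(kind,
                log = sum(x <= 0, na.rm = TRUE),
                log1p = sum(x <= -1, na.rm = TRUE),
                0L)
  if (bad > 0L) {
    stop("transform_response: ", bad, " value(s) outside the domain of '",
         kind, "'")
  }
  switch(kind, identity = x, log1p = log1p(x), log = log(x), asinh = asinh(x))
}

#' @rdname transform_response
#' @export
inverse_transform <- function(x, kind = c("identity", "log1p", "log", "asinh")) {
  kind <- match.arg(kind)
  switch(kind, identity = x, log1p = expm1(x), log = exp(x), asinh = sinh(x))
}

#' Fit a linear mixed model of a SOC metric on management
#'
#' Fits `g(y) = X beta + u_zone + e` with a random intercept per
#' pedoclimatic zone, via `lmerTest::lmer()`. The response is transformed
#' with [transform_response()] before fitting.
#'
#' @param data Analysis table (one row per point), complete cases of the
#'   model variables are used.
#' @param response Response column (`stock`, `benchmark_ratio`,
#'   `delta_soc`, ...).
#' @param fixed_terms Character vector of fixed-effect terms, formula syntax
#'   (e.g. `"manure_share_n_med * land_use"`, `"I(n_input_med^2)"`).
#' @param transform Response transformation kind.
#' @param zone_col Grouping column for the random intercept; needs >= 2
#'   levels.
#' @param REML Use REML (reporting) or ML (likelihood-ratio testing).
#' @return Object of class `soc_lmm`: the `lmerTest` fit plus metadata
#'   (`coefficients` table with Satterthwaite p-values, variance components,
#'   log-likelihood, the term set and the data used).
#' @export
fit_soc_lmm <- function(data, response, fixed_terms,
                        transform = c("identity", "log1p", "log", "asinh"),
                        zone_col = "zone", REML = TRUE) {
  transform <- match.arg(transform)
  vars <- unique(c(response, zone_col,
                   all.vars(as.formula(paste(
                     "~", paste(c("1", fixed_terms), collapse = "+"))))))
  d <- data[complete.cases(data[, vars, drop = FALSE]), vars, drop = FALSE]
  if (length(unique(d[[zone_col]])) < 2L) {
    stop("fit_soc_lmm: need at least 2 levels of '", zone_col, "'")
  }
  if (nrow(d) <= length(fixed_terms) + 2L) {
    stop("fit_soc_lmm: too few complete observations")
  }
  d$.y <- transform_response(d[[response]], transform)
  rhs <- paste(c(if (length(fixed_terms) > 0L) fixed_terms else "1",
                 paste0("(1 | ", zone_col, ")")), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))
  fit <- lmerTest::lmer(fml, data = d, REML = REML)
  if (lme4::isSingular(fit)) {
    warning("fit_soc_lmm: singular fit (a variance component is zero)")
  }
  as_soc_lmm(fit, d, response, transform, fixed_terms, zone_col, REML)
}

as_soc_lmm <- function(fit, data, response, transform, fixed_terms,
                       zone_col, REML) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    model = fit, data = data, response = response, transform = transform,
    fixed_terms = fixed_terms, zone_col = zone_col, REML = REML,
    coefficients = as.data.frame(coef(summary(fit))),
    zone_variance = vc$vcov[vc$grp == zone_col],
    residual_variance = vc$vcov[vc$grp == "Residual"],
    logLik = as.numeric(logLik(fit))
  ), class = "soc_lmm")
}

#' @export
print.soc_lmm <- function(x, ...) {
  cat("Linear mixed model:", x$response, "(", x$transform, ") ~",
      if (length(x$fixed_terms)) paste(x$fixed_terms, collapse = " + ") else "1",
      "+ (1 |", x$zone_col, ")\n")
  cat(sprintf("n = %d, zone SD = %.3f, residual SD = %.3f, logLik = %.1f (%s)\n",
              nrow(x$data), sqrt(x$zone_variance), sqrt(x$residual_variance),
              x$logLik, if (x$REML) "REML" else "ML"))
  print(round(x$coefficients, 4))
  invisible(x)
}

refit_ml <- function(fit) {
  if (!fit$REML) return(fit$model)
  update(fit$model, REML = FALSE)
}

#' Backward elimination of non-significant fixed terms
#'
#' Iteratively refits the ML model, tests each droppable term with a
#' likelihood-ratio test (`drop1`, which respects marginality: main effects
#' are never dropped while their interactions remain) and removes the least
#' significant term with `p > alpha`, until every remaining term is
#' significant. The final model is refitted with the original estimation
#' method.
#'
#' @param fit A [fit_soc_lmm()] result.
#' @param alpha Retention threshold.
#' @return A `soc_lmm` for the reduced model; `$eliminated` lists the
#'   dropped terms in order.
#' @export
backward_eliminate <- function(fit, alpha = 0.05) {
  ml <- refit_ml(fit)
  dropped <- character()
  repeat {
    d1 <- drop1(ml, test = "Chisq")
    pcol <- intersect(c("Pr(>F)", "Pr(Chi)", "Pr(>Chi)"), colnames(d1))[1L]
    cand <- rownames(d1)[rownames(d1) != "<none>" & !is.na(d1[[pcol]])]
    if (length(cand) == 0L) break
    p <- d1[cand, pcol]
    worst <- which.max(p)
    if (p[worst] <= alpha) break
    dropped <- c(dropped, cand[worst])
    ml <- update(ml, as.formula(paste(". ~ . -", cand[worst])))
  }
  kept <- attr(terms(ml, fixed.only = TRUE), "term.labels")
  final <- if (fit$REML) update(ml, REML = TRUE) else ml
  out <- as_soc_lmm(final, fit$data, fit$response, fit$transform,
                    kept, fit$zone_col, fit$REML)
  out$eliminated <- dropped
  out
}

#' Likelihood-ratio test against the random-intercept-only model
#'
#' Refits the model and its fixed-effects-free null by maximum likelihood on
#' the same data and compares them: chi-squared is twice the log-likelihood
#' difference, degrees of freedom is the difference in fixed-effect
#' parameters.
#'
#' @param fit A [fit_soc_lmm()] result.
#' @return List with `chisq`, `df`, `p_value`, and both ML log-likelihoods.
#' @export
lrt_vs_null <- function(fit) {
  ml <- refit_ml(fit)
  null_fml <- as.formula(paste(".y ~ 1 + (1 |", fit$zone_col, ")"))
  null_ml <- lme4::lmer(null_fml, data = fit$data, REML = FALSE)
  df <- length(lme4::fixef(ml)) - 1L
  chisq <- max(0, 2 * (as.numeric(logLik(ml)) - as.numeric(logLik(null_ml))))
  p <- if (df > 0L) pchisq(chisq, df, lower.tail = FALSE) else 1
  list(chisq = chisq, df = df, p_value = p,
       logLik_model = as.numeric(logLik(ml)),
       logLik_null = as.numeric(logLik(null_ml)))
}

#' Marginal-effect curve of one model variable
#'
#' Predicted response along a grid of the focal variable with all other
#' covariates held at their observed distribution (the whole dataset is
#' counterfactually set to each grid value and the fixed-effect predictions
#' averaged, which holds continuous covariates at their means and factors at
#' their observed mix), the random intercept at zero, back-transformed to
#' the response scale. Confidence bounds come from the fixed-effect
#' covariance on the transformed scale and are back-transformed (no smearing
#' correction).
#'
#' @param fit A [fit_soc_lmm()] result.
#' @param variable Focal model variable (must appear in the fixed terms).
#' @param grid Grid values (default: 25 points spanning the observed range).
#' @param by Optional factor column (e.g. land use): one curve per level.
#' @param level Confidence level.
#' @return `data.frame` with the grid, optional `by` level, `predicted`,
#'   `conf_low`, `conf_high` on the response scale.
#' @export
marginal_effects <- function(fit, variable, grid = NULL, by = NULL,
                             level = 0.95) {
  used <- all.vars(as.formula(paste(
    "~", paste(c("1", fit$fixed_terms), collapse = "+"))))
  if (!variable %in% used) {
    stop("marginal_effects: '", variable, "' is not in the model")
  }
  d <- fit$data
  if (is.null(grid)) {
    grid <- seq(min(d[[variable]], na.rm = TRUE),
                max(d[[variable]], na.rm = TRUE), length.out = 25L)
  }
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  z <- qnorm(1 - (1 - level) / 2)
  levels_by <- if (is.null(by)) NA else unique(as.character(d[[by]]))
  rows <- list()
  for (lv in levels_by) {
    for (g in grid) {
      nd <- d
      nd[[variable]] <- g
      if (!is.null(by)) nd[[by]] <- lv
      X <- fixed_effect_matrix(fit, nd)
      xbar <- colMeans(X)
      est <- sum(xbar * beta)
      se <- sqrt(drop(t(xbar) %*% V %*% xbar))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = variable, value = g,
        by = if (is.null(by)) NA_character_ else lv,
        predicted = inverse_transform(est, fit$transform),
        conf_low = inverse_transform(est - z * se, fit$transform),
        conf_high = inverse_transform(est + z * se, fit$transform),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# fixed-effect design matrix for new data, columns aligned to the fitted
# coefficients (factor levels absent from `nd` contribute zero columns)
fixed_effect_matrix <- function(fit, nd) {
  tt <- delete.response(terms(fit$model, fixed.only = TRUE))
  # align categorical columns with the levels seen at fit time so that
  # single-level or partial new data still produce the fitted contrasts
  for (v in intersect(names(nd), all.vars(tt))) {
    ref <- fit$data[[v]]
    if (is.character(ref) || is.factor(ref)) {
      lev <- if (is.factor(ref)) levels(ref) else sort(unique(ref))
      nd[[v]] <- factor(as.character(nd[[v]]), levels = lev)
    }
  }
  X <- model.matrix(tt, model.frame(tt, nd, na.action = stats::na.pass))
  beta_names <- names(lme4::fixef(fit$model))
  out <- matrix(0, nrow = nrow(X), ncol = length(beta_names),
                dimnames = list(NULL, beta_names))
  common <- intersect(colnames(X), beta_names)
  out[, common] <- X[, common]
  out
}
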