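#' Survey-weighted least squares with robust (sandwich) variance
#'
#' Coefficients minimise the weighted residual sum of squares
#' `sum(w_i * (y_i - x_i b)^2)`. The variance is the weights-only robust
#' sandwich estimator `B (sum w_i^2 e_i^2 x_i x_i') B` with
#' `B = (X'WX)^{-1}`, the standard design-based approximation when only
#' analysis weights (no strata/PSU) are available. Estimates are invariant
#' to rescaling all weights by a positive constant.
#'
#' @param y Outcome vector.
#' @param X Design matrix (named columns); supply an intercept column
#'   explicitly if wanted.
#' @param w Positive weights, one per row (default equal).
#' @return List of class `dietcost_fit`: `coefficients`, `vcov`, `se`,
#'   `r_squared` (weighted), `residuals`, `n`, `df`.
#' @export
weighted_lsq <- function(y, X, w = rep(1, length(y))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y) || length(w) != length(y))
    stop_dietcost("y, X and w must have aligned rows",
                  "dietcost_validation_error")
  if (any(!(w > 0)))
    stop_dietcost("weights must be positive", "dietcost_validation_error")
  sw <- sqrt(w)
  qx <- qr(X * sw)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_dietcost(sprintf("singular design: collinear column(s) %s",
                          paste(dropped, collapse = ", ")),
                  "dietcost_singular_design_error")
  }
  beta <- qr.coef(qx, y * sw)
  e <- as.numeric(y - X %*% beta)
  bread <- chol2inv(qr.R(qx))
  score <- X * (w * e)
  meat <- crossprod(score)
  vc <- bread %*% meat %*% bread
  dimnames(vc) <- list(colnames(X), colnames(X))
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - sum(w * e^2) / tss else NA_real_
  structure(list(coefficients = beta, vcov = vc, se = sqrt(diag(vc)),
                 r_squared = r2, residuals = e, n = length(y),
                 df = length(y) - ncol(X)),
            class = "dietcost_fit")
}

#' @export
print.dietcost_fit <- function(x, ...) {
  cat("Survey-weighted least squares fit\n")
  cat(sprintf("  n = %d, weighted R-squared = %.4f\n", x$n, x$r_squared))
  print(cbind(estimate = x$coefficients, robust_se = x$se))
  invisible(x)
}

# Expand covariates into a numeric matrix with every column centred at its
# weighted mean, so group coefficients in a no-intercept group model are
# covariate-adjusted means.
centred_covariate_matrix <- function(covariates, w) {
  if (is.null(covariates) || ncol(covariates) == 0) return(NULL)
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (anyNA(v))
      stop_dietcost(sprintf("missing values in covariate '%s'", nm),
                    "dietcost_validation_error")
    if (is.numeric(v)) {
      cols[[nm]] <- v - sum(w * v) / sum(w)
    } else {
      f <- factor(v)
      for (lv in levels(f)[-1]) {
        ind <- as.numeric(f == lv)
        cols[[paste0(nm, "_", lv)]] <- ind - sum(w * ind) / sum(w)
      }
    }
  }
  do.call(cbind, cols)
}

#' Survey-weighted (crude or adjusted) group means with 95 % CI
#'
#' Crude means come from a weighted regression on group indicators without
#' an intercept, whose coefficients are the weighted group means. The
#' adjusted model adds covariates centred at their weighted means
#' (categorical covariates as indicator contrasts centred at weighted
#' proportions), so the group coefficients are covariate-adjusted means.
#' Confidence intervals are estimate +/- 1.96 robust SE; groups with fewer
#' than 2 members keep their estimate but have the CI suppressed, with a
#' warning.
#'
#' @param y Outcome vector (e.g. cost per 2000 kcal, pence).
#' @param group Factor (or coercible) of group membership.
#' @param w Survey weights.
#' @param covariates Data frame of confounders, or `NULL` for crude.
#' @param model Label stored in the output: `"crude"` or `"adjusted"`.
#' @return Tibble: `group`, `n`, `mean`, `ci_low`, `ci_high`, `model`.
#' @export
group_means <- function(y, group, w = rep(1, length(y)), covariates = NULL,
                        model = if (is.null(covariates)) "crude"
                                else "adjusted") {
  group <- droplevels(factor(group))
  if (anyNA(group))
    stop_dietcost("missing group labels", "dietcost_validation_error")
  G <- stats::model.matrix(~ 0 + group)
  colnames(G) <- levels(group)
  X <- cbind(G, centred_covariate_matrix(covariates, w))
  fit <- weighted_lsq(y, X, w)
  k <- nlevels(group)
  est <- fit$coefficients[seq_len(k)]
  se <- fit$se[seq_len(k)]
  n_g <- as.integer(table(group))
  small <- n_g < 2
  if (any(small)) {
    rlang::warn(sprintf("group level(s) with < 2 members, CI suppressed: %s",
                        paste(levels(group)[small], collapse = ", ")))
    se[small] <- NA_real_
  }
  tibble::tibble(group = levels(group), n = n_g, mean = unname(est),
                 ci_low = unname(est - 1.96 * se),
                 ci_high = unname(est + 1.96 * se),
                 model = model)
}

# z statistic with a floor for numerically-zero estimates, so an exactly
# flat outcome reports p = 1 rather than a 0/0 artefact
zstat <- function(b, se, tol = 1e-10) {
  if (abs(b) < tol && se < tol) return(0)
  if (se == 0) return(sign(b) * Inf)
  b / se
}

#' Survey-weighted difference between two groups
#'
#' Weighted regression of the outcome on a membership indicator (plus
#' centred covariates): the indicator coefficient is the (adjusted)
#' mean difference, with robust SE, 95 % CI and two-sided normal p-value.
#'
#' @param y Outcome vector.
#' @param indicator Logical/0-1 vector (e.g. recommendation met).
#' @param w Survey weights.
#' @param covariates Optional data frame of confounders.
#' @return One-row tibble: `diff`, `se`, `ci_low`, `ci_high`, `p_value`.
#' @export
group_difference <- function(y, indicator, w = rep(1, length(y)),
                             covariates = NULL) {
  X <- cbind(intercept = 1, indicator = as.numeric(indicator),
             centred_covariate_matrix(covariates, w))
  fit <- weighted_lsq(y, X, w)
  d <- fit$coefficients[["indicator"]]
  se <- fit$se[["indicator"]]
  z <- zstat(d, se)
  tibble::tibble(diff = d, se = se, ci_low = d - 1.96 * se,
                 ci_high = d + 1.96 * se, p_value = 2 * pnorm(-abs(z)))
}

#' Percent cost difference between met and not-met groups
#'
#' `100 * (met - not_met) / not_met`, rounded to the nearest integer
#' percent as reported.
#'
#' @param met,not_met Mean costs (numeric scalars, or one-row tibbles from
#'   [group_means()] with a `mean` column).
#' @return Integer percent difference.
#' @export
percent_difference <- function(met, not_met) {
  if (is.data.frame(met)) met <- met$mean
  if (is.data.frame(not_met)) not_met <- not_met$mean
  if (!(not_met > 0))
    stop_dietcost("percent difference undefined: baseline mean is not positive",
                  "dietcost_undefined_percent_error")
  round(100 * (met - not_met) / not_met)
}

#' Linear trend across quintiles
#'
#' Weighted regression of the outcome on the quintile index (1-5) as a
#' single numeric regressor, plus optional centred covariates; two-sided
#' p-value from the robust SE with a normal reference.
#'
#' @param y Outcome vector.
#' @param quintile Integer quintile index per person (1-5).
#' @param w Survey weights.
#' @param covariates Optional data frame of confounders.
#' @return One-row tibble: `slope`, `se`, `p_value`.
#' @export
linear_trend <- function(y, quintile, w = rep(1, length(y)),
                         covariates = NULL) {
  X <- cbind(intercept = 1, quintile = as.numeric(quintile),
             centred_covariate_matrix(covariates, w))
  fit <- weighted_lsq(y, X, w)
  b <- fit$coefficients[["quintile"]]
  se <- fit$se[["quintile"]]
  z <- zstat(b, se)
  tibble::tibble(slope = b, se = se, p_value = 2 * pnorm(-abs(z)))
}

#' Unweighted regression of daily diet cost on daily energy
#'
#' Simple least squares of cost per day on energy per day, reporting slope,
#' intercept and R-squared (the strength of the cost-energy association
#' that motivates presenting costs per 2000 kcal).
#'
#' @param cost_per_day Pence per day.
#' @param energy_per_day kcal per day.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
cost_energy_regression <- function(cost_per_day, energy_per_day) {
  if (length(cost_per_day) < 3)
    stop_dietcost("need at least 3 observations",
                  "dietcost_validation_error")
  if (stats::var(energy_per_day) == 0)
    stop_dietcost("energy vector is constant; fit is degenerate",
                  "dietcost_degenerate_fit_error")
  X <- cbind(intercept = 1, energy = energy_per_day)
  fit <- weighted_lsq(cost_per_day, X)
  b <- fit$coefficients[["energy"]]
  se <- fit$se[["energy"]]
  z <- zstat(b, se)
  list(slope = b, intercept = fit$coefficients[["intercept"]],
       r_squared = fit$r_squared, p_value = 2 * pnorm(-abs(z)),
       n = length(cost_per_day))
}
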