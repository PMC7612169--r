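#' Heterogeneity Q statistic
#'
#' Weighted residual sum of squares of the outcome associations around the
#' fitted values implied by a candidate effect vector:
#' `Q = sum_j (1/se_y_j^2) (beta_y_j - x_j' theta)^2` over the chosen
#' variant subset, on `|subset| - K` degrees of freedom.  Under valid
#' instruments and fixed-effect assumptions Q is approximately chi-squared;
#' excess Q indicates pleiotropy.
#'
#' @param data a [summary_dataset()].
#' @param theta length-K effect vector at which to evaluate the residuals.
#' @param subset optional variant ids or indices; all variants by default.
#' @return list with `q` and `df`.
#' @export
q_statistic <- function(data, theta, subset = NULL) {
  stopifnot(inherits(data, "summary_dataset"))
  K <- n_exposures(data)
  stopifnot(length(theta) == K)
  idx <- if (is.null(subset)) seq_len(n_variants(data)) else if
    (is.character(subset)) match(subset, data$variant_ids) else subset
  if (anyNA(idx)) stop("unknown variant in subset", call. = FALSE)
  p <- length(idx)
  if (p <= K)
    stop("subset has ", p, " variants; need more than K = ", K,
         " for positive degrees of freedom", call. = FALSE)
  r <- data$beta_outcome[idx] -
    as.numeric(data$beta_exposure[idx, , drop = FALSE] %*% theta)
  list(q = sum(r^2 / data$se_outcome[idx]^2), df = p - K)
}

#' Mean F statistic of one exposure
#'
#' Marginal instrument strength: the mean over variants of
#' `(beta_exposure/se_exposure)^2` for exposure `k`.  Values well above 10
#' indicate the variants are collectively strong instruments for that
#' exposure, ignoring the other exposures.
#'
#' @param data a [summary_dataset()].
#' @param k exposure index.
#' @return a single number.
#' @export
mean_f <- function(data, k = 1) {
  stopifnot(inherits(data, "summary_dataset"))
  stopifnot(k >= 1, k <= n_exposures(data))
  mean((data$beta_exposure[, k] / data$se_exposure[, k])^2)
}

#' Conditional F statistic of one exposure
#'
#' Instrument strength for exposure `k` conditional on the other `K - 1`
#' exposures, computed Q-statistic-style from summary data.  The
#' association column of exposure `k` is regressed, with intercept, on the
#' other exposures' association columns; because the regressor columns are
#' themselves estimates, the weights are the errors-in-variables variances
#' `se[,k]^2 + sum_l coef_l^2 * se[,l]^2`, and the coefficients and weights
#' are iterated to convergence (a generalized weighted least squares fixed
#' point).  The conditional F statistic is the weighted residual sum of
#' squares scaled by `1/(p - K + 1)`.  Values near 1 mean exposure `k`
#' adds no independent instrument strength beyond the other exposures; the
#' conventional adequacy threshold is 10.
#'
#' With `K = 1` there is nothing to condition on and the statistic equals
#' [mean_f()].  Between-exposure sampling covariance of the association
#' estimates is taken as zero, matching inputs that carry only per-trait
#' standard errors.
#'
#' @inheritParams mean_f
#' @param tol,max_iter convergence control of the coefficient/weight
#'   iteration.
#' @return a single number.
#' @export
conditional_f <- function(data, k = 1, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(data, "summary_dataset"))
  K <- n_exposures(data)
  stopifnot(k >= 1, k <= K)
  if (K == 1) return(mean_f(data, k))
  p <- n_variants(data)
  y <- data$beta_exposure[, k]
  X <- cbind(`(intercept)` = 1, data$beta_exposure[, -k, drop = FALSE])
  v_y <- data$se_exposure[, k]^2
  V_x <- data$se_exposure[, -k, drop = FALSE]^2
  coef <- wls_fit(X, y, 1 / v_y)$coef
  for (it in seq_len(max_iter)) {
    w <- 1 / (v_y + as.numeric(V_x %*% coef[-1]^2))
    coef_new <- wls_fit(X, y, w)$coef
    if (max(abs(coef_new - coef)) <= tol * max(1, max(abs(coef)))) {
      coef <- coef_new
      break
    }
    coef <- coef_new
  }
  w <- 1 / (v_y + as.numeric(V_x %*% coef[-1]^2))
  rss <- sum(w * (y - X %*% coef)^2)
  rss / (p - K + 1)
}

#' Condition number of the exposure association matrix
#'
#' Ratio of the largest to the smallest singular value of the exposure
#' association matrix after column scaling (each column divided by its
#' Euclidean norm by default, making the statistic invariant to per-exposure
#' units).  Values above 30 conventionally indicate multicollinearity severe
#' enough to destabilize multivariable estimates; a warning is emitted in
#' that case.
#'
#' @param data a [summary_dataset()].
#' @param scaling `"norm"` (default) to scale columns to unit Euclidean
#'   norm, `"sd"` to scale by column standard deviation, `"none"` for the
#'   raw matrix.
#' @param warn_threshold warning threshold.
#' @return a single number; `Inf` (with a warning) if the matrix is
#'   numerically rank deficient.
#' @export
condition_number <- function(data, scaling = c("norm", "sd", "none"),
                             warn_threshold = 30) {
  stopifnot(inherits(data, "summary_dataset"))
  scaling <- match.arg(scaling)
  X <- data$beta_exposure
  X <- switch(scaling,
              norm = sweep(X, 2, sqrt(colSums(X^2)), "/"),
              sd = sweep(X, 2, apply(X, 2, stats::sd), "/"),
              none = X)
  d <- svd(X, nu = 0, nv = 0)$d
  if (min(d) < max(d) * .Machine$double.eps * max(dim(X))) {
    warning("exposure association matrix is numerically rank deficient; ",
            "condition number is infinite", call. = FALSE)
    return(Inf)
  }
  kappa <- max(d) / min(d)
  if (kappa > warn_threshold)
    warning("condition number ", signif(kappa, 4), " exceeds ",
            warn_threshold, "; estimates may be unstable due to ",
            "multicollinearity", call. = FALSE)
  kappa
}

#' Residual-versus-fitted table for a fitted model
#'
#' Per-variant fitted values and residuals under a fit's effect estimates,
#' with `se_outcome` as error-bar half-widths and an invalid flag taken from
#' the fit.  The table is the multivariable analogue of the univariable
#' scatterplot of outcome against exposure associations and is intended for
#' plotting heterogeneity and spotting outliers.
#'
#' @param data a [summary_dataset()].
#' @param fit an [mvmr_fit()] on (a subset of) the same variants.
#' @return a data.frame with columns `variant`, `fitted`, `residual`,
#'   `se_outcome`, `invalid`.
#' @export
residual_fitted <- function(data, fit) {
  stopifnot(inherits(data, "summary_dataset"), inherits(fit, "mvmr_fit"))
  fitted <- as.numeric(data$beta_exposure %*% fit$theta)
  data.frame(
    variant = data$variant_ids,
    fitted = fitted,
    residual = data$beta_outcome - fitted,
    se_outcome = unname(data$se_outcome),
    invalid = data$variant_ids %in% fit$invalid_set,
    row.names = NULL)
}
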