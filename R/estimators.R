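#' Multivariable inverse-variance weighted estimator (MVMR-IVW)
#'
#' Weighted least-squares regression, without intercept, of the
#' variant-outcome associations on the variant-exposure associations with
#' weights `1/se_outcome^2`.  Consistent when all instruments are valid, or
#' when pleiotropy is balanced and instrument strength is independent of the
#' direct effects (InSIDE); sensitive to outliers and directional pleiotropy.
#'
#' @param data a [summary_dataset()].
#' @param se_model `"random"` (default) for multiplicative random-effects
#'   standard errors — the fixed-effect SE scaled by `max(1, sqrt(Q/df))`
#'   where `Q` is the heterogeneity statistic on `df = p - K` degrees of
#'   freedom — or `"fixed"` for unscaled weighted least-squares SEs.
#' @param alpha_level two-sided significance level for confidence intervals.
#' @param subset optional variant subset (ids or indices) to fit on.
#' @return an [mvmr_fit()].
#' @references Residual heterogeneity above chance under fixed-effect
#'   weighting indicates pleiotropy; the multiplicative random-effects model
#'   inflates the SEs accordingly and never deflates them.
#' @export
#' @examples
#' d <- summary_dataset(paste0("rs", 1:5),
#'   matrix(runif(10, 0.05, 0.15), 5, 2), matrix(0.01, 5, 2),
#'   rnorm(5, 0.02, 0.01), rep(0.01, 5))
#' mvmr_ivw(d)
mvmr_ivw <- function(data, se_model = c("random", "fixed"),
                     alpha_level = 0.05, subset = NULL) {
  stopifnot(inherits(data, "summary_dataset"))
  se_model <- match.arg(se_model)
  if (!is.null(subset)) data <- data[subset]
  X <- data$beta_exposure
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  p <- nrow(X)
  K <- ncol(X)
  fit <- wls_fit(X, y, w)
  q <- sum(w * (y - X %*% fit$coef)^2)
  df <- p - K
  scale2 <- if (se_model == "random" && df > 0) max(1, q / df) else 1
  se <- sqrt(diag(fit$cov_unscaled) * scale2)
  mvmr_fit(method = "MVMR-IVW", exposure_names = data$exposure_names,
           theta = fit$coef, se = se, alpha_level = alpha_level,
           n_variants_used = p, q_statistic = q, q_df = df,
           notes = paste0("se_model=", se_model))
}

#' Multivariable MR-Egger estimator (MVMR-Egger)
#'
#' Adds a common pleiotropy intercept to the IVW regression.  The intercept
#' absorbs directional pleiotropy, so the slope estimates remain consistent
#' under directional pleiotropy provided the InSIDE assumption holds, at the
#' cost of precision.  Results depend on variant orientation: the data are
#' oriented internally so that every variant associates positively with the
#' reference exposure.
#'
#' @inheritParams mvmr_ivw
#' @param reference exposure index used to orient the variants.
#' @return an [mvmr_fit()] with `intercept`/`intercept_se` populated.
#' @export
mvmr_egger <- function(data, reference = 1, se_model = c("random", "fixed"),
                       alpha_level = 0.05) {
  stopifnot(inherits(data, "summary_dataset"))
  se_model <- match.arg(se_model)
  data <- orient(data, reference)
  X <- data$beta_exposure
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  p <- nrow(X)
  K <- ncol(X)
  if (p <= K + 1)
    stop("MVMR-Egger needs p > K + 1 variants (no residual degrees of ",
         "freedom with p = ", p, ", K = ", K, ")", call. = FALSE)
  Xi <- cbind(`(intercept)` = 1, X)
  fit <- wls_fit(Xi, y, w)
  q <- sum(w * (y - Xi %*% fit$coef)^2)
  df <- p - K - 1
  scale2 <- if (se_model == "random") max(1, q / df) else 1
  se_all <- sqrt(diag(fit$cov_unscaled) * scale2)
  mvmr_fit(method = "MVMR-Egger", exposure_names = data$exposure_names,
           theta = fit$coef[-1], se = se_all[-1], alpha_level = alpha_level,
           intercept = fit$coef[1], intercept_se = se_all[1],
           n_variants_used = p, q_statistic = q, q_df = df,
           notes = paste0("se_model=", se_model, "; oriented to exposure ",
                          reference))
}

#' Multivariable MR-PRESSO outlier test and estimator
#'
#' Detects outlying (pleiotropic) variants by comparing each variant's
#' observed weighted squared residual — computed under leave-one-out IVW
#' estimates — with its parametric null distribution, then refits MVMR-IVW
#' with the flagged variants removed.
#'
#' The procedure: (i) leave-one-out IVW estimates `theta_{-j}`; (ii) the
#' global observed residual sum of squares `RSS_obs` sums the per-variant
#' weighted squared residuals; (iii) `n_sim` parametric replicates redraw the
#' exposure associations around their estimates and the outcome associations
#' around the leave-one-out fitted values, giving simulated residual sums of
#' squares; (iv) each variant's empirical P-value is the proportion of its
#' simulated contributions exceeding its observed one; (v) variants with
#' Bonferroni-adjusted empirical P below `alpha_level` are removed.  If no
#' variant is flagged the estimate equals [mvmr_ivw()] exactly.
#'
#' The decision uses the raw empirical P-value (which can be zero, as in the
#' reference implementation); reported per-variant P-values are floored at
#' `1/n_sim`.
#'
#' @inheritParams mvmr_ivw
#' @param n_sim number of parametric replicates `M` (at least 100).
#' @param seed integer seed for the parametric replicates.
#' @param outlier_alpha significance level for the Bonferroni-corrected
#'   outlier test; defaults to `alpha_level`.
#' @return a list with elements `fit` (an [mvmr_fit()] on the retained
#'   variants) and `report` (a `presso_report` with the global test and
#'   per-variant empirical P-values).
#' @export
mvmr_presso <- function(data, n_sim = 1000, alpha_level = 0.05,
                        seed = NULL, se_model = c("random", "fixed"),
                        outlier_alpha = alpha_level) {
  stopifnot(inherits(data, "summary_dataset"))
  se_model <- match.arg(se_model)
  if (n_sim < 100) stop("n_sim must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- data$beta_exposure
  y <- data$beta_outcome
  sy <- data$se_outcome
  sx <- data$se_exposure
  w <- 1 / sy^2
  p <- nrow(X)
  K <- ncol(X)

  # leave-one-out IVW by rank-one downdate of the normal equations
  A <- crossprod(X * w, X)  # t(X) %*% diag(w) %*% X
  b <- crossprod(X * w, y)
  theta_loo <- matrix(NA_real_, p, K)
  for (j in seq_len(p)) {
    xj <- X[j, ]
    Aj <- A - w[j] * tcrossprod(xj)
    bj <- b - w[j] * y[j] * xj
    theta_loo[j, ] <- solve(Aj, bj)
  }

  fitted_loo <- rowSums(X * theta_loo)
  obs <- w * (y - fitted_loo)^2
  rss_obs <- sum(obs)

  # Simulated residuals: beta_Y^(m) ~ N(fitted_loo, sy^2) and
  # beta_X^(m) ~ N(beta_X, sx^2) give residual_j^(m) =
  # sy_j Z_y - sum_k sx_jk theta_loo[j,k] Z_k; all p x M at once.
  M <- as.integer(n_sim)
  resid_sim <- sy * matrix(stats::rnorm(p * M), p, M)
  for (k in seq_len(K)) {
    resid_sim <- resid_sim -
      (sx[, k] * theta_loo[, k]) * matrix(stats::rnorm(p * M), p, M)
  }
  exp_sim <- w * resid_sim^2
  rss_exp <- colSums(exp_sim)
  global_p <- mean(rss_exp > rss_obs)
  variant_p_raw <- rowMeans(exp_sim > obs)
  variant_p <- pmax(variant_p_raw, 1 / M)

  if (1 / M * p > outlier_alpha) {
    resolution_note <- paste0(
      "n_sim = ", M, " resolves Bonferroni-corrected P only down to ",
      signif(p / M, 3), "; only empirical P = 0 can be flagged")
    warning(resolution_note, call. = FALSE)
  } else resolution_note <- character(0)

  outliers <- data$variant_ids[variant_p_raw * p < outlier_alpha]
  report <- structure(list(
    rss_observed = rss_obs, global_p = global_p,
    variant_p = stats::setNames(variant_p, data$variant_ids),
    n_sim = M, outliers = outliers), class = "presso_report")

  if (length(outliers) == p)
    stop("MR-PRESSO flagged every variant as an outlier; no data left ",
         "to fit", call. = FALSE)
  keep <- setdiff(data$variant_ids, outliers)
  if (length(keep) <= K)
    stop("MR-PRESSO retained only ", length(keep),
         " variants (need > K = ", K, ")", call. = FALSE)
  fit <- mvmr_ivw(data, se_model = se_model, alpha_level = alpha_level,
                  subset = keep)
  fit$method <- "MVMR-PRESSO"
  fit$invalid_set <- outliers
  fit$notes <- c(fit$notes, paste0("n_sim=", M, "; global_p=", global_p),
                 resolution_note)
  list(fit = fit, report = report)
}

#' @export
print.presso_report <- function(x, ...) {
  cat("MR-PRESSO report: RSS_obs =", signif(x$rss_observed, 5),
      ", global P =", x$global_p, "over", x$n_sim, "replicates\n")
  cat("outliers:", if (length(x$outliers) == 0) "none" else
    paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' Robust multivariable MR via MM-estimation (MVMR-Robust)
#'
#' Replaces the least-squares criterion of MVMR-IVW with MM-estimation using
#' Tukey's bisquare objective: rows are scaled by `1/se_outcome` (so the
#' weighted model becomes homoscedastic), an initial high-breakdown
#' S-estimate of scale is computed, and an efficiency-tuned bisquare M-step
#' (`c = 4.685`, 95% Gaussian efficiency) follows.  Large residuals are
#' effectively capped, giving robustness to a minority of pleiotropic
#' variants without removing them.
#'
#' @inheritParams mvmr_ivw
#' @param max_iter maximum IRLS iterations of the M-step.
#' @param c_tukey bisquare tuning constant of the M-step.
#' @return an [mvmr_fit()] with robust asymptotic standard errors.
#' @export
mvmr_robust <- function(data, alpha_level = 0.05, max_iter = 500,
                        c_tukey = 4.685) {
  stopifnot(inherits(data, "summary_dataset"))
  X <- data$beta_exposure
  y <- data$beta_outcome
  sy <- data$se_outcome
  p <- nrow(X)
  K <- ncol(X)
  Xs <- X / sy
  ys <- y / sy
  # Degenerate exact-fit data (zero residual scale) breaks the S-estimate;
  # the least-squares solution is then already the MM solution, with the
  # fixed-effect weighted covariance as the (residual-free) SE.
  wls <- wls_fit(X, y, 1 / sy^2)
  r_wls <- ys - Xs %*% wls$coef
  if (max(abs(r_wls)) < 1e-8 * max(1, max(abs(ys)))) {
    return(mvmr_fit(method = "MVMR-Robust",
                    exposure_names = data$exposure_names,
                    theta = wls$coef, se = sqrt(diag(wls$cov_unscaled)),
                    alpha_level = alpha_level, n_variants_used = p,
                    q_statistic = sum(r_wls^2), q_df = p - K,
                    notes = "degenerate exact fit; least-squares solution"))
  }
  fit <- suppressWarnings(
    MASS::rlm(Xs, ys, method = "MM", psi = MASS::psi.bisquare, c = c_tukey,
              maxit = max_iter))
  if (anyNA(fit$coefficients))
    stop("MM-estimation produced undefined coefficients", call. = FALSE)
  if (!fit$converged)
    stop("MM-estimation failed to converge after ", max_iter,
         " iterations; final coefficients ",
         paste(signif(fit$coefficients, 4), collapse = ", "), call. = FALSE)
  sm <- summary(fit, method = "XtWX")
  se <- sm$coefficients[, "Std. Error"]
  w <- 1 / sy^2
  q <- sum(w * (y - X %*% fit$coefficients)^2)
  mvmr_fit(method = "MVMR-Robust", exposure_names = data$exposure_names,
           theta = fit$coefficients, se = se, alpha_level = alpha_level,
           n_variants_used = p, q_statistic = q, q_df = p - K,
           notes = paste0("MM bisquare c=", c_tukey, ", scale=",
                          signif(fit$s, 5)))
}

#' Median-based multivariable MR (MVMR-Median)
#'
#' Estimates the causal effects by weighted least-absolute-deviations (LAD)
#' regression — median (tau = 0.5) quantile regression of the outcome
#' associations on the exposure associations with weights `1/se_outcome^2`
#' and no intercept.  With a single exposure this reduces exactly to the
#' weighted-median estimator of univariable MR with weights
#' `|beta_exposure|/se_outcome^2`.  The LAD criterion down-weights outlying
#' variants and tolerates directional pleiotropy up to moderate levels of
#' invalidity.
#'
#' Standard errors come from a parametric bootstrap: each draw redraws every
#' outcome association from `N(beta_outcome, se_outcome^2)` and every
#' exposure association from a multivariate normal centred at the estimates
#' with diagonal covariance `diag(se_exposure^2)` (between-exposure
#' correlation deliberately ignored), refits the LAD regression, and the SE
#' is the standard deviation of the bootstrap estimates.
#'
#' @inheritParams mvmr_ivw
#' @param n_boot number of parametric bootstrap draws (at least 100).
#' @param seed integer seed for the bootstrap.
#' @param ci_type `"normal"` (default) for `estimate +/- z * SE`, or
#'   `"percentile"` for bootstrap percentile intervals.
#' @return an [mvmr_fit()]; `q_statistic` is the heterogeneity Q at the LAD
#'   estimate.
#' @export
mvmr_median <- function(data, n_boot = 1000, seed = NULL, alpha_level = 0.05,
                        ci_type = c("normal", "percentile")) {
  stopifnot(inherits(data, "summary_dataset"))
  ci_type <- match.arg(ci_type)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  X <- data$beta_exposure
  y <- data$beta_outcome
  sy <- data$se_outcome
  sx <- data$se_exposure
  w <- 1 / sy^2
  p <- nrow(X)
  K <- ncol(X)

  fit <- lad_fit(X, y, w)

  boot <- matrix(NA_real_, n_boot, K)
  for (b in seq_len(n_boot)) {
    Xb <- X + sx * matrix(stats::rnorm(p * K), p, K)
    yb <- y + sy * stats::rnorm(p)
    boot[b, ] <- lad_fit(Xb, yb, w)$theta
  }
  se <- apply(boot, 2, stats::sd)

  res <- mvmr_fit(method = "MVMR-Median",
                  exposure_names = data$exposure_names,
                  theta = fit$theta, se = se, alpha_level = alpha_level,
                  n_variants_used = p,
                  q_statistic = sum(w * (y - X %*% fit$theta)^2),
                  q_df = p - K,
                  notes = paste0("n_boot=", n_boot, "; ci_type=", ci_type))
  if (ci_type == "percentile") {
    qs <- apply(boot, 2, stats::quantile,
                probs = c(alpha_level / 2, 1 - alpha_level / 2))
    res$ci_lower <- stats::setNames(qs[1, ], data$exposure_names)
    res$ci_upper <- stats::setNames(qs[2, ], data$exposure_names)
  }
  res$lad_objective <- fit$objective
  res
}
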