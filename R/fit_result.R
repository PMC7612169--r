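#' Construct an estimator fit result
#'
#' Common return type of all MVMR estimators: per-exposure causal effect
#' estimates with normal-approximation inference, plus method-specific extras
#' (Egger intercept, per-variant lasso intercepts, outlier/invalid sets).
#' Users normally obtain these from [mvmr_ivw()] and friends rather than
#' calling this constructor.
#'
#' @param method method label.
#' @param exposure_names length-K exposure labels.
#' @param theta length-K point estimates.
#' @param se length-K positive standard errors.
#' @param alpha_level two-sided significance level used for the CI.
#' @param intercept,intercept_se optional scalar pleiotropy intercept
#'   (MVMR-Egger) and its SE.
#' @param variant_intercepts optional length-p per-variant intercepts
#'   (MVMR-Lasso).
#' @param invalid_set character vector of variant ids flagged
#'   invalid/outlying.
#' @param n_variants_used number of variants contributing to `theta`.
#' @param q_statistic heterogeneity Q statistic at `theta` (variants used).
#' @param q_df degrees of freedom of `q_statistic`.
#' @param notes free-text notes (e.g. "three-sample").
#' @return an object of class `mvmr_fit`.
#' @export
mvmr_fit <- function(method, exposure_names, theta, se,
                     alpha_level = 0.05,
                     intercept = NULL, intercept_se = NULL,
                     variant_intercepts = NULL,
                     invalid_set = character(0),
                     n_variants_used, q_statistic = NA_real_,
                     q_df = NA_integer_, notes = character(0)) {
  K <- length(theta)
  stopifnot(length(se) == K, all(se > 0), length(exposure_names) == K,
            alpha_level > 0, alpha_level < 1)
  z <- stats::qnorm(1 - alpha_level / 2)
  theta <- stats::setNames(as.numeric(theta), exposure_names)
  se <- stats::setNames(as.numeric(se), exposure_names)
  structure(list(
    method = method,
    exposure_names = exposure_names,
    theta = theta,
    se = se,
    ci_lower = theta - z * se,
    ci_upper = theta + z * se,
    p_value = 2 * stats::pnorm(-abs(theta / se)),
    intercept = intercept,
    intercept_se = intercept_se,
    variant_intercepts = variant_intercepts,
    invalid_set = as.character(invalid_set),
    n_variants_used = as.integer(n_variants_used),
    q_statistic = q_statistic,
    q_df = q_df,
    alpha_level = alpha_level,
    notes = notes
  ), class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, digits = 4, ...) {
  cat(x$method, "fit:", x$n_variants_used, "variants,",
      length(x$theta), "exposures\n")
  df <- as.data.frame(x)
  df[-1] <- round(df[-1], digits)
  print(df)
  if (!is.null(x$intercept))
    cat(sprintf("intercept: %.*f (SE %.*f)\n", digits, x$intercept,
                digits, x$intercept_se))
  if (length(x$invalid_set) > 0)
    cat("variants flagged invalid:", paste(x$invalid_set, collapse = ", "),
        "\n")
  if (is.finite(x$q_statistic))
    cat(sprintf("heterogeneity Q = %.*f on %d df\n", digits,
                x$q_statistic, x$q_df))
  invisible(x)
}

#' @export
as.data.frame.mvmr_fit <- function(x, ...) {
  data.frame(exposure = x$exposure_names, estimate = unname(x$theta),
             se = unname(x$se), ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper), p_value = unname(x$p_value))
}

#' Serialize a fit result
#'
#' `write_fit_json()` writes the full result (estimates, CIs, invalid set,
#' provenance notes) as JSON; `write_fit_tsv()` writes a one-row-per-exposure
#' TSV of the estimate table.
#'
#' @param fit an [mvmr_fit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- unclass(fit)
  out$variant_intercepts <-
    if (is.null(out$variant_intercepts)) NULL else
      as.list(out$variant_intercepts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_fit_tsv <- function(fit, path) {
  utils::write.table(as.data.frame(fit), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
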