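#' Penalized per-variant intercept fit at a single penalty value
#'
#' Solves the convex problem underlying MVMR-Lasso at one value of the
#' tuning parameter `lambda`:
#' minimize over `(theta_01..theta_0p, theta_1..theta_K)` of
#' `sum_j (1/se_y_j^2) (beta_y_j - theta_0j - x_j' theta)^2 +
#'  lambda * sum_j |theta_0j|`.
#' Each variant receives its own intercept `theta_0j`; the L1 penalty
#' shrinks the intercepts of valid instruments exactly to zero while leaving
#' pleiotropic variants with non-zero intercepts.
#'
#' Solved by block coordinate descent: given `theta`, each intercept has the
#' closed form `theta_0j = soft(r_j, lambda * se_y_j^2 / 2)` where `r_j` is
#' the variant's residual; given the intercepts, `theta` is weighted least
#' squares on the intercept-adjusted outcome.  The objective is convex so
#' the alternation converges to the global optimum.
#'
#' @param data a [summary_dataset()]; orient first for a
#'   reference-dependent analysis (see [mvmr_lasso()]).
#' @param lambda positive penalty.
#' @param theta_init optional warm start for `theta`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum coordinate-descent sweeps.
#' @return list with `theta` (length K), `intercepts` (length p, exact
#'   zeros for thresholded variants), `objective`, `iterations`,
#'   `converged`.
#' @export
mvmr_lasso_at_lambda <- function(data, lambda, theta_init = NULL,
                                 tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(data, "summary_dataset"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number", call. = FALSE)
  X <- data$beta_exposure
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  p <- nrow(X)
  K <- ncol(X)
  thresh <- lambda / (2 * w)  # = lambda * se_y^2 / 2

  theta <- if (is.null(theta_init)) wls_fit(X, y, w)$coef else theta_init
  soft <- function(r, t) sign(r) * pmax(abs(r) - t, 0)
  objective <- function(theta, t0) {
    sum(w * (y - t0 - X %*% theta)^2) + lambda * sum(abs(t0))
  }
  # the weighted normal equations have a constant K x K left-hand side
  Xw <- X * w
  A <- crossprod(X, Xw)
  if (qr(A)$rank < K)
    stop("rank-deficient weighted design matrix", call. = FALSE)
  t0 <- soft(as.numeric(y - X %*% theta), thresh)
  f_old <- objective(theta, t0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    theta <- as.numeric(solve(A, crossprod(Xw, y - t0)))
    t0 <- soft(as.numeric(y - X %*% theta), thresh)
    f_new <- objective(theta, t0)
    if (abs(f_old - f_new) <= tol * max(1, abs(f_old))) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  if (!converged)
    stop("coordinate descent did not converge in ", max_iter,
         " iterations at lambda = ", lambda, call. = FALSE)
  list(theta = theta,
       intercepts = stats::setNames(t0, data$variant_ids),
       objective = f_old, iterations = it, converged = converged)
}

# Smallest lambda at which the all-zero intercept vector is optimal: from
# the soft-threshold condition at the IVW residuals, |r_j| <= lambda/(2 w_j)
# for all j.
lambda_max <- function(data) {
  X <- data$beta_exposure
  y <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  r <- as.numeric(y - X %*% wls_fit(X, y, w)$coef)
  max(2 * w * abs(r))
}

#' MVMR-Lasso: heterogeneity-tuned invalid-instrument selection with a
#' post-lasso estimator
#'
#' Runs [mvmr_lasso_at_lambda()] over a descending grid of penalties,
#' treating variants with intercepts shrunk exactly to zero as valid
#' instruments.  The tuning parameter is chosen by a heterogeneity stopping
#' rule: descending from `lambda_max` (where every variant is retained), the
#' selected penalty is the largest one whose valid set has a post-selection
#' IVW heterogeneity Q below the upper 0.05 critical value of chi-squared
#' with `|V| - K` degrees of freedom.  The causal effects are then
#' re-estimated without penalty by MVMR-IVW on the selected valid set
#' (post-lasso), with multiplicative random-effects standard errors.
#'
#' Because the post-selection SEs ignore the selection event they can be
#' anti-conservative; supplying an independent `estimation_data` (three
#' sample mode) performs selection on `data` and estimation on
#' `estimation_data`, restoring nominal type I error.
#'
#' @param data a [summary_dataset()] used for selection (and estimation in
#'   two-sample mode).
#' @param reference exposure index used to orient the variants before
#'   penalization (intercept-based methods are orientation-sensitive).
#' @param lambda_grid optional descending positive grid; defaults to 50
#'   log-spaced values from `lambda_max` down to `lambda_max/1000`.
#' @param alpha_level two-sided significance level for the post-lasso CIs.
#' @param estimation_data optional independent [summary_dataset()] with the
#'   same variants for the post-lasso fit (three-sample mode).
#' @param se_model passed to the post-lasso [mvmr_ivw()].
#' @return list with `fit` (post-lasso [mvmr_fit()]) and `path` (a
#'   `lasso_path` with per-lambda solutions, valid-set sizes and Q
#'   statistics).
#' @export
mvmr_lasso <- function(data, reference = 1, lambda_grid = NULL,
                       alpha_level = 0.05, estimation_data = NULL,
                       se_model = "random") {
  stopifnot(inherits(data, "summary_dataset"))
  data <- orient(data, reference)
  p <- n_variants(data)
  K <- n_exposures(data)
  if (!is.null(estimation_data)) {
    stopifnot(inherits(estimation_data, "summary_dataset"))
    if (!setequal(estimation_data$variant_ids, data$variant_ids))
      stop("estimation_data must contain the same variants as data",
           call. = FALSE)
  }

  if (is.null(lambda_grid)) {
    # start a hair above lambda_max so round-off cannot activate an
    # intercept at the all-valid end of the path
    lmax <- lambda_max(data) * (1 + 1e-6)
    lambda_grid <- exp(seq(log(lmax), log(lmax / 1000), length.out = 50))
  }
  if (any(lambda_grid <= 0))
    stop("lambda_grid must be strictly positive", call. = FALSE)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  L <- length(lambda_grid)

  theta_by_lambda <- matrix(NA_real_, L, K,
                            dimnames = list(NULL, data$exposure_names))
  intercepts_by_lambda <- matrix(NA_real_, L, p,
                                 dimnames = list(NULL, data$variant_ids))
  n_invalid <- integer(L)
  q_valid <- rep(NA_real_, L)
  # an intercept this far below the outcome-association scale is round-off
  # from a degenerate (near-exact-fit) problem, not a pleiotropy signal
  zero_tol <- 1e-8 * max(abs(data$beta_outcome))
  theta_warm <- NULL
  for (i in seq_len(L)) {
    sol <- mvmr_lasso_at_lambda(data, lambda_grid[i],
                                theta_init = theta_warm)
    theta_warm <- sol$theta
    theta_by_lambda[i, ] <- sol$theta
    intercepts_by_lambda[i, ] <- sol$intercepts
    valid <- which(abs(sol$intercepts) <= zero_tol)
    n_invalid[i] <- p - length(valid)
    if (length(valid) > K) {
      ivw_v <- mvmr_ivw(data, subset = valid, se_model = "fixed")
      q_valid[i] <- ivw_v$q_statistic
    }
  }

  # stopping rule: largest lambda whose valid-set Q is below the 0.95
  # chi-squared quantile on |V| - K df
  crit <- stats::qchisq(0.95, pmax(p - n_invalid - K, 1))
  ok <- which(!is.na(q_valid) & q_valid <= crit)
  rule <- "heterogeneity"
  if (length(ok) > 0) {
    sel <- ok[1]
  } else if (any(!is.na(q_valid))) {
    sel <- which.min(q_valid)
    rule <- "min-Q fallback (no grid point met the heterogeneity criterion)"
    warning(rule, call. = FALSE)
  } else {
    stop("valid set had <= K variants at every grid point; supply a ",
         "lambda_grid extending to larger values", call. = FALSE)
  }

  valid_ids <- data$variant_ids[abs(intercepts_by_lambda[sel, ]) <=
                                  zero_tol]
  invalid_ids <- setdiff(data$variant_ids, valid_ids)
  est_data <- if (is.null(estimation_data)) data else
    orient(estimation_data, reference)
  fit <- mvmr_ivw(est_data, subset = valid_ids, se_model = se_model,
                  alpha_level = alpha_level)
  fit$method <- "MVMR-Lasso"
  fit$invalid_set <- invalid_ids
  fit$variant_intercepts <- intercepts_by_lambda[sel, ]
  fit$notes <- c(fit$notes,
                 paste0("lambda=", signif(lambda_grid[sel], 6), "; rule=",
                        rule),
                 if (!is.null(estimation_data)) "three-sample" else
                   "two-sample")

  path <- structure(list(
    lambdas = lambda_grid,
    theta_by_lambda = theta_by_lambda,
    intercepts_by_lambda = intercepts_by_lambda,
    n_invalid_by_lambda = n_invalid,
    q_by_lambda = q_valid,
    q_critical = crit,
    selected_lambda = lambda_grid[sel],
    selected_index = sel,
    rule = rule), class = "lasso_path")
  list(fit = fit, path = path)
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("MVMR-Lasso path over", length(x$lambdas), "penalties; selected",
      "lambda =", signif(x$selected_lambda, 5), "(", x$rule, ")\n")
  cat("invalid variants at selection:",
      x$n_invalid_by_lambda[x$selected_index], "\n")
  invisible(x)
}

#' Serialize a lasso path to TSV
#'
#' One row per grid penalty: lambda, number of invalid variants, valid-set
#' heterogeneity Q, and the penalized estimates.
#'
#' @param path a `lasso_path` from [mvmr_lasso()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_lasso_path_tsv <- function(path, file) {
  out <- data.frame(lambda = path$lambdas,
                    n_invalid = path$n_invalid_by_lambda,
                    q_valid = path$q_by_lambda,
                    selected = seq_along(path$lambdas) == path$selected_index)
  out <- cbind(out, as.data.frame(path$theta_by_lambda))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
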