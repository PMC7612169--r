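#' Configure a benchmarking scenario
#'
#' Full parameterization of the data-generating model used by the
#' simulation harness.  Individual-level data are generated as
#' \deqn{X_{ik} = \sum_j \beta_{Xjk} G_{ij} + \gamma_{Xk} U_i + v_{Xik}}
#' \deqn{Y_i = \sum_k \theta_k X_{ik} + \sum_j \alpha_j G_{ij} +
#'       \gamma_Y U_i + v_{Yi}}
#' with confounder \eqn{U_i = \sum_j \delta_j G_{ij} + w_i}, genotypes
#' `Binomial(2, 0.3)`, true variant-exposure effects `Uniform(0,
#' beta_x_upper)` and standard-normal error terms.  A chosen proportion of
#' variants is invalid; their direct effects `alpha_j` (and, when InSIDE is
#' violated, confounder effects `delta_j`) are drawn per scenario:
#'
#' * Scenario 1 — balanced pleiotropy, InSIDE met: `alpha ~ N(0, 0.2^2)`,
#'   `delta = 0`.
#' * Scenario 2 — directional pleiotropy, InSIDE met:
#'   `alpha ~ N(0.1, 0.2^2)`, `delta = 0`.
#' * Scenario 3 — directional pleiotropy, InSIDE violated:
#'   `alpha ~ N(0, 0.2^2)`, `delta ~ U(0, 0.1)`.
#' * Scenario 4 — balanced pleiotropy, InSIDE violated:
#'   `alpha ~ N(0, 0.2^2)`, `delta ~ U(-0.05, 0.05)`.
#'
#' The defaults (`p = 100`, `K = 4`, `n = 20000`, `gamma_x = 1/K`,
#' `gamma_y = 1`) give the genetic variants an expected coefficient of
#' determination of roughly 12% for each exposure.  With fewer variants,
#' `beta_x_upper` defaults to `0.1 * sqrt(100/p)` so the total genetically
#' explained variance is preserved.
#'
#' @param scenario integer 1-4.
#' @param prop_invalid proportion of invalid variants; `prop_invalid * p`
#'   must be an integer (the benchmark grid uses 0.1, 0.3, 0.5, 0.7).
#' @param theta length-K true causal effects, or `"A"` for
#'   `(0.2, 0.1, 0.3, 0.4)` / `"B"` for `(0, -0.1, 0.1, 0.2)`.
#' @param p,K,n number of variants, exposures, individuals per cohort.
#' @param beta_x_upper upper bound of the uniform variant-exposure effects.
#' @param maf allele frequency of the `Binomial(2, maf)` genotypes.
#' @param gamma_x,gamma_y confounder effects on each exposure and on the
#'   outcome.
#' @param exposure_error_corr common correlation of the exposure error terms
#'   `v_Xik` across exposures (0 default, 0.5 for the correlated-risk-factor
#'   variant).
#' @param design `"two"` (default; exposure and outcome associations from
#'   independent cohorts), `"one"` (single shared cohort) or `"three"`
#'   (additional independent cohort used for MVMR-Lasso selection).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = 1, prop_invalid = 0.1, theta = "A",
                            p = 100, K = 4, n = 20000,
                            beta_x_upper = 0.1 * sqrt(100 / p), maf = 0.3,
                            gamma_x = 1 / K, gamma_y = 1,
                            exposure_error_corr = 0,
                            design = c("two", "one", "three")) {
  design <- match.arg(design)
  if (!scenario %in% 1:4)
    stop("scenario must be 1, 2, 3 or 4", call. = FALSE)
  if (is.character(theta))
    theta <- switch(match.arg(theta, c("A", "B")),
                    A = c(0.2, 0.1, 0.3, 0.4),
                    B = c(0, -0.1, 0.1, 0.2))
  if (length(theta) != K)
    stop("theta must have length K = ", K, call. = FALSE)
  n_invalid <- prop_invalid * p
  if (abs(n_invalid - round(n_invalid)) > 1e-8)
    stop("prop_invalid * p must be an integer (got ", n_invalid, ")",
         call. = FALSE)
  if (prop_invalid < 0 || prop_invalid >= 1)
    stop("prop_invalid must be in [0, 1)", call. = FALSE)
  if (exposure_error_corr < 0 || exposure_error_corr >= 1)
    stop("exposure_error_corr must be in [0, 1)", call. = FALSE)
  structure(list(
    scenario = as.integer(scenario), prop_invalid = prop_invalid,
    theta = theta, p = as.integer(p), K = as.integer(K), n = as.integer(n),
    beta_x_upper = beta_x_upper, maf = maf,
    gamma_x = gamma_x, gamma_y = gamma_y,
    alpha_mean = if (scenario == 2) 0.1 else 0, alpha_sd = 0.2,
    delta_range = switch(scenario, NULL, NULL, c(0, 0.1), c(-0.05, 0.05)),
    exposure_error_corr = exposure_error_corr,
    design = design), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  lab <- c("balanced pleiotropy, InSIDE met",
           "directional pleiotropy, InSIDE met",
           "directional pleiotropy, InSIDE violated",
           "balanced pleiotropy, InSIDE violated")[x$scenario]
  cat("Scenario", x$scenario, paste0("(", lab, ")"), "\n")
  cat(sprintf("  p = %d variants (%.0f%% invalid), K = %d exposures, n = %d, %s-sample\n",
              x$p, 100 * x$prop_invalid, x$K, x$n, x$design))
  cat("  theta =", paste(x$theta, collapse = ", "), "\n")
  invisible(x)
}

# One replication's true parameters: variant-exposure effects, the invalid
# subset, and its pleiotropy (alpha) and confounder (delta) effects.  All
# are redrawn each replication.
draw_parameters <- function(config) {
  p <- config$p
  K <- config$K
  beta_x <- matrix(stats::runif(p * K, 0, config$beta_x_upper), p, K)
  n_invalid <- round(config$prop_invalid * p)
  invalid <- sort(sample.int(p, n_invalid))
  alpha <- numeric(p)
  delta <- numeric(p)
  if (n_invalid > 0) {
    alpha[invalid] <- stats::rnorm(n_invalid, config$alpha_mean,
                                   config$alpha_sd)
    if (!is.null(config$delta_range))
      delta[invalid] <- stats::runif(n_invalid, config$delta_range[1],
                                     config$delta_range[2])
  }
  list(beta_x = beta_x, alpha = alpha, delta = delta, invalid = invalid)
}

#' Simulate one individual-level cohort
#'
#' Draws genotypes, exposures and outcome for `config$n` individuals under
#' the data-generating model of [scenario_config()], given one
#' replication's true parameters.
#'
#' @param config a [scenario_config()].
#' @param params a parameter draw as produced internally (list with
#'   `beta_x`, `alpha`, `delta`, `invalid`); drawn fresh if `NULL`.
#' @return list with `G` (n x p genotype matrix), `X` (n x K exposures),
#'   `Y` (length-n outcome) and `params`.
#' @export
simulate_cohort <- function(config, params = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(params)) params <- draw_parameters(config)
  n <- config$n
  p <- config$p
  K <- config$K
  G <- .rbinom2_matrix(n, p, config$maf)
  U <- as.numeric(G %*% params$delta) + stats::rnorm(n)
  vX <- matrix(stats::rnorm(n * K), n, K)
  rho <- config$exposure_error_corr
  if (rho > 0) {
    R <- matrix(rho, K, K)
    diag(R) <- 1
    vX <- vX %*% chol(R)
  }
  X <- G %*% params$beta_x + config$gamma_x * U + vX
  Y <- as.numeric(X %*% config$theta + G %*% params$alpha +
                    config$gamma_y * U + stats::rnorm(n))
  list(G = G, X = X, Y = Y, params = params)
}

#' Reduce a cohort to per-variant summary statistics
#'
#' For each variant and each trait column, the slope and standard error of
#' the simple linear regression (with intercept) of the trait on the
#' variant's genotype, computed in closed form for all variants at once.
#'
#' @param G n x p genotype matrix.
#' @param traits n x T matrix (or vector) of trait values.
#' @return list with `beta` (p x T slopes) and `se` (p x T standard
#'   errors).
#' @export
summarize_cohort <- function(G, traits) {
  traits <- as.matrix(traits)
  n <- nrow(G)
  stopifnot(nrow(traits) == n, n > 2)
  # centered cross-products without materializing centered copies
  gm <- colMeans(G)
  tm <- colMeans(traits)
  Sxx <- colSums(G * G) - n * gm^2
  mono <- which(Sxx <= 0)
  if (length(mono) > 0)
    stop("monomorphic variant(s): ",
         paste(utils::head(mono, 5), collapse = ", "), call. = FALSE)
  Syy <- colSums(traits * traits) - n * tm^2
  Sxy <- crossprod(G, traits) - n * outer(gm, tm)   # p x T
  beta <- Sxy / Sxx
  rss <- outer(rep(1, length(Sxx)), Syy) - Sxy^2 / Sxx
  rss <- pmax(rss, 0)                        # guard tiny negative round-off
  se <- sqrt(rss / ((n - 2) * Sxx))
  if (any(se == 0))
    warning("zero standard error for some variant-trait pair ",
            "(degenerate, perfectly fitted trait)", call. = FALSE)
  list(beta = beta, se = se)
}

# Build the summary_dataset(s) for one replication under the configured
# sampling design.  Returns list(data = ..., selection = NULL or dataset).
simulate_summary_data <- function(config, params = NULL) {
  if (is.null(params)) params <- draw_parameters(config)
  ids <- paste0("rs", seq_len(config$p))
  make_ds <- function(exp_cohort, out_cohort) {
    ex <- summarize_cohort(exp_cohort$G, exp_cohort$X)
    out <- summarize_cohort(out_cohort$G, out_cohort$Y)
    summary_dataset(ids, ex$beta, ex$se, out$beta[, 1], out$se[, 1])
  }
  if (config$design == "one") {
    c1 <- simulate_cohort(config, params)
    data <- make_ds(c1, c1)
    selection <- NULL
  } else {
    c1 <- simulate_cohort(config, params)
    c2 <- simulate_cohort(config, params)
    data <- make_ds(c1, c2)
    selection <- if (config$design == "three") {
      c3 <- simulate_cohort(config, params)
      make_ds(c3, c3)
    } else NULL
  }
  list(data = data, selection = selection, params = params)
}

# Per-method aggregation of replication results; kept separate from
# run_study so the arithmetic can be checked directly against hand-computed
# values.
aggregate_metrics <- function(est, se, reject, theta_hat_full, theta_true,
                              target_exposure) {
  truth <- theta_true[target_exposure]
  err_full <- sweep(theta_hat_full, 2, theta_true)
  mse <- mean((est - truth)^2)
  data.frame(
    mean = mean(est),
    sd_estimates = stats::sd(est),
    mean_se = mean(se),
    rejection_rate = mean(reject),
    mse = mse,
    log_mse = log(mse),
    full_vector_mse = mean(rowSums(err_full^2)),
    n_reps = length(est))
}

#' Run a Monte-Carlo benchmarking study
#'
#' Replicates the full pipeline — draw true parameters, simulate cohorts
#' per the sampling design, reduce to summary statistics, fit each
#' requested estimator — and aggregates per-method estimation and inference
#' metrics for a target exposure: mean and SD of estimates, mean standard
#' error, rejection rate of `H0: theta_target = 0` at `alpha_level`
#' (power under a non-zero truth, type I error under a zero truth), MSE,
#' log MSE, and full-vector MSE.
#'
#' @param config a [scenario_config()].
#' @param methods subset of `"ivw"`, `"egger"`, `"presso"`, `"robust"`,
#'   `"median"`, `"lasso"`.
#' @param n_reps number of replications.
#' @param seed integer seed; every replication derives an independent
#'   sub-seed from it.
#' @param target_exposure exposure whose effect is reported on.
#' @param alpha_level two-sided test level.
#' @param n_boot parametric bootstrap draws for MVMR-Median.
#' @param n_sim_presso parametric replicates for MR-PRESSO.
#' @param reference orientation reference for Egger and lasso.
#' @param keep_estimates if `TRUE`, attach the per-replication estimates
#'   and SEs for audit.
#' @return a `replication_metrics` object: a data.frame with one row per
#'   method plus attributes `config`, `seed`, `n_failures`.
#' @export
run_study <- function(config, methods = c("ivw", "egger", "presso",
                                          "robust", "median", "lasso"),
                      n_reps = 1000, seed = 1, target_exposure = 1,
                      alpha_level = 0.05, n_boot = 1000,
                      n_sim_presso = 1000, reference = 1,
                      keep_estimates = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 1)
  methods <- match.arg(methods, c("ivw", "egger", "presso", "robust",
                                  "median", "lasso"), several.ok = TRUE)
  K <- config$K
  z <- stats::qnorm(1 - alpha_level / 2)
  seeds <- derive_seeds(seed, n_reps)

  est <- se <- array(NA_real_, c(n_reps, length(methods)),
                     dimnames = list(NULL, methods))
  full <- array(NA_real_, c(n_reps, K, length(methods)),
                dimnames = list(NULL, NULL, methods))
  failures <- stats::setNames(vector("list", length(methods)), methods)

  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    sim <- simulate_summary_data(config)
    for (m in methods) {
      fit <- tryCatch(suppressWarnings(switch(
        m,
        ivw = mvmr_ivw(sim$data, alpha_level = alpha_level),
        egger = mvmr_egger(sim$data, reference = reference,
                           alpha_level = alpha_level),
        presso = mvmr_presso(sim$data, n_sim = n_sim_presso,
                             alpha_level = alpha_level)$fit,
        robust = mvmr_robust(sim$data, alpha_level = alpha_level),
        median = mvmr_median(sim$data, n_boot = n_boot,
                             alpha_level = alpha_level),
        lasso = mvmr_lasso(sim$data, reference = reference,
                           alpha_level = alpha_level,
                           estimation_data = sim$selection)$fit)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[m]] <- c(failures[[m]],
                           stats::setNames(conditionMessage(fit), i))
        next
      }
      est[i, m] <- fit$theta[target_exposure]
      se[i, m] <- fit$se[target_exposure]
      full[i, , m] <- fit$theta
    }
  }

  n_fail <- vapply(failures, length, integer(1))
  if (any(n_fail > 0.01 * n_reps)) {
    bad <- names(n_fail)[n_fail > 0.01 * n_reps]
    stop("method(s) ", paste(bad, collapse = ", "), " failed on more than ",
         "1% of replications; first messages: ",
         paste(vapply(failures[bad], `[`, "", 1), collapse = " | "),
         call. = FALSE)
  }

  rows <- lapply(methods, function(m) {
    ok <- !is.na(est[, m])
    cbind(method = method_label(m),
          aggregate_metrics(est[ok, m], se[ok, m],
                            abs(est[ok, m] / se[ok, m]) > z,
                            matrix(full[ok, , m], ncol = K),
                            config$theta, target_exposure))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  attr(out, "target_exposure") <- target_exposure
  attr(out, "n_failures") <- n_fail
  if (keep_estimates) {
    attr(out, "estimates") <- est
    attr(out, "ses") <- se
  }
  class(out) <- c("replication_metrics", "data.frame")
  out
}

method_label <- function(m) {
  c(ivw = "MVMR-IVW", egger = "MVMR-Egger", presso = "MVMR-PRESSO",
    robust = "MVMR-Robust", median = "MVMR-Median",
    lasso = "MVMR-Lasso")[[m]]
}

#' @export
print.replication_metrics <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    print(cfg)
    cat(x$n_reps[1], "replications; rejection rate is",
        if (cfg$theta[attr(x, "target_exposure")] != 0) "power"
        else "type I error", "\n")
  }
  print.data.frame(cbind(x[, "method", drop = FALSE],
                         round(x[, -1], digits)), row.names = FALSE)
  invisible(x)
}

#' Invalid-instrument selection accuracy of MVMR-Lasso
#'
#' Over replications, compares the variants MVMR-Lasso flags as invalid
#' with the truly planted invalid set and reports mean true/false positive
#' and negative rates.
#'
#' @inheritParams run_study
#' @return data.frame with one row of mean rates: `sensitivity` (truly
#'   invalid flagged), `specificity` (truly valid kept),
#'   `false_positive_rate`, `false_negative_rate`, `precision` (flagged
#'   variants that are truly invalid; averaged over replications that flag
#'   at least one variant), plus counts.
#' @export
selection_accuracy <- function(config, n_reps = 100, seed = 1,
                               reference = 1) {
  stopifnot(inherits(config, "scenario_config"))
  seeds <- derive_seeds(seed, n_reps)
  sens <- spec <- prec <- rep(NA_real_, n_reps)
  n_flag <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seeds[i])
    sim <- simulate_summary_data(config)
    res <- suppressWarnings(
      mvmr_lasso(sim$data, reference = reference,
                 estimation_data = sim$selection))
    flagged <- match(res$fit$invalid_set, sim$data$variant_ids)
    truth <- sim$params$invalid
    n_flag[i] <- length(flagged)
    tp <- length(intersect(flagged, truth))
    fp <- length(setdiff(flagged, truth))
    if (length(truth) > 0) sens[i] <- tp / length(truth)
    spec[i] <- 1 - fp / (config$p - length(truth))
    if (length(flagged) > 0) prec[i] <- tp / length(flagged)
  }
  data.frame(
    sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec),
    false_positive_rate = 1 - mean(spec),
    false_negative_rate = 1 - mean(sens, na.rm = TRUE),
    precision = if (all(is.na(prec))) NA_real_ else mean(prec, na.rm = TRUE),
    mean_n_flagged = mean(n_flag),
    n_reps = n_reps)
}
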