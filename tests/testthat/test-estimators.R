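test_that("IVW equals the ratio estimate in the univariable consistent case", {
  # two variants implying the same ratio 0.5/0.25 = 2 (the p > K invariant
  # forbids a literal single-variant dataset)
  d <- summary_dataset(c("a", "b"), matrix(c(0.25, 0.5), 2, 1),
                       matrix(0.01, 2, 1), c(0.5, 1.0), c(1, 1))
  expect_equal(unname(mvmr_ivw(d)$theta), 2.0, tolerance = 1e-12)
})

test_that("IVW and Egger match explicit normal-equation oracles to 1e-10", {
  for (seed in 1:5) {
    K <- sample(1:3, 1)
    d <- make_dataset(p = 5 + K, K = K, seed = seed)
    w <- 1 / d$se_outcome^2
    f <- mvmr_ivw(d)
    expect_equal(unname(f$theta),
                 wls_oracle(d$beta_exposure, d$beta_outcome, w),
                 tolerance = 1e-10)
    fe <- mvmr_egger(d, reference = 1)
    oe <- wls_oracle(cbind(1, d$beta_exposure), d$beta_outcome, w)
    expect_equal(unname(c(fe$intercept, fe$theta)), oe, tolerance = 1e-10)
  }
})

test_that("random-effects SEs scale the fixed-effect SEs by max(1, sqrt(Q/df))", {
  d <- make_dataset(p = 25, K = 2, noise = 0.05, seed = 11)
  ff <- mvmr_ivw(d, se_model = "fixed")
  fr <- mvmr_ivw(d, se_model = "random")
  scale <- max(1, sqrt(ff$q_statistic / ff$q_df))
  expect_equal(fr$se, ff$se * scale, tolerance = 1e-12)
  expect_true(all(fr$ci_lower <= fr$theta & fr$theta <= fr$ci_upper))
})

test_that("Egger recovers an exactly planted pleiotropy intercept", {
  d <- make_exact_dataset(p = 12, K = 3, theta = c(0.2, -0.1, 0.4))
  d$beta_outcome <- d$beta_outcome + 0.3
  f <- mvmr_egger(d, reference = 1)
  expect_equal(f$intercept, 0.3, tolerance = 1e-10)
  expect_equal(unname(f$theta), c(0.2, -0.1, 0.4), tolerance = 1e-10)
  # no residual degrees of freedom
  d4 <- make_dataset(p = 4, K = 3, seed = 1)
  expect_error(mvmr_egger(d4, 1), "p > K \\+ 1")
})

test_that("IVW equals Egger with the intercept constrained to zero", {
  d <- make_dataset(p = 15, K = 2, noise = 0.03, seed = 12)
  # refit the Egger design without its intercept column: that is IVW
  f_ivw <- mvmr_ivw(d)
  o <- orient(d, 1)
  coef_no_int <- wls_oracle(o$beta_exposure, o$beta_outcome,
                            1 / o$se_outcome^2)
  expect_equal(unname(f_ivw$theta), coef_no_int, tolerance = 1e-10)
})

test_that("MR-PRESSO is exact IVW on clean data and flags planted outliers", {
  d <- make_dataset(p = 30, K = 2, noise = 0, seed = 13)
  res <- suppressWarnings(mvmr_presso(d, n_sim = 300, seed = 1))
  expect_length(res$fit$invalid_set, 0)
  expect_equal(res$fit$theta, mvmr_ivw(d)$theta, tolerance = 1e-12)
  expect_equal(res$fit$n_variants_used, 30L)
  expect_true(all(res$report$variant_p >= 1 / 300))

  # planted gross outlier (alpha = 1.0) recovered across seeds
  hits <- 0L
  for (s in 1:20) {
    alpha <- numeric(30)
    alpha[7] <- 1.0
    dp <- make_dataset(p = 30, K = 2, alpha = alpha, seed = 100 + s)
    r <- suppressWarnings(mvmr_presso(dp, n_sim = 300, seed = s))
    hits <- hits + ("rs7" %in% r$fit$invalid_set)
  }
  expect_gte(hits, 15L)
})

test_that("MR-PRESSO validates inputs and reports structure", {
  d <- make_dataset(p = 10, K = 2, seed = 14)
  expect_error(mvmr_presso(d, n_sim = 50), "at least 100")
  res <- suppressWarnings(mvmr_presso(d, n_sim = 200, seed = 2))
  expect_s3_class(res$report, "presso_report")
  expect_length(res$report$variant_p, 10)
  expect_true(res$report$global_p >= 0 && res$report$global_p <= 1)
  expect_equal(res$fit$n_variants_used,
               10L - length(res$fit$invalid_set))
})

test_that("MVMR-Robust recovers exact data and resists a gross outlier", {
  theta <- c(0.2, -0.1, 0.4)
  d <- make_exact_dataset(p = 12, K = 3, theta = theta)
  f <- mvmr_robust(d)
  expect_equal(unname(f$theta), theta, tolerance = 1e-8)

  alpha <- numeric(30)
  alpha[11] <- 1.0
  dp <- make_dataset(p = 30, K = 2, alpha = alpha, seed = 15)
  set.seed(21)
  fr <- mvmr_robust(dp)
  f_clean <- mvmr_ivw(dp, subset = setdiff(dp$variant_ids, "rs11"))
  expect_true(all(abs(fr$theta - f_clean$theta) <
                    2 * pmax(fr$se, f_clean$se)))
})

test_that("MVMR-Median solves the weighted LAD problem exactly", {
  theta <- c(0.25, -0.15)
  d <- make_exact_dataset(p = 10, K = 2, theta = theta)
  f <- mvmr_median(d, n_boot = 100, seed = 1)
  expect_equal(unname(f$theta), theta, tolerance = 1e-10)
  expect_equal(f$lad_objective, 0, tolerance = 1e-10)

  # p = 6, K = 2: objective matches the exhaustive vertex oracle to 1e-6
  for (seed in 1:10) {
    d2 <- make_dataset(p = 6, K = 2, noise = 0.05, seed = 300 + seed)
    f2 <- mvmr_median(d2, n_boot = 100, seed = seed)
    orc <- lad_oracle(d2$beta_exposure, d2$beta_outcome,
                      1 / d2$se_outcome^2)
    expect_equal(f2$lad_objective, orc$objective, tolerance = 1e-6)
  }
})

test_that("univariable MVMR-Median equals the weighted-median estimator", {
  for (seed in 1:10) {
    d <- make_dataset(p = 15, K = 1, noise = 0.05, seed = 400 + seed)
    f <- mvmr_median(d, n_boot = 100, seed = seed)
    wm <- weighted_median_oracle(d$beta_exposure[, 1], d$beta_outcome,
                                 d$se_outcome)
    expect_equal(unname(f$theta), wm, tolerance = 1e-8)
  }
})

test_that("median LAD objective at its solution is below the IVW solution's", {
  for (seed in 1:5) {
    d <- make_dataset(p = 20, K = 2, noise = 0.05, seed = 500 + seed)
    w <- 1 / d$se_outcome^2
    obj <- function(th) sum(w * abs(d$beta_outcome -
                                      d$beta_exposure %*% th))
    f_med <- mvmr_median(d, n_boot = 100, seed = seed)
    f_ivw <- mvmr_ivw(d)
    expect_lte(obj(f_med$theta), obj(f_ivw$theta) + 1e-10)
  }
})

test_that("median percentile CIs come from the bootstrap quantiles", {
  d <- make_dataset(p = 15, K = 2, noise = 0.03, seed = 16)
  fn <- mvmr_median(d, n_boot = 200, seed = 3, ci_type = "normal")
  fp <- mvmr_median(d, n_boot = 200, seed = 3, ci_type = "percentile")
  expect_equal(fn$theta, fp$theta)
  expect_false(isTRUE(all.equal(fn$ci_lower, fp$ci_lower)))
  expect_true(all(fp$ci_lower < fp$ci_upper))
})

test_that("all estimators are equivariant to variant relabeling", {
  d <- make_dataset(p = 24, K = 2, noise = 0.02, seed = 17)
  set.seed(18)
  perm <- sample(24)
  dp <- d[perm]
  expect_equal(mvmr_ivw(dp)$theta, mvmr_ivw(d)$theta, tolerance = 1e-10)
  expect_equal(mvmr_egger(dp, 1)$theta, mvmr_egger(d, 1)$theta,
               tolerance = 1e-10)
  expect_equal(mvmr_robust(dp)$theta, mvmr_robust(d)$theta,
               tolerance = 1e-6)
  expect_equal(mvmr_median(dp, n_boot = 100, seed = 1)$theta,
               mvmr_median(d, n_boot = 100, seed = 1)$theta,
               tolerance = 1e-8)
})

test_that("IVW and median are invariant to variant orientation", {
  d <- make_dataset(p = 20, K = 2, noise = 0.04, seed = 19)
  d$beta_exposure[1:9, 1] <- -d$beta_exposure[1:9, 1]
  o <- orient(d, 1)
  expect_equal(mvmr_ivw(o)$theta, mvmr_ivw(d)$theta, tolerance = 1e-12)
  expect_equal(mvmr_median(o, n_boot = 100, seed = 2)$theta,
               mvmr_median(d, n_boot = 100, seed = 2)$theta,
               tolerance = 1e-8)
})

test_that("every estimator recovers theta exactly as noise vanishes", {
  theta <- c(0.2, 0.35)
  d <- make_exact_dataset(p = 20, K = 2, theta = theta, seed = 20)
  tol <- 1e-7
  expect_equal(unname(mvmr_ivw(d)$theta), theta, tolerance = tol)
  expect_equal(unname(mvmr_egger(d, 1)$theta), theta, tolerance = tol)
  expect_equal(unname(mvmr_robust(d)$theta), theta, tolerance = tol)
  expect_equal(unname(mvmr_median(d, n_boot = 100, seed = 1)$theta),
               theta, tolerance = tol)
  pres <- suppressWarnings(mvmr_presso(d, n_sim = 200, seed = 1))
  expect_equal(unname(pres$fit$theta), theta, tolerance = tol)
  las <- mvmr_lasso(d, 1)
  expect_equal(unname(las$fit$theta), theta, tolerance = tol)
})
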