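# Small configs keep these tests fast; the acceptance suite exercises the
# full-size data-generating model.
small_config <- function(..., n = 1500, p = 20) {
  scenario_config(n = n, p = p, ...)
}

test_that("scenario configuration validates its inputs", {
  cfg <- scenario_config(2, 0.3, "A")
  expect_equal(cfg$alpha_mean, 0.1)
  expect_null(cfg$delta_range)
  expect_equal(scenario_config(3, 0.1, "B")$delta_range, c(0, 0.1))
  expect_equal(scenario_config(4, 0.1, "B")$delta_range, c(-0.05, 0.05))
  expect_equal(scenario_config(1, 0.1, "B")$theta, c(0, -0.1, 0.1, 0.2))
  expect_error(scenario_config(5), "scenario")
  expect_error(scenario_config(1, 0.123), "integer")
  expect_error(scenario_config(1, 0.1, theta = c(1, 2)), "length K")
  # fewer-instruments variant preserves total genetic variance
  expect_equal(scenario_config(1, 0.1, "A", p = 20)$beta_x_upper,
               0.1 * sqrt(5))
})

test_that("cohort simulation is deterministic and structurally sound", {
  cfg <- small_config(scenario = 1, prop_invalid = 0.1, theta = "A")
  set.seed(42)
  c1 <- simulate_cohort(cfg)
  set.seed(42)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$G, c2$G)
  expect_identical(c1$Y, c2$Y)
  expect_equal(dim(c1$G), c(1500L, 20L))
  expect_equal(dim(c1$X), c(1500L, 4L))
  expect_true(all(c1$G %in% 0:2))
  expect_length(c1$params$invalid, 2L)
  expect_true(all(c1$params$alpha[-c1$params$invalid] == 0))

  # under the global null with no pleiotropy, variants do not associate
  # with the outcome
  cfg0 <- small_config(scenario = 1, prop_invalid = 0,
                       theta = c(0, 0, 0, 0))
  set.seed(43)
  c0 <- simulate_cohort(cfg0)
  expect_lt(max(abs(cor(c0$G, c0$Y))), 4 / sqrt(1500) + 0.02)
})

test_that("summarize_cohort matches per-variant OLS oracles", {
  # 5-individual instance worked against the textbook formulas
  g <- c(0, 1, 2, 1, 0)
  y <- c(1.0, 2.1, 2.9, 1.8, 1.2)
  fit <- lm(y ~ g)
  s <- summarize_cohort(matrix(g, 5, 1), y)
  expect_equal(s$beta[1, 1], unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(s$se[1, 1], unname(summary(fit)$coefficients[2, 2]),
               tolerance = 1e-12)

  # full-size agreement with lm() per variant and trait
  set.seed(44)
  G <- mvmrtools:::.rbinom2_matrix(60, 4, 0.3)
  traits <- cbind(rnorm(60), rnorm(60, G[, 2] * 0.5))
  s2 <- summarize_cohort(G, traits)
  for (j in 1:4) for (t in 1:2) {
    f <- lm(traits[, t] ~ G[, j])
    expect_equal(s2$beta[j, t], unname(coef(f)[2]), tolerance = 1e-10)
    expect_equal(s2$se[j, t], unname(summary(f)$coefficients[2, 2]),
                 tolerance = 1e-10)
  }

  # degenerate perfectly-explained trait is flagged
  expect_warning(s3 <- summarize_cohort(matrix(g, 5, 1), 2 * g),
                 "zero standard error")
  expect_equal(s3$beta[1, 1], 2, tolerance = 1e-12)

  # monomorphic variant is rejected by name
  Gm <- cbind(G[, 1:2], 0)
  expect_error(summarize_cohort(Gm, traits[, 1]), "monomorphic")
})

test_that("metric aggregation matches hand-computed values", {
  est <- c(0.1, 0.3, 0.2, 0.4)
  se <- c(0.05, 0.2, 0.08, 0.1)
  reject <- abs(est / se) > qnorm(0.975)
  full <- cbind(est, c(0, 0.1, 0.2, 0.3))
  m <- mvmrtools:::aggregate_metrics(est, se, reject, full,
                                     theta_true = c(0.25, 0.1),
                                     target_exposure = 1)
  expect_equal(m$mean, 0.25)
  expect_equal(m$sd_estimates, sd(est))
  expect_equal(m$mean_se, mean(se))
  expect_equal(m$rejection_rate, 0.75)  # t-ratios 2, 1.5, 2.5, 4
  expect_equal(m$mse, mean((est - 0.25)^2))
  expect_equal(m$log_mse, log(m$mse))
  expect_equal(m$full_vector_mse,
               mean((est - 0.25)^2 + (full[, 2] - 0.1)^2))
  # mse reconciles with bias^2 + variance (population form)
  expect_equal(m$mse, (m$mean - 0.25)^2 +
                 mean((est - mean(est))^2), tolerance = 1e-12)
})

test_that("run_study is reproducible and honours its design settings", {
  cfg <- small_config(scenario = 1, prop_invalid = 0.1, theta = "A")
  m1 <- run_study(cfg, c("ivw", "median"), n_reps = 4, seed = 9,
                  n_boot = 100)
  m2 <- run_study(cfg, c("ivw", "median"), n_reps = 4, seed = 9,
                  n_boot = 100)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  expect_equal(m1$method, c("MVMR-IVW", "MVMR-Median"))
  expect_equal(m1$n_reps, c(4L, 4L))
  expect_true(all(m1$rejection_rate >= 0 & m1$rejection_rate <= 1))

  m3 <- run_study(cfg, c("ivw", "median"), n_reps = 4, seed = 10,
                  n_boot = 100)
  expect_false(isTRUE(all.equal(m1$mean, m3$mean)))

  # one-sample and three-sample designs run end to end
  cfg1 <- small_config(scenario = 1, prop_invalid = 0.1, theta = "A",
                       design = "one")
  expect_s3_class(run_study(cfg1, "ivw", n_reps = 2, seed = 1),
                  "replication_metrics")
  cfg3 <- small_config(scenario = 1, prop_invalid = 0.1, theta = "A",
                       design = "three")
  expect_s3_class(suppressWarnings(
    run_study(cfg3, "lasso", n_reps = 2, seed = 1)),
    "replication_metrics")
})

test_that("selection accuracy reports planted-set recovery", {
  cfg <- small_config(scenario = 2, prop_invalid = 0.2, theta = "A",
                      n = 4000)
  acc <- suppressWarnings(selection_accuracy(cfg, n_reps = 5, seed = 3))
  expect_true(acc$sensitivity >= 0 && acc$sensitivity <= 1)
  expect_equal(acc$false_positive_rate, 1 - acc$specificity)
  expect_equal(acc$n_reps, 5)
})

test_that("derived sub-seeds are deterministic and 32-bit safe", {
  s1 <- mvmrtools:::derive_seeds(7, 10)
  s2 <- mvmrtools:::derive_seeds(7, 10)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_false(any(duplicated(s1)))
})
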