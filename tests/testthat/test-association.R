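test_that("derived volumes follow the subtraction and averaging rules", {
  df <- data.frame(wmh_volume_baseline = c(16.56, 5, 2),
                   wmh_volume_followup = c(22.32, 5, NA),
                   icv_baseline = c(1400, 1500, 1450),
                   icv_followup = c(1420, 1500, 1450))
  out <- derive_volumes(df)
  expect_equal(out$delta_wmh, c(5.76, 0, NA))
  expect_equal(out$icv_mean, c(1410, 1500, 1450))
})

test_that("predictor transforms: log-scale, z-score, inversion", {
  set.seed(10)
  df <- data.frame(solidity = runif(200, 0.05, 0.6),
                   convexity = rnorm(200, 1, 0.2),
                   wmh_volume_baseline = rlnorm(200, 2.4, 0.8))
  out <- transform_predictors(df, c("solidity", "convexity",
                                    "wmh_volume_baseline"))
  # solidity 0.19 -> ln(19) before z-scoring
  expect_equal(log(100 * 0.19), 2.944439, tolerance = 1e-6)
  lg <- log(100 * df$solidity)
  expect_equal(out$z_solidity, (lg - mean(lg)) / sd(lg), tolerance = 1e-12)
  for (col in c("z_solidity", "z_convexity", "z_wmh_volume_baseline")) {
    expect_lt(abs(mean(out[[col]])), 1e-12)
    expect_equal(sd(out[[col]]), 1, tolerance = 1e-12)
  }
  # inversion flips the listed markers only
  inv <- transform_predictors(df, c("solidity", "convexity",
                                    "wmh_volume_baseline"), invert = TRUE)
  expect_equal(inv$z_solidity, -out$z_solidity)
  expect_equal(inv$z_convexity, -out$z_convexity)
  expect_equal(inv$z_wmh_volume_baseline, out$z_wmh_volume_baseline)

  expect_error(transform_predictors(data.frame(solidity = c(-0.1, 0.5)),
                                    "solidity"), "log")
  expect_error(transform_predictors(data.frame(convexity = rep(1, 5)),
                                    "convexity"), "variance")
})

test_that("OLS matches the closed-form normal-equation oracle", {
  set.seed(77)
  n <- 30
  df <- data.frame(age = rnorm(n, 74, 5), sex = rbinom(n, 1, 0.5),
                   icv_mean = rnorm(n, 1500, 100),
                   z_marker = rnorm(n))
  df$delta_wmh <- 5 + 2 * df$z_marker + 0.1 * df$age + rnorm(n, 0, 3)
  fit <- fit_linear(df, "marker")

  X <- cbind(1, df$z_marker, df$age, df$sex, df$icv_mean)
  beta <- solve(t(X) %*% X, t(X) %*% df$delta_wmh)
  res <- df$delta_wmh - X %*% beta
  s2 <- sum(res^2) / (n - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$estimate, beta[2], tolerance = 1e-10)
  expect_equal(fit$ci_low, beta[2] - qt(0.975, n - 5) * se, tolerance = 1e-10)
  expect_equal(fit$ci_high, beta[2] + qt(0.975, n - 5) * se, tolerance = 1e-10)
  expect_equal(fit$n_used, n)
  expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
})

test_that("logistic fit reproduces the 2x2 cross-product odds ratio", {
  # binary predictor, no covariates: the MLE odds ratio is the
  # contingency-table cross-product ratio
  df <- data.frame(z_x = rep(c(0, 1), times = c(60, 40)),
                   y_new = c(rep(c(0, 1), times = c(45, 15)),
                             rep(c(0, 1), times = c(18, 22))))
  fit <- fit_logistic(df, "x", "y_new", covariates = character(0),
                      at_risk_only = FALSE)
  expect_equal(fit$estimate, (22 * 45) / (18 * 15), tolerance = 1e-6)
  expect_equal(fit$model, "logistic")
})

test_that("sign-flipped predictors give exactly reciprocal odds ratios", {
  cfg <- cohort_config(n = 1500)
  co <- derive_volumes(simulate_cohort(cfg, seed = 5))
  plus <- transform_predictors(co, "convexity", invert = FALSE)
  minus <- transform_predictors(co, "convexity", invert = TRUE)
  f1 <- fit_logistic(plus, "convexity", "microbleed_new")
  f2 <- fit_logistic(minus, "convexity", "microbleed_new")
  expect_equal(f2$estimate, 1 / f1$estimate, tolerance = 1e-10)
  expect_equal(f2$ci_low, 1 / f1$ci_high, tolerance = 1e-10)
  expect_equal(f2$ci_high, 1 / f1$ci_low, tolerance = 1e-10)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-10)
})

test_that("at-risk subsetting and casewise deletion shape the n per model", {
  cfg <- cohort_config(n = 800, missing_deep_rate = 0.05)
  co <- derive_volumes(simulate_cohort(cfg, seed = 8))
  co <- transform_predictors(co, c("concavity_index", "eccentricity"))
  at_risk <- fit_logistic(co, "concavity_index", "microbleed_new")
  everyone <- fit_logistic(co, "concavity_index", "microbleed_new",
                           at_risk_only = FALSE)
  expect_equal(at_risk$n_used, sum(co$microbleed_baseline == 0))
  expect_equal(everyone$n_used, 800L)

  # missing deep markers drop case-wise for deep-marker models only
  deep_fit <- fit_linear(co, "eccentricity")
  pvc_fit <- fit_linear(co, "concavity_index")
  expect_equal(deep_fit$n_used, sum(!is.na(co$eccentricity)))
  expect_equal(pvc_fit$n_used, 800L)
  expect_lt(deep_fit$n_used, pvc_fit$n_used)

  one_class <- co
  one_class$epvs_new <- 0
  expect_error(fit_logistic(one_class, "concavity_index", "epvs_new"),
               "single class")
})

test_that("the results table forms the marker-by-outcome grid with stars", {
  cfg <- cohort_config(n = 400)
  co <- simulate_cohort(cfg, seed = 12)
  res <- run_association(co)
  expect_equal(nrow(res), 7L * 6L)  # 7 markers x (1 linear + 5 logistic)
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  expect_true(all(res$estimate[res$model == "logistic"] > 0))

  tab <- build_results_table(res)
  expect_equal(dim(tab), c(7L, 6L))
  expect_false(any(is.na(tab)))
  expect_equal(length(attr(tab, "n_used")), 7L)

  expect_equal(wmhshape:::significance_stars(0.004), "**")
  expect_equal(wmhshape:::significance_stars(0.2), "")
  expect_equal(wmhshape:::significance_stars(0.0004), "***")
  expect_equal(wmhshape:::significance_stars(0.04), "*")
})
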