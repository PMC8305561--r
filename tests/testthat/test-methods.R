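test_that("closed-form estimators match their matrix-based fits", {
  for (seed in 1:10) {
    tr <- random_trial(seed, het = seed %% 2 == 0)
    for (m in c("anova_post", "ancova_i", "ancova_ii", "anova_change")) {
      fit <- prepost:::pp_run_method(tr, m)
      expect_equal(prepost:::pp_estimate(tr, m), fit$estimate,
                   tolerance = 1e-12, label = m)
    }
  }
})

test_that("change-score ANOVA and RM share one estimator", {
  for (seed in 1:10) {
    tr <- random_trial(seed, het = TRUE)
    expect_equal(anova_change(tr)$estimate, fit_rm(tr)$estimate,
                 tolerance = 1e-10)
  }
})

test_that("RM plug-in SE equals the change-score model SE", {
  # same estimator, same pooled variance estimate (denominator n-2)
  for (seed in 1:6) {
    tr <- random_trial(seed)
    expect_equal(fit_rm(tr)$flavors$se, anova_change(tr)$flavors$se,
                 tolerance = 1e-6)
    expect_equal(fit_rm(tr)$flavors$df, nrow(tr) - 4)
    expect_equal(anova_change(tr)$flavors$df, nrow(tr) - 2)
  }
})

test_that("baseline adjustment vanishes without baseline imbalance", {
  tr <- random_trial(2, n0 = 10L, n1 = 15L)
  i1 <- tr$arm == 1
  tr$y_pre[i1] <- tr$y_pre[i1] - mean(tr$y_pre[i1]) + mean(tr$y_pre[!i1])
  expect_equal(ancova_i(tr)$estimate, anova_post(tr)$estimate,
               tolerance = 1e-10)
})

test_that("a perfect pre-post relationship is fitted exactly", {
  tr <- prepost_trial(paste0("s", 1:6), c(0, 0, 0, 1, 1, 1),
                      y_pre = c(1, 2, 3, 1.5, 2.5, 3.5),
                      y_post = c(1, 2, 3, 2.5, 3.5, 4.5))  # post = pre + arm
  f <- ancova_i(tr)
  expect_equal(f$estimate, 1, tolerance = 1e-10)
  expect_equal(f$details$fit$sigma2_hat, 0, tolerance = 1e-20)
})

test_that("identical arms give a null estimate with p = 1", {
  tr <- prepost_trial(paste0("s", 1:4), c(0, 0, 1, 1),
                      y_pre = c(1, 2, 1, 2), y_post = c(3, 3, 3, 3))
  f <- anova_post(tr)
  expect_equal(f$estimate, 0)
  expect_equal(f$flavors$p, 1)
})

test_that("the aHC correction vanishes when the arms share one slope", {
  # same baselines, treatment post shifted by a constant: equal slopes, b3 = 0
  x <- c(70, 80, 90, 100, 110)
  y <- c(68, 79, 88, 99, 108)
  tr <- prepost_trial(paste0("s", 1:10), rep(0:1, each = 5),
                      y_pre = c(x, x), y_post = c(y, y - 3))
  f <- ancova_ii(tr)
  expect_equal(f$details$b3, 0, tolerance = 1e-12)
  flav <- f$flavors
  expect_equal(flav$se[flav$flavor == "ahc"], flav$se[flav$flavor == "hc2"],
               tolerance = 1e-12)
})

test_that("the interaction model centers at the pooled baseline mean", {
  tr <- random_trial(8, het = TRUE)
  f <- ancova_ii(tr)
  expect_equal(f$details$center, mean(tr$y_pre))
  expect_equal(f$details$ahc_term,
               f$details$b3^2 * var(tr$y_pre) / nrow(tr))
})

test_that("the printed-tables df convention is available but not default", {
  tr <- random_trial(4)
  n <- nrow(tr)
  f1 <- ancova_i(tr)
  f2 <- ancova_i(tr, df_convention = "tables")
  m1 <- f1$flavors[f1$flavors$flavor == "model", ]
  m2 <- f2$flavors[f2$flavors$flavor == "model", ]
  expect_equal(m1$df, n - 3)
  expect_equal(m2$df, n - 4)
  expect_equal(m2$se, m1$se * sqrt((n - 3) / (n - 4)), tolerance = 1e-12)
  expect_equal(ancova_ii(tr, df_convention = "tables")$flavors$df[1], n - 5)
})

test_that("heteroscedasticity in an unbalanced design triggers the advisory note", {
  p <- scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 6, sigma11 = 20,
                       rho0 = 0.3, rho1 = 0.3, n0 = 40, n1 = 120)
  tr <- generate_trial(p, seed = 5)
  expect_match(ancova_i(tr)$notes, "unbalanced design", all = FALSE)
  d <- residual_diagnostics(tr, "ancova_ii")
  expect_gt(d$ratio, 2)
  expect_length(d$note, 1)
  # balanced homogeneous data: quiet
  tr2 <- generate_trial(scenario_preset("homogeneous_balanced"), seed = 5)
  expect_false(any(grepl("unbalanced", ancova_i(tr2)$notes)))
})

test_that("residual diagnostics report zero variance for an exact fit", {
  tr <- prepost_trial(paste0("s", 1:4), c(0, 0, 1, 1),
                      y_pre = c(1, 2, 1, 2), y_post = c(2, 4, 7, 9))
  # y_post = 2*y_pre + 5*arm exactly; n = 4, p = 3
  d <- residual_diagnostics(tr, "ancova_i")
  expect_equal(unname(d$resid_var), c(0, 0), tolerance = 1e-20)
})

test_that("the stratified bootstrap is reproducible and handles degeneracy", {
  tr <- random_trial(7, n0 = 12L, n1 = 12L)
  b1 <- bootstrap_se(tr, "ancova_i", B = 300, seed = 11)
  b2 <- bootstrap_se(tr, "ancova_i", B = 300, seed = 11)
  expect_identical(b1$replicates, b2$replicates)
  expect_gt(b1$se, 0)
  expect_error(bootstrap_se(tr, "ancova_i", B = 50, seed = 1), "at least 100")
  expect_error(bootstrap_se(tr, "ancova_i", B = 300), "seed")
  # an all-constant trial has a degenerate (zero) bootstrap distribution
  cst <- prepost_trial(paste0("s", 1:4), c(0, 0, 1, 1),
                       y_pre = c(5, 5, 5, 5), y_post = c(5, 5, 5, 5))
  expect_equal(bootstrap_se(cst, "anova_change", B = 200, seed = 2)$se, 0)
})

test_that("bootstrap SEs track the model SE in a homogeneous scenario", {
  tr <- generate_trial(scenario_preset("homogeneous_balanced"), seed = 19)
  b <- bootstrap_se(tr, "ancova_i", B = 600, seed = 3)
  model_se <- ancova_i(tr)$flavors$se[1]
  expect_lt(abs(b$se - model_se) / model_se, 0.15)
})

test_that("analyze_trial returns one row per method and flavor", {
  tr <- random_trial(9)
  tab <- analyze_trial(tr, methods = c("anova_change", "rm"))
  expect_identical(tab$method, c("anova_change", "rm"))
  expect_equal(tab$estimate[1], tab$estimate[2], tolerance = 1e-10)
  tab2 <- analyze_trial(tr, methods = "ancova_ii", boot_B = 150, seed = 4)
  expect_identical(tab2$flavor, c("model", "hc2", "ahc", "bootstrap"))
})
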