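p_hom <- scenario_preset("homogeneous_balanced")$params
p_het_b <- scenario_preset("heterogeneous_balanced")$params
p_het_u <- scenario_preset("heterogeneous_unbalanced")$params

test_that("closed-form variances reproduce hand arithmetic at the presets", {
  expect_equal(true_variance("anova_post", p_hom), 5.0)
  expect_equal(true_variance("anova_change", p_hom), (2 / 90) * 43)
  expect_equal(true_variance("rm", p_hom), (2 / 90) * 43)
  expect_equal(true_variance("ancova_i", p_hom), (2 / 90) * 42.75)
  expect_equal(true_variance("crm_pooled", p_hom), (2 / 90) * 42.75)
  # heterogeneous interaction-model variance, balanced then unbalanced
  expect_equal(true_variance("ancova_ii", p_het_b), 1.8)
  expect_equal(sqrt(true_variance("ancova_ii", p_het_b)), 1.3416, tolerance = 1e-4)
  expect_equal(true_variance("ancova_ii", p_het_u), 1.71875)
  expect_equal(sqrt(true_variance("ancova_ii", p_het_u)), 1.3110, tolerance = 1e-4)
  expect_equal(true_variance("crm_by_arm", p_het_u), 1.71875)
})

test_that("efficiency deltas behave as derived", {
  expect_equal(delta1(p_hom), 196 - 378)  # ANOVA much worse at rho = 0.9
  p0 <- p_hom; p0$rho <- 0
  expect_equal(delta1(p0), p0$sigma0^2)   # ANOVA better with no correlation
  pth <- p_hom; pth$rho <- pth$sigma0 / (2 * pth$sigma1)
  expect_equal(delta1(pth), 0)            # sign threshold
  expect_equal(delta2(p_hom), 0.25)
  peq <- p_hom; peq$rho <- peq$sigma0 / peq$sigma1
  expect_equal(delta2(peq), 0)
  expect_error(delta1(p_het_b), "homogeneous")
})

test_that("delta2 is nonnegative over random parameter draws", {
  set.seed(12)
  for (i in 1:200) {
    p <- scenario_params(0, 0, 0, sigma0 = runif(1, 0.1, 30),
                         sigma1 = runif(1, 0.1, 30),
                         rho = runif(1, -0.99, 0.99), n0 = 10, n1 = 10)
    expect_gte(delta2(p), 0)
  }
})

test_that("the interaction model never loses to the main-effect model", {
  for (seed in 1:100) {
    p <- random_het_params(seed)
    v1 <- true_variance("ancova_i", p)
    v2 <- true_variance("ancova_ii", p)
    expect_lte(v2, v1 + 1e-12)
    if (p$n0 == p$n1) expect_equal(v1, v2, tolerance = 1e-12)
  }
  # equality holds only in balanced designs (given a real slope difference)
  pu <- p_het_u
  expect_lt(true_variance("ancova_ii", pu), true_variance("ancova_i", pu))
})

test_that("heterogeneous formulas collapse to the homogeneous ones", {
  ph <- scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 15, sigma11 = 15,
                        rho0 = 0.9, rho1 = 0.9, n0 = 90, n1 = 90)
  for (m in c("anova_post", "ancova_i", "ancova_ii", "anova_change",
              "rm", "crm_pooled", "crm_by_arm")) {
    expect_equal(true_variance(m, ph), true_variance(m, p_hom),
                 tolerance = 1e-12, label = m)
  }
  expect_equal(ols_bias_delta(ph, "ancova_ii"), 0)
  expect_equal(unconditional_inflation(ph), 0)
})

test_that("the OLS model-variance gap follows the imbalance rule", {
  # balanced: no gap whatever the heteroscedasticity
  expect_equal(ols_bias_delta(p_het_b, "ancova_ii"), 0)
  expect_equal(ols_bias_delta(p_het_b, "ancova_i"), 0)
  # unbalanced with the larger-variance arm larger: model variance overstates
  expect_equal(ols_bias_delta(p_het_u, "ancova_ii"), 0.6)
  expect_gt(ols_bias_delta(p_het_u, "ancova_i"), 0)
  # equal residual variances: no gap at any allocation
  pe <- scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 15, sigma11 = 15,
                        rho0 = 0.8, rho1 = 0.8, n0 = 30, n1 = 150)
  expect_equal(ols_bias_delta(pe, "ancova_ii"), 0)
})

test_that("the centering-mean inflation term scales as 1/(n0+n1)", {
  expect_equal(unconditional_inflation(p_het_b), 0.05)
  expect_equal(unconditional_inflation(p_het_u), 0.05)  # same total n
  p2 <- p_het_b; p2$n0 <- 180L; p2$n1 <- 180L
  expect_equal(unconditional_inflation(p2), 0.025)
  # vanishes when the slopes coincide
  pz <- scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 10, sigma11 = 14,
                        rho0 = 0.7, rho1 = 0.5, n0 = 90, n1 = 90)
  expect_equal(unconditional_inflation(pz), 0)
})

test_that("scenario parameter validation catches bad regimes", {
  expect_error(scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15,
                               rho = 0.9, sigma01 = 15, sigma11 = 15,
                               rho0 = 0.9, rho1 = 0.7, n0 = 90, n1 = 90),
               "not both")
  expect_error(scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15,
                               n0 = 90, n1 = 90), "rho")
  expect_error(scenario_params(88, 86, 83, sigma0 = -1, sigma1 = 15,
                               rho = 0.9, n0 = 90, n1 = 90), "positive")
  expect_error(scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15,
                               rho = 1, n0 = 90, n1 = 90), "inside")
  expect_equal(tau(p_hom), -3)
})
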