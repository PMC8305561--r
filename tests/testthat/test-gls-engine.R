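test_that("saturated-mean REML equals the pooled within-arm sample covariance", {
  for (seed in 1:5) {
    tr <- random_trial(seed, n0 = 8L, n1 = 11L)
    ce <- reml_covariance(tr, "rm", "pooled")
    d0 <- as.matrix(tr[tr$arm == 0, c("y_pre", "y_post")])
    d1 <- as.matrix(tr[tr$arm == 1, c("y_pre", "y_post")])
    Sp <- (crossprod(scale(d0, scale = FALSE)) +
           crossprod(scale(d1, scale = FALSE))) / (nrow(tr) - 2)
    expect_equal(ce$groups$pooled$sigma, unname(Sp), tolerance = 1e-8)
    # by-arm: per-arm sample covariances
    cb <- reml_covariance(tr, "rm", "by_arm")
    expect_equal(cb$groups$arm0$sigma,
                 unname(crossprod(scale(d0, scale = FALSE)) / (nrow(d0) - 1)),
                 tolerance = 1e-8)
  }
})

test_that("closed-form saturated REML agrees with the numerical maximizer", {
  # brute-force check on a small toy: maximize the profiled restricted
  # likelihood numerically and compare with the closed form
  tr <- random_trial(3, n0 = 6L, n1 = 7L)
  stats <- prepost:::pp_suffstats(tr)
  nll <- function(th) {
    S <- prepost:::pp_theta_to_sig(th)
    -prepost:::pp_restricted_ll(list(S, S), stats, "rm")$ll
  }
  Sp <- reml_covariance(tr, "rm", "pooled")$groups$pooled$sigma
  opt <- optim(prepost:::pp_sig_to_theta(Sp * 1.5), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(prepost:::pp_theta_to_sig(opt$par), Sp, tolerance = 1e-4)
})

test_that("RM interaction coefficient is the difference-in-differences exactly", {
  for (seed in 1:8) {
    tr <- random_trial(seed, het = TRUE)
    did <- with(tr, (mean(y_post[arm == 1]) - mean(y_pre[arm == 1])) -
                    (mean(y_post[arm == 0]) - mean(y_pre[arm == 0])))
    g_pool <- gls_fit(tr, "rm", "pooled")
    g_arm <- gls_fit(tr, "rm", "by_arm")
    expect_equal(g_pool$coefficients[["gamma3"]], did, tolerance = 1e-10)
    # invariant to the covariance structure
    expect_equal(g_pool$coefficients[["gamma3"]],
                 g_arm$coefficients[["gamma3"]], tolerance = 1e-10)
  }
})

test_that("pooled cRM matches its baseline-adjustment closed form", {
  for (seed in 1:8) {
    tr <- random_trial(seed, n0 = 9L, n1 = 14L)
    g <- gls_fit(tr, "crm", "pooled")
    S <- g$cov_estimate$groups$pooled
    lam <- S$cov / S$var_pre
    closed <- with(tr, (mean(y_post[arm == 1]) - mean(y_post[arm == 0])) -
                       lam * (mean(y_pre[arm == 1]) - mean(y_pre[arm == 0])))
    expect_equal(g$coefficients[["gamma3"]], closed, tolerance = 1e-8)
  }
})

test_that("cRM fits agree with an independent GLS implementation", {
  tr <- random_trial(5, n0 = 25L, n1 = 30L)
  long <- data.frame(
    subject = rep(tr$subject_id, each = 2),
    arm = rep(tr$arm, each = 2),
    time = rep(c(0, 1), nrow(tr)),
    y = as.vector(rbind(tr$y_pre, tr$y_post)))
  ref <- nlme::gls(y ~ time + arm:time, data = long,
                   correlation = nlme::corSymm(form = ~1 | subject),
                   weights = nlme::varIdent(form = ~1 | time),
                   method = "REML",
                   control = nlme::glsControl(tolerance = 1e-8))
  g <- gls_fit(tr, "crm", "pooled")
  expect_equal(g$coefficients[["gamma3"]],
               unname(coef(ref)[["time:arm"]]), tolerance = 1e-5)
  expect_equal(sqrt(g$vcov["gamma3", "gamma3"]),
               unname(sqrt(diag(ref$varBeta))[["time:arm"]]),
               tolerance = 1e-4)
})

test_that("degenerate and undersized inputs are refused", {
  tr <- prepost_trial(paste0("s", 1:6), c(0, 0, 0, 1, 1, 1),
                      y_pre = c(1, 2, 3, 4, 5, 6),
                      y_post = c(1, 2, 3, 4, 5, 6))  # post == pre
  expect_error(reml_covariance(tr, "rm", "pooled"), "positive definite")
  tr2 <- random_trial(1, n0 = 2L, n1 = 5L)
  expect_error(reml_covariance(tr2, "crm", "by_arm"), "at least 3")
})

test_that("cRM with no baseline imbalance returns the raw post difference", {
  tr <- random_trial(6, n0 = 10L, n1 = 12L)
  # shift treatment baselines so the arm baseline means coincide exactly
  i1 <- tr$arm == 1
  tr$y_pre[i1] <- tr$y_pre[i1] - mean(tr$y_pre[i1]) + mean(tr$y_pre[!i1])
  post_diff <- mean(tr$y_post[i1]) - mean(tr$y_post[!i1])
  expect_equal(gls_fit(tr, "crm", "pooled")$coefficients[["gamma3"]],
               post_diff, tolerance = 1e-8)
  expect_equal(gls_fit(tr, "crm", "by_arm")$coefficients[["gamma3"]],
               post_diff, tolerance = 1e-8)
})

test_that("cRM REML covariance is consistent at large n", {
  p <- scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15, rho = 0.9,
                       n0 = 4000, n1 = 4000)
  ce <- reml_covariance(generate_trial(p, seed = 13), "crm", "pooled")
  g <- ce$groups$pooled
  n <- 8000
  expect_lt(abs(sqrt(g$var_pre) - 14), 3 * 14 / sqrt(2 * n))
  expect_lt(abs(sqrt(g$var_post) - 15), 3 * 15 / sqrt(2 * n))
  expect_lt(abs(g$rho - 0.9), 3 * (1 - 0.81) / sqrt(n))
})
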