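# Fixture builders.  Everything is generated in code; no data files.

# deterministic 4-subject toy: two per arm
toy_trial <- function() {
  prepost_trial(c("s1", "s2", "s3", "s4"), c(0L, 0L, 1L, 1L),
                y_pre = c(1, 3, 2, 4), y_post = c(2, 4, 5, 6))
}

# the worked weight-loss toy: each arm duplicated so the trial is valid,
# means unchanged (88 -> 86 control, 88 -> 83 treatment)
weight_toy <- function() {
  prepost_trial(c("c1", "c2", "t1", "t2"), c(0L, 0L, 1L, 1L),
                y_pre = c(88, 88, 88, 88), y_post = c(86, 86, 83, 83))
}

# random but reproducible trial from a mildly random scenario
random_trial <- function(seed, n0 = 15L, n1 = 20L, het = FALSE) {
  set.seed(seed)
  mu0 <- runif(1, 50, 120)
  if (het) {
    p <- scenario_params(mu0, mu0 + rnorm(1, 0, 5), mu0 + rnorm(1, 0, 5),
                         sigma0 = runif(1, 5, 20),
                         sigma01 = runif(1, 5, 20), sigma11 = runif(1, 5, 20),
                         rho0 = runif(1, -0.8, 0.95), rho1 = runif(1, -0.8, 0.95),
                         n0 = n0, n1 = n1)
  } else {
    p <- scenario_params(mu0, mu0 + rnorm(1, 0, 5), mu0 + rnorm(1, 0, 5),
                         sigma0 = runif(1, 5, 20), sigma1 = runif(1, 5, 20),
                         rho = runif(1, -0.8, 0.95), n0 = n0, n1 = n1)
  }
  generate_trial(p, seed = seed + 7L)
}

# random heterogeneous scenario parameters for property tests
random_het_params <- function(seed) {
  set.seed(seed)
  scenario_params(88, 86, 83,
                  sigma0 = runif(1, 1, 25),
                  sigma01 = runif(1, 1, 25), sigma11 = runif(1, 1, 25),
                  rho0 = runif(1, -0.95, 0.95), rho1 = runif(1, -0.95, 0.95),
                  n0 = sample(2:200, 1), n1 = sample(2:200, 1))
}

expect_trial_equal <- function(a, b) {
  expect_identical(a$subject_id, b$subject_id)
  expect_identical(a$arm, b$arm)
  expect_identical(a$y_pre, b$y_pre)
  expect_identical(a$y_post, b$y_post)
}
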