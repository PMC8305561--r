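# Synthetic-trial generator.  Each arm is drawn from its own deterministic
# RNG substream derived from (seed, arm), so arm 0's draws do not depend on
# how many subjects arm 1 has, and the same seed always reproduces the same
# trial on any platform with R's default Mersenne-Twister generator.

# deterministic substream seed; a 31-bit LCG-style mix of (seed, stream)
pp_substream <- function(seed, stream) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + 1000003 * (as.numeric(stream) + 1)) %% m)
}

#' Scenario presets
#'
#' Three study conditions for a hypothetical 6-month weight-loss trial
#' (weights in kg): baseline mean 88, SD 14 in both arms; post-treatment
#' mean 86, SD 15 in the control arm (about a 2.3% mean reduction) and 83,
#' SD 15 in the treatment arm (about 5.7%), so the treatment effect is
#' \eqn{\tau = -3} kg.
#'
#' * `homogeneous_balanced`: common pre-post correlation 0.9,
#'   `n = (90, 90)`;
#' * `heterogeneous_balanced`: correlation 0.9 in the control arm, 0.7 in
#'   the treatment arm, `n = (90, 90)`;
#' * `heterogeneous_unbalanced`: same covariances, `n = (60, 120)`.
#'
#' @param name preset name (see above).
#' @return A list of class `scenario_preset` with `name` and `params`
#'   (a [scenario_params]).
#' @examples
#' scenario_preset("heterogeneous_unbalanced")$params
#' @export
scenario_preset <- function(name = c("homogeneous_balanced",
                                     "heterogeneous_balanced",
                                     "heterogeneous_unbalanced")) {
  name <- match.arg(name)
  params <- switch(name,
    homogeneous_balanced =
      scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15, rho = 0.9,
                      n0 = 90, n1 = 90),
    heterogeneous_balanced =
      scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 15, sigma11 = 15,
                      rho0 = 0.9, rho1 = 0.7, n0 = 90, n1 = 90),
    heterogeneous_unbalanced =
      scenario_params(88, 86, 83, sigma0 = 14, sigma01 = 15, sigma11 = 15,
                      rho0 = 0.9, rho1 = 0.7, n0 = 60, n1 = 120))
  structure(list(name = name, params = params), class = "scenario_preset")
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat("<scenario_preset> ", x$name, "\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Null variant of a scenario
#'
#' Same population with the treatment-arm post mean set equal to the
#' control's, so the true treatment effect is zero; used for type-I-error
#' experiments.  The covariance structure is unchanged.
#'
#' @param x a [scenario_preset] or [scenario_params].
#' @return A [scenario_params] with `tau() == 0`.
#' @export
null_variant <- function(x) {
  params <- if (inherits(x, "scenario_preset")) x$params else x
  stopifnot(inherits(params, "scenario_params"))
  params$mu_post_1 <- params$mu_post_0
  params
}

# per-arm 2x2 covariance matrices implied by scenario parameters
pp_sigma_matrices <- function(params) {
  a <- pp_arm_params(params)
  mk <- function(s_post, r) {
    S <- matrix(c(a$s0^2, r * a$s0 * s_post,
                  r * a$s0 * s_post, s_post^2), 2)
    if (det(S) <= 0) stop("implied covariance not positive definite",
                          call. = FALSE)
    S
  }
  list(mk(a$s01, a$r0), mk(a$s11, a$r1))
}

#' Simulate a pre-post trial from scenario parameters
#'
#' Draws `n_j` subjects per arm from the bivariate normal with mean
#' `(mu_pre, mu_post_j)` and the arm's implied 2 x 2 covariance.  Each arm
#' uses its own RNG substream derived from `(seed, arm)`, so the control
#' arm's data are identical across scenarios that share `seed` and the
#' control parameters, whatever the treatment arm looks like.
#'
#' @param params a [scenario_params] (or a [scenario_preset]).
#' @param seed integer seed; required.
#' @return A [prepost_trial] with subject ids `c001...` (control) and
#'   `t001...` (treatment).
#' @examples
#' tr <- generate_trial(scenario_preset("homogeneous_balanced"), seed = 1)
#' summary(tr)
#' @export
generate_trial <- function(params, seed) {
  if (inherits(params, "scenario_preset")) params <- params$params
  stopifnot(inherits(params, "scenario_params"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  Sig <- pp_sigma_matrices(params)
  mu <- list(c(params$mu_pre, params$mu_post_0),
             c(params$mu_pre, params$mu_post_1))
  n <- c(params$n0, params$n1)
  prefix <- c("c", "t")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  arms <- lapply(1:2, function(j) {
    set.seed(pp_substream(seed, j - 1L))
    z <- matrix(stats::rnorm(2 * n[j]), n[j], 2)
    y <- sweep(z %*% chol(Sig[[j]]), 2, mu[[j]], "+")
    data.frame(subject_id = sprintf("%s%03d", prefix[j], seq_len(n[j])),
               arm = j - 1L, y_pre = y[, 1], y_post = y[, 2],
               stringsAsFactors = FALSE)
  })
  validate_trial(do.call(rbind, arms))
}

#' Read scenario parameters from a YAML file
#'
#' Keys mirror the [scenario_params()] argument names exactly
#' (`mu_pre`, `mu_post_0`, `mu_post_1`, `sigma0`, then either
#' `sigma1`/`rho` or `sigma01`/`sigma11`/`rho0`/`rho1`, and `n0`, `n1`).
#'
#' @param path path to a YAML file.
#' @return A [scenario_params].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  allowed <- c("mu_pre", "mu_post_0", "mu_post_1", "sigma0", "sigma1",
               "rho", "sigma01", "sigma11", "rho0", "rho1", "n0", "n1")
  extra <- setdiff(names(vals), allowed)
  if (length(extra)) stop("unknown scenario key(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  do.call(scenario_params, vals)
}
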