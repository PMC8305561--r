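#' Population parameters of a two-arm pre-post scenario
#'
#' Describes the bivariate-normal population behind a trial: common
#' baseline mean `mu_pre` and SD `sigma0` (randomization makes them equal
#' across arms), arm-specific post-treatment means, and either a common
#' post SD / pre-post correlation (`sigma1`, `rho`: the *homogeneous*
#' regime) or arm-specific ones (`sigma01`, `sigma11`, `rho0`, `rho1`:
#' the *heterogeneous* regime).  All SDs are on the outcome scale.
#'
#' @param mu_pre baseline mean, both arms.
#' @param mu_post_0,mu_post_1 post-treatment means, control and treatment.
#' @param sigma0 baseline SD (> 0).
#' @param sigma1,rho common post SD and pre-post correlation (homogeneous).
#' @param sigma01,sigma11,rho0,rho1 arm-specific post SDs and correlations
#'   (heterogeneous); supply either this set or (`sigma1`, `rho`).
#' @param n0,n1 arm sizes (>= 2).
#' @return An object of class `scenario_params`.
#' @examples
#' scenario_params(88, 86, 83, sigma0 = 14, sigma1 = 15, rho = 0.9,
#'                 n0 = 90, n1 = 90)
#' @export
scenario_params <- function(mu_pre, mu_post_0, mu_post_1, sigma0,
                            sigma1 = NULL, rho = NULL,
                            sigma01 = NULL, sigma11 = NULL,
                            rho0 = NULL, rho1 = NULL, n0, n1) {
  homog <- !is.null(sigma1) || !is.null(rho)
  heter <- !is.null(sigma01) || !is.null(sigma11) ||
           !is.null(rho0) || !is.null(rho1)
  if (homog && heter)
    stop("give either (sigma1, rho) or (sigma01, sigma11, rho0, rho1), ",
         "not both", call. = FALSE)
  if (homog) {
    if (is.null(sigma1) || is.null(rho))
      stop("homogeneous regime needs both sigma1 and rho", call. = FALSE)
  } else {
    if (is.null(sigma01) || is.null(sigma11) || is.null(rho0) || is.null(rho1))
      stop("heterogeneous regime needs sigma01, sigma11, rho0 and rho1",
           call. = FALSE)
  }
  sds <- c(sigma0, sigma1, sigma01, sigma11)
  if (any(sds <= 0)) stop("all SDs must be positive", call. = FALSE)
  cors <- c(rho, rho0, rho1)
  if (any(abs(cors) >= 1))
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  if (n0 < 2L || n1 < 2L) stop("need n0, n1 >= 2", call. = FALSE)
  structure(list(mu_pre = mu_pre, mu_post_0 = mu_post_0,
                 mu_post_1 = mu_post_1, sigma0 = sigma0,
                 sigma1 = sigma1, rho = rho,
                 sigma01 = sigma01, sigma11 = sigma11,
                 rho0 = rho0, rho1 = rho1,
                 n0 = n0, n1 = n1,
                 regime = if (homog) "homogeneous" else "heterogeneous"),
            class = "scenario_params")
}

#' @export
print.scenario_params <- function(x, ...) {
  cat(sprintf("<scenario_params> %s, n = (%d, %d), tau = %.3g\n",
              x$regime, x$n0, x$n1, tau(x)))
  cat(sprintf("  baseline: mean %.3g, sd %.3g\n", x$mu_pre, x$sigma0))
  if (x$regime == "homogeneous") {
    cat(sprintf("  post: means (%.3g, %.3g), sd %.3g, rho %.3g\n",
                x$mu_post_0, x$mu_post_1, x$sigma1, x$rho))
  } else {
    cat(sprintf("  post: means (%.3g, %.3g), sds (%.3g, %.3g), rho (%.3g, %.3g)\n",
                x$mu_post_0, x$mu_post_1, x$sigma01, x$sigma11,
                x$rho0, x$rho1))
  }
  invisible(x)
}

#' True treatment effect of a scenario
#' @param params a [scenario_params].
#' @return `mu_post_1 - mu_post_0`.
#' @export
tau <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  params$mu_post_1 - params$mu_post_0
}

# arm-specific view of the parameters (homogeneous collapses to equal arms)
pp_arm_params <- function(params) {
  if (params$regime == "homogeneous") {
    list(s01 = params$sigma1, s11 = params$sigma1,
         r0 = params$rho, r1 = params$rho, s0 = params$sigma0)
  } else {
    list(s01 = params$sigma01, s11 = params$sigma11,
         r0 = params$rho0, r1 = params$rho1, s0 = params$sigma0)
  }
}

# slope gap between arms: beta3 = rho1*sigma11/sigma0 - rho0*sigma01/sigma0
pp_beta3 <- function(params) {
  a <- pp_arm_params(params)
  (a$r1 * a$s11 - a$r0 * a$s01) / a$s0
}

#' True (unconditional) variance of a treatment-effect estimator
#'
#' Closed-form population variance of each method's estimator given
#' scenario parameters.  With arm allocation proportions
#' `p0 = n0/(n0+n1)`, `p1 = n1/(n0+n1)` and slope gap
#' \eqn{\beta_3 = (\rho_1\sigma_{11} - \rho_0\sigma_{01})/\sigma_0}:
#'
#' * `anova_post`: \eqn{\sigma_{01}^2/n_0 + \sigma_{11}^2/n_1};
#' * `anova_change`, `rm`:
#'   \eqn{(\sigma_{01}^2+\sigma_0^2-2\rho_0\sigma_0\sigma_{01})/n_0 +
#'        (\sigma_{11}^2+\sigma_0^2-2\rho_1\sigma_0\sigma_{11})/n_1};
#' * `ancova_i`, `crm_pooled`:
#'   \eqn{[(1-\rho_0^2)\sigma_{01}^2 + (\beta_3 p_1)^2\sigma_0^2]/n_0 +
#'        [(1-\rho_1^2)\sigma_{11}^2 + (\beta_3 p_0)^2\sigma_0^2]/n_1};
#' * `ancova_ii`, `crm_by_arm`:
#'   \eqn{(1-\rho_0^2)\sigma_{01}^2/n_0 + (1-\rho_1^2)\sigma_{11}^2/n_1 +
#'        \beta_3^2\sigma_0^2/(n_0+n_1)}.
#'
#' In the homogeneous regime \eqn{\beta_3 = 0} and the ANCOVA rows both
#' collapse to \eqn{(1/n_0+1/n_1)(1-\rho^2)\sigma_1^2}.  The constrained
#' GLS models share the variance of their ANCOVA counterparts because the
#' estimators are asymptotically identical.
#'
#' @param method one of `"anova_post"`, `"ancova_i"`, `"ancova_ii"`,
#'   `"anova_change"`, `"rm"`, `"crm_pooled"`, `"crm_by_arm"`.
#' @param params a [scenario_params] (either regime; homogeneous
#'   parameters are used for all methods via the collapse above).
#' @return Nonnegative scalar variance.
#' @examples
#' p <- scenario_preset("homogeneous_balanced")$params
#' sqrt(true_variance("anova_post", p))   # sqrt(5)
#' @export
true_variance <- function(method, params) {
  stopifnot(inherits(params, "scenario_params"))
  method <- match.arg(method, c("anova_post", "ancova_i", "ancova_ii",
                                "anova_change", "rm", "crm_pooled",
                                "crm_by_arm"))
  a <- pp_arm_params(params)
  n0 <- params$n0; n1 <- params$n1
  p0 <- n0 / (n0 + n1); p1 <- n1 / (n0 + n1)
  b3 <- pp_beta3(params)
  switch(method,
    anova_post = a$s01^2 / n0 + a$s11^2 / n1,
    anova_change = ,
    rm = (a$s01^2 + a$s0^2 - 2 * a$r0 * a$s0 * a$s01) / n0 +
         (a$s11^2 + a$s0^2 - 2 * a$r1 * a$s0 * a$s11) / n1,
    ancova_i = ,
    crm_pooled =
      ((1 - a$r0^2) * a$s01^2 + (b3 * p1)^2 * a$s0^2) / n0 +
      ((1 - a$r1^2) * a$s11^2 + (b3 * p0)^2 * a$s0^2) / n1,
    ancova_ii = ,
    crm_by_arm =
      (1 - a$r0^2) * a$s01^2 / n0 + (1 - a$r1^2) * a$s11^2 / n1 +
      b3^2 * a$s0^2 / (n0 + n1))
}

#' Efficiency gap between ANOVA and the change-score analyses
#'
#' Difference between the unconditional variances of the post-score ANOVA
#' estimator and the change-score (or RM) estimator, per `(1/n0 + 1/n1)`
#' unit: \eqn{\Delta_1 = \sigma_0^2 - 2\rho\sigma_0\sigma_1}.  Positive
#' means ANOVA has the smaller variance; the sign flips at
#' \eqn{\rho = \sigma_0 / (2\sigma_1)}.
#'
#' @param params homogeneous [scenario_params].
#' @return Signed scalar.
#' @export
delta1 <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$regime != "homogeneous")
    stop("delta1 is defined for homogeneous parameters", call. = FALSE)
  params$sigma0^2 - 2 * params$rho * params$sigma0 * params$sigma1
}

#' Efficiency gap between the change-score and ANCOVA analyses
#'
#' \eqn{\Delta_2 = (\sigma_0 - \rho\sigma_1)^2 \ge 0}: the change-score
#' (and RM) estimator never beats baseline-adjusted ANCOVA (or cRM) in the
#' homogeneous regime, with equality only when \eqn{\rho\sigma_1=\sigma_0}.
#'
#' @inheritParams delta1
#' @return Nonnegative scalar.
#' @export
delta2 <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  if (params$regime != "homogeneous")
    stop("delta2 is defined for homogeneous parameters", call. = FALSE)
  (params$sigma0 - params$rho * params$sigma1)^2
}

#' Asymptotic bias of the OLS model-based conditional variance
#'
#' Under arm-specific residual variances the OLS common-variance assumption
#' makes the model-based conditional variance of the ANCOVA arm coefficient
#' biased; asymptotically the gap is
#' \eqn{\Delta = (\sigma^2_{\epsilon 0} - \sigma^2_{\epsilon 1})
#'      (1/n_1 - 1/n_0)},
#' with the per-arm residual variances of the fitted model: for the
#' interaction model \eqn{(1-\rho_j^2)\sigma_{j1}^2}; for the main-effect
#' model these plus \eqn{(\beta_3 p_{1-j})^2 \sigma_0^2} (the interaction
#' left in the error).  The gap vanishes in a balanced design; it is
#' positive (model SE overstates) when the arm with the larger residual
#' variance is also the larger arm.
#'
#' @param params heterogeneous [scenario_params] (homogeneous input gives 0).
#' @param model `"ancova_ii"` (interaction model) or `"ancova_i"`.
#' @return Signed scalar on the variance scale.
#' @export
ols_bias_delta <- function(params, model = c("ancova_ii", "ancova_i")) {
  stopifnot(inherits(params, "scenario_params"))
  model <- match.arg(model)
  a <- pp_arm_params(params)
  n0 <- params$n0; n1 <- params$n1
  p0 <- n0 / (n0 + n1); p1 <- n1 / (n0 + n1)
  b3 <- pp_beta3(params)
  e0 <- (1 - a$r0^2) * a$s01^2
  e1 <- (1 - a$r1^2) * a$s11^2
  if (model == "ancova_i") {
    e0 <- e0 + (b3 * p1)^2 * a$s0^2
    e1 <- e1 + (b3 * p0)^2 * a$s0^2
  }
  (e0 - e1) * (1 / n1 - 1 / n0)
}

#' Unconditional-variance inflation of the interaction ANCOVA
#'
#' The conditional variance of the interaction-model estimator understates
#' its unconditional variance by \eqn{\beta_3^2 \sigma_0^2 / (n_0 + n_1)}
#' — the variance contributed by estimating the centering (overall
#' baseline) mean.  This is exactly the term the adjusted-HC standard
#' error adds back.
#'
#' @param params a [scenario_params].
#' @return Nonnegative scalar.
#' @export
unconditional_inflation <- function(params) {
  stopifnot(inherits(params, "scenario_params"))
  pp_beta3(params)^2 * params$sigma0^2 / (params$n0 + params$n1)
}

#' Table of true standard errors for every method
#'
#' @param params a [scenario_params].
#' @return Data frame with columns `method`, `true_var`, `true_se`.
#' @export
theory_table <- function(params) {
  methods <- c("anova_post", "ancova_i", "ancova_ii", "anova_change",
               "rm", "crm_pooled", "crm_by_arm")
  v <- vapply(methods, true_variance, numeric(1), params = params)
  data.frame(method = methods, true_var = unname(v),
             true_se = sqrt(unname(v)), row.names = NULL)
}
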