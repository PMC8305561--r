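# The six analysis methods.  Each returns a `prepost_fit` carrying the
# treatment-effect estimate and a table of standard-error flavors.

pp_flavor_row <- function(flavor, est, var, df) {
  se <- sqrt(max(var, 0))
  if (se == 0) {
    t <- if (est == 0) 0 else sign(est) * Inf
    p <- if (est == 0) 1 else 0
  } else {
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(flavor = flavor, se = se, df = df, t = t, p = p,
             stringsAsFactors = FALSE)
}

pp_fit <- function(method, estimate, flavors, n0, n1, notes = character(),
                   details = list()) {
  structure(list(method = method, estimate = estimate, flavors = flavors,
                 n0 = n0, n1 = n1, notes = notes, details = details),
            class = "prepost_fit")
}

#' @export
print.prepost_fit <- function(x, ...) {
  cat(sprintf("<prepost_fit> %s: estimate %.4f (n0 = %d, n1 = %d)\n",
              x$method, x$estimate, x$n0, x$n1))
  print(x$flavors, row.names = FALSE, digits = 4)
  for (nt in x$notes) cat("note: ", nt, "\n", sep = "")
  invisible(x)
}

# per-arm residual variances of an OLS fit on a trial, plus the standard
# heteroscedasticity note (triggers when the ratio leaves [0.5, 2] in an
# unbalanced design, where the model-based SE is no longer trustworthy)
pp_het_note <- function(fit, trial) {
  v0 <- stats::var(fit$residuals[trial$arm == 0L])
  v1 <- stats::var(fit$residuals[trial$arm == 1L])
  ratio <- v1 / v0
  n <- arm_sizes(trial)
  note <- character()
  if (is.finite(ratio) && (ratio < 0.5 || ratio > 2) && n[1] != n[2]) {
    note <- paste0("arm residual variances differ (ratio ",
                   signif(ratio, 3), ") in an unbalanced design: the ",
                   "model-based SE is biased; prefer hc2/ahc flavors")
  }
  list(v0 = v0, v1 = v1, ratio = ratio, note = note)
}

pp_ols_flavors <- function(fit, trial, coef_name, se_flavors, df_convention,
                           df_table, ahc_term = NULL) {
  est <- fit$coefficients[[coef_name]]
  n <- nrow(fit$design)
  df_model <- fit$df_resid
  scale2 <- 1
  if (df_convention == "tables" && !is.null(df_table)) {
    # variance rescaled to the alternative printed residual denominator
    scale2 <- df_model / df_table
    df_model <- df_table
  }
  rows <- list()
  for (fl in se_flavors) {
    if (fl == "model") {
      rows[[fl]] <- pp_flavor_row("model",
        est, fit$model_cov[coef_name, coef_name] * scale2, df_model)
    } else if (fl %in% c("hc0", "hc1", "hc2", "hc3")) {
      v <- hc_cov(fit, toupper(fl))[coef_name, coef_name]
      rows[[fl]] <- pp_flavor_row(fl, est, v, df_model)
    } else if (fl == "ahc") {
      if (is.null(ahc_term))
        stop("ahc flavor is only defined for the interaction model (ancova_ii)",
             call. = FALSE)
      v <- hc_cov(fit, "HC2")[coef_name, coef_name] + ahc_term
      rows[[fl]] <- pp_flavor_row("ahc", est, v, df_model)
    } else {
      stop("unknown se flavor: ", fl, call. = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' ANOVA on the post-treatment score
#'
#' One-way ANOVA of the post score on the arm indicator.  The estimate is
#' the raw difference in mean post scores; the model-based standard error
#' is \eqn{\hat\sigma_1 \sqrt{1/n_0 + 1/n_1}} with `n0 + n1 - 2` residual
#' degrees of freedom.  Because no baseline covariate is involved, the
#' model-based variance estimator is unbiased for the unconditional
#' variance and the usual t-test is valid unconditionally.  This is the
#' least efficient of the six methods whenever the pre-post correlation is
#' appreciable.
#'
#' @param trial a [prepost_trial].
#' @return A `prepost_fit`.
#' @export
anova_post <- function(trial) {
  trial <- validate_trial(trial)
  X <- cbind(intercept = 1, arm = trial$arm)
  fit <- fit_ols(X, trial$y_post)
  n <- arm_sizes(trial)
  pp_fit("anova_post", fit$coefficients[["arm"]],
         pp_ols_flavors(fit, trial, "arm", "model", "n_minus_p", NULL),
         n[1], n[2],
         notes = "model-based inference valid unconditionally",
         details = list(fit = fit))
}

#' ANCOVA on the post score with the baseline as covariate (main-effect model)
#'
#' Regression of the post score on arm and baseline.  The arm coefficient
#' is the post-score mean difference adjusted by the common OLS slope times
#' the baseline imbalance.  In a homogeneous population its model-based SE
#' is valid unconditionally; under arm-specific residual variances it
#' remains valid in a balanced design, and the HC2 sandwich flavor repairs
#' it in an unbalanced one (a note is attached when that situation is
#' detected).
#'
#' @param trial a [prepost_trial].
#' @param se_flavors subset of `"model"`, `"hc0"`, `"hc1"`, `"hc2"`, `"hc3"`.
#' @param df_convention `"n_minus_p"` (default; residual df `n - 3`) or
#'   `"tables"` (the alternative printed convention, `n - 4`).
#' @return A `prepost_fit`.
#' @export
ancova_i <- function(trial, se_flavors = c("model", "hc2"),
                     df_convention = c("n_minus_p", "tables")) {
  trial <- validate_trial(trial)
  df_convention <- match.arg(df_convention)
  if (stats::var(trial$y_pre) == 0)
    stop("degenerate data: zero baseline variance", call. = FALSE)
  X <- cbind(intercept = 1, arm = trial$arm, baseline = trial$y_pre)
  fit <- fit_ols(X, trial$y_post)
  n <- arm_sizes(trial)
  het <- pp_het_note(fit, trial)
  flv <- pp_ols_flavors(fit, trial, "arm", se_flavors, df_convention,
                        df_table = nrow(trial) - 4L)
  pp_fit("ancova_i", fit$coefficients[["arm"]], flv, n[1], n[2],
         notes = het$note,
         details = list(fit = fit, resid_var = c(het$v0, het$v1),
                        slope = fit$coefficients[["baseline"]]))
}

#' ANCOVA with a baseline-by-treatment interaction (centered baselines)
#'
#' Regression of the post score on arm, the baseline centered at the pooled
#' sample baseline mean, and their interaction.  With that centering the
#' arm coefficient estimates the marginal treatment effect; it equals the
#' post mean difference adjusted by arm-specific slopes times the centered
#' arm baseline means.
#'
#' Three SE flavors matter here.  The model-based flavor assumes a common
#' residual variance and, more importantly, treats the estimated centering
#' mean as a known constant, so it misses the variability of estimating
#' the overall baseline mean; the `hc2` sandwich fixes heteroscedasticity
#' but not that second gap; the adjusted flavor
#' `ahc = sqrt(hc2 variance + b3^2 s0^2/(n0+n1))`, with `b3` the fitted
#' interaction slope and `s0^2` the overall sample baseline variance,
#' restores a valid unconditional SE and is the recommended choice.
#'
#' @inheritParams ancova_i
#' @param se_flavors subset of `"model"`, `"hc0"`-`"hc3"`, `"ahc"`.
#' @param df_convention `"n_minus_p"` (residual df `n - 4`) or `"tables"`
#'   (`n - 5`).
#' @return A `prepost_fit`.
#' @export
ancova_ii <- function(trial, se_flavors = c("model", "hc2", "ahc"),
                      df_convention = c("n_minus_p", "tables")) {
  trial <- validate_trial(trial)
  df_convention <- match.arg(df_convention)
  n <- arm_sizes(trial)
  if (any(n < 3L))
    stop("ancova_ii needs at least 3 subjects per arm", call. = FALSE)
  for (j in 0:1) {
    if (stats::var(trial$y_pre[trial$arm == j]) == 0)
      stop("degenerate data: zero baseline variance in arm ", j,
           call. = FALSE)
  }
  mu0_hat <- mean(trial$y_pre)
  xc <- trial$y_pre - mu0_hat
  X <- cbind(intercept = 1, arm = trial$arm, baseline_c = xc,
             `arm:baseline_c` = trial$arm * xc)
  fit <- fit_ols(X, trial$y_post)
  b3 <- fit$coefficients[["arm:baseline_c"]]
  ahc_term <- b3^2 * stats::var(trial$y_pre) / sum(n)
  het <- pp_het_note(fit, trial)
  notes <- c(het$note,
             paste0("model SE ignores the sampling variability of the ",
                    "estimated centering mean; ahc adds it back"))
  flv <- pp_ols_flavors(fit, trial, "arm", se_flavors, df_convention,
                        df_table = nrow(trial) - 5L, ahc_term = ahc_term)
  pp_fit("ancova_ii", fit$coefficients[["arm"]], flv, n[1], n[2],
         notes = notes,
         details = list(fit = fit, resid_var = c(het$v0, het$v1),
                        b3 = b3, center = mu0_hat, ahc_term = ahc_term))
}

#' ANOVA on the change score
#'
#' One-way ANOVA of the change score (post minus baseline) on the arm
#' indicator.  The estimate is the difference-in-differences of arm means;
#' the model-based SE uses the pooled within-arm change-score variance with
#' `n0 + n1 - 2` df and is valid unconditionally.  Identical in point
#' estimate to the repeated-measures GLS fit ([fit_rm()]).
#'
#' @param trial a [prepost_trial].
#' @return A `prepost_fit`.
#' @export
anova_change <- function(trial) {
  trial <- validate_trial(trial)
  X <- cbind(intercept = 1, arm = trial$arm)
  fit <- fit_ols(X, trial$y_post - trial$y_pre)
  n <- arm_sizes(trial)
  pp_fit("anova_change", fit$coefficients[["arm"]],
         pp_ols_flavors(fit, trial, "arm", "model", "n_minus_p", NULL),
         n[1], n[2],
         notes = "model-based inference valid unconditionally",
         details = list(fit = fit))
}

#' Repeated-measures GLS model
#'
#' Joint GLS model of the baseline and post scores with the saturated
#' arm-by-time mean structure; the interaction coefficient is the
#' treatment-effect estimator and equals the change-score
#' difference-in-differences exactly, for any covariance estimate.
#' The REML plug-in SE is reported.
#'
#' @param trial a [prepost_trial].
#' @param structure covariance structure, `"pooled"` (default) or `"by_arm"`.
#' @return A `prepost_fit`.
#' @export
fit_rm <- function(trial, structure = c("pooled", "by_arm")) {
  structure <- match.arg(structure)
  g <- gls_fit(trial, "rm", structure)
  est <- g$coefficients[["gamma3"]]
  pp_fit("rm", est,
         pp_flavor_row("reml", est, g$vcov["gamma3", "gamma3"], g$df),
         g$n0, g$n1, details = list(gls = g))
}

#' Constrained repeated-measures GLS model
#'
#' Like [fit_rm()] but with the arms constrained to share one baseline
#' mean, as randomization warrants; this removes one mean parameter and is
#' what makes the method as efficient as the baseline-adjusted ANCOVA.
#' With `structure = "pooled"` it is the homogeneous constrained model
#' (asymptotically equivalent to [ancova_i()]); with `"by_arm"` it is the
#' heterogeneous-variance constrained model (asymptotically equivalent to
#' [ancova_ii()]).
#'
#' @inheritParams fit_rm
#' @return A `prepost_fit` (method label `"crm_pooled"` or `"crm_by_arm"`).
#' @export
fit_crm <- function(trial, structure = c("pooled", "by_arm")) {
  structure <- match.arg(structure)
  g <- gls_fit(trial, "crm", structure)
  est <- g$coefficients[["gamma3"]]
  pp_fit(paste0("crm_", structure), est,
         pp_flavor_row("reml", est, g$vcov["gamma3", "gamma3"], g$df),
         g$n0, g$n1, details = list(gls = g))
}

# fast point-estimate-only path, used by the bootstrap and the Monte Carlo
# engine where the full flavor table is not needed
pp_estimate <- function(trial, method) {
  d0 <- trial$arm == 0L
  x0 <- trial$y_pre[d0];  y0 <- trial$y_post[d0]
  x1 <- trial$y_pre[!d0]; y1 <- trial$y_post[!d0]
  switch(method,
    anova_post = mean(y1) - mean(y0),
    anova_change = (mean(y1) - mean(x1)) - (mean(y0) - mean(x0)),
    rm = (mean(y1) - mean(x1)) - (mean(y0) - mean(x0)),
    ancova_i = {
      sxx <- sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)
      sxy <- sum((x0 - mean(x0)) * (y0 - mean(y0))) +
             sum((x1 - mean(x1)) * (y1 - mean(y1)))
      (mean(y1) - mean(y0)) - (sxy / sxx) * (mean(x1) - mean(x0))
    },
    ancova_ii = {
      b0 <- sum((x0 - mean(x0)) * (y0 - mean(y0))) / sum((x0 - mean(x0))^2)
      b1 <- sum((x1 - mean(x1)) * (y1 - mean(y1))) / sum((x1 - mean(x1))^2)
      mu <- mean(trial$y_pre)
      (mean(y1) - b1 * (mean(x1) - mu)) - (mean(y0) - b0 * (mean(x0) - mu))
    },
    crm_pooled = fit_crm(trial, "pooled")$estimate,
    crm_by_arm = fit_crm(trial, "by_arm")$estimate,
    stop("unknown method: ", method, call. = FALSE))
}

#' Stratified pairs bootstrap standard error
#'
#' Resamples subjects with replacement within each arm (preserving the
#' design sizes `n0`, `n1`), re-estimates the chosen method's
#' treatment-effect estimate on every resample, and reports the standard
#' deviation (denominator `B - 1`) of the replicate estimates.  Resamples
#' on which the method fails (e.g. zero baseline variance in an arm) are
#' redrawn and counted; more than 1% redraws is an error.
#'
#' @param trial a [prepost_trial].
#' @param method one of `"anova_post"`, `"ancova_i"`, `"ancova_ii"`,
#'   `"anova_change"`, `"rm"`, `"crm_pooled"`, `"crm_by_arm"`.
#' @param B number of bootstrap resamples (default 5000; at least 100).
#' @param seed integer seed; required, so results are reproducible.
#' @return A list with `se`, `replicates`, `B`, `redraws`.
#' @export
bootstrap_se <- function(trial, method, B = 5000L, seed) {
  trial <- validate_trial(trial)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  method <- match.arg(method, c("anova_post", "ancova_i", "ancova_ii",
                                "anova_change", "rm", "crm_pooled",
                                "crm_by_arm"))
  i0 <- which(trial$arm == 0L); i1 <- which(trial$arm == 1L)
  n0 <- length(i0); n1 <- length(i1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  reps <- numeric(B)
  redraws <- 0L
  max_redraws <- ceiling(0.01 * B)
  for (b in seq_len(B)) {
    repeat {
      idx <- c(sample(i0, n0, replace = TRUE), sample(i1, n1, replace = TRUE))
      boot <- trial[idx, ]
      boot$subject_id <- paste0("b", seq_along(idx))
      val <- tryCatch(pp_estimate(boot, method), error = function(e) NULL)
      if (!is.null(val)) { reps[b] <- val; break }
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("more than 1% of bootstrap resamples were degenerate (",
             redraws, " redraws)", call. = FALSE)
    }
  }
  list(se = stats::sd(reps), replicates = reps, B = B, redraws = redraws)
}

#' Residual diagnostics for the ANCOVA models
#'
#' Per-arm residual variances from the fitted ANCOVA model, their ratio
#' (treatment over control), and a leverage summary — the numerical
#' counterpart of the residual-by-arm boxplots used to judge
#' heteroscedasticity.
#'
#' @param trial a [prepost_trial].
#' @param method `"ancova_i"` or `"ancova_ii"`.
#' @return A list of class `residual_diagnostics` with `resid_var`
#'   (named per arm), `ratio`, `leverage` (min/mean/max), `residuals`,
#'   `arm`, and `note` (heteroscedasticity warning or empty).
#' @export
residual_diagnostics <- function(trial, method = c("ancova_i", "ancova_ii")) {
  method <- match.arg(method)
  res <- if (method == "ancova_i") ancova_i(trial) else ancova_ii(trial)
  fit <- res$details$fit
  trial <- validate_trial(trial)
  v <- res$details$resid_var
  out <- list(resid_var = c(control = v[1], treatment = v[2]),
              ratio = v[2] / v[1],
              leverage = c(min = min(fit$leverage),
                           mean = mean(fit$leverage),
                           max = max(fit$leverage)),
              residuals = fit$residuals, arm = trial$arm,
              note = res$notes[grepl("residual variances", res$notes)])
  class(out) <- "residual_diagnostics"
  out
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  cat(sprintf("residual variance: control %.4g, treatment %.4g (ratio %.3f)\n",
              x$resid_var[1], x$resid_var[2], x$ratio))
  cat(sprintf("leverage: min %.3f, mean %.3f, max %.3f\n",
              x$leverage["min"], x$leverage["mean"], x$leverage["max"]))
  for (nt in x$note) cat("note: ", nt, "\n", sep = "")
  invisible(x)
}

#' Run several analysis methods on one trial
#'
#' Convenience wrapper producing one row per method and SE flavor, the
#' shape used by the command-line report.
#'
#' @param trial a [prepost_trial].
#' @param methods character vector of method ids (see [bootstrap_se()] for
#'   the list); defaults to all six (cRM in both covariance structures
#'   counts once each).
#' @param boot_B if not `NULL`, also add a `"bootstrap"` flavor with this
#'   many resamples (requires `seed`).
#' @param seed integer seed for the bootstrap flavor.
#' @return A data frame with columns `method`, `estimate`, `flavor`,
#'   `se`, `df`, `t`, `p`.
#' @export
analyze_trial <- function(trial,
                          methods = c("anova_post", "ancova_i", "ancova_ii",
                                      "anova_change", "rm", "crm_pooled"),
                          boot_B = NULL, seed = NULL) {
  trial <- validate_trial(trial)
  rows <- lapply(methods, function(m) {
    f <- pp_run_method(trial, m)
    tab <- cbind(method = m, estimate = f$estimate, f$flavors)
    if (!is.null(boot_B)) {
      if (is.null(seed)) stop("seed required for bootstrap", call. = FALSE)
      bs <- bootstrap_se(trial, m, B = boot_B, seed = seed)
      tab <- rbind(tab, data.frame(method = m, estimate = f$estimate,
                                   flavor = "bootstrap", se = bs$se,
                                   df = NA_real_, t = NA_real_, p = NA_real_))
    }
    tab
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pp_run_method <- function(trial, method, se_flavors = NULL) {
  switch(method,
    anova_post = anova_post(trial),
    anova_change = anova_change(trial),
    ancova_i = if (is.null(se_flavors)) ancova_i(trial)
               else ancova_i(trial, se_flavors),
    ancova_ii = if (is.null(se_flavors)) ancova_ii(trial)
                else ancova_ii(trial, se_flavors),
    rm = fit_rm(trial),
    crm_pooled = fit_crm(trial, "pooled"),
    crm_by_arm = fit_crm(trial, "by_arm"),
    stop("unknown method: ", method, call. = FALSE))
}
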