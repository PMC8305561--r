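# Replicated-simulation engine: bias, empirical vs theoretical variance,
# SE calibration, CI coverage and type-I error for every method x flavor.

pp_default_flavors <- function(method) {
  switch(method,
    anova_post = "model", anova_change = "model",
    ancova_i = c("model", "hc2"),
    ancova_ii = c("model", "hc2", "ahc"),
    rm = "reml", crm_pooled = "reml", crm_by_arm = "reml",
    stop("unknown method: ", method, call. = FALSE))
}

#' Monte Carlo experiment over simulated trials
#'
#' Generates `R` independent trials from `params` (replicate `r` uses the
#' RNG substream derived from `(seed, r)`), analyzes each with the
#' requested methods, and aggregates per method and SE flavor: mean
#' estimate, bias against the true effect, empirical SD, mean estimated
#' SE, relative SE bias (mean SE / empirical SD - 1), coverage of the
#' nominal 95% t-interval, and the rejection rate of the two-sided test at
#' `alpha`.  Every cell carries its Monte Carlo standard error: binomial
#' for coverage/rejection, `sd/sqrt(R)` for means, and the normal-theory
#' approximation `sd/sqrt(2(R-1))` for the empirical SD.
#'
#' @param params a [scenario_params] or [scenario_preset].
#' @param methods character vector of method ids.
#' @param R number of replicates (>= 100; default 2000, giving a Monte
#'   Carlo SE of about 0.005 on a rejection rate).
#' @param seed integer master seed; required.
#' @param flavors optional character vector restricting SE flavors.
#' @param alpha test level for the rejection-rate column.
#' @param keep_estimates keep the per-replicate estimates (one vector per
#'   method, in `$estimates`)? Needed for paired comparisons between
#'   methods, whose Monte Carlo error is far smaller than the marginal one.
#' @return An object of class `mc_report`: list with `table` (one row per
#'   method x flavor), `R`, `seed`, `params`, `tau`, `failures`, and
#'   optionally `estimates`.
#' @export
run_mc <- function(params,
                   methods = c("anova_post", "ancova_i", "ancova_ii",
                               "anova_change", "rm", "crm_pooled"),
                   R = 2000L, seed, flavors = NULL, alpha = 0.05,
                   keep_estimates = FALSE) {
  if (inherits(params, "scenario_preset")) params <- params$params
  stopifnot(inherits(params, "scenario_params"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  R <- as.integer(R)
  if (R < 100L) stop("R must be at least 100", call. = FALSE)
  tau0 <- tau(params)

  cells <- list()
  for (m in methods) {
    fl <- pp_default_flavors(m)
    if (!is.null(flavors)) fl <- intersect(fl, flavors)
    for (f in fl) cells[[paste(m, f, sep = ".")]] <- list(method = m, flavor = f)
  }
  est <- se <- df <- pval <- matrix(NA_real_, length(cells), R,
                                    dimnames = list(names(cells), NULL))
  failures <- 0L
  for (r in seq_len(R)) {
    trial <- generate_trial(params, seed = pp_substream(seed, r))
    for (m in methods) {
      fit <- tryCatch(pp_run_method(trial, m), error = function(e) NULL)
      if (is.null(fit)) { failures <- failures + 1L; next }
      for (f in intersect(fit$flavors$flavor, vapply(cells, `[[`, "", "flavor"))) {
        key <- paste(m, f, sep = ".")
        if (!key %in% rownames(est)) next
        row <- fit$flavors[fit$flavors$flavor == f, ]
        est[key, r] <- fit$estimate
        se[key, r] <- row$se
        df[key, r] <- row$df
        pval[key, r] <- row$p
      }
    }
    if (failures > 0.01 * R)
      stop("more than 1% of replicates failed (", failures,
           " failures after ", r, " replicates)", call. = FALSE)
  }

  agg <- lapply(names(cells), function(key) {
    e <- est[key, ]; s <- se[key, ]; d <- df[key, ]; p <- pval[key, ]
    ok <- !is.na(e)
    e <- e[ok]; s <- s[ok]; d <- d[ok]; p <- p[ok]
    Rk <- length(e)
    emp_sd <- stats::sd(e)
    mean_se <- mean(s)
    crit <- stats::qt(0.975, d)
    cover <- mean(e - crit * s <= tau0 & tau0 <= e + crit * s)
    rej <- mean(p < alpha)
    rel <- mean_se / emp_sd - 1
    mcse_emp_sd <- emp_sd / sqrt(2 * (Rk - 1))
    # delta method: rel bias combines mean-SE noise and empirical-SD noise
    mcse_rel <- sqrt(stats::var(s) / Rk / emp_sd^2 +
                     (mean_se / emp_sd)^2 / (2 * (Rk - 1)))
    data.frame(method = cells[[key]]$method, flavor = cells[[key]]$flavor,
               R = Rk, mean_est = mean(e), bias = mean(e) - tau0,
               emp_sd = emp_sd, mean_se = mean_se, rel_se_bias = rel,
               coverage = cover, reject = rej,
               mcse_bias = emp_sd / sqrt(Rk), mcse_emp_sd = mcse_emp_sd,
               mcse_rel_se_bias = mcse_rel,
               mcse_coverage = sqrt(cover * (1 - cover) / Rk),
               mcse_reject = sqrt(rej * (1 - rej) / Rk),
               stringsAsFactors = FALSE)
  })
  out <- list(table = do.call(rbind, agg), R = R, seed = seed,
              params = params, tau = tau0, failures = failures)
  if (keep_estimates) {
    keys <- vapply(methods, function(m)
      grep(paste0("^", m, "\\."), rownames(est), value = TRUE)[1], "")
    out$estimates <- stats::setNames(lapply(keys, function(k) est[k, ]),
                                     methods)
  }
  class(out) <- "mc_report"
  out
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("<mc_report> R = %d, seed = %d, tau = %.3g, failures = %d\n",
              x$R, x$seed, x$tau, x$failures))
  print(x$table[, c("method", "flavor", "bias", "emp_sd", "mean_se",
                    "rel_se_bias", "coverage", "reject")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Standard-error calibration against theory
#'
#' Compares each flavor's relative SE bias from an [run_mc()] report with
#' what the closed-form theory predicts.  A flavor is flagged *calibrated*
#' when its relative SE bias is within 3 Monte Carlo SEs of zero.  For the
#' model-based ANCOVA flavors the predicted sign of the miscalibration is
#' derived from [ols_bias_delta()] (heteroscedasticity x imbalance) minus,
#' for the interaction model, the centering-mean inflation
#' [unconditional_inflation()].
#'
#' @param report an `mc_report`.
#' @param params optional [scenario_params]; must match the report's
#'   (guards against pairing a report with the wrong scenario).
#' @return Data frame with one row per method x flavor: relative SE bias,
#'   its MC-SE, `calibrated`, and for model ANCOVA flavors
#'   `predicted_gap` and `sign_match`.
#' @export
se_calibration <- function(report, params = NULL) {
  stopifnot(inherits(report, "mc_report"))
  if (!is.null(params)) {
    if (inherits(params, "scenario_preset")) params <- params$params
    if (!identical(unclass(params), unclass(report$params)))
      stop("params do not match the scenario the report was run under",
           call. = FALSE)
  }
  params <- report$params
  tab <- report$table
  pred <- mapply(function(m, f) {
    if (f != "model" || !m %in% c("ancova_i", "ancova_ii")) return(NA_real_)
    ols_bias_delta(params, m) -
      if (m == "ancova_ii") unconditional_inflation(params) else 0
  }, tab$method, tab$flavor)
  out <- data.frame(method = tab$method, flavor = tab$flavor,
                    rel_se_bias = tab$rel_se_bias,
                    mcse = tab$mcse_rel_se_bias,
                    calibrated = abs(tab$rel_se_bias) < 3 * tab$mcse_rel_se_bias,
                    predicted_gap = unname(pred),
                    stringsAsFactors = FALSE)
  out$sign_match <- ifelse(is.na(out$predicted_gap), NA,
                           sign(out$predicted_gap) == sign(out$rel_se_bias))
  out
}

#' Finite-sample gap between asymptotically equivalent estimator pairs
#'
#' The constrained GLS estimators and their ANCOVA counterparts coincide
#' asymptotically (they differ only in how the adjustment slope is
#' estimated: REML covariance plug-in vs OLS), and the change-score and RM
#' estimators coincide exactly at every sample size.  This experiment
#' measures the median absolute difference between the two estimates of a
#' pair over `R` simulated trials at each total sample size in `n_grid`
#' (allocation ratio kept from `params`).
#'
#' @param pair character vector of two method ids; one of
#'   `c("ancova_i", "crm_pooled")`, `c("ancova_ii", "crm_by_arm")`,
#'   `c("anova_change", "rm")`.
#' @param params a [scenario_params] or [scenario_preset].
#' @param n_grid total sample sizes to scan.
#' @param R replicates per grid point.
#' @param seed integer master seed; required.
#' @return Data frame with columns `n`, `n0`, `n1`, `median_gap`.
#' @export
equivalence_gap <- function(pair, params, n_grid = c(40, 160, 640),
                            R = 500L, seed) {
  if (inherits(params, "scenario_preset")) params <- params$params
  stopifnot(inherits(params, "scenario_params"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  allowed <- list(c("ancova_i", "crm_pooled"),
                  c("ancova_ii", "crm_by_arm"),
                  c("anova_change", "rm"))
  if (!any(vapply(allowed, setequal, logical(1), pair)))
    stop("pair must be one of: ancova_i/crm_pooled, ancova_ii/crm_by_arm, ",
         "anova_change/rm", call. = FALSE)
  p0 <- params$n0 / (params$n0 + params$n1)
  rows <- lapply(seq_along(n_grid), function(k) {
    n <- n_grid[k]
    n0 <- max(3L, round(n * p0)); n1 <- n - n0
    pk <- params; pk$n0 <- as.integer(n0); pk$n1 <- as.integer(n1)
    gaps <- vapply(seq_len(R), function(r) {
      trial <- generate_trial(pk, seed = pp_substream(seed, (k - 1L) * R + r))
      abs(pp_estimate(trial, pair[1]) - pp_estimate(trial, pair[2]))
    }, numeric(1))
    data.frame(n = n, n0 = n0, n1 = n1, median_gap = stats::median(gaps))
  })
  do.call(rbind, rows)
}
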