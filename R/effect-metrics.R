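#' Treatment-effect metrics for a pre-post trial
#'
#' Three metrics are in common use for a two-arm pre-post design, and under
#' randomization they target the same population quantity
#' \eqn{\tau = \mu_{1t_1} - \mu_{0t_1}}:
#'
#' * `tau_post`: difference in mean post-treatment scores,
#'   \eqn{\bar y_{.1t_1} - \bar y_{.0t_1}};
#' * `tau_change`: difference in mean change scores
#'   \eqn{\Delta_{ij} = y_{ij t_1} - y_{ij t_0}} between arms;
#' * `tau_pct`: difference in mean percent changes from baseline,
#'   \eqn{\varphi_{ij} = 100(y_{ij t_1} - y_{ij t_0})/y_{ij t_0}},
#'   reported on the 0-100 scale.
#'
#' On any sample, `tau_change = tau_post - (difference in baseline means)`
#' exactly; the two coincide in expectation because randomization balances
#' baselines.  The percent-change metric is reported for completeness only:
#' it is a ratio statistic with a skewed distribution, it is asymmetric in
#' its reference value (see [percent_asymmetry()]) and not additive over
#' periods (see [compound_percent()]), so no normal-theory standard error
#' or test is attached to it here.
#'
#' @param trial a [prepost_trial].
#' @param pct compute the percent-change metric? Set `FALSE` to skip it
#'   (required if some baseline value is exactly zero, where the percent
#'   change is undefined).
#' @return A list of class `effect_estimates` with components `tau_post`,
#'   `tau_change`, `tau_pct` (the latter `NA` when `pct = FALSE`), and
#'   `baseline_diff` (treatment minus control mean baseline).
#' @examples
#' tr <- prepost_trial(c("a", "b", "c", "d"), c(0, 0, 1, 1),
#'                     c(87, 89, 86, 90), c(85, 87, 81, 85))
#' effect_estimates(tr)
#' @export
effect_estimates <- function(trial, pct = TRUE) {
  trial <- validate_trial(trial)
  d0 <- trial[trial$arm == 0L, ]
  d1 <- trial[trial$arm == 1L, ]
  base_diff <- mean(d1$y_pre) - mean(d0$y_pre)
  tau_post <- mean(d1$y_post) - mean(d0$y_post)
  tau_change <- (mean(d1$y_post) - mean(d1$y_pre)) -
                (mean(d0$y_post) - mean(d0$y_pre))
  tau_pct <- NA_real_
  if (isTRUE(pct)) {
    if (any(trial$y_pre == 0)) {
      stop("percent change undefined: some y_pre equals 0 ",
           "(rerun with pct = FALSE)", call. = FALSE)
    }
    phi <- 100 * (trial$y_post - trial$y_pre) / trial$y_pre
    tau_pct <- mean(phi[trial$arm == 1L]) - mean(phi[trial$arm == 0L])
  }
  structure(list(tau_post = tau_post, tau_change = tau_change,
                 tau_pct = tau_pct, baseline_diff = base_diff),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("tau_post   = %.4f\n", x$tau_post))
  cat(sprintf("tau_change = %.4f  (baseline imbalance %.4f)\n",
              x$tau_change, x$baseline_diff))
  if (!is.na(x$tau_pct))
    cat(sprintf("tau_pct    = %.4f %% (no normal-theory inference offered)\n",
                x$tau_pct))
  invisible(x)
}

#' Asymmetry of the percent-change measure
#'
#' For two positive values `a >= b`, the same absolute gap `a - b` yields
#' two different percentages depending on the divisor: `a` is
#' `100 (a - b) / b` percent above `b`, while `b` is only
#' `100 (a - b) / a` percent below `a`.  The first is always at least the
#' second, with equality only when `a = b`.
#'
#' @param a,b positive reals with `a >= b`.
#' @return Named numeric vector `c(pct_above, pct_below)`.
#' @examples
#' percent_asymmetry(197.8, 170.5)  # c(16.0, 13.8), approximately
#' @export
percent_asymmetry <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("a and b must be scalars", call. = FALSE)
  if (!(a > 0 && b > 0)) stop("a and b must be positive", call. = FALSE)
  if (a < b) stop("need a >= b", call. = FALSE)
  c(pct_above = 100 * (a - b) / b, pct_below = 100 * (a - b) / a)
}

#' Compound a sequence of percent changes
#'
#' Percent changes do not add: +10% followed by -10% leaves 99% of the
#' starting value.  This helper returns the final value as a fraction of
#' the starting value, i.e. the product of `1 + c_k/100`.
#'
#' @param changes numeric vector of percent changes, each greater than -100.
#' @return The final-to-start ratio (1 for an empty sequence).
#' @examples
#' compound_percent(c(10, -10))  # 0.99
#' @export
compound_percent <- function(changes) {
  if (length(changes) == 0L) return(1)
  if (!is.numeric(changes) || any(!is.finite(changes)))
    stop("changes must be finite numerics", call. = FALSE)
  if (any(changes <= -100))
    stop("a percent change must be greater than -100", call. = FALSE)
  prod(1 + changes / 100)
}
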