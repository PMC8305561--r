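#' Least-squares fit with explicit hat and variance quantities
#'
#' Minimal OLS engine behind the ANOVA/ANCOVA analyses.  Solves the
#' least-squares problem by QR decomposition (no normal equations), and
#' keeps the quantities the variance estimators need: residuals, leverage
#' \eqn{h_{ii}}, the unbiased residual variance \eqn{RSS/(n-p)}, and the
#' model-based coefficient covariance \eqn{\hat\sigma^2 (X'X)^{-1}}.
#'
#' @param design numeric matrix (n x p), full column rank, n > p.
#'   Column names are kept as coefficient labels.
#' @param response numeric n-vector.
#' @return An object of class `ols_fit`: list with `coefficients`,
#'   `residuals`, `fitted`, `leverage`, `sigma2_hat`, `df_resid`,
#'   `model_cov`, `design_labels`, and the `design` matrix itself
#'   (needed by [hc_cov()]).
#' @seealso [hc_cov()]
#' @export
fit_ols <- function(design, response) {
  X <- as.matrix(design)
  y <- as.numeric(response)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("design and response sizes differ", call. = FALSE)
  if (n <= p) stop("need more observations than columns (n > p)", call. = FALSE)
  labels <- colnames(X)
  if (is.null(labels)) labels <- paste0("x", seq_len(p))
  qx <- qr(X, tol = 1e-10)
  if (qx$rank < p) {
    bad <- labels[qx$pivot[(qx$rank + 1L):p]]
    stop("singular design: column(s) ", paste(bad, collapse = ", "),
         " are collinear with earlier columns", call. = FALSE)
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  # leverage from the thin Q factor
  Q <- qr.Q(qx)
  h <- rowSums(Q * Q)
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  o <- order(qx$pivot)
  xtx_inv <- xtx_inv[o, o, drop = FALSE]
  names(coef) <- labels
  dimnames(xtx_inv) <- list(labels, labels)
  structure(list(coefficients = coef, residuals = res, fitted = fitted,
                 leverage = h, sigma2_hat = sigma2, df_resid = n - p,
                 model_cov = sigma2 * xtx_inv, xtx_inv = xtx_inv,
                 design = X, design_labels = labels),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> %d obs, %d coefficients, df_resid = %d, sigma2 = %.6g\n",
              nrow(x$design), length(x$coefficients), x$df_resid, x$sigma2_hat))
  print(x$coefficients)
  invisible(x)
}

#' Heteroscedasticity-consistent coefficient covariance
#'
#' Sandwich covariance
#' \eqn{(X'X)^{-1} X' \mathrm{diag}(w_i e_i^2) X (X'X)^{-1}}
#' with weights by flavor: HC0 \eqn{w_i = 1}; HC1 \eqn{n/(n-p)};
#' HC2 \eqn{1/(1-h_{ii})}; HC3 \eqn{1/(1-h_{ii})^2}.  HC2 is the package
#' default wherever a robust flavor is requested, on finite-sample
#' performance grounds.
#'
#' @param fit an [fit_ols()] result.
#' @param flavor one of `"HC0"`, `"HC1"`, `"HC2"`, `"HC3"`.
#' @return p x p covariance matrix.
#' @export
hc_cov <- function(fit, flavor = c("HC2", "HC0", "HC1", "HC3")) {
  stopifnot(inherits(fit, "ols_fit"))
  flavor <- match.arg(toupper(flavor), c("HC2", "HC0", "HC1", "HC3"))
  X <- fit$design
  n <- nrow(X); p <- ncol(X)
  h <- fit$leverage
  if (flavor %in% c("HC2", "HC3") && any(h >= 1 - 1e-12)) {
    stop(flavor, " undefined: some leverage equals 1", call. = FALSE)
  }
  w <- switch(flavor,
              HC0 = rep(1, n),
              HC1 = rep(n / (n - p), n),
              HC2 = 1 / (1 - h),
              HC3 = 1 / (1 - h)^2)
  meat <- crossprod(X * (w * fit$residuals^2), X)
  out <- fit$xtx_inv %*% meat %*% fit$xtx_inv
  dimnames(out) <- dimnames(fit$xtx_inv)
  out
}
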