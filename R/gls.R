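# GLS / REML engine for the joint (baseline, post) models.
#
# With two time points and complete data, every subject in arm j shares the
# same 2-row design block X_j, so the restricted likelihood depends on the
# data only through per-arm sufficient statistics: n_j, the mean vector
# ybar_j, and the centered SSCP matrix S_j.  All fits below work on those,
# which makes each likelihood evaluation O(1) in the sample size.

pp_suffstats <- function(trial) {
  lapply(0:1, function(j) {
    d <- unname(as.matrix(trial[trial$arm == j, c("y_pre", "y_post")]))
    m <- colMeans(d)
    cd <- sweep(d, 2, m)
    list(n = nrow(d), mean = m, sscp = unname(crossprod(cd)))
  })
}

# per-arm 2x3 / 2x4 mean-design blocks; rows are (t0, t1)
pp_mean_design <- function(mean_model) {
  if (mean_model == "rm") {
    list(rbind(c(1, 0, 0, 0), c(1, 0, 1, 0)),   # control
         rbind(c(1, 1, 0, 0), c(1, 1, 1, 1)),   # treatment
         labels = c("gamma0", "gamma1", "gamma2", "gamma3"))
  } else {
    list(rbind(c(1, 0, 0), c(1, 1, 0)),
         rbind(c(1, 0, 0), c(1, 1, 1)),
         labels = c("gamma0", "gamma2", "gamma3"))
  }
}

# Profiled restricted log-likelihood (constants dropped) at fixed per-arm
# covariances.  Returns the GLS mean solve as a by-product.
pp_restricted_ll <- function(Sig, stats, mean_model) {
  des <- pp_mean_design(mean_model)
  A <- lapply(Sig, solve)
  p <- ncol(des[[1]])
  M <- matrix(0, p, p); v <- numeric(p)
  for (j in 1:2) {
    XA <- crossprod(des[[j]], A[[j]])
    M <- M + stats[[j]]$n * XA %*% des[[j]]
    v <- v + stats[[j]]$n * XA %*% stats[[j]]$mean
  }
  gamma <- solve(M, v)
  Q <- 0; ld <- 0
  for (j in 1:2) {
    d <- stats[[j]]$mean - drop(des[[j]] %*% gamma)
    Q <- Q + sum(A[[j]] * stats[[j]]$sscp) +
      stats[[j]]$n * drop(crossprod(d, A[[j]] %*% d))
    ld <- ld + stats[[j]]$n * determinant(Sig[[j]])$modulus
  }
  ll <- -0.5 * (ld + Q + determinant(M)$modulus)
  list(ll = as.numeric(ll), gamma = drop(gamma), M = M, labels = des$labels)
}

pp_theta_to_sig <- function(theta) {
  sp <- exp(theta[1]); sq <- exp(theta[2]); r <- tanh(theta[3])
  matrix(c(sp^2, r * sp * sq, r * sp * sq, sq^2), 2)
}

pp_sig_to_theta <- function(S) {
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  c(log(sqrt(S[1, 1])), log(sqrt(S[2, 2])), atanh(min(max(r, -0.999), 0.999)))
}

pp_check_pd <- function(S, where) {
  if (S[1, 1] <= 0 || S[2, 2] <= 0)
    stop("degenerate data: zero variance in ", where, call. = FALSE)
  r <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  if (abs(r) >= 1 - 1e-10)
    stop("covariance estimate not positive definite: pre-post correlation ",
         "is 1 in ", where, call. = FALSE)
  invisible(r)
}

#' REML estimate of the pre/post covariance structure
#'
#' Estimates the 2 x 2 covariance of the (baseline, post-treatment) pair by
#' restricted maximum likelihood, under a repeated-measures mean structure
#' (`"rm"`: arm-by-time saturated means) or the constrained variant
#' (`"crm"`: both arms share the baseline mean).  The covariance is either
#' pooled across arms or arm-specific (`by_arm`, the heterogeneous model).
#'
#' For the saturated `rm` mean structure REML has a closed form: the pooled
#' within-arm sample covariance with denominator `n0 + n1 - 2` (pooled), or
#' the per-arm sample covariances with denominators `n_j - 1` (`by_arm`).
#' For `crm` the profiled restricted likelihood is maximized numerically
#' (BFGS on log-SD / atanh-correlation coordinates, which keeps every
#' iterate positive definite), initialized at the closed-form `rm`
#' estimate; relative tolerance `1e-12` on the objective, at most 200
#' iterations.  Maximum-likelihood (biased) covariance estimation is
#' deliberately not offered.
#'
#' @param trial a [prepost_trial].
#' @param mean_model `"crm"` (default) or `"rm"`.
#' @param structure `"pooled"` or `"by_arm"` (arm-specific covariance;
#'   needs at least 3 subjects per arm).
#' @return An object of class `cov_estimate`: list with `groups` (named
#'   list of per-group `var_pre`, `var_post`, `cov`, `rho`, `sigma`),
#'   `structure`, `mean_model`, `loglik`, `converged`, `iterations`.
#' @export
reml_covariance <- function(trial, mean_model = c("crm", "rm"),
                            structure = c("pooled", "by_arm")) {
  mean_model <- match.arg(mean_model)
  structure <- match.arg(structure)
  trial <- validate_trial(trial)
  stats <- pp_suffstats(trial)
  n0 <- stats[[1]]$n; n1 <- stats[[2]]$n
  if (structure == "by_arm" && (n0 < 3L || n1 < 3L))
    stop("by_arm covariance needs at least 3 subjects per arm", call. = FALSE)

  S_arm <- lapply(1:2, function(j) stats[[j]]$sscp / (stats[[j]]$n - 1L))
  S_pool <- (stats[[1]]$sscp + stats[[2]]$sscp) / (n0 + n1 - 2L)
  if (structure == "pooled") {
    pp_check_pd(S_pool, "the pooled sample covariance")
  } else {
    pp_check_pd(S_arm[[1]], "arm 0"); pp_check_pd(S_arm[[2]], "arm 1")
  }

  if (mean_model == "rm") {
    Sig <- if (structure == "pooled") list(S_pool, S_pool) else S_arm
    ll <- pp_restricted_ll(Sig, stats, "rm")$ll
    conv <- TRUE; iters <- 0L
  } else {
    if (structure == "pooled") {
      par0 <- pp_sig_to_theta(S_pool)
      make <- function(th) {
        S <- pp_theta_to_sig(th); list(S, S)
      }
    } else {
      par0 <- c(pp_sig_to_theta(S_arm[[1]]), pp_sig_to_theta(S_arm[[2]]))
      make <- function(th) list(pp_theta_to_sig(th[1:3]),
                                pp_theta_to_sig(th[4:6]))
    }
    nll <- function(th) -pp_restricted_ll(make(th), stats, "crm")$ll
    opt <- stats::optim(par0, nll, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    if (opt$convergence != 0L) {
      g <- tryCatch(max(abs(vapply(seq_along(opt$par), function(k) {
        e <- 1e-6; d <- opt$par; d[k] <- d[k] + e
        (nll(d) - opt$value) / e
      }, numeric(1)))), error = function(e) NA_real_)
      stop("REML did not converge after 200 iterations (code ",
           opt$convergence, ", last gradient norm ", signif(g, 3), ")",
           call. = FALSE)
    }
    Sig <- make(opt$par)
    ll <- -opt$value
    conv <- TRUE; iters <- as.integer(opt$counts[["function"]])
  }

  grp <- function(S) list(var_pre = S[1, 1], var_post = S[2, 2],
                          cov = S[1, 2],
                          rho = S[1, 2] / sqrt(S[1, 1] * S[2, 2]),
                          sigma = S)
  groups <- if (structure == "pooled") list(pooled = grp(Sig[[1]]))
            else list(arm0 = grp(Sig[[1]]), arm1 = grp(Sig[[2]]))
  structure(list(groups = groups, structure = structure,
                 mean_model = mean_model, loglik = ll,
                 converged = conv, iterations = iters,
                 sigma_list = Sig),
            class = "cov_estimate")
}

#' @export
print.cov_estimate <- function(x, ...) {
  cat(sprintf("<cov_estimate> %s covariance under %s mean model (REML)\n",
              x$structure, toupper(x$mean_model)))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %s: var_pre %.4g, var_post %.4g, cov %.4g (rho %.4f)\n",
                nm, g$var_pre, g$var_post, g$cov, g$rho))
  }
  invisible(x)
}

#' GLS fit of the repeated-measures mean structures
#'
#' Generalized least squares for the joint (baseline, post) outcome at the
#' REML covariance from [reml_covariance()].  The `rm` mean structure is
#' saturated (intercept, arm, time, arm x time), so its interaction
#' coefficient is the difference-in-differences of arm x time means exactly,
#' whatever the covariance; the `crm` structure drops the arm main effect,
#' constraining both arms to one baseline mean, and its arm x time
#' coefficient is the treatment-effect estimator.
#'
#' Inference uses the plug-in coefficient covariance
#' \eqn{(X'V^{-1}X)^{-1}} with a containment degrees-of-freedom
#' convention, `n0 + n1` minus the number of mean parameters.
#'
#' @inheritParams reml_covariance
#' @return An object of class `gls_fit`: `coefficients`, `vcov`,
#'   `cov_estimate`, `df`, `converged`, `iterations`, `n0`, `n1`,
#'   `mean_model`, `structure`.
#' @export
gls_fit <- function(trial, mean_model = c("crm", "rm"),
                    structure = c("pooled", "by_arm")) {
  mean_model <- match.arg(mean_model)
  structure <- match.arg(structure)
  trial <- validate_trial(trial)
  cov_est <- reml_covariance(trial, mean_model, structure)
  stats <- pp_suffstats(trial)
  sol <- pp_restricted_ll(cov_est$sigma_list, stats, mean_model)
  vc <- solve(sol$M)
  names(sol$gamma) <- sol$labels
  dimnames(vc) <- list(sol$labels, sol$labels)
  n0 <- stats[[1]]$n; n1 <- stats[[2]]$n
  structure(list(coefficients = sol$gamma, vcov = vc, cov_estimate = cov_est,
                 df = n0 + n1 - length(sol$gamma),
                 converged = cov_est$converged,
                 iterations = cov_est$iterations,
                 n0 = n0, n1 = n1,
                 mean_model = mean_model, structure = structure),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("<gls_fit> %s mean model, %s covariance (REML), df = %d\n",
              toupper(x$mean_model), x$structure, x$df))
  out <- cbind(estimate = x$coefficients, se = sqrt(diag(x$vcov)))
  print(out, digits = 5)
  invisible(x)
}
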