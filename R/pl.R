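## Joint ML fit of (mu, tau2); the PL point estimate.
ml_joint <- function(yi, vi, tol = 1e-10, max_iter = 100L) {
  fit <- ml_reml_fit(yi, vi, reml = FALSE, tol = tol, max_iter = max_iter)
  w <- 1 / (vi + fit$tau2)
  list(mu = sum(w * yi) / sum(w), tau2 = fit$tau2,
       converged = fit$converged)
}

## Profile log-likelihood of mu: tau2 re-maximised (truncated at 0) at each
## fixed mu.  Constant -k/2 log(2 pi) dropped throughout.
profile_ll <- function(mu, yi, vi, upper = NULL) {
  ll <- function(tau2) -0.5 * sum(log(vi + tau2) + (yi - mu)^2 / (vi + tau2))
  if (is.null(upper))
    upper <- max(vi) + max((yi - mu)^2) + 1
  opt <- stats::optimise(ll, c(0, upper), maximum = TRUE, tol = 1e-10)
  max(opt$objective, ll(0))   # boundary can beat the interior optimum
}

#' Profile-likelihood estimate and confidence interval
#'
#' The point estimate is the joint maximum-likelihood solution for
#' `(mu, tau2)`.  The confidence bounds are the two values of `mu` at which
#' twice the drop in the profile log-likelihood (with `tau2` re-maximised,
#' truncated at zero, at each fixed `mu`) equals the chi-square(1) quantile.
#' Unlike the Wald interval at a plugged-in `tau2`, this interval propagates
#' the uncertainty in the heterogeneity estimate.  Root finding brackets
#' outward from the Wald interval; failure to bracket or converge is
#' reported as a non-converged fit, not an error.
#'
#' @param yi,vi study effects and within-study variances.
#' @param level confidence level.
#' @param tol convergence tolerance on `mu` for the bound search.
#' @param max_iter iteration cap for the inner ML fit.
#' @return list with `mu`, `tau2`, `se` (Wald, at the ML tau2), `ci.lb`,
#'   `ci.ub`, `converged`.
#' @export
pl_estimate <- function(yi, vi, level = 0.95, tol = 1e-8, max_iter = 100L) {
  ml <- ml_joint(yi, vi, max_iter = max_iter)
  w <- 1 / (vi + ml$tau2)
  se <- sqrt(1 / sum(w))
  crit <- stats::qchisq(level, 1) / 2
  ll_hat <- profile_ll(ml$mu, yi, vi)
  target <- ll_hat - crit
  g <- function(mu) profile_ll(mu, yi, vi) - target

  find_bound <- function(dir) {
    step <- stats::qnorm(1 - (1 - level) / 2) * se
    lo <- ml$mu; hi <- ml$mu + dir * step
    for (i in 1:50) {
      if (g(hi) < 0) break
      lo <- hi
      hi <- hi + dir * step
      step <- 2 * step
    }
    if (g(hi) >= 0) return(NA_real_)
    r <- tryCatch(stats::uniroot(g, sort(c(lo, hi)), tol = tol),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else r$root
  }
  lb <- find_bound(-1)
  ub <- find_bound(+1)
  conv <- ml$converged && !is.na(lb) && !is.na(ub)
  list(mu = ml$mu, tau2 = ml$tau2, se = se,
       ci.lb = lb, ci.ub = ub, converged = conv)
}
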