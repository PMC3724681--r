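## Internal: inverse-variance pooling at a given tau2 (tau2 = 0 gives the
## fixed-effect numbers exactly).
pool_at <- function(yi, vi, tau2, level = 0.95) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(mu = mu, se = se, ci.lb = mu - z * se, ci.ub = mu + z * se, w = w)
}

conclusion_from_ci <- function(mu, se, level = 0.95, null = 0) {
  if (is.na(mu) || is.na(se)) return("NoComp")
  if (se == 0) return(if (mu == null) "NS" else "Sig")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (abs(mu - null) / se >= z) "Sig" else "NS"
}

#' Random-effects pooled estimate at a given heterogeneity value
#'
#' Inverse-variance pooling with weights `1/(vi + tau2)` and a normal-theory
#' confidence interval.  With `tau2 = 0` this reproduces the fixed-effect
#' fit exactly.
#'
#' @inheritParams pool_iv_fixed
#' @param tau2 non-negative between-study variance to pool at.
#' @param null null value for the significance conclusion (0 on additive and
#'   log scales).
#' @return A `"hetmeta"` model object (`model = "RE"`).
#' @export
pool_random <- function(yi, vi = NULL, tau2, ni = NULL, level = 0.95,
                        null = 0, measure = NULL) {
  ef <- as_effects(yi, vi, ni, measure)
  stopifnot(tau2 >= 0)
  p <- pool_at(ef$yi, ef$vi, tau2, level)
  hs <- het_stats(ef$yi, ef$vi)
  structure(list(
    mu = p$mu, se = p$se, ci.lb = p$ci.lb, ci.ub = p$ci.ub,
    model = if (tau2 > 0) "RE" else "RE(tau2=0)", method = "IV",
    tau2 = tau2, tau2_method = "fixed", measure = ef$measure, k = ef$k,
    level = level, Q = hs$Q, df = hs$df, H2 = hs$H2, I2 = hs$I2,
    yi = ef$yi, vi = ef$vi, ni = ef$ni,
    conclusion = conclusion_from_ci(p$mu, p$se, level, null),
    converged = TRUE, call = sys.call()), class = "hetmeta")
}

#' Fit a meta-analysis model
#'
#' The main fitting function.  Pools study effects `yi` with known
#' within-study variances `vi` under a fixed-effect model (`method = "FE"`)
#' or a random-effects model whose between-study variance is estimated by
#' any of the estimators in [tau2_estimate()], or by profile likelihood
#' (`method = "PL"`, which uses the ML point estimate and a
#' likelihood-ratio confidence interval that propagates the uncertainty in
#' tau^2).
#'
#' @param yi effect estimates, a data frame from [compute_effects()], or a
#'   column name resolved in `data`.
#' @param vi within-study variances (or column name in `data`).
#' @param data optional data frame in which `yi`, `vi`, `ni` are looked up.
#' @param ni per-study subject counts (needed for `method = "B0"`).
#' @param method `"FE"`, `"PL"`, or a tau^2 estimator label.
#' @param level confidence level (default 0.95).
#' @param null null value used for the significance conclusion.
#' @param theta_f optional fixed-effect estimate at which the Q statistic of
#'   Q-based estimators is centred (Mantel-Haenszel/Peto approaches).
#' @param boot_reps,seed,tol,max_iter passed to the tau^2 estimator / the
#'   likelihood iterations.
#' @return An object of class `"hetmeta"` with components `mu`, `se`,
#'   `ci.lb`, `ci.ub`, `tau2`, `tau2_method`, `Q`, `I2`, `H2`, `conclusion`
#'   and the data; supports `print()`, `summary()`, `coef()`, `vcov()`,
#'   `confint()`, `residuals()`, `weights()`, `plot()` (forest plot) and
#'   `simulate()`.
#' @examples
#' fit <- hetmeta(yi = c(0, 2), vi = c(1, 1), method = "DL")
#' fit$tau2      # 1
#' coef(fit)     # 1
#' @export
hetmeta <- function(yi, vi = NULL, data = NULL, ni = NULL,
                    method = c("DL", "FE", "DL2", "DLb", "DLi", "VC", "VC2",
                               "ML", "REML", "MVa", "MVb", "B0", "BP", "PL"),
                    level = 0.95, null = 0, theta_f = NULL,
                    boot_reps = 10000L, seed = NULL,
                    tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  cl <- match.call()
  if (!is.null(data)) {
    yi <- eval(cl$yi, data, parent.frame())
    vi <- eval(cl$vi, data, parent.frame())
    if (!is.null(cl$ni)) ni <- eval(cl$ni, data, parent.frame())
  }
  ef <- as_effects(yi, vi, ni)
  if (is.null(ni)) ni <- ef$ni
  yi <- ef$yi; vi <- ef$vi; k <- ef$k
  if (k < 1) stop("no studies to pool")

  if (method == "FE" || k < 2) {
    fit <- pool_iv_fixed(yi, vi, ni, level, ef$measure)
    fit$call <- cl
    return(fit)
  }

  hs <- het_stats(yi, vi)
  converged <- TRUE
  t2 <- NULL

  if (method == "PL") {
    pl <- pl_estimate(yi, vi, level = level, tol = tol, max_iter = max_iter)
    out <- structure(list(
      mu = pl$mu, se = pl$se, ci.lb = pl$ci.lb, ci.ub = pl$ci.ub,
      model = "RE", method = "IV", tau2 = pl$tau2, tau2_method = "PL",
      measure = ef$measure, k = k, level = level,
      Q = hs$Q, df = hs$df, H2 = hs$H2, I2 = hs$I2,
      yi = yi, vi = vi, ni = ni,
      conclusion = if (!pl$converged) "NoConv" else
        if (pl$ci.lb > null || pl$ci.ub < null) "Sig" else "NS",
      converged = pl$converged, call = cl), class = "hetmeta")
    return(out)
  }

  t2 <- tau2_estimate(yi, vi, method, ni = ni, theta_f = theta_f,
                      boot_reps = boot_reps, seed = seed,
                      tol = tol, max_iter = max_iter)
  if (is.na(t2$tau2)) {
    out <- not_computable(ef$measure, "IV")
    out$tau2_method <- method
    out$call <- cl
    return(out)
  }
  converged <- !isFALSE(t2$converged)
  p <- pool_at(yi, vi, t2$tau2, level)
  structure(list(
    mu = p$mu, se = p$se, ci.lb = p$ci.lb, ci.ub = p$ci.ub,
    model = "RE", method = "IV", tau2 = t2$tau2, tau2_method = method,
    tau2_fit = t2, measure = ef$measure, k = k, level = level,
    Q = hs$Q, df = hs$df, H2 = hs$H2, I2 = hs$I2,
    yi = yi, vi = vi, ni = ni,
    conclusion = if (!converged) "NoConv" else
      conclusion_from_ci(p$mu, p$se, level, null),
    converged = converged, call = cl), class = "hetmeta")
}

#' Classify the statistical conclusion of a fitted meta-analysis
#'
#' `"Sig"` if the null value lies outside the Wald interval (equivalently
#' `|mu - null| / se >= z`), `"NS"` otherwise; non-converged or
#' non-computable fits pass through as `"NoConv"` / `"NoComp"`.
#'
#' @param object a `"hetmeta"` fit.
#' @param null null value (default 0).
#' @return One of `"NS"`, `"Sig"`, `"NoConv"`, `"NoComp"`.
#' @export
classify_conclusion <- function(object, null = 0) {
  if (is.na(object$mu) || is.na(object$se)) return("NoComp")
  if (isFALSE(object$converged)) return("NoConv")
  conclusion_from_ci(object$mu, object$se, object$level, null)
}
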