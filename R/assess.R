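#' Bias summaries for a set of heterogeneity estimates
#'
#' Mean bias (mean of `tau2_hat - tau2_true`; positive and negative biases
#' cancel) and mean absolute bias (mean of `|tau2_hat - tau2_true|`).
#' `NA` estimates (non-converged or failed replicates) are dropped.
#'
#' @param tau2_hats vector of estimates.
#' @param tau2_true true between-study variance.
#' @return list with `mean_bias` and `mean_abs_bias`.
#' @export
bias_summary <- function(tau2_hats, tau2_true) {
  x <- tau2_hats[!is.na(tau2_hats)]
  if (!length(x)) stop("no estimates to summarise")
  list(mean_bias = mean(x - tau2_true),
       mean_abs_bias = mean(abs(x - tau2_true)))
}

#' Percentage of zero heterogeneity estimates
#'
#' Share of estimates exactly equal to zero (truncation assigns the literal
#' value 0, so no epsilon is involved).
#'
#' @param tau2_hats vector of estimates (`NA`s dropped).
#' @return percentage in [0, 100].
#' @export
zero_rate <- function(tau2_hats) {
  x <- tau2_hats[!is.na(tau2_hats)]
  if (!length(x)) stop("no estimates to summarise")
  100 * mean(x == 0)
}

#' Coverage of the true overall effect
#'
#' Percentage of confidence intervals containing the true effect.
#'
#' @param ci_lb,ci_ub interval bounds (`NA` pairs dropped and counted by the
#'   caller).
#' @param mu_true true overall effect (default 0.5).
#' @return percentage in [0, 100].
#' @export
coverage_rate <- function(ci_lb, ci_ub, mu_true = 0.5) {
  ok <- !is.na(ci_lb) & !is.na(ci_ub)
  if (!any(ok)) stop("no intervals to summarise")
  100 * mean(ci_lb[ok] <= mu_true & mu_true <= ci_ub[ok])
}

#' Error-interval ratio
#'
#' Width of the confidence interval computed at the estimated `tau2`
#' relative to the width computed, on the same data and at the same level,
#' at the true `tau2`.  A value of 1 means the error interval is estimated
#' exactly; below 1, under-estimated.
#'
#' @param pooled_hat,pooled_true `"hetmeta"` fits (or any lists with
#'   `ci.lb`/`ci.ub`) at the estimated and true heterogeneity.
#' @return the width ratio `c`.
#' @export
c_ratio <- function(pooled_hat, pooled_true) {
  wt <- pooled_true$ci.ub - pooled_true$ci.lb
  if (wt <= 0) stop("zero-width reference interval")
  (pooled_hat$ci.ub - pooled_hat$ci.lb) / wt
}

#' Assess heterogeneity estimators over one simulation scenario
#'
#' Simulates `reps` meta-analyses from a scenario cell and, for each
#' estimator, summarises the four performance criteria: mean and mean
#' absolute bias of `tau2_hat`, the percentage of zero estimates, the
#' coverage of the nominal-level interval for the true overall effect, and
#' the quartiles of the error-interval ratio `c` (estimated interval width
#' over the width at the true `tau2`).  Non-converged replicates are
#' excluded from all four summaries and counted in `n_nonconv`.
#'
#' @inheritParams sim_scenario
#' @param methods character vector of estimator labels (see
#'   [tau2_estimate()]); `"FE"` and `"PL"` are also accepted (no `tau2`
#'   summaries for `"FE"` beyond its implicit zero; `"PL"` contributes
#'   coverage and `c` from its profile interval).
#' @param level confidence level for coverage and `c`.
#' @param boot_reps bootstrap replicates per meta-analysis for `"DLb"`.
#' @return data frame with one row per method: `distribution`, `tau2_true`,
#'   `k`, `reps`, `method`, `mean_bias`, `mean_abs_bias`, `pct_zero`,
#'   `coverage`, `c_q25`, `c_median`, `c_q75`, `n_nonconv`.
#' @export
assess_methods <- function(distribution = "normal", tau2 = 0.01, k = 10,
                           reps = 1000, methods = c("DL", "DLb", "REML"),
                           seed = 1, mu = 0.5, level = 0.95,
                           boot_reps = 500L) {
  metas <- sim_scenario(distribution, tau2, k, reps, seed, mu)
  z <- stats::qnorm(1 - (1 - level) / 2)

  rows <- lapply(methods, function(m) {
    t2h <- rep(NA_real_, reps)
    cov <- wid <- rep(NA_real_, reps)
    nonconv <- 0L
    for (r in seq_len(reps)) {
      d <- metas[[r]]
      w_true <- 1 / (d$sigma2 + tau2)
      width_true <- 2 * z / sqrt(sum(w_true))
      if (m == "PL") {
        fit <- pl_estimate(d$yi, d$sigma2, level)
        if (!fit$converged) { nonconv <- nonconv + 1L; next }
        t2h[r] <- fit$tau2
        cov[r] <- fit$ci.lb <= mu && mu <= fit$ci.ub
        wid[r] <- (fit$ci.ub - fit$ci.lb) / width_true
        next
      }
      t2 <- if (m == "FE") list(tau2 = 0, converged = TRUE)
      else tau2_estimate(d$yi, d$sigma2, m, ni = d$ni,
                         boot_reps = boot_reps)
      if (is.na(t2$tau2) || isFALSE(t2$converged)) {
        nonconv <- nonconv + 1L
        next
      }
      t2h[r] <- t2$tau2
      p <- pool_at(d$yi, d$sigma2, t2$tau2, level)
      cov[r] <- p$ci.lb <= mu && mu <= p$ci.ub
      wid[r] <- (p$ci.ub - p$ci.lb) / width_true
    }
    b <- bias_summary(t2h, tau2)
    q <- stats::quantile(wid, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(distribution = distribution, tau2_true = tau2, k = k,
               reps = reps, method = m,
               mean_bias = b$mean_bias, mean_abs_bias = b$mean_abs_bias,
               pct_zero = zero_rate(t2h),
               coverage = 100 * mean(cov, na.rm = TRUE),
               c_q25 = unname(q[1]), c_median = unname(q[2]),
               c_q75 = unname(q[3]), n_nonconv = nonconv,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assess estimators over a grid of scenarios
#'
#' Convenience wrapper running [assess_methods()] over the cross product of
#' distributions, true heterogeneity values and meta-analysis sizes.  Each
#' cell gets its own derived seed so cells are independent and the grid is
#' reproducible.
#'
#' @inheritParams assess_methods
#' @param distributions,tau2s,ks vectors defining the grid.
#' @return row-bound data frame of per-cell summaries.
#' @export
assess_grid <- function(distributions = "normal",
                        tau2s = c(0.01, 0.03, 0.10),
                        ks = c(2, 5, 10, 20, 30),
                        reps = 1000, methods = c("DL", "DLb", "REML"),
                        seed = 1, level = 0.95, boot_reps = 500L) {
  grid <- expand.grid(distribution = distributions, tau2 = tau2s, k = ks,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    assess_methods(grid$distribution[i], grid$tau2[i], grid$k[i], reps,
                   methods, seed = seed + 7919L * i, level = level,
                   boot_reps = boot_reps)
  })
  do.call(rbind, out)
}
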