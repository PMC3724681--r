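#' @export
print.hetmeta <- function(x, digits = 4, ...) {
  cat(sprintf("%s meta-analysis (%s pooling), k = %d\n",
              if (identical(x$model, "FE")) "Fixed-effect" else "Random-effects",
              x$method, x$k))
  if (!is.null(x$measure) && !is.na(x$measure))
    cat("  measure:", x$measure, "\n")
  if (x$conclusion == "NoComp") {
    cat("  not computable (fewer than two eligible studies)\n")
    return(invisible(x))
  }
  if (!identical(x$model, "FE"))
    cat(sprintf("  tau^2 = %s (%s)%s\n", format(x$tau2, digits = digits),
                x$tau2_method,
                if (isFALSE(x$converged)) " [did not converge]" else ""))
  cat(sprintf("  pooled estimate = %s, se = %s\n",
              format(x$mu, digits = digits), format(x$se, digits = digits)))
  cat(sprintf("  %g%% CI: [%s, %s]   conclusion: %s\n", 100 * x$level,
              format(x$ci.lb, digits = digits),
              format(x$ci.ub, digits = digits), x$conclusion))
  invisible(x)
}

#' @export
summary.hetmeta <- function(object, ...) {
  structure(list(fit = object), class = "summary.hetmeta")
}

#' @export
print.summary.hetmeta <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  if (f$k >= 2 && !is.na(f$Q)) {
    pq <- stats::pchisq(f$Q, f$df, lower.tail = FALSE)
    cat(sprintf("  heterogeneity: Q = %s (df = %d, p = %s), H^2 = %s, I^2 = %s%%\n",
                format(f$Q, digits = digits), f$df,
                format.pval(pq, digits = digits),
                format(f$H2, digits = digits), format(f$I2, digits = 3)))
  }
  if (length(f$yi)) {
    w <- weights(f)
    cat("  study weights (%):",
        paste(format(100 * w, digits = 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
coef.hetmeta <- function(object, ...) c(mu = object$mu)

#' @export
vcov.hetmeta <- function(object, ...) {
  matrix(object$se^2, 1, 1, dimnames = list("mu", "mu"))
}

#' @export
confint.hetmeta <- function(object, parm, level = NULL, ...) {
  if (is.null(level) || isTRUE(all.equal(level, object$level)))
    return(matrix(c(object$ci.lb, object$ci.ub), 1, 2,
                  dimnames = list("mu", c("lower", "upper"))))
  p <- pool_at(object$yi, object$vi, object$tau2, level)
  matrix(c(p$ci.lb, p$ci.ub), 1, 2,
         dimnames = list("mu", c("lower", "upper")))
}

#' @export
residuals.hetmeta <- function(object, standardized = FALSE, ...) {
  r <- object$yi - object$mu
  if (standardized) r <- r / sqrt(object$vi + object$tau2)
  r
}

#' @export
weights.hetmeta <- function(object, ...) {
  w <- 1 / (object$vi + object$tau2)
  w / sum(w)
}

#' Forest plot of a fitted meta-analysis
#'
#' Base-graphics forest plot: one square per study at `yi` with a horizontal
#' line for its normal confidence interval, and a diamond for the pooled
#' estimate.
#'
#' @param x a `"hetmeta"` fit.
#' @param labels optional study labels.
#' @param xlab x-axis label.
#' @param ... further arguments passed to `plot()`.
#' @return `x`, invisibly.
#' @export
plot.hetmeta <- function(x, labels = NULL, xlab = "effect size", ...) {
  k <- x$k
  z <- stats::qnorm(1 - (1 - x$level) / 2)
  lo <- x$yi - z * sqrt(x$vi); hi <- x$yi + z * sqrt(x$vi)
  ys <- rev(seq_len(k)) + 1
  graphics::plot(NA, xlim = range(lo, hi, x$ci.lb, x$ci.ub),
                 ylim = c(0, k + 2), yaxt = "n", ylab = "", xlab = xlab, ...)
  graphics::segments(lo, ys, hi, ys)
  graphics::points(x$yi, ys, pch = 15,
                   cex = 0.6 + 1.4 * weights(x) / max(weights(x)))
  if (is.null(labels)) labels <- paste("study", seq_len(k))
  graphics::axis(2, at = ys, labels = labels, las = 1, tick = FALSE)
  graphics::polygon(c(x$ci.lb, x$mu, x$ci.ub, x$mu), c(1, 1.3, 1, 0.7),
                    col = "grey40")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Simulate replicate meta-analyses from a fitted model
#'
#' Draws new study effects from the fitted marginal model
#' `N(mu, vi + tau2)`, holding the within-study variances fixed.
#'
#' @param object a `"hetmeta"` fit.
#' @param nsim number of replicate data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns, each a replicate `yi` vector.
#' @export
simulate.hetmeta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- object$k
  sd <- sqrt(object$vi + object$tau2)
  out <- as.data.frame(replicate(nsim, stats::rnorm(k, object$mu, sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
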