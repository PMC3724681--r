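## Truncation interval for the within-study variance law: sigma2 = X/4 with
## X ~ chi-square(1 df), rejection-sampled into (0.009, 0.6).
.sig2_lo <- 0.009
.sig2_hi <- 0.6

#' Draw within-study variances
#'
#' Independent draws of `X/4` with `X ~ chi-square(1 df)`, rejection-sampled
#' into the interval (0.009, 0.6).  The truncated law has mean 0.173.
#' Uses the current RNG state.
#'
#' @param k number of draws.
#' @return numeric vector of length `k`, all values strictly inside
#'   (0.009, 0.6).
#' @export
sim_within_var <- function(k) {
  out <- numeric(0)
  while (length(out) < k) {
    x <- stats::rchisq(max(2 * k, 16), df = 1) / 4
    out <- c(out, x[x > .sig2_lo & x < .sig2_hi])
  }
  out[seq_len(k)]
}

## Density/CDF of the truncated scaled chi-square law (for tests and
## quadrature).
sig2_cdf <- function(q) {
  lo <- 4 * .sig2_lo; hi <- 4 * .sig2_hi
  Z <- stats::pchisq(hi, 1) - stats::pchisq(lo, 1)
  p <- (stats::pchisq(pmin(pmax(4 * q, lo), hi), 1) - stats::pchisq(lo, 1)) / Z
  p
}

#' Moments of the within-variance law and implied heterogeneity indices
#'
#' Computes `m = E[1/sigma_i^2]` under the truncated scaled chi-square
#' within-variance law by numerical quadrature, and the heterogeneity
#' indices implied by a given between-study variance:
#' `H2 = 1 + tau2 * m` and `I2 = 100 * tau2 * m / (1 + tau2 * m)`.
#' Under this law, `tau2` of 0.01, 0.03 and 0.10 correspond to H2 of 1.18,
#' 1.54 and 2.78 and I2 of about 15.1%, 34.9% and 64.1%.
#'
#' @param tau2 non-negative between-study variance (vectorised).
#' @return list with `m`, `mean_sig2` (mean of the law, 0.173), `H2` and
#'   `I2` (percentage).
#' @export
implied_heterogeneity <- function(tau2) {
  stopifnot(all(tau2 >= 0))
  lo <- 4 * .sig2_lo; hi <- 4 * .sig2_hi
  Z <- stats::pchisq(hi, 1) - stats::pchisq(lo, 1)
  m <- stats::integrate(function(x) (4 / x) * stats::dchisq(x, 1) / Z,
                        lo, hi, rel.tol = 1e-12)$value
  mean_sig2 <- stats::integrate(function(x) (x / 4) * stats::dchisq(x, 1) / Z,
                                lo, hi, rel.tol = 1e-12)$value
  H2 <- 1 + tau2 * m
  list(m = m, mean_sig2 = mean_sig2, H2 = H2, I2 = 100 * tau2 * m / H2)
}

## Fleishman power-method moments for Y = -c + b Z + c Z^2 + d Z^3, Z ~ N(0,1):
## returns (variance, skewness, excess kurtosis).
fleishman_moments <- function(p) {
  b <- p[1]; c <- p[2]; d <- p[3]
  c(b^2 + 6 * b * d + 2 * c^2 + 15 * d^2,
    2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2),
    24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
            d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)))
}

## Newton solve for Fleishman coefficients matching (skewness, full kurtosis),
## unit variance.  Cached per target.
.fleishman_cache <- new.env(parent = emptyenv())
fleishman_coef <- function(skewness, kurtosis) {
  key <- paste(skewness, kurtosis)
  if (!is.null(.fleishman_cache[[key]])) return(.fleishman_cache[[key]])
  target <- c(1, skewness, kurtosis - 3)
  p <- c(0.9, 0.15 * skewness, 0.05)
  for (i in 1:200) {
    f <- fleishman_moments(p) - target
    if (max(abs(f)) < 1e-12) break
    J <- matrix(0, 3, 3)
    h <- 1e-7
    for (j in 1:3) {
      pp <- p; pp[j] <- pp[j] + h
      J[, j] <- (fleishman_moments(pp) - target - f) / h
    }
    p <- p - solve(J, f)
  }
  if (max(abs(fleishman_moments(p) - target)) > 1e-8)
    stop("Fleishman coefficients did not converge for skewness = ", skewness,
         ", kurtosis = ", kurtosis)
  .fleishman_cache[[key]] <- p
  p
}

#' Draw true study effects
#'
#' Draws `k` true study effects with mean `mu` (default 0.5) and variance
#' `tau2` from one of six shapes: `normal`; `skew_moderate`
#' (skewness 1, kurtosis 4) and `skew_extreme` (skewness 2, kurtosis 9),
#' both generated by a moment-matching Fleishman polynomial transform of a
#' standard normal (the targets lie outside the skew-normal family's reach);
#' `uniform` on `mu +/- sqrt(3 tau2)`; `bimodal`, an equal mixture of
#' `N(mu - delta, delta^2)` and `N(mu + delta, delta^2)` with
#' `delta = sqrt(tau2/2)`; and `double_spike`, equal point masses at
#' `mu +/- sqrt(tau2)`.  Kurtosis values are full (normal = 3), not excess.
#' Uses the current RNG state.
#'
#' @param k number of effects.
#' @param distribution one of `"normal"`, `"skew_moderate"`,
#'   `"skew_extreme"`, `"uniform"`, `"bimodal"`, `"double_spike"`.
#' @param tau2 non-negative between-study variance.
#' @param mu mean true effect (default 0.5).
#' @return numeric vector of length `k`.
#' @export
sim_true_effects <- function(k, distribution = c("normal", "skew_moderate",
                                                 "skew_extreme", "uniform",
                                                 "bimodal", "double_spike"),
                             tau2, mu = 0.5) {
  distribution <- match.arg(distribution)
  stopifnot(tau2 >= 0)
  if (tau2 == 0) return(rep(mu, k))
  s <- sqrt(tau2)
  switch(distribution,
    normal = mu + s * stats::rnorm(k),
    skew_moderate = ,
    skew_extreme = {
      p <- if (distribution == "skew_moderate") fleishman_coef(1, 4)
           else fleishman_coef(2, 9)
      z <- stats::rnorm(k)
      mu + s * (-p[2] + p[1] * z + p[2] * z^2 + p[3] * z^3)
    },
    uniform = stats::runif(k, mu - sqrt(3) * s, mu + sqrt(3) * s),
    bimodal = {
      delta <- sqrt(tau2 / 2)
      mu + sample(c(-delta, delta), k, replace = TRUE) +
        stats::rnorm(k, 0, delta)
    },
    double_spike = mu + sample(c(-s, s), k, replace = TRUE))
}

#' Simulate one meta-analysis
#'
#' Generates a meta-analysis of `k` studies: true effects from
#' [sim_true_effects()], within-study variances from [sim_within_var()],
#' observed effects `yi = theta_i + N(0, sigma2_i)` (the variances are
#' treated as known, so the estimated variance equals the true one), and
#' study sizes `ni` drawn as integers uniformly on [50, 500], independent of
#' the effects.  Uses the current RNG state; see [sim_scenario()] for seeded,
#' replicate-addressable generation.
#'
#' @inheritParams sim_true_effects
#' @return data frame with columns `theta`, `sigma2`, `yi`, `ni`.
#' @export
sim_meta <- function(k, distribution = "normal", tau2 = 0, mu = 0.5) {
  theta <- sim_true_effects(k, distribution, tau2, mu)
  sigma2 <- sim_within_var(k)
  yi <- theta + stats::rnorm(k, 0, sqrt(sigma2))
  ni <- sample(50:500, k, replace = TRUE)
  data.frame(theta = theta, sigma2 = sigma2, yi = yi, ni = ni)
}

#' Simulate a scenario of replicate meta-analyses
#'
#' A scenario is a cell of the simulation design: an effect distribution, a
#' true `tau2`, a meta-analysis size `k` and a replicate count.  Each
#' replicate draws its own substream seed from the scenario seed, so
#' replicate `r` is individually reproducible and the full scenario is
#' reproducible as a whole.
#'
#' @inheritParams sim_true_effects
#' @param reps number of replicate meta-analyses.
#' @param seed integer scenario seed.
#' @param rep_index optional vector of replicate indices to generate (all by
#'   default).
#' @return list of data frames as returned by [sim_meta()], with the
#'   scenario stored in attribute `"scenario"`.
#' @export
sim_scenario <- function(distribution = "normal", tau2 = 0.01, k = 10,
                         reps = 10000, seed = 1, mu = 0.5,
                         rep_index = NULL) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  if (is.null(rep_index)) rep_index <- seq_len(reps)
  out <- lapply(rep_index, function(r) {
    set.seed(rep_seeds[r])
    sim_meta(k, distribution, tau2, mu)
  })
  attr(out, "scenario") <- list(distribution = distribution, tau2 = tau2,
                                k = k, reps = reps, seed = seed, mu = mu)
  out
}
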