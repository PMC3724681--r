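#' Heterogeneity statistics around a fixed-effect estimate
#'
#' Cochran's Q computed with inverse-variance weights around a supplied
#' fixed-effect estimate, with the derived H2 and I2 measures.  `theta_f` may
#' come from inverse-variance, Mantel-Haenszel or Peto pooling; Q is always
#' formed with weights `1/vi`.
#'
#' @param yi effect estimates.
#' @param vi within-study variances (all positive).
#' @param theta_f fixed-effect pooled estimate to centre at; defaults to the
#'   inverse-variance estimate.
#' @return list with `Q`, `df` (= k - 1), `H2` (= Q/df) and `I2` (percentage,
#'   `max(0, (Q - df)/Q) * 100`).
#' @export
het_stats <- function(yi, vi, theta_f = NULL) {
  w <- 1 / vi
  if (is.null(theta_f)) theta_f <- sum(w * yi) / sum(w)
  k <- length(yi)
  Q <- sum(w * (yi - theta_f)^2)
  df <- k - 1
  H2 <- if (df > 0) Q / df else NA_real_
  I2 <- if (Q > df) 100 * (Q - df) / Q else 0
  list(Q = Q, df = df, H2 = H2, I2 = I2)
}

## Shared constructor for fixed-effect pooled fits.
new_fixed_pooled <- function(mu, se, method, measure, k, yi, vi, ni = NULL,
                             level = 0.95, call = sys.call(-1)) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  hs <- if (k >= 2) het_stats(yi, vi, mu) else
    list(Q = NA_real_, df = k - 1, H2 = NA_real_, I2 = NA_real_)
  structure(list(
    mu = mu, se = se, ci.lb = mu - z * se, ci.ub = mu + z * se,
    model = "FE", method = method, tau2 = 0, tau2_method = "FE",
    measure = measure, k = k, level = level,
    Q = hs$Q, df = hs$df, H2 = hs$H2, I2 = hs$I2,
    yi = yi, vi = vi, ni = ni,
    conclusion = conclusion_from_ci(mu, se, level),
    converged = TRUE, call = call),
    class = "hetmeta")
}

#' Inverse-variance fixed-effect pooling
#'
#' @param yi effect estimates; alternatively a data frame from
#'   [compute_effects()] (excluded studies are dropped).
#' @param vi within-study variances.
#' @param ni optional per-study subject counts.
#' @param level confidence level, default 0.95.
#' @param measure optional effect-measure label.
#' @return A `"hetmeta"` fixed-effect fit with weights `1/vi`,
#'   `se = 1/sqrt(sum(w))`, and Q/H2/I2 around the pooled estimate.
#' @export
pool_iv_fixed <- function(yi, vi = NULL, ni = NULL, level = 0.95,
                          measure = NULL) {
  ef <- as_effects(yi, vi, ni, measure)
  if (ef$k == 0) stop("no non-excluded studies to pool")
  w <- 1 / ef$vi
  mu <- sum(w * ef$yi) / sum(w)
  se <- sqrt(1 / sum(w))
  new_fixed_pooled(mu, se, "IV", ef$measure, ef$k, ef$yi, ef$vi, ef$ni, level)
}

## Normalise (yi, vi) vectors or a compute_effects() frame into a list.
as_effects <- function(yi, vi = NULL, ni = NULL, measure = NULL) {
  if (is.data.frame(yi)) {
    if (is.null(measure)) measure <- attr(yi, "measure")
    keep <- !yi$excluded
    ni <- if (!is.null(yi$ni)) yi$ni[keep]
    vi <- yi$vi[keep]
    yi <- yi$yi[keep]
  }
  if (is.null(vi) || length(vi) != length(yi))
    stop("'vi' must match 'yi' in length")
  if (any(vi <= 0)) stop("all within-study variances must be positive")
  list(yi = yi, vi = vi, ni = ni, k = length(yi), measure = measure)
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' Pools dichotomous studies with Mantel-Haenszel weights.  The variance of
#' the pooled log odds ratio is Robins-Breslow-Greenland; the pooled log risk
#' ratio and risk difference use the Greenland-Robins variances.  Studies are
#' first screened with the same exclusion/continuity rules as
#' [compute_effects()]; with fewer than one computable study the fit is
#' returned with conclusion `"NoComp"`.
#'
#' @param records data frame of dichotomous study records.
#' @param measure `"logOR"`, `"logRR"` or `"RD"`.
#' @param level confidence level.
#' @param continuity correction added to zero-cell tables (ratio measures).
#' @return A `"hetmeta"` fixed-effect fit.  Heterogeneity statistics are the
#'   inverse-variance-weighted Q around the MH estimate.
#' @export
pool_mh <- function(records, measure = c("logOR", "logRR", "RD"),
                    level = 0.95, continuity = 0.5) {
  measure <- match.arg(measure)
  records <- validate_studies(records)
  ef <- compute_effects(records, measure, continuity)
  ## double-zero (and double-full) tables are excluded for ratio measures but
  ## retained under RD, where they carry MH weight despite a zero variance
  keep <- if (measure == "RD") rep(TRUE, nrow(records)) else !ef$excluded
  recs <- records[keep, , drop = FALSE]
  k <- nrow(recs)
  if (k < 1) return(not_computable(measure, "MH"))

  a <- recs$a; b <- recs$n1 - recs$a; c <- recs$c; d <- recs$n2 - recs$c
  if (measure %in% c("logOR", "logRR")) {
    zero <- a == 0 | b == 0 | c == 0 | d == 0
    a[zero] <- a[zero] + continuity; b[zero] <- b[zero] + continuity
    c[zero] <- c[zero] + continuity; d[zero] <- d[zero] + continuity
  }
  n1 <- a + b; n2 <- c + d; N <- n1 + n2

  if (measure == "logOR") {
    R <- a * d / N; S <- b * c / N
    P <- (a + d) / N; Q <- (b + c) / N
    mu <- log(sum(R) / sum(S))
    v <- sum(P * R) / (2 * sum(R)^2) +
      sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
      sum(Q * S) / (2 * sum(S)^2)
  } else if (measure == "logRR") {
    R <- a * n2 / N; S <- c * n1 / N
    P <- (n1 * n2 * (a + c) - a * c * N) / N^2
    mu <- log(sum(R) / sum(S))
    v <- sum(P) / (sum(R) * sum(S))
  } else {
    w <- n1 * n2 / N
    mu <- sum(w * (a / n1 - c / n2)) / sum(w)
    v <- sum((a * b * n2^3 + c * d * n1^3) / (n1 * n2 * N^2)) / sum(w)^2
  }
  qok <- keep & !ef$excluded & !is.na(ef$vi) & ef$vi > 0
  new_fixed_pooled(mu, sqrt(v), "MH", measure, k, ef$yi[qok], ef$vi[qok],
                   records$n_total[qok], level)
}

#' Peto fixed-effect pooling of 2x2 tables
#'
#' Pooled log Peto odds ratio `sum(O - E) / sum(V)` with standard error
#' `1/sqrt(sum(V))`.  Studies with an empty margin (V = 0) are excluded.
#'
#' @inheritParams pool_mh
#' @return A `"hetmeta"` fixed-effect fit on the log Peto odds-ratio scale;
#'   per-study inverse-variance weights `V` are used for the Q statistic.
#' @export
pool_peto <- function(records, level = 0.95) {
  records <- validate_studies(records)
  a <- records$a; b <- records$n1 - records$a
  c <- records$c; d <- records$n2 - records$c
  N <- a + b + c + d
  E <- (a + b) * (a + c) / N
  V <- (a + b) * (c + d) * (a + c) * (b + d) / (N^2 * (N - 1))
  keep <- V > 0
  if (!any(keep)) return(not_computable("logPetoOR", "Peto"))
  OE <- (a - E)[keep]; V <- V[keep]
  mu <- sum(OE) / sum(V)
  se <- sqrt(1 / sum(V))
  new_fixed_pooled(mu, se, "Peto", "logPetoOR", sum(keep),
                   yi = OE / V, vi = 1 / V, ni = records$n_total[keep], level)
}

not_computable <- function(measure, method) {
  structure(list(mu = NA_real_, se = NA_real_, ci.lb = NA_real_,
                 ci.ub = NA_real_, model = "FE", method = method,
                 tau2 = NA_real_, tau2_method = "FE", measure = measure,
                 k = 0L, level = NA_real_, Q = NA_real_, df = NA_real_,
                 H2 = NA_real_, I2 = NA_real_, yi = numeric(0),
                 vi = numeric(0), ni = NULL, conclusion = "NoComp",
                 converged = NA, call = NULL),
            class = "hetmeta")
}
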