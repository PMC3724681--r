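#' Between-study variance estimators
#'
#' Estimates the between-study (heterogeneity) variance tau^2 of a
#' random-effects meta-analysis with study effects `yi` and known
#' within-study variances `vi`.  Twelve estimators are provided, in two
#' groups:
#'
#' * zero-or-positive: `"DL"` (DerSimonian-Laird moment estimator), `"DL2"`
#'   (two-step DerSimonian-Kacker refinement), `"DLb"` (non-parametric
#'   bootstrap of DL: resample studies with replacement, average the
#'   truncated estimates), `"VC"` (Hedges variance-component estimator),
#'   `"VC2"` (its two-step refinement), `"ML"` and `"REML"` (iterative
#'   likelihood estimators with truncation at every step), `"B0"` (Rukhin
#'   Bayes estimator with zero prior variance; needs subject counts `ni`);
#' * positive-only: `"DLi"` (DL floored at 0.01 when DL <= 0), `"MVa"` and
#'   `"MVb"` (Sidik-Jonkman model error variance estimators with crude and
#'   VC-informed prior ratios), `"BP"` (Rukhin's always-positive Bayes
#'   estimator).
#'
#' Negative moment/likelihood solutions are truncated to zero and flagged.
#' For Q-based estimators (`DL`, `DLi`, `DLb`) the Cochran statistic may be
#' centred at a supplied fixed-effect estimate `theta_f` (inverse-variance by
#' default; pass the Mantel-Haenszel or Peto estimate for those approaches).
#'
#' @param yi effect estimates (or a data frame from [compute_effects()]).
#' @param vi within-study variances.
#' @param method estimator label (see above).
#' @param ni per-study subject counts, required for `"B0"`.
#' @param theta_f optional fixed-effect estimate at which Q is centred.
#' @param boot_reps bootstrap replicates for `"DLb"` (default 10000).
#' @param seed optional integer seed for `"DLb"` resampling.
#' @param tol convergence tolerance on successive tau^2 iterates (ML/REML).
#' @param max_iter iteration cap for ML/REML.
#' @return An object of class `"tau2_est"`: a list with `tau2`, `method`,
#'   `group`, `truncated`, `converged`, `iterations` and (DLb) `boot_reps`.
#'   `tau2` is `NA` with `converged = NA` when the estimator fails (MVa with
#'   all effects equal).
#' @examples
#' tau2_estimate(c(0, 2), c(1, 1), "DL")$tau2   # 1
#' tau2_estimate(c(0, 2), c(1, 1), "ML")$tau2   # 0
#' @export
tau2_estimate <- function(yi, vi = NULL, method = c("DL", "DL2", "DLb", "DLi",
                                                    "VC", "VC2", "ML", "REML",
                                                    "MVa", "MVb", "B0", "BP"),
                          ni = NULL, theta_f = NULL, boot_reps = 10000L,
                          seed = NULL, tol = 1e-10, max_iter = 100L) {
  method <- match.arg(method)
  ef <- as_effects(yi, vi, ni)
  yi <- ef$yi; vi <- ef$vi
  if (is.null(ni)) ni <- ef$ni
  k <- length(yi)
  if (k < 2) stop("at least two studies are needed to estimate tau^2")

  group <- if (method %in% c("DLi", "MVa", "MVb", "BP"))
    "positive-only" else "zero-or-positive"
  res <- list(tau2 = NA_real_, method = method, group = group,
              truncated = FALSE, converged = TRUE, iterations = 0L,
              boot_reps = NA_integer_)

  raw_dl <- function(y, v, tf = NULL) {
    w <- 1 / v
    if (is.null(tf)) tf <- sum(w * y) / sum(w)
    Q <- sum(w * (y - tf)^2)
    (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w))
  }
  raw_vc <- function(y, v) {
    kk <- length(y)
    sum((y - mean(y))^2) / (kk - 1) - sum(v) / kk
  }
  ## DerSimonian-Kacker generalized moment equation with weights a and centre
  ## at the a-weighted mean (the step-1 random-effects estimate).
  raw_dk <- function(y, v, a) {
    yb <- sum(a * y) / sum(a)
    num <- sum(a * (y - yb)^2) - (sum(a * v) - sum(a^2 * v) / sum(a))
    num / (sum(a) - sum(a^2) / sum(a))
  }
  truncate0 <- function(x) {
    res$truncated <<- x < 0
    max(0, x)
  }

  if (method == "DL") {
    res$tau2 <- truncate0(raw_dl(yi, vi, theta_f))
  } else if (method == "VC") {
    res$tau2 <- truncate0(raw_vc(yi, vi))
  } else if (method == "DL2") {
    step1 <- max(0, raw_dl(yi, vi, theta_f))
    res$tau2 <- truncate0(raw_dk(yi, vi, 1 / (vi + step1)))
  } else if (method == "VC2") {
    step1 <- max(0, raw_vc(yi, vi))
    res$tau2 <- truncate0(raw_dk(yi, vi, 1 / (vi + step1)))
  } else if (method == "DLi") {
    dl <- raw_dl(yi, vi, theta_f)
    res$tau2 <- if (dl > 0) dl else 0.01
    res$truncated <- dl <= 0
  } else if (method == "DLb") {
    if (boot_reps < 1) stop("'boot_reps' must be >= 1")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    res$tau2 <- dlb_mean(yi, vi, boot_reps)
    res$boot_reps <- as.integer(boot_reps)
  } else if (method %in% c("ML", "REML")) {
    fit <- ml_reml_fit(yi, vi, reml = method == "REML",
                       tol = tol, max_iter = max_iter)
    res$tau2 <- fit$tau2
    res$converged <- fit$converged
    res$iterations <- fit$iterations
    res$truncated <- fit$truncated
  } else if (method == "MVa") {
    tau0 <- sum((yi - mean(yi))^2) / k
    if (tau0 == 0) {            # all effects equal: estimator fails
      res$converged <- NA
      return(structure(res, class = "tau2_est"))
    }
    res$tau2 <- sj_mv(yi, vi, tau0)
  } else if (method == "MVb") {
    vc <- max(0, raw_vc(yi, vi))
    if (vc == 0) vc <- 0.01     # arbitrary positive denominator
    res$tau2 <- sj_mv(yi, vi, vc)
  } else if (method == "B0") {
    if (is.null(ni) || anyNA(ni))
      stop("B0 needs the number of subjects 'ni' for every study")
    N <- sum(ni)
    b0 <- sum((yi - mean(yi))^2) / (k + 1) -
      (k - 1) / (k + 1) * sum((ni - 1) * vi) / (N - k)
    res$tau2 <- truncate0(b0)
  } else if (method == "BP") {
    res$tau2 <- sum((yi - mean(yi))^2) / (k + 1)
  }
  structure(res, class = "tau2_est")
}

## Sidik-Jonkman model error variance estimator for a given prior tau0^2:
## ratios r_i = v_i / tau0^2, weights 1/(r_i + 1), weighted SS / (k - 1).
sj_mv <- function(yi, vi, tau0) {
  r <- vi / tau0
  v <- 1 / (r + 1)
  mu <- sum(v * yi) / sum(v)
  sum(v * (yi - mu)^2) / (length(yi) - 1)
}

## Mean truncated DL over B bootstrap resamples of (yi, vi) pairs,
## vectorised across resamples.  Uses the current RNG state.
dlb_mean <- function(yi, vi, B) {
  k <- length(yi)
  idx <- matrix(sample.int(k, k * B, replace = TRUE), nrow = k)
  Y <- matrix(yi[idx], nrow = k)
  W <- matrix(1 / vi[idx], nrow = k)
  sw <- colSums(W); sw2 <- colSums(W^2)
  mu <- colSums(W * Y) / sw
  Q <- colSums(W * Y^2) - sw * mu^2
  tau2 <- (Q - (k - 1)) / (sw - sw2 / sw)
  mean(pmax(0, tau2))
}

## Exact expectation of the truncated DL estimator over all k^k equally
## likely ordered resamples (enumeration oracle; only feasible for tiny k).
dlb_exact <- function(yi, vi) {
  k <- length(yi)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  vals <- apply(grid, 1, function(ix) {
    y <- yi[ix]; v <- vi[ix]; w <- 1 / v
    mu <- sum(w * y) / sum(w)
    Q <- sum(w * (y - mu)^2)
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  })
  mean(vals)
}

## Truncated fixed-point iteration for ML/REML with weights 1/(vi + tau2):
##   ML:   tau2 <- sum(w^2 ((y - mu)^2 - v)) / sum(w^2)
##   REML: the same plus 1/sum(w)
## mu is recomputed at each iteration; truncation applied at every step.
ml_reml_fit <- function(yi, vi, reml = FALSE, tol = 1e-10, max_iter = 100L) {
  tau2 <- max(0, sum((yi - mean(yi))^2) / (length(yi) - 1) - mean(vi))
  converged <- FALSE; truncated <- FALSE; iter <- 0L; mu <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / (vi + tau2)
    mu <- sum(w * yi) / sum(w)
    new <- sum(w^2 * ((yi - mu)^2 - vi)) / sum(w^2)
    if (reml) new <- new + 1 / sum(w)
    truncated <- new < 0
    new <- max(0, new)
    if (abs(new - tau2) <= tol) {
      tau2 <- new; converged <- TRUE
      break
    }
    tau2 <- new
  }
  w <- 1 / (vi + tau2)
  list(tau2 = tau2, mu = sum(w * yi) / sum(w), converged = converged,
       iterations = iter, truncated = truncated)
}

#' @export
print.tau2_est <- function(x, digits = 4, ...) {
  cat("Between-study variance estimate (", x$method, ", ",
      x$group, ")\n", sep = "")
  if (is.na(x$tau2)) {
    cat("  estimator failed to produce an estimate\n")
  } else {
    cat("  tau^2 =", format(x$tau2, digits = digits))
    if (isTRUE(x$truncated)) cat("  [truncated]")
    if (isFALSE(x$converged)) cat("  [did not converge]")
    cat("\n")
  }
  invisible(x)
}
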