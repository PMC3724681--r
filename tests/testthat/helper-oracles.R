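# Independent transcriptions of the estimator formulas, written directly
# from their printed definitions and kept separate from the package code
# paths they check.

oracle_iv <- function(y, v) {
  w <- 1 / v
  list(mu = sum(w * y) / sum(w), se = sqrt(1 / sum(w)))
}

oracle_Q <- function(y, v, tf = oracle_iv(y, v)$mu) sum((y - tf)^2 / v)

oracle_dl <- function(y, v, tf = NULL) {
  w <- 1 / v
  if (is.null(tf)) tf <- sum(w * y) / sum(w)
  max(0, (oracle_Q(y, v, tf) - (length(y) - 1)) /
        (sum(w) - sum(w^2) / sum(w)))
}

oracle_vc <- function(y, v) {
  k <- length(y)
  max(0, sum((y - mean(y))^2) / (k - 1) - sum(v) / k)
}

# DerSimonian-Kacker generalized moment equation, one refinement step
oracle_two_step <- function(y, v, step1) {
  a <- 1 / (v + step1)
  yb <- sum(a * y) / sum(a)
  num <- sum(a * (y - yb)^2) - (sum(a * v) - sum(a^2 * v) / sum(a))
  max(0, num / (sum(a) - sum(a^2) / sum(a)))
}

oracle_mva <- function(y, v) {
  k <- length(y)
  tau0 <- sum((y - mean(y))^2) / k
  r <- v / tau0
  vv <- 1 / (r + 1)
  mu <- sum(vv * y) / sum(vv)
  sum(vv * (y - mu)^2) / (k - 1)
}

oracle_mvb <- function(y, v) {
  k <- length(y)
  vc <- oracle_vc(y, v)
  den <- if (vc == 0) 0.01 else vc
  r <- v / den
  vv <- 1 / (r + 1)
  mu <- sum(vv * y) / sum(vv)
  sum(vv * (y - mu)^2) / (k - 1)
}

oracle_b0 <- function(y, v, n) {
  k <- length(y)
  max(0, sum((y - mean(y))^2) / (k + 1) -
        (k - 1) / (k + 1) * sum((n - 1) * v) / (sum(n) - k))
}

oracle_bp <- function(y, v) sum((y - mean(y))^2) / (length(y) + 1)

# log-likelihood (constants dropped) and restricted log-likelihood in tau2,
# profiled over mu analytically (mu-hat is the weighted mean at each tau2)
oracle_ll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2) + (y - mu)^2 / (v + tau2))
}
oracle_rll <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
    0.5 * sum((y - mu)^2 / (v + tau2))
}

# grid-search maximisation of a likelihood over tau2 >= 0, refined locally
oracle_grid_max <- function(fn, y, v, upper = NULL) {
  if (is.null(upper)) upper <- max(stats::var(y) * 5, 1) + max(v)
  grid <- seq(0, upper, length.out = 2001)
  vals <- vapply(grid, fn, numeric(1), y = y, v = v)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimise(fn, c(lo, hi), y = y, v = v, maximum = TRUE,
                         tol = 1e-12)
  if (fn(0, y, v) >= opt$objective) 0 else opt$maximum
}

# random meta-analysis instance on the simulation's scale
rand_meta <- function(k, tau2 = NULL) {
  if (is.null(tau2)) tau2 <- stats::runif(1, 0, 0.3)
  v <- sim_within_var(k)
  theta <- stats::rnorm(k, 0.5, sqrt(tau2))
  list(y = theta + stats::rnorm(k, 0, sqrt(v)), v = v,
       n = sample(50:500, k, replace = TRUE), tau2 = tau2)
}

canon_y <- c(0, 2)
canon_v <- c(1, 1)
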