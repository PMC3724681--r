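test_that("the canonical two-study instance pins the estimator family", {
  expect_equal(tau2_estimate(canon_y, canon_v, "DL")$tau2, 1)
  expect_equal(tau2_estimate(canon_y, canon_v, "VC")$tau2, 1)
  expect_equal(tau2_estimate(canon_y, canon_v, "REML")$tau2, 1, tolerance = 1e-8)
  expect_equal(tau2_estimate(canon_y, canon_v, "MVa")$tau2, 1)
  expect_equal(tau2_estimate(canon_y, canon_v, "ML")$tau2, 0)
  expect_equal(tau2_estimate(canon_y, canon_v, "DLi")$tau2, 1)
})

test_that("closed-form estimators equal independent transcriptions on random instances", {
  set.seed(101)
  for (i in 1:300) {
    k <- sample(2:30, 1)
    m <- rand_meta(k)
    expect_equal(tau2_estimate(m$y, m$v, "DL")$tau2, oracle_dl(m$y, m$v),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "VC")$tau2, oracle_vc(m$y, m$v),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "DL2")$tau2,
                 oracle_two_step(m$y, m$v, oracle_dl(m$y, m$v)),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "VC2")$tau2,
                 oracle_two_step(m$y, m$v, oracle_vc(m$y, m$v)),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "MVa")$tau2, oracle_mva(m$y, m$v),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "MVb")$tau2, oracle_mvb(m$y, m$v),
                 tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "B0", ni = m$n)$tau2,
                 oracle_b0(m$y, m$v, m$n), tolerance = 1e-10)
    expect_equal(tau2_estimate(m$y, m$v, "BP")$tau2, oracle_bp(m$y, m$v),
                 tolerance = 1e-10)
    dl <- oracle_dl(m$y, m$v)
    expect_equal(tau2_estimate(m$y, m$v, "DLi")$tau2,
                 if (dl > 0) dl else 0.01, tolerance = 1e-10)
  }
})

test_that("moment estimators agree with an established implementation", {
  library(metafor)
  set.seed(102)
  for (i in 1:25) {
    k <- sample(3:20, 1)
    m <- rand_meta(k)
    for (pair in list(c("DL", "DL"), c("VC", "HE"), c("MVa", "SJ"))) {
      ours <- tau2_estimate(m$y, m$v, pair[1])$tau2
      ref <- rma(yi = m$y, vi = m$v, method = pair[2])$tau2
      expect_equal(ours, ref, tolerance = 1e-6)
    }
  }
})

test_that("likelihood estimators maximise their stated likelihoods", {
  library(metafor)
  set.seed(103)
  for (i in 1:40) {
    k <- sample(3:25, 1)
    m <- rand_meta(k)
    ml <- tau2_estimate(m$y, m$v, "ML")
    reml <- tau2_estimate(m$y, m$v, "REML")
    if (ml$converged) {
      expect_lt(abs(ml$tau2 - oracle_grid_max(oracle_ll, m$y, m$v)), 1e-4)
      ref <- rma(yi = m$y, vi = m$v, method = "ML",
                 control = list(tau2.max = 100))$tau2
      expect_lt(abs(ml$tau2 - ref), 1e-4)
    }
    if (reml$converged) {
      expect_lt(abs(reml$tau2 - oracle_grid_max(oracle_rll, m$y, m$v)), 1e-4)
      ref <- rma(yi = m$y, vi = m$v, method = "REML",
                 control = list(tau2.max = 100))$tau2
      expect_lt(abs(reml$tau2 - ref), 1e-4)
    }
  }
  # canonical instance: ML maximum at the boundary, REML interior at 1
  expect_equal(oracle_grid_max(oracle_ll, canon_y, canon_v), 0)
  expect_equal(oracle_grid_max(oracle_rll, canon_y, canon_v), 1,
               tolerance = 1e-6)
})

test_that("homogeneous input yields zero for zero-or-positive and floors for positive-only", {
  y <- rep(0.7, 6); v <- runif(6, 0.05, 0.4)
  for (m in c("DL", "DL2", "VC", "VC2", "ML", "REML")) {
    r <- tau2_estimate(y, v, m)
    expect_equal(r$tau2, 0, info = m)
  }
  expect_true(tau2_estimate(y, v, "DL")$truncated)
  expect_equal(tau2_estimate(y, v, "DLi")$tau2, 0.01)
  expect_equal(tau2_estimate(y, v, "DLb", boot_reps = 50, seed = 1)$tau2, 0)
  # MVa fails outright when all effects are equal (tagged, not an error)
  mva <- tau2_estimate(y, v, "MVa")
  expect_true(is.na(mva$tau2))
  # MVb falls back to the 0.01 denominator and stays positive
  expect_gt(tau2_estimate(y, v, "MVb")$tau2, 0)
  expect_equal(tau2_estimate(y, v, "B0", ni = rep(100, 6))$tau2, 0)
})

test_that("bootstrapped DL matches exhaustive enumeration of resamples", {
  # k = 2 canonical: resamples {11},{22} give 0 and {12},{21} give DL = 1
  expect_equal(dlb_exact(canon_y, canon_v), 0.5)
  got <- tau2_estimate(canon_y, canon_v, "DLb", boot_reps = 1e5, seed = 4)$tau2
  mc_se <- 0.5 / sqrt(1e5)   # bound: resample values are in {0, 1}
  expect_lt(abs(got - 0.5), 3 * mc_se)

  # k = 3: mean over all 27 ordered resamples
  set.seed(104)
  m <- rand_meta(3, tau2 = 0.1)
  exact <- dlb_exact(m$y, m$v)
  draws <- replicate(40, dlb_mean(m$y, m$v, 500))
  est <- mean(draws); se <- sd(draws) / sqrt(40)
  expect_lt(abs(est - exact), 4 * se + 1e-8)
})

test_that("DLb is seed-reproducible and leaves the global RNG untouched", {
  set.seed(105); m <- rand_meta(6, 0.05)
  a <- tau2_estimate(m$y, m$v, "DLb", boot_reps = 200, seed = 9)$tau2
  set.seed(42); before <- runif(1)
  b <- tau2_estimate(m$y, m$v, "DLb", boot_reps = 200, seed = 9)$tau2
  expect_identical(a, b)
  set.seed(42)
  expect_identical(runif(1), before)
})

test_that("estimator invariants hold across random inputs", {
  set.seed(106)
  for (i in 1:60) {
    k <- sample(2:15, 1)
    m <- rand_meta(k)
    for (meth in c("DL", "DL2", "VC", "VC2", "ML", "REML", "MVa", "MVb", "BP")) {
      r <- tau2_estimate(m$y, m$v, meth)
      if (!is.na(r$tau2)) expect_gte(r$tau2, 0)
    }
    expect_gte(tau2_estimate(m$y, m$v, "B0", ni = m$n)$tau2, 0)
    expect_gt(tau2_estimate(m$y, m$v, "BP")$tau2, 0)
    dli <- tau2_estimate(m$y, m$v, "DLi")$tau2
    dl <- tau2_estimate(m$y, m$v, "DL")$tau2
    expect_true((dl > 0 && dli == dl) || dli == 0.01)
    # DL = 0 exactly when Q <= k - 1
    Q <- oracle_Q(m$y, m$v)
    expect_identical(tau2_estimate(m$y, m$v, "DL")$tau2 == 0, Q <= k - 1)
  }
})

test_that("ML/REML interior solutions zero their score updates", {
  set.seed(107)
  for (i in 1:20) {
    m <- rand_meta(sample(4:20, 1), tau2 = runif(1, 0.05, 0.3))
    for (reml in c(FALSE, TRUE)) {
      fit <- ml_reml_fit(m$y, m$v, reml = reml)
      if (!fit$converged || fit$tau2 == 0) next
      w <- 1 / (m$v + fit$tau2)
      mu <- sum(w * m$y) / sum(w)
      upd <- sum(w^2 * ((m$y - mu)^2 - m$v)) / sum(w^2)
      if (reml) upd <- upd + 1 / sum(w)
      expect_lt(abs(upd - fit$tau2), 1e-8)
    }
  }
})

test_that("B0 requires study sizes and truncates negative values", {
  expect_error(tau2_estimate(canon_y, canon_v, "B0"), "subjects")
  # homogeneous effects with large within-variances force Eq-12 negative
  r <- tau2_estimate(c(0.5, 0.5, 0.5), rep(0.5, 3), "B0", ni = c(50, 60, 70))
  expect_equal(r$tau2, 0)
  expect_true(r$truncated)
})
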