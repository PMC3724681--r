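test_that("continuous effects match their defining formulas", {
  d <- data.frame(study_id = 1:2, design = "continuous",
                  n1 = c(10, 50), mean1 = c(1, 2), sd1 = c(1, 2),
                  n2 = c(10, 50), mean2 = c(1, 1), sd2 = c(1, 2))
  ef <- compute_effects(d, "MD")
  expect_equal(ef$yi, c(0, 1))
  expect_equal(ef$vi, c(0.2, 0.16))

  # random arm summaries against a direct transcription
  set.seed(11)
  for (i in 1:50) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, .2, 3); s2 <- runif(1, .2, 3)
    row <- data.frame(study_id = 1, design = "continuous", n1 = n1,
                      mean1 = m1, sd1 = s1, n2 = n2, mean2 = m2, sd2 = s2)
    md <- compute_effects(row, "MD")
    expect_equal(md$yi, m1 - m2)
    expect_equal(md$vi, s1^2 / n1 + s2^2 / n2)
    g <- compute_effects(row, "SMD")
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    gg <- (1 - 3 / (4 * (n1 + n2) - 9)) * (m1 - m2) / sp
    expect_equal(g$yi, gg)
    expect_equal(g$vi, (n1 + n2) / (n1 * n2) + gg^2 / (2 * (n1 + n2 - 3.94)))
  }
})

test_that("dichotomous effects follow the documented continuity and exclusion rules", {
  sym <- data.frame(study_id = 1, design = "dichotomous",
                    a = 5, n1 = 10, c = 5, n2 = 10)
  ef <- compute_effects(sym, "logOR")
  expect_equal(ef$yi, 0)
  expect_equal(ef$vi, 0.8)

  # one zero cell: 0.5 added to all four cells
  z1 <- data.frame(study_id = 1, design = "dichotomous",
                   a = 0, n1 = 10, c = 5, n2 = 10)
  ef <- compute_effects(z1, "logOR")
  expect_equal(ef$yi, log(0.5 * 5.5 / (10.5 * 5.5)))
  expect_equal(ef$vi, 1 / 0.5 + 1 / 10.5 + 1 / 5.5 + 1 / 5.5)

  # double-zero: excluded for ratio measures, retained (flagged) for RD
  z2 <- data.frame(study_id = 1, design = "dichotomous",
                   a = 0, n1 = 10, c = 0, n2 = 10)
  expect_true(compute_effects(z2, "logOR")$excluded)
  expect_true(compute_effects(z2, "logRR")$excluded)
  rd <- compute_effects(z2, "RD")
  expect_equal(rd$yi, 0)

  # RD has no correction
  rd1 <- compute_effects(z1, "RD")
  expect_equal(rd1$yi, 0 - 0.5)
  expect_equal(rd1$vi, 0 + 5 * 5 / 1000)
})

test_that("the continuity correction is idempotent on corrected counts", {
  cc1 <- continuity_correct(0, 10, 5, 5)
  cc2 <- do.call(continuity_correct, cc1)
  expect_identical(cc1, cc2)
  expect_identical(continuity_correct(1, 2, 3, 4), list(a = 1, b = 2, c = 3, d = 4))
})

test_that("swapping arm order negates effects and preserves variances", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(10:100, 1); n2 <- sample(10:100, 1)
    a <- sample(1:(n1 - 1), 1); c <- sample(1:(n2 - 1), 1)
    fwd <- data.frame(study_id = 1, design = "dichotomous",
                      a = a, n1 = n1, c = c, n2 = n2)
    rev <- data.frame(study_id = 1, design = "dichotomous",
                      a = c, n1 = n2, c = a, n2 = n1)
    for (ms in c("logOR", "logRR", "RD")) {
      f <- compute_effects(fwd, ms); r <- compute_effects(rev, ms)
      expect_equal(f$yi, -r$yi)
      expect_equal(f$vi, r$vi)
    }
    mf <- data.frame(study_id = 1, design = "continuous", n1 = n1, mean1 = 1,
                     sd1 = 1.3, n2 = n2, mean2 = 0.4, sd2 = 0.8)
    mr <- transform(mf, n1 = n2, mean1 = 0.4, sd1 = 0.8,
                    n2 = n1, mean2 = 1, sd2 = 1.3)
    expect_equal(compute_effects(mf, "MD")$yi, -compute_effects(mr, "MD")$yi)
    expect_equal(compute_effects(mf, "MD")$vi, compute_effects(mr, "MD")$vi)
  }
})

test_that("Peto components match hand evaluation and flag empty margins", {
  pc <- peto_components(5, 5, 5, 5)
  expect_equal(pc$O_minus_E, 0)
  expect_equal(pc$V, 10 * 10 * 10 * 10 / (400 * 19))

  pc <- peto_components(10, 0, 0, 10)
  expect_equal(pc$O_minus_E, 5)
  expect_equal(pc$V, 10 * 10 * 10 * 10 / (400 * 19))

  expect_equal(peto_components(0, 10, 0, 10)$V, 0)
  d <- data.frame(study_id = 1, design = "dichotomous",
                  a = 0, n1 = 10, c = 0, n2 = 10)
  expect_true(compute_effects(d, "logPetoOR")$excluded)
})

test_that("every non-excluded effect has positive variance", {
  set.seed(31)
  for (i in 1:30) {
    k <- sample(2:8, 1)
    n1 <- sample(5:60, k, TRUE); n2 <- sample(5:60, k, TRUE)
    d <- data.frame(study_id = 1:k, design = "dichotomous",
                    a = rbinom(k, n1, runif(k, 0, 0.3)), n1 = n1,
                    c = rbinom(k, n2, runif(k, 0, 0.3)), n2 = n2)
    for (ms in c("logOR", "logRR", "RD", "logPetoOR")) {
      ef <- compute_effects(d, ms)
      expect_true(all(ef$vi[!ef$excluded] > 0))
    }
  }
})

test_that("record validation enforces the design invariants", {
  expect_error(validate_studies(data.frame(study_id = 1, design = "widget")),
               "unknown design")
  expect_error(validate_studies(
    data.frame(study_id = 1, design = "dichotomous",
               a = 11, n1 = 10, c = 1, n2 = 10)), "events")
  expect_error(validate_studies(
    data.frame(study_id = 1, design = "precomputed",
               effect = 1, variance = 0)), "variance")
  expect_error(validate_studies(
    data.frame(study_id = 1, design = "continuous", n1 = 1, mean1 = 0,
               sd1 = 1, n2 = 10, mean2 = 0, sd2 = 1)), "n >= 2")
})

test_that("reading a study CSV round-trips and fills n_total", {
  f <- tempfile(fileext = ".csv")
  d <- data.frame(study_id = c("s1", "s2"), design = "dichotomous",
                  a = c(3, 4), n1 = c(20, 30), c = c(5, 2), n2 = c(25, 28))
  write.csv(d, f, row.names = FALSE)
  got <- read_studies(f)
  expect_equal(got$n_total, c(45, 58))
  expect_equal(got$a, d$a)
})
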