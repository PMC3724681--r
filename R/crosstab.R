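#' Generate a synthetic corpus of meta-analyses
#'
#' Builds a corpus of continuous-outcome and dichotomous (2x2) meta-analyses
#' in the study CSV dialect of [read_studies()], as a synthetic stand-in for
#' a large database of published meta-analyses.  Meta-analysis sizes are
#' drawn from a 2-3-heavy distribution (by default 55% of analyses have two
#' or three studies, the remainder decaying geometrically up to `k_max`);
#' each analysis draws a true between-study variance from `tau2_mix`
#' (a point mass at zero included) and a true overall effect from
#' `N(0, effect_sd^2)`.  Each analysis is assigned a declared baseline model
#' (`"FE"` or `"RE"`) to mimic reviewer model choice, an analysis `approach`
#' (`IV` for continuous outcomes; `MH` or `Peto` for dichotomous), and an
#' `alpha` level.
#'
#' @param n_analyses number of meta-analyses.
#' @param p_small probability that an analysis has 2 or 3 studies.
#' @param k_max maximum number of studies.
#' @param tau2_mix data frame with columns `tau2` and `prob` (mixture over
#'   true heterogeneity values).
#' @param p_dichotomous share of dichotomous-outcome analyses.
#' @param p_peto share of dichotomous analyses assigned the Peto approach.
#' @param p_fe_baseline probability an analysis declares a fixed-effect
#'   baseline.
#' @param effect_sd standard deviation of true overall effects across
#'   analyses.
#' @param seed integer seed; the same seed yields an identical corpus.
#' @return data frame, one row per study, with `analysis_id`, `approach`,
#'   `baseline_model`, `alpha`, `tau2_true`, and the study-record columns.
#' @export
generate_corpus <- function(n_analyses = 200, p_small = 0.55, k_max = 20,
                            tau2_mix = data.frame(
                              tau2 = c(0, 0.01, 0.03, 0.10),
                              prob = c(0.4, 0.2, 0.2, 0.2)),
                            p_dichotomous = 0.5, p_peto = 0.15,
                            p_fe_baseline = 0.6, effect_sd = 0.3,
                            seed = 1) {
  stopifnot(nrow(tau2_mix) >= 1, all(tau2_mix$prob >= 0))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ## sizes: mass p_small split between k = 2 and 3, geometric tail above
  tail_k <- 4:k_max
  tail_p <- 0.65^(tail_k - 4)
  sizes <- c(2, 3, tail_k)
  probs <- c(p_small * 0.55, p_small * 0.45,
             (1 - p_small) * tail_p / sum(tail_p))

  rows <- vector("list", n_analyses)
  for (a in seq_len(n_analyses)) {
    k <- sample(sizes, 1, prob = probs)
    tau2 <- sample(tau2_mix$tau2, 1, prob = tau2_mix$prob)
    mu_a <- stats::rnorm(1, 0, effect_sd)
    theta <- stats::rnorm(k, mu_a, sqrt(tau2))
    dich <- stats::runif(1) < p_dichotomous
    approach <- if (!dich) "IV" else
      if (stats::runif(1) < p_peto) "Peto" else "MH"
    baseline <- if (stats::runif(1) < p_fe_baseline) "FE" else "RE"
    if (dich) {
      n1 <- sample(20:200, k, replace = TRUE)
      n2 <- sample(20:200, k, replace = TRUE)
      p0 <- stats::runif(1, 0.05, 0.4)          # control-arm risk
      p1 <- stats::plogis(stats::qlogis(p0) + theta)
      rows[[a]] <- data.frame(
        analysis_id = a, study_id = paste0(a, "_", seq_len(k)),
        design = "dichotomous", approach = approach,
        baseline_model = baseline, alpha = 0.05, tau2_true = tau2,
        a = stats::rbinom(k, n1, p1), n1 = n1,
        c = stats::rbinom(k, n2, p0), n2 = n2,
        stringsAsFactors = FALSE)
    } else {
      n1 <- sample(20:150, k, replace = TRUE)
      n2 <- sample(20:150, k, replace = TRUE)
      rows[[a]] <- data.frame(
        analysis_id = a, study_id = paste0(a, "_", seq_len(k)),
        design = "continuous", approach = "IV",
        baseline_model = baseline, alpha = 0.05, tau2_true = tau2,
        n1 = n1, mean1 = theta + stats::rnorm(k, 0, 1 / sqrt(n1)),
        sd1 = sqrt(stats::rchisq(k, n1 - 1) / (n1 - 1)),
        n2 = n2, mean2 = stats::rnorm(k, 0, 1 / sqrt(n2)),
        sd2 = sqrt(stats::rchisq(k, n2 - 1) / (n2 - 1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    need <- c("analysis_id", "study_id", "design", "approach",
              "baseline_model", "alpha", "tau2_true", "a", "n1", "mean1",
              "sd1", "c", "n2", "mean2", "sd2")
    for (cl in setdiff(need, names(r))) r[[cl]] <- NA
    r[need]
  }))
  rownames(out) <- NULL
  out
}

## Fit one analysis of the corpus under one candidate method, given the
## approach-appropriate fixed fit and effects.
fit_candidate <- function(method, ef, fixed, ni, alpha, boot_reps, seed) {
  level <- 1 - alpha
  if (fixed$conclusion == "NoComp" || sum(!ef$excluded) < 2)
    return(list(tau2 = NA_real_, mu = NA_real_, se = NA_real_,
                conclusion = "NoComp"))
  yi <- ef$yi[!ef$excluded]; vi <- ef$vi[!ef$excluded]
  ni <- ni[!ef$excluded]
  if (method == "FE")
    return(list(tau2 = 0, mu = fixed$mu, se = fixed$se,
                conclusion = conclusion_from_ci(fixed$mu, fixed$se, level)))
  if (method == "PL") {
    pl <- pl_estimate(yi, vi, level)
    return(list(tau2 = pl$tau2, mu = pl$mu, se = pl$se,
                conclusion = if (!pl$converged) "NoConv" else
                  if (pl$ci.lb > 0 || pl$ci.ub < 0) "Sig" else "NS"))
  }
  t2 <- tau2_estimate(yi, vi, method, ni = ni, theta_f = fixed$mu,
                      boot_reps = boot_reps, seed = seed)
  if (is.na(t2$tau2))
    return(list(tau2 = NA_real_, mu = NA_real_, se = NA_real_,
                conclusion = "NoComp"))
  if (isFALSE(t2$converged))
    return(list(tau2 = t2$tau2, mu = NA_real_, se = NA_real_,
                conclusion = "NoConv"))
  p <- pool_at(yi, vi, t2$tau2, level)
  list(tau2 = t2$tau2, mu = p$mu, se = p$se,
       conclusion = conclusion_from_ci(p$mu, p$se, level))
}

#' Re-analyse a corpus under a set of heterogeneity methods
#'
#' For every analysis in a corpus: computes study effects on the
#' approach-appropriate scale (mean difference for continuous outcomes, log
#' odds ratio for Mantel-Haenszel, log Peto odds ratio for Peto), fits the
#' approach's fixed-effect model, computes the DerSimonian-Laird estimate
#' with Q centred at that fixed estimate, assigns the analysis to a baseline
#' stratum, and evaluates the statistical conclusion of every candidate
#' method.  Strata are: `"FE tau2=0"` (no heterogeneity detected; the
#' random-effects DL model reduces to fixed-effect), `"FE tau2>0"`
#' (heterogeneity detected but the declared baseline ignores it) and
#' `"RE tau2>0"` (heterogeneity detected and modelled).  When the corpus
#' does not declare `baseline_model`, the baseline is FE when the DL
#' estimate is zero and RE-DL otherwise.
#'
#' @param corpus data frame from [generate_corpus()] or [read_studies()]
#'   with an `analysis_id` column.
#' @param methods candidate method labels (see [hetmeta()]).
#' @param alpha default significance level when the corpus has no `alpha`
#'   column.
#' @param seed integer seed (drives DLb resampling only).
#' @param boot_reps bootstrap replicates for `"DLb"`.
#' @return data frame with one row per (analysis, method): `analysis_id`,
#'   `approach`, `k`, `tau2_dl`, `baseline_model`, `stratum`,
#'   `baseline_conclusion`, `method`, `tau2`, `mu`, `se`, `conclusion`.
#' @export
run_method_matrix <- function(corpus, methods = c("FE", "DL", "DLb"),
                              alpha = 0.05, seed = 1, boot_reps = 1000L) {
  stopifnot("analysis_id" %in% names(corpus))
  ids <- unique(corpus$analysis_id)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    an <- corpus[corpus$analysis_id == ids[j], , drop = FALSE]
    approach <- if (!is.null(an$approach)) an$approach[1] else
      if (an$design[1] == "continuous") "IV" else "MH"
    a_level <- if (!is.null(an$alpha)) an$alpha[1] else alpha
    measure <- switch(approach, IV = if (an$design[1] == "continuous")
      "MD" else "logOR", MH = "logOR", Peto = "logPetoOR")
    ef <- tryCatch(compute_effects(an, measure), error = function(e) NULL)
    if (is.null(ef)) next                     # unparseable analysis: skip
    fixed <- switch(approach,
      IV = if (sum(!ef$excluded) >= 1)
        pool_iv_fixed(ef, level = 1 - a_level) else
          not_computable(measure, "IV"),
      MH = pool_mh(an, "logOR", level = 1 - a_level),
      Peto = pool_peto(an, level = 1 - a_level))
    k_eff <- sum(!ef$excluded)

    computable <- fixed$conclusion != "NoComp" && k_eff >= 2
    tau2_dl <- if (computable)
      tau2_estimate(ef$yi[!ef$excluded], ef$vi[!ef$excluded], "DL",
                    theta_f = fixed$mu)$tau2 else NA_real_
    declared <- if (!is.null(an$baseline_model)) an$baseline_model[1] else
      if (isTRUE(tau2_dl > 0)) "RE" else "FE"
    baseline <- if (isTRUE(tau2_dl == 0)) "FE" else declared
    stratum <- if (!computable) NA_character_
      else if (tau2_dl == 0) "FE tau2=0"
      else if (baseline == "FE") "FE tau2>0" else "RE tau2>0"
    base_con <- if (!computable) "NoComp"
      else if (baseline == "FE")
        conclusion_from_ci(fixed$mu, fixed$se, 1 - a_level)
      else {
        p <- pool_at(ef$yi[!ef$excluded], ef$vi[!ef$excluded], tau2_dl,
                     1 - a_level)
        conclusion_from_ci(p$mu, p$se, 1 - a_level)
      }

    rws <- lapply(methods, function(m) {
      fc <- fit_candidate(m, ef, fixed, ef$ni, a_level, boot_reps,
                          seed + 131L * j)
      data.frame(analysis_id = ids[j], approach = approach, k = k_eff,
                 tau2_dl = tau2_dl, baseline_model = baseline,
                 stratum = stratum, baseline_conclusion = base_con,
                 method = m, tau2 = fc$tau2, mu = fc$mu, se = fc$se,
                 conclusion = fc$conclusion, stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, rws)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate candidate conclusions against the baseline
#'
#' Contingency counts of candidate-method conclusions against baseline
#' conclusions, per baseline stratum, with cell percentages within each
#' stratum and the share of computable analyses whose conclusion changed.
#'
#' @param results output of [run_method_matrix()].
#' @param candidate method label to tabulate.
#' @return object of class `"crosstab"`: list with `table` (data frame of
#'   `stratum`, `baseline_conclusion`, `conclusion`, `count`, `cell_pct`),
#'   `pct_changed` (named by stratum) and `candidate`.
#' @export
conclusion_crosstab <- function(results, candidate) {
  r <- results[results$method == candidate & !is.na(results$stratum), ,
               drop = FALSE]
  if (!nrow(r)) stop("no computable analyses for candidate '", candidate, "'")
  tab <- as.data.frame(table(stratum = r$stratum,
                             baseline_conclusion = r$baseline_conclusion,
                             conclusion = r$conclusion),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  tot <- stats::ave(tab$count, tab$stratum, FUN = sum)
  tab$cell_pct <- ifelse(tot > 0, 100 * tab$count / tot, 0)
  tab <- tab[order(tab$stratum, tab$baseline_conclusion, tab$conclusion), ]
  rownames(tab) <- NULL

  ok <- r$conclusion %in% c("NS", "Sig") &
    r$baseline_conclusion %in% c("NS", "Sig")
  ch <- tapply(r$conclusion[ok] != r$baseline_conclusion[ok],
               r$stratum[ok], function(z) 100 * mean(z))
  ch <- stats::setNames(as.numeric(ch), names(ch))
  structure(list(table = tab, pct_changed = ch, candidate = candidate),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Conclusion cross-tabulation, candidate =", x$candidate, "\n")
  nz <- x$table[x$table$count > 0, , drop = FALSE]
  print(nz, row.names = FALSE)
  cat("\n% conclusions changed by stratum:\n")
  print(round(x$pct_changed, 2))
  invisible(x)
}
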