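#' Read study-level meta-analysis data from CSV
#'
#' Reads a CSV file with one row per study.  Required columns are `study_id`
#' and `design` (one of `"continuous"`, `"dichotomous"`, `"precomputed"`).
#' Depending on the design, rows must carry the arm summaries
#' (`n1,mean1,sd1,n2,mean2,sd2` for continuous outcomes; events and totals
#' `a,n1,c,n2` for dichotomous outcomes) or a precomputed `effect` and
#' `variance`.  An optional `n_total` column gives the number of subjects in
#' each study (needed by the Rukhin B0 estimator); when absent it defaults to
#' `n1 + n2` where those are available.  An optional `analysis_id` column
#' groups studies into meta-analyses.
#'
#' @param file path to a CSV file (header required, UTF-8).
#' @return A data frame of study records, validated.
#' @seealso [compute_effects()]
#' @export
read_studies <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_studies(df)
}

#' Validate a data frame of study records
#'
#' Checks the invariants each design must satisfy: positive totals and
#' `0 <= events <= total` for dichotomous rows, `sd > 0` and `n >= 2` per arm
#' for continuous rows, `variance > 0` for precomputed rows.  Fills in
#' `n_total` from arm sizes where missing.
#'
#' @param df data frame of study records (see [read_studies()] for columns).
#' @return The validated (and possibly augmented) data frame.
#' @export
validate_studies <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("study data must be a non-empty data frame")
  if (!all(c("study_id", "design") %in% names(df)))
    stop("study data must have 'study_id' and 'design' columns")
  bad <- setdiff(unique(df$design), c("continuous", "dichotomous", "precomputed"))
  if (length(bad))
    stop("unknown design(s): ", paste(bad, collapse = ", "))

  need <- function(cols, rows, what) {
    if (!all(cols %in% names(df)))
      stop(what, " rows need columns: ", paste(cols, collapse = ", "))
    for (cl in cols)
      if (anyNA(df[rows, cl]))
        stop("missing values in '", cl, "' for ", what, " rows")
  }
  ic <- df$design == "continuous"
  if (any(ic)) {
    need(c("n1", "mean1", "sd1", "n2", "mean2", "sd2"), ic, "continuous")
    if (any(df$n1[ic] < 2 | df$n2[ic] < 2))
      stop("continuous studies need n >= 2 per arm")
    if (any(df$sd1[ic] < 0 | df$sd2[ic] < 0))
      stop("continuous studies need sd >= 0")
  }
  id <- df$design == "dichotomous"
  if (any(id)) {
    need(c("a", "n1", "c", "n2"), id, "dichotomous")
    if (any(df$n1[id] < 1 | df$n2[id] < 1))
      stop("dichotomous studies need totals >= 1")
    if (any(df$a[id] < 0 | df$a[id] > df$n1[id] |
            df$c[id] < 0 | df$c[id] > df$n2[id]))
      stop("dichotomous studies need 0 <= events <= total in each arm")
  }
  ip <- df$design == "precomputed"
  if (any(ip)) {
    need(c("effect", "variance"), ip, "precomputed")
    if (any(df$variance[ip] <= 0))
      stop("precomputed studies need variance > 0")
  }
  if (is.null(df$n_total)) df$n_total <- NA_real_
  fill <- is.na(df$n_total) & (ic | id)
  df$n_total[fill] <- df$n1[fill] + df$n2[fill]
  df
}

## 2x2 cells from a dichotomous record: a = events arm 1, b = non-events arm 1,
## c = events arm 2, d = non-events arm 2.
cells_2x2 <- function(rec) {
  list(a = rec$a, b = rec$n1 - rec$a, c = rec$c, d = rec$n2 - rec$c,
       n1 = rec$n1, n2 = rec$n2, N = rec$n1 + rec$n2)
}

## +0.5 to all four cells when any cell is zero (documented continuity rule,
## applied for ratio measures only).  Idempotent on corrected counts: after
## correction no cell is zero, so a second pass changes nothing.
continuity_correct <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(a = a, b = b, c = c, d = d)
}

effect_md <- function(n1, m1, s1, n2, m2, s2) {
  list(yi = m1 - m2, vi = s1^2 / n1 + s2^2 / n2)
}

## Hedges' g with the small-sample correction and the variance used by the
## software whose documentation is followed here: N/(n1 n2) + g^2/(2(N-3.94)).
effect_smd <- function(n1, m1, s1, n2, m2, s2) {
  N <- n1 + n2
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (N - 2))
  if (sp == 0) stop("degenerate study: zero standard deviation in both arms")
  j <- 1 - 3 / (4 * N - 9)
  g <- j * (m1 - m2) / sp
  list(yi = g, vi = N / (n1 * n2) + g^2 / (2 * (N - 3.94)))
}

#' Per-study effect estimates on the analysis scale
#'
#' Converts raw study summaries into effect estimates `yi` and within-study
#' variances `vi`.  Ratio measures (`logOR`, `logRR`, `logPetoOR`) are
#' returned on the log scale.  For `logOR`/`logRR`, 0.5 is added to all four
#' cells of a 2x2 table whenever any cell is zero, and studies with zero
#' events in both arms are flagged `excluded` (they carry no information on a
#' ratio scale); `RD` is computed without correction and double-zero studies
#' are retained.  `logPetoOR` uses the one-step (O - E)/V approximation.
#'
#' @param records data frame of study records (see [read_studies()]).
#' @param measure one of `"MD"`, `"SMD"`, `"logOR"`, `"logRR"`, `"RD"`,
#'   `"logPetoOR"`.  Precomputed rows pass through unchanged for any measure.
#' @param continuity continuity-correction constant added to all four cells
#'   of a table containing a zero cell (ratio measures only).  Default 0.5.
#' @return A data frame with columns `study_id`, `yi`, `vi`, `ni` (subjects),
#'   `excluded` (logical) and `reason`; the measure is recorded as an
#'   attribute.  Non-excluded rows always have `vi > 0`.
#' @examples
#' d <- data.frame(study_id = 1:2, design = "dichotomous",
#'                 a = c(5, 8), n1 = c(10, 20), c = c(5, 4), n2 = c(10, 20))
#' compute_effects(d, "logOR")
#' @export
compute_effects <- function(records,
                            measure = c("MD", "SMD", "logOR", "logRR", "RD",
                                        "logPetoOR"),
                            continuity = 0.5) {
  measure <- match.arg(measure)
  records <- validate_studies(records)
  k <- nrow(records)
  yi <- vi <- rep(NA_real_, k)
  excluded <- rep(FALSE, k)
  reason <- rep(NA_character_, k)

  for (i in seq_len(k)) {
    rec <- records[i, ]
    if (rec$design == "precomputed") {
      yi[i] <- rec$effect; vi[i] <- rec$variance
      next
    }
    if (rec$design == "continuous") {
      if (!measure %in% c("MD", "SMD"))
        stop("measure '", measure, "' needs dichotomous data")
      e <- if (measure == "MD")
        effect_md(rec$n1, rec$mean1, rec$sd1, rec$n2, rec$mean2, rec$sd2)
      else
        effect_smd(rec$n1, rec$mean1, rec$sd1, rec$n2, rec$mean2, rec$sd2)
      if (e$vi <= 0) stop("degenerate continuous study: non-positive variance")
      yi[i] <- e$yi; vi[i] <- e$vi
      next
    }
    ## dichotomous
    if (!measure %in% c("logOR", "logRR", "RD", "logPetoOR"))
      stop("measure '", measure, "' needs continuous data")
    cc <- cells_2x2(rec)
    if (measure == "logPetoOR") {
      pc <- peto_components(cc$a, cc$b, cc$c, cc$d)
      if (pc$V <= 0) {
        excluded[i] <- TRUE; reason[i] <- "empty margin (Peto V = 0)"
      } else {
        yi[i] <- pc$O_minus_E / pc$V; vi[i] <- 1 / pc$V
      }
      next
    }
    if (measure == "RD") {
      yi[i] <- cc$a / cc$n1 - cc$c / cc$n2
      vi[i] <- cc$a * cc$b / cc$n1^3 + cc$c * cc$d / cc$n2^3
      if (vi[i] <= 0) {       # all-zero or all-event tables: flag, keep row
        excluded[i] <- TRUE; reason[i] <- "zero variance (degenerate table)"
      }
      next
    }
    ## logOR / logRR
    if (cc$a == 0 && cc$c == 0) {
      excluded[i] <- TRUE; reason[i] <- "zero events in both arms"
      next
    }
    if (cc$b == 0 && cc$d == 0) {
      excluded[i] <- TRUE; reason[i] <- "all events in both arms"
      next
    }
    if (any(c(cc$a, cc$b, cc$c, cc$d) == 0)) {
      cc$a <- cc$a + continuity; cc$b <- cc$b + continuity
      cc$c <- cc$c + continuity; cc$d <- cc$d + continuity
      cc$n1 <- cc$a + cc$b; cc$n2 <- cc$c + cc$d
    }
    if (measure == "logOR") {
      yi[i] <- log(cc$a * cc$d / (cc$b * cc$c))
      vi[i] <- 1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d
    } else {
      yi[i] <- log((cc$a / cc$n1) / (cc$c / cc$n2))
      vi[i] <- 1 / cc$a - 1 / cc$n1 + 1 / cc$c - 1 / cc$n2
    }
  }

  out <- data.frame(study_id = records$study_id, yi = yi, vi = vi,
                    ni = records$n_total, excluded = excluded,
                    reason = reason, stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  out
}

#' Peto one-step components of a 2x2 table
#'
#' Computes the observed-minus-expected number of events in the first arm and
#' its hypergeometric variance: `O - E = a - (a+b)(a+c)/N` and
#' `V = (a+b)(c+d)(a+c)(b+d) / (N^2 (N-1))`.  The per-study log Peto odds
#' ratio is `(O-E)/V` with variance `1/V`.
#'
#' @param a,b,c,d cell counts (events/non-events in arm 1, then arm 2).
#' @return list with elements `O_minus_E` and `V` (`V = 0` flags an empty
#'   margin; such studies are excluded from Peto pooling).
#' @export
peto_components <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N < 2) return(list(O_minus_E = 0, V = 0))
  E <- (a + b) * (a + c) / N
  V <- (a + b) * (c + d) * (a + c) * (b + d) / (N^2 * (N - 1))
  list(O_minus_E = a - E, V = V)
}
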