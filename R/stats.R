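#' Intraclass correlation coefficient
#'
#' Single-measure ICC from a two-way model, computed from the ANOVA mean
#' squares of a subjects x raters table. The default variant is absolute
#' agreement (`ICC(A,1)` in the McGraw-Wong taxonomy, two-way model), which
#' penalizes systematic offsets between raters; `"consistency"` (`ICC(C,1)`)
#' does not. 95% confidence intervals use the F-distribution method
#' (Satterthwaite degrees of freedom for the agreement variant).
#'
#' @param truth,estimate paired measurements per subject (e.g. ground-truth
#'   and pipeline SUVR), or give `ratings` directly.
#' @param ratings optional n x k matrix (k raters) overriding
#'   `truth`/`estimate`.
#' @param variant `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level for the CI.
#' @return list of class `icc_result`: `icc`, `ci` (low, high), `variant`,
#'   `n`, `k`, plus the mean squares.
#' @examples
#' x <- c(1, 1.2, 1.5, 1.1, 1.4, 1.3)
#' icc(x, x + 0.2, variant = "consistency")$icc   # exactly 1
#' @export
icc <- function(truth = NULL, estimate = NULL, ratings = NULL,
                variant = c("agreement", "consistency"),
                conf_level = 0.95) {
  variant <- match.arg(variant)
  if (is.null(ratings)) {
    if (is.null(truth) || is.null(estimate))
      stop("give either `truth` and `estimate`, or `ratings`")
    ratings <- cbind(truth, estimate)
  }
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3) stop("need at least 3 subjects")
  if (k < 2) stop("need at least 2 raters")
  if (!all(is.finite(ratings))) stop("ratings must be finite")
  gm <- mean(ratings)
  if (sum((ratings - gm)^2) <= 0)
    stop("zero total variance: ICC is undefined for constant data")
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  SSR <- k * sum((rowm - gm)^2)
  SSC <- n * sum((colm - gm)^2)
  SSE <- sum((ratings - gm)^2) - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (variant == "consistency") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    df2 <- (n - 1) * (k - 1)
    FL <- Fobs / stats::qf(1 - alpha / 2, n - 1, df2)
    FU <- Fobs * stats::qf(1 - alpha / 2, df2, n - 1)
    ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(n * (MSR - FL * MSE) /
              (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
            n * (FU * MSR - MSE) /
              (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
  }
  structure(list(icc = est, ci = pmin(pmax(ci, -1), 1), variant = variant,
                 n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE,
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measures) = %.4f, %g%% CI [%.4f, %.4f], n = %d, k = %d\n",
              x$variant, x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Pearson correlation with Bonferroni family correction
#'
#' Pearson r with the p-value from the t transform on n - 2 degrees of
#' freedom. `one_sided_negative` tests the alternative r < 0 (half the
#' two-sided p when r is negative, `1 - p/2` otherwise). The adjusted p is
#' `min(1, family_m * p)`.
#'
#' @param x,y numeric vectors.
#' @param sidedness `"two_sided"` or `"one_sided_negative"`.
#' @param family_m Bonferroni family size (1 = no correction).
#' @return list of class `correlation_result`: `r`, `p`, `p_adjusted`,
#'   `sidedness`, `family_m`, `n`.
#' @export
correlate <- function(x, y, sidedness = c("two_sided", "one_sided_negative"),
                      family_m = 1L) {
  sidedness <- match.arg(sidedness)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p2 <- 2 * stats::pt(-abs(tt), df = n - 2)
  p <- if (sidedness == "two_sided") p2 else if (r < 0) p2 / 2 else 1 - p2 / 2
  structure(list(r = r, p = p, p_adjusted = min(1, family_m * p),
                 sidedness = sidedness, family_m = as.integer(family_m),
                 n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, %s), p = %.4g, Bonferroni (m = %d) p = %.4g\n",
              x$r, x$n, x$sidedness, x$p, x$family_m, x$p_adjusted))
  invisible(x)
}

#' Clinical staging from CDR global scores
#'
#' CN is `cdr == 0`. The CDR-based MCI/AD definitions overlap at 0.5, so a
#' CDR of 0.5 is resolved by a `diagnosis` column when the cohort provides
#' one, and labeled `"CDR0.5_unresolved"` otherwise; CDR > 0.5 is AD.
#'
#' @param cohort data.frame with `cdr_global` and optionally `diagnosis`.
#' @return The cohort with a `clinical_stage` column added.
#' @export
stage_subjects <- function(cohort) {
  cdr <- cohort$cdr_global
  stage <- ifelse(cdr == 0, "CN",
                  ifelse(cdr > 0.5, "AD", "CDR0.5_unresolved"))
  if (!is.null(cohort$diagnosis)) {
    half <- !is.na(cdr) & cdr == 0.5 & !is.na(cohort$diagnosis)
    stage[half] <- cohort$diagnosis[half]
  }
  cohort$clinical_stage <- stage
  cohort
}

#' Quintile stratification of cognitive scores
#'
#' Splits scores at their 20/40/60/80th percentiles (linear-interpolation
#' percentile definition; values tied with an edge go to the lower bin) and
#' returns the mean SUVR per quintile and ROI. If all scores are equal the
#' single degenerate bin is flagged.
#'
#' @param scores numeric vector, one per subject.
#' @param suvr_table data.frame with `subject_id`, `roi_role`, `suvr`; rows
#'   are matched to `scores` by `names(scores)` when present, else by order
#'   of unique `subject_id`.
#' @return data.frame with `roi_role`, `quintile` (1 = lowest scores),
#'   `mean_suvr`, `n`; attribute `degenerate` is `TRUE` when all scores tie.
#' @export
quintile_stratify <- function(scores, suvr_table) {
  ids <- if (!is.null(names(scores))) names(scores) else
    unique(suvr_table$subject_id)
  if (length(ids) != length(scores))
    stop("`scores` must have one value per subject in `suvr_table`")
  degenerate <- length(unique(scores)) == 1L
  if (degenerate) {
    bin <- rep(1L, length(scores))
  } else {
    q <- stats::quantile(scores, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
    bin <- as.integer(cut(scores, breaks = c(-Inf, q, Inf), right = TRUE))
  }
  bins <- data.frame(subject_id = ids, quintile = bin,
                     stringsAsFactors = FALSE)
  merged <- merge(suvr_table, bins, by = "subject_id")
  agg <- stats::aggregate(suvr ~ roi_role + quintile, data = merged,
                          FUN = mean)
  cnt <- stats::aggregate(suvr ~ roi_role + quintile, data = merged,
                          FUN = length)
  out <- data.frame(roi_role = agg$roi_role, quintile = agg$quintile,
                    mean_suvr = agg$suvr, n = cnt$suvr,
                    stringsAsFactors = FALSE)
  out <- out[order(out$roi_role, out$quintile), ]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Longitudinal change ratio
#'
#' Relative change in a clinical measure between the earliest and latest
#' visit: `(post - pre) / (pre + 0.1)`. The 0.1 in the denominator guards
#' the probability-valued measures against division by zero and is applied
#' verbatim to all measures.
#'
#' @param pre,post scores at the earliest / latest matched exam.
#' @return The change ratio (vectorized).
#' @export
change_ratio <- function(pre, post) {
  (post - pre) / (pre + 0.1)
}

#' Longitudinal association of baseline tau with cognitive decline
#'
#' For every subject with at least two scans and two exams: baseline SUVR is
#' taken from the earliest scan; Pre and Post scores are the exams matched to
#' the earliest and latest scans by minimum absolute date difference (ties
#' resolved to the earlier exam); the change ratio [change_ratio()] is
#' computed per measure; subjects with any |ratio| > 0.5 are excluded as
#' outliers. Baseline SUVR in each ROI is then correlated with each measure's
#' ratio, Bonferroni-corrected for the `length(rois) * length(measures)`
#' family.
#'
#' @param cohort visit-level data.frame with `subject_id`, `scan_date`,
#'   `exam_date` and the measure columns.
#' @param suvr_table data.frame with `subject_id`, `roi_role`, `suvr`
#'   (baseline scan).
#' @param rois ROI roles to use as baseline predictors.
#' @param measures score columns to follow over time.
#' @param sidedness passed to [correlate()].
#' @return list with `rows` (per-subject baseline SUVR, ratios, follow-up
#'   days, exclusion flag), `results` (one correlation per ROI x measure),
#'   and `excluded` (subject ids dropped, with reasons).
#' @export
longitudinal_analysis <- function(cohort, suvr_table,
                                  rois = c("ec", "itg"),
                                  measures = c("mmse", "moca",
                                               "recall_durable"),
                                  sidedness = "two_sided") {
  family_m <- length(rois) * length(measures)
  excluded <- list()
  rows <- list()
  for (id in unique(cohort$subject_id)) {
    cs <- cohort[cohort$subject_id == id, ]
    scans <- sort(unique(cs$scan_date))
    exams <- cs[order(cs$exam_date), ]
    if (length(scans) < 2 || nrow(exams) < 2) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = id, reason = "single visit")
      next
    }
    match_exam <- function(scan_day) {
      d <- abs(exams$exam_date - scan_day)
      # ties broken toward the earlier exam (exams are date-sorted)
      exams[which.min(d), ]
    }
    pre <- match_exam(scans[1])
    post <- match_exam(scans[length(scans)])
    ratios <- vapply(measures, function(mm)
      change_ratio(pre[[mm]], post[[mm]]), numeric(1))
    out <- any(abs(ratios) > 0.5)
    if (out) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(subject_id = id, reason = "|change ratio| > 0.5")
    }
    base <- suvr_table[suvr_table$subject_id == id, ]
    suvrs <- vapply(rois, function(r) {
      v <- base$suvr[base$roi_role == r]
      if (length(v)) v[1] else NA_real_
    }, numeric(1))
    row <- data.frame(subject_id = id, t(suvrs), t(ratios),
                      followup_days = scans[length(scans)] - scans[1],
                      excluded = out, stringsAsFactors = FALSE)
    names(row) <- c("subject_id", paste0("suvr_", rois),
                    paste0("ratio_", measures), "followup_days", "excluded")
    rows[[length(rows) + 1L]] <- row
  }
  rows <- do.call(rbind, rows)
  kept <- rows[!rows$excluded, , drop = FALSE]
  res <- list()
  for (r in rois) for (mm in measures) {
    xs <- kept[[paste0("suvr_", r)]]
    ys <- kept[[paste0("ratio_", mm)]]
    if (sum(is.finite(xs) & is.finite(ys)) < 3) {
      warning("fewer than 3 subjects remain for ", r, " vs ", mm,
              "; correlation not estimable")
      res[[length(res) + 1L]] <- data.frame(
        roi_role = r, measure = mm, r = NA_real_, p = NA_real_,
        p_adjusted = NA_real_, n = nrow(kept), stringsAsFactors = FALSE)
    } else {
      cr <- correlate(xs, ys, sidedness = sidedness, family_m = family_m)
      res[[length(res) + 1L]] <- data.frame(
        roi_role = r, measure = mm, r = cr$r, p = cr$p,
        p_adjusted = cr$p_adjusted, n = cr$n, stringsAsFactors = FALSE)
    }
  }
  list(rows = rows, results = do.call(rbind, res),
       excluded = if (length(excluded)) do.call(rbind, excluded) else
         data.frame(subject_id = character(0), reason = character(0)))
}

#' Plain-text validation report
#'
#' Formats the pipeline's result tables as an aligned plain-text report:
#' per-ROI ICC with confidence intervals, correlation analyses with raw and
#' Bonferroni-adjusted p-values, and (optionally) the longitudinal
#' change-ratio correlations.
#'
#' @param icc_table data.frame with `roi_role`, `icc`, `ci_low`, `ci_high`
#'   (as returned in `mrfree_validation()$icc`); may be `NULL`.
#' @param correlations data.frame with `roi_role`/`measure`/`r`/`p`/
#'   `p_adjusted` columns (e.g. `longitudinal_analysis()$results`); may be
#'   `NULL`.
#' @param path optional file to write the report to.
#' @return The report as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
validation_report <- function(icc_table = NULL, correlations = NULL,
                              path = NULL) {
  out <- character(0)
  if (!is.null(icc_table)) {
    out <- c(out, "Intraclass correlation of SUVR vs ground truth",
             sprintf("  %-14s %6s   (95%% CI)", "region", "ICC"))
    for (i in seq_len(nrow(icc_table))) {
      out <- c(out, sprintf("  %-14s %6.3f   (%.3f-%.3f)",
                            icc_table$roi_role[i], icc_table$icc[i],
                            icc_table$ci_low[i], icc_table$ci_high[i]))
    }
  }
  if (!is.null(correlations)) {
    out <- c(out, "", "Correlations with clinical measures",
             sprintf("  %-14s %-16s %7s %9s %9s", "region", "measure",
                     "r", "P", "adj. P"))
    for (i in seq_len(nrow(correlations))) {
      out <- c(out, sprintf("  %-14s %-16s %7.3f %9.4g %9.4g",
                            correlations$roi_role[i],
                            correlations$measure[i], correlations$r[i],
                            correlations$p[i], correlations$p_adjusted[i]))
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
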