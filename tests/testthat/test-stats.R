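test_that("ICC reproduces reference values on a fixed table", {
  truth <- c(1.02, 1.15, 1.48, 1.10, 1.85, 1.33)
  est <- c(1.05, 1.12, 1.52, 1.16, 1.78, 1.30)
  # reference values computed independently with pingouin.intraclass_corr
  a <- icc(truth, est, variant = "agreement")
  expect_equal(a$icc, 0.9876290253991566, tolerance = 1e-12)
  expect_equal(round(a$ci, 2), c(0.91, 1.00))
  c1 <- icc(truth, est, variant = "consistency")
  expect_equal(c1$icc, 0.9851914696695069, tolerance = 1e-12)
  expect_equal(round(c1$ci, 2), c(0.90, 1.00))

  expect_equal(icc(truth, truth)$icc, 1)

  # constant offset: consistency stays 1, absolute agreement drops
  sh_a <- icc(truth, truth + 0.2, variant = "agreement")
  sh_c <- icc(truth, truth + 0.2, variant = "consistency")
  expect_equal(sh_c$icc, 1, tolerance = 1e-12)
  expect_equal(sh_a$icc, 0.825749, tolerance = 1e-6)
  expect_lt(sh_a$icc, sh_c$icc)

  expect_error(icc(rep(1, 5), rep(1, 5)), "variance")
  expect_error(icc(c(1, 2), c(1, 2)), "3 subjects")
})

test_that("ICC agrees with an aov() mean-squares oracle on random tables", {
  set.seed(77)
  for (rep in 1:50) {
    tab <- matrix(rnorm(10, mean = 1.5, sd = 0.4), 5, 2)
    tab[, 2] <- tab[, 1] + rnorm(5, sd = 0.2) + rnorm(1, sd = 0.1)
    df <- data.frame(score = as.vector(tab),
                     subject = factor(rep(1:5, 2)),
                     rater = factor(rep(1:2, each = 5)))
    ms <- summary(stats::aov(score ~ subject + rater, data = df))[[1]][["Mean Sq"]]
    MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
    n <- 5; k <- 2
    exp_a <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    exp_c <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    expect_equal(icc(ratings = tab, variant = "agreement")$icc, exp_a,
                 tolerance = 1e-9)
    expect_equal(icc(ratings = tab, variant = "consistency")$icc, exp_c,
                 tolerance = 1e-9)
    res <- icc(ratings = tab)
    expect_true(res$ci[1] <= res$icc && res$icc <= res$ci[2])
    # under a systematic rater offset consistency always >= agreement
    sh <- tab; sh[, 2] <- sh[, 2] + 0.5
    expect_gte(icc(ratings = sh, variant = "consistency")$icc,
               icc(ratings = sh, variant = "agreement")$icc - 1e-9)
  }
})

test_that("Pearson correlation matches the closed form and cor.test", {
  x <- c(0.3, 1.2, -0.5, 2.2, 0.9, -1.4, 0.1, 1.8, -0.2, 0.6)
  y <- c(1.1, -0.7, 0.4, -2.0, -0.3, 1.6, 0.2, -1.1, 0.5, -0.4)
  r <- correlate(x, y)
  ct <- stats::cor.test(x, y)
  expect_equal(r$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)

  expect_equal(correlate(x, -x)$r, -1)

  one <- correlate(x, y, sidedness = "one_sided_negative")
  ct1 <- stats::cor.test(x, y, alternative = "less")
  expect_equal(one$p, ct1$p.value, tolerance = 1e-12)
  pos <- correlate(x, x + rnorm(10, sd = 1e-3),
                   sidedness = "one_sided_negative")
  expect_gt(pos$p, 0.5)

  # Bonferroni bounds
  b <- correlate(x, y, family_m = 8)
  expect_equal(b$p_adjusted, min(1, 8 * b$p))
  expect_gte(b$p_adjusted, b$p)
  expect_lte(b$p_adjusted, 1)
})

test_that("correlation test holds its nominal level under permutation", {
  set.seed(99)
  x <- rnorm(30)
  y <- rnorm(30)
  rej <- vapply(1:1000, function(i) {
    correlate(x, sample(y))$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("CDR staging follows the documented rule", {
  cohort <- data.frame(cdr_global = c(0, 0.5, 1, 2, 0.5),
                       diagnosis = c(NA, NA, NA, NA, "MCI"))
  staged <- stage_subjects(cohort)
  expect_identical(staged$clinical_stage,
                   c("CN", "CDR0.5_unresolved", "AD", "AD", "MCI"))
  # without a diagnosis column the 0.5 tie stays unresolved
  staged2 <- stage_subjects(data.frame(cdr_global = c(0, 0.5)))
  expect_identical(staged2$clinical_stage, c("CN", "CDR0.5_unresolved"))
})

test_that("quintile stratification uses interpolated percentile edges", {
  suvr <- data.frame(subject_id = sprintf("S%02d", 1:10),
                     roi_role = "metatemporal", suvr = seq(1, 2, length = 10))
  scores <- stats::setNames(1:10, sprintf("S%02d", 1:10))
  out <- quintile_stratify(scores, suvr)
  expect_equal(out$n, rep(2, 5))
  expect_false(attr(out, "degenerate"))

  flat <- quintile_stratify(stats::setNames(rep(5, 10), names(scores)), suvr)
  expect_true(attr(flat, "degenerate"))
  expect_equal(unique(flat$quintile), 1L)

  # sort-and-slice oracle on a random cohort
  set.seed(7)
  sc <- stats::setNames(rnorm(50), sprintf("S%02d", 1:50))
  sv <- data.frame(subject_id = names(sc), roi_role = "ec",
                   suvr = runif(50, 1, 2))
  out2 <- quintile_stratify(sc, sv)
  q <- stats::quantile(sc, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  bin <- findInterval(sc, q, left.open = TRUE) + 1L
  for (b in 1:5) {
    expect_equal(out2$mean_suvr[out2$quintile == b],
                 mean(sv$suvr[bin == b]), tolerance = 1e-12)
  }
})

test_that("change ratio implements (post - pre)/(pre + 0.1)", {
  expect_equal(change_ratio(30, 30), 0)
  expect_equal(change_ratio(0, 1), 10)
  expect_equal(change_ratio(30, 27), -3 / 30.1)
  expect_equal(change_ratio(c(30, 0), c(27, 1)), c(-3 / 30.1, 10))
})

test_that("longitudinal analysis matches exams, excludes outliers, ties early", {
  mk <- function(id, scans, exams, mmse) {
    data.frame(subject_id = id, scan_date = scans, exam_date = exams,
               mmse = mmse, moca = mmse, recall_durable = 0.8)
  }
  cohort <- rbind(
    mk("A", c(0, 400), c(5, 395), c(29, 27)),       # ratio -2/29.1
    mk("B", c(0, 400), c(-3, 410), c(10, 19)),      # ratio 9/10.1 -> excluded
    mk("C", c(0, 700), c(10, 690), c(28, 26)))
  suvr <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                     roi_role = rep(c("ec", "itg"), 3),
                     suvr = c(1.2, 1.3, 1.8, 1.9, 1.1, 1.15))
  warns <- capture_warnings(
    res <- longitudinal_analysis(cohort, suvr, measures = "mmse"))
  expect_match(warns, "fewer than 3", all = TRUE)   # one warning per ROI
  expect_identical(res$excluded$subject_id, "B")
  expect_equal(sum(res$rows$excluded), 1)
  expect_equal(res$rows$ratio_mmse[res$rows$subject_id == "A"], -2 / 29.1)
  # only 2 subjects survive the outlier cut: correlations are flagged NA
  expect_equal(res$results$n, rep(2, 2))
  expect_true(all(is.na(res$results$r)))

  # subjects with a single visit are excluded with a log entry
  cohort2 <- rbind(cohort, mk("D", 0, 2, 30)[1, ])
  res2 <- suppressWarnings(longitudinal_analysis(cohort2, suvr,
                                                 measures = "mmse"))
  expect_true("D" %in% res2$excluded$subject_id)

  # equidistant exams resolve to the earlier exam
  tie <- mk("T", c(0, 100), c(-10, 10), c(20, 24))  # both 10 d from scan 0
  suvrT <- data.frame(subject_id = "T", roi_role = c("ec", "itg"),
                      suvr = c(1, 1))
  rowsT <- suppressWarnings(longitudinal_analysis(
    rbind(tie, mk("U", c(0, 100), c(0, 100), c(25, 25))),
    rbind(suvrT, data.frame(subject_id = "U", roi_role = c("ec", "itg"),
                            suvr = c(1, 1))),
    measures = "mmse"))$rows
  # Pre for T is the exam at -10 (earlier of the two equidistant exams)
  expect_equal(rowsT$ratio_mmse[rowsT$subject_id == "T"],
               (24 - 20) / (20 + 0.1))
})

test_that("a planted decline proportional to baseline tau is detected", {
  ch <- make_cohort(60, effect = 2, noise_sd_scores = 0.2, n_visits = 3,
                    seed = 42, effect_long = 8, volumes = FALSE)
  res <- longitudinal_analysis(ch$cohort, ch$suvr)
  itg_mmse <- res$results[res$results$roi_role == "itg" &
                            res$results$measure == "mmse", ]
  expect_lt(itg_mmse$r, 0)
  expect_lt(itg_mmse$p_adjusted, 0.05)
})

test_that("the plain-text report renders ICC and correlation tables", {
  icc_tab <- data.frame(roi_role = c("braak12", "metatemporal"),
                        icc = c(0.972, 0.991),
                        ci_low = c(0.959, 0.987), ci_high = c(0.980, 0.994))
  cors <- data.frame(roi_role = "itg", measure = "mmse", r = -0.28,
                     p = 0.0003, p_adjusted = 0.0018)
  rep <- validation_report(icc_tab, cors)
  expect_true(any(grepl("braak12", rep)))
  expect_true(any(grepl("0.972", rep)))
  expect_true(any(grepl("mmse", rep)))
  path <- withr::local_tempfile(fileext = ".txt")
  validation_report(icc_tab, NULL, path = path)
  expect_true(any(grepl("metatemporal", readLines(path))))
})
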