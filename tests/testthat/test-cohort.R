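# build a minimal records table for n patients of one VOI class
make_records <- function(pred, post = NULL, qf = NULL, covar = NULL,
                         voi_class = "lesion") {
  n <- max(length(pred), length(qf))
  df <- data.frame(id = sprintf("p%02d", seq_len(n)),
                   voi_class = voi_class)
  if (!is.null(pred)) { df$Dmean_pred <- pred; df$Dmean_post <- post }
  if (!is.null(qf)) df$qf <- qf
  if (!is.null(covar)) df$covar <- covar
  df
}

test_that("normality test matches frozen external reference values", {
  # reference statistics computed once with an independent implementation
  # of the same omnibus test (scipy.stats.normaltest) on frozen samples
  gauss20 <- c(10.609434, 7.920032, 11.500902, 11.881129, 6.09793,
               7.395641, 10.255681, 9.367515, 9.966398, 8.293912,
               11.758796, 11.555584, 10.132061, 12.254482, 10.935019,
               8.281415, 10.737502, 8.082235, 11.756901, 9.900148)
  r1 <- dagostino_pearson(gauss20)
  expect_equal(r1$statistic, 1.6864872489, tolerance = 1e-9)
  expect_equal(r1$p.value, 0.4303124852, tolerance = 1e-9)

  exp15 <- c(1.247386, 0.223576, 1.83797, 1.227086, 0.655796, 0.417087,
             0.45332, 0.077077, 0.179632, 0.68532, 0.38868, 1.264207,
             0.708491, 0.23793, 0.461088)
  r2 <- dagostino_pearson(exp15)
  expect_equal(r2$statistic, 3.4312165357, tolerance = 1e-9)
  expect_equal(r2$p.value, 0.1798542879, tolerance = 1e-9)

  # unassessable below n = 8
  expect_true(is.na(dagostino_pearson(rnorm(7))$p.value))
})

test_that("identical paired samples give p = 1 and equal medians", {
  x <- c(40, 50, 60, 70, 80)
  res <- paired_index_comparison(make_records(x, x), "lesion", "Dmean")
  expect_equal(res$p, 1)
  expect_equal(res$median_pred, res$median_post)
  expect_error(paired_index_comparison(make_records(x[1:2], x[1:2]),
                                       "lesion", "Dmean"),
               "at least 3")
})

test_that("a constant shift is detected with p < 0.001 at n = 50", {
  set.seed(77)
  pred <- rnorm(50, 60, 10)
  res <- paired_index_comparison(make_records(pred, pred + 5),
                                 "lesion", "Dmean")
  expect_lt(res$p, 0.001)
})

test_that("the normality gate routes to the correct paired branch", {
  set.seed(31)
  pred <- rnorm(40, 60, 5)
  gauss <- paired_index_comparison(
    make_records(pred, pred + rnorm(40, 1, 2)), "lesion", "Dmean")
  expect_equal(gauss$test_used, "paired t")
  heavy <- paired_index_comparison(
    make_records(pred, pred + rcauchy(40)), "lesion", "Dmean")
  expect_equal(heavy$test_used, "wilcoxon signed-rank")
})

test_that("univariate QF tests dichotomize at the median with <= downward", {
  qf <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.15, 0.25, 0.35)
  cov <- c(1, 2, 3, 4, 5, 6, 7, 4)         # median 4; the 4s go low
  res <- univariate_qf_association(make_records(NULL, qf = qf, covar = cov),
                                   "covar", "lesion")
  expect_equal(sort(res$group_n), c(3L, 5L))  # {5,6,7} vs {1,2,3,4,4}
  expect_match(res$groups[1], ">")
  expect_equal(res$multiplicity_correction, "none")
})

test_that("three-level covariates route to the 3-group branch", {
  set.seed(5)
  grp <- rep(c("whole_liver_single", "whole_liver_split", "uni_lobar"),
             each = 9)
  qf <- abs(rnorm(27, 0.25, 0.08))
  res <- univariate_qf_association(
    make_records(NULL, qf = qf, covar = grp), "covar", "lesion")
  expect_true(res$test_used %in% c("one-way ANOVA", "kruskal-wallis"))
  expect_length(res$group_medians, 3)
  expect_error(univariate_qf_association(
    make_records(NULL, qf = qf[1:3], covar = c("a", "b", "c")),
    "covar", "lesion"), "at least 2")
})

test_that("a +0.15 QF shift at n = 13 per group is usually detected", {
  hits <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    qf <- c(abs(rnorm(13, 0.22, 0.10)), abs(rnorm(13, 0.37, 0.10)))
    cov <- rep(c("A", "B"), each = 13)
    res <- univariate_qf_association(
      make_records(NULL, qf = qf, covar = cov), "covar", "lesion")
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 40)   # >= 80% of seeded replicates
})

test_that("null two-group p-values are roughly uniform (quick check)", {
  set.seed(2024)
  ps <- replicate(400, {
    qf <- abs(rnorm(26, 0.25, 0.08))
    univariate_qf_association(
      make_records(NULL, qf = qf, covar = rep(c("A", "B"), each = 13)),
      "covar", "lesion")$p
  })
  expect_gt(min(ps), 0)
  expect_lt(abs(median(ps) - 0.5), 0.08)
})

test_that("processing influence curves report binned mean differences", {
  ph <- small_phantom(noise_sigma = 0.3, lesion_dose = 60, ntl_dose = 30)
  d <- ph$dose

  same <- processing_influence(d, d, ph$liver)
  nz <- same$n_voxels > 0
  expect_true(all(same$mean_diff[nz] == 0))
  expect_true(all(same$ci95_low[nz] == 0 & same$ci95_high[nz] == 0))
  expect_true(all(is.na(same$mean_diff[!nz])))   # empty bins stay NA

  shifted <- processing_influence(
    d, dose_grid(d$values + 3, d$geometry), ph$liver)
  nz <- shifted$n_voxels > 0
  expect_equal(shifted$mean_diff[nz], rep(3, sum(nz)), tolerance = 1e-9)
  expect_true(all(shifted$ci95_low[nz] <= shifted$mean_diff[nz] + 1e-9 &
                  shifted$mean_diff[nz] <= shifted$ci95_high[nz] + 1e-9))
})

test_that("smooth deformation keeps processing influence within clinical bounds", {
  # seeded smooth deformation of a synthetic phantom; the reported
  # clinical experience is <= 10 Gy for TL and < 6 Gy for NTL, used here
  # as a soft regression envelope for well-behaved fields
  ph <- small_phantom(noise_sigma = 0.2, lesion_dose = 60, ntl_dose = 30)
  dvf <- generate_dvf(ph$dose$geometry, amplitude_mm = 3,
                      correlation_mm = 15, seed = 4)
  warped <- apply_displacement(ph$dose, dvf)
  for (voi in list(ph$vois$TL, ph$vois$NTL)) {
    curve <- processing_influence(ph$dose, warped, voi)
    ok <- curve$n_voxels >= 5     # bins with enough voxels to average
    bound <- if (voi$name == "TL") 10 else 6
    expect_lt(max(abs(curve$mean_diff[ok])), bound)
  }
})

test_that("cohort summaries compute quartiles and concordance rates", {
  one <- cohort_summary(data.frame(voi_class = "TL", qf = 0.2))
  expect_equal(one$qf_median, 0.2)
  expect_equal(one$qf_q1, one$qf_q3)

  four <- cohort_summary(data.frame(voi_class = "lesion",
                                    qf = c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(four$qf_median, 0.25)

  cats <- cohort_summary(data.frame(voi_class = "NTL",
                                    qf = c(0.05, 0.1, 0.4, 0.5)))
  expect_equal(cats$pct_good, 50)
  expect_equal(cats$pct_acceptable, 0)
  expect_equal(cats$pct_poor, 50)
  expect_equal(cats$pct_good + cats$pct_acceptable + cats$pct_poor, 100)

  # percentages always sum to 100 over random cohorts
  set.seed(15)
  for (r in 1:10) {
    s <- cohort_summary(data.frame(voi_class = "lesion",
                                   qf = abs(rnorm(26, 0.25, 0.1))))
    expect_equal(s$pct_good + s$pct_acceptable + s$pct_poor, 100)
  }
})

test_that("p-value formatting matches the reporting convention", {
  expect_equal(format_p(c(0.5, 0.0431, 9e-5)),
               c("0.5000", "0.0431", "< 0.0001"))
})
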