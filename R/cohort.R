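#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z-score and the Anscombe-Glynn
#' kurtosis z-score into the K-squared statistic, referred to a
#' chi-squared distribution with 2 df. This is the omnibus test used to
#' gate parametric vs rank-based branches in the cohort comparisons.
#' Below n = 8 the kurtosis transformation is unreliable; the test then
#' returns `NA`, and callers fall back to the rank-based branch.
#'
#' @param x numeric vector.
#' @return A list with `statistic` (K-squared), `p.value`, `n`. `NA`
#'   entries when `n < 8` or `x` is essentially constant.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8 || stats::sd(x) == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, n = n))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)
  # kurtosis z (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = stats::pchisq(k2, df = 2,
                                               lower.tail = FALSE), n = n)
}

# TRUE when every supplied sample passes the normality gate at alpha;
# FALSE (-> rank branch) when any test is unassessable (small n) or rejects
normal_gate <- function(..., alpha = 0.05) {
  for (x in list(...)) {
    p <- dagostino_pearson(x)$p.value
    if (is.na(p) || p < alpha) return(FALSE)
  }
  TRUE
}

q13 <- function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)

#' Format a p-value for reporting
#'
#' Four decimals; values below 1e-4 render as `"< 0.0001"`.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-4, "< 0.0001", sprintf("%.4f", p))
}

#' Paired predictive vs post-treatment comparison of a DVH index
#'
#' For one VOI class and one DVH index, compares the paired predictive
#' and post-treatment values across patients. The paired differences are
#' gated through the D'Agostino-Pearson normality test (alpha 0.05):
#' normal differences go to the paired t test, non-normal (or too few to
#' assess, n < 8) to the Wilcoxon matched-pairs signed-rank test.
#'
#' @param records a data frame with one row per (patient, VOI); must
#'   contain `voi_class` plus `<index_name>_pred` and `<index_name>_post`
#'   columns (see [cohort_records_template()]).
#' @param voi_class one of the values in `records$voi_class` (e.g.
#'   `"lesion"`, `"TL"`, `"NTL"`).
#' @param index_name one of `"D90"`, `"D70"`, `"D50"`, `"Dmean"`, `"D20"`.
#' @return A list: `median_pred`, `iqr_pred` (c(Q1, Q3)), `median_post`,
#'   `iqr_post`, `p`, `p_formatted`, `test_used`
#'   (`"paired t"` or `"wilcoxon signed-rank"`), `n`.
#' @export
paired_index_comparison <- function(records, voi_class, index_name) {
  rows <- records[records$voi_class == voi_class, , drop = FALSE]
  cp <- paste0(index_name, "_pred"); ct <- paste0(index_name, "_post")
  if (!all(c(cp, ct) %in% names(rows)))
    stop(sprintf("records lack columns %s / %s", cp, ct))
  pred <- rows[[cp]]; post <- rows[[ct]]
  ok <- is.finite(pred) & is.finite(post)
  pred <- pred[ok]; post <- post[ok]
  if (length(pred) < 3) stop("need at least 3 paired observations")
  diffs <- post - pred
  if (all(diffs == 0)) {
    # identical pairs: no evidence of any shift
    p <- 1; test_used <- "wilcoxon signed-rank"
  } else if (normal_gate(diffs)) {
    p <- stats::t.test(post, pred, paired = TRUE)$p.value
    test_used <- "paired t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(post, pred, paired = TRUE, exact = FALSE)$p.value)
    test_used <- "wilcoxon signed-rank"
  }
  list(median_pred = stats::median(pred), iqr_pred = q13(pred),
       median_post = stats::median(post), iqr_post = q13(post),
       p = p, p_formatted = format_p(p), test_used = test_used,
       n = length(pred))
}

#' Univariate association of QF with a covariate
#'
#' Tests whether the quality factor differs across the levels of one
#' covariate within one VOI class. Continuous covariates are dichotomized
#' at the cohort median, with values equal to the median assigned to the
#' lower group (`> median` vs `<= median`). Two-level covariates are
#' compared with the unpaired t test (when both groups pass the normality
#' gate) or the Mann-Whitney U test; three-level covariates with one-way
#' ANOVA or the Kruskal-Wallis test. No multiple-testing correction is
#' applied (mirrored from the univariate design); the output flags this.
#'
#' @param records data frame with `voi_class`, `qf` and the covariate
#'   column.
#' @param covariate name of the covariate column.
#' @param voi_class VOI class to subset on.
#' @return A list: `groups` (level labels), `group_n`, `group_medians`,
#'   `iqrs` (list of c(Q1, Q3)), `p`, `p_formatted`, `test_used`,
#'   `multiplicity_correction = "none"`.
#' @export
univariate_qf_association <- function(records, covariate, voi_class) {
  rows <- records[records$voi_class == voi_class, , drop = FALSE]
  if (!covariate %in% names(rows))
    stop(sprintf("no covariate column '%s'", covariate))
  qf <- rows$qf
  cv <- rows[[covariate]]
  ok <- is.finite(qf) & !is.na(cv)
  qf <- qf[ok]; cv <- cv[ok]
  if (is.numeric(cv)) {
    med <- stats::median(cv)
    grp <- factor(ifelse(cv > med, paste0("> ", signif(med, 4)),
                         paste0("<= ", signif(med, 4))),
                  levels = c(paste0("> ", signif(med, 4)),
                             paste0("<= ", signif(med, 4))))
  } else {
    grp <- factor(cv)
  }
  grp <- droplevels(grp)
  k <- nlevels(grp)
  if (!k %in% c(2L, 3L))
    stop("covariate must have 2 or 3 levels after dichotomization")
  ns <- table(grp)
  if (any(ns < 2)) stop("each group needs at least 2 members")
  split_qf <- split(qf, grp)
  if (k == 2L) {
    if (normal_gate(split_qf[[1]], split_qf[[2]])) {
      p <- stats::t.test(split_qf[[1]], split_qf[[2]],
                         var.equal = TRUE)$p.value
      test_used <- "unpaired t"
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(split_qf[[1]], split_qf[[2]],
                           exact = FALSE)$p.value)
      test_used <- "mann-whitney U"
    }
  } else {
    if (do.call(normal_gate, split_qf)) {
      p <- summary(stats::aov(qf ~ grp))[[1]][["Pr(>F)"]][1]
      test_used <- "one-way ANOVA"
    } else {
      p <- stats::kruskal.test(qf, grp)$p.value
      test_used <- "kruskal-wallis"
    }
  }
  list(groups = levels(grp), group_n = as.integer(ns),
       group_medians = vapply(split_qf, stats::median, numeric(1)),
       iqrs = lapply(split_qf, q13),
       p = p, p_formatted = format_p(p), test_used = test_used,
       multiplicity_correction = "none")
}

#' Dose-binned processing-influence curve
#'
#' Quantifies how much a processing step (deformation or resampling)
#' changed the dose, as a function of the dose itself: in-VOI voxels are
#' binned by their original dose (1-Gy bins spanning 0-250 Gy by
#' default), and within each bin the mean of (processed - original) is
#' reported with a t-based 95% confidence interval across the
#' contributing voxels. Empty bins yield `NA` entries, not zeros.
#'
#' @param original,processed [dose_grid()]s on one geometry (the
#'   processed grid mapped back, or the comparison done in DVH dose
#'   coordinates upstream).
#' @param voi a non-empty [voi_mask()] on the same geometry.
#' @param bin_width_gy bin width, Gy (default 1).
#' @param max_gy upper end of the binned range, Gy (default 250).
#' @return A data frame of class `binned_difference_curve`:
#'   `dose_bin_left`, `mean_diff`, `ci95_low`, `ci95_high`, `n_voxels`.
#' @export
processing_influence <- function(original, processed, voi,
                                 bin_width_gy = 1, max_gy = 250) {
  stopifnot(is_dose_grid(original), is_dose_grid(processed),
            is_voi_mask(voi))
  if (!same_geometry(original$geometry, processed$geometry))
    stop_geometry_mismatch(original$geometry, processed$geometry,
                           "processing_influence")
  if (!same_geometry(original$geometry, voi$geometry))
    stop_geometry_mismatch(original$geometry, voi$geometry,
                           "processing_influence")
  if (!any(voi$values)) stop("VOI is empty")
  d0 <- original$values[voi$values]
  d1 <- processed$values[voi$values]
  edges <- seq(0, max_gy, by = bin_width_gy)
  bin <- findInterval(d0, edges, rightmost.closed = FALSE)
  bin[d0 >= max_gy] <- NA  # beyond the reported range
  diffs <- d1 - d0
  nb <- length(edges) - 1L
  out <- data.frame(dose_bin_left = edges[-length(edges)],
                    mean_diff = NA_real_, ci95_low = NA_real_,
                    ci95_high = NA_real_, n_voxels = 0L)
  for (b in seq_len(nb)) {
    v <- diffs[!is.na(bin) & bin == b]
    n <- length(v)
    if (n == 0) next
    m <- mean(v)
    out$mean_diff[b] <- m
    out$n_voxels[b] <- n
    if (n >= 2) {
      half <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
      out$ci95_low[b] <- m - half
      out$ci95_high[b] <- m + half
    } else {
      out$ci95_low[b] <- m
      out$ci95_high[b] <- m
    }
  }
  class(out) <- c("binned_difference_curve", "data.frame")
  out
}

#' Cohort QF summary table
#'
#' Per VOI class: QF median, first and third quartile (linear
#' interpolation between order statistics), and the percentage of cases
#' in each concordance category.
#'
#' @param records data frame with `voi_class` and `qf` columns.
#' @return A data frame with one row per VOI class: `voi_class`, `n`,
#'   `qf_median`, `qf_q1`, `qf_q3`, `pct_good`, `pct_acceptable`,
#'   `pct_poor`.
#' @export
cohort_summary <- function(records) {
  if (nrow(records) < 1) stop("need at least 1 record")
  out <- lapply(split(records, records$voi_class), function(rows) {
    qf <- rows$qf[is.finite(rows$qf)]
    cat_ <- classify_qf(qf)
    data.frame(voi_class = rows$voi_class[1], n = length(qf),
               qf_median = stats::median(qf),
               qf_q1 = q13(qf)[1], qf_q3 = q13(qf)[2],
               pct_good = 100 * mean(cat_ == "good"),
               pct_acceptable = 100 * mean(cat_ == "acceptable"),
               pct_poor = 100 * mean(cat_ == "poor"))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Template for cohort record tables
#'
#' Returns a zero-row data frame with the documented column schema for
#' cohort analyses: one row per (patient, VOI), with patient covariates,
#' per-VOI DVH indices for both dosimetries, and the QF.
#'
#' @return A zero-row data frame.
#' @export
cohort_records_template <- function() {
  data.frame(id = character(), sex = character(), age_years = numeric(),
             delay_days = numeric(),
             targeting = character(), net_activity_mbq = numeric(),
             voi_class = character(), voi_name = character(),
             volume_ml = numeric(),
             D90_pred = numeric(), D70_pred = numeric(),
             D50_pred = numeric(), Dmean_pred = numeric(),
             D20_pred = numeric(),
             D90_post = numeric(), D70_post = numeric(),
             D50_post = numeric(), Dmean_post = numeric(),
             D20_post = numeric(),
             qf = numeric(), qf_category = character())
}
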