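#' Clinical dose-weighting specification
#'
#' Piecewise-linear weighting of voxel doses used when building the QVH.
#' Doses below `zero_low` Gy or above `zero_high` Gy carry weight 0 (dose
#' differences there are not clinically meaningful for resin-microsphere
#' radioembolization of metastatic colorectal cancer: below ~10 Gy no
#' dose-response is seen, above ~200 Gy the response curves have
#' saturated); doses in `[full_low, full_high]` carry weight 1 (the range
#' where mean-dose/response and toxicity relationships are steepest);
#' weights are linearly interpolated in between. The per-voxel weight is
#' the maximum of the predictive and post-treatment weights, overridden to
#' 1 when one dose is below `straddle_low` and the other above
#' `straddle_high` -- such gross discrepancies must never be masked.
#'
#' Defaults encode the resin-sphere mCRC calibration; re-weighting for
#' glass spheres or other histologies is a configuration change here, not
#' a code change.
#'
#' @param zero_low,full_low,full_high,zero_high breakpoints in Gy of the
#'   trapezoidal weight: 0 below `zero_low`, 1 on `[full_low, full_high]`,
#'   0 above `zero_high`.
#' @param straddle_low,straddle_high the override thresholds: weight 1
#'   whenever one dose is `< straddle_low` while the other is
#'   `> straddle_high`.
#' @return An object of class `weight_spec`.
#' @examples
#' ws <- weight_spec()
#' weight_single(c(5, 25, 80, 160, 250), ws)  # 0, 0.5, 1, 0.5, 0
#' @export
weight_spec <- function(zero_low = 10, full_low = 40,
                        full_high = 120, zero_high = 200,
                        straddle_low = full_low, straddle_high = full_high) {
  vals <- c(zero_low, full_low, full_high, zero_high,
            straddle_low, straddle_high)
  if (anyNA(vals) || any(!is.finite(vals)) || any(vals < 0))
    stop("all weight thresholds must be finite and non-negative")
  if (!(zero_low < full_low && full_low <= full_high && full_high < zero_high))
    stop("need zero_low < full_low <= full_high < zero_high")
  if (straddle_low < full_low || straddle_high > full_high)
    stop("straddle thresholds must lie within [full_low, full_high]")
  structure(list(zero_low = zero_low, full_low = full_low,
                 full_high = full_high, zero_high = zero_high,
                 straddle_low = straddle_low, straddle_high = straddle_high),
            class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  cat(sprintf(
    "weight_spec: 0 below %g Gy, ramp to 1 at %g Gy, 1 until %g Gy, 0 above %g Gy\n",
    x$zero_low, x$full_low, x$full_high, x$zero_high))
  cat(sprintf("  straddle override: W = 1 when one dose < %g Gy and the other > %g Gy\n",
              x$straddle_low, x$straddle_high))
  invisible(x)
}

#' Per-voxel quality ratio Q
#'
#' The voxel-wise comparison statistic: `Q = log10(d_post / d_pred)`. Q is
#' zero when post-treatment and predictive doses agree, positive when the
#' voxel received more dose than predicted, negative when less; the
#' logarithm makes the distribution symmetric under swapping the two dose
#' matrices (Q changes sign only). Both doses are clamped from below at
#' `floor_gy` before the ratio so Q stays finite on zero-dose voxels;
#' those voxels almost always carry weight 0 downstream.
#'
#' @param d_pred,d_post predictive / post-treatment doses in Gy
#'   (non-negative; vectorized).
#' @param floor_gy dose floor in Gy applied to both arguments
#'   (default 0.01).
#' @return Q, dimensionless, same length as the inputs.
#' @examples
#' quality_ratio(1, 3)     # log10(3) ~ 0.48
#' quality_ratio(50, 100)  # log10(2) ~ 0.30
#' @export
quality_ratio <- function(d_pred, d_post, floor_gy = 0.01) {
  if (anyNA(d_pred) || anyNA(d_post) ||
      any(!is.finite(d_pred)) || any(!is.finite(d_post)))
    stop("doses must be finite")
  if (any(d_pred < 0) || any(d_post < 0))
    stop("doses must be non-negative")
  if (!is.finite(floor_gy) || floor_gy <= 0)
    stop("floor_gy must be positive")
  log10(pmax(d_post, floor_gy) / pmax(d_pred, floor_gy))
}

#' Single-dose weighting factor
#'
#' Evaluates the trapezoidal clinical weight of a single dose value: 0 up
#' to `zero_low`, linear rise to 1 at `full_low`, 1 through `full_high`,
#' linear fall to 0 at `zero_high`, 0 beyond. Continuous and piecewise
#' linear with breakpoints exactly at the [weight_spec()] values
#' (W(10) = 0, W(40) = 1, W(120) = 1, W(200) = 0 under the defaults).
#'
#' @param d dose in Gy (non-negative; vectorized).
#' @param spec a [weight_spec()].
#' @return Weight in `[0, 1]`.
#' @export
weight_single <- function(d, spec = weight_spec()) {
  stopifnot(inherits(spec, "weight_spec"))
  if (anyNA(d) || any(!is.finite(d))) stop("doses must be finite")
  if (any(d < 0)) stop("doses must be non-negative")
  w <- numeric(length(d))
  up <- d > spec$zero_low & d < spec$full_low
  w[up] <- (d[up] - spec$zero_low) / (spec$full_low - spec$zero_low)
  w[d >= spec$full_low & d <= spec$full_high] <- 1
  down <- d > spec$full_high & d < spec$zero_high
  w[down] <- (spec$zero_high - d[down]) / (spec$zero_high - spec$full_high)
  w
}

#' Combined predictive/post-treatment weighting factor
#'
#' The per-voxel QVH weight: `max(W(d_pred), W(d_post))`, overridden to 1
#' when one dose falls below the straddle-low threshold while the other
#' exceeds the straddle-high threshold (strict inequalities). The override
#' exists precisely for voxels whose single weights would both vanish --
#' e.g. 5 Gy predicted vs 250 Gy delivered -- where the discrepancy is the
#' clinically critical signal. Symmetric in its two arguments.
#'
#' @inheritParams weight_single
#' @param d_pred,d_post doses in Gy (vectorized).
#' @return Weight in `[0, 1]`.
#' @examples
#' combine_weights(80, 80)   # 1
#' combine_weights(5, 5)     # 0
#' combine_weights(5, 250)   # 1 (straddle override)
#' @export
combine_weights <- function(d_pred, d_post, spec = weight_spec()) {
  w <- pmax(weight_single(d_pred, spec), weight_single(d_post, spec))
  straddle <- (d_pred < spec$straddle_low & d_post > spec$straddle_high) |
              (d_post < spec$straddle_low & d_pred > spec$straddle_high)
  w[straddle] <- 1
  w
}

#' Per-voxel quality map over a VOI
#'
#' Evaluates Q and W for every voxel of the VOI on an already-aligned
#' predictive / post-treatment dose pair. Alignment (deformation,
#' resampling) is the caller's responsibility -- see [align_dosimetry()];
#' here the three geometries must match exactly.
#'
#' @param d_pred,d_post aligned [dose_grid()]s on one geometry.
#' @param voi a [voi_mask()] on the same geometry (non-empty).
#' @param spec a [weight_spec()].
#' @param floor_gy dose floor passed to [quality_ratio()].
#' @return An object of class `quality_map`: list with `q`, `w` (3D arrays,
#'   `NA` outside the VOI), `mask` (logical array), `geometry`, `voi_name`,
#'   `spec`, `floor_gy`.
#' @export
quality_map <- function(d_pred, d_post, voi, spec = weight_spec(),
                        floor_gy = 0.01) {
  stopifnot(is_dose_grid(d_pred), is_dose_grid(d_post), is_voi_mask(voi))
  if (!same_geometry(d_pred$geometry, d_post$geometry))
    stop_geometry_mismatch(d_pred$geometry, d_post$geometry,
                           "quality_map: predictive vs post-treatment")
  if (!same_geometry(d_pred$geometry, voi$geometry))
    stop_geometry_mismatch(d_pred$geometry, voi$geometry,
                           "quality_map: dose vs VOI")
  m <- voi$values
  if (!any(m)) stop("VOI is empty")
  q <- array(NA_real_, dim = d_pred$geometry$shape)
  w <- array(NA_real_, dim = d_pred$geometry$shape)
  q[m] <- quality_ratio(d_pred$values[m], d_post$values[m], floor_gy)
  w[m] <- combine_weights(d_pred$values[m], d_post$values[m], spec)
  structure(list(q = q, w = w, mask = m, geometry = d_pred$geometry,
                 voi_name = voi$name, spec = spec, floor_gy = floor_gy),
            class = "quality_map")
}

#' @export
print.quality_map <- function(x, ...) {
  n <- sum(x$mask)
  cat(sprintf("quality_map%s: %d voxels, Q range [%.3g, %.3g], weighted fraction %.3f\n",
              if (nzchar(x$voi_name)) paste0(" \"", x$voi_name, "\"") else "",
              n, min(x$q[x$mask]), max(x$q[x$mask]), sum(x$w[x$mask]) / n))
  invisible(x)
}

#' Quality-volume histogram curve
#'
#' Builds the QVH from a [quality_map()]: the cumulative fraction of
#' weighted VOI volume whose |Q| is at least each bin edge (each voxel
#' contributes voxel volume times its weight W), normalized by the total
#' weighted volume. A signed differential histogram over Q is returned
#' alongside, since both renderings are useful: the cumulative |Q| curve
#' summarizes spread, the signed density shows the direction of
#' discrepancies (over- vs under-delivery).
#'
#' @param qm a [quality_map()].
#' @param bin_width histogram bin width on the Q axis (default 0.01).
#' @return An object of class `qvh_curve`: `q_bin_edges`,
#'   `weighted_volume_fraction` (non-increasing, starts at 1),
#'   `signed_breaks` / `signed_density` (weighted-volume fractions per
#'   signed-Q bin), `total_weighted_volume_ml`, and `undefined` (`TRUE`
#'   when the VOI carries no weighted volume, in which case the curve
#'   entries are `NA`).
#' @export
compute_qvh <- function(qm, bin_width = 0.01) {
  stopifnot(inherits(qm, "quality_map"), bin_width > 0)
  q <- qm$q[qm$mask]
  w <- qm$w[qm$mask]
  vol <- voxel_volume_ml(qm$geometry)
  wt <- w * vol
  total <- sum(wt)
  aq <- abs(q)
  n_bins <- max(1L, ceiling(max(aq) / bin_width + 1e-12))
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # signed bins are centred on multiples of the bin width (one bin centred
  # at Q = 0), so a sign-symmetric map gives a mirror-symmetric histogram
  signed_breaks <- (seq.int(-n_bins, n_bins + 1L) - 0.5) * bin_width
  if (total <= 0) {
    warning("VOI carries no weighted volume; QVH undefined")
    return(structure(list(
      q_bin_edges = edges,
      weighted_volume_fraction = rep(NA_real_, length(edges)),
      signed_breaks = signed_breaks,
      signed_density = rep(NA_real_, length(signed_breaks) - 1L),
      total_weighted_volume_ml = 0, undefined = TRUE),
      class = "qvh_curve"))
  }
  # fraction of weighted volume with |Q| >= edge
  cumfrac <- vapply(edges, function(e) sum(wt[aq >= e]), numeric(1)) / total
  bins <- findInterval(q, signed_breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
  dens <- vapply(seq_len(length(signed_breaks) - 1L),
                 function(b) sum(wt[bins == b]), numeric(1)) / total
  structure(list(q_bin_edges = edges,
                 weighted_volume_fraction = cumfrac,
                 signed_breaks = signed_breaks,
                 signed_density = dens,
                 total_weighted_volume_ml = total,
                 undefined = FALSE),
            class = "qvh_curve")
}

#' @export
print.qvh_curve <- function(x, ...) {
  if (x$undefined) {
    cat("qvh_curve: undefined (no weighted volume)\n")
  } else {
    cat(sprintf("qvh_curve: %d |Q| bins of width %.3g, weighted volume %.1f mL\n",
                length(x$q_bin_edges) - 1L,
                diff(x$q_bin_edges[1:2]), x$total_weighted_volume_ml))
  }
  invisible(x)
}

#' Quality factor of a quality map
#'
#' The scalar summary of a QVH: the weighted mean of |Q| over the VOI,
#' `QF = sum(|Q_i| W_i) / sum(W_i)`. A QF of 0 means the post-treatment
#' dose distribution matched the predictive one perfectly on every
#' clinically weighted voxel; larger QF means larger spread of the QVH
#' away from zero. When the VOI carries no weight at all (all doses
#' outside the clinically meaningful range) the QF is undefined and
#' returned as `NaN` with category `"undefined"`.
#'
#' @param qm a [quality_map()].
#' @return An object of class `qf_result`: `qf`, `category` (see
#'   [classify_qf()]), `weighted_fraction` (sum of weights over voxel
#'   count, a coverage diagnostic), `n_voxels`.
#' @examples
#' g <- grid_geometry(c(4, 4, 4), c(3, 3, 3))
#' pred <- dose_grid(array(100, c(4, 4, 4)), g)
#' post <- dose_grid(array(50, c(4, 4, 4)), g)
#' voi <- voi_mask(array(TRUE, c(4, 4, 4)), g)
#' quality_factor(quality_map(pred, post, voi))  # QF = log10(2), "poor"
#' @export
quality_factor <- function(qm) {
  stopifnot(inherits(qm, "quality_map"))
  q <- qm$q[qm$mask]
  w <- qm$w[qm$mask]
  sw <- sum(w)
  if (sw <= 0) {
    warning("sum of weights is zero; QF undefined")
    qf <- NaN
    category <- "undefined"
  } else {
    qf <- sum(abs(q) * w) / sw
    category <- classify_qf(qf)
  }
  structure(list(qf = qf, category = category,
                 weighted_fraction = sw / length(w),
                 n_voxels = length(w)),
            class = "qf_result")
}

#' @export
print.qf_result <- function(x, ...) {
  cat(sprintf("QF = %.4f (%s); weighted fraction %.3f of %d voxels\n",
              x$qf, x$category, x$weighted_fraction, x$n_voxels))
  invisible(x)
}

#' Classify a quality factor
#'
#' Concordance categories on half-open intervals: good on `[0, 0.18)`,
#' acceptable on `[0.18, 0.3)`, poor on `[0.3, Inf)`. The 0.18 and 0.3
#' cut-offs correspond to one dose map being systematically 33% and 50%
#' lower than the other, respectively (`1 - 10^-0.18` and `1 - 10^-0.3`).
#'
#' @param qf quality factor(s), non-negative (vectorized).
#' @return Character vector in `{"good", "acceptable", "poor"}`.
#' @examples
#' classify_qf(c(0.05, 0.24, 0.32))  # good, acceptable, poor
#' @export
classify_qf <- function(qf) {
  if (anyNA(qf)) stop("qf must not be NA")
  if (any(qf < 0)) stop("qf must be non-negative")
  ifelse(qf < 0.18, "good", ifelse(qf < 0.3, "acceptable", "poor"))
}

#' Export a quality map as volumes
#'
#' Writes the signed-Q volume and the weight volume (both `NA`/non-finite
#' outside the VOI) as NIfTI files with the map's grid geometry, for
#' overlay on the dose images ("Q map").
#'
#' @param qm a [quality_map()].
#' @param q_path,w_path output paths (`.nii` or `.nii.gz`). `w_path`
#'   defaults to `q_path` with a `_weights` suffix.
#' @return Invisibly, the two paths written.
#' @export
q_map_export <- function(qm, q_path, w_path = NULL) {
  stopifnot(inherits(qm, "quality_map"))
  if (is.null(w_path))
    w_path <- sub("(\\.nii(\\.gz)?)$", "_weights\\1", q_path)
  write_volume(qm$q, qm$geometry, q_path)
  write_volume(qm$w, qm$geometry, w_path)
  invisible(c(q = q_path, w = w_path))
}
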