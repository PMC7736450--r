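#' Fit a quality-volume histogram comparison
#'
#' The package's central entry point: compares an aligned predictive /
#' post-treatment dose pair over a VOI and returns the full QVH analysis
#' -- per-voxel quality map, QVH curve, quality factor with its
#' concordance category, and the DVH indices of both dosimetries. If a
#' displacement field is supplied, the predictive dose is first deformed
#' into the post-treatment anatomy and the post-treatment dose (and the
#' VOI) are resampled onto the deformed-predictive grid, so the
#' comparison runs at the coarser simulation resolution.
#'
#' @param pred predictive [dose_grid()].
#' @param post post-treatment [dose_grid()].
#' @param voi [voi_mask()] to analyse over.
#' @param dvf optional [displacement_field()] (predictive onto
#'   post-treatment anatomy).
#' @param weights a [weight_spec()].
#' @param floor_gy dose floor for the log ratio (Gy).
#' @param qvh_bin_width QVH bin width on the Q axis.
#' @param dvh_bin_width_gy DVH bin width, Gy.
#' @return An object of class `qvh`: list with `qf` ([quality_factor()]
#'   result), `map` ([quality_map()]), `curve` ([compute_qvh()] result),
#'   `dvh_pred`, `dvh_post`, `indices_pred`, `indices_post`, `voi_name`,
#'   `weights`, `call`.
#' @examples
#' ph <- generate_phantom(phantom_spec(
#'   geometry = grid_geometry(c(24, 24, 24), c(6, 6, 6),
#'                            origin = -c(69, 69, 69)),
#'   liver_semiaxes_mm = c(60, 55, 50),
#'   lesions = list(list(centre_mm = c(0, 0, 0), radius_mm = 18,
#'                       mean_dose_gy = 90)),
#'   ntl_mean_dose_gy = 45, noise_sigma = 0.15, seed = 7))
#' post <- apply_mismatch(ph$dose, mismatch_spec("global_scale", 0.8))
#' fit <- qvh(ph$dose, post, ph$vois$TL)
#' fit
#' summary(fit)
#' @export
qvh <- function(pred, post, voi, dvf = NULL, weights = weight_spec(),
                floor_gy = 0.01, qvh_bin_width = 0.01,
                dvh_bin_width_gy = 1) {
  cl <- match.call()
  if (!is.null(dvf)) {
    al <- align_dosimetry(pred, post, dvf, vois = list(voi = voi))
    pred <- al$pred; post <- al$post; voi <- al$vois$voi
  }
  qm <- quality_map(pred, post, voi, spec = weights, floor_gy = floor_gy)
  curve <- compute_qvh(qm, bin_width = qvh_bin_width)
  qf <- quality_factor(qm)
  dvh_p <- compute_dvh(pred, voi, dvh_bin_width_gy)
  dvh_t <- compute_dvh(post, voi, dvh_bin_width_gy)
  structure(list(qf = qf, map = qm, curve = curve,
                 dvh_pred = dvh_p, dvh_post = dvh_t,
                 indices_pred = extract_indices(dvh_p),
                 indices_post = extract_indices(dvh_t),
                 voi_name = voi$name, weights = weights, call = cl),
            class = "qvh")
}

#' @export
print.qvh <- function(x, ...) {
  cat("Quality-volume histogram comparison\n")
  if (nzchar(x$voi_name)) cat(sprintf("  VOI: %s\n", x$voi_name))
  cat(sprintf("  QF = %.4f -> %s concordance\n", x$qf$qf, x$qf$category))
  cat(sprintf("  weighted fraction of VOI: %.3f (%d voxels)\n",
              x$qf$weighted_fraction, x$qf$n_voxels))
  invisible(x)
}

#' @export
summary.qvh <- function(object, ...) {
  out <- list(qf = object$qf$qf, category = object$qf$category,
              weighted_fraction = object$qf$weighted_fraction,
              n_voxels = object$qf$n_voxels,
              indices = rbind(predictive = unclass(object$indices_pred),
                              post_treatment = unclass(object$indices_post)),
              voi_name = object$voi_name)
  class(out) <- "summary.qvh"
  out
}

#' @export
print.summary.qvh <- function(x, ...) {
  cat("Quality-volume histogram comparison\n")
  if (nzchar(x$voi_name)) cat(sprintf("  VOI: %s\n", x$voi_name))
  cat(sprintf("  QF = %.4f (%s); weighted fraction %.3f of %d voxels\n\n",
              x$qf, x$category, x$weighted_fraction, x$n_voxels))
  cat("  DVH indices (Gy):\n")
  print(round(x$indices, 1))
  invisible(x)
}

#' @export
coef.qvh <- function(object, ...) {
  c(QF = object$qf$qf)
}

#' Per-voxel residuals of a QVH comparison
#'
#' The signed per-voxel quality ratios Q (NA outside the VOI): the
#' natural residual of the "post-treatment reproduces predictive"
#' model.
#'
#' @param object a [qvh()] fit.
#' @param ... unused.
#' @return 3D array of Q values.
#' @export
residuals.qvh <- function(object, ...) {
  object$map$q
}

#' Plot a QVH comparison
#'
#' Draws the cumulative |Q| curve (weighted volume fraction with |Q| at
#' least each abscissa) and, optionally, the signed differential QVH.
#'
#' @param x a [qvh()] fit.
#' @param which `"cumulative"`, `"signed"` or `"both"`.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.qvh <- function(x, which = c("cumulative", "signed", "both"), ...) {
  which <- match.arg(which)
  if (x$curve$undefined) {
    warning("QVH undefined (no weighted volume); nothing to plot")
    return(invisible(x))
  }
  if (which == "both") {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  if (which %in% c("cumulative", "both")) {
    graphics::plot(x$curve$q_bin_edges, x$curve$weighted_volume_fraction,
                   type = "s", xlab = "|Q|",
                   ylab = "weighted volume fraction  >= |Q|",
                   main = sprintf("QVH (QF = %.3f, %s)",
                                  x$qf$qf, x$qf$category), ...)
    graphics::abline(v = x$qf$qf, lty = 2, col = "grey40")
  }
  if (which %in% c("signed", "both")) {
    mids <- x$curve$signed_breaks[-length(x$curve$signed_breaks)] +
      diff(x$curve$signed_breaks) / 2
    keep <- abs(mids) <= 2  # display range
    graphics::plot(mids[keep], x$curve$signed_density[keep], type = "h",
                   xlab = "Q", ylab = "weighted volume fraction per bin",
                   main = "signed QVH", ...)
    graphics::abline(v = 0, lty = 2, col = "grey40")
  }
  invisible(x)
}

#' Write a full QVH comparison report
#'
#' Writes, under `out_dir`: the predictive and post-treatment DVH curves
#' (CSV), the QVH cumulative curve (CSV), the QF summary (JSON with
#' `qf`, `category`, `weighted_fraction`) and the Q/W map volumes
#' (NIfTI).
#'
#' @param fit a [qvh()] object.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the named vector of paths written.
#' @export
write_qvh_report <- function(fit, out_dir) {
  stopifnot(inherits(fit, "qvh"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dvh_pred = file.path(out_dir, "dvh_predictive.csv"),
    dvh_post = file.path(out_dir, "dvh_post_treatment.csv"),
    qvh = file.path(out_dir, "qvh.csv"),
    qf = file.path(out_dir, "qf.json"),
    q_map = file.path(out_dir, "q_map.nii.gz"))
  write_dvh_csv(fit$dvh_pred, paths["dvh_pred"])
  write_dvh_csv(fit$dvh_post, paths["dvh_post"])
  utils::write.csv(
    data.frame(q_bin_edge = fit$curve$q_bin_edges,
               weighted_volume_fraction = fit$curve$weighted_volume_fraction),
    paths["qvh"], row.names = FALSE)
  jsonlite::write_json(
    list(qf = fit$qf$qf, category = fit$qf$category,
         weighted_fraction = fit$qf$weighted_fraction,
         indices_pred = as.list(unclass(fit$indices_pred)),
         indices_post = as.list(unclass(fit$indices_post))),
    paths["qf"], auto_unbox = TRUE, digits = NA)
  q_map_export(fit$map, paths["q_map"])
  invisible(paths)
}
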