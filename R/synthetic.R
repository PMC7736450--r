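#' Digital liver phantom specification
#'
#' Describes a synthetic test phantom: an ellipsoidal liver containing
#' spherical lesions, with region-wise target mean doses and spatially
#' correlated multiplicative (log-normal) dose noise. The defaults
#' emulate the scale of a real radioembolization cohort: a ~1.4 L liver,
#' lesions of a few to ~17 mL, lesion mean dose ~60 Gy, non-tumoural
#' liver mean dose ~32 Gy, on a 96^3 grid at 3 mm.
#'
#' @param geometry a [grid_geometry()] (default 96^3 voxels at 3 mm,
#'   centred on the origin).
#' @param liver_semiaxes_mm ellipsoid semi-axes, mm.
#' @param liver_centre_mm ellipsoid centre, mm.
#' @param lesions list of `list(centre_mm=, radius_mm=, mean_dose_gy=)`.
#' @param ntl_mean_dose_gy target mean dose of the non-lesion liver, Gy.
#' @param noise_sigma log-scale sigma of the multiplicative noise
#'   (0 disables noise).
#' @param noise_correlation_mm correlation length of the noise field, mm.
#' @param seed integer seed; the generator is deterministic given it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = NULL,
                         liver_semiaxes_mm = c(90, 70, 54),
                         liver_centre_mm = c(0, 0, 0),
                         lesions = list(
                           list(centre_mm = c(-40, 10, 0), radius_mm = 8.5,
                                mean_dose_gy = 60),
                           list(centre_mm = c(5, 25, 12), radius_mm = 12,
                                mean_dose_gy = 60),
                           list(centre_mm = c(45, -20, -12), radius_mm = 16,
                                mean_dose_gy = 60)),
                         ntl_mean_dose_gy = 32,
                         noise_sigma = 0.3,
                         noise_correlation_mm = 15,
                         seed = 1L) {
  if (is.null(geometry)) {
    sh <- c(96L, 96L, 96L); sp <- c(3, 3, 3)
    geometry <- grid_geometry(sh, sp, origin = -(sh - 1) * sp / 2)
  }
  stopifnot(is_grid_geometry(geometry))
  if (any(liver_semiaxes_mm <= 0)) stop("liver semi-axes must be positive")
  for (l in lesions) {
    if (l$radius_mm <= 0) stop("lesion radii must be positive")
    if (l$mean_dose_gy < 0) stop("lesion mean doses must be non-negative")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(geometry = geometry,
                 liver_semiaxes_mm = liver_semiaxes_mm,
                 liver_centre_mm = liver_centre_mm,
                 lesions = lesions,
                 ntl_mean_dose_gy = ntl_mean_dose_gy,
                 noise_sigma = noise_sigma,
                 noise_correlation_mm = noise_correlation_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a digital liver phantom
#'
#' Builds the liver and lesion masks by evaluating the analytic shapes at
#' the voxel centres, then synthesizes a dose map: a log-normal,
#' spatially correlated multiplicative noise field modulates each region,
#' after which every region (each lesion, and the non-lesion liver) is
#' rescaled so its mean dose hits the target exactly. Dose is 0 outside
#' the liver. Deterministic for a fixed spec seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list: `liver` ([voi_mask()]), `lesions` (`lesion_set`),
#'   `vois` (the `TL` / `NTL` pair from [build_voi_set()]), `dose`
#'   ([dose_grid()]), `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  pts <- voxel_centres(g)
  rel <- sweep(pts, 2, spec$liver_centre_mm, "-")
  liver_arr <- array(rowSums(sweep(rel, 2, spec$liver_semiaxes_mm, "/")^2) <= 1,
                     g$shape)
  if (!any(liver_arr)) stop("liver ellipsoid contains no voxels")
  liver <- voi_mask(liver_arr, g, name = "liver")
  lesion_masks <- list()
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    r2 <- rowSums(sweep(pts, 2, l$centre_mm, "-")^2)
    m <- array(r2 <= l$radius_mm^2, g$shape)
    if (!any(m)) stop(sprintf("lesion %d contains no voxels", i))
    if (any(m & !liver_arr))
      stop(sprintf("lesion %d escapes the liver", i))
    lesion_masks[[i]] <- voi_mask(m, g, name = paste0("lesion_", i))
  }
  labels <- array(0L, g$shape)
  for (i in seq_along(lesion_masks)) labels[lesion_masks[[i]]$values] <- i
  lesions <- structure(list(lesions = lesion_masks, labels = labels,
                            threshold = NA_real_),
                       class = "lesion_set")
  vois <- build_voi_set(liver, lesion_masks)
  dose <- run_with_seed(spec$seed, {
    vals <- array(0, g$shape)
    noise <- if (spec$noise_sigma > 0)
      exp(spec$noise_sigma *
            correlated_noise_field(g, spec$noise_correlation_mm))
    else array(1, g$shape)
    ntl <- vois$NTL$values
    if (any(ntl)) {
      vals[ntl] <- noise[ntl] *
        (spec$ntl_mean_dose_gy / mean(noise[ntl]))
    }
    for (i in seq_along(lesion_masks)) {
      m <- lesion_masks[[i]]$values
      vals[m] <- noise[m] * (spec$lesions[[i]]$mean_dose_gy / mean(noise[m]))
    }
    vals
  })
  list(liver = liver, lesions = lesions, vois = vois,
       dose = dose_grid(dose, g, label = "phantom"), spec = spec)
}

#' Dose-mismatch specification
#'
#' One controllable discrepancy between a predictive and a post-treatment
#' dose map, standing in for the clinical discrepancy sources (flow
#' redirection, particle-size differences, registration residue). Specs
#' compose as an ordered list in [apply_mismatch()].
#'
#' @param mode one of `"none"`, `"global_scale"` (multiply everywhere by
#'   `magnitude`), `"lesion_scale"` (multiply inside TL only),
#'   `"hot_spot"` / `"cold_spot"` (add / subtract a Gaussian blob of peak
#'   `magnitude` Gy), `"shift_mm"` (translate by `magnitude` mm along
#'   `axis`), `"blur_mm"` (Gaussian blur, sigma `magnitude` mm).
#' @param magnitude mode-dependent scalar.
#' @param seed integer seed used when a random blob centre is drawn.
#' @param centre_mm optional blob centre (world mm) for the spot modes;
#'   drawn uniformly from the liver when omitted.
#' @param sigma_mm blob sigma for the spot modes (default 20 mm).
#' @param axis translation axis for `shift_mm` (default 1).
#' @return An object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(mode = c("none", "global_scale", "lesion_scale",
                                   "hot_spot", "cold_spot", "shift_mm",
                                   "blur_mm"),
                          magnitude = 1, seed = NULL, centre_mm = NULL,
                          sigma_mm = 20, axis = 1L) {
  mode <- match.arg(mode)
  if (!is.finite(magnitude)) stop("magnitude must be finite")
  if (mode %in% c("global_scale", "lesion_scale") && magnitude < 0)
    stop("scale magnitudes must be non-negative")
  structure(list(mode = mode, magnitude = magnitude, seed = seed,
                 centre_mm = centre_mm, sigma_mm = sigma_mm,
                 axis = as.integer(axis)),
            class = "mismatch_spec")
}

#' Apply mismatch specs to a dose grid
#'
#' Applies an ordered list of [mismatch_spec()]s to a dose map. Any
#' voxels driven negative (cold spots) are clipped to 0 Gy and the clip
#' count is reported via a message.
#'
#' @param dose a [dose_grid()].
#' @param specs a single [mismatch_spec()] or a list of them, applied in
#'   order.
#' @param vois optional list with `TL` (needed for `lesion_scale`) and
#'   `liver` (used to draw random blob centres) masks.
#' @return A [dose_grid()] on the same geometry.
#' @export
apply_mismatch <- function(dose, specs, vois = NULL) {
  stopifnot(is_dose_grid(dose))
  if (inherits(specs, "mismatch_spec")) specs <- list(specs)
  g <- dose$geometry
  vals <- dose$values
  for (sp in specs) {
    stopifnot(inherits(sp, "mismatch_spec"))
    vals <- switch(sp$mode,
      none = vals,
      global_scale = vals * sp$magnitude,
      lesion_scale = {
        if (is.null(vois$TL)) stop("lesion_scale needs vois$TL")
        v <- vals
        m <- vois$TL$values
        v[m] <- v[m] * sp$magnitude
        v
      },
      hot_spot = vals + mismatch_blob(g, sp, vois),
      cold_spot = vals - mismatch_blob(g, sp, vois),
      shift_mm = {
        shift <- numeric(3); shift[sp$axis] <- sp$magnitude
        pts <- sweep(voxel_centres(g), 2, shift, "-")
        array(trilinear_sample_index(
          vals, world_to_index(g, pts), fill = 0), g$shape)
      },
      blur_mm = gaussian_smooth(vals, sp$magnitude / g$spacing))
  }
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    message(sprintf("apply_mismatch: %d voxel(s) clipped to 0 Gy", n_neg))
    vals[vals < 0] <- 0
  }
  dose_grid(vals, g, label = dose$label)
}

mismatch_blob <- function(g, sp, vois) {
  centre <- sp$centre_mm
  if (is.null(centre)) {
    centre <- run_with_seed(sp$seed, {
      if (!is.null(vois$liver)) {
        cand <- which(vois$liver$values)
        voxel_centres(g)[sample(cand, 1), ]
      } else {
        g$origin + (g$shape - 1) * g$spacing / 2
      }
    })
  }
  r2 <- rowSums(sweep(voxel_centres(g), 2, centre, "-")^2)
  array(sp$magnitude * exp(-r2 / (2 * sp$sigma_mm^2)), g$shape)
}

#' Generate a smooth, fold-free random displacement field
#'
#' Synthesizes per-component Gaussian random fields, smooths them to the
#' requested correlation length, and normalizes each component to the
#' requested peak amplitude. To guarantee invertibility the amplitude is
#' capped at `correlation_mm / 3`: the steepest slope of a Gaussian
#' feature of width sigma and height a is about `0.61 a / sigma`, so the
#' cap keeps every Jacobian eigenvalue well away from zero. Requests
#' above the cap are rejected with the bound in the message. The result
#' is verified fold-free before being returned.
#'
#' @param geometry a [grid_geometry()].
#' @param amplitude_mm peak displacement per component, mm.
#' @param correlation_mm smoothing length, mm.
#' @param seed integer seed.
#' @return A [displacement_field()].
#' @export
generate_dvf <- function(geometry, amplitude_mm = 3, correlation_mm = 15,
                         seed = 1L) {
  stopifnot(is_grid_geometry(geometry))
  if (amplitude_mm < 0) stop("amplitude must be >= 0")
  bound <- correlation_mm / 3
  if (amplitude_mm > bound)
    stop(sprintf(
      "amplitude %.3g mm exceeds the folding bound %.3g mm for correlation length %.3g mm",
      amplitude_mm, bound, correlation_mm))
  vec <- run_with_seed(seed, {
    v <- array(0, c(geometry$shape, 3))
    for (m in 1:3) {
      f <- correlated_noise_field(geometry, correlation_mm)
      mx <- max(abs(f))
      if (mx > 0) f <- f * (amplitude_mm / mx)
      v[, , , m] <- f
    }
    v
  })
  dvf <- displacement_field(vec, geometry)
  if (!jacobian_determinant(dvf)$fold_free)
    stop("generated field is not fold-free; reduce amplitude or increase correlation length")
  dvf
}
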