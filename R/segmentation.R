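#' Background SUV statistics
#'
#' Mean and standard deviation of the reference background region -- in
#' the clinical workflow a 3-cm diameter sphere placed in healthy liver
#' parenchyma on the FDG-PET.
#'
#' @param mean SUV mean of the background region (> 0).
#' @param sd SUV standard deviation of the region (>= 0).
#' @return An object of class `background_stats`.
#' @export
background_stats <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    stop("background SUV mean must be positive")
  if (!is.finite(sd) || sd < 0)
    stop("background SUV sd must be non-negative")
  structure(list(mean = mean, sd = sd), class = "background_stats")
}

#' Measure background statistics from an SUV volume
#'
#' Convenience helper: evaluates [background_stats()] over a spherical
#' reference VOI of given diameter centred at `centre_mm` (world
#' coordinates).
#'
#' @param suv a [dose_grid()]-like volume holding SUV values.
#' @param centre_mm world coordinates (mm) of the sphere centre.
#' @param diameter_mm sphere diameter in mm (default 30, the standard
#'   3-cm reference sphere).
#' @return A [background_stats()].
#' @export
measure_background <- function(suv, centre_mm, diameter_mm = 30) {
  stopifnot(is_dose_grid(suv))
  pts <- voxel_centres(suv$geometry)
  r2 <- rowSums(sweep(pts, 2, centre_mm, "-")^2)
  inside <- r2 <= (diameter_mm / 2)^2
  if (!any(inside)) stop("reference sphere contains no voxels")
  v <- suv$values[inside]
  background_stats(mean(v), stats::sd(v))
}

#' PERCIST lesion threshold
#'
#' The fixed SUV threshold for target-lesion delineation:
#' `1.5 * SUV_mean(background) + 2 * SD(background)`.
#'
#' @param bg a [background_stats()].
#' @return SUV threshold (scalar).
#' @examples
#' percist_threshold(background_stats(2.0, 0.5))  # 4.0
#' @export
percist_threshold <- function(bg) {
  stopifnot(inherits(bg, "background_stats"))
  1.5 * bg$mean + 2 * bg$sd
}

# 26-connected component labelling of a logical 3D array, by iterative
# minimum-label propagation over all 26 neighbour shifts (vectorized;
# converges quickly for compact lesions).
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  lab[mask] <- seq_len(sum(mask))
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  pad <- function(a, s) {
    # neighbour values of `a` at offset s, 0 outside
    out <- array(0L, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
      if (s[k] >= 0) { src[[k]] <- seq_len(d[k] - s[k])
                       dst[[k]] <- seq_len(d[k] - s[k]) + s[k] }
      else           { src[[k]] <- seq_len(d[k] + s[k]) - s[k]
                       dst[[k]] <- seq_len(d[k] + s[k]) }
      if (length(src[[k]]) == 0) return(out)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  repeat {
    best <- lab
    for (r in seq_len(nrow(shifts))) {
      nb <- pad(lab, shifts[r, ])
      upd <- mask & nb > 0L & (best == 0L | nb < best)
      best[upd] <- nb[upd]
    }
    if (identical(best, lab)) break
    lab <- best
  }
  # compact labels to 1..n_components
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

#' Lesion delineation by PERCIST thresholding
#'
#' Voxels inside the liver with SUV at or above the PERCIST threshold are
#' partitioned into 26-connected components; components smaller than
#' `min_volume_ml` are discarded. Inclusive comparison (`>=`) gives
#' deterministic tie handling. Optionally a one-voxel morphological
#' opening separates lesions connected by thin bridges (off by default;
#' the clinical workflow corrected bridging manually).
#'
#' @param suv SUV volume as a [dose_grid()]-like object.
#' @param liver liver [voi_mask()] sharing the SUV geometry (non-empty).
#' @param bg a [background_stats()] defining the threshold.
#' @param min_volume_ml minimum lesion volume in mL (default 0: no
#'   filtering).
#' @param open logical; apply a 6-connected one-voxel opening before
#'   labelling (default `FALSE`).
#' @return An object of class `lesion_set`: list with `lesions` (list of
#'   [voi_mask()], labelled `lesion_1`, ... in label order), `labels`
#'   (integer 3D array), `threshold`.
#' @export
delineate_lesions <- function(suv, liver, bg, min_volume_ml = 0,
                              open = FALSE) {
  stopifnot(is_dose_grid(suv), is_voi_mask(liver),
            inherits(bg, "background_stats"))
  if (!same_geometry(suv$geometry, liver$geometry))
    stop_geometry_mismatch(suv$geometry, liver$geometry, "delineate_lesions")
  if (!any(liver$values)) stop("liver mask is empty")
  thr <- percist_threshold(bg)
  hot <- liver$values & suv$values >= thr
  if (open) hot <- morph_open6(hot)
  lab <- label_components_26(hot)
  vol <- voxel_volume_ml(suv$geometry)
  keep <- which(tabulate(lab[lab > 0L]) * vol >= max(min_volume_ml, vol / 2))
  lesions <- list()
  relab <- array(0L, dim(lab))
  for (i in seq_along(keep)) {
    m <- lab == keep[i]
    relab[m] <- i
    lesions[[i]] <- voi_mask(m, suv$geometry, name = paste0("lesion_", i))
  }
  structure(list(lesions = lesions, labels = relab, threshold = thr),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("lesion_set: %d lesion(s), SUV threshold %.3g\n",
              length(x$lesions), x$threshold))
  for (l in x$lesions)
    cat(sprintf("  %s: %d voxels (%.2f mL)\n", l$name, sum(l$values),
                voi_volume_ml(l)))
  invisible(x)
}

# 6-connected erosion followed by dilation
morph_open6 <- function(mask) {
  d <- dim(mask)
  shift <- function(a, k, s, fill) {
    out <- array(fill, d)
    n <- d[k]
    if (n <= abs(s)) return(out)
    src <- if (s >= 0) 1:(n - s) else (1 - s):n
    dst <- if (s >= 0) (1 + s):n else 1:(n + s)
    ix_src <- ix_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ix_src[[k]] <- src; ix_dst[[k]] <- dst
    out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
      a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
    out
  }
  nb <- function(a, fill) {
    r <- a
    for (k in 1:3) for (s in c(-1L, 1L))
      r <- if (fill) r & shift(a, k, s, TRUE) else r | shift(a, k, s, FALSE)
    r
  }
  nb(nb(mask, fill = TRUE), fill = FALSE)
}

#' Tumoural / non-tumoural liver VOI construction
#'
#' Boolean VOI algebra: the tumoural liver (TL) is the union of all
#' lesion masks; the non-tumoural liver (NTL) is the whole-liver mask
#' minus TL. Lesion voxels falling outside the liver are clipped to the
#' liver with a warning, so that TL and NTL always partition the liver
#' exactly: `TL | NTL == liver` and `TL & NTL == empty`.
#'
#' @param liver whole-liver [voi_mask()].
#' @param lesions a `lesion_set` or a list of [voi_mask()] on the same
#'   geometry.
#' @return A list with `TL` and `NTL` [voi_mask()]s.
#' @export
build_voi_set <- function(liver, lesions) {
  stopifnot(is_voi_mask(liver))
  if (inherits(lesions, "lesion_set")) lesions <- lesions$lesions
  tl <- array(FALSE, liver$geometry$shape)
  for (l in lesions) {
    stopifnot(is_voi_mask(l))
    if (!same_geometry(l$geometry, liver$geometry))
      stop_geometry_mismatch(l$geometry, liver$geometry, "build_voi_set")
    tl <- tl | l$values
  }
  outside <- tl & !liver$values
  if (any(outside)) {
    warning(sprintf("%d lesion voxel(s) outside the liver; clipped", sum(outside)))
    tl <- tl & liver$values
  }
  list(TL = voi_mask(tl, liver$geometry, name = "TL"),
       NTL = voi_mask(liver$values & !tl, liver$geometry, name = "NTL"))
}

#' Write a lesion-set manifest
#'
#' Writes the integer label volume as NIfTI plus a CSV manifest with one
#' row per lesion: label, voxel count, volume (mL) and centroid (mm,
#' world coordinates).
#'
#' @param ls a `lesion_set`.
#' @param geometry the grid geometry of the labels.
#' @param label_path NIfTI output path; `NULL` to skip the volume.
#' @param csv_path CSV manifest path.
#' @return Invisibly, the manifest data frame.
#' @export
write_lesion_manifest <- function(ls, geometry, csv_path,
                                  label_path = NULL) {
  stopifnot(inherits(ls, "lesion_set"), is_grid_geometry(geometry))
  if (!is.null(label_path))
    write_volume(ls$labels, geometry, label_path, datatype = "uint8")
  rows <- lapply(seq_along(ls$lesions), function(i) {
    m <- ls$lesions[[i]]$values
    ctr <- colMeans(voxel_centres(geometry)[as.vector(m), , drop = FALSE])
    data.frame(label = i, n_voxels = sum(m),
               volume_ml = sum(m) * voxel_volume_ml(geometry),
               centroid_x_mm = ctr[1], centroid_y_mm = ctr[2],
               centroid_z_mm = ctr[3])
  })
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(manifest))
    manifest <- data.frame(label = integer(), n_voxels = integer(),
                           volume_ml = numeric(), centroid_x_mm = numeric(),
                           centroid_y_mm = numeric(), centroid_z_mm = numeric())
  utils::write.csv(manifest, csv_path, row.names = FALSE)
  invisible(manifest)
}
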