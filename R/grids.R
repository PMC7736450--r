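#' Grid geometry
#'
#' Describes an axis-aligned 3D sampling grid: voxel counts, isotropic or
#' anisotropic spacing in mm, and the world position (mm) of the centre of
#' the first voxel. All volumetric containers in the package
#' ([dose_grid()], [voi_mask()], [displacement_field()]) carry one.
#'
#' Direction cosines (oblique grids) are not supported: images are assumed
#' normalized to a common axis-aligned frame upstream.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#' @param origin numeric vector of length 3, world coordinates (mm) of the
#'   first voxel centre. Default `c(0, 0, 0)`.
#' @return An object of class `grid_geometry`.
#' @examples
#' grid_geometry(c(64, 64, 48), spacing = c(3, 3, 3))
#' @export
grid_geometry <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (anyNA(shape) || any(shape < 1L))
    stop("all shape entries must be >= 1")
  if (anyNA(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be positive and finite")
  if (anyNA(origin) || any(!is.finite(origin)))
    stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (first voxel centre): (%.4g, %.4g, %.4g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @rdname grid_geometry
#' @param x object to test or query.
#' @export
is_grid_geometry <- function(x) inherits(x, "grid_geometry")

#' Voxel volume of a grid geometry, in mL
#'
#' @param geometry a [grid_geometry()].
#' @return Voxel volume in millilitres (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(geometry) {
  stopifnot(is_grid_geometry(geometry))
  prod(geometry$spacing) / 1000
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_geometry_mismatch <- function(a, b, what) {
  stop(sprintf(
    "%s: geometries differ\n  first:  shape %s spacing %s origin %s\n  second: shape %s spacing %s origin %s",
    what,
    paste(a$shape, collapse = "x"), paste(signif(a$spacing, 6), collapse = "x"),
    paste(signif(a$origin, 6), collapse = ","),
    paste(b$shape, collapse = "x"), paste(signif(b$spacing, 6), collapse = "x"),
    paste(signif(b$origin, 6), collapse = ",")))
}

# world coordinates (mm) of all voxel centres, as an n x 3 matrix in
# column-major voxel order
voxel_centres <- function(geometry) {
  g <- geometry
  ax <- lapply(1:3, function(k)
    g$origin[k] + (seq_len(g$shape[k]) - 1) * g$spacing[k])
  n <- prod(g$shape)
  cbind(
    rep(ax[[1]], times = n / g$shape[1]),
    rep(rep(ax[[2]], each = g$shape[1]), times = g$shape[3]),
    rep(ax[[3]], each = g$shape[1] * g$shape[2]))
}

#' Absorbed-dose grid
#'
#' A 3D scalar field of absorbed dose (Gy) on a [grid_geometry()]. Holds,
#' e.g., the predictive dose matrix derived from the MAA simulation, the
#' post-treatment dose matrix from quantitative 90Y PET, and their
#' deformed / resampled variants.
#'
#' @param values numeric 3D array of non-negative, finite doses in Gy.
#' @param geometry a [grid_geometry()] matching `dim(values)`.
#' @param label free-text label (e.g. `"predictive"`, `"post-treatment"`).
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, geometry, label = "") {
  stopifnot(is_grid_geometry(geometry))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$shape))
    stop("values array does not conform to geometry$shape")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  structure(list(values = values, geometry = geometry,
                 label = as.character(label)[1]),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid%s: %s voxels, dose range [%.3g, %.3g] Gy\n",
              if (nzchar(x$label)) paste0(" \"", x$label, "\"") else "",
              paste(x$geometry$shape, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @rdname dose_grid
#' @param x object to test.
#' @export
is_dose_grid <- function(x) inherits(x, "dose_grid")

#' Binary volume-of-interest mask
#'
#' A per-voxel boolean membership map on a [grid_geometry()]: whole liver,
#' an individual lesion, the tumoural liver (TL) or non-tumoural liver
#' (NTL).
#'
#' @param values logical (or 0/1) 3D array conforming to the geometry.
#' @param geometry a [grid_geometry()].
#' @param name VOI label.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, geometry, name = "") {
  stopifnot(is_grid_geometry(geometry))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$shape))
    stop("mask array does not conform to geometry$shape")
  if (is.numeric(values)) {
    if (!all(values %in% c(0, 1)))
      stop("numeric mask values must be strictly 0/1")
    values <- array(values == 1, dim = dim(values))
  }
  if (!is.logical(values)) stop("mask values must be logical or 0/1")
  if (anyNA(values)) stop("mask values must not contain NA")
  structure(list(values = values, geometry = geometry,
                 name = as.character(name)[1]),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("voi_mask%s: %d of %s voxels set (%.1f mL)\n",
              if (nzchar(x$name)) paste0(" \"", x$name, "\"") else "",
              sum(x$values), paste(x$geometry$shape, collapse = " x "),
              voi_volume_ml(x)))
  invisible(x)
}

#' @rdname voi_mask
#' @param x object to test.
#' @export
is_voi_mask <- function(x) inherits(x, "voi_mask")

#' Volume of a VOI mask in mL
#'
#' Binary voxel membership: each in-mask voxel contributes its full
#' geometric volume (product of spacings).
#'
#' @param voi a [voi_mask()].
#' @return volume in millilitres.
#' @export
voi_volume_ml <- function(voi) {
  stopifnot(is_voi_mask(voi))
  sum(voi$values) * voxel_volume_ml(voi$geometry)
}

#' Displacement vector field
#'
#' A per-voxel 3D displacement, in mm and in the world frame, defined on a
#' [grid_geometry()]. Typically the output of a deformable registration of
#' the simulation CT onto the treatment CT; this package applies a given
#' field and diagnoses it, it does not compute registrations.
#'
#' @param vectors numeric 4D array `shape x 3` of displacements in mm.
#' @param geometry a [grid_geometry()].
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, geometry) {
  stopifnot(is_grid_geometry(geometry))
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || !all(d[1:3] == geometry$shape) || d[4] != 3L)
    stop("vectors must be a shape x 3 array conforming to the geometry")
  storage.mode(vectors) <- "double"
  if (any(!is.finite(vectors))) stop("displacement vectors must be finite")
  structure(list(vectors = vectors, geometry = geometry),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("displacement_field: %s voxels, |u| max %.3g mm, mean %.3g mm\n",
              paste(x$geometry$shape, collapse = " x "), max(mag), mean(mag)))
  invisible(x)
}

#' @rdname displacement_field
#' @param x object to test.
#' @export
is_displacement_field <- function(x) inherits(x, "displacement_field")

# trilinear sampling of a 3D array at continuous voxel indices (1-based).
# points: n x 3 matrix. Out-of-support samples get `fill`.
trilinear_sample_index <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i0 <- floor(idx)
  f <- idx - i0
  # singleton axes use constant extension within the voxel's own extent
  inside <- rep(TRUE, nrow(idx))
  for (k in 1:3) {
    if (d[k] == 1L) {
      inside <- inside & idx[, k] >= 0.5 & idx[, k] <= 1.5
      i0[, k] <- 1
      f[, k] <- 0
    } else {
      inside <- inside & idx[, k] >= 1 & idx[, k] <= d[k]
      # exact upper-border samples: pull i0 back so the cell exists
      at_top <- i0[, k] >= d[k]
      i0[at_top, k] <- d[k] - 1
      f[at_top, k] <- idx[at_top, k] - i0[at_top, k]
    }
  }
  i0[i0 < 1] <- 1  # arbitrary valid cell for outside points, masked later
  f[!inside, ] <- 0
  lin <- function(a, b, c) (c - 1) * d[1] * d[2] + (b - 1) * d[1] + a
  a0 <- i0[, 1]; b0 <- i0[, 2]; c0 <- i0[, 3]
  a1 <- pmin(a0 + 1, d[1]); b1 <- pmin(b0 + 1, d[2]); c1 <- pmin(c0 + 1, d[3])
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  v <- arr[lin(a0, b0, c0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[lin(a1, b0, c0)] * fx       * (1 - fy) * (1 - fz) +
       arr[lin(a0, b1, c0)] * (1 - fx) * fy       * (1 - fz) +
       arr[lin(a1, b1, c0)] * fx       * fy       * (1 - fz) +
       arr[lin(a0, b0, c1)] * (1 - fx) * (1 - fy) * fz +
       arr[lin(a1, b0, c1)] * fx       * (1 - fy) * fz +
       arr[lin(a0, b1, c1)] * (1 - fx) * fy       * fz +
       arr[lin(a1, b1, c1)] * fx       * fy       * fz
  v[!inside] <- fill
  v
}

nearest_sample_index <- function(arr, idx, fill = 0) {
  d <- dim(arr)
  i <- round(idx)
  inside <- i[, 1] >= 1 & i[, 1] <= d[1] &
            i[, 2] >= 1 & i[, 2] <= d[2] &
            i[, 3] >= 1 & i[, 3] <= d[3]
  i[!inside, ] <- 1
  v <- arr[(i[, 3] - 1) * d[1] * d[2] + (i[, 2] - 1) * d[1] + i[, 1]]
  v[!inside] <- fill
  v
}

# world points (n x 3, mm) -> continuous 1-based voxel indices of `geometry`
world_to_index <- function(geometry, pts) {
  sweep(sweep(pts, 2, geometry$origin, "-"), 2, geometry$spacing, "/") + 1
}

#' Resample a dose grid or VOI mask onto a target geometry
#'
#' Sampling happens at the target voxel centres, mapped through world
#' coordinates. Dose grids use trilinear interpolation; VOI masks use
#' nearest-neighbour (the two are deliberately not interchangeable:
#' interpolating a binary mask manufactures partial membership, and
#' nearest-neighbour dose resampling aliases gradients). Samples falling
#' outside the support of the source grid are set to 0 Gy (dose) or
#' background (mask).
#'
#' @param source a [dose_grid()] or [voi_mask()].
#' @param target a [grid_geometry()] to resample onto.
#' @param method `"trilinear"` (dose only) or `"nearest"` (mask only).
#'   Defaults to the appropriate method for the input class.
#' @return An object of the same class as `source`, on `target`.
#' @examples
#' g <- grid_geometry(c(8, 8, 8), c(4.79, 4.79, 4.79))
#' d <- dose_grid(array(50, c(8, 8, 8)), g)
#' fine <- grid_geometry(c(15, 15, 15), c(2.4, 2.4, 2.4), origin = c(2, 2, 2))
#' r <- resample_to(d, fine)   # constant field is preserved exactly
#' @export
resample_to <- function(source, target,
                        method = c("trilinear", "nearest")) {
  stopifnot(is_grid_geometry(target))
  if (missing(method))
    method <- if (is_voi_mask(source)) "nearest" else "trilinear"
  method <- match.arg(method)
  if (is_dose_grid(source)) {
    if (method != "trilinear")
      stop("dose grids are resampled with trilinear interpolation only")
    if (any(!is.finite(source$values)))
      stop("source dose grid contains non-finite values")
    idx <- world_to_index(source$geometry, voxel_centres(target))
    vals <- trilinear_sample_index(source$values, idx, fill = 0)
    vals[vals < 0] <- 0  # guard against tiny negative round-off
    dose_grid(array(vals, target$shape), target, label = source$label)
  } else if (is_voi_mask(source)) {
    if (method != "nearest")
      stop("VOI masks are resampled with nearest-neighbour only")
    idx <- world_to_index(source$geometry, voxel_centres(target))
    vals <- nearest_sample_index(source$values + 0, idx, fill = 0)
    voi_mask(array(vals == 1, target$shape), target, name = source$name)
  } else {
    stop("source must be a dose_grid or voi_mask")
  }
}

#' Apply a displacement field to a dose grid
#'
#' Warps a dose grid into the frame of the displacement field: for each
#' voxel of the field's grid, the output value is the trilinear sample of
#' `source` at (voxel world position + displacement). This implements the
#' workflow step in which the predictive dose matrix is deformed into the
#' post-treatment anatomy using a registration-derived vector field.
#' Samples outside the source support are set to 0 Gy.
#'
#' @param source a [dose_grid()].
#' @param dvf a [displacement_field()]; its geometry defines the output grid.
#' @return A [dose_grid()] on `dvf`'s geometry.
#' @export
apply_displacement <- function(source, dvf) {
  stopifnot(is_dose_grid(source), is_displacement_field(dvf))
  pts <- voxel_centres(dvf$geometry) +
    matrix(dvf$vectors, ncol = 3)
  idx <- world_to_index(source$geometry, pts)
  vals <- trilinear_sample_index(source$values, idx, fill = 0)
  vals[vals < 0] <- 0
  dose_grid(array(vals, dvf$geometry$shape), dvf$geometry,
            label = if (nzchar(source$label))
              paste0(source$label, "-deformed") else "deformed")
}

#' Jacobian determinant of a displacement field
#'
#' Computes, per voxel, the determinant of the Jacobian of the deformation
#' x -> x + u(x), using central differences in world units (one-sided at
#' grid borders). A strictly positive determinant everywhere indicates a
#' locally invertible, fold-free deformation; negative values flag folding.
#'
#' @param dvf a [displacement_field()] with at least 2 voxels per axis.
#' @return A list with `determinant` (3D array), `fold_free` (logical;
#'   `TRUE` iff all interior determinants are > 0 -- border voxels use
#'   one-sided differences and are excluded from the predicate), and
#'   `interior` (logical array marking the voxels the predicate covers).
#' @examples
#' g <- grid_geometry(c(6, 6, 6), c(3, 3, 3))
#' dvf <- displacement_field(array(0, c(6, 6, 6, 3)), g)
#' jacobian_determinant(dvf)$fold_free       # TRUE; determinant 1 everywhere
#' @export
jacobian_determinant <- function(dvf) {
  stopifnot(is_displacement_field(dvf))
  g <- dvf$geometry
  if (any(g$shape < 2L))
    stop("Jacobian requires at least 2 voxels along each axis")
  sh <- g$shape
  # gradient of component m along axis k, world units (mm/mm)
  grad_axis <- function(a, k) {
    n <- sh[k]
    out <- array(0, sh)
    idx <- function(range_k) {
      ix <- list(seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3]))
      ix[[k]] <- range_k
      ix
    }
    h <- g$spacing[k]
    if (n >= 3) {
      ip <- idx(3:n); im <- idx(1:(n - 2)); ic <- idx(2:(n - 1))
      out[ic[[1]], ic[[2]], ic[[3]]] <-
        (a[ip[[1]], ip[[2]], ip[[3]]] - a[im[[1]], im[[2]], im[[3]]]) / (2 * h)
    }
    lo <- idx(1); lo2 <- idx(2)
    out[lo[[1]], lo[[2]], lo[[3]]] <-
      (a[lo2[[1]], lo2[[2]], lo2[[3]]] - a[lo[[1]], lo[[2]], lo[[3]]]) / h
    hi <- idx(n); hi2 <- idx(n - 1)
    out[hi[[1]], hi[[2]], hi[[3]]] <-
      (a[hi[[1]], hi[[2]], hi[[3]]] - a[hi2[[1]], hi2[[2]], hi2[[3]]]) / h
    out
  }
  J <- vector("list", 9)  # J[[3*(m-1)+k]] = d u_m / d x_k
  for (m in 1:3) for (k in 1:3)
    J[[3 * (m - 1) + k]] <- grad_axis(dvf$vectors[, , , m], k)
  # determinant of I + J
  a11 <- 1 + J[[1]]; a12 <- J[[2]];     a13 <- J[[3]]
  a21 <- J[[4]];     a22 <- 1 + J[[5]]; a23 <- J[[6]]
  a31 <- J[[7]];     a32 <- J[[8]];     a33 <- 1 + J[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  interior <- array(FALSE, sh)
  if (all(sh >= 3L))
    interior[2:(sh[1] - 1), 2:(sh[2] - 1), 2:(sh[3] - 1)] <- TRUE
  fold_free <- if (any(interior)) all(det[interior] > 0) else all(det > 0)
  list(determinant = det, fold_free = fold_free, interior = interior)
}

#' Align a predictive / post-treatment dose pair for voxel-wise comparison
#'
#' Reproduces the comparison frame of the processing workflow: the
#' predictive dose matrix is deformed into the post-treatment anatomy by
#' applying the supplied displacement field, then the post-treatment dose
#' matrix is trilinearly resampled onto the deformed-predictive grid, so
#' the comparison runs on the (coarser) simulation-resolution grid. VOI
#' masks are carried over by nearest-neighbour resampling. Without a
#' field, both volumes are simply brought onto the predictive grid.
#'
#' @param pred predictive [dose_grid()].
#' @param post post-treatment [dose_grid()].
#' @param dvf optional [displacement_field()] mapping the predictive
#'   anatomy onto the post-treatment anatomy.
#' @param vois optional (named) list of [voi_mask()] to resample onto the
#'   comparison grid.
#' @return A list with `pred`, `post` (aligned [dose_grid()]s on one
#'   geometry) and `vois` (aligned masks).
#' @export
align_dosimetry <- function(pred, post, dvf = NULL, vois = list()) {
  stopifnot(is_dose_grid(pred), is_dose_grid(post))
  if (!is.null(dvf)) {
    stopifnot(is_displacement_field(dvf))
    pred_a <- apply_displacement(pred, dvf)
  } else {
    pred_a <- pred
  }
  target <- pred_a$geometry
  post_a <- if (same_geometry(post$geometry, target)) post else
    resample_to(post, target, "trilinear")
  vois_a <- lapply(vois, function(v) {
    stopifnot(is_voi_mask(v))
    if (same_geometry(v$geometry, target)) v else
      resample_to(v, target, "nearest")
  })
  list(pred = pred_a, post = post_a, vois = vois_a)
}
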