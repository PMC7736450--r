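# shared low-level NIfTI writer: 3D or 4D array + geometry
write_volume <- function(values, geometry, path, datatype = "auto") {
  stopifnot(is_grid_geometry(geometry))
  img <- RNifti::asNifti(values)
  d <- dim(values)
  RNifti::pixdim(img) <- geometry$spacing
  m <- diag(c(geometry$spacing, 1))
  m[1:3, 4] <- geometry$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  origin <- xf[1:3, 4]
  # the package writes axis-aligned positive-diagonal xforms; reading an
  # externally produced oblique volume is rejected rather than silently
  # mis-geometried
  if (any(abs(xf[1:3, 1:3] - diag(abs(sp))) > 1e-3 * max(abs(sp))))
    stop("only axis-aligned volumes with positive spacing are supported")
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))
  list(values = vals,
       geometry = grid_geometry(dim(vals)[1:3], abs(sp), origin))
}

#' Read / write dose grids as NIfTI
#'
#' Dose values in Gy; grid geometry carried in the NIfTI header (pixdim
#' and an axis-aligned sform). Oblique orientations are not supported.
#'
#' @param dose a [dose_grid()].
#' @param path `.nii` or `.nii.gz` path.
#' @param label label for the grid read back.
#' @return `write_dose_grid` invisibly returns `path`; `read_dose_grid`
#'   returns a [dose_grid()].
#' @export
write_dose_grid <- function(dose, path) {
  stopifnot(is_dose_grid(dose))
  write_volume(dose$values, dose$geometry, path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path, label = "") {
  v <- read_volume(path)
  if (length(dim(v$values)) != 3L) stop("expected a 3D dose volume")
  dose_grid(v$values, v$geometry, label = label)
}

#' Read / write VOI masks as NIfTI (uint8)
#'
#' Masks are stored as uint8 0/1 volumes, which round-trip bit-exact.
#'
#' @param voi a [voi_mask()].
#' @param path `.nii` or `.nii.gz` path.
#' @param name VOI name for the mask read back.
#' @return `write_voi_mask` invisibly returns `path`; `read_voi_mask`
#'   returns a [voi_mask()].
#' @export
write_voi_mask <- function(voi, path) {
  stopifnot(is_voi_mask(voi))
  write_volume(voi$values + 0L, voi$geometry, path, datatype = "uint8")
}

#' @rdname write_voi_mask
#' @export
read_voi_mask <- function(path, name = "") {
  v <- read_volume(path)
  if (length(dim(v$values)) != 3L) stop("expected a 3D mask volume")
  voi_mask(v$values == 1, v$geometry, name = name)
}

#' Read / write displacement fields as 4D NIfTI
#'
#' Stored as a shape x 3 volume of world-frame displacements in mm.
#'
#' @param dvf a [displacement_field()].
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_displacement_field` invisibly returns `path`;
#'   `read_displacement_field` returns a [displacement_field()].
#' @export
write_displacement_field <- function(dvf, path) {
  stopifnot(is_displacement_field(dvf))
  write_volume(dvf$vectors, dvf$geometry, path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  v <- read_volume(path)
  d <- dim(v$values)
  if (length(d) != 4L || d[4] != 3L)
    stop("expected a 4D (shape x 3) displacement volume")
  displacement_field(v$values, v$geometry)
}

#' Read / write activity grids as NIfTI plus a units sidecar
#'
#' The units (`"counts"`, `"MBq"`, `"MBq_h"`) travel in a JSON sidecar
#' next to the volume (`<path>.json`).
#'
#' @param grid an [activity_grid()].
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_activity_grid` invisibly returns `path`;
#'   `read_activity_grid` returns an [activity_grid()].
#' @export
write_activity_grid <- function(grid, path) {
  stopifnot(inherits(grid, "activity_grid"))
  write_volume(grid$values, grid$geometry, path)
  jsonlite::write_json(list(units = grid$units),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_activity_grid
#' @export
read_activity_grid <- function(path) {
  v <- read_volume(path)
  sidecar <- paste0(path, ".json")
  units <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar)$units else "counts"
  activity_grid(v$values, v$geometry, units = units)
}

#' Read / write a weighting specification as JSON
#'
#' Schema: `{"zero_low": 10, "full_low": 40, "full_high": 120,
#' "zero_high": 200}` with optional `straddle_low` / `straddle_high`.
#'
#' @param spec a [weight_spec()].
#' @param path JSON path.
#' @return `write_weight_spec` invisibly returns `path`;
#'   `read_weight_spec` returns a [weight_spec()].
#' @export
write_weight_spec <- function(spec, path) {
  stopifnot(inherits(spec, "weight_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_weight_spec
#' @export
read_weight_spec <- function(path) {
  x <- jsonlite::read_json(path)
  do.call(weight_spec, x[intersect(names(x),
    c("zero_low", "full_low", "full_high", "zero_high",
      "straddle_low", "straddle_high"))])
}
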