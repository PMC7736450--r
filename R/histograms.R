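#' Cumulative dose-volume histogram over a VOI
#'
#' Bins the in-VOI voxel doses (each voxel contributes its full geometric
#' volume -- membership is binary, no partial-volume weighting) and
#' accumulates from the top: `cumulative_fraction[k]` is the fraction of
#' VOI volume receiving at least `bin_edges[k]` Gy. The curve starts at 1
#' and is non-increasing.
#'
#' @param dose a [dose_grid()].
#' @param voi a non-empty [voi_mask()] sharing the dose geometry.
#' @param bin_width_gy histogram bin width in Gy (default 1).
#' @return An object of class `dvh_curve`: `bin_edges` (Gy, from 0),
#'   `cumulative_fraction`, `bin_width_gy`, plus the raw in-VOI voxel
#'   doses (`doses`) used for exact mean-dose extraction.
#' @export
compute_dvh <- function(dose, voi, bin_width_gy = 1) {
  stopifnot(is_dose_grid(dose), is_voi_mask(voi), bin_width_gy > 0)
  if (!same_geometry(dose$geometry, voi$geometry))
    stop_geometry_mismatch(dose$geometry, voi$geometry, "compute_dvh")
  if (!any(voi$values)) stop("VOI is empty")
  d <- dose$values[voi$values]
  n_bins <- max(1L, ceiling(max(d) / bin_width_gy + 1e-12))
  edges <- seq(0, by = bin_width_gy, length.out = n_bins + 1L)
  # accumulate from the top: fraction of voxels with dose >= each edge
  sd <- sort(d)
  cumfrac <- (length(d) -
    findInterval(edges, sd, left.open = TRUE)) / length(d)
  structure(list(bin_edges = edges, cumulative_fraction = cumfrac,
                 bin_width_gy = bin_width_gy, doses = d),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("dvh_curve: %d bins of %g Gy, %d voxels, mean dose %.1f Gy\n",
              length(x$bin_edges) - 1L, x$bin_width_gy,
              length(x$doses), mean(x$doses)))
  invisible(x)
}

# D_X from a cumulative curve: linear interpolation at fraction X/100.
# If the curve equals the level exactly on a plateau of edges, the lowest
# edge of the plateau is taken ("minimum dose received by at least X%").
dx_from_curve <- function(edges, cumfrac, x_percent) {
  y <- x_percent / 100
  eq <- which(abs(cumfrac - y) < 1e-12)
  if (length(eq)) return(edges[eq[1]])
  above <- which(cumfrac > y)
  if (!length(above)) return(edges[1])
  k <- max(above)                     # last edge with fraction above level
  if (k == length(edges)) return(edges[k])
  f0 <- cumfrac[k]; f1 <- cumfrac[k + 1]
  edges[k] + (f0 - y) / (f0 - f1) * (edges[k + 1] - edges[k])
}

#' Extract DVH indices
#'
#' D90, D70, D50 and D20 (the minimum dose received by at least X% of the
#' VOI volume) are read off the cumulative curve by linear interpolation
#' at fraction X/100; exact plateaus resolve to their lowest dose. Dmean
#' is the arithmetic mean of the unbinned in-VOI voxel doses, never a
#' binned approximation.
#'
#' @param curve a [compute_dvh()] result.
#' @param doses optional raw in-VOI voxel doses for the exact mean;
#'   defaults to the doses stored on the curve.
#' @return An object of class `dvh_indices`: named numeric with `D90`,
#'   `D70`, `D50`, `Dmean`, `D20` in Gy.
#' @examples
#' g <- grid_geometry(c(4, 4, 4), c(3, 3, 3))
#' d <- dose_grid(array(50, c(4, 4, 4)), g)
#' v <- voi_mask(array(TRUE, c(4, 4, 4)), g)
#' extract_indices(compute_dvh(d, v))   # all indices 50 Gy
#' @export
extract_indices <- function(curve, doses = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (is.null(doses)) doses <- curve$doses
  # interpolated D_X can overshoot inside the final bin; by definition no
  # index exceeds the maximum voxel dose
  dx <- function(x) min(dx_from_curve(curve$bin_edges,
                                      curve$cumulative_fraction, x),
                        max(doses))
  out <- c(D90 = dx(90), D70 = dx(70), D50 = dx(50),
           Dmean = mean(doses), D20 = dx(20))
  structure(out, class = "dvh_indices")
}

#' @export
print.dvh_indices <- function(x, ...) {
  cat(sprintf("D90 %.1f | D70 %.1f | D50 %.1f | Dmean %.1f | D20 %.1f Gy\n",
              x["D90"], x["D70"], x["D50"], x["Dmean"], x["D20"]))
  invisible(x)
}

#' DVH indices straight from a dose grid and VOI
#'
#' Convenience wrapper: [compute_dvh()] then [extract_indices()].
#'
#' @inheritParams compute_dvh
#' @return A `dvh_indices` object.
#' @export
dvh_indices <- function(dose, voi, bin_width_gy = 1) {
  extract_indices(compute_dvh(dose, voi, bin_width_gy))
}

#' Write a DVH curve to CSV
#'
#' Columns `bin_left_gy`, `cumulative_fraction`.
#'
#' @param curve a `dvh_curve`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_dvh_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  utils::write.csv(
    data.frame(bin_left_gy = curve$bin_edges,
               cumulative_fraction = curve$cumulative_fraction),
    path, row.names = FALSE)
  invisible(path)
}
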