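#' Yttrium-90 physical constants
#'
#' Defaults for the 90Y physical half-life and mean beta energy per decay,
#' kept as configuration rather than hard-coded literals so other isotope
#' data evaluations (or non-90Y tracers) can be substituted.
#'
#' @param half_life_hours physical half-life in hours (default 64.05).
#' @param mean_energy_mev mean beta energy per decay in MeV
#'   (default 0.9337).
#' @return A named list of class `y90_constants`.
#' @export
y90_constants <- function(half_life_hours = 64.05,
                          mean_energy_mev = 0.9337) {
  if (half_life_hours <= 0 || mean_energy_mev <= 0)
    stop("physical constants must be positive")
  structure(list(half_life_hours = half_life_hours,
                 mean_energy_mev = mean_energy_mev),
            class = "y90_constants")
}

#' Administration record
#'
#' Prepared and residual activities of one treatment session. The
#' residual is what stays in the injection box after administration; the
#' net administered activity is their difference.
#'
#' @param prepared_activity prepared activity, MBq.
#' @param residual_activity residual activity, MBq
#'   (`0 <= residual <= prepared`).
#' @param half_life_hours physical half-life used downstream, hours.
#' @return An object of class `administration_record`.
#' @export
administration_record <- function(prepared_activity, residual_activity = 0,
                                  half_life_hours = 64.05) {
  if (!is.finite(prepared_activity) || prepared_activity < 0)
    stop("prepared_activity must be a non-negative number")
  if (!is.finite(residual_activity) || residual_activity < 0)
    stop("residual_activity must be a non-negative number")
  if (residual_activity > prepared_activity)
    stop("residual activity exceeds prepared activity")
  if (half_life_hours <= 0) stop("half_life_hours must be positive")
  structure(list(prepared_activity = prepared_activity,
                 residual_activity = residual_activity,
                 half_life_hours = half_life_hours),
            class = "administration_record")
}

#' Net administered activity
#'
#' @param rec an [administration_record()].
#' @return Net activity (prepared minus residual), MBq.
#' @examples
#' net_activity(administration_record(1300, 38))  # 1262 MBq
#' @export
net_activity <- function(rec) {
  stopifnot(inherits(rec, "administration_record"))
  rec$prepared_activity - rec$residual_activity
}

#' Activity grid
#'
#' A 3D non-negative scalar field on a [grid_geometry()] holding either
#' raw MAA counts (relative distribution only), an activity map in MBq,
#' or a time-integrated activity (TIA) map in MBq h.
#'
#' @param values numeric 3D array, non-negative and finite.
#' @param geometry a [grid_geometry()].
#' @param units one of `"counts"`, `"MBq"`, `"MBq_h"`.
#' @return An object of class `activity_grid`.
#' @export
activity_grid <- function(values, geometry,
                          units = c("counts", "MBq", "MBq_h")) {
  stopifnot(is_grid_geometry(geometry))
  units <- match.arg(units)
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == geometry$shape))
    stop("values array does not conform to geometry$shape")
  storage.mode(values) <- "double"
  if (any(!is.finite(values)) || any(values < 0))
    stop("activity values must be finite and non-negative")
  structure(list(values = values, geometry = geometry, units = units),
            class = "activity_grid")
}

#' @export
print.activity_grid <- function(x, ...) {
  cat(sprintf("activity_grid [%s]: %s voxels, total %.4g\n", x$units,
              paste(x$geometry$shape, collapse = " x "), sum(x$values)))
  invisible(x)
}

#' Predictive time-integrated activity from an MAA count map
#'
#' Distributes the net administered 90Y activity over the voxels in
#' proportion to their MAA counts, and integrates the mono-exponential
#' physical decay to infinity: voxel TIA = `a_net * (counts_i /
#' sum(counts)) * half_life / ln 2` (MBq h). The total TIA is exactly
#' `a_net * half_life / ln 2` -- microspheres are permanently implanted,
#' so only physical decay removes activity. The output is invariant to
#' any uniform rescaling of the raw counts.
#'
#' @param maa_counts an [activity_grid()] with units `"counts"` (strictly
#'   positive total).
#' @param a_net net administered activity, MBq.
#' @param half_life_hours 90Y physical half-life, hours.
#' @return An [activity_grid()] with units `"MBq_h"`.
#' @export
maa_to_tia <- function(maa_counts, a_net,
                       half_life_hours = y90_constants()$half_life_hours) {
  stopifnot(inherits(maa_counts, "activity_grid"))
  if (maa_counts$units != "counts")
    stop("maa_to_tia expects a counts map")
  if (!is.finite(a_net) || a_net <= 0) stop("a_net must be positive")
  total <- sum(maa_counts$values)
  if (total <= 0) stop("count map is all zero")
  tia <- a_net * (maa_counts$values / total) * half_life_hours / log(2)
  activity_grid(tia, maa_counts$geometry, units = "MBq_h")
}

#' Absorbed dose from a TIA map (local deposition)
#'
#' Converts a time-integrated-activity map into absorbed dose under the
#' local deposition model: every decay deposits the mean beta energy in
#' the voxel where it occurs (no kernel transport -- the 90Y beta range,
#' a few mm, is comparable to the voxel size, and this is the standard
#' first-order voxel dosimetry convention; the model choice is recorded
#' on the returned grid's label). Dose = deposited energy / voxel mass,
#' with mass from a uniform tissue density.
#'
#' @param tia an [activity_grid()] with units `"MBq_h"`.
#' @param density_g_per_ml uniform tissue density (default 1.03 g/mL,
#'   soft-tissue).
#' @param constants a [y90_constants()] supplying the mean beta energy.
#' @return A [dose_grid()] in Gy, labelled `"local-deposition"`.
#' @export
tia_to_dose <- function(tia, density_g_per_ml = 1.03,
                        constants = y90_constants()) {
  stopifnot(inherits(tia, "activity_grid"))
  if (tia$units != "MBq_h") stop("tia_to_dose expects a TIA map in MBq_h")
  if (!is.finite(density_g_per_ml) || density_g_per_ml <= 0)
    stop("density must be positive")
  mev_to_j <- 1.602176634e-13
  decays <- tia$values * 1e6 * 3600          # MBq h -> decays
  energy_j <- decays * constants$mean_energy_mev * mev_to_j
  mass_kg <- density_g_per_ml * voxel_volume_ml(tia$geometry) / 1000
  dose_grid(energy_j / mass_kg, tia$geometry, label = "local-deposition")
}

#' Predictive dose matrix in one call
#'
#' MAA counts + administration record -> TIA -> absorbed dose, i.e. the
#' full predictive-dosimetry chain.
#'
#' @param maa_counts an [activity_grid()] of MAA counts.
#' @param rec an [administration_record()].
#' @param density_g_per_ml uniform tissue density, g/mL.
#' @param constants a [y90_constants()].
#' @return A [dose_grid()] in Gy.
#' @export
predictive_dose <- function(maa_counts, rec, density_g_per_ml = 1.03,
                            constants = y90_constants()) {
  tia <- maa_to_tia(maa_counts, net_activity(rec), constants$half_life_hours)
  d <- tia_to_dose(tia, density_g_per_ml, constants)
  d$label <- "predictive"
  d
}

#' Post-treatment dose from a quantitative 90Y activity map
#'
#' An activity map in MBq (e.g. quantitative 90Y PET at a reference time
#' taken as the administration time) is decay-integrated to a TIA map and
#' converted through the same local-deposition path as the predictive
#' dose.
#'
#' @param activity an [activity_grid()] with units `"MBq"`.
#' @param density_g_per_ml uniform tissue density, g/mL.
#' @param constants a [y90_constants()].
#' @return A [dose_grid()] in Gy, labelled `"post-treatment"`.
#' @export
posttreatment_dose <- function(activity, density_g_per_ml = 1.03,
                               constants = y90_constants()) {
  stopifnot(inherits(activity, "activity_grid"))
  if (activity$units != "MBq")
    stop("posttreatment_dose expects an activity map in MBq")
  tia <- activity_grid(activity$values * constants$half_life_hours / log(2),
                       activity$geometry, units = "MBq_h")
  d <- tia_to_dose(tia, density_g_per_ml, constants)
  d$label <- "post-treatment"
  d
}
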