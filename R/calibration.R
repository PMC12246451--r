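#' Camera length from diffraction spot distances
#'
#' Inverts the camera equation `R_hkl * d_hkl = lambda * L` (small-angle
#' Bragg geometry): the effective camera length follows from the measured
#' distance of a known reflection.
#'
#' @param R_hkl_mm Measured spot distance from the direct beam, in mm.
#' @param d_hkl_A Known lattice spacing of the reflection, in Angstrom.
#' @param lambda_pm Electron wavelength in pm.
#' @return Effective camera length in cm.
#' @examples
#' camera_length_from_spots(1.583, 1.9201, electron_wavelength(200))
#' @export
camera_length_from_spots <- function(R_hkl_mm, d_hkl_A, lambda_pm) {
  assert_positive(R_hkl_mm, "R_hkl_mm")
  assert_positive(d_hkl_A, "d_hkl_A")
  assert_positive(lambda_pm, "lambda_pm")
  (R_hkl_mm * 1e-3) * (d_hkl_A * 1e-10) / (lambda_pm * 1e-12) * 1e2
}

#' Spot distance expected for a camera length
#'
#' Forward form of the camera equation; round-trips exactly with
#' [camera_length_from_spots()].
#'
#' @param L_cm Effective camera length in cm.
#' @inheritParams camera_length_from_spots
#' @return Spot distance in mm.
#' @export
spot_distance_from_L <- function(L_cm, d_hkl_A, lambda_pm) {
  assert_positive(L_cm, "L_cm")
  assert_positive(d_hkl_A, "d_hkl_A")
  assert_positive(lambda_pm, "lambda_pm")
  (lambda_pm * 1e-12) * (L_cm * 1e-2) / (d_hkl_A * 1e-10) * 1e3
}

#' Convergence semi-angle from Bragg disk geometry
#'
#' The semi-angle is proportional to the ratio between the aperture (BF disk)
#' radius and the spacing of Bragg disks of known angle:
#' `alpha = bragg_angle * (aperture_px / 2) / spacing_px`.
#'
#' @param bragg_angle_mrad Known disk-to-disk Bragg angle (2 theta_B), mrad.
#' @param disk_spacing_px Measured spacing of the Bragg disks, pixels.
#' @param aperture_diameter_px Measured BF disk (aperture image) diameter, pixels.
#' @return Convergence semi-angle in mrad.
#' @export
semi_angle_from_disks <- function(bragg_angle_mrad, disk_spacing_px,
                                  aperture_diameter_px) {
  assert_positive(bragg_angle_mrad, "bragg_angle_mrad")
  assert_positive(disk_spacing_px, "disk_spacing_px")
  assert_positive(aperture_diameter_px, "aperture_diameter_px")
  bragg_angle_mrad * (aperture_diameter_px / 2) / disk_spacing_px
}

#' Scan-step correction factor from a known lattice repeat
#'
#' From an image of a row of atoms with known spacing, the correction factor
#' between real and nominal scan pixel size is
#' `expected_spacing / (measured_pixels_per_repeat * nominal_step)`.
#'
#' @param nominal_step_A Nominal scan step, Angstrom per pixel.
#' @param expected_spacing_A Known inter-atomic spacing, Angstrom.
#' @param measured_pixels_per_repeat Measured pixels per lattice repeat.
#' @return Dimensionless correction factor; corrected step =
#'   `nominal_step_A * factor`.
#' @export
scan_step_correction <- function(nominal_step_A, expected_spacing_A,
                                 measured_pixels_per_repeat) {
  assert_positive(nominal_step_A, "nominal_step_A")
  assert_positive(expected_spacing_A, "expected_spacing_A")
  assert_positive(measured_pixels_per_repeat, "measured_pixels_per_repeat")
  expected_spacing_A / (measured_pixels_per_repeat * nominal_step_A)
}

#' Read a microscope calibration table
#'
#' The calibration file is a long-format CSV with columns `table`, `key`,
#' `value` holding, per microscope, the available accelerating voltages,
#' the aperture name to convergence semi-angle map (mrad), the magnification
#' to field-of-view map (Angstrom), the nominal to effective camera length
#' map (cm), and detector properties (`n_pixels`, `pitch_um`, `binnings`
#' comma-separated, optional `paar_mrad`, optional `dtheta_mrad` measured at
#' the camera length named by `dtheta_at_nominal_cl`).
#'
#' @param path Path to the CSV file.
#' @return A list with elements `voltages_kV` (numeric), `apertures`
#'   (named numeric, mrad), `magnifications` (named numeric, Angstrom FOV),
#'   `camera_lengths` (data.frame nominal_cm/effective_cm) and `detector`
#'   (named list).
#' @export
read_calibrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("table", "key", "value")
  if (!all(need %in% names(df))) stop_domain("calibration CSV needs columns table,key,value")
  pick <- function(tab) df[df$table == tab, , drop = FALSE]
  volt <- pick("voltages")
  ap <- pick("apertures")
  mag <- pick("magnifications")
  cl <- pick("camera_lengths")
  det <- pick("detector")
  detl <- as.list(det$value)
  names(detl) <- det$key
  num_or_chr <- function(x) {
    y <- suppressWarnings(as.numeric(x))
    if (all(!is.na(y))) y else x
  }
  detl <- lapply(detl, num_or_chr)
  if (!is.null(detl$binnings) && is.character(detl$binnings)) {
    detl$binnings <- as.numeric(strsplit(detl$binnings, ";")[[1]])
  }
  list(
    voltages_kV = as.numeric(volt$value),
    apertures = stats::setNames(as.numeric(ap$value), ap$key),
    magnifications = stats::setNames(as.numeric(mag$value), mag$key),
    camera_lengths = data.frame(nominal_cm = as.numeric(cl$key),
                                effective_cm = as.numeric(cl$value)),
    detector = detl
  )
}

#' Effective camera length for a nominal setting
#'
#' @param calib A calibration list from [read_calibrations()].
#' @param nominal_cm Nominal camera length (must be present in the table).
#' @return Effective camera length in cm.
#' @export
effective_camera_length <- function(calib, nominal_cm) {
  tab <- calib$camera_lengths
  i <- match(nominal_cm, tab$nominal_cm)
  if (is.na(i)) stop_domain("nominal camera length not found in calibration table")
  tab$effective_cm[i]
}
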