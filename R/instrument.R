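#' Electron beam settings
#'
#' Bundles the beam-side acquisition parameters: accelerating voltage,
#' probe-forming convergence semi-angle, defocus, probe current and the
#' focused probe diameter (the vendor-defined diameter containing 59% of the
#' beam intensity).
#'
#' @param voltage_kV Accelerating voltage in kV (> 0).
#' @param alpha_mrad Convergence semi-angle in mrad (> 0).
#' @param defocus_nm Defocus magnitude in nm (>= 0; the sign convention is
#'   magnitude-only, underfocus assumed).
#' @param current_pA Probe current in pA (>= 0).
#' @param d0_A Focused probe diameter in Angstrom (>= 0), defined as the
#'   diameter of the disk containing 59% of the total beam intensity.
#' @return An object of class `beam_setting`.
#' @examples
#' beam_setting(200, 27.42, defocus_nm = 0, current_pA = 11, d0_A = 0.8)
#' @export
beam_setting <- function(voltage_kV, alpha_mrad, defocus_nm = 0,
                         current_pA = 0, d0_A = 0) {
  assert_positive(voltage_kV, "voltage_kV")
  assert_positive(alpha_mrad, "alpha_mrad")
  assert_nonneg(defocus_nm, "defocus_nm")
  assert_nonneg(current_pA, "current_pA")
  assert_nonneg(d0_A, "d0_A")
  structure(list(voltage_kV = voltage_kV, alpha_mrad = alpha_mrad,
                 defocus_nm = defocus_nm, current_pA = current_pA,
                 d0_A = d0_A),
            class = "beam_setting")
}

#' Scan settings
#'
#' @param step_A Nominal scanning step in Angstrom (> 0).
#' @param nx,ny Scan grid size in positions (>= 1).
#' @param dwell_us Dwell time per position in microseconds (> 0).
#' @param skip Non-negative integer; every `(skip + 1)`-th position is used
#'   along each axis, so the effective step is `step_A * (skip + 1)` and the
#'   dose drops by `(skip + 1)^2`.
#' @return An object of class `scan_setting`.
#' @export
scan_setting <- function(step_A, nx = 128L, ny = nx, dwell_us = 1,
                         skip = 0L) {
  assert_positive(step_A, "step_A")
  assert_positive(dwell_us, "dwell_us")
  if (nx < 1 || ny < 1) stop_domain("scan grid must have at least 1 position per axis")
  assert_nonneg(skip, "skip")
  if (skip != round(skip)) stop_domain("`skip` must be an integer")
  structure(list(step_A = step_A, nx = as.integer(nx), ny = as.integer(ny),
                 dwell_us = dwell_us, skip = as.integer(skip)),
            class = "scan_setting")
}

#' Effective scan step after skipping
#' @param scan A [scan_setting()].
#' @return Step in Angstrom actually used, `step_A * (skip + 1)`.
#' @export
scan_step_used <- function(scan) scan$step_A * (scan$skip + 1)

#' Pixelated detector model
#'
#' Describes the detector geometry and its angular calibration. The angular
#' pitch per effective (binned) pixel is taken from `dtheta_mrad` when a
#' measured calibration is available, otherwise from the small-angle camera
#' geometry `p_eff / L`.
#'
#' @param n_pixels Unbinned pixels per side (>= 2).
#' @param pitch_um Physical pixel pitch in micrometres (> 0).
#' @param binning Integer binning factor (>= 1, must divide `n_pixels`).
#' @param padding Zero-pad pixels added per side post-acquisition, counted in
#'   effective (binned) pixels; enlarges the half-width used for the
#'   reconstruction pixel size only, never the detected angle.
#' @param camera_length_cm Effective camera length in cm, or `NA` when only a
#'   measured `dtheta_mrad` is known.
#' @param dtheta_mrad Optional measured angular pitch per effective pixel
#'   (mrad); overrides the value derived from the camera length.
#' @param paar_mrad Optional pumping-aperture angle restriction: maximum
#'   scattering semi-angle (mrad) passed to the detector.
#' @return An object of class `detector_model`.
#' @export
detector_model <- function(n_pixels = 192L, pitch_um = 100, binning = 1L,
                           padding = 0L, camera_length_cm = NA_real_,
                           dtheta_mrad = NULL, paar_mrad = NULL) {
  if (n_pixels < 2) stop_domain("`n_pixels` must be >= 2")
  assert_positive(pitch_um, "pitch_um")
  if (binning < 1 || n_pixels %% binning != 0)
    stop_domain("`binning` must be a positive divisor of `n_pixels`")
  assert_nonneg(padding, "padding")
  if (!is.null(dtheta_mrad)) assert_positive(dtheta_mrad, "dtheta_mrad")
  if (!is.null(paar_mrad)) assert_positive(paar_mrad, "paar_mrad")
  if (!is.na(camera_length_cm)) assert_positive(camera_length_cm, "camera_length_cm")
  structure(list(n_pixels = as.integer(n_pixels), pitch_um = pitch_um,
                 binning = as.integer(binning), padding = as.integer(padding),
                 camera_length_cm = camera_length_cm,
                 dtheta_mrad = dtheta_mrad, paar_mrad = paar_mrad),
            class = "detector_model")
}

#' Full acquisition plan
#'
#' @param beam A [beam_setting()].
#' @param scan A [scan_setting()].
#' @param detector A [detector_model()].
#' @param method Reconstruction method the plan targets: `"SSB"` (direct
#'   single side band) or `"ITR"` (iterative, e.g. ePIE).
#' @return An object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(beam, scan, detector, method = c("ITR", "SSB")) {
  stopifnot(inherits(beam, "beam_setting"), inherits(scan, "scan_setting"),
            inherits(detector, "detector_model"))
  method <- match.arg(method)
  structure(list(beam = beam, scan = scan, detector = detector,
                 method = method),
            class = "acquisition_plan")
}

#' Relativistic electron wavelength
#'
#' de Broglie wavelength of an electron accelerated through `voltage_kV`,
#' with the relativistic correction: lambda = h / sqrt(2 m0 e V (1 + eV /
#' (2 m0 c^2))).
#'
#' @param voltage_kV Accelerating voltage in kV (> 0). Vectorised.
#' @return Wavelength in picometres.
#' @examples
#' electron_wavelength(200)  # 2.508 pm
#' @export
electron_wavelength <- function(voltage_kV) {
  assert_positive(voltage_kV, "voltage_kV")
  V <- voltage_kV * 1e3
  with(.const, h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * c^2))) * 1e12)
}

#' Electrons per position and areal dose
#'
#' Electrons per diffraction pattern `I t / e` and areal dose
#' `electrons / step_used^2`, where the step used accounts for position
#' skipping.
#'
#' @param beam A [beam_setting()] (probe current is read from it).
#' @param scan A [scan_setting()].
#' @return A list with `electrons_per_position` and `dose_e_per_A2`.
#' @examples
#' b <- beam_setting(200, 27.42, current_pA = 11)
#' s <- scan_setting(0.15903, dwell_us = 50)
#' dose_budget(b, s)  # ~3433 electrons, ~136,000 e/A^2
#' @export
dose_budget <- function(beam, scan) {
  assert_positive(beam$current_pA, "current_pA")
  ne <- beam$current_pA * 1e-12 * scan$dwell_us * 1e-6 / .const$e
  dr <- scan_step_used(scan)
  list(electrons_per_position = ne, dose_e_per_A2 = ne / dr^2)
}

#' Geometric probe diameter at defocus
#'
#' Composes the focused probe diameter with the defocus cone. The default
#' additive convention `d0 + 2 defocus tan(alpha)` is the conservative
#' (larger) bound; quadrature composition is available.
#'
#' @param beam A [beam_setting()].
#' @param convention `"additive"` (default) or `"quadrature"`.
#' @return Probe diameter in Angstrom.
#' @export
geometric_probe_diameter <- function(beam, convention = c("additive", "quadrature")) {
  convention <- match.arg(convention)
  cone <- 2 * beam$defocus_nm * 10 * tan(beam$alpha_mrad / 1000)
  if (convention == "additive") beam$d0_A + cone else sqrt(beam$d0_A^2 + cone^2)
}

#' Derived detector/beam geometry for a plan
#'
#' Computes the wavelength, angular calibration, detected-angle range,
#' bright-field disk size and dose figures implied by an acquisition plan.
#' The maximum detected angle is the semi-angle at the midpoint of the
#' detector edge (half-width `M = (N / binning) / 2` effective pixels),
#' clipped to the pumping-aperture restriction when one is set. Padding
#' enlarges the half-width used for the reconstruction pixel size
#' (`padding_factor`) but does not change the angular pitch or detected
#' angle.
#'
#' @param plan An [acquisition_plan()].
#' @return An object of class `derived_geometry`: list with `lambda_pm`,
#'   `dtheta_mrad`, `theta_mrad` (clipped), `theta_unclipped_mrad`,
#'   `half_width_px`, `padding_factor`, `bf_disk_diameter_px`,
#'   `coverage_alpha`, `electrons_per_position`, `dose_e_per_A2`.
#' @export
derive_geometry <- function(plan) {
  det <- plan$detector
  beam <- plan$beam
  lambda_pm <- electron_wavelength(beam$voltage_kV)
  M <- (det$n_pixels / det$binning) / 2
  if (!is.null(det$dtheta_mrad)) {
    dtheta <- det$dtheta_mrad
  } else if (!is.na(det$camera_length_cm)) {
    # small-angle camera geometry: one effective pixel subtends p_eff / L
    p_eff_m <- det$pitch_um * det$binning * 1e-6
    dtheta <- p_eff_m / (det$camera_length_cm * 1e-2) * 1e3
  } else {
    stop_domain("detector needs a camera length or a measured angular pitch")
  }
  theta_unclipped <- M * dtheta
  theta <- if (!is.null(det$paar_mrad)) min(theta_unclipped, det$paar_mrad) else theta_unclipped
  dose <- if (beam$current_pA > 0) dose_budget(beam, plan$scan) else
    list(electrons_per_position = 0, dose_e_per_A2 = 0)
  structure(list(
    lambda_pm = lambda_pm,
    dtheta_mrad = dtheta,
    theta_mrad = theta,
    theta_unclipped_mrad = theta_unclipped,
    half_width_px = M,
    padding_factor = (M + det$padding) / M,
    bf_disk_diameter_px = 2 * beam$alpha_mrad / dtheta,
    coverage_alpha = theta / beam$alpha_mrad,
    electrons_per_position = dose$electrons_per_position,
    dose_e_per_A2 = dose$dose_e_per_A2
  ), class = "derived_geometry")
}

#' @export
print.derived_geometry <- function(x, ...) {
  cat(sprintf("wavelength      %8.4f pm\n", x$lambda_pm))
  cat(sprintf("angular pitch   %8.5f mrad/px\n", x$dtheta_mrad))
  cat(sprintf("max angle       %8.2f mrad (%.2f alpha)\n", x$theta_mrad, x$coverage_alpha))
  cat(sprintf("BF disk         %8.2f px\n", x$bf_disk_diameter_px))
  if (x$dose_e_per_A2 > 0) {
    cat(sprintf("electrons/pos   %8.0f\n", x$electrons_per_position))
    cat(sprintf("dose            %8.0f e/A^2\n", x$dose_e_per_A2))
  }
  invisible(x)
}
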