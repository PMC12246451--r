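#' Probe window size
#'
#' The computational probe window is the real-space field of view implied by
#' the detector angular pitch, `D_psi = lambda / dtheta`; Nyquist sampling of
#' the probe requires the probe diameter not to exceed half the window,
#' `d_probe_max = D_psi / 2`.
#'
#' @param lambda_pm Wavelength in pm.
#' @param dtheta_mrad Angular pitch per effective detector pixel, mrad.
#' @return List with `D_psi_A` and `d_probe_max_A` (Angstrom).
#' @examples
#' probe_window(electron_wavelength(200), 0.83125)  # ~30.2 A window
#' @export
probe_window <- function(lambda_pm, dtheta_mrad) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(dtheta_mrad, "dtheta_mrad")
  D <- 10 * lambda_pm / dtheta_mrad
  list(D_psi_A = D, d_probe_max_A = D / 2)
}

#' Lateral resolution of direct (SSB) ptychography
#'
#' `r_xy = lambda / sin(2 alpha)` — the double-aperture transfer limit, exact
#' sine form.
#'
#' @inheritParams probe_window
#' @param alpha_mrad Convergence semi-angle, mrad (2 alpha below pi/2).
#' @return Resolution in Angstrom.
#' @export
lateral_resolution <- function(lambda_pm, alpha_mrad) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(alpha_mrad, "alpha_mrad")
  two_alpha <- 2 * alpha_mrad / 1000
  if (two_alpha >= pi / 2) stop_domain("2*alpha must be below pi/2")
  0.01 * lambda_pm / sin(two_alpha)
}

#' Maximum recommended SSB scanning step
#'
#' Nyquist sampling of the SSB resolution limit:
#' `dR_SSB = lambda / (2 sin(2 alpha))`, i.e. half of [lateral_resolution()].
#'
#' @inheritParams lateral_resolution
#' @return Step in Angstrom.
#' @examples
#' ssb_max_step(electron_wavelength(200), 27.42)  # ~0.23 A
#' @export
ssb_max_step <- function(lambda_pm, alpha_mrad) {
  lateral_resolution(lambda_pm, alpha_mrad) / 2
}

#' Reconstruction pixel size of iterative ptychography
#'
#' `Pix_ITR = lambda / theta`, set by the maximum detected angle; zero
#' padding of the diffraction patterns shrinks it by `padding_factor`.
#'
#' @inheritParams probe_window
#' @param theta_mrad Maximum detected semi-angle, mrad.
#' @param padding_factor Dimensionless >= 1.
#' @return Pixel size in Angstrom.
#' @export
itr_pixel_size <- function(lambda_pm, theta_mrad, padding_factor = 1) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(theta_mrad, "theta_mrad")
  if (padding_factor < 1) stop_domain("`padding_factor` must be >= 1")
  10 * lambda_pm / theta_mrad / padding_factor
}

#' Real-space overlap / oversampling metrics
#'
#' Geometric probe overlap percentage (clamped at 0 when positions no longer
#' overlap) plus the linear and areal oversampling ratios.
#'
#' @param d_probe_A Probe diameter, Angstrom.
#' @param step_used_A Scan step actually used (after skipping), Angstrom.
#' @return List with `SR_overlap` (percent), `SR_linear`, `SR_areal`.
#' @export
overlap_metrics <- function(d_probe_A, step_used_A) {
  assert_positive(d_probe_A, "d_probe_A")
  assert_positive(step_used_A, "step_used_A")
  list(
    SR_overlap = max(0, (d_probe_A - step_used_A) / d_probe_A * 100),
    SR_linear = d_probe_A / step_used_A,
    SR_areal = pi * (d_probe_A / 2)^2 / step_used_A^2
  )
}

#' Combined real/reciprocal sampling
#'
#' `S_hat = lambda / (2 dR dtheta)`; proper iterative reconstruction requires
#' `S_hat >= 1` in both scan axes (an isotropic grid is assumed).
#'
#' @inheritParams probe_window
#' @param step_used_A Scan step actually used, Angstrom.
#' @return Dimensionless sampling amount.
#' @examples
#' combined_sampling(electron_wavelength(200), 0.81, 79.8 / 3)  # ~0.6
#' @export
combined_sampling <- function(lambda_pm, step_used_A, dtheta_mrad) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(step_used_A, "step_used_A")
  assert_positive(dtheta_mrad, "dtheta_mrad")
  0.01 * lambda_pm / (2 * step_used_A * dtheta_mrad / 1000)
}

#' Maximum recommended defocus
#'
#' The defocused probe must still fit half the probe window. Under the
#' additive probe-diameter convention the focused diameter `d0` is subtracted
#' first: `df_max = (d_probe_max - d0) / (2 tan(alpha))`, floored at zero.
#' With `d0 = 0` this reduces to the pure geometric bound.
#'
#' @param d_probe_max_A Maximum probe diameter (half probe window), Angstrom.
#' @param alpha_mrad Convergence semi-angle, mrad.
#' @param d0_A Focused probe diameter, Angstrom.
#' @return Maximum defocus in nm.
#' @export
max_defocus <- function(d_probe_max_A, alpha_mrad, d0_A = 0) {
  assert_positive(d_probe_max_A, "d_probe_max_A")
  assert_positive(alpha_mrad, "alpha_mrad")
  assert_nonneg(d0_A, "d0_A")
  max(0, (d_probe_max_A - d0_A)) / (2 * tan(alpha_mrad / 1000)) / 10
}

#' Depth resolution limit for multislice reconstruction
#'
#' `r_z = lambda / (2 sin^2(theta / 2))` — the minimal useful slice
#' thickness, set by the maximum detected angle.
#'
#' @inheritParams itr_pixel_size
#' @return Slice thickness in Angstrom.
#' @export
depth_resolution <- function(lambda_pm, theta_mrad) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(theta_mrad, "theta_mrad")
  th <- theta_mrad / 1000
  if (th >= pi) stop_domain("theta must be below pi")
  0.01 * lambda_pm / (2 * sin(th / 2)^2)
}

#' Nyquist step for a target spacing
#'
#' The scan step needed to minimally sample a lattice spacing: half the
#' spacing.
#'
#' @param spacing_A Target real-space spacing, Angstrom.
#' @return Step in Angstrom.
#' @examples
#' nyquist_step(1.2)  # 0.6 A
#' @export
nyquist_step <- function(spacing_A) {
  assert_positive(spacing_A, "spacing_A")
  spacing_A / 2
}

#' Full sampling report for an acquisition plan
#'
#' Evaluates every derived design quantity for one plan: probe window,
#' probe diameter, lateral and depth resolution, SSB step bound, iterative
#' reconstruction pixel, overlap and combined-sampling metrics, maximum
#' defocus and resolution gain.
#'
#' @param plan An [acquisition_plan()].
#' @return An object of class `sampling_report` (a list; see fields in the
#'   details) carrying the derived geometry as attribute `geometry`.
#' @details Fields: `D_psi_A`, `d_probe_max_A`, `d_probe_A` (geometric probe
#'   at plan defocus), `r_xy_A`, `ssb_step_A`, `itr_pixel_A`, `SR_overlap`,
#'   `SR_linear`, `SR_areal`, `S_hat`, `max_defocus_nm`, `r_z_A`,
#'   `resolution_gain`, `step_used_A`, plus dose figures.
#' @export
build_report <- function(plan) {
  geom <- derive_geometry(plan)
  beam <- plan$beam
  dr_used <- scan_step_used(plan$scan)
  pw <- probe_window(geom$lambda_pm, geom$dtheta_mrad)
  d_probe <- geometric_probe_diameter(beam)
  ov <- overlap_metrics(max(d_probe, 1e-12), dr_used)
  pix_itr <- itr_pixel_size(geom$lambda_pm, geom$theta_mrad, geom$padding_factor)
  rep <- list(
    D_psi_A = pw$D_psi_A,
    d_probe_max_A = pw$d_probe_max_A,
    d_probe_A = d_probe,
    r_xy_A = lateral_resolution(geom$lambda_pm, beam$alpha_mrad),
    ssb_step_A = ssb_max_step(geom$lambda_pm, beam$alpha_mrad),
    itr_pixel_A = pix_itr,
    SR_overlap = ov$SR_overlap,
    SR_linear = ov$SR_linear,
    SR_areal = ov$SR_areal,
    S_hat = combined_sampling(geom$lambda_pm, dr_used, geom$dtheta_mrad),
    max_defocus_nm = max_defocus(pw$d_probe_max_A, beam$alpha_mrad, beam$d0_A),
    r_z_A = depth_resolution(geom$lambda_pm, geom$theta_mrad),
    resolution_gain = dr_used / pix_itr,
    step_used_A = dr_used,
    electrons_per_position = geom$electrons_per_position,
    dose_e_per_A2 = geom$dose_e_per_A2
  )
  structure(rep, geometry = geom, class = "sampling_report")
}

#' @export
print.sampling_report <- function(x, ...) {
  g <- attr(x, "geometry")
  cat("Sampling report\n")
  cat(sprintf("  wavelength        %9.4f pm\n", g$lambda_pm))
  cat(sprintf("  detector coverage %9.2f mrad (%.2f alpha)\n", g$theta_mrad, g$coverage_alpha))
  cat(sprintf("  BF disk           %9.2f px\n", g$bf_disk_diameter_px))
  cat(sprintf("  probe window      %9.2f A (d_probe_max %.2f A)\n", x$D_psi_A, x$d_probe_max_A))
  cat(sprintf("  probe diameter    %9.2f A (geometric, at plan defocus)\n", x$d_probe_A))
  cat(sprintf("  lateral resol.    %9.3f A   SSB max step %.3f A\n", x$r_xy_A, x$ssb_step_A))
  cat(sprintf("  ITR pixel         %9.3f A   resolution gain %.2f\n", x$itr_pixel_A, x$resolution_gain))
  cat(sprintf("  step used         %9.4f A\n", x$step_used_A))
  cat(sprintf("  overlap           %9.1f %%  linear %.2f  areal %.2f\n",
              x$SR_overlap, x$SR_linear, x$SR_areal))
  cat(sprintf("  combined sampling %9.2f\n", x$S_hat))
  cat(sprintf("  max defocus       %9.1f nm\n", x$max_defocus_nm))
  cat(sprintf("  depth resolution  %9.2f A\n", x$r_z_A))
  if (x$dose_e_per_A2 > 0)
    cat(sprintf("  dose              %9.0f e/A^2 (%.0f e/position)\n",
                x$dose_e_per_A2, x$electrons_per_position))
  invisible(x)
}
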