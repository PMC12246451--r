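# Frequency of maximum SSB transfer, in multiples of alpha. Stationary point
# of lens(w) - lens(2w): -sqrt(4 - w^2) + 2 sqrt(4 - 4 w^2) = 0 => w = 2/sqrt(5).
OMEGA_SSB_MAX <- 2 / sqrt(5)

# Area of the lens-shaped intersection of two unit disks whose centers are a
# distance d apart (0 for d >= 2).
lens_area <- function(d) {
  out <- numeric(length(d))
  i <- d < 2
  di <- d[i]
  out[i] <- 2 * acos(di / 2) - (di / 2) * sqrt(4 - di^2)
  out
}

#' Net SSB double-disk overlap area
#'
#' Area of the double-overlap region between the direct-beam disk and one
#' disk diffracted to spatial frequency `omega` (in multiples of alpha; all
#' disks have unit radius alpha), with the triple-overlap region — where the
#' +omega and -omega diffracted disks both intersect the direct disk —
#' excluded. The triple overlap is the lens of the two diffracted disks
#' (separation `2 omega`), which always lies inside the direct disk, so the
#' net area is `lens(omega) - lens(2 omega)`, zero from `omega >= 2`.
#'
#' @param omega Spatial frequency in multiples of alpha (>= 0). Vectorised.
#' @return Net overlap area in units of alpha^2.
#' @examples
#' ssb_overlap_area(1)    # 1.2284
#' ssb_overlap_area(2.5)  # 0: disjoint disks
#' @export
ssb_overlap_area <- function(omega) {
  if (any(!is.finite(omega)) || any(omega < 0))
    stop_domain("`omega` must be non-negative")
  lens_area(omega) - ifelse(omega < 1, lens_area(2 * omega), 0)
}

#' Analytic SSB phase contrast transfer function
#'
#' The intrinsic transfer of single-side-band ptychography is set by the net
#' double-disk overlap area at each scan frequency: zero at 0 and 2 alpha,
#' maximal at ~0.9 alpha. One sideband's net area is counted (one trotter per
#' +/-Q pair).
#'
#' @param omega Frequency grid in multiples of alpha (default 0..2.5, step
#'   0.001).
#' @param alpha_mrad Optional convergence semi-angle; stored for axis
#'   conversions.
#' @param lambda_pm Optional wavelength; stored for axis conversions.
#' @param normalization `"max_one"` (peak transfer scaled to exactly 1) or
#'   `"area_ratio"` (net area divided by the full disk area pi alpha^2).
#' @return A `ctf_curve`: data.frame with columns `frequency` and `transfer`,
#'   attributes `unit` (`"omega"`), `normalization`, `alpha_mrad`, `lambda_pm`.
#' @examples
#' ctf <- ssb_ctf()
#' ctf$frequency[which.max(ctf$transfer)]  # ~0.894
#' @export
ssb_ctf <- function(omega = seq(0, 2.5, by = 0.001), alpha_mrad = NULL,
                    lambda_pm = NULL,
                    normalization = c("max_one", "area_ratio")) {
  normalization <- match.arg(normalization)
  a <- ssb_overlap_area(omega)
  denom <- switch(normalization,
                  # scale so the curve's maximum is exactly 1; a grid that
                  # misses the peak entirely falls back to the analytic peak
                  max_one = if (any(a > 0)) max(a) else ssb_overlap_area(OMEGA_SSB_MAX),
                  area_ratio = pi)
  structure(data.frame(frequency = omega, transfer = a / denom),
            unit = "omega", normalization = normalization,
            alpha_mrad = alpha_mrad, lambda_pm = lambda_pm,
            class = c("ctf_curve", "data.frame"))
}

#' Convert the frequency axis of a CTF curve
#'
#' Between `omega` (multiples of alpha), `mrad` (scattering angle
#' `omega * alpha`) and `angstrom` (real-space spacing `lambda / angle`).
#' Transfer values are unchanged; converting to Angstrom drops zero-frequency
#' points (infinite spacing). Round trips are identities.
#'
#' @param curve A `ctf_curve`.
#' @param unit Target unit: `"omega"`, `"mrad"` or `"angstrom"`.
#' @param alpha_mrad,lambda_pm Conversion parameters; defaults come from the
#'   curve's attributes.
#' @return A `ctf_curve` in the target unit.
#' @export
convert_axis <- function(curve, unit = c("omega", "mrad", "angstrom"),
                         alpha_mrad = attr(curve, "alpha_mrad"),
                         lambda_pm = attr(curve, "lambda_pm")) {
  unit <- match.arg(unit)
  from <- attr(curve, "unit")
  if (is.null(from)) stop_domain("curve has no axis unit attribute")
  if (unit != "omega" || from != "omega") {
    if (is.null(alpha_mrad)) stop_domain("alpha_mrad needed for axis conversion")
  }
  # go through omega
  f <- curve$frequency
  omega <- switch(from,
    omega = f,
    mrad = f / alpha_mrad,
    angstrom = {
      if (is.null(lambda_pm)) stop_domain("lambda_pm needed to convert from angstrom")
      (0.01 * lambda_pm / f) / (alpha_mrad / 1000)
    })
  out_f <- switch(unit,
    omega = omega,
    mrad = omega * alpha_mrad,
    angstrom = {
      if (is.null(lambda_pm)) stop_domain("lambda_pm needed to convert to angstrom")
      0.01 * lambda_pm / (omega * alpha_mrad / 1000)
    })
  keep <- is.finite(out_f)
  structure(data.frame(frequency = out_f[keep], transfer = curve$transfer[keep]),
            unit = unit, normalization = attr(curve, "normalization"),
            alpha_mrad = alpha_mrad, lambda_pm = lambda_pm,
            class = c("ctf_curve", "data.frame"))
}

#' Write a CTF curve to CSV
#'
#' Columns `axis_unit`, `frequency`, `transfer`.
#' @param curve A `ctf_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ctf_csv <- function(curve, path) {
  utils::write.csv(data.frame(axis_unit = attr(curve, "unit"),
                              frequency = curve$frequency,
                              transfer = curve$transfer),
                   path, row.names = FALSE)
  invisible(path)
}
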