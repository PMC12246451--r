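#' Simulate a focused or defocused electron probe
#'
#' Fourier-optics probe model: a hard circular aperture of semi-angle
#' `alpha` with the defocus aberration phase `chi(k) = pi lambda defocus k^2`
#' applied, inverse-transformed to real space. The returned field is
#' DC-centered and normalised to unit total intensity
#' (`sum(|psi|^2) * dx^2 = 1`).
#'
#' @param lambda_pm Wavelength, pm.
#' @param alpha_mrad Convergence semi-angle, mrad.
#' @param defocus_nm Defocus magnitude, nm (phase sign is irrelevant to the
#'   intensities used downstream).
#' @param side_A Real-space grid side length, Angstrom.
#' @param samples Samples per side.
#' @return An object of class `probe_field`: list with complex matrix `psi`,
#'   `dx_A`, `side_A` and the beam metadata.
#' @details Errors if the aperture is sampled by fewer than 4 pixels across
#'   or extends beyond the grid Nyquist frequency (aliased parameters).
#' @export
simulate_probe <- function(lambda_pm, alpha_mrad, defocus_nm = 0,
                           side_A = 32, samples = 128L) {
  assert_positive(lambda_pm, "lambda_pm")
  assert_positive(alpha_mrad, "alpha_mrad")
  assert_nonneg(defocus_nm, "defocus_nm")
  assert_positive(side_A, "side_A")
  n <- as.integer(samples)
  dx <- side_A / n
  lambda_A <- 0.01 * lambda_pm
  k_ap <- (alpha_mrad / 1000) / lambda_A          # aperture radius, 1/A
  dk <- 1 / side_A
  if (2 * k_ap / dk < 4)
    stop_domain(sprintf("aperture spans %.2f samples (< 4): increase side_A", 2 * k_ap / dk))
  if (k_ap > 1 / (2 * dx))
    stop_domain(sprintf("aperture (%.3f 1/A) exceeds grid Nyquist (%.3f 1/A): decrease dx",
                        k_ap, 1 / (2 * dx)))
  psi <- .probe_psi(lambda_pm, alpha_mrad, defocus_nm, side_A, n)
  psi <- psi / sqrt(sum(Mod(psi)^2) * dx^2)
  structure(list(psi = psi, dx_A = dx, side_A = side_A,
                 lambda_pm = lambda_pm, alpha_mrad = alpha_mrad,
                 defocus_nm = defocus_nm),
            class = "probe_field")
}

# Centered complex probe wavefield on an n x n grid of side side_A: hard
# circular aperture with anti-aliased edge (pixels crossed by the rim get the
# fraction of their area inside it, 8x8 subsampling, so pixel-sampled disk
# products converge to the continuum overlap areas) times the defocus phase
# chi(k) = pi lambda defocus k^2. Unnormalised; no sampling guards.
.probe_psi <- function(lambda_pm, alpha_mrad, defocus_nm, side_A, n) {
  lambda_A <- 0.01 * lambda_pm
  k_ap <- (alpha_mrad / 1000) / lambda_A
  dk <- 1 / side_A
  kz <- fft_freq_index(n) * dk
  k2 <- outer(kz^2, kz^2, "+")
  r_pix <- sqrt(k2) / dk
  ap_pix <- k_ap / dk
  amp <- (r_pix < ap_pix - 0.75) * 1
  band <- which(abs(r_pix - ap_pix) <= 0.75)
  if (length(band)) {
    kyp <- matrix(fft_freq_index(n), n, n)[band]
    kxp <- t(matrix(fft_freq_index(n), n, n))[band]
    off <- (seq_len(8) - 4.5) / 8
    cov <- rowMeans(sapply(off, function(oy)
      rowMeans(sapply(off, function(ox)
        sqrt((kyp + oy)^2 + (kxp + ox)^2) < ap_pix))))
    amp[band] <- cov
  }
  A <- amp * exp(-1i * pi * lambda_A * (defocus_nm * 10) * k2)
  fftshift2(stats::fft(A, inverse = TRUE))
}

#' Wrap a complex amplitude matrix as a probe field
#'
#' For user-supplied analytic probes (e.g. top-hat test probes). The field is
#' renormalised to unit total intensity.
#' @param psi Complex (or numeric) square matrix.
#' @param dx_A Pixel pitch, Angstrom.
#' @return A `probe_field`.
#' @export
probe_field <- function(psi, dx_A) {
  assert_positive(dx_A, "dx_A")
  psi <- as.matrix(psi)
  psi <- psi / sqrt(sum(Mod(psi)^2) * dx_A^2)
  structure(list(psi = psi, dx_A = dx_A, side_A = nrow(psi) * dx_A,
                 lambda_pm = NA_real_, alpha_mrad = NA_real_,
                 defocus_nm = NA_real_),
            class = "probe_field")
}

# Intensity centroid of a probe field (Angstrom offsets from grid center).
probe_centroid <- function(field) {
  I <- Mod(field$psi)^2
  x <- centered_coord(ncol(I)) * field$dx_A
  y <- centered_coord(nrow(I)) * field$dx_A
  tot <- sum(I)
  c(y = sum(rowSums(I) * y) / tot, x = sum(colSums(I) * x) / tot)
}

#' Probe diameter containing a given intensity fraction
#'
#' Diameter of the smallest circle, centered on the intensity centroid, that
#' contains `fraction` of the total probe intensity (the vendor convention
#' uses 59%). Found by bisection on the radius; never below one pixel.
#'
#' @param field A `probe_field`.
#' @param fraction Intensity fraction, default 0.59.
#' @return Diameter in Angstrom.
#' @export
probe_d59 <- function(field, fraction = 0.59) {
  if (fraction <= 0 || fraction >= 1) stop_domain("`fraction` must be in (0, 1)")
  I <- Mod(field$psi)^2
  I <- I / sum(I)
  ctr <- probe_centroid(field)
  x <- centered_coord(ncol(I)) * field$dx_A - ctr["x"]
  y <- centered_coord(nrow(I)) * field$dx_A - ctr["y"]
  r <- sqrt(outer(y^2, x^2, "+"))
  enc <- function(rad) sum(I[r <= rad])
  lo <- 0; hi <- max(r)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (enc(mid) >= fraction) hi <- mid else lo <- mid
  }
  max(2 * hi, field$dx_A)
}

#' Fraction of probe intensity inside the probe window
#'
#' Intensity fraction within the centered `D_psi x D_psi` square (centering
#' on the intensity centroid). 1 when the window covers the whole grid.
#'
#' @param field A `probe_field`.
#' @param D_psi_A Probe window side, Angstrom.
#' @return Fraction in \[0, 1\].
#' @export
window_coverage_fraction <- function(field, D_psi_A) {
  assert_positive(D_psi_A, "D_psi_A")
  I <- Mod(field$psi)^2
  I <- I / sum(I)
  ctr <- probe_centroid(field)
  x <- abs(centered_coord(ncol(I)) * field$dx_A - ctr["x"])
  y <- abs(centered_coord(nrow(I)) * field$dx_A - ctr["y"])
  h <- D_psi_A / 2
  sum(I[y <= h, x <= h])
}

#' Illumination map of a scan
#'
#' Accumulates the probe intensity at every scan position on a map grid with
#' the probe's pixel pitch, and summarises the illumination uniformity
#' `U = 100 * min / max` over the interior region — the scanned area trimmed
#' by one probe diameter (59% definition) from the outermost positions.
#'
#' @param field A `probe_field`.
#' @param scan A [scan_setting()]; skipping is honoured.
#' @return An object of class `illumination_map`: list with matrix `map`
#'   (intensity), `dx_A`, `uniformity_percent`, `n_positions` and the
#'   interior index ranges.
#' @export
illumination_map <- function(field, scan) {
  dx <- field$dx_A
  I <- Mod(field$psi)^2              # sums to 1/dx^2 scale; keep raw sums
  I <- I / sum(I)
  np <- nrow(I)
  dr <- scan_step_used(scan)
  ix <- seq(0L, scan$nx - 1L, by = scan$skip + 1L)
  iy <- seq(0L, scan$ny - 1L, by = scan$skip + 1L)
  # map extent: scan span plus one probe grid on each side
  span_x <- max(ix) * dr; span_y <- max(iy) * dr
  nmx <- ceiling(span_x / dx) + 2L * np
  nmy <- ceiling(span_y / dx) + 2L * np
  map <- matrix(0, nmy, nmx)
  for (jy in iy) {
    oy <- np + round(jy * dr / dx)
    rows <- (oy - np / 2 + 1):(oy + np / 2)
    for (jx in ix) {
      ox <- np + round(jx * dr / dx)
      cols <- (ox - np / 2 + 1):(ox + np / 2)
      map[rows, cols] <- map[rows, cols] + I
    }
  }
  d <- probe_d59(field)
  trim <- d / dx
  lo_y <- np + trim + 1; hi_y <- np + span_y / dx - trim + 1
  lo_x <- np + trim + 1; hi_x <- np + span_x / dx - trim + 1
  if (hi_y < lo_y || hi_x < lo_x)
    stop_domain("scan too small: interior region (one probe diameter inside the scanned area) is empty")
  in_y <- max(1, lo_y):min(nmy, hi_y)
  in_x <- max(1, lo_x):min(nmx, hi_x)
  interior <- map[in_y, in_x, drop = FALSE]
  U <- if (max(interior) > 0) 100 * min(interior) / max(interior) else 0
  structure(list(map = map, dx_A = dx, uniformity_percent = U,
                 n_positions = length(ix) * length(iy),
                 interior_rows = range(in_y), interior_cols = range(in_x)),
            class = "illumination_map")
}

#' Write a 2D map (illumination or phase) as CSV
#' @param m A matrix, `illumination_map` or `probe_field` (intensity used).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(m, path) {
  if (inherits(m, "illumination_map")) m <- m$map
  if (inherits(m, "probe_field")) m <- Mod(m$psi)^2
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
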