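# Weak-phase SSB algebra used below. With a normalised probe
# a(r) = (c/N^2) sum_K A(K) e^{2pi i K r / N}, c = N / sqrt(N_ap), and a weak
# phase object phi with coefficients Phi(Q) (phi = sum_Q Phi e^{2pi i Q r/N}),
# the scan-frequency transform of the per-pattern-normalised intensities is
#   sum_{K in +trotter} G(K, Q) = i Phi(Q) * Nscan * N_t(Q) / N_ap,
# where the +trotter is {A(K) = 1, A(K - Q) = 1, A(K + Q) = 0} and N_t its
# pixel count. ssb_reconstruct inverts this relation exactly (focused probe).

#' Trotter (double-disk overlap) masks for one scan frequency
#'
#' Classifies detector pixel centers into the double-overlap regions of the
#' direct-beam disk and the two disks diffracted by a scan frequency `q`,
#' excluding the triple-overlap pixels. The `plus` mask carries the
#' transfer of `+q` (overlap of the direct disk with the disk centered at
#' `+q`), `minus` its mirror image through DC.
#'
#' @param q_omega Length-2 scan frequency `(qy, qx)` in multiples of alpha.
#' @param dtheta_omega Detector pixel pitch in multiples of alpha.
#' @param k_side Detector side, pixels (DC-centered grid).
#' @return List with logical matrices `plus`, `minus`, integer `n_aperture`
#'   (pixels inside the direct disk) and counts `n_plus`, `n_minus`.
#' @export
trotter_masks <- function(q_omega, dtheta_omega, k_side) {
  assert_positive(dtheta_omega, "dtheta_omega")
  k <- as.integer(k_side)
  w <- centered_coord(k) * dtheta_omega
  ky <- matrix(w, k, k)          # row coordinate
  kx <- t(ky)
  r0 <- ky^2 + kx^2
  rm <- (ky - q_omega[1])^2 + (kx - q_omega[2])^2
  rp <- (ky + q_omega[1])^2 + (kx + q_omega[2])^2
  in0 <- r0 < 1; inm <- rm < 1; inp <- rp < 1
  list(plus = in0 & inm & !inp,
       minus = in0 & inp & !inm,
       n_aperture = sum(in0),
       n_plus = sum(in0 & inm & !inp),
       n_minus = sum(in0 & inp & !inm))
}

# 2D FFT over the scan axes of a 4D array (Ny, Nx, Ky, Kx).
.scan_fft <- function(arr) {
  dn <- dim(arr)
  m <- matrix(arr, dn[1], prod(dn[-1]))
  g <- stats::mvfft(m)
  g <- array(g, dn)
  g <- aperm(g, c(2, 1, 3, 4))
  m <- matrix(g, dn[2], prod(dn[-2]))
  g <- stats::mvfft(m)
  aperm(array(g, dn[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
}

#' Single-side-band reconstruction
#'
#' Direct ptychographic phase retrieval: the recorded intensities are
#' Fourier-transformed over the scan axes, each scan frequency's transform is
#' integrated over its `+Q` trotter, and the accumulated phase spectrum is
#' inverse-transformed onto the scan grid (reconstruction pixel = scan step).
#' Quantitative for a focused probe and a weak-phase object.
#'
#' @param ds A `dataset4d`.
#' @param normalization `"ctf"`: spectrum scaled by the analytic peak trotter
#'   area, so recovered amplitudes follow the max-one SSB transfer curve;
#'   `"flat"`: each frequency divided by its own trotter area (flat response
#'   where any transfer exists).
#' @return An object of class `recon_result`: list with `phase` (radians, on
#'   the scan grid), `pix_A`, `spectrum` (complex), `method`.
#' @export
ssb_reconstruct <- function(ds, normalization = c("ctf", "flat")) {
  normalization <- match.arg(normalization)
  dn <- dim(ds$data)
  ny <- dn[1]; nx <- dn[2]; k <- dn[3]
  if (ny < 2 || nx < 2) stop_domain("need at least a 2x2 scan")
  if (ds$step_A > ssb_max_step(ds$lambda_pm, ds$alpha_mrad) + 1e-12)
    warning("scan step exceeds the SSB Nyquist bound; high frequencies fold")
  alpha_rad <- ds$alpha_mrad / 1000
  lambda_A <- 0.01 * ds$lambda_pm
  dtheta_omega <- (ds$dtheta_mrad / 1000) / alpha_rad
  # per-pattern normalisation (counts -> fractions)
  tot <- apply(ds$data, c(1, 2), sum)
  dat <- ds$data / mean(tot)
  G <- .scan_fft(dat)
  # scan-frequency -> omega conversion, per axis index
  qy_idx <- fft_freq_index(ny); qx_idx <- fft_freq_index(nx)
  wy <- qy_idx * lambda_A / (ny * ds$step_A) / alpha_rad
  wx <- qx_idx * lambda_A / (nx * ds$step_A) / alpha_rad
  w <- centered_coord(k) * dtheta_omega
  kym <- matrix(w, k, k); kxm <- t(kym)
  d0 <- sqrt(kym^2 + kxm^2)
  # edge-aware disk coverage: linear ramp one pixel wide across the rim,
  # matching the anti-aliased aperture of the simulated probe
  h <- dtheta_omega / 2
  ramp <- function(d) pmin(1, pmax(0, (1 + h - d) / (2 * h)))
  c0 <- ramp(d0)
  n_ap <- sum(c0^2)   # sum of |A|^2 over the (anti-aliased) aperture
  n_ref <- switch(normalization,
                  ctf = ssb_overlap_area(OMEGA_SSB_MAX) / dtheta_omega^2,
                  flat = NA_real_)
  spec <- matrix(0 + 0i, ny, nx)
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      if (iy == 1 && ix == 1) next       # DC: unknown mean phase
      qo <- c(wy[iy], wx[ix])
      if (qo[1]^2 + qo[2]^2 >= 4) next   # disjoint disks
      cm <- ramp(sqrt((kym - qo[1])^2 + (kxm - qo[2])^2))
      cp <- ramp(sqrt((kym + qo[1])^2 + (kxm + qo[2])^2))
      plus <- c0 > 0 & cm > 0 & cm > cp
      if (!any(plus)) next
      s <- sum(G[iy, ix, , ][plus])
      nr <- if (normalization == "flat") sum((c0 * cm - c0 * cp)[plus]) else n_ref
      spec[iy, ix] <- -1i * s * n_ap / (ny * nx * nr)
    }
  }
  phase <- Re(stats::fft(spec, inverse = TRUE))
  structure(list(phase = phase, pix_A = ds$step_A, spectrum = spec,
                 method = "ssb", error = NULL),
            class = "recon_result")
}

#' ePIE iterative reconstruction
#'
#' Minimal extended ptychographic iterative engine: sequential per-position
#' updates of a complex object (and optionally the probe) so the modelled
#' far-field amplitudes match the measured ones. Periodic boundary
#' conditions; the object grid pitch is the reconstruction pixel
#' `lambda / (K dtheta)` and scan steps must land on it.
#'
#' @param ds A `dataset4d`.
#' @param iterations Number of sweeps (>= 1).
#' @param beta_object,beta_probe Update step sizes; 0 freezes the component.
#' @param probe Optional `probe_field` initialisation; by default simulated
#'   from the dataset metadata with a 10% defocus error so probe refinement
#'   has something to correct.
#' @param shuffle_seed Optional integer; when set, position order is
#'   reshuffled each sweep (raster order otherwise).
#' @return A `recon_result`: `object` (complex), `phase` (radians),
#'   `probe` (complex matrix), `pix_A`, `error` (per-sweep RMS amplitude
#'   mismatch), `method`.
#' @export
epie_reconstruct <- function(ds, iterations = 50, beta_object = 0.9,
                             beta_probe = 0, probe = NULL,
                             shuffle_seed = NULL) {
  if (iterations < 1) stop_domain("`iterations` must be >= 1")
  if (any(!is.finite(ds$data))) stop_domain("dataset contains non-finite values")
  dn <- dim(ds$data)
  ny <- dn[1]; nx <- dn[2]; k <- dn[3]
  pix <- 10 * ds$lambda_pm / (k * ds$dtheta_mrad)
  s_px <- ds$step_A / pix
  if (abs(s_px - round(s_px)) > 1e-3)
    stop_domain(sprintf("scan step (%.4f A) is not a multiple of the reconstruction pixel (%.4f A)",
                        ds$step_A, pix))
  s_px <- as.integer(round(s_px))
  n_obj <- max(ny * s_px, k)
  if (n_obj %% k != 0 && ny * s_px < k) n_obj <- k
  S_hat <- combined_sampling(ds$lambda_pm, ds$step_A, ds$dtheta_mrad)
  if (S_hat < 1)
    warning(sprintf("combined sampling %.2f < 1: reconstruction may fail", S_hat))
  if (is.null(probe)) {
    # default init: model aperture with a 10% defocus error so probe
    # refinement has something to correct; no sampling guard (tiny binned
    # detectors are legitimate here)
    psi <- .probe_psi(ds$lambda_pm, ds$alpha_mrad, ds$defocus_nm * 1.1,
                      k * pix, k)
    probe <- list(psi = psi)
  }
  P <- ifftshift2(probe$psi)
  P <- P / sqrt(sum(Mod(P)^2))
  O <- matrix(1 + 0i, n_obj, n_obj)
  # measured amplitudes, fft order, scaled to the unit-power probe
  amps <- vector("list", ny * nx)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    pat <- ds$data[iy, ix, , ]
    amps[[(iy - 1) * nx + ix]] <- ifftshift2(sqrt(pat / sum(pat))) * k
  }
  offs <- cbind(rep(seq_len(ny) - 1L, each = nx) * s_px,
                rep(seq_len(nx) - 1L, times = ny) * s_px)
  idx_base <- 0:(k - 1)
  err <- numeric(iterations)
  order0 <- seq_len(ny * nx)
  for (it in seq_len(iterations)) {
    ord <- order0
    if (!is.null(shuffle_seed)) {
      set.seed(shuffle_seed + it)
      ord <- sample(order0)
    }
    e2 <- 0
    for (j in ord) {
      rows <- ((offs[j, 1] + idx_base) %% n_obj) + 1L
      cols <- ((offs[j, 2] + idx_base) %% n_obj) + 1L
      patch <- O[rows, cols]
      exitw <- P * patch
      Psi <- stats::fft(exitw)
      amp <- amps[[j]]
      mo <- Mod(Psi)
      e2 <- e2 + mean((mo - amp)^2)
      Psi2 <- amp * Psi / (mo + 1e-12)
      d <- stats::fft(Psi2, inverse = TRUE) / (k * k) - exitw
      O[rows, cols] <- patch + beta_object * Conj(P) * d / max(Mod(P)^2)
      if (beta_probe > 0)
        P <- P + beta_probe * Conj(patch) * d / max(Mod(patch)^2)
    }
    err[it] <- sqrt(e2 / (ny * nx))
  }
  structure(list(object = O, phase = Arg(O), probe = fftshift2(P),
                 pix_A = pix, error = err, method = "epie"),
            class = "recon_result")
}

#' Phase correlation between a reconstruction and ground truth
#'
#' Pearson correlation of the mean-subtracted phase maps (insensitive to the
#' global phase offset of ptychographic reconstructions).
#'
#' @param recon A `recon_result` or phase matrix.
#' @param truth Phase matrix of the same size.
#' @return Correlation coefficient.
#' @export
phase_correlation <- function(recon, truth) {
  p <- if (inherits(recon, "recon_result")) recon$phase else recon
  if (!all(dim(p) == dim(truth))) stop_domain("phase maps differ in size")
  stats::cor(as.vector(p - mean(p)), as.vector(truth - mean(truth)))
}

#' Numerical CTF of iterative reconstruction
#'
#' The single-atom recipe: simulate a 4D dataset from an isolated radially
#' symmetric phase bump (no noise), reconstruct it iteratively, deconvolve
#' the known bump in Fourier space (regularised division) and azimuthally
#' average the ratio.
#'
#' @param object A `phase_object` holding the isolated bump.
#' @param lambda_pm,alpha_mrad,defocus_nm Beam parameters for the simulation.
#' @param step_px Scan step in object pixels.
#' @param iterations,beta_object,beta_probe,probe Passed to
#'   [epie_reconstruct()].
#' @param floor_frac Division floor as a fraction of the peak denominator
#'   magnitude (default 1e-3); Fourier samples below it are dropped.
#' @return A `ctf_curve` on an omega axis (transfer = magnitude of the
#'   azimuthal complex mean of the deconvolved ratio).
#' @export
numerical_itr_ctf <- function(object, lambda_pm, alpha_mrad, defocus_nm = 0,
                              step_px = 1L, iterations = 30,
                              beta_object = 0.9, beta_probe = 0,
                              probe = NULL, floor_frac = 1e-3) {
  ds <- simulate_4dstem(object, lambda_pm, alpha_mrad, defocus_nm,
                        step_px = step_px)
  rec <- epie_reconstruct(ds, iterations = iterations,
                          beta_object = beta_object, beta_probe = beta_probe,
                          probe = probe)
  n <- nrow(object$phase)
  if (!all(dim(rec$phase) == n))
    stop_domain("reconstruction grid does not match the object grid")
  Ft <- stats::fft(object$phase - mean(object$phase))
  Fr <- stats::fft(rec$phase - mean(rec$phase))
  valid <- Mod(Ft) >= floor_frac * max(Mod(Ft))
  if (mean(valid) < 0.5 && sum(valid) < 0.5 * length(valid)) {
    # tolerated: compact bumps have compact spectra; hard error only if
    # almost nothing survives
    if (sum(valid) < 16) stop_domain("denominator floor leaves too few samples")
  }
  ratio <- Fr[valid] / Ft[valid]
  alpha_rad <- alpha_mrad / 1000
  lambda_A <- 0.01 * lambda_pm
  qi <- fft_freq_index(n)
  qy <- matrix(qi, n, n); qx <- t(qy)
  w_all <- sqrt(qy^2 + qx^2) * lambda_A / (n * object$pitch_A) / alpha_rad
  w <- w_all[valid]
  dw <- lambda_A / (n * object$pitch_A) / alpha_rad
  bin <- round(w / dw)
  agg <- tapply(ratio, bin, mean)
  structure(data.frame(frequency = as.numeric(names(agg)) * dw,
                       transfer = Mod(agg)),
            unit = "omega", normalization = "deconvolution",
            alpha_mrad = alpha_mrad, lambda_pm = lambda_pm,
            class = c("ctf_curve", "data.frame"))
}
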