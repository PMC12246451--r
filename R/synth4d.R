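#' Construct a weak-phase test object
#'
#' Periodic phase maps used by the synthetic 4D-STEM generator: vacuum, one
#' or more phase sinusoids, or a lattice of radially symmetric Gaussian
#' bumps ("atoms").
#'
#' @param n Grid side (pixels).
#' @param pitch_A Pixel size, Angstrom.
#' @param motif `"vacuum"`, `"sinusoid"` or `"atoms"`.
#' @param amplitude_rad Phase amplitude(s), radians; one per sinusoid or one
#'   per atom motif. Weak-phase validity needs |phase| well below 1.
#' @param freq_cyc_per_A For sinusoids: frequency vectors, a 2-column matrix
#'   (`qy`, `qx` in cycles/Angstrom) or a length-2 vector; each is rounded to
#'   the nearest grid frequency and must be within the grid Nyquist.
#' @param phase_rad Phase offsets of the sinusoids (radians), recycled.
#' @param centers_A For atoms: 2-column matrix of (y, x) centers, Angstrom
#'   (origin at the grid corner).
#' @param sigma_A Gaussian width of each atom, Angstrom.
#' @return An object of class `phase_object`: list with matrix `phase`
#'   (radians), `pitch_A` and construction metadata.
#' @export
make_phase_object <- function(n, pitch_A, motif = c("vacuum", "sinusoid", "atoms"),
                              amplitude_rad = 0.05, freq_cyc_per_A = NULL,
                              phase_rad = 0, centers_A = NULL, sigma_A = 0.3) {
  motif <- match.arg(motif)
  assert_positive(pitch_A, "pitch_A")
  n <- as.integer(n)
  phase <- matrix(0, n, n)
  meta <- list(motif = motif)
  if (motif == "sinusoid") {
    q <- freq_cyc_per_A
    if (is.null(q)) stop_domain("sinusoid motif needs `freq_cyc_per_A`")
    if (!is.matrix(q)) q <- matrix(q, ncol = 2, byrow = TRUE)
    amplitude_rad <- rep_len(amplitude_rad, nrow(q))
    phase_rad <- rep_len(phase_rad, nrow(q))
    side <- n * pitch_A
    idx <- round(q * side)           # integer cycles over the periodic field
    if (any(abs(idx) > n / 2))
      stop_domain("sinusoid frequency beyond the grid Nyquist")
    yy <- (0:(n - 1)); xx <- (0:(n - 1))
    for (i in seq_len(nrow(idx))) {
      arg <- 2 * pi * (outer(yy * idx[i, 1], xx * idx[i, 2], "+")) / n
      phase <- phase + amplitude_rad[i] * cos(arg + phase_rad[i])
    }
    meta$cycles <- idx
    meta$amplitude_rad <- amplitude_rad
  } else if (motif == "atoms") {
    if (is.null(centers_A)) stop_domain("atoms motif needs `centers_A`")
    centers_A <- matrix(centers_A, ncol = 2)
    amplitude_rad <- rep_len(amplitude_rad, nrow(centers_A))
    side <- n * pitch_A
    yy <- (0:(n - 1)) * pitch_A
    for (i in seq_len(nrow(centers_A))) {
      # periodic (wrapped) distance
      dy <- abs(yy - centers_A[i, 1]); dy <- pmin(dy, side - dy)
      dx <- abs(yy - centers_A[i, 2]); dx <- pmin(dx, side - dx)
      phase <- phase + amplitude_rad[i] * exp(-outer(dy^2, dx^2, "+") / (2 * sigma_A^2))
    }
    meta$centers_A <- centers_A
    meta$sigma_A <- sigma_A
    meta$amplitude_rad <- amplitude_rad
  }
  structure(list(phase = phase, pitch_A = pitch_A, meta = meta),
            class = "phase_object")
}

#' Simulate a weak-phase 4D-STEM dataset
#'
#' Single-slice forward model on the object grid: at each scan position the
#' probe is shifted (circularly; objects are periodic), multiplied by
#' `exp(i phase)`, propagated to the far field, and the centered intensity
#' pattern recorded. The detector grid is the probe's reciprocal grid, so
#' the angular pitch is `lambda / (n * pitch)`. Scan steps must be integer
#' multiples of the object pixel. Optionally Poisson noise is drawn at
#' `electrons` expected counts per pattern with a per-position seed derived
#' from `poisson_seed` (order-independent).
#'
#' @param object A [make_phase_object()].
#' @param lambda_pm,alpha_mrad,defocus_nm Beam parameters.
#' @param step_px Scan step in object pixels (integer >= 1).
#' @param nx,ny Scan grid (defaults to covering the full object once).
#' @param electrons Expected electrons per pattern for Poisson sampling
#'   (`NULL` or 0: noiseless, intensities sum to 1 per pattern).
#' @param poisson_seed Integer seed for the noise (required with
#'   `electrons`).
#' @param detector_px Optional detector side smaller than the object grid:
#'   the forward model then uses the probe-window-limited (windowed-patch)
#'   geometry — the probe lives on a `detector_px^2` grid with the object
#'   pixel pitch, each exit wave is probe times the local object patch, and
#'   the angular pitch is `lambda / (detector_px * pitch)`. This emulates a
#'   small detector array whose probe window is honoured exactly.
#' @return An object of class `dataset4d`: list with 4D array
#'   `data[ny, nx, ky, kx]` (DC-centered detector), `step_A`, `dtheta_mrad`,
#'   `lambda_pm`, `alpha_mrad`, `defocus_nm`, `electrons_per_position`,
#'   `dose_e_per_A2`, `seed`, `warnings`.
#' @export
simulate_4dstem <- function(object, lambda_pm, alpha_mrad, defocus_nm = 0,
                            step_px = 1L, nx = NULL, ny = NULL,
                            electrons = NULL, poisson_seed = NULL,
                            detector_px = NULL) {
  stopifnot(inherits(object, "phase_object"))
  n <- nrow(object$phase)
  step_px <- as.integer(step_px)
  if (step_px < 1) stop_domain("`step_px` must be >= 1")
  if (is.null(nx)) nx <- n %/% step_px
  if (is.null(ny)) ny <- n %/% step_px
  k <- if (is.null(detector_px)) n else as.integer(detector_px)
  if (k > n) stop_domain("`detector_px` cannot exceed the object grid")
  probe <- simulate_probe(lambda_pm, alpha_mrad, defocus_nm,
                          side_A = n * object$pitch_A, samples = n)
  warnings <- character(0)
  d_geo <- probe_d59(probe)
  dtheta_mrad <- 10 * lambda_pm / (k * object$pitch_A)
  pw <- probe_window(lambda_pm, dtheta_mrad)
  if (d_geo > pw$d_probe_max_A)
    warnings <- c(warnings, sprintf(
      "probe diameter %.2f A exceeds half probe window %.2f A: aliasing expected",
      d_geo, pw$d_probe_max_A))
  if (k < n) {
    # windowed-patch forward model on the k x k probe grid
    psi <- .probe_psi(lambda_pm, alpha_mrad, defocus_nm, k * object$pitch_A, k)
    a <- ifftshift2(psi / sqrt(sum(Mod(psi)^2)))
  } else {
    a <- ifftshift2(probe$psi)       # probe center at pixel 0: position R maps to object pixel R
  }
  trans <- exp(1i * object$phase)
  data <- array(0, dim = c(ny, nx, k, k))
  noisy <- !is.null(electrons) && electrons > 0
  if (noisy && is.null(poisson_seed))
    stop_domain("Poisson sampling needs `poisson_seed`")
  idx <- 0:(k - 1)
  for (iy in seq_len(ny)) {
    sy <- ((iy - 1L) * step_px) %% n
    ay <- if (k < n) NULL else if (sy == 0) a else
      a[c((n - sy + 1):n, 1:(n - sy)), , drop = FALSE]
    for (ix in seq_len(nx)) {
      sx <- ((ix - 1L) * step_px) %% n
      if (k < n) {
        rows <- ((sy + idx) %% n) + 1L
        cols <- ((sx + idx) %% n) + 1L
        psi_exit <- a * trans[rows, cols]
      } else {
        axy <- if (sx == 0) ay else ay[, c((n - sx + 1):n, 1:(n - sx)), drop = FALSE]
        psi_exit <- axy * trans
      }
      pat <- Mod(stats::fft(psi_exit))^2
      pat <- fftshift2(pat / sum(pat))
      if (noisy) {
        set.seed((poisson_seed + (iy - 1L) * nx + (ix - 1L)) %% .Machine$integer.max)
        pat <- matrix(stats::rpois(length(pat), pat * electrons), k, k)
      }
      data[iy, ix, , ] <- pat
    }
  }
  step_A <- step_px * object$pitch_A
  structure(list(data = data, step_A = step_A, dtheta_mrad = dtheta_mrad,
                 lambda_pm = lambda_pm, alpha_mrad = alpha_mrad,
                 defocus_nm = defocus_nm,
                 electrons_per_position = if (noisy) electrons else NA_real_,
                 dose_e_per_A2 = if (noisy) electrons / step_A^2 else NA_real_,
                 seed = if (noisy) poisson_seed else NA_integer_,
                 warnings = warnings),
            class = "dataset4d")
}

#' Bin diffraction patterns
#'
#' Block-sums detector pixels; counts are conserved and the angular pitch
#' grows by the binning factor.
#'
#' @param ds A `dataset4d`.
#' @param factor Integer dividing the detector side.
#' @return A binned `dataset4d`.
#' @export
rebin_patterns <- function(ds, factor) {
  factor <- as.integer(factor)
  k <- dim(ds$data)[3]
  if (factor < 1 || k %% factor != 0)
    stop_domain("`factor` must be a positive divisor of the detector side")
  if (factor == 1) return(ds)
  kb <- k %/% factor
  dn <- dim(ds$data)
  # sum factor x factor blocks over the detector axes
  d <- array(ds$data, dim = c(dn[1], dn[2], factor, kb, factor, kb))
  ds$data <- apply(d, c(1, 2, 4, 6), sum)
  ds$dtheta_mrad <- ds$dtheta_mrad * factor
  ds
}

#' Subsample scan positions
#'
#' Keeps positions whose 0-based index is a multiple of `skip + 1` along
#' each axis; the step metadata grows by `(skip + 1)` and the dose drops by
#' `(skip + 1)^2`.
#'
#' @param ds A `dataset4d`.
#' @param skip Non-negative integer.
#' @return A subsampled `dataset4d`.
#' @export
subsample_scan <- function(ds, skip) {
  skip <- as.integer(skip)
  if (skip < 0) stop_domain("`skip` must be >= 0")
  if (skip == 0) return(ds)
  dn <- dim(ds$data)
  iy <- seq(1L, dn[1], by = skip + 1L)
  ix <- seq(1L, dn[2], by = skip + 1L)
  if (length(iy) < 1 || length(ix) < 1) stop_domain("subsampling left no positions")
  ds$data <- ds$data[iy, ix, , , drop = FALSE]
  ds$step_A <- ds$step_A * (skip + 1)
  if (!is.na(ds$dose_e_per_A2)) ds$dose_e_per_A2 <- ds$dose_e_per_A2 / (skip + 1)^2
  ds
}

#' Position-averaged diffraction pattern (PACBED)
#'
#' @param ds A `dataset4d`.
#' @return Matrix: mean pattern over all scan positions (DC-centered).
#' @export
pacbed <- function(ds) {
  dn <- dim(ds$data)
  if (dn[1] < 1 || dn[2] < 1) stop_domain("empty dataset")
  apply(ds$data, c(3, 4), mean)
}

#' Save / load a 4D dataset
#'
#' Serialises the dataset container (array `data[Ny, Nx, Ky, Kx]` plus the
#' metadata fields `step_A`, `dtheta_mrad`, `lambda_pm`, `alpha_mrad`,
#' `defocus_nm`, `electrons_per_position`, `dose_e_per_A2`, `seed`) to an
#' RDS file.
#'
#' @param ds A `dataset4d`.
#' @param path File path.
#' @return `path` (write) or the `dataset4d` (read).
#' @export
write_dataset4d <- function(ds, path) {
  stopifnot(inherits(ds, "dataset4d"))
  saveRDS(ds, path)
  invisible(path)
}

#' @rdname write_dataset4d
#' @export
read_dataset4d <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "dataset4d")) stop_domain("file does not hold a dataset4d")
  ds
}
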