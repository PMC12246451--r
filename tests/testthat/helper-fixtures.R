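# Shared fixtures. Heavy synthetic datasets are memoised so that module and
# acceptance tests reuse one simulation.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

LAMBDA200 <- electron_wavelength(200)

flagship_beam <- function(d0 = 0.8, defocus = 0) {
  beam_setting(200, 27.42, defocus_nm = defocus, current_pA = 11, d0_A = d0)
}

flagship_scan <- function(skip = 0) {
  scan_setting(0.15903, nx = 128, ny = 128, dwell_us = 50, skip = skip)
}

flagship_detector <- function(binning = 1) {
  detector_model(192, 100, binning = binning, camera_length_cm = 12.12,
                 dtheta_mrad = 0.83125 * binning)
}

flagship_plan <- function(method = "ITR", binning = 1, skip = 0, d0 = 0.8,
                          defocus = 0) {
  acquisition_plan(flagship_beam(d0, defocus), flagship_scan(skip),
                   flagship_detector(binning), method)
}

# 64^2 scan / 64^2 detector weak-phase multi-sinusoid fixture used for the
# SSB transfer measurement: detector pixel 1/16 alpha, scan Nyquist 2 alpha.
ssb_transfer_fixture <- function() memo("ssb64", {
  n <- 64; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  idx <- c(5, 10, 15, 20, 25)
  omegas <- idx * wu
  q <- omegas * (alpha / 1000) / (0.01 * LAMBDA200)
  obj <- make_phase_object(n, dx, "sinusoid", amplitude_rad = rep(0.02, 5),
                           freq_cyc_per_A = cbind(0, q),
                           phase_rad = c(0.1, 0.4, 0.9, 1.4, 2.0))
  ds <- simulate_4dstem(obj, LAMBDA200, alpha, 0, step_px = 1)
  list(object = obj, dataset = ds, alpha = alpha, idx = idx, omegas = omegas,
       amplitude = 0.02)
})

# 32^2 atom-lattice fixture (coverage 2 alpha) for ePIE recovery.
epie_fixture <- function() memo("epie32", {
  n <- 32; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  ctr <- rbind(c(2.0, 2.0), c(5.0, 4.0), c(3.0, 6.0))
  obj <- make_phase_object(n, dx, "atoms", amplitude_rad = 0.2,
                           centers_A = ctr, sigma_A = 0.45)
  ds <- simulate_4dstem(obj, LAMBDA200, alpha, 0, step_px = 1)
  probe <- simulate_probe(LAMBDA200, alpha, 0, side_A = n * dx, samples = n)
  list(object = obj, dataset = ds, probe = probe, alpha = alpha, dx = dx)
})

# broadband atom-lattice fixture at 1.1 alpha coverage whose probe fits the
# window of a 4x4 detector; used for the small-detector comparisons.
small_detector_fixture <- function() memo("smalldet", {
  n <- 32; alpha <- 25; wu <- 2.2 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  ctr <- as.matrix(expand.grid(y = c(2, 6, 10), x = c(2, 6, 10)))[, c("y", "x")]
  obj <- make_phase_object(n, dx, "atoms", amplitude_rad = 0.15,
                           centers_A = as.matrix(ctr), sigma_A = 0.8)
  full <- simulate_4dstem(obj, LAMBDA200, alpha, 0, step_px = 1)
  tiny <- simulate_4dstem(obj, LAMBDA200, alpha, 0, step_px = 1, detector_px = 4)
  list(object = obj, full = full, tiny = tiny, alpha = alpha, dx = dx)
})

# Monte-Carlo oracle for the net double-minus-triple disk overlap area,
# sampling uniformly in the bounding box of the double-overlap lens.
mc_overlap_area <- function(omega, n = 1e7, seed = 1) {
  set.seed(seed)
  y0 <- sqrt(1 - omega^2 / 4)
  x <- stats::runif(n, omega - 1, 1)
  y <- stats::runif(n, -y0, y0)
  hit <- (x^2 + y^2 < 1) & ((x - omega)^2 + y^2 < 1) &
    !((x + omega)^2 + y^2 < 1)
  mean(hit) * (2 - omega) * 2 * y0
}
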