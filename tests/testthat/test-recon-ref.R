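test_that("trotter masks reproduce the closed-form overlap geometry", {
  tm <- trotter_masks(c(0, 2.5), 0.05, 80)
  expect_equal(tm$n_plus, 0)
  expect_equal(tm$n_minus, 0)
  # mirror symmetry through DC
  tm1 <- trotter_masks(c(0.3, 0.9), 0.05, 64)
  flip <- function(m) m[c(1, nrow(m):2), c(1, ncol(m):2)]
  expect_identical(tm1$minus, flip(tm1$plus))
  # pixel-counted area approaches the closed form at omega = 1
  tm2 <- trotter_masks(c(0, 1), 0.025, 120)
  expect_equal(tm2$n_plus * 0.025^2, ssb_overlap_area(1), tolerance = 0.05)
  # and converges with detector resolution
  err <- sapply(c(0.1, 0.05, 0.025), function(dth) {
    t <- trotter_masks(c(0, 0.9), dth, round(3 / dth))
    abs(t$n_plus * dth^2 - ssb_overlap_area(0.9))
  })
  expect_true(err[3] < err[1])
  expect_lt(err[3] / ssb_overlap_area(0.9), 0.02)
})

test_that("SSB reconstruction of vacuum is numerically zero", {
  obj <- make_phase_object(16, 0.25, "vacuum")
  ds <- simulate_4dstem(obj, LAMBDA200, 20, 0, step_px = 1)
  rec <- suppressWarnings(ssb_reconstruct(ds))
  expect_lt(max(abs(rec$phase)), 1e-8)
  expect_equal(rec$pix_A, 0.25)
})

test_that("SSB recovers sinusoid amplitudes at the analytic transfer", {
  fx <- ssb_transfer_fixture()
  rec <- ssb_reconstruct(fx$dataset)
  sp <- stats::fft(rec$phase) / length(rec$phase)
  meas <- 2 * Mod(sp[1, fx$idx + 1]) / fx$amplitude
  ana <- ssb_overlap_area(fx$omegas) / ssb_overlap_area(2 / sqrt(5))
  # each frequency individually within 2%
  expect_true(all(abs(meas / ana - 1) < 0.02))
  # recovered phase offsets are faithful too
  expect_equal(Arg(sp[1, fx$idx[3] + 1]), 0.9, tolerance = 0.01)
})

test_that("weak-phase SSB is linear in the object", {
  n <- 32; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  q1 <- 6 * wu * (alpha / 1000) / (0.01 * LAMBDA200)
  q2 <- 10 * wu * (alpha / 1000) / (0.01 * LAMBDA200)
  mk <- function(freqs, amps, phases) make_phase_object(n, dx, "sinusoid",
    amplitude_rad = amps, freq_cyc_per_A = freqs, phase_rad = phases)
  r <- function(o) ssb_reconstruct(simulate_4dstem(o, LAMBDA200, alpha, 0))$phase
  p12 <- r(mk(rbind(c(0, q1), c(q2, 0)), c(0.03, 0.03), c(0.2, 1.1)))
  p1 <- r(mk(rbind(c(0, q1)), 0.03, 0.2))
  p2 <- r(mk(rbind(c(q2, 0)), 0.03, 1.1))
  expect_lt(max(abs(p12 - p1 - p2)) / max(abs(p12)), 0.01)
})

test_that("SSB needs a scan and warns above the Nyquist step", {
  obj <- make_phase_object(16, 0.25, "vacuum")
  ds <- simulate_4dstem(obj, LAMBDA200, 20, 0, step_px = 1, nx = 1, ny = 1)
  expect_error(ssb_reconstruct(ds), "2x2")
  ds2 <- simulate_4dstem(obj, LAMBDA200, 20, 0, step_px = 8)
  expect_warning(ssb_reconstruct(ds2), "Nyquist")
})

test_that("ePIE with zero step sizes returns its initialisation", {
  fx <- epie_fixture()
  rec <- epie_reconstruct(fx$dataset, iterations = 2, beta_object = 0,
                          beta_probe = 0, probe = fx$probe)
  expect_true(all(rec$object == 1 + 0i))
  expect_equal(length(rec$error), 2)
  expect_equal(rec$error[1], rec$error[2])
})

test_that("ePIE recovers the object phase with a known fixed probe", {
  fx <- epie_fixture()
  rec <- epie_reconstruct(fx$dataset, iterations = 50, beta_object = 0.9,
                          beta_probe = 0, probe = fx$probe)
  expect_gt(phase_correlation(rec, fx$object$phase), 0.95)
  # the data error shrinks monotonically early on and overall
  expect_true(all(diff(rec$error[1:10]) <= 1e-12))
  expect_lt(rec$error[50], rec$error[1])
})

test_that("probe refinement improves on a deliberately wrong start", {
  n <- 32; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  obj <- make_phase_object(n, dx, "atoms", amplitude_rad = 0.2,
                           centers_A = rbind(c(2, 2), c(5, 4)), sigma_A = 0.5)
  ds <- simulate_4dstem(obj, LAMBDA200, alpha, 10, step_px = 1)
  # default initialisation carries a 10% defocus error; allow refinement
  rec <- epie_reconstruct(ds, iterations = 40, beta_object = 0.9,
                          beta_probe = 0.5, shuffle_seed = 5)
  frozen <- epie_reconstruct(ds, iterations = 40, beta_object = 0.9,
                             beta_probe = 0, shuffle_seed = 5)
  expect_lt(rec$error[40], frozen$error[40])
  expect_gt(phase_correlation(rec, obj$phase), 0.9)
})

test_that("ePIE rejects undecomposable data and warns on poor sampling", {
  fx <- epie_fixture()
  bad <- fx$dataset
  bad$data[1, 1, 1, 1] <- NaN
  expect_error(epie_reconstruct(bad, iterations = 1), "non-finite")
  sparse <- subsample_scan(fx$dataset, 17)
  expect_warning(epie_reconstruct(sparse, iterations = 1, probe = fx$probe),
                 "sampling")
})

test_that("the deconvolution CTF recipe is the identity on a perfect run", {
  n <- 32; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  bump <- make_phase_object(n, dx, "atoms", amplitude_rad = 0.2,
                            centers_A = matrix(c(4, 4), 1), sigma_A = 0.2)
  ctf <- numerical_itr_ctf(bump, LAMBDA200, alpha, step_px = 1,
                           iterations = 50)
  # dense noiseless scan with the true probe model: transfer is flat at 1
  inner <- ctf$transfer[ctf$frequency > 0 & ctf$frequency < 1.8]
  expect_true(all(abs(inner - 1) < 0.05))
  # superresolution: transfer persists beyond the 2-alpha SSB cutoff
  outer_ <- ctf$transfer[ctf$frequency > 2.05 & ctf$frequency < 2.3]
  expect_gt(length(outer_), 0)
  expect_gt(min(outer_), 0.01)
})

test_that("azimuthal averaging of an isotropic ratio is its radial profile", {
  # a radially symmetric object reconstructed radially symmetrically gives a
  # curve indexed purely by |omega|; check the binning is radius-faithful
  n <- 32; alpha <- 25; wu <- 4 / n
  dx <- 10 * LAMBDA200 / (n * alpha * wu)
  bump <- make_phase_object(n, dx, "atoms", amplitude_rad = 0.2,
                            centers_A = matrix(c(4, 4), 1), sigma_A = 0.3)
  ctf <- numerical_itr_ctf(bump, LAMBDA200, alpha, step_px = 1,
                           iterations = 40)
  expect_true(all(diff(ctf$frequency) > 0))
  expect_true(all(is.finite(ctf$transfer)))
})
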