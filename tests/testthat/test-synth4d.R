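test_that("phase-object construction matches its advertised spectra", {
  # a single sinusoid occupies exactly one conjugate Fourier pair
  obj <- make_phase_object(32, 0.25, "sinusoid", amplitude_rad = 0.1,
                           freq_cyc_per_A = c(0, 3 / (32 * 0.25)))
  sp <- stats::fft(obj$phase)
  nz <- which(Mod(sp) > 1e-9 * max(Mod(sp)))
  expect_equal(length(nz), 2)
  expect_equal(max(abs(obj$phase)), 0.1, tolerance = 1e-12)
  # vacuum is identically zero
  expect_true(all(make_phase_object(16, 0.2, "vacuum")$phase == 0))
  # atom peaks recovered by argmax at the requested positions
  obj2 <- make_phase_object(64, 0.05, "atoms", amplitude_rad = 0.3,
                            centers_A = rbind(c(1.0, 1.0), c(1.0, 2.2)),
                            sigma_A = 0.15)
  i <- which(obj2$phase == max(obj2$phase), arr.ind = TRUE)[1, ]
  expect_true(all(abs((i - 1) * 0.05 - c(1.0, 1.0)) < 0.05 + 1e-9) ||
                all(abs((i - 1) * 0.05 - c(1.0, 2.2)) < 0.05 + 1e-9))
  # frequencies beyond the grid Nyquist are rejected
  expect_error(make_phase_object(16, 0.2, "sinusoid", freq_cyc_per_A = c(0, 10)),
               "Nyquist")
})

test_that("vacuum datasets are pure aperture disks with unit energy", {
  obj <- make_phase_object(32, 0.3, "vacuum")
  ds <- simulate_4dstem(obj, LAMBDA200, 20, 0, step_px = 8)
  sums <- apply(ds$data, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-10)
  # every pattern equals the position-averaged pattern
  pb <- pacbed(ds)
  expect_equal(max(abs(ds$data[1, 1, , ] - pb)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ds$data[3, 2, , ] - pb)), 0, tolerance = 1e-12)
  # the disk radius in pixels matches alpha / dtheta
  r_px <- 20 / ds$dtheta_mrad
  on <- which(pb > 0.5 * max(pb), arr.ind = TRUE)
  cc <- floor(32 / 2) + 1
  expect_lt(max(sqrt((on[, 1] - cc)^2 + (on[, 2] - cc)^2)), r_px + 1.5)
})

test_that("noiseless patterns conserve energy; Poisson draws are reproducible", {
  fx <- epie_fixture()
  sums <- apply(fx$dataset$data, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-10)
  obj <- make_phase_object(16, 0.4, "vacuum")
  d1 <- simulate_4dstem(obj, LAMBDA200, 15, 0, step_px = 4,
                        electrons = 500, poisson_seed = 11)
  d2 <- simulate_4dstem(obj, LAMBDA200, 15, 0, step_px = 4,
                        electrons = 500, poisson_seed = 11)
  expect_identical(d1$data, d2$data)
  expect_true(all(d1$data >= 0))
  expect_equal(mean(apply(d1$data, c(1, 2), sum)), 500, tolerance = 0.1)
  expect_error(simulate_4dstem(obj, LAMBDA200, 15, 0, electrons = 500),
               "seed")
})

test_that("a window-violating probe is flagged in the metadata, not silently", {
  obj <- make_phase_object(32, 0.3, "vacuum")
  ds <- simulate_4dstem(obj, LAMBDA200, 27.42, 80, step_px = 8)
  expect_gt(length(ds$warnings), 0)
  expect_match(ds$warnings[1], "probe window")
})

test_that("rebinning conserves counts and commutes with subsampling", {
  fx <- epie_fixture()
  ds <- fx$dataset
  expect_identical(rebin_patterns(ds, 1), ds)
  b <- rebin_patterns(ds, 8)
  expect_equal(dim(b$data)[3:4], c(4, 4))
  expect_equal(sum(b$data), sum(ds$data), tolerance = 1e-9)
  expect_equal(b$dtheta_mrad, ds$dtheta_mrad * 8)
  expect_error(rebin_patterns(ds, 5), "divisor")
  # corruption operators commute
  a1 <- subsample_scan(rebin_patterns(ds, 4), 3)
  a2 <- rebin_patterns(subsample_scan(ds, 3), 4)
  expect_equal(a1$data, a2$data)
  expect_equal(a1$step_A, a2$step_A)
  expect_equal(a1$dtheta_mrad, a2$dtheta_mrad)
})

test_that("subsampling keeps every (skip+1)-th position with scaled metadata", {
  dummy <- structure(list(data = array(seq_len(128 * 128 * 4),
                                       dim = c(128, 128, 2, 2)),
                          step_A = 0.15903, dtheta_mrad = 0.83125,
                          lambda_pm = LAMBDA200, alpha_mrad = 27.42,
                          defocus_nm = 0, electrons_per_position = 3433,
                          dose_e_per_A2 = 135736, seed = NA_integer_,
                          warnings = character(0)), class = "dataset4d")
  expect_identical(subsample_scan(dummy, 0), dummy)
  s4 <- subsample_scan(dummy, 4)
  expect_equal(dim(s4$data)[1:2], c(26, 26))   # ceiling(128 / 5)
  expect_equal(s4$step_A, 0.15903 * 5)
  expect_equal(s4$dose_e_per_A2, 135736 / 25)
  expect_equal(s4$data[1, 1, , ], dummy$data[1, 1, , ])
  expect_equal(s4$data[2, 1, , ], dummy$data[6, 1, , ])
})

test_that("PACBED is linear and averages down Poisson noise", {
  fx <- epie_fixture()
  ds <- fx$dataset
  expect_equal(pacbed(rebin_patterns(ds, 4)),
               {p <- pacbed(ds)
        # rebin of the mean pattern
        d <- array(p, dim = c(4, 8, 4, 8))
        apply(d, c(2, 4), sum)}, tolerance = 1e-12)
  # noise on the mean shrinks roughly as 1 / sqrt(positions)
  obj <- make_phase_object(16, 0.4, "vacuum")
  noiseless <- pacbed(simulate_4dstem(obj, LAMBDA200, 15, 0, step_px = 4))
  noisy <- simulate_4dstem(obj, LAMBDA200, 15, 0, step_px = 1,
                           electrons = 200, poisson_seed = 3)
  few <- subsample_scan(noisy, 3)
  rms <- function(d) sqrt(mean((pacbed(d) / 200 - noiseless)^2))
  ratio <- rms(few) / rms(noisy)
  expect_gt(ratio, 2)      # 16x fewer positions: expect about 4x the noise
  expect_lt(ratio, 8)
})

test_that("datasets round-trip through the on-disk container", {
  fx <- epie_fixture()
  path <- tempfile(fileext = ".rds")
  write_dataset4d(fx$dataset, path)
  back <- read_dataset4d(path)
  expect_identical(back$data, fx$dataset$data)
  expect_equal(back$step_A, fx$dataset$step_A)
  unlink(path)
  saveRDS(list(1), path)
  expect_error(read_dataset4d(path), "dataset4d")
  unlink(path)
})
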