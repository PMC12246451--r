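test_that("probe window and its Nyquist half-limit", {
  pw <- probe_window(LAMBDA200, 0.83125)
  expect_equal(pw$D_psi_A, 30.17, tolerance = 1e-3)
  expect_equal(pw$d_probe_max_A, pw$D_psi_A / 2)
  # at binning 48 the window shrinks below the focused probe diameter
  pw48 <- probe_window(LAMBDA200, 39.9)
  expect_equal(pw48$D_psi_A, 0.629, tolerance = 1e-2)
  expect_lt(pw48$D_psi_A, 0.8)
  # inverse proportionality
  expect_equal(probe_window(LAMBDA200, 0.4)$D_psi_A,
               2 * probe_window(LAMBDA200, 0.8)$D_psi_A)
})

test_that("lateral resolution and the SSB step bound use the exact sine", {
  r <- lateral_resolution(LAMBDA200, 27.42)
  expect_equal(r, 0.4575, tolerance = 1e-3)
  expect_equal(lateral_resolution(LAMBDA200, 6.02), 2.08, tolerance = 1e-2)
  expect_equal(r * sin(2 * 27.42 / 1000), 0.01 * LAMBDA200)
  s <- ssb_max_step(LAMBDA200, 27.42)
  expect_equal(round(s, 2), 0.23)
  expect_equal(s, r / 2)
  # small-angle form agrees to < 0.2% at this angle
  expect_equal(s / (0.01 * LAMBDA200 / (4 * 0.02742)), 1, tolerance = 2e-3)
})

test_that("iterative reconstruction pixel size and padding", {
  p <- itr_pixel_size(LAMBDA200, 79.8)
  expect_equal(p, 0.314, tolerance = 1e-2)
  expect_equal(itr_pixel_size(LAMBDA200, 79.8, 2), p / 2)
  expect_equal(p * 79.8 / 10, LAMBDA200)
  expect_error(itr_pixel_size(LAMBDA200, 79.8, 0.5), ">= 1")
})

test_that("overlap metrics match the printed flagship values and clamp", {
  ov <- overlap_metrics(0.8, 0.15903)
  expect_equal(ov$SR_overlap, 80.1, tolerance = 1e-3)
  expect_equal(ov$SR_linear, 5.03, tolerance = 1e-3)
  expect_equal(ov$SR_areal, 19.9, tolerance = 1e-2)
  # zero geometric overlap at the 0.81 A step
  expect_equal(overlap_metrics(0.8, 0.81)$SR_overlap, 0)
  # step equal to the diameter
  ov2 <- overlap_metrics(0.8, 0.8)
  expect_equal(ov2$SR_overlap, 0)
  expect_equal(ov2$SR_linear, 1)
  expect_equal(ov2$SR_areal, pi / 4)
})

test_that("combined sampling reproduces the worked values", {
  expect_equal(round(combined_sampling(LAMBDA200, 0.81, 79.8 / 3), 1), 0.6)
  expect_equal(combined_sampling(LAMBDA200, 0.15903, 0.83125), 94.9,
               tolerance = 1e-3)
  # boundary: dR dtheta = lambda / 2 gives exactly 1
  dr <- 0.3
  dth <- 0.01 * LAMBDA200 / (2 * dr) * 1000
  expect_equal(combined_sampling(LAMBDA200, dr, dth), 1)
  # exact inverse proportionality in both factors
  expect_equal(combined_sampling(LAMBDA200, 2 * dr, dth),
               combined_sampling(LAMBDA200, dr, dth) / 2)
  expect_equal(combined_sampling(LAMBDA200, dr, 2 * dth),
               combined_sampling(LAMBDA200, dr, dth) / 2)
})

test_that("maximum defocus keeps the probe within half the window", {
  expect_equal(max_defocus(15.0855, 27.42, 0), 27.5, tolerance = 1e-3)
  expect_equal(max_defocus(0.5, 27.42, 0.8), 0)
  expect_equal(max_defocus(20, 27.42, 0), 2 * max_defocus(10, 27.42, 0))
})

test_that("depth resolution follows the half-angle sine-squared form", {
  expect_equal(depth_resolution(LAMBDA200, 79.8), 7.88, tolerance = 1e-3)
  expect_equal(depth_resolution(LAMBDA200, 30), 55.7, tolerance = 1e-2)
  # small-angle limit 2 lambda / theta^2 to < 0.2%
  expect_equal(depth_resolution(LAMBDA200, 79.8) /
                 (2 * 0.01 * LAMBDA200 / 0.0798^2), 1, tolerance = 2e-3)
  # strict monotone decrease with angle
  th <- c(10, 30, 50, 79.8, 120, 300)
  expect_true(all(diff(sapply(th, depth_resolution, lambda_pm = LAMBDA200)) < 0))
})

test_that("nyquist helper halves the target spacing", {
  expect_equal(nyquist_step(1.2), 0.6)
})

test_that("the sampling report aggregates consistently", {
  rep <- build_report(flagship_plan("ITR"))
  expect_equal(rep$S_hat, 94.9, tolerance = 1e-3)
  expect_equal(attr(rep, "geometry")$coverage_alpha, 2.91, tolerance = 2e-3)
  expect_equal(rep$ssb_step_A, rep$r_xy_A / 2)
  expect_equal(rep$resolution_gain, rep$step_used_A / rep$itr_pixel_A)
  # skipping every 5th position scales the used step and sampling exactly
  rep4 <- build_report(flagship_plan("ITR", skip = 4))
  expect_equal(rep4$step_used_A, 5 * rep$step_used_A)
  expect_equal(rep4$S_hat, rep$S_hat / 5)
  expect_equal(rep4$dose_e_per_A2, rep$dose_e_per_A2 / 25)
})

test_that("window limit and maximum defocus are two views of one bound", {
  # d_probe <= d_probe_max exactly when defocus <= max_defocus (additive form)
  set.seed(7)
  for (i in 1:25) {
    alpha <- runif(1, 5, 35)
    d0 <- runif(1, 0, 1.5)
    dth <- runif(1, 0.5, 40)
    df <- runif(1, 0, 60)
    beam <- beam_setting(200, alpha, defocus_nm = df, d0_A = d0)
    dmax <- probe_window(LAMBDA200, dth)$d_probe_max_A
    fmax <- max_defocus(dmax, alpha, d0)
    fits <- geometric_probe_diameter(beam) <= dmax + 1e-9
    expect_equal(fits, df <= fmax + 1e-9)
  }
})
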