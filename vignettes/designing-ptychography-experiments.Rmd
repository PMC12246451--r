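---
title: "Designing 4D-STEM ptychography experiments with ptychodesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing 4D-STEM ptychography experiments with ptychodesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptychodesign)
```

## The design problem

Electron ptychography reconstructs the phase of a specimen's transmission
function from a 4D-STEM dataset: a full 2D diffraction pattern recorded at
every position of a 2D probe scan. Whether a reconstruction succeeds — and
at what resolution and dose — is decided before the experiment, by the
interplay of the probe-forming convergence semi-angle $\alpha$, the defocus,
the scan step $\Delta R$, the detector's angular pitch $\Delta\theta$, the
camera length and the probe current. `ptychodesign` evaluates this
parameter space the way an operator at the microscope would: enter a
candidate plan, read off every derived quantity, and check it against the
feasibility rules of the intended reconstruction method — direct single
side band (SSB) or iterative engines (ePIE and relatives, "ITR").

## The quantities the package derives

For a plan with wavelength $\lambda$ (relativistic, from the accelerating
voltage), the core relations are:

* **Probe window.** The computational field of the reconstructed probe is
  $D_\psi = \lambda/\Delta\theta$; Nyquist sampling of the diffraction
  patterns requires the probe diameter to stay below
  $d_\mathrm{probe\,max} = D_\psi/2$.
* **Lateral resolution and SSB step.** Direct methods transfer frequencies
  up to $2\alpha$, so $r_{xy} = \lambda/\sin 2\alpha$ and the Nyquist scan
  step for SSB is $\Delta R_\mathrm{SSB} = \lambda/(2\sin 2\alpha)$.
* **Iterative reconstruction pixel.** $\mathrm{Pix}_\mathrm{ITR} =
  \lambda/\theta$ with $\theta$ the maximum detected semi-angle (clipped by
  the differential-pumping aperture when one limits the camera); zero
  padding of the patterns shrinks it proportionally.
* **Overlap and combined sampling.** The geometric probe overlap
  $(d_\mathrm{probe}-\Delta R)/d_\mathrm{probe}$, the linear and areal
  oversampling ratios, and the combined real/reciprocal criterion
  $\hat S = \lambda/(2\,\Delta R\,\Delta\theta) \ge 1$, which is what lets
  tiny detector arrays work when the scan is dense.
* **Defocus bound.** A defocused probe of diameter
  $d_0 + 2\Delta f\tan\alpha$ must fit half the window, giving
  $\Delta f_\mathrm{max} = (d_\mathrm{probe\,max}-d_0)/(2\tan\alpha)$. The
  subtraction of the focused diameter $d_0$ is this package's (conservative)
  extension of the pure geometric bound, consistent with its additive
  probe-diameter convention; a quadrature composition is available as an
  option.
* **Depth resolution.** The minimal useful slice thickness for multislice
  iterative reconstruction, $r_z = \lambda/(2\sin^2(\theta/2))$.
* **Dose.** Electrons per pattern $I t/e$ and areal dose
  $It/(e\,\Delta R_\mathrm{used}^2)$, where skipping every $(s+1)$-th
  position multiplies the used step by $s+1$ and divides the dose by
  $(s+1)^2$.

All formulas use the exact trigonometric forms; the small-angle versions
appear only as test oracles. Interfaces use the field's units (kV, mrad, Å,
nm, pA, µs, cm, e/Å²); values are rounded only at presentation.

```{r report}
plan <- acquisition_plan(
  beam_setting(200, 27.42, defocus_nm = 0, current_pA = 11, d0_A = 0.8),
  scan_setting(0.15903, nx = 128, ny = 128, dwell_us = 50),
  detector_model(192, 100, camera_length_cm = 12.12, dtheta_mrad = 0.83125),
  method = "ITR")
build_report(plan)
```

## The SSB transfer function

The intrinsic SSB phase contrast transfer at scan frequency $Q =
\omega\alpha$ is proportional to the net area of the double-disk overlap
between the direct beam and one diffracted beam, with the triple-overlap
region (where both $\pm Q$ disks intersect the direct disk) excluded. With
unit-radius disks the double overlap is the circle lens at separation
$\omega$ and the triple overlap is the lens at separation $2\omega$ (it
always lies inside the direct disk), so the net transfer is
$A(\omega) = \mathrm{lens}(\omega) - \mathrm{lens}(2\omega)$ for
$\omega < 1$ and $\mathrm{lens}(\omega)$ beyond. Setting the derivative to
zero gives the peak analytically at $\omega = 2/\sqrt5 \approx 0.894$,
i.e. $0.9\alpha$ to plotting precision, with exact zeros at $0$ and
$2\alpha$. One sideband's area is counted (one trotter per $\pm Q$ pair);
the both-sideband convention differs only by a factor of two, which both
normalisations remove. Because the transfer curve's absolute scale is not
observable, two normalisations are exposed: `max_one` (peak scaled to 1)
and `area_ratio` (area over the full disk $\pi\alpha^2$).

```{r ctf}
ctf <- ssb_ctf(alpha_mrad = 27.42, lambda_pm = electron_wavelength(200))
ctf$frequency[which.max(ctf$transfer)]
head(convert_axis(ctf, "angstrom"))
```

## The rules engine and camera-length guide

`run_checks()` evaluates the built-in feasibility rules. For iterative
methods: detector coverage within 1–6$\alpha$ (at least the bright-field
disk, below the low-count region; the upper bound is configurable since no
quantitative low-count criterion exists), probe overlap at least 70%,
detected angle within the 10° small-angle limit, resolution gain
$\Delta R_\mathrm{used}/\mathrm{Pix}_\mathrm{ITR} \ge 1$, combined sampling
$\hat S \ge 1$, a user-chosen pattern-recovery level below $\hat S$, and
the probe-window rule. For SSB: the step bound of
$\Delta R_\mathrm{SSB}$, at least 1$\alpha$ coverage (fixed) and a
bright-field disk of at least 4 pixels (fixed). Fixed rules fail hard;
editable rules warn within 10% of their threshold, so a command-line run
can map pass/warn/fail onto exit codes 0/1/2. Verdicts are pure functions
of the plan and thresholds and serialise to byte-stable JSON.

A deliberate consequence of the resolution-gain rule: a dense focused scan
(e.g. a 0.159 Å step against a 0.314 Å reconstruction pixel) *fails* it,
because the scan then carries more positions than the reconstruction has
pixels. Balanced plans that pass all iterative rules pair a moderate
defocus with position skipping, which is exactly the dose-efficient regime
the defocused-probe constraints describe.

`camera_length_guide()` tabulates all metrics over the calibrated camera
lengths; for SSB it also reports the longest camera length that still
keeps 1$\alpha$ on the detector.

## Calibrations

Three pure computations mirror how the underlying quantities are measured:
the camera equation $R_{hkl}\,d_{hkl} = \lambda L$ inverted for the
effective camera length from known diffraction-spot distances; the
convergence semi-angle from the ratio of the bright-field disk diameter to
a known Bragg-disk spacing; and a scan-step correction factor from a row of
atoms of known spacing. Peak finding on calibration images is deliberately
out of scope — the functions accept measured numbers. A long-format CSV
(`inst/extdata/calibrations_synthetic.csv`, synthetic values) holds the
per-microscope tables; the detector entry may carry a measured angular
pitch, which takes precedence over the small-angle $p_\mathrm{eff}/L$
estimate and is rescaled inversely with camera length in the guide.

## The synthetic validation loop

The package closes the loop between its design formulas and actual
reconstructions without any external data:

* `make_phase_object()` builds periodic weak-phase objects — sinusoids with
  exactly one Fourier pair each, or lattices of Gaussian "atoms".
* `simulate_4dstem()` is a single-slice weak-phase forward model: the
  simulated probe (hard aperture with an anti-aliased rim, defocus phase
  $\chi = \pi\lambda\Delta f k^2$, no other aberrations, full coherence) is
  multiplied by $e^{i\varphi}$ and propagated to the far field; the
  detector grid is the probe's reciprocal grid. The anti-aliased rim makes
  pixel-sampled disk-overlap sums converge to the continuum areas, which is
  what a physical pixel integrating intensity over its area does. Poisson
  noise is optional, with a per-position seed derived from one integer so
  draws are order-independent and bit-reproducible. Setting `detector_px`
  switches to the probe-window-limited forward model (the probe lives on a
  small detector-sized grid), emulating tiny detector arrays whose window
  constraint is honoured exactly.
* `rebin_patterns()` and `subsample_scan()` are the corruption operators
  (count-conserving block sums; every-$(s{+}1)$-th-position selection);
  they commute, and `pacbed()` gives position-averaged patterns.
* `ssb_reconstruct()` implements direct SSB: Fourier transform over scan
  positions, integration over each frequency's trotter (with the same
  edge-aware disk model as the simulator), and an analytically calibrated
  inverse transform, quantitative for focused probes and weak phases.
* `epie_reconstruct()` is a minimal textbook ePIE with periodic boundary
  conditions, sequential raster (optionally shuffled) updates, and a
  per-sweep RMS amplitude-error trace. By default the probe starts with a
  10% defocus error so probe refinement is observable.
* `numerical_itr_ctf()` runs the single-atom recipe for the iterative
  method's transfer: simulate an isolated radially symmetric Gaussian phase
  bump, reconstruct, deconvolve the known bump in Fourier space (Wiener-like
  floor at $10^{-3}$ of the peak denominator) and azimuthally average.
  Element-specific scattering potentials are an extension point; the
  Gaussian bump is a synthetic stand-in.

On noiseless fixtures the reconstruction-measured SSB transfer matches the
analytic curve to well under 3% RMS at five probe frequencies, ePIE reaches
phase correlation above 0.95 with ground truth, and the numerical iterative
transfer stays flat near 1 out to — and beyond — the $2\alpha$ SSB cutoff,
the superresolution the dense-scan sampling trade-off predicts.

## Numerical choices and problem sizes

* Grids are even-sized with the DC pixel at 0-based index $n/2$; objects
  and probes are periodic, avoiding windowing choices.
* The SSB transfer fixture uses a 64² scan over a 64² detector (detector
  pixel $\alpha/16$, scan Nyquist at $2\alpha$); iterative fixtures use 32²
  grids. These sizes hold the full suite to a couple of minutes on one CPU
  while keeping discretisation errors around the percent level.
* The illumination-uniformity summary $U = 100\cdot I_\min/I_\max$ is
  evaluated over the scanned area trimmed by one probe diameter (59%
  definition); published work introduces a uniformity figure without a
  printed formula, so the definition here is a documented, swappable
  strategy and its absolute values should not be compared across tools.
* The probe-window feasibility rule compares the *geometric* probe diameter
  against half the window. With the vendor-quoted 0.8 Å focused diameter it
  already fails at binning 24 of the 192-pixel reference detector; with the
  ideal diffraction-limited diameter the simulator computes (≈0.56 Å at
  27.42 mrad), it fails exactly from binning 48 — the intensity-fraction
  view of the same transition. Users supplying a measured $d_0$ get the
  conservative verdict.
* Dose arithmetic reports computed values only. The skip-based dose series
  of the reference acquisition (136,000 e/Å² unskipped) gives 530 e/Å² at
  skip 15 and 236 e/Å² at skip 23; a published value of 231 e/Å² for the
  latter implies an undocumented scan-step calibration factor, so the
  computed number stands.
* No attempt is made to emulate detector MTF, flat-field or dead pixels,
  partial coherence, source size, or multislice scattering. Passing the
  synthetic suite therefore validates the sampling and transfer geometry,
  not radiation-damage or thickness effects in real specimens.

## Known limitations

The weak-phase, single-slice simulator cannot probe dynamical scattering or
thickness-dependent contrast; the ePIE reference is a minimal engine, far
less robust than maximum-likelihood reconstructions to model mismatch such
as post-hoc pattern binning (which violates its forward model — use the
window-limited simulation for small-detector studies); and the SSB
calibration is quantitative only for focused probes. The aberration model
stops at defocus, matching corrected instruments.
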