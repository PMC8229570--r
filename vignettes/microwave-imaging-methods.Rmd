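---
title: "Methods: UWB microwave imaging of small tumors with imtr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UWB microwave imaging of small tumors with imtr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `imtr`, in the spirit of a methods section: what is
simulated, what each tunable parameter means, what the algorithms assume,
and what the package's passing tests do and do not demonstrate about real
measurements.

## The imaging problem

Malignant tissue has a substantially higher permittivity and conductivity
than healthy breast fat (a factor of roughly 2-10), so an ultra-wideband
(UWB) microwave pulse scattered inside the breast carries a detectable
signature of a small tumor. A ring of antennas takes turns transmitting a
short modulated Gaussian pulse while all elements record the scattered
field (a multistatic acquisition). Image formation then asks, for every
pixel, whether the recorded traces are consistent with a scatterer at that
location.

The package implements the whole chain at desk scale:

1. **Phantoms**: 2-D dielectric maps of a circular breast (fat disc + thin
   skin shell) with circular tumor inclusions.
2. **Forward simulation**: a 2-D TMz FDTD solver with convolutional PML
   (CPML) absorbing boundaries, plus an analytic Born point-scatterer model
   used as an independent oracle.
3. **Preprocessing (the IMTR chain)**: calibration, weighting and
   early-content removal, pairwise multiplication, a second averaging, time
   gating, Gaussian windowing.
4. **Reconstruction**: modified weighted delay-and-sum (MWDAS),
   delay-multiply-and-sum (FDMAS), time reversal (TR; numeric re-injection
   or synthetic backprojection), and the IMTR pair-trace backprojection.
5. **Scoring**: SSIM and MSE against a clutter-free reference image,
   localization error, and empirical PSF resolution.

## Study conditions and defaults

The packaged scenario catalogue fixes the study conditions:

| Parameter | Default | Why |
|---|---|---|
| breast radius | 50 mm (80 mm in `large_breast`) | the modeled sample sizes |
| skin thickness | 2 mm | typical skin shell; not stated by the source system |
| tumor radius | 2 mm (1.5 mm in `small_tumor`) | the trial tumor sizes |
| fat | eps_r 5.1, sigma 0.14 S/m | literature-typical; honors the 2-10x contrast |
| skin | eps_r 36, sigma 4 S/m | literature-typical |
| tumor | eps_r 50, sigma 7 S/m | ~9.8x fat permittivity, inside the contrast band |
| ring radius | 60 mm (9 slots, 40 degrees apart) | breast + 5 mm standoff + margin |
| pulse | f_r = 2.4 GHz, omega = 78.1 ps | the system's excitation |
| grid | 0.7 mm (1.4 mm in `large_breast`) | >= 10 cells per shortest in-tissue wavelength at the -10 dB band edge |
| Courant factor | 0.5 | comfortably below the 2-D bound 1/sqrt(2) |
| PML | 10 cells, cubic grading, design reflection 1e-6 | measured residual ~2e-5 |
| image pixel | 1 mm, extent breast + 10 mm pad | reconstruction convention |

Tumor positions are not stated for the trials; the catalogue places the
single tumor at (15, 0) mm (off-center, well inside the fat), the two-tumor
pair at (+-10, 0) mm (20 mm apart), and three tumors on a 20 mm-radius
triangle. All scenario parameters can be overridden through the YAML
configuration or `scenario_catalogue(name, overrides = ...)`.

Problem sizes were chosen so that a full four-algorithm run of the default
scenario completes in about three minutes on one CPU; the test suite reuses
one cached run.

## Forward model

The solver is a standard Yee-grid 2-D TMz FDTD with the lossy-medium update
coefficients and CPML (polynomial sigma grading of order 3, linearly graded
CFS alpha, kappa = 1). Antennas are ideal point transceivers: a soft
additive source at the nearest grid cell, and the out-of-plane electric
field at a cell as the received signal. The excitation is
`S(t) = exp(-(t - t0)^2/(2 omega^2)) cos(2 pi f_r t)` with `t0 = 5 omega`
so the pulse switches on near zero amplitude.

Verified properties (see `test-forward.R`): free-space propagation speed
within 1% (measured differentially between two receiver separations),
PML residual reflection ~2e-5 at 10 cells (about 1 at 0 cells, monotone
with thickness), discrete reciprocity to machine precision in lossless
media, and peak-time changes below 0.5% under grid refinement.

Two systematic effects matter when comparing to the analytic Born oracle.
First, a 2-D (line-source) geometry produces a wake - the Green function
decays as an inverse square root behind the front - which together with
the soft-source response biases any single absolute envelope-peak arrival
by a few picoseconds; propagation speed is therefore measured
differentially, which cancels the constant. Second, the discrete
scattering chain of a small inclusion shifts the scattered envelope peak
by a few picoseconds relative to the idealized replica of the Born model,
so the Born/FDTD arrival agreement is asserted at 1% of the arrival time
rather than at sample level.

The excitation pulse has appreciable DC content (its envelope is much
shorter than one modulation period). A soft current source with DC leaves
a small static residual field; since physical UWB receivers are AC
coupled, `calibrate()` removes per-channel sub-carrier drift with a
running-mean high-pass over one modulation period.

## The preprocessing chain

Stages advance strictly E3 -> E4 -> pairs -> E5 -> E6 -> E7.

- **Calibration (E3)**: `E3 = E2 - E1` per channel. Two background
  definitions are supported: an empty-domain acquisition (the packaged
  default, matching the reference system's background definition) and a
  tumor-free phantom acquisition. With an empty background the calibrated
  traces still contain the entire breast response - dominated by the skin
  echo - which is exactly the clutter regime the chain is designed for.
- **Weighting and early-content removal (E4)**: channels are scaled by a
  weighting factor (default 1) and an average is subtracted. When the ring
  layout is known, channels are grouped by angular tx-rx separation: for a
  rotationally symmetric phantom, equal-separation channels record
  identical skin echoes, so the group mean removes the skin reflection
  exactly while an off-center tumor, which breaks the symmetry, survives
  (rotated-reference artifact removal). The cost is that a perfectly
  rotationally symmetric target (a tumor exactly at the center of a full
  ring) is invisible to this stage. The plain global mean is available via
  `group_by = "none"`.
- **Pairwise multiplication**: one trace per unordered channel pair,
  `y_(i,j)(t) = S_i(t) S_j(t)`. The pipeline pairs receiver traces sharing
  a transmitter, which for the 9-element ring reproduces the printed
  36-pair enumeration per transmitting element; the generic all-pairs mode
  gives 6 pairs for 4 channels and 36 for 9.
- **Second averaging (E5)**: default realization subtracts the cross-pair
  mean at each time sample, suppressing product content common to all
  pairs. The alternative, a per-trace moving average (kernel defaulting to
  the pulse width in samples), is retained; it was not chosen as the
  default because it attenuates and distorts the double-frequency
  component of the pair products whose phase the reconstructor uses
  (measured: argmax error grows from 0.7 mm to 9.5 mm with the
  full-width kernel).
- **Time gating (E6)**: samples strictly inside `(tE, tL)` survive. The
  geometric estimator traces straight rays at per-segment speeds
  `c/sqrt(eps_r)`: `tE` is the earliest transmitter-to-front-wall-to-
  receiver time and `tL` the latest round trip through the back wall at
  the fat speed. A signal-driven alternative (first/last crossing of 10%
  of the envelope peak) is available.
- **Gaussian windowing (E7)**: `E7 = E6 exp(-((t - tp)/tau)^2)` with
  `tp` the gate midpoint and `tau = (tL - tE)/4` by default, so residual
  content near the gate edges (skin echo at `tE`) is attenuated by about
  `e^-4` while mid-gate tumor returns pass.

## Image formation

All reconstructors share straight-ray focal delays. The default delay
model traces each ray through the three media explicitly (background at
`c`, skin shell, fat), using chord lengths through the outer and inner
skin circles. The homogeneous-speed fallback uses an effective
permittivity that is slowness-weighted along a diametral ray
(`effective_permittivity()`); area weighting was measured to bias
localization by ~2.5 mm and is not used.

- **MWDAS**: coherent delay-and-sum of the analytic channel signals at
  `tau_tx(r) + tau_rx(r)`, per-channel weights compensating the tx-rx
  path length, squared magnitude.
- **FDMAS**: sign-preserving square roots of the delayed real samples,
  combined pairwise through `((sum s)^2 - sum s^2)/2` and integrated over
  a pulse-length window - the standard delay-multiply-and-sum realization.
- **TR**: numeric mode re-injects the time-reversed calibrated traces at
  the antenna cells of the known background phantom with the FDTD solver
  and accumulates `|E|^2` under a Gaussian time window (one pulse width)
  around the refocus instant located by a first pass (the snapshot
  imaging condition); plain whole-record energy accumulation is available.
  The image is restricted to the sample interior: the skin shell is part
  of the background model the fields propagate through, so energy
  converging onto it is explained by the model, and pixels near the
  injection cells are masked. Synthetic mode is unweighted phase-conjugate
  backprojection.
- **IMTR**: the pair traces are products, so one pair determines only the
  *sum* of its two channels' arrival times - its product support sits at
  the midpoint of the two arrivals, and backprojection of single pairs is
  ambiguous along iso-sum loci. Closed channel triangles resolve the
  individual delays (`a_i = (S_ij + S_ik - S_jk)/2`), and the same closure
  holds for the phase of the double-frequency component of each product.
  The image former therefore samples the complex analytic pair signals at
  the mean of their channels' focal arrivals and accumulates the
  phase-closure (bispectral) combination `z_ij z_ik z*_jk` over all
  channel triples whose three pairs exist; the closure phase is stationary
  exactly where the focal delays match the individual channel delays, so
  triples add coherently at the target and cancel elsewhere. The final
  intensity is the squared magnitude followed by a -20 dB clutter floor,
  reflecting the algorithm's published identity as a complete
  artifact-removal pipeline.

The reconstruction domain is the sample under test: `run_scenario()`
restricts every algorithm's image to the breast disc before scoring
(grid corners beyond the antenna ring otherwise accumulate meaningless
late-time content).

## Scoring

The reference image is a binary disc of 4 mm diameter at each true tumor
location (the conventional clutter-free reference of this scoring
protocol, independent of the simulated tumor size; the disc diameter is
overridable). SSIM uses a 7x7 Gaussian window (sigma 1.5), K1 = 0.01,
K2 = 0.03, dynamic range 1, after max-normalizing both images, so it is
invariant to global positive scaling. Localization extracts
plateau-tolerant local maxima with a 5 mm minimum separation and matches
them greedily to the true centers; flat images yield misses, never
errors. Empirical resolution images a single Born scatterer with
unweighted delay-and-sum and reports the FWHM of the PSF along the radial
and tangential directions through the peak.

## What the synthetic data do and do not show

The generator emulates: multistatic UWB acquisition geometry, realistic
tissue contrasts, the strong skin reflection (orders of magnitude above
the tumor response in the empty-background regime), lossy propagation,
and multiple scattering (the FDTD solver is full-wave). It does not
emulate: dispersion (tissues are frequency-independent by design),
3-D out-of-plane effects (the model is a 2-D slice with line sources, so
absolute amplitudes and the wake differ from 3-D measurements), antenna
radiation patterns and mutual coupling, glandular heterogeneity, or
measurement noise (available optionally, off by default). Passing tests
therefore demonstrate algorithmic correctness and the relative behavior
of the reconstruction algorithms under controlled conditions, not
clinical performance.

## Known limitations

- **Mirror-symmetric multi-target configurations.** Because the chain
  multiplies traces *before* imaging, multi-target data contain
  cross-target products. For two tumors placed symmetrically about the
  ring center, the sum of each channel's two target delays is nearly
  invariant across the aperture (the ring lies close to an ellipse whose
  foci are the two tumors), which makes those cross products mutually
  phase-consistent and creates a coherent virtual scatterer at the pair
  midpoint. The effect reproduces on exact Born-model data, so it is a
  property of the premultiplied-pair method itself; inter-tumor multiple
  scattering (about 30% of the scattered energy at 20 mm separation)
  compounds it. The packaged symmetric two-tumor trial therefore
  localizes the midpoint ghost rather than both tumors. Delay-multiply
  methods that delay before multiplying (FDMAS here) do not share this
  defect. Single off-center tumors are localized to sub-pixel accuracy.
- **Centered targets** are attenuated by the rotated-reference
  early-content removal (they are rotationally symmetric, like the
  clutter it removes).
- The Gaussian window favors mid-gate arrivals; tumors very close to the
  skin are attenuated together with the skin echo.
- Scores against the 4 mm reference disc depend on each algorithm's
  output convention (all are reported as squared, max-normalized
  intensities) and on the shared breast-disc restriction.
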