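# imtr

Ultra-wideband (UWB) microwave radar imaging of small tumors in layered
breast/skin phantoms, end to end and fully synthetic: a 2-D FDTD
electromagnetic solver with CPML absorbing boundaries generates multistatic
radar acquisitions from dielectric phantoms; the IMTR preprocessing chain
(calibration, early-content removal, pairwise multiplication, averaging,
time gating, Gaussian windowing) isolates the tumor response; four
reconstruction algorithms form images; SSIM/MSE/localization metrics score
them. The package is aimed at people studying confocal microwave imaging
algorithms who need a reproducible, measurement-free testbed.

## The science in brief

Malignant tissue is 2-10x more polarizable than breast fat, so a
sub-nanosecond modulated Gaussian pulse
`S(t) = exp(-(t - t0)^2 / (2 omega^2)) cos(2 pi f_r t)`
(f_r = 2.4 GHz, omega = 78.1 ps) scattered inside the breast carries a
tumor signature. Antennas sit on a 9-slot ring (`theta_A = (A-1) * 2pi/9`,
40 degrees apart) around a 50 mm-radius breast with a 2 mm skin shell.
After calibrating total against background acquisitions (`E3 = E2 - E1`)
and suppressing the skin echo, images are formed by backprojection at
straight-ray focal delays:

- **MWDAS** - weighted coherent delay-and-sum, `I(r) = |sum_ch w_ch a_ch(tau_tx + tau_rx)|^2`;
- **FDMAS** - delay-multiply-and-sum with sign-preserving square roots;
- **TR** - numeric time reversal: the recorded traces are time-reversed and
  re-injected into the known background medium with the FDTD solver, and
  field energy is accumulated at the refocus instant;
- **IMTR** - the pair traces `y_ij = S_i S_j` are backprojected by
  phase-closure over channel triples (`z_ij z_ik z*_jk` sampled at the mean
  focal arrivals), which pins down individual channel delays that single
  premultiplied pairs cannot, followed by a -20 dB clutter floor.

Reconstructions are scored against a clutter-free reference (a 4 mm disc at
each true tumor position) with SSIM (7x7 Gaussian window, K1 = 0.01,
K2 = 0.03) and MSE, plus peak-matching localization errors.

## Worked example

```r
library(imtr)

# the packaged default trial: 9 antennas, 50 mm breast, 2 mm tumor at (15, 0) mm
res <- run_scenario("nine_antennas", algorithms = "all",
                    out_dir = "out_nine", seed = 1)
res$metrics
#>        scenario algorithm      ssim         mse max_loc_error_mm n_missed
#> 1 nine_antennas     mwdas 0.3235766 0.215648139       50.5222723        0
#> 2 nine_antennas     fdmas 0.3568091 0.103331197       47.4605099        0
#> 3 nine_antennas        tr 0.3912412 0.103505645        8.5146932        0
#> 4 nine_antennas      imtr 0.9209345 0.002049772        0.7071068        0

image_argmax(res$images$imtr) * 1e3   # mm
#> [1] 15.5 -0.5
```

Reading the table: the background acquisition is an empty-domain
measurement, so the calibrated channels still carry the full breast
response. The plain beamformers (MWDAS, FDMAS) image mostly skin clutter
(SSIM ~ 0.32-0.36 against the clutter-free reference, localization tens of
mm off); matched-medium time reversal does somewhat better; the full IMTR
chain suppresses the skin echo and recovers the tumor to sub-pixel accuracy
(0.7 mm) with SSIM 0.92. `out_nine/` receives per-algorithm CSV + PNG
images, the signal sets (RDS), a metrics table, and a JSON run manifest.

Scenario configurations are YAML files (units mm/GHz/ps); see
`system.file("extdata", "scenarios", package = "imtr")` and
`scenario_catalogue()` for the seven packaged trials (3/6/9 antennas,
small tumor, two and three tumors, 16 cm breast). A thin command-line
front end lives at `inst/cli/imtr.R`
(`Rscript imtr.R run nine_antennas --algo all --out out_nine`).

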