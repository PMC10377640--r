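---
title: "Monte Carlo modelling of ring-type pulse oximeters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo modelling of ring-type pulse oximeters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

A ring-type pulse oximeter (RPO) places an LED and a photodetector (PD) on
the inner surface of a finger ring and estimates peripheral oxygen
saturation (SpO2) from the pulsatile attenuation of light at two
wavelengths, red (660 nm) and near-infrared (940 nm).  The design question
this package addresses numerically is geometric: how far around the ring
(angular separation `theta_PL` between PD and LED) can the detector be
placed before the detected signal becomes too weak and noisy to classify
SpO2 reliably — and how much does coating the inner ring surface with a
mirror (the "reflection-boosted" RPO-R variant, versus the absorbing
RPO-NR) extend that range and boost the perfusion index?

`rpoxim` answers this with a 3D weighted-photon Monte Carlo transport
simulation on a layered cylindrical finger model, plus the downstream
pipeline: dc/ac detected intensity over the cardiac cycle, perfusion index
(PI = ac/dc), the two-wavelength R ratio (PI_red/PI_nir), the SpO2
calibration curve, reliability limits, and the maximum reliable PD angle.
A separate module implements the matching waveform-analysis chain for
measured (or synthetic) photoplethysmography traces.

## The finger model

The finger is a circular cylinder of diameter 1.7 cm — coincident with the
ring inner surface (zero gap) — and length 4 cm with absorbing end caps
(long enough that end losses are negligible for a mid-plane source; both
configurable).  Inside it, from the surface inward:

* five concentric skin shells — epidermis (0.010 cm), papillary dermis
  (0.020 cm), upper blood net dermis (0.008 cm), reticular dermis
  (0.080 cm), deep blood net dermis (0.030 cm);
* subcutaneous fat filling the remaining interior;
* an elliptical bone cross-section, semi-axes 0.25 x 0.15 cm, centered
  0.3 cm from the axis (the tabulated "size" 0.5 x 0.3 cm is read as full
  widths, the most common convention);
* two mirrored digital arteries of radius 0.08 cm at (+/-0.4, 0.45) cm.

Coordinates: the cylinder axis is z, the LED sits at the bottom of the
cross-section (rim angle 0), and the bone/artery heights are measured
positive toward the LED (palmar) side — internally the bone is at
(0, -0.3) and the arteries at (+/-0.4, -0.45), i.e. *beneath* the bone on
the LED side, as the anatomical description requires.  The reference
tables list a single vessel position; we read it as two mirrored vessels,
consistent with the anatomy of paired digital arteries.  Both the sign
convention and the mirroring are configurable.

Classification priority at a point is artery > bone > skin shell by radial
depth > fat, evaluated analytically (no voxelization), so the thin
epidermis is represented without discretization bias.

## Optical properties

Per-layer absorption is mixed from chromophore volume fractions:

    mu_a(layer; lambda, S, m) = sum_i f_i mu_a,i(lambda),

where the blood fraction contributes
`f_blood * m * [S * mu_a,HbO2 + (1 - S) * mu_a,Hb]`, `S` is the SpO2
fraction and `m` the cardiac-phase capillary blood-volume multiplier.  The
shipped chromophore spectra (oxy-/deoxyhemoglobin as whole blood at
150 g Hb/L, water, lipid, melanosome melanin, bloodless skin baseline,
collagen) are a literature-based compilation tabulated over 600–1000 nm;
lookups interpolate linearly and are exact at tabulated wavelengths.  The
per-layer volume fractions, scattering coefficients (660/940 nm, power-law
interpolated in between), Henyey–Greenstein anisotropies and refractive
indices are literature-typical defaults for fair-to-medium skin.  The
original reference tabulation for this geometry is not publicly printed,
so these defaults are documented stand-ins: every value can be overridden
through the configuration, and absolute detected intensities should be
read as order-of-magnitude quantities while ratios (PI, R, enhancement
factors, angular trends) are much less sensitive.

Two cardiac phases are modelled exactly as tabulated: systole with artery
radius 0.080 cm and capillary multiplier 1, diastole with 0.092 cm and
1.5.  Note this assigns *more* blood to diastole, which is the reverse of
physiology; we implement the table as printed.  Consequently the literal
subtraction `I_diastolic - I_systolic` is negative, while the source text
defines ac by exactly that subtraction.  The default convention therefore
reports magnitudes — `ac = |I_dia - I_sys|`, `dc = max(I_sys, I_dia)` —
records the signed raw difference, and a `convention = "paper"` switch in
`paired_run()` reproduces the literal definition.  PI and R use only
magnitudes, so downstream quantities are unaffected.

## The transport kernel

The kernel (C++, single execution lane) implements the canonical
weighted-photon hop–drop–spin scheme:

* **Launch**: positions uniform over the 0.15 cm LED disk on the surface,
  directions Lambertian about the inward normal (a pencil-beam profile is
  available for verification runs).
* **Hop**: free paths `s = -ln(xi)/mu_t`; the step is taken analytically,
  with exact ray–cylinder intersection for surface crossings.  Internal
  layer interfaces within a step are located by bisection (24 iterations,
  position accuracy far below the mean free path); interior refractive-index
  mismatches are ignored (index-matched interior), as the surround model
  is purely absorber-versus-mirror.
* **Drop**: survival weighting, `dW = W mu_a/mu_t`, accumulated into the
  energy ledger and (optionally) a 200 x 200 cross-sectional fluence grid.
* **Spin**: Henyey–Greenstein deflection via the standard inverse CDF;
  azimuth uniform.
* **Roulette**: below weight 1e-4 photons survive with probability 0.1
  and are reweighted by 10 (unbiased).
* **Boundary**: a photon crossing the rim inside the PD aperture
  (0.3 x 0.3 cm, all arrival angles) deposits its weight as detected
  signal — detection takes precedence over the surround.  Otherwise it is
  specularly reflected with probability `rho` (1 = ideal mirror, RPO-R;
  0 = ideal absorber, RPO-NR) or terminated into the surround ledger.

The RNG is a single xoshiro256++ stream seeded per run, so every result is
bitwise reproducible from its seed; repeats use consecutive seeds that are
recorded in the output.

**Energy accounting.** Per launched unit weight,
`detected + tissue + surround + caps + roulette_net = 1` to better than
1e-6 on every run.  `roulette_net` (weight destroyed minus weight created
by roulette) is an explicit ledger term: it vanishes in expectation but
not exactly per run, and making it explicit is what lets the ledger close
exactly.

**Verification oracles** (all in the test suite): Beer–Lambert
transmission for a non-scattering uniform slab; the Henyey–Greenstein
first moment (mean deflection cosine = g at g = 0, 0.5, 0.9); exponential
step-length distribution by Kolmogorov distance; 1/N scaling of the
relative variance of the detected fraction; exact ledger closure under
absorbing, mirror and partial surrounds.

## Derived quantities

`paired_run()` executes the systolic and diastolic states and forms dc/ac.
The two phases share one kernel seed by default (common random numbers):
ac is a small difference of two nearly equal intensities, and correlating
the photon histories cancels most of the Monte Carlo noise in that
difference.  Independent seeding is available (`common_rng = FALSE`).

`angle_sweep()` covers the 15-angle grid (25–95 degrees in 5-degree
steps) per wavelength, surround and SpO2 level.  `calibration_curve()`
averages the 15 per-angle R ratios at each SpO2 level of the
absorbing-surround reference sweep; `reliability_limits()` takes the
midpoints of adjacent calibration values (for the published curve 0.9 /
1.25 / 1.5 / 1.9 these are exactly 1.075 / 1.375 / 1.7); and
`classify_reliable()` applies the strict-inequality bin rule (an R exactly
on a limit is unreliable — a measure-zero choice made for literalness).
`theta_max()` returns the largest grid angle such that *every* angle up to
it classifies all four SpO2 levels reliably; if none does, the condition
is "not measurable" (`NA`).  The published reference curve is shipped as
`reference_calibration_curve()` for downstream analysis against a fixed
standard.

## PPG waveform analysis

The measured-signal chain mirrors the simulation definitions:

* zero-phase bandpass (order-4 Butterworth, forward–backward) over the
  0.7–4 Hz cardiac band, chosen so envelope peak positions do not shift;
* envelope extraction: local extrema with minimum separation of a quarter
  cardiac period (heart rate estimated from the spectral peak in-band) and
  height at least 10% of the interquartile range, refined by 3-point
  parabolic interpolation (at 25 Hz sampling the raw sampled extremum
  undershoots the true crest by up to ~1%); dc = mean bottom-envelope
  level restored to the raw baseline, ac = mean top-envelope level minus
  dc; peaks within 2 s of the edges are discarded (filter transients);
* SNR: Welch mean periodogram (10-s Hann segments, 50% overlap),
  band-power ratio (0.7–4 Hz over 7–10 Hz) in dB — power spectra, i.e.
  `10 log10`, which we adopt where the source is ambiguous between
  amplitude and power conventions;
* reliability flags: SNR at both wavelengths >= 15 dB and R strictly
  inside (0.5, 0.7), the screening window for SpO2 > 95%.

The synthetic generator produces `dc + ac * pulse(t)` with a
peak-normalized two-harmonic pulse, optional sub-band baseline drift and
white noise; the trough level is exactly `dc`, so ground-truth PI = ac/dc
is recorded in the metadata for recovery tests.  What the generator does
*not* emulate: motion artifacts, baseline steps, waveform dichrotic
detail, quantization, or the 135-microsecond intra-frame offset between
the two wavelengths (negligible against cardiac timescales).  Passing
recovery tests therefore demonstrate the correctness of the analysis
chain, not robustness to every artifact of real measurements.

## Problem sizes and numerical choices

The published experiments use 1e7–1e8 photons and 100 repeats.  The
package defaults and test suite run at desk scale — classification clouds
of 2e5–4e5 points, transport runs of 1e3–1e6 photons, variance scaling at
N in {1e4, 1e5, 1e6} with 6 repeats, and the acceptance script at 1e7
photons for the absorbing-surround intensity and 1e6 per condition for the
mirror-enhancement ratio (the mirror case costs ~50x more per photon since
photons terminate only by absorption).  At 25 degrees the relative Monte
Carlo error is ~0.4% at 1e7 and ~1.2% at 1e6, far below the property-table
uncertainty.  Full-scale runs are provided by `scripts/longrun.R`, which
reproduces the 100 x 1e7 repetition statistics, the four-level calibration
sweeps for both surrounds, the theta_max ladder and the PI-at-theta_max
comparison.

Degenerate inputs are handled explicitly: zero-detection runs return
I = 0; dc = 0 makes PI undefined (error, excluded downstream); a
calibration curve that is not strictly monotone is rejected; a fully
absorbed photon (mu_a = mu_t) terminates without roulette.

## Known limitations

* Absolute detected intensities inherit the uncertainty of the embedded
  property table; compare orders of magnitude, not digits.  The mirror
  enhancement ratio is particularly sensitive to tissue absorption (a more
  absorbing finger yields a smaller mirror gain).
* No Fresnel refraction or total internal reflection at the finger
  surface by default (the surround is a pure absorber/mirror); a real
  tissue–air–coating interface partially reflects even without a mirror,
  which raises absorbing-surround detection and lowers the relative
  mirror gain.
* Veins are excluded (randomly distributed across individuals), as in the
  reference geometry; no melanin sweeps across skin tones; no
  polarization, coherence, fluorescence or time-resolved transport.
* The gap between finger and ring electronics (a constant additive dc in
  real devices) is out of scope; simulated dc is tissue-derived only.
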