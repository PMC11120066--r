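---
title: "Methods: predicting external H*(10) around permanent I-125 implants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting external H*(10) around permanent I-125 implants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

After permanent low-dose-rate (LDR) prostate brachytherapy the patient
carries I-125 seeds for good, and the people around them — caregivers,
household members, the public — receive a small external dose.  Release
guidance caps the effective dose at 5 mSv/year for caregivers and
1 mSv/year for the public.  The operational quantity measured outside the
patient is the ambient dose equivalent rate H\*(10), and the practical
question is: given the implant's total air-kerma strength and the tissue
thickness between the prostate and the body surface, what H\*(10) rate
should a survey meter read at the surface, at 30 cm, and at 100 cm?

`brachysafe` models this with a normalized exponential attenuation curve
per detector distance,

$$\dot H^*(10)_{d} (z) \;=\; S_k \,\Lambda\, \mathrm{CF}\; A_d\, e^{-b_d z},$$

where $z$ is the water-equivalent thickness (WET, cm) from the implant
centre to the body surface, $S_k$ the total air-kerma strength (U),
$\Lambda$ the TG-43 dose-rate constant (cGy h⁻¹ U⁻¹, default 0.954),
CF the air-kerma→H\*(10) conversion factor (≈1.00 Sv/Gy at the I-125
effective energy of 27.4 keV), and $(A_d, b_d)$ fitted coefficients for
detector distance $d \in \{0, 30, 100\}$ cm.  The registry of published
coefficients is `paper_model_registry()`; users can refit their own with
the package's Monte Carlo engine.

The unit chain is fixed once: $S_k\Lambda$ is cGy/h; ×10⁴ µSv/cGy × CF
(Sv/Gy) gives µSv/h.  This is the only chain consistent with the model's
µSv/h outputs.  Note the model asserts the TG-43 1-cm dose-rate prefactor
against curves normalized at $z = 1$ cm and measured at external detector
positions; the package implements the equations as published and surfaces
this assumption here rather than re-deriving it.

## The Monte Carlo engine

The depth-dose curves come from a simplified analog photon transport in a
35 × 35 × 37 cm³ Mylar-window water phantom: an isotropic point source of
the bare five-line I-125 spectrum at depth $z$ (1–20 cm) behind the window
centre, a point detector in air on the source axis at 0/30/100 cm from the
surface.  Key numerical choices:

* **Next-event (expected-value) point-detector estimator** at the emission
  vertex and at every scatter vertex.  This is what makes 10⁵-history runs
  informative where an analog surface tally would need ~10⁹; it is
  unbiased for this geometry.
* **Cross-sections**: water and air photoelectric/incoherent/coherent
  linear coefficients on a 5–60 keV grid transcribed from standard
  compilations, log-log interpolated, no extrapolation (out-of-grid is an
  error — safety code should fail loudly).  The total is defined as the
  sum of partials.
* **Compton scattering** samples the free-electron Klein–Nishina
  distribution by rejection (the forward-peak envelope is efficient below
  ~100 keV); the scattered energy follows the Compton relation.
  **Rayleigh scattering** is kept in the cross-section but re-emitted
  isotropically — a documented approximation, toggleable
  (`include_rayleigh`).
* **Cutoff** 5 keV; at most 10 scatter orders (survival beyond that is
  negligible at ~28 keV in water).  The fluence→H\*(10) response is taken
  as zero below its 10 keV grid floor (the meter itself cuts off at
  15 keV).
* **Variance bound**: contributions from scatter vertices clamp the
  tally radius at 0.5 cm (an exclusion-sphere fix).  Without it the 1/r²
  estimator has unbounded second moment at the surface detector, where
  vertices can approach the detector point.  Primary (emission-vertex)
  contributions are never clamped, since the source sits at $z \ge 1$ cm.
* **Reproducibility**: every tally records its seed; the same seed gives
  bit-identical results; the caller's RNG state is restored.
* The Mylar window (0.254 mm), the plastic seed tube, the seed capsule
  and air attenuation over ≤ 100 cm are all neglected (each < 1% at
  28 keV).  Tallies whose relative SE exceeds 3% are *flagged*, never
  silently accepted.

`fit_exponential()` fits $A e^{-bz}$ by nonlinear least squares on the
linear scale, initialized from the log-linear regression, with R²
reported on the linear scale (the convention behind "R² of the
exponential fit"); tally SEs are not used as weights by default because
the published procedure gives no indication of weighting.
Normalization is per-series at $z = 1$ cm: evaluating the published
models at $z = 1$ gives 0.993, 1.006 and 1.011 — consistent with each
series being normalized to its own 1 cm value, so that is the default
(the reference depth is an argument).

### The near field, honestly

With a *point* detector exactly at the phantom surface, the 0 cm series
contains a $1/z^2$ geometric factor that no single exponential can
absorb: the linear-scale R² converges to ≈0.9986 as statistics increase
(it is shape-limited, not noise-limited), and the fitted surface decay
constant is ≈1.5 cm⁻¹.  The published surface coefficients
($b_0 = 0.5841$) imply the real survey meter's effective measurement
point sat well away from the phantom surface — plausible for a ~23 cm
instrument in contact with the phantom, but not quantified anywhere — and
we deliberately do not fix an effective-centre offset that would
reproduce the published value, because choosing it *to* reproduce the
value would be calibration toward the target.  Consequences: the 30 cm
and 100 cm fits reproduce the published decay constants within +7%
(0.379 vs 0.3555 and 0.348 vs 0.3273 cm⁻¹) with R² > 0.999, the ordering
$b_0 > b_{30} > b_{100}$ holds, but the 0 cm R² ≥ 0.999 acceptance
expectation fails and is left failing.  Predictions through
`predict_h10_rate()` default to the published registry, so this
limitation affects curve *regeneration*, not the assessment layer.

## The synthetic cohort: what it is and is not

`generate_cohort()` draws patients from truncated-at-zero normal
distributions with the published 21-patient moments — WET anterior
10.33 ± 1.42, posterior 10.41 ± 0.92, left 17.19 ± 1.51, right
17.24 ± 1.53 cm; total $S_k$ 35.15 ± 8.73 U — with no correlation between
directions or with $S_k$ (none is published; a correlation structure can
be supplied).  The measurement emulator adds the 0.20 µSv/h background,
2% multiplicative Gaussian noise (the meter's statistical-error rule) and
clips to the 50 nSv/h–10 Sv/h detector range; nine weekly phantom
sessions include I-125 decay (half-life 59.4 d, the standard TG-43 value
— configurable, since the source never states it).
`simulate_patient_measurements()` applies the predictive model plus a
configurable bias (default −10% at the surface, reflecting the reported
overprediction there due to the prostate's finite volume, zero farther
out) and noise.

A green end-to-end test therefore establishes *internal consistency* —
the pipeline's statistics recover the structure the generator put in — and
nothing about real patients: real WETs are measured with 1–2 mm error on
CT, real seeds are spatially distributed, and real detectors have volume.
The clinical comparison numbers (3.14 ± 0.44% etc.) depend on physical
measurements and are out of desk-scale reach by design.

## Statistics

Percent differences are signed, `100 (measured − calculated)/calculated`,
summarized per group as the mean and SD (n−1) of *absolute* differences
(the published "average difference" values are all positive with small
SDs, consistent with absolute summaries; signed summaries are reported
alongside, and both depth-wise and session-wise spreads can be computed).
The two-tailed Mann–Whitney U test is from scratch: midrank U; exact
p-values from the tie-free counting distribution (identical to full
enumeration) or, under ties, explicit enumeration of labelings; otherwise
a normal approximation with midrank tie correction and 0.5 continuity
correction.  The auto rule is exact for total n ≤ 12, so the n≈21
clinical-style comparisons use the approximation while small problems
stay exact.  Significance is declared at p < 0.05 with no
multiple-testing correction, matching the published analysis.  The exact
test's discreteness makes its true size at n = 12 + 12 equal 4.49%, which
is why the 5% ± 1% type-I calibration property is attainable.

## Safety assessment conventions

Cumulative dose integrates the decaying rate:
$D(T) = R_0 f\,(1 - e^{-\lambda T})/\lambda$ with
$f = \text{daily hours}/24 \times \text{occupancy}$, and
$D(\infty) = R_0 f\, T_{1/2} \cdot 24/\ln 2$.  The occupancy model is an
assessment convention, fully configurable.  Release limits are 5 mSv/year
(caregiver) and 1 mSv/year (public) with an *inclusive* boundary (a dose
exactly at the limit passes), flagged in reports.  The far-field shortcut
`far_field_rate()` — inverse square plus one halving per 2 cm WET — is
valid beyond roughly three times the prostate size, where the implant
acts as a point source at its centre of gravity.  Uncertainty components
combine in quadrature (`combine_quadrature()`; the published budget
{0.50, 6.90, 4.00}% gives 8.0%), and `consensus_lambda()` forms weighted
consensus dose-rate constants (equal weights over 0.954 and 0.938 give
0.946).

## Known limitations

* No seed anisotropy function, capsule filtration or electron transport;
  the bare five-line spectrum's mean is 28.37 keV, while 27.4 keV is the
  seed's conventional *effective* (filtered) energy — treated as a
  convention, not a reproduction target.
* The near-field (0 cm) curve regeneration limitation described above.
* Isotropic Rayleigh angles; conversion-coefficient band restricted to
  10–60 keV.
* Cohort directions are uncorrelated by default; WET measurement error
  (1–2 mm) is available only as an optional additive Gaussian
  (SD 1.5 mm) because its distribution is unpublished.
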