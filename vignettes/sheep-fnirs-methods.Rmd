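---
title: "Methods: multi-distance fNIRS analysis for freely moving sheep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-distance fNIRS analysis for freely moving sheep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ovifnirs)
```

## The measurement problem

Continuous-wave fNIRS measures changes in the optical density (OD) of tissue
at two near-infrared wavelengths and converts them into changes of oxy- and
deoxy-hemoglobin concentration. In sheep, the scalp-skull-CSF complex above
the cortex is about 10 mm thick, so a single long source-detector channel
mixes superficial (extra-cerebral) and cortical signals. The design this
package analyzes uses two channels per hemisphere — &rho; = 10 mm and
&rho; = 30 mm at 751 and 839 nm, sampled at 10 Hz — and separates the two
tissue compartments with a two-layer photon-diffusion model: a slab of
thickness *s* = 10 mm over a semi-infinite cortical layer.

The analysis chain is:

1. segment the recording into task blocks; the last 5 s before each block
   onset is the baseline; &Delta;OD(t) = OD(t) − mean(OD over baseline);
2. fit &Delta;OD at &rho; = 10 mm with a homogeneous semi-infinite model to
   estimate the upper-layer absorption change
   &Delta;&mu;<sub>a</sub><sup>UP</sup>(t) per wavelength (short-channel
   photons are assumed to travel only in extra-cerebral tissue — an
   assumption the Monte Carlo module quantifies: at &rho; = 10 mm about 2% of
   the detected pathlength lies below 10 mm depth);
3. fit &Delta;OD at &rho; = 30 mm with the two-layer model, holding the
   upper layer at the short-channel result, to estimate the lower-layer
   (cortical) change &Delta;&mu;<sub>a</sub><sup>DOWN</sup>(t);
4. convert the absolute coefficients &mu;<sub>a0</sub> + &Delta;&mu;<sub>a</sub>
   of both layers at both wavelengths into [O&#8322;Hb] and [HHb] with Beer's
   law, using extinction coefficients measured on adult sheep blood
   (751 nm: &epsilon;<sub>HHb</sub> = 1.672, &epsilon;<sub>O2Hb</sub> = 0.752;
   839 nm: &epsilon;<sub>HHb</sub> = 0.824, &epsilon;<sub>O2Hb</sub> = 1.084
   cm&#8315;&sup1; mM&#8315;&sup1;), then re-reference to the block baseline;
5. exclude blocks whose analysis window overlaps interfering behaviors
   (head shaking, chewing, running, jumping) from the video ethogram,
   stratify startle blocks into Move (flight) and Stand (freezing), and
   average per hemisphere and layer.

## Forward models and numerical conventions

All internal units are mm, mm&#8315;&sup1; and ns; concentrations are
reported in &mu;M; &Delta;OD is decadic.

**Diffusion coefficient.** The package uses the absorption-independent
convention D = 1/(3&mu;<sub>s</sub>&prime;). With it the time-resolved
solution depends on &mu;<sub>a</sub> only through exp(−&mu;<sub>a</sub>vt),
which makes three identities exact rather than approximate: the CW
reflectance is the time integral of the TR reflectance; multiplying a DTOF by
exp(+&mu;<sub>a</sub>vt) removes its absorption dependence; and the mean time
of flight equals −&part;lnR/&part;&mu;<sub>a</sub>/v, so the differential
pathlength factor DPF = v&lt;t&gt;/&rho; coincides with the modified
Beer-Lambert pathlength. In the regime of interest
(&mu;<sub>a</sub> &asymp; 0.01–0.02, &mu;<sub>s</sub>&prime; &asymp; 1
mm&#8315;&sup1;) the alternative D = 1/(3(&mu;<sub>a</sub>+&mu;<sub>s</sub>&prime;))
changes CW reflectance by under 1%.

**Boundary condition.** Extrapolated boundary at z = −z<sub>b</sub>,
z<sub>b</sub> = 2AD, with A computed by numerical integration of the angular
moments of the unpolarized Fresnel reflection coefficient
(A &asymp; 2.95 for n = 1.4 tissue against air; A = 1 matched). The isotropic
source sits at z<sub>0</sub> = 1/&mu;<sub>s</sub>&prime;; the alternative
1/(&mu;<sub>a</sub>+&mu;<sub>s</sub>&prime;) differs negligibly here.

**Two-layer solution.** Per spatial frequency q the 1-D two-point boundary
problem (continuity of fluence and flux at depth *s*, extrapolated boundary
at the surface, decay at infinity) is solved in closed form in an
overflow-safe scaled representation, and the surface flux is
inverse-Hankel-transformed with a fixed-node Gauss-Legendre rule on
[0, q<sub>max</sub>]. The q-space flux decays like exp(−q z<sub>0</sub>), so
the rule uses q<sub>max</sub> = 30&mu;<sub>s</sub>&prime; (truncated tail
&lt; 10&#8315;&sup1;&#8304; of the integral; at 10&mu;<sub>s</sub>&prime;
the truncation error would reach several percent at &rho; = 30 mm). Node
count is chosen by doubling until successive estimates agree to a relative
10&#8315;&#8310;, then frozen and cached for the geometry. A hot C++ kernel
evaluates the same formula vectorized over samples; the R implementation
remains the readable reference and the two are compared in the tests.

**Per-sample inversion.** Each time sample and wavelength is an independent
scalar least-squares problem (no temporal regularization, matching the
original analysis). A damped Newton (Levenberg-Marquardt) iteration on the
residual converges to |residual| &lt; 10&#8315;&#8312; OD in a handful of
steps because the forward models are smooth and monotone in the absorption
perturbation. Fits that would drive an absolute &mu;<sub>a</sub> below a
configurable floor (10&#8315;&#8310; mm&#8315;&sup1;) are clamped and
flagged, never dropped. Negative concentration *changes* are legitimate and
never clamped.

**Beer step.** The 2&times;2 system is solved exactly; the round trip
hemoglobin &rarr; &mu;<sub>a</sub> &rarr; hemoglobin is machine-precision.
The printed sheep extinction coefficients are applied directly to the
physical absorption coefficient (&mu;<sub>a</sub> = &epsilon;c). Whether the
tabulated values are natural or decadic coefficients is not stated in the
source; `mua_to_hemoglobin(scale = "decadic")` exposes the alternative,
which rescales all concentrations by ln 10 and nothing else.

## Monte Carlo validation

`run_mc()` is an independent oracle: weight-based photon transport in a
plane-layered medium with similarity-reduced scattering (isotropic at
&mu;<sub>s</sub>&prime;, g = 0 — sufficient for reflectance and pathlength
observables at these distances, and halving the parameter count), Fresnel
reflection/refraction at the surface, Russian roulette (threshold
10&#8315;&#8308;, survival 0.1), a 10&#8308; mm total-pathlength cap, and an
annular detector of &plusmn;1 mm half-width (the instrument aperture is not
specified; this is a documented stand-in). The RNG is an own xoshiro256++
stream seeded per run, so identical seeds give bitwise-identical tallies
regardless of platform threading.

The tests verify: energy accounting closes to numerical precision; CW
diffusion reflectance at &rho; = 30 mm agrees with a 10&#8310;-photon run
within 10% and 3 standard errors (observed &asymp; 0.3%); the detected mean
pathlength equals DPF&middot;&rho; within 10%; and in the layered sheep
medium photons detected at &rho; = 30 mm penetrate deeper than at
&rho; = 10 mm, with under 5% (observed &asymp; 2%) of the short-channel
pathlength in the cortical layer — the quantitative content of the
"short channel stays extra-cerebral" assumption.

## The synthetic world

`generate_cohort()` emulates the two experimental designs: a motor task
(10 blocks per sheep, 30 s walking / 30 s rest; analysis window 5 s baseline
+ 30 s walk + 5 s recovery) and a startle test (5 blocks, 30 s baseline, 3 s
umbrella opening, 60 s reaction). The planted physiology is:

* a cortical canonical hemodynamic response confined to the lower layer —
  difference of two gamma-variates, peak +1 &mu;M O&#8322;Hb and −0.3 &mu;M
  HHb, onset 1 s, time-to-peak 6 s, FWHM 6 s, undershoot fraction 0.2. The
  source figures give no amplitude scale for sheep, so these are
  order-of-magnitude fNIRS-typical values, exposed in `ground_truth()`;
* superficial systemics confined to the upper layer: a 0.1 Hz Mayer-type
  oscillation (default 0.2 &mu;M on O&#8322;Hb, a quarter of that mirrored
  on HHb) plus a slow drift (0.05 &mu;M/min);
* white Gaussian OD noise, default &sigma; = 10&#8315;&sup3; OD per sample
  (no noise figure is reported for the instrument; this is a typical CW
  system magnitude);
* behavior annotations driving the exclusions: planted chewing/head-shake
  intervals, flight and freezing intervals, and "frequent shaker" subjects
  (the subject-exclusion threshold is a configurable fraction, default 0.5 —
  no number is given in the source).

Generation always uses the full two-layer forward model at *both* distances,
while the analysis fits the short channel with the homogeneous model. The
short-channel approximation is therefore genuinely tested, not assumed: on a
noise-free cortical-only block the recovered cortical peak is biased about
−12% (the short channel picks up ~2% of the cortical change, and the
two-step subtraction amplifies that by the upper/lower pathlength ratio of
the long channel, &asymp;5.6). This bias is the method's, not the
implementation's; the end-to-end tolerance of 15% contains it.

**Noise amplification and the recovery metric.** The same pathlength-ratio
amplification applies to the short-channel noise, so at
&sigma; = 10&#8315;&sup3; OD the per-sample noise of the recovered cortical
concentration is several &mu;M. The maximum of a noisy group-average curve
is therefore a biased peak estimator. Parameter recovery is measured
instead with the GLM amplitude (`matched_amplitude()`): the least-squares
projection of the group-average curve onto the planted waveform — the
standard fNIRS amplitude estimate, unbiased under additive noise. A green
recovery test establishes that the pipeline recovers the planted cortical
amplitude within tolerance and keeps a signal-free extra-cerebral layer
near zero; it does not establish performance under motion artifacts,
colored physiological noise, or baseline-property misestimation, none of
which the generator emulates.

## Statistics

The significance procedure behind the original group results is not named in
the source. The package implements a documented stand-in: a one-sample
two-sided t-test across contributors (subjects for the motor task, retained
blocks for the startle test) of the window-averaged concentration change
against zero, with the window defaulting to the full task phase. Under the
null with Gaussian noise the test is exact; the acceptance suite checks the
type-I rate empirically and the power to detect a planted 1 &mu;M cortical
effect at n = 10. Degenerate inputs (zero variance across contributors) are
reported with a flag rather than an arbitrary p-value.

## Design choices on open points

* **Ethogram vocabulary** — the full table is in unavailable supplementary
  material; `ethogram_codes()` ships the behaviors named in the text and the
  vocabulary is config-extensible.
* **Baseline optical properties** — the per-wavelength
  &mu;<sub>a0</sub>/&mu;<sub>s0</sub>&prime; table is likewise unavailable;
  the defaults (0.015 and 1.0 mm&#8315;&sup1; at both wavelengths,
  `default_baseline()`) are placeholders in the physiological range and are
  plain configuration values.
* **&Delta;OD sign convention** — an OD increase means an intensity decrease
  (&Delta;OD = −&Delta;log&#8321;&#8320;I); absorption increases give
  positive &Delta;OD.
* **Per-wavelength fits** — the two wavelengths are inverted independently
  (the description treats &mu;<sub>a</sub> per wavelength); joint spectral
  fitting is a noted extension, not implemented.
* **Instrument response function** — `fit_dtof()` ignores it (its handling
  for the time-resolved spectrometer is not described); fitted
  &mu;<sub>a</sub>/&mu;<sub>s</sub>&prime; from measured DTOFs would inherit
  that approximation.
* **Half-open intervals** — all time windows and annotations are
  [start, end) in seconds, making overlap tests unambiguous; an annotation
  starting exactly at a window's end does not overlap it.
* **Configuration files** — JSON (the installed stack has no YAML reader);
  the schema is written by `write_cohort()` and read by `run_pipeline()`.

## Known limitations

Plane-layered geometry only (no curvature or MRI meshes); two layers (no
separate scalp/skull/CSF compartments); no motion-artifact correction beyond
behavioral exclusion, and no filtering or detrending, matching the original
analysis; water, lipid and collagen chromophores are disregarded; the slab
thickness *s* and the scattering coefficients are a-priori constants, never
fitted.
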