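---
title: "Cerebrovascular impedance from pulsatile flow and volume: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebrovascular impedance from pulsatile flow and volume: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvimp)
```

## The problem

Cerebral autoregulation (CA) holds cerebral blood flow (CBF) near-constant
over a range of cerebral perfusion pressures (CPP = ABP − ICP). Classically
the intact range is read off Lassen's curve — mean CBF versus CPP, flat
between the lower and upper limits of autoregulation (LLA, ULA). CA acts only
on slow pressure changes; at cardiac frequencies there is no vasomotor
response, so the ratio of pulsatile pressure to pulsatile flow at the cardiac
fundamental and first harmonic reflects the *cerebrovascular impedance* (CVI)
that the autoregulatory machinery has set. Inside the intact range,
vasoconstriction with rising CPP raises impedance; outside it, passive vessel
dilation (above the ULA) or partial collapse (below the LLA) lowers it. An
impedance-versus-CPP curve therefore rises between the limits and falls
outside them, and its breakpoints estimate the same limits as Lassen's curve.

`cvimp` implements this measurement chain for co-localized diffuse optical
recordings: a diffuse correlation spectroscopy (DCS) flow index for pulsatile
CBF, and near-infrared spectroscopy (NIRS) total-hemoglobin changes
(ΔHbT) as the pulsatile blood-volume — and, under a constant vascular elastic
modulus, pulsatile-pressure — surrogate.

## The impedance index

Within each 30 s analysis window (15 s overlap), flow `Q` and the pressure
surrogate `P` are mean-subtracted, high-pass filtered (cutoff 1.2 Hz), and
Fourier transformed. With the cardiac fundamental at `f0` and first harmonic
at `2 f0`, the window's impedance index is

    index = |P(f0)| / |Q(f0)| + |P(2 f0)| / |Q(2 f0)|

i.e. the magnitude of `Z(jw) = P(jw)/Q(jw)` summed over the two cardiac
peaks. Two variants are computed by the same code path: CBV-based
(`P = ΔHbT`) and CPP-based (`P = ΔCPP`, using the invasive pressures).
Per-window means of the *unfiltered* CPP, ABP, ICP and CBF channels are kept
alongside.

Windows are screened by a spectral SNR: the power at the fundamental (peak
±1 bin) divided by the total power in the bins strictly between the guarded
fundamental and harmonic (2 guard bins on each side). A window is accepted
only when both the `Q` and `P` SNRs are at least 3; exactly 3 is accepted
(the rule rejects strictly-less-than). We use the *total* in-between power in
the denominator rather than its per-bin mean: the fundamental is selected as
the band maximum, which biases a per-bin comparison high enough that
noise-only windows would typically survive a threshold of 3, whereas against
the whole in-between band's power a noise-only window scores ~0.1 and is
rejected.

Accepted windows are binned by mean CPP into half-open 3 mmHg bins anchored
at multiples of 3 ([3k, 3k+3)); bins with one or fewer windows are discarded.
Per subject, curves are normalized to the bin containing CPP = 65 mmHg
([63, 66)), then cohort-averaged per bin across subjects (unweighted mean,
cross-subject standard error; bins present in fewer than two subjects drop).
The same binning applied to window-mean CBF gives Lassen's curve.

## Limit estimation

The limits are estimated from a binned curve by an exhaustive search over
ordered breakpoint pairs, fitting a continuous three-segment piecewise-linear
model by least squares at each pair and keeping the SSE-minimizing pair that
satisfies the shape constraints: slopes (−, +, −) for impedance curves
("tent"), (+, 0, +) for Lassen curves ("plateau"). Candidate breakpoints lie
on a half-bin (1.5 mmHg) grid spanning the curve. The half-bin grid matters:
physiological limits typically sit at bin *edges* as often as centers, and a
center-only grid could never return, e.g., 60 mmHg on a [3k, 3k+3) grid. Each
segment must contain at least two bins for identifiability. This estimator is
an addition of the package — the in-vivo precedent read the limits off the
curve by eye — and its grid search is deliberately optimizer-free so it can
be checked against an independent exhaustive scan.

## DCS flow index

The flow index comes from fitting intensity autocorrelation curves
`g2(tau)` with the Siegert relation `g2 = 1 + beta |g1|^2`, where `g1` is the
semi-infinite extrapolated-boundary Green's-function solution of the
correlation-diffusion equation with Brownian dynamics: decay argument
`K(tau) = sqrt(3 mua musp' + 6 musp'^2 k0^2 alphaDb tau)`,
`k0 = 2 pi n / lambda`, image sources from `z0 = 1/musp'` and
`zb = 2(1+Reff)/(3 musp'(1−Reff))`, normalized so `g1(0) = 1`. Defaults
(config-overridable): `mua` 0.1 /cm, `musp'` 10 /cm, `n` 1.4, `Reff` 0.493,
wavelength 852 nm, source-detector distance 1.5 cm. The fit is bounded
nonlinear least squares on `alphaDb` (log-scaled, bounds 1e-12..1e-4 cm²/s)
and `beta` ((0, 1]), with residuals weighted per lag by an SNR curve
`SNR(tau) = (mean(g2) − 1) / sd(g2)` accumulated over the trailing 10 s of
curves (sample standard deviation; at thousands of curves the n−1 choice is
negligible). Initialization: `beta` from the short-lag intercept, `alphaDb`
from a coarse logarithmic scan.

A caveat we document because the package's own simulations expose it: the
benefit of SNR weighting depends on the noise structure. Against the
generator's additive Gaussian noise (sd `noise_scale × (1 + (g2−1))`, i.e.
nearly lag-independent), uniform weights are close to the generalized
least-squares optimum and the SNR-weighted fit carries a ~30–60% *larger*
mean-squared error in `alphaDb`, because weighting by signal-to-noise
suppresses the late-decay lags that carry most of the flow information. The
weighting earns its keep against the strongly lag-dependent instrument and
quantization noise of real photon-counting hardware, which an iid Gaussian
emulation does not reproduce. The acceptance suite measures this comparison
as specified rather than hiding it.

## NIRS volume

Two-wavelength intensities (685/852 nm) convert to absorption changes by the
modified Beer-Lambert law, `dmua = ln(I0/I)/(rho × DPF)` (natural-log
convention throughout; DPF defaults to 4.0 at both wavelengths), and then to
ΔHbO/ΔHb by solving the 2×2 extinction system per sample; ΔHbT = ΔHbO + ΔHb
holds identically. Extinction defaults are explicit numbers in the config
(derived from the standard compiled tabulation, converted to ln-based
1/(cm·µM)), so the package has no hidden data dependency. The extinction
matrix must have condition number < 100. An optional exponential
pressure–volume transform `dP = (exp(kappa·ΔHbT) − 1)/kappa` (kappa > 0,
default 0.1 /µM) models a stiffening vascular bed; it reduces to the linear
surrogate as ΔHbT → 0, and in synthetic sensitivity runs shifts the estimated
limits by less than one bin.

## Stream alignment

Pressure (100 Hz) and optical (500 Hz) streams are aligned through shared
sync pulses by a two-parameter clock model (offset + drift) fit by least
squares to the pulse-time pairs; fitted |drift − 1| > 1% is treated as pulse
mispairing and refused. Pressure is then linearly interpolated *up* to the
optical grid, restricted to the overlapping interval, never extrapolated.
Linear interpolation is deliberate: 30 s window means are insensitive to
interpolation order and linear kernels cannot ring. The residual cost is a
small sinc-type attenuation of cardiac amplitudes carried by the 100 Hz
pressure stream (~0.2% at 2.4 Hz, ~0.8% at 4.8 Hz), which touches only the
CPP-based index variant.

## The synthetic world

Because no recordings are deposited, every stage is validated against a
generator with known ground truth. The generator realizes exactly the model
the pipeline assumes:

* **Protocol** (`protocol_spec`): baseline, a vasopressor-like MAP staircase,
  return to baseline, then 5 mmHg ICP steps — the in-vivo protocol shape at
  desk scale. Defaults: baseline ABP 75 / ICP 10 mmHg (CPP 65, the
  normalization reference, so every subject dwells at it), 12 MAP steps of
  3 mmHg × 75 s, 3 ICP steps of 5 mmHg × 90 s, 90 s baselines (~22 simulated
  minutes per subject). The 3 mmHg MAP spacing is the desk-scale counterpart
  of the hours-long in-vivo staircases: it guarantees that every 3 mmHg
  analysis bin across CPP ≈ 45–100 mmHg collects at least two windows.
  Cardiac pulsatility rides on both channels (ABP amplitudes 4 / 1.6 mmHg at
  the fundamental/harmonic, ICP 1 / 0.4 mmHg) plus slow colored wander
  (low-passed white noise, sd 2 mmHg).
* **Hemodynamics** (`generate_hemodynamics`): with slow CPP extracted by
  low-pass filter, `CBF = F(CPP) + A1 sin(2π f0 t) + A2 sin(4π f0 t) + noise`
  and ΔHbT cardiac amplitudes `Z(CPP, k) × A_k` per harmonic, plus
  independent white noise and slow drift. Defaults: heart rate 2.4 Hz (an
  integer multiple of the 1/30 Hz window resolution, so exact-bin arithmetic
  is exact, and above the 1.2 Hz high-pass; NHP-plausible), flow amplitudes
  0.25 / 0.10 flow units on a plateau flow of 1, CBF noise sd 0.10, ΔHbT
  noise sd 0.05 µM, drift sd 0.02 µM, ΔHbT split 75%/25% into ΔHbO/ΔHb.
* **Truth** (`ground_truth`): tent impedance transfer (0.8 at the LLA rising
  to 1.4 at the ULA, falling at 0.03–0.04 /mmHg outside) with breakpoints
  LLA 60 / ULA 72 mmHg, and a Lassen plateau of the same breakpoints.
* **Forward optics** (`forward_dcs`, `forward_nirs`): the correlation-
  diffusion model plus additive Gaussian noise of sd
  `noise_scale × (1 + (g2 − 1))` per lag, and the Beer-Lambert exponential
  plus multiplicative Gaussian noise. For noisy-fit studies the DCS noise
  scale is fixed at 0.05 (per-lag sd 0.05–0.075 against a signal `beta` of
  0.5, i.e. per-lag SNR ≈ 7–10 — plausible for four-detector-averaged curves
  at a 500 Hz cadence).

Every generator is a pure function of (parameters, seed); the same seed
reproduces the same recording bit for bit.

What the generator does *not* emulate — and hence what passing tests do not
show about animal or patient data: realistic cardiac waveform shape beyond
two harmonics, heart-rate variability (optional wander is off in tests),
respiratory and Mayer-wave oscillations, pressure-waveform distortion between
the carotid and the microvasculature, photon-counting quantization noise, or
motion artifacts. Recovery of the limits to within one bin in ≥90% of seeded
replicates is a statement about the pipeline's correctness under its own
model, not about in-vivo accuracy.

## Numerical choices and degenerate inputs

* High-pass: 4th-order Butterworth applied forward–backward (zero phase), so
  window means and peak timing are unskewed; passband loss at 2.4 Hz is
  <0.5%. A lower-order design run both ways would lose ~6% at the
  fundamental.
* FFT windows are rectangular (no taper): the cardiac tones sit on exact bins
  in the synthetic world, amplitude bookkeeping stays exact, and peak *ratios*
  at matched bins are taper-insensitive.
* One-sided amplitudes are scaled so a unit sinusoid at an exact bin reads
  1.0.
* Peak search: fundamental = largest local maximum in 1.2–4.0 Hz (lower edge
  = the high-pass cutoff; upper edge covers NHP heart rates); harmonic =
  largest local maximum within ±3 bins of twice the fundamental (the band
  limit applies to the fundamental only). Peak indices are taken from the
  flow spectrum and reused for `P`, with the requirement that `P` has a local
  maximum within ±2 bins; failures mark the window rejected, never an error.
* `|Q|` below 1e-12 of the spectrum maximum at either peak rejects the window
  (impedance undefined).
* Zero-phase filtering of a finite record leaves small edge transients; the
  first and last analysis windows of a record can deviate at the 1e-4 level
  on otherwise exact-bin tones, while interior windows are clean to better
  than 1e-9. Exactness statements therefore apply to windows fully inside
  the record.
* Scale equivariance of the index (scaling `P` by `c` scales every index by
  `c`) is exact in floating point for dyadic `c` and holds to ~1e-9 relative
  otherwise, limited by rounding inside the recursive filter.
* Ties in the grid search resolve to the first-scanned (smallest) breakpoint
  pair; in practice SSE ties occur only on degenerate flat curves.
* All readers refuse NaN cells, non-uniform time grids (relative tolerance
  1e-6) and missing channels with named errors; writers emit 17 significant
  digits so numeric round trips are bit-identical.

## Problem sizes

The validation studies use three subjects of ~22 simulated minutes each at
500 Hz optical / 100 Hz pressure rates, 50 seeded replicates for limit
recovery, 200 seeds for the weighting comparison, and a 200×200 grid for the
fit-oracle check — sizes chosen so the full suite exercises every stage at
full sampling rates while remaining a desk-scale computation.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
study <- run_synthetic_study(n_subjects = 3, seed = 42)
study$limits_impedance[c("lla", "ula")]   # $lla 60, $ula 72
study$limits_lassen[c("lla", "ula")]      # $lla 60, $ula 72
head(study$impedance)                      # normalized cohort curve
```

## Known limitations

* Impedance phase is discarded; only magnitudes enter the index.
* The CPP-based variant inherits interpolation attenuation and, in real
  data, extra-cranial waveform distortion; the CBV-based variant is the
  primary quantity.
* Absolute impedance is out of reach: flow and volume are relative, so
  curves are only meaningful after the 65 mmHg normalization.
* The limit estimator assumes exactly one rising segment between two falling
  segments (or one plateau); pathologies that break the tent/plateau shape
  (e.g. absent autoregulation) yield a named error rather than a forced fit.
```
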