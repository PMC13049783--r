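---
title: "Methods: tracheal-sound estimation of the ventilatory threshold and peak oxygen uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracheal-sound estimation of the ventilatory threshold and peak oxygen uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cardiopulmonary exercise test (CPET) grades workload stepwise on a cycle
ergometer while gas exchange is measured breath by breath. Two indices matter
clinically: the ventilatory anaerobic threshold (AT) — the oxygen uptake at
which metabolism shifts from predominantly aerobic to anaerobic — and the
peak oxygen uptake (VO2peak). Both normally require a metabolic cart.
`cpetsound` estimates them from a much cheaper signal: tracheal breath
sounds recorded by a microphone at the suprasternal notch.

The physiological chain that makes this possible: above the AT, buffering of
lactic acid releases excess CO2, which drives a disproportionate rise in
minute ventilation (VE). Tracheal sound intensity tracks airflow
approximately linearly, so the breakpoint in VE appears as a breakpoint in
the sound-intensity trace. Locating that knee in time locates the AT.

## The acoustic pipeline

1. **Band-pass 100–3000 Hz.** The typical spectral range of normal tracheal
   respiratory sounds. The filter is an order-4 Butterworth applied
   zero-phase (forward–backward, as second-order sections), so breath-onset
   timing is not shifted. The effective gain is the squared magnitude
   response; it is essentially flat for content concentrated mid-band, where
   tracheal sounds live.
2. **Resample to 6000 Hz** by cubic-spline interpolation. The preceding
   band-pass acts as the anti-alias filter; tones inside the band are
   preserved to well under 1%.
3. **Ambient-noise suppression.** Short-time spectral suppression on a Hann
   STFT (50 ms frames, 75% overlap). The per-frequency noise floor is the
   10th percentile of spectral power over time, rescaled by
   $1/(-\log 0.9)$ — the exact percentile-to-mean factor for
   exponentially distributed noise power — so breath-free gaps calibrate the
   floor. Gains are $\sqrt{\max(1 - \alpha N/P,\ g_{\min}^2)}$ with
   oversubtraction $\alpha = 2$ and floor gain $g_{\min} = 0.05$; gains
   never exceed one, so no time–frequency cell gains energy. The signal is
   rebuilt by weighted overlap-add; the input is reflection-padded by one
   frame so the overlap-add normalization is well conditioned at the edges
   (without this, modified spectra explode at the boundaries where the Hann
   window vanishes). Reconstruction is exact to machine precision when the
   gains are unity.
4. **Spike removal.** Motion artifacts are sparse, high-amplitude and
   sub-second. The 100-ms RMS envelope is compared against a rolling robust
   threshold, median + 5·MAD over 2 s. Inside a breath burst the envelope is
   locally near-constant and the raw MAD can collapse to zero, so the MAD is
   floored at 0.3 of the rolling median; a genuine impulse at several times
   the local level still clears the threshold easily. Flagged runs are
   linearly interpolated; everything else passes through bit-identically.

## Breath segmentation and features

Phases are detected on the 50-ms log-power envelope with dual-threshold
hysteresis: open above baseline + 6 dB, close below baseline + 3 dB, where
the baseline is a rolling 20th percentile over 15 s. The rolling baseline
tracks the rising sound floor across exercise stages and makes detection
exactly invariant to global gain. Phases shorter than 150 ms are dropped and
gaps shorter than 100 ms merged. Tracheal audio shows two bursts per breath
(inspiration, expiration), so consecutive phases are paired into cycles;
each cycle runs onset-to-onset, which makes the instantaneous respiratory
rate robust to an occasional missed phase (parity flips shift which burst
anchors the cycle but barely change the onset-to-onset interval).

Per breath: sound **energy** is the sum of squared amplitude over the cycle;
**intensity** is energy over cycle duration (average acoustic power, the
quantity that tracks airflow); **respiratory rate** (RR) comes from
onset-to-onset intervals; **acoustic ventilation** is RR × intensity, the
acoustic analogue of minute ventilation. Energy and intensity are unitless
because the device gain is uncalibrated — every downstream statistic is
invariant to an affine rescaling of the features. Per-breath values are
smoothed with a centered 5-breath rolling median and interpolated onto a 1-s
grid labelled with protocol stages; grid points more than 5 s from any
breath are flagged missing rather than zero-filled.

## Threshold detection

The detector restricts the intensity (or energy) trace to the exercise phase
and fits a continuous two-segment model — two straight lines forced to meet
at the knee — by exhaustive search over every candidate grid point (3-point
margins). Exhaustive search is deterministic, trivially verifiable against a
brute-force oracle, and immune to local minima. A detection is declared only
when (a) the two-segment fit improves the residual sum of squares by at
least 20% over a single line, (b) the slope steepens at the knee
(ventilation accelerates at the threshold; it never slows), and (c) the knee
is at least 60 s from either end of the fitted span. Traces without a
distinct breakpoint therefore return "not detected" rather than a spurious
time — reproducing the failure mode in which early-exercise irregularities
mask the knee, which affects sound energy (whose trace also carries breath
duration) more than intensity.

The reference AT is automated from the gas exchange: VE/VO2 is smoothed with
a 7-breath rolling median and its global minimum (nadir) over the exercise
phase located; the exact breath is then refined to the raw minimum within 4
breaths of the smoothed nadir. The refinement matters: a median filter
applied to an asymmetric V-shape (the VE/VO2 nadir falls slowly and rises
fast) shifts the smoothed minimum several seconds toward the shallow side,
and taking the raw minimum nearby removes that bias while keeping the noise
robustness of the smoothed search. The candidate is accepted only where
VE/VCO2 is still flat or decreasing (local linear slope over 60 s at most
0.002 s⁻¹ — a small positive tolerance for breath noise); at the true AT
VE/VO2 has its nadir while VE/VCO2 is still falling, whereas both rising
indicates the respiratory compensation region. A nadir on the boundary of
the exercise phase is rejected as undetermined rather than reported.

Agreement between acoustic and reference AT is scored as in standard
practice: same protocol stage (workload agreement), signed time difference,
the |Δt| ≤ 20 s flag, and the relative error of the 10-s-averaged oxygen
uptake at the two times.

## Oxygen-uptake regression

The target is 1-s bin-mean-smoothed VO2 normalized by body mass (mL/kg/min).
Three predictor sets are predefined: *respiratory* (RR, energy, acoustic
ventilation), *respiratory + HR + workload*, and *all-acoustic* (the four
features). Backends: a regression random forest (500 trees by default, seed
recorded in the configuration) and ordinary least squares. Validation:

- **subject-specific**: the subject's rows are split into five *contiguous
  time blocks*; each block is predicted from the others. Contiguous blocks
  are the default because random row assignment would leak temporal
  autocorrelation between neighbouring seconds into training; a seeded
  random scheme is available.
- **subject-independent**: leave-one-subject-out (LOSO); no row of the
  held-out subject ever enters training. Leakage is asserted structurally in
  the tests (a held-out subject's distinctive target must be missed).

The predicted VO2peak is the maximum of the reassembled predicted trace; the
reference is the peak 10-s window mean of measured VO2 per kilogram.

## The synthetic CPET generator

No public recordings exist for this kind of data, so the package carries a
generator that encodes the physiology above with known ground truth, and the
whole pipeline is validated against it.

**Protocol.** 3-min unloaded warmup, five 2-min stages, 2-min recovery. The
per-stage increment is individualized with the standard sedentary capacity
formulas (unloaded VO2 = 150 + 6·weight mL/min; predicted peak
weight·(50.72 − 0.372·age) for men and (weight + 43)·(22.78 − 0.17·age) for
women; per-minute ramp = (peak − unloaded)/100 W), doubled for the 2-min
stages and rounded to 5 W. Every coefficient is exposed in configuration.

**Subjects.** 75% female; age ~ N(31, 9.1²) years in [18, 65]; BMI ~
N(23.5, 3.3²); heights by sex. The achieved peak is 0.83 × the predicted
sedentary capacity with lognormal scatter (σ = 0.18), clamped to a
physiologic 15–60 mL/kg/min. Tying the achieved peak to the demographics —
rather than drawing it independently — reflects how real capacity behaves
and is what gives heart rate and workload their predictive value in the
regression experiments; the 0.83 fraction represents the submaximal
termination at 85% of (220 − age) and calibrates the cohort to
27.1 ± 6.7 mL/kg/min. The true AT time is uniform in 45–70% of the duration
up to the end of exercise.

**Gas exchange.** VO2 rises linearly from the unloaded value to the peak
over the exercise ramp, holds a 20-s plateau at the peak (so the 10-s
averaged reference recovers the programmed peak exactly), then decays in
recovery. VCO2 follows VO2 with slope 0.95 below the AT and 1.40 above
(the V-slope geometry). VE = a + 26·VCO2 + c·(VO2 − VO2,AT)₊ with dead-space
intercept a = weight/12 L/min and a post-threshold ventilatory drive c
capped at 0.75·a·1.40/VCO2,AT — the cap is exactly what keeps VE/VCO2 still
decreasing at the AT while VE/VO2 has its nadir there, as the reference
method requires. Breath times integrate a linear RR ramp (12–16 to
28–38 breaths/min) with 2% interval jitter. Noise: a shared per-breath
multiplicative tidal-volume fluctuation (CV 5%) hits VE, VO2 and VCO2
jointly — it cancels in the ventilatory equivalents, which is why the nadir
stays identifiable at realistic breath-to-breath variability — plus 0.3%
independent channel noise for instrument error. Heart rate ramps from rest
to 85% of (220 − age) on its own 5-s base.

**Audio.** Two band-limited noise bursts per breath (inspiration at 2–40% of
the cycle, a softer expiration at 52–82%) with raised-cosine ramps, at the
device's native 15,277 Hz so the resampler is exercised. Each breath's
mean-square burst power is coupling × VE — the generator couples *power*,
not amplitude, to ventilation, because intensity (mean squared amplitude) is
the feature that must inherit the VE breakpoint linearly; coupling amplitude
to VE would square the trace and bias the fitted knee by tens of seconds
even without noise. Per-breath coupling scatter is 3% (power domain;
a documented guess — the real within-subject variability of the
intensity–flow coupling is unknown). The per-subject coupling constant has
10% lognormal spread: subject-independent regression from acoustic features
alone only works at all if acoustic feature scales are roughly comparable
across subjects, so the spread is kept modest; widening it is the natural
way to stress-test cross-subject transfer. Stationary ambient noise shaped to the
same band is added at a segmental SNR of 10 dB (mean in-burst signal power
over noise power), plus sparse 30-ms motion spikes at 2/min. The gas
generator's breath-level noise is treated as measurement-side and is not
propagated into the audio amplitude.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: realistic tracheal spectra (bursts are shaped
noise, not physiological sound), early-exercise hyperventilation and erratic
breathing, stage-transition ventilatory transients, cardiac sounds,
footfall-type non-stationary noise, sensor detachment, and any saturation of
the intensity–flow coupling (a saturating option exists for stress-testing).
Results on the simulator bound what the algorithms can do when their
assumptions hold; they do not certify field performance.

## Numerical choices and degenerate inputs

- Two-segment ties are broken toward the earliest candidate; the fit refuses
  fewer than 8 samples.
- The improvement ratio is defined as 0 when the single-line fit is already
  exact.
- PCM-16 WAV codec uses the symmetric scale i/32767 so write→read
  round-trips are bit-identical; multi-channel files reduce to the channel
  mean with a warning; loading rescales only when samples exceed [−1, 1].
- Stage intervals are half-open [start, end); warmup is stage 0, recovery
  the sentinel −1.
- The breath-cycle minimum duration is 1 s; an unpaired trailing phase is
  dropped.
- Empty 1-s VO2 bins are filled by linear interpolation; constant-envelope
  silence floors at −120 dB rather than −∞.

## Problem sizes in the test-suite and reproduction script

The cohort benchmarks run the full audio pipeline on 24 simulated subjects
(≈ 15-min recordings at 15,277 Hz each); the forest-versus-linear ordering
experiment uses ten seeded cohorts with feature-level simulation (the
idealized per-breath features the audio pipeline recovers under perfect
segmentation), which adds regression realism without re-rendering audio.
These sizes were chosen to keep a complete reproduction run on a single CPU
in the tens of minutes while leaving the statistical conclusions stable
across seeds.

## Known limitations

- The reference-AT automation replaces expert adjudication; its residual
  bias (a few seconds early, from the noisy argmin on an asymmetric V) is
  small compared with the 20-s agreement criterion but not zero.
- Detection near stage boundaries can disagree on workload even when the
  time error is small; with both estimates near the true AT this is a
  boundary-crossing coin flip, which is why workload agreement is reported
  over detected subjects.
- The breakpoint model assumes a single knee; tests terminated well past the
  respiratory compensation point would need a three-segment extension.
- Under the generator's linear within-subject VO2–workload law (the same
  assumption behind the individualized increment), ordinary least squares
  with workload among the predictors is already near-optimal, so the
  simulator provides no systematic advantage for the forest backend over
  the linear one in leave-one-subject-out validation; forest-versus-linear
  orderings observed on real cohorts may reflect nonlinearities (or
  sampling noise) that this generator deliberately does not invent.
- Ramp (continuously increasing) protocols are out of scope.
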