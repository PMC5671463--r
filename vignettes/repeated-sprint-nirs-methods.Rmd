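---
title: "Methods: muscle and cerebral NIRS analysis of repeated sprints to exhaustion"
author: "sprintnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle and cerebral NIRS analysis of repeated sprints to exhaustion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintnirs)
```

## The problem

Repeated-sprint-ability testing (RSAT) — 10-s all-out cycling sprints
separated by 20-s active recoveries, continued to volitional exhaustion or
task failure (cadence < 70 rpm) — stresses both peripheral (muscle) and
cerebral oxygen delivery, especially under normobaric hypoxia. Near-infrared
spectroscopy (NIRS) over the vastus lateralis and the prefrontal cortex
tracks oxy- and deoxyhemoglobin concentrations (O2Hb, HHb, in µM change) and
the tissue saturation index (TSI, %). The analytical questions are: how large
is the sprint-phase (de)oxygenation excursion, how does it evolve across a
set whose length differs between subjects and altitude conditions, and do the
excursions differ between conditions once between-subject variability is
accounted for?

`sprintnirs` implements the full chain: signal conditioning, automatic
sprint-phase segmentation referenced to muscle HHb, per-sprint
maximum−minimum delta (Δ) extraction, normalization of Δ profiles to percent
of set duration, per-session performance summaries, and linear mixed-model
inference. A seeded synthetic-session generator with known ground truth
closes the loop: every stage is validated against quantities the generator
can state in closed form.

## Signal conditioning

All NIRS channels are linearly resampled to a common 10 Hz analysis grid
(muscle optodes record natively at 10 Hz, cerebral at 50 Hz), then low-pass
filtered with a 4th-order Butterworth filter at a 0.2 Hz cutoff applied
forward and backward. The forward–backward pass squares the magnitude
response and cancels the phase, so sprint onsets are not delayed by
filtering; at the 85-rpm pedal-stroke frequency (85/60 ≈ 1.417 Hz) the
combined response is $(1 + (f/f_c)^8)^{-1} \approx 1.6\times 10^{-7}$, which
removes pedal artifacts entirely.

Edge handling is part of the contract, since an IIR filter run over a finite
record is otherwise implementation-defined: the series is extended by odd
(point-symmetric) reflection of $3(\mathrm{order}+1)$ samples at each end and
the filter state is initialized to its steady-state response to the first
padded sample. These are the conventions of the widely used
`scipy.signal.filtfilt` defaults, and `lowpass_zero_phase()` reproduces that
reference bit-for-bit, so processed traces are comparable across toolchains.
Two numerical consequences worth knowing:

* Residual energy near the record edges is dominated by the filter's edge
  transient, not by stopband leakage. Stopband attenuation should therefore
  be assessed on the steady-state interior of a record.
* The 0.2 Hz passband is narrower than the sprint-phase waveform's harmonic
  content, so filtering attenuates the realized per-sprint max−min by roughly
  10% — uniformly across sprints, channels and conditions. Relative
  comparisons (across conditions, across set duration) are unaffected; the
  delta-extraction arithmetic itself is validated on unfiltered noiseless
  channels where the generator's closed form applies exactly.

After filtering, the derived channels are computed with the standard NIRS
definitions: the hemoglobin difference Hbdiff = O2Hb − HHb (oxygenation
balance) and total hemoglobin tHb = O2Hb + HHb (regional blood volume).
Because the filter is linear, deriving before or after filtering is
equivalent; the resample → filter → derive order is fixed for
reproducibility. SpO2 is exempt from this chain: its only downstream use is
the session minimum, taken on the raw 5 Hz stream.

## Sprint-phase segmentation

Published descriptions of this protocol typically state only that sprint
start points are detected automatically with deoxyhemoglobin as the
reference signal, leaving the algorithm open. We use a two-stage detector on
the filtered muscle HHb:

1. **Candidate discovery.** Upward crossings of the first derivative over a
   robust threshold (3 × MAD of the derivative), separated by a 25-s
   refractory gap (less than one 30-s work:rest cycle). The MAD base makes
   the threshold insensitive to slow drift and to the proportion of the
   record spent in transients.
2. **Matched-filter refinement.** A zero-phase low-pass smears the
   deoxygenation onset symmetrically in time, so the raw crossing time is
   biased early by about half the filter rise time (≈ 0.6 s at these
   settings) — too coarse when onsets are scored at ±0.5 s. Each candidate is
   therefore refined by cross-correlating the local derivative with the
   derivative of a canonical sprint excursion (mono-exponential rise over the
   10-s sprint, time constant 2.5 s by default, passed through the same
   filter). The onset is placed at the best-scoring shift; candidates whose
   best correlation is below 0.5 — stretches that do not resemble a
   sprint-phase rise, such as edge transients — are dropped. Refinement
   requires the full template window (15 s of lead context) inside the
   record, which the 60-s protocol lead-in always provides.

If fewer than three onsets survive, the detector can fall back to the
protocol grid, phase-aligned by maximizing the summed template correlation
over one cycle; a featureless record aligns to the protocol lead-in. Each
segment spans `[onset, onset + 10 s]`, and the detected count defines the
number of sprints for every downstream stage. Cerebral channels reuse the
muscle-derived segments — one session clock, one event set.

On synthetic sessions with white noise at 10% of the sprint amplitude,
detection recovers the exact sprint count in 50/50 sessions with every onset
within 0.5 s of truth (maximum error ≈ 0.4 s); the template time constant
matters little because the correlation is normalized, but it is exposed
(`template_tau_s`) for tissues with slower kinetics.

Per-sprint deltas are max − min over the sprint window for each channel; the
window can be extended into recovery by `lag_s` for channels whose extremum
lags the sprint (default 0: the sprint phase only). Ties in the extrema
resolve to the earliest sample, which never affects the delta itself.

## Performance metrics

* per-sprint mean power: arithmetic mean of power samples in each (closed)
  sprint window, using the segmentation windows so the pipeline is
  single-sourced;
* percent decrement score
  $S_{dec} = \left[1 - \frac{\sum_k S_k}{S_{best}\, n}\right]\times 100$
  with $S_{best}$ the best scored sprint — 0 when all sprints equal the best,
  invariant to rescaling;
* total work: trapezoidal integral of power over the sprint windows (kJ);
* task failure: first sprint whose cadence dips below 70 rpm;
* highest 30-s oxygen uptake: maximum over all sample-anchored 30-s windows
  of the time-weighted (trapezoidal) mean, appropriate for irregular
  breath-by-breath data;
* SpO2 minimum of the raw 5 Hz stream; maximal heart rate; pre/post percent
  change for the femoral blood-flow pair;
* pacing check: both of the first two sprints must reach ≥ 95% of the best
  warm-up sprint, which is carried as session metadata — the scored-set best
  is used only inside $S_{dec}$.

One ambiguity is resolved here explicitly: "mean power" is the mean of the
per-sprint means (not the mean over all sprint samples). With equal-length
sprints the two agree; the choice is documented so that other implementations
can match it.

## Set-duration normalization

Sessions end at exhaustion, so sprint counts differ; profiles are compared
at 20, 40, 60, 80 and 100% of the set. For grid point $k$ of 5 the target
position on the 1-based sprint index is $x = kN/5$: integer positions take
that sprint's delta, fractional positions interpolate linearly between the
flanking sprints. This convention guarantees the 100% point is exactly the
final sprint, matching "duration of the set to exhaustion". The map is linear
in the delta vector and reproduces the raw deltas whenever $N$ is a multiple
of 5. Sessions with fewer than 5 sprints are rejected rather than
extrapolated (observed minima in this protocol are around 7); the generator's
default draw floor is therefore also 5.

`set_pct` is modeled as a 5-level categorical factor, not a continuous
covariate, because the discrete-point contrasts (e.g. "different from the
20% point") are the quantities of interest.

## Mixed-model inference

For each response (site × channel), the long table of normalized deltas is
fitted with

$$\Delta_{ijk} = \mu + \alpha_{condition(j)} + \beta_{set\_pct(k)}
  \,(+\, \gamma_{jk}) + b_i + \varepsilon_{ijk}, \qquad
  b_i \sim N(0, \sigma^2_{subject})$$

a random intercept per participant and categorical fixed effects, via
`lme4::lmer`. Displayed estimates come from the REML fit; each effect's
p-value comes from a likelihood-ratio test of maximum-likelihood refits with
and without the effect, referred to a chi-square with df equal to the
difference in fixed-effect parameters. When the interaction is requested,
its LRT compares the full against the additive model, and main-effect LRTs
are taken from the additive model. Singular fits (random-intercept variance
at the boundary) are flagged with a warning, never silently dropped.

Pairwise condition and set-duration contrasts are least-squares means from
`emmeans` with the Tukey adjustment, using Satterthwaite degrees of freedom —
the standard choice for `lmer` models in this toolchain; unadjusted p-values
are reported alongside so the adjustment is auditable. Random slopes are not
fitted: the design states a participant random intercept only.

Calibration, by simulation at the study's design size (11 subjects × 3
conditions): under a null with equal amplitudes across conditions (subject
SD 0.15, delta noise 1.5 µM), the condition-effect LRT rejects at
α = 0.05 in 4.8% of 500 cohorts; with the highest-altitude amplitude reduced
to 60% of sea level, power exceeds 0.99 over 200 cohorts. These checks run on
the delta-level cohort simulator (below), and their problem sizes — 500 null
and 200 alternative cohorts — were chosen as the smallest giving a
Monte-Carlo standard error comfortably inside the calibration band.

## The synthetic-data generator

`generate_session()` emulates the study's signal structure with known ground
truth:

* **Kinetics.** Within each sprint, HHb rises mono-exponentially toward the
  sprint's amplitude target (τ_deoxy = 2.5 s); within recovery it decays back
  (τ_reoxy = 3 s). These are typical sprint (de)oxygenation half-times; the
  mono-exponential shape is the simplest with a closed-form realized delta,
  $\Delta_k (1 - e^{-10/\tau})$, which is what makes oracle tests possible.
  After a 20-s recovery the residual excursion is ~0.1% of the amplitude, so
  the closed form holds to well under 1%.
* **Channels.** O2Hb and TSI mirror the HHb excursion with opposite sign,
  scaled by their amplitude ratios; Hbdiff/tHb then follow with amplitudes
  $(1+r)$ and $|1-r|$ times the HHb delta. Amplitudes are per-condition and
  per-site: muscle deltas are largest near sea level and decline more
  steeply across the set at altitude, cerebral deltas grow with hypoxia —
  the directions reported for this protocol, with magnitudes chosen once as
  field-realistic (muscle HHb ≈ 17–22 µM, cerebral ≈ 5–7 µM, TSI ≈ 14–20%).
* **Nuisance structure.** A pedal-stroke sinusoid (85/60 Hz) added only
  during sprint phases and riding on the excursion so it mirrors into every
  channel (cerebral probes see 30% of the amplitude); slow linear drift on
  the concentration channels (TSI, being ratiometric, is drift-free); white
  noise per channel; a multiplicative per-subject random intercept on
  amplitude shared across that subject's sessions.
* **Protocol streams.** Per-sprint mean power decays geometrically from the
  best sprint (2% per sprint by default, giving study-typical decrement
  scores in the low 20s); cadence stays above the 70-rpm threshold until the
  final sprint, where it ramps below it (task failure); SpO2 declines
  logistically to the condition floor at 5 Hz; heart rate rises toward the
  condition maximum; oxygen uptake is breath-by-breath with intervals
  shortening as breathing frequency rises. Sprint counts are drawn from
  rounded normals with the study's per-condition means and SDs, re-drawn
  below the floor.
* **Determinism.** Every draw descends from the params seed (sessions get
  derived sub-seeds), so identical inputs give bit-identical sessions and
  the full pipeline produces byte-identical output files across runs.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: motion-artifact spikes, optode displacement,
heterogeneous or state-dependent kinetics, autocorrelated physiological
noise, incomplete recoveries at short work:rest ratios, and any biophysical
(Beer–Lambert) forward model — concentrations are generated directly, with
the differential pathlength factors carried as metadata only. The detector's
template and the generator's kinetics share the mono-exponential family; on
real data the template time constant should be regarded as a tunable.

`simulate_delta_cohort()` draws per-sprint deltas from the same delta model
without synthesizing waveforms. It exists for Monte-Carlo studies of the
inference stage, where hundreds of cohorts are required and the waveform
layer — whose extraction accuracy is validated separately against the closed
form — would add nothing to the statistical question.

## Numerical choices and degenerate inputs

* Resampling refuses duplicate timestamps and series shorter than 2 samples;
  no extrapolation beyond the recorded range.
* The filter refuses cutoffs at or above Nyquist and series shorter than the
  padding; variance can only decrease for zero-mean inputs.
* A constant HHb series yields zero detections: an error without the
  fallback, the protocol grid with it.
* `normalize_profile` rejects sessions with fewer sprints than grid points.
* `fatigue_index` requires positive powers; `percent_change` a nonzero
  baseline; `rolling_peak` a span at least one window wide.
* Tie-breaks (equal extrema) resolve to the earliest sample; all output
  writers use fixed dialects (tab-separated, LF, `.` decimal) so reruns are
  byte-identical.

## Known limitations

* The delta attenuation of the 0.2 Hz filter (~10% at these kinetics) means
  absolute deltas are conservative; between-condition and along-set
  comparisons are unaffected.
* LRT p-values rely on the chi-square asymptotics; at 11 subjects the
  simulated type-I error is well inside [0.03, 0.07], but much smaller
  designs should be re-calibrated.
* The detector assumes the protocol's sprint duration when closing segments;
  protocols with variable sprint lengths would need per-segment end
  detection.
* Onsets within the template lead (15 s) of the record start cannot be
  refined and are dropped — irrelevant with the standard 60-s lead-in, but a
  constraint for truncated records.
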