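---
title: "From regular-interval noise to cluster statistics: the methods behind pitchonset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From regular-interval noise to cluster statistics: the methods behind pitchonset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchonset)
```

`pitchonset` implements an auditory-neuroscience analysis chain around one
question: does auditory cortex produce a distinct evoked response to the
*onset of pitch-evoking temporal regularity*, over and above responses to
sound energy and to regularity as such? This vignette documents the models
and procedures, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do not
establish.

## 1. Stimulus model

All stimuli live inside a 1–4 kHz passband so that no spectral energy
exists at the fundamental: any pitch percept at F0 must come from temporal
regularity (the "missing fundamental" regime). Three regular classes share
an F0:

* **Harmonic complex (HC).** Equal-amplitude cosine partials at n·F0 for
  all n·F0 ≤ fs/2, with Schroeder phases θₙ = s·π·n(n−1)/N (s = +1 by
  default). Schroeder phasing spreads the partials' peaks across the
  period; the package asserts only the consequence that matters — the
  crest factor is strictly below that of cosine phase — which holds for
  either sign of s. The phase convention is configurable
  (`schroeder_sign`).
* **Click train (CT).** Unit impulses of one sample (1/44100 s) at
  multiples of 1/F0, the first click at t = 0 of the regular segment. In
  RNR sequences the 20-ms onset ramp therefore attenuates the first click,
  so the earliest unattenuated regularity cue arrives one period later —
  50 ms at F0 = 20 Hz.
* **Regular-interval noise (RIN).** Iterated delay-and-add on fresh
  Gaussian noise. Two recursions are shipped because the procedure's
  naming in the literature is ambiguous: the default `cascade` variant
  applies y ← y + g·delay(y) to the running sum 16 times with g = 1; the
  `add_original` variant re-injects the base noise at each stage. Both
  create the autocorrelation peak at lag 1/F0 that carries the pitch, and
  no analysis here depends on which is chosen, so neither is asserted as
  canonical.

**Delay quantization.** The delay is `round(fs/F0)` samples: 176 samples
at 250 Hz/44.1 kHz (0.23% short of the true 176.4-sample period) and 2205
at 20 Hz (exact). Tests that look for periodicity at 1/F0 in *assembled*
sequences scan the integer lags adjacent to fs/F0, since the click train's
rounding spreads the autocorrelation peak over neighboring lags.

**Sequence assembly.** A trial is three contiguous segments
(0.5, 0.9, 0.9 s → 2300 ms), ordered noise–regular–noise (NRN) or
regular–noise–regular (RNR); all noise/RIN realizations derive from the
trial seed, so each of the 720 session trials is unique. Processing order
follows the synthesis chain: concatenate → bandpass (1–4 kHz, designed
order 4) → add masker → pink-shape → ramp. Butterworth filters are applied
forward–backward (`signal::filtfilt`), trading the stated design order for
zero phase — the magnitude response is the square of the designed one, and
group-delay artifacts at segment boundaries are avoided. Pink shaping is a
501-tap linear-phase FIR approximating a 1/√f magnitude (1/f power) by
frequency sampling, applied once with exact group-delay compensation; the
acceptance property is the measured log–log spectral slope (−1 ± 0.15 over
100 Hz–10 kHz), not any particular coefficient set.

**Masker level.** The masker (Gaussian noise bandpassed to 0.5–1.5·F0,
2nd-order Butterworth) exists to cover distortion products near F0. Its
absolute level is a free parameter; the default gain is 0.1 (−20 dB
relative to the unit-variance pre-filter signal). At unit gain the pink
shaping — which boosts the low-frequency masker band by roughly 10 dB
relative to the 1–4 kHz signal band — would let the masker dominate the
waveform and visibly dilute the very regularity the stimulus is built to
carry; −20 dB keeps the masker well above the distortion-product floor
while leaving the periodicity marker (windowed ACF at 1/F0) clearly
segment-specific. `masker_gain` exposes the choice.

**Output scale.** Sequences are normalized to RMS 0.05 full scale before
WAV export; presentation level is outside the model.

## 2. The synthetic MEG generator

No raw recordings ship with the package, so every downstream stage is
validated against `simulate_cohort()`, which plants known structure:

* **Component family.** Each evoked component is a Gaussian-windowed
  cosine (Gabor): amplitude × exp(−(t−μ)²/2σ²) × cos(2πf(t−μ)). This
  matches the morphology of transient evoked fields without claiming any
  specific functional form for real responses.
* **Default component table** (`default_component_table()`), qualitative
  by design: an energy-onset response (~100 ms, all conditions); an early
  regularity-onset response (~90 ms) for 20-Hz HC/CT only; a pitch-onset
  response (~140 ms) for 250-Hz conditions with RIN250 at 0.7× the HC/CT
  amplitude; a sustained response over the regular segment (absent for
  RIN20, whose transitions evoke nothing); a 20-Hz steady-state component
  for HC20/CT20 (stronger for CT), which is what makes the evoked
  autocorrelation peak at the 50-ms lag; and a small offset response.
  Amplitudes are stand-ins in arbitrary units — no quantitative
  per-condition amplitudes are assumed — and are the first thing a user should
  change to probe a different hypothesis.
* **Topographies.** Sensor maps are smooth random fields (low-order
  polynomial basis on a Fibonacci sphere). Within a subject, each
  component's map is √ρ·(shared map) + √(1−ρ)·(component-specific map)
  with `topo_overlap` ρ = 0.8. The overlap is essential, not cosmetic:
  evoked components of one subject arise from neighboring cortical
  patches, so their sensor maps overlap strongly, and that overlap is what
  lets a *single* DSS spatial filter capture all of them with a consistent
  sign. With independent maps (ρ = 0), DSS1 would project the pitch-onset
  component with a random sign per subject and the group-level frequency
  contrast would cancel.
* **Noise.** 1/f-shaped channel noise, drawn directly in the frequency
  domain (Hermitian complex-Gaussian spectrum × 1/√f, zero DC) for exact
  pink power. The scale `noise_sd = 0.26` was calibrated once so that the
  DSS1 evoked-to-total power ratio of a default cohort sits near 0.43,
  the generator's stated working point; it was not revisited afterwards.
* **Between-subject variability.** Log-normal amplitude scaling
  (`subject_amp_sd = 0.2`) and Gaussian latency jitter
  (`subject_lat_sd = 5` ms) per component.

**What the generator does not emulate.** Real MEG has ~300 sensors with a
physical forward model, correlated sensor noise, eye/heart artifacts,
head movement, and cortical sources whose geometry constrains topographies
— none of which are modeled. Passing tests therefore demonstrate that the
*inference chain* is correct and calibrated (it finds what was planted and
rejects at nominal rates when nothing is planted), not that real cortical
pitch responses behave like the defaults.

## 3. Preprocessing

Filters are Hamming-window linear-phase FIRs (`signal::fir1`) with length
set by the 3.3/Δf transition-bandwidth heuristic. Default transition
bandwidths: lowpass `max(min(0.25·fc, 10), 2)` Hz; highpass capped at the
cutoff (`min(max(0.25·fc, 2), fc)`) so that a 0.5-Hz highpass still nulls
DC — a 2-Hz transition band centered on a 0.5-Hz cutoff would leak half
the DC through, which is why the cap exists. One-pass filtering is made
zero-phase by compensating the integer group delay of the (even-order)
FIR with reflection padding; the notch is applied in two passes
(forward–backward), squaring its magnitude response.

Re-epoching is pure index slicing on the parent (stimulus-locked) epochs —
no interpolation — with half-open windows [t, t+Δ). Transition times
derive from the segment boundaries: NR at 0.5 s (NRN) or 1.4 s (RNR), RN
at the other boundary. Baseline correction subtracts the per-trial,
per-channel mean over [−250, 0) ms *before stimulus onset* and is applied
before transition re-epoching; there is deliberately no re-baselining
before transitions, so pre-transition differences between conditions
survive into the transition epochs (a property one test asserts
explicitly).

Resampling applies an anti-alias lowpass at 0.45·fs_new, then evaluates
the filtered signal on the new time grid (length `round(n·fs_new/fs)`,
`t0` preserved).

## 4. Denoising source separation

DSS seeks the channel weighting w maximizing the bias
λ = wᵀC_evoked w / wᵀC_total w, where C_total averages per-trial channel
covariances (each trial demeaned over time) and C_evoked is the covariance
of the trial average. The solution whitens C_total by eigendecomposition —
truncating eigenvalues below `rank_tolerance` (10⁻⁹) times the largest,
which keeps the problem well-posed after any rank-reducing preprocessing —
and eigendecomposes the whitened C_evoked. The generalized eigenvalues are
the bias scores (evoked-to-total power ratios, descending); filters are
orthonormal in the whitened metric, and patterns are the pseudo-inverse
field maps. On any full-rank instance the result matches a brute-force
generalized eigensolver to 10⁻⁸, and no random channel combination attains
a higher evoked ratio than DSS1 — both are tested.

DSS is fit per subject on trials pooled across all conditions (the
default; a per-condition mode exists). Pooling gives one spatial filter
per subject, which every condition's trials are projected through, so
condition contrasts downstream cannot be driven by condition-specific
filters. Component signs are arbitrary; each subject's DSS1 is flipped to
correlate non-negatively with a reference subject's component, with an
exactly-zero correlation left at +1.

## 5. Statistical inference

At every time sample (or vertex × time sample), condition means per
subject enter a classical within-subject ANOVA: F = MS_effect /
MS_(effect×subject), with effect projections built from commuting
per-factor averaging operators (valid for balanced, fully crossed
designs; missing cells are rejected). Degenerate samples with zero effect
variance are assigned F = 0. No sphericity correction is applied at this
stage: the sample-wise F only forms clusters, and the permutation null —
not the F distribution — calibrates the final p-values.

Clusters are maximal contiguous suprathreshold runs (temporal) or
connected components over mesh-edge-at-equal-time plus
same-vertex-at-adjacent-times adjacency (spatiotemporal; no adjacency
across meshes). The cluster statistic is the mass (sum of F), the
cluster-forming threshold the parametric p < 0.001 quantile. The null
distribution of the *maximum* cluster mass is built by shuffling condition
labels independently within each subject, synchronized across samples;
p-values use the add-one estimator, so they are bounded below by
1/(n_perm+1). Full within-subject shuffling is used for all effects,
including interactions — an approximate interaction null, since exact
restricted permutation for interactions is unresolved in the literature; a
`restricted` scheme (shuffling only the tested factor's levels within
strata of the remaining factors) is provided for comparison. Planned
contrasts are corrected by step-down Bonferroni–Holm (first-step threshold
α/m, e.g. 0.0167 for three contrasts at α = 0.05).

The permutation inner loop is compiled (Rcpp): each draw permutes
condition rows per subject, recomputes the effect's F time series and its
maximum cluster mass. The exchangeability of the null (distribution of
max mass invariant to the seed), the FWER calibration (rejection rate at
nominal 0.05 within the binomial 95% interval over 500 null cohorts) and
power monotonicity in planted amplitude are all tested.

`autocorr_peaks()` computes the normalized autocorrelation of an evoked
time course and reports local maxima near candidate lags with a
prominence relative to the median autocorrelation — used to show that
20-Hz (but not 250-Hz) regularity leaves a 50-ms periodicity in the
evoked response.

## 6. Problem sizes and numerical choices

The package's own test and calibration runs use desk-scale sizes chosen
once: cohorts of 19 subjects (the canonical sensor-level cohort), 8
sensors, 8 trials per condition at 600 Hz over [−250, 2550] ms epochs;
null calibration with 12 subjects × 2×3 design × 200 samples × 1000
permutations × 500 replicates; effect recovery over 100 simulated cohorts
with 500 permutations each. Canonical inference parameters (threshold
p < 0.001; 10,000 permutations) remain the documented defaults of
`cluster_permutation_test()`.

Other numerical conventions: seeds derive from a master seed via a seeded
integer draw (all below 2³¹); polarity ties break to +1; eigenvalue
clipping keeps bias scores in [0, 1]; covariances are computed over the
full epoch window (a sub-window is configurable); WAV export is 16-bit
PCM.

## 7. Known limitations

* Source modeling (head geometry, BEM, inverse operators) is out of
  scope; spatiotemporal statistics run on icosphere stand-ins for a
  cortical surface, carrying only adjacency.
* The generator's condition amplitudes are qualitative; effect sizes in
  power tests are statements about the defaults, not about cortex.
* The RM-ANOVA applies only to balanced fully crossed within-subject
  designs with one value per cell (condition means), by construction of
  the projection operators.
* Interaction permutation nulls are approximate (see above).
* The pink-shaping FIR leaves the first/last few hundred samples subject
  to boundary conditions (reflection padding); ramps make this moot for
  assembled stimuli.

## Session info

```{r}
sessionInfo()
```
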