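---
title: "Methods: respiration coupling, unison accuracy, and their statistical linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration coupling, unison accuracy, and their statistical linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choirsync)
```

`choirsync` implements a complete analysis chain relating interpersonal
respiration phase synchronization to intonation and timing accuracy in a
vocal ensemble, together with generative models that make the whole chain
testable under known ground truth. This vignette is the package's own
account of the methods: what each stage assumes, which parameters matter,
what the simulators do and do not emulate, and where genuinely open
design choices were resolved.

## The study design model

The unit of organisation is a recording session: voices (four, two
singers each singing in unison), musical pieces grouped into recording
units of at least six minutes, repeated performances of those units
arranged into blocks (3 + 2 + 3 = 8 in the default design), and three
spatial arrangements of the ensemble (modern, touch, no-touch). The
design object pins down every downstream row count:

```{r}
design <- default_design()
design
c(files = observation_count(design, "audio_file"),
  piece = observation_count(design, "piece"),
  unit  = observation_count(design, "recording_unit"),
  block_voice = observation_count(design, "block_voice_mean"),
  resp_grid   = observation_count(design, "respiration_grid"))
```

Two representational choices deserve note. A piece in which a voice does
not sing (the two-voice Agnus II) is simply a zero repeat count; no
counting rule special-cases it. And where a piece's per-condition repeats
do not divide evenly over its unit's blocks (Agnus III: 4 repeats over 3
Agnus blocks), repeats are assigned round-robin (2/1/1). The printed
column sums (31/25/25/31) are invariant to this allocation; only the
within-block composition depends on it, and no computed quantity is
sensitive to that beyond sampling noise. The Latin-square ordering of
conditions within blocks is deliberately not modelled: no computed
quantity depends on serial order.

## Simulating respiration: coupled noisy phase oscillators

Respiration is emulated, not modelled mechanistically. Each singer *i* is
a phase oscillator

$$\dot\varphi_i = 2\pi f_i(t) + \sum_{j\ne i} K_{ij}\,
  \sin(\varphi_j - \varphi_i) + \sigma_\varphi\,\xi_i(t),$$

integrated by fixed-step Euler–Maruyama at the sampling rate, with signal
$s_i(t) = \sin\varphi_i(t)$ plus white amplitude noise. The contract of
this generator is *controllable pairwise phase coupling inside the
analysis band* — nothing more. Defaults, chosen once as a realistic
emulation of quiet singing-adjacent breathing:

| parameter | default | rationale |
|---|---|---|
| base rate mean ± SD | 0.25 ± 0.03 Hz | centre of adult breathing range, inter-individual spread |
| sampling rate | 10 Hz | ≫ 2 × 0.40 Hz band edge; keeps wavelet runs fast |
| coupling κ (scalar) | 0.3 rad/s | moderate coupling, above chance but far from locking |
| phase noise | 0.15 rad/√s | keeps uncoupled pairs drifting through all phase lags |
| slow modulation | ±0.02 Hz at 0.01 Hz | breathing-rate wander within a trial |
| trial duration | 420 s (pipeline: 380 s) | exceeds the 360-s clip window |

A scalar κ is divided by (n − 1) so it is each oscillator's *total* pull;
a full matrix `K` allows per-pair structure. With κ = 0 and distinct
rates, downstream ACI sits at its chance level 0.25; with κ = 1 rad/s and
equal rates, pairs lock and ACI exceeds 0.9; in between, mean ACI is
monotone in κ. Those three facts are the generator's test contract.

What the generator does *not* emulate: respiratory waveform shape
(inhalation/exhalation asymmetry), phrase-locked inhalation imposed by the
music, apnoea during long phrases, movement artefacts, or belt-gain
drift beyond a linear trend. Passing tests therefore show that the
*analysis* behaves correctly on signals whose coupling is known — not
that real choir breathing is a Kuramoto system.

## Simulating unison performance

Two singers render the same score line. The onset of note *k* for singer
*s* is

$$t_{sk} = \text{beat}_k/\text{tempo} + w_k + \varepsilon_{sk},\qquad
  \varepsilon_{sk}\sim N(0, \sigma_t^2),$$

where $w_k$ is a smooth random walk *shared by the pair* — expressive
timing is a property of the interpretation, so it must not contribute to
between-singer differences, mirroring the rationale for measuring
deviations between singers rather than from the score. Pitch in cents
adds independent jitter $N(0, \sigma_c^2)$, a linear drift slope, and a
constant offset per singer; rare gross errors substitute the pitch by
1–2 semitones or displace the onset by 0.35–0.60 s, and notes can be
omitted.

Defaults target the accuracy of a professional ensemble:
$\sigma_t = 46$ ms and $\sigma_c = 14.5$ cents make the expected absolute
between-singer differences $2\sigma/\sqrt{\pi}$ come out near 52 ms and
16.4 cents. Gross error rates (1% pitch, 0.6% onset) produce overall
removal fractions near the ~1.6% annotation studies report. The default
score is a deterministic diatonic pseudo-score with 96 notes per voice
per piece, so a full default-design study contains ~64,500 tone events
across its 672 streams — the annotation volume such a session actually
yields. Piece durations are free parameters (the source design gives
none); the bundled compact score (`extdata/score_default.csv`) documents
the file format at 8 events per piece.

## Wavelet phases and the coupling indices

Phases come from an analytic Morlet continuous wavelet transform,
$\hat\psi(s\omega) \propto e^{-(s\omega-\omega_0)^2/2}$ for
$\omega > 0$, computed by FFT, with $\omega_0 = 6$ (the common
compromise between time and frequency resolution) and scales set so the
wavelet's Fourier period matches each component frequency. Ten components
span 0.025–0.40 Hz. Component spacing is logarithmic by default — the
band spans more than a decade, and log spacing gives each octave equal
representation — with linear spacing available; the choice is
configurable precisely because it is not dictated by anything deeper.

Numerical conventions, stated once and used everywhere:

- Traces are linearly detrended and z-scored per trial before the
  transform. Belt offset and gain are arbitrary, and all indices are
  phase-based, so this is information-preserving.
- Samples closer to a series edge than the wavelet e-folding time
  $\sqrt{2}s$ are masked (cone of influence) and excluded from every
  index. An index on an entirely-masked series is an error, not a
  silent NaN.
- Phase differences are wrapped to $(-\pi, \pi]$ via `atan2`, so
  $\Delta\varphi_{ab} = -\Delta\varphi_{ba}$ pointwise away from the
  $\pm\pi$ cut.
- ACI counts $|\Delta\varphi| \le \pi/4$ (closed interval); ICI counts
  $\Delta\varphi \in (0, +\pi/4]$ (half-open, so a pair sitting exactly
  at zero lag contributes to neither direction). Under uniform phase
  differences the expectations are exactly 1/4 and 1/8.
- PSI is the circular mean resultant length. The literature the index
  names descend from defines PSI and ICI only by reference; the mean
  resultant length is the canonical circular-statistics measure with the
  described behaviour ("takes into account more data with larger phase
  differences"), and the positive-window fraction is the minimal
  asymmetric companion of the ACI. Both sit behind plain one-argument
  functions (`psi()`, `ici()`) so alternative definitions can be swapped
  in without touching any caller.

Aggregation follows the each-singer-to-all-others rationale: a singer's
coupling is the mean over their seven partners and the selected
components; a voice's coupling is the mean of its two singers. Band
splits (very low < 0.04 Hz, low 0.04–0.15 Hz, high 0.15–0.40 Hz) follow
the autonomic-frequency convention, with membership by component centre
frequency.

## The accuracy cascade

The stage order is fixed: score linking → gross-error removal →
pitch-drift regression → pair matching → pair filters → aggregation.

*Gross errors.* A note at least one semitone from its score target, or
more than 300 ms from its reference onset, is a production error, not an
inaccuracy, and is removed before anything else. The pitch rule is
anchored by the score; the onset rule needs a performance-time anchor the
source procedure leaves unstated. The default anchor is the median onset
of that score event across the singers of the recording — robust and
score-timeline-free, but with only two singers sharing an event index it
is their midpoint, which absorbs half of a unilateral displacement. A
score-anchored alternative (per-recording OLS beat→time map, or an
explicit tempo) is provided and is the right choice when a reliable
tempo exists; tests exercising the 300-ms boundary use it.

*Drift removal.* Within each singer × recording, pitch deviation is
regressed on onset time (OLS) and replaced by its residual. The grouping
is per singer — the source says only that a linear regression removed
drift — which means constant between-singer offsets are absorbed:
**MAPE measures dispersion, not bias**. This is logged prominently
because it changes the interpretation of small MAPE values. Detrending
is applied exactly once (a processing flag makes re-detrending an
error); groups too short to estimate a slope (< 3 events) are centred
only, and a group with all-equal onsets is a hard error.

*Pair filters.* Matched pairs (equal score event, both singers
surviving) pass two independent screens: residual pitch gaps
> 2.5 semitones leave the intonation set (this is how temporary
score-prescribed voice splits are handled — by the filter, not by
score-aware logic), and onset gaps > 300 ms leave the timing set. The
1.5·IQR outlier diagnostic on onset gaps is computed and reported but
deliberately not used as a filter.

*Records.* MAPE is reported in cents; the negative logs use
fractional-MIDI units (LMAPE) and seconds (LMOE) inside the natural log.
The unit choice shifts L-values by an additive constant that model
intercepts absorb; it is configurable in effect because the raw MAPE/MOE
columns are always carried alongside. Zero-error or empty groups yield
flagged `NA` L-values and are excluded downstream with a logged warning.

## Statistical layer

The paired t-test compares touch vs no-touch on block × voice means (32
pairs in the default design; df = n − 1), with Cohen's d for paired data
(mean difference over SD of differences) and a 95% CI from the standard
normal-approximation standard error $\sqrt{1/n + d^2/2n}$ — the d-CI
method is unstated in the sources, so the conventional approximation is
used and documented here. All-zero differences return t = 0, d = 0 by
definition; constant non-zero differences are a degeneracy error.

The condition contrast is coded ±0.5 (first listed condition positive),
so the beta is directly the condition difference, in the random-effects
structure `(1|voice) + (1|piece)`. Mixed models report Satterthwaite
p-values alongside the |t| > 2 convention.

Coupling-prediction models start from the stated maximal-feasible
structures (random slopes for block and condition with timing; for voice
and block with intonation) and reduce backwards: at each step every
one-step simplification (slope → intercept, intercept → removed) is
fitted by ML, and the candidate with the largest likelihood-ratio p is
accepted while p > 0.05 — the conventional retention threshold, fixed
here since the sources cite the procedure without a number. Singular or
non-convergent fits are recorded and force further reduction rather than
entering model selection; the selected structure is refitted by REML for
reporting. A grouping factor with fewer than two levels cannot carry a
random effect and is dropped from the start structure. The full trace
(formula, parameter count, log-likelihood, LRT p, acceptance) is part of
every result.

## Calibration and problem sizes

The package's quantitative contracts are verified by its test suite at
sizes chosen to estimate each quantity precisely while staying
seconds-to-minutes fast; these sizes are the package's own choices:

- analytic nulls at $n = 10^5$ uniform phase differences, asserted
  within three Monte-Carlo standard errors;
- accuracy closed forms on 4,000–6,000-note unison streams, within
  three standard errors;
- slope recovery and shuffled-coupling nulls over 100 simulated
  96-row studies (≥ 90% CI coverage; ≤ 10% null rejections);
- full null-pipeline type-I calibration over 200 replicate tiny
  studies (rejection rates inside the binomial 95% band around 5%)
  using a two-voice, two-block design with 12-note pieces;
- κ-monotonicity over a five-point grid with 30 seeds per point
  (Spearman ρ > 0.9), on 240-s two-oscillator runs analysed over
  0.10–0.40 Hz so the cone of influence leaves ample samples.

## Known limitations

- The oscillator model produces stationary coupling; real ensembles
  switch between coupled and decoupled states within a trial, and the
  indices average over that dynamics.
- MAPE's drift-removal grouping absorbs constant between-singer offsets
  (dispersion, not bias; see above).
- The ensemble-median onset anchor under-detects unilateral gross onset
  displacements in two-singer recordings; prefer the score anchor when a
  tempo map exists.
- PSI and ICI are documented local definitions behind a swappable
  interface, not re-derivations of reference implementations.
- Vibrato is not modelled (appropriate for the repertoire emulated, a
  limitation for most others), and f0 extraction from audio is out of
  scope entirely: the package starts from annotated note events.
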