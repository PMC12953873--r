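# choirsync

Does synchronized breathing make an ensemble sing better? `choirsync` is an
R package for analysing that question in vocal-ensemble hyperscanning
studies, where respiration is belt-recorded from every singer while the
performance is captured and annotated note by note. It implements the full
analysis chain for a session of the kind studied in professional
Renaissance-polyphony ensembles — eight singers in four voices, two singers
per voice in unison, three spatial arrangements on stage (modern, touch,
no-touch) — together with simulators that generate fully synthetic studies,
so every stage can be exercised and calibrated without any recordings.

The package is aimed at researchers in music psychology and
psychophysiology who want a tested, reusable implementation of these
measures, and at methodologists who want to study their sampling behaviour
under known ground truth.

## What it computes

**Respiration phase coupling.** Each trace is clipped to a common window
(360 s), detrended, standardized, and transformed with an analytic Morlet
continuous wavelet transform (ω₀ = 6) over ten log-spaced components in
0.025–0.40 Hz. For every singer pair and component, the wrapped phase
difference Δφ(t) (cone-of-influence masked) feeds three indices:

- **ACI** (absolute coupling index): the fraction of points with
  |Δφ| ≤ π/4. Chance level under independent phases is 1/4.
- **PSI** (phase synchronization index): the circular mean resultant
  length |⟨e^{iΔφ}⟩|, which unlike the ACI is pulled down smoothly by
  large phase differences. Uniform-phase expectation ≈ n^{−1/2}.
- **ICI** (integrative coupling index): the directional companion,
  counting points with Δφ ∈ (0, π/4] only. Chance level 1/8.

Pairwise values aggregate to singer means (each singer against all seven
partners), voice means (the two unison singers), and autonomic frequency
bands (very low < 0.04 Hz, low 0.04–0.15 Hz, high 0.15–0.40 Hz).

**Singing accuracy.** Annotated note events (onset, duration, f0) are
linked to a digital score, converted to fractional MIDI (a′ = 440 Hz =
MIDI 69), screened for gross errors (≥ 1 semitone from the score, or
> 300 ms from the event's reference onset), residualized against a
per-singer linear pitch-drift regression, and matched into unison pairs by
score event. After independent pair filters (> 2.5 semitones for
intonation; > 300 ms for timing), each piece repeat × voice × condition
yields

- **MAPE** — mean absolute pitch error between the two singers, in cents,
- **MOE** — mean absolute onset error, in seconds,

and their negative logs **LMAPE**/**LMOE** (higher = more accurate).

**Statistics.** Paired t-tests with Cohen's d on block × voice means
(touch vs no-touch), mixed-effects condition contrasts
`accuracy ~ condition + (1|voice) + (1|piece)`, and mixed-effects
prediction of accuracy from coupling, starting from
`LMOE ~ ACI + (1|voice) + (1 + ACI|block) + (1 + ACI|condition)` (timing)
or `LMAPE ~ ACI + (1 + ACI|voice) + (1 + ACI|block) + (1|condition)`
(intonation) and reducing the random-effects structure by likelihood-ratio
tests (lme4/lmerTest, Satterthwaite p-values, the |t| > 2 convention also
reported).

**Simulators.** Respiration ensembles are noisy Kuramoto phase oscillators
with tunable pairwise coupling κ; unison performances add shared
expressive timing plus independent onset jitter, cents-scale pitch jitter,
linear drift, and rare gross errors to a score rendering. Both are
deterministic under a seed, and the analysis provably recovers their
parameters (E[MAPE] = 2σ_c/√π, E[MOE] = 2σ_t/√π; mean ACI monotone
in κ).

## Worked example

```r
library(choirsync)

design <- default_design()
observation_count(design, "piece")        # 336
nrow(enumerate_recordings(design))        # 672

res <- run_pipeline(pipeline_config(seed = 1))

res$manifest$row_counts$notes             # 64512 tone events
round(mean(res$piece_table$MOE) * 1000, 1)   # 51.8  (ms onset difference)
round(mean(res$piece_table$MAPE), 1)         # 16.3  (cents pitch difference)

res$ttests$timing$df                      # 31
round(res$index_correlations$r, 2)        # 0.71 0.86 0.61 (ACI-PSI, ACI-ICI, PSI-ICI)
subset(res$prediction_table, model == "aci_timing",
       select = c(formula, beta, t, p))
```

The run simulates the full default design (24 trials of 8 respiration
traces, 672 note streams), computes coupling and accuracy, and fits all
models; with the default generator settings the synthetic ensemble sings
with ~52 ms onset and ~16 cents pitch differences between unison partners
— the accuracy scale of a professional ensemble — and the coupling
indices correlate strongly with each other across the 640-point
trial × singer × frequency grid. Because the default world injects no
condition effect and no coupling→accuracy link, the t-tests, contrasts
and prediction slopes hover around null, as they should.

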