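---
title: "Topographic permutation statistics for ERP data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topographic permutation statistics for ERP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erptopo)
```

## The problem

Event-related potentials (ERPs) are multichannel scalp voltage time series
averaged over trials. Comparing conditions electrode by electrode and
timepoint by timepoint invites two problems: an arbitrary choice of
electrodes, and a massive multiple-comparison burden. Topographic analysis
of variance (TANOVA) addresses the first by collapsing the whole scalp map
into a single dissimilarity measure per timepoint; global duration
statistics (GDS) address the second by requiring significant effects to
persist for longer than chance runs do.

`erptopo` implements this stack for within-subject factorial designs — in
particular the cued repetition-probability paradigm, in which the
subcategory of a first stimulus (S1) signals whether the second stimulus
(S2) is likely to repeat it, crossing *repetition* (repeated vs. alternated)
with *expectation* (expected vs. unexpected) within subjects, across
several stimulus categories. Because real recordings are large and
licence-bound, the package ships a fully seeded synthetic generator for
this design, so every statistical stage can be tested against ground truth.

## Statistics

**Global field power (GFP).** For a scalp map $v$ over $C$ channels,
$\mathrm{GFP}(v) = \sqrt{\tfrac1C \sum_i (v_i - \bar v)^2}$ — the standard
deviation of voltage across the scalp, a reference-free amplitude measure.

**Global dissimilarity index (GDI).** For two maps $a, b$,
$\mathrm{GDI}(a,b) = \sqrt{\tfrac1C \sum_i (a_i - b_i)^2}$. Under the
average reference this equals the GFP of the difference map, an identity
the test suite asserts on random re-referenced maps.

**Pointwise TANOVA.** At each timepoint the observed statistic is the GDI
between the grand-mean marginal maps of the tested factor; for the
interaction it is the RMS across channels of the grand-mean
double-difference map (any positive scaling of that statistic is
permutation-invariant, so the p-value does not depend on the convention).
The null model randomly reassigns, within each subject, that subject's
condition maps to the design cells (uniformly over all cell permutations),
matching the exchangeability assumption of a within-subject design. The
p-value estimator is $(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{perm})$:
ties count as exceedances and p is never exactly zero. The default
full-cell reassignment tests each effect under the global null; a
`restricted` scheme that permutes only the tested factor within levels of
the other factor is available for main effects when other effects are
known to be present.

**GDS correction.** Every permutation's statistic series is re-ranked
within the permutation distribution at its timepoint, yielding a null
ensemble of p-value series with no new resampling. The duration threshold
is the 95th percentile (ceiling-rank quantile, since run lengths are small
tied integers) of the per-permutation maximum run length of $p < \alpha$;
an observed run of consecutive sub-$\alpha$ samples survives only if
strictly longer. Runs are broken by any single sample at or above
$\alpha$ — no gap bridging. When re-ranking a permutation we count
exceedances among the *other* permutations (plus one, in the numerator and
denominator); a column of totally tied statistics therefore yields
$p = n/(n+1)$ rather than exactly 1, which is immaterial at any practical
$\alpha$.

**GFP normalization.** Pure topography contrasts divide each map by its
GFP first, removing amplitude differences; the factorial TANOVAs run on
raw (non-normalized) maps, normalization being reserved for the dedicated
topography comparisons (window-mean difference-map contrasts and
early-versus-late interval tests), mirroring standard practice.

**Effect sizes.** Two are reported. (1) A variance-partition partial
$\eta^2$: with $c_s$ the window-mean contrast map of subject $s$ and $g$
their grand mean, $SS_\text{effect} = N \sum_i g_i^2$,
$SS_\text{error} = \sum_s \sum_i (c_{s,i} - g_i)^2$, and
$\eta^2 = SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$ — the
one-sample ANOVA partition of the subject contrast maps. It converts to
Cohen's d by the deterministic relation $d = 2\sqrt{\eta^2/(1-\eta^2)}$,
rounded to two decimals for reporting. (2) A permutation z-score over a
window — the observed window-mean statistic standardized against the
permutation distribution of window means — divided by
$\sqrt{p_1 p_2 N}$ with the condition proportions $p_1, p_2$. Both appear
in the pipeline's effect-size tables; the deterministic conversion is the
primary report because it is exactly reproducible, while the z-based value
inherits Monte-Carlo noise. In the degenerate zero-residual limit
($\eta^2 = 1$, possible only in noise-free simulation) the conversion is
undefined and the report shows `Inf`.

## The synthetic generator

`design_spec()` + `build_full_design()` build the trial structure with
*exact* cell counts — with the defaults (480 trials per category, cues
equiprobable, repetition probability 0.75 after a high cue and 0.25 after
a low cue) each category contains 180 expected repetitions, 180 expected
alternations, 60 unexpected repetitions, 60 unexpected alternations, 20%
of trials being targets. Counts are allocated deterministically and the
order randomized, rather than drawn per trial, because the design is a
balanced list; any probability that does not yield whole trials per cell
is an error rather than a silent rounding. Stimulus identities are drawn
from per-subcategory pools of 60 exemplars, avoiding reuse within a
sliding window of 4 trials; on alternation trials S2 is a different
exemplar from the category pool (a configurable policy — the pairing rule
is not uniquely determined by the design). The 18% size reduction of one
pair member is recorded as a bookkeeping column only; image rendering is
out of scope.

`simulate_subject_epochs()` is a linear forward model: each trial's signal
is a sum of effect templates — a zero-mean, unit-GFP topography (Gaussian
bumps on focus electrodes, re-centred and rescaled) times a raised-cosine
or boxcar envelope inside a latency window, signed by the trial's
condition so that `amplitude` equals the induced condition-difference at
the envelope peak. Noise is white Gaussian per channel, filtered to a
stationary AR(1) along time, then mixed across channels by the symmetric
square root of a distance-based Gaussian kernel with unit diagonal, so the
marginal SD stays `trial_noise_sd` while the two correlations that matter
for permutation validity — temporal and spatial — are present and
controllable. Per-subject effect amplitudes scale by a lognormal factor
with median 1, keeping effect signs consistent across subjects, as
group-level TANOVA assumes.

Defaults: 64-channel idealized 10-10 montage on the unit disc (a
32-channel subset for desk-scale work), 250 Hz sampling (configurable to
1000 Hz), epochs −150 to 850 ms, `trial_noise_sd` 20 µV, AR(1)
coefficient 0.7, spatial kernel scale 0.6 montage units, subject
amplitude sigma 0.3, and 33 subjects for a full study. The noise
parameters are stated choices, not estimates: no signal-to-noise figures
exist to calibrate against, so they were fixed once at values that give
single-trial variability, channel-neighbour correlation and lag-1
autocorrelation in the range a practitioner would call plausible for
band-passed scalp EEG, and are documented as arbitrary.

`simulate_condition_erps()` is the ERP-level shortcut used by the
calibration studies: it draws subject-by-cell *averaged* maps directly,
with `erp_noise_sd` playing the role of the residual noise left after
trial averaging. This keeps null and power simulations at hundreds of
replicates affordable without changing what is being tested, since the
statistics only ever see subject-by-condition maps.

What the generator does *not* emulate: ocular and movement artifacts,
bad channels, volume-conduction forward physics, non-stationary noise,
inter-electrode impedance differences. Passing tests therefore show that
the statistics are calibrated and sensitive under a clean, exchangeable
within-subject generative model — not that any given real dataset meets
those assumptions.

## Preprocessing

The deterministic chain mirrors standard ERP practice and the order is
filter → average reference → baseline (−150 to 0 ms) → ±80 µV rejection →
nontarget-only condition averaging. Filtering is a cascade of 4th-order
Butterworth high-pass (0.3 Hz) and low-pass (30 Hz) sections, each applied
forward and backward (zero phase), so the effective amplitude response is
the squared magnitude; epochs are padded by odd reflection because the
published chain filters continuous EEG, which the simulation does not
produce. Rejection uses a strict inequality (a peak of exactly 80 µV is
kept — "exceeding" read literally) and is applied after baseline
correction, a point the source chain leaves unstated. Ocular ICA and
bad-channel interpolation are deliberately absent: the synthetic data
contain no such artifacts, and those steps are dataset-specific
judgement calls.

## Numerical choices and edge cases

- Exceedance counting uses a relative tolerance of $10^{-9}$ on the
  observed statistic, because the observed and permuted statistics flow
  through different BLAS kernels (matrix-vector vs. matrix-matrix) whose
  last-bit rounding can otherwise break exact ties — which matters
  precisely when the observed value is the enumeration maximum.
- Permutation statistics are computed in chunks of 500 label matrices to
  bound memory at roughly `chunk × channels × timepoints` doubles.
- `normalize_by_gfp()` refuses flat maps (GFP below $10^{-12}$) and names
  the offending timepoint.
- Duration thresholds use type-1 (ceiling-rank) quantiles on integer run
  lengths; "exceeds the 95th percentile" is implemented as strictly
  greater, the conservative reading with heavily tied integers.
- The repetition-by-category interaction across three categories uses a
  dispersion statistic — the RMS across channels and categories of the
  category-level grand-mean difference maps around their common mean —
  with category labels permuted within subject; for two levels this is
  proportional to the pairwise GDI, so p-values agree with the
  two-condition test.
- All seeds derive deterministically from user-supplied integers; the
  generator restores the caller's RNG state afterwards.

## Scale of the validation studies

The bundled calibration studies run at a desk scale chosen once: the
false-positive study uses 200 global-null replicates of 20 subjects,
32 channels and 250 timepoints with 1000 permutations; the recovery study
injects a 200–300 ms repetition effect at three times the grand-average
noise SD and requires the surviving window to overlap the injected one
with Jaccard at least 0.5 in at least 80% of 50 replicates. The
full-study configuration (33 subjects, 64 channels, 1000 Hz, 5000
permutations) is available through the same functions.

## Known limitations

- TANOVA as implemented handles two crossed within-subject factors; the
  three-category comparison is run as difference-map contrasts rather
  than a three-factor model, which is also how such analyses are
  conventionally reported.
- The variance partition behind partial $\eta^2$ is documented above and
  validated against the internal $\eta^2 \leftrightarrow d$ consistency of
  published values, not against any third-party implementation, whose
  exact partition is not public.
- The per-effect (not global) maximum-run distribution drives the GDS
  threshold; with three effects tested per category, epoch-level control
  is per effect.
- The generator's exchangeable noise makes the permutation null exactly
  true under no-effect simulations; real EEG can violate exchangeability
  (e.g. condition-dependent trial counts after rejection), which TANOVA
  shares with all permutation approaches of this family.

## A worked example

```{r example, eval = FALSE}
library(erptopo)

montage <- make_montage(32)
topo <- make_topography(montage, c("PO7", "PO8"), 0.4, signs = c(-1, -1))
effect <- effect_spec("N250r-like repetition suppression", "repetition_main",
                      topo, window_ms = c(200, 300), amplitude = 0.8)

erps <- simulate_condition_erps(n_subjects = 20, effects = list(effect),
                                erp_noise_sd = 1, montage = montage,
                                n_timepoints = 250, seed = 42)

out <- run_factorial_analysis(erps, config = analysis_config(n_perm = 1000,
                                                             seed = 7))
tidy(out)           # every run of pointwise-significant samples
out$effect_sizes    # eta^2, Cohen's d, permutation z for surviving windows
autoplot(out$gds$repetition_main)
```
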