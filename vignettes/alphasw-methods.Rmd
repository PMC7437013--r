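---
title: "Alpha-band connectivity and small-world organization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-band connectivity and small-world organization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphasw)
```

## The question the package addresses

Resting-state EEG studies commonly summarize a subject twice: by the overall
strength of functional connectivity (FC) between channels, and by the
topology of the binary graph built from the strongest connections — most
prominently its small-worldness. Because the graph metrics are normalized
against degree-matched random null models, there is no mathematical reason
for the two summaries to be related: for random graphs the mean edge weight
and small-worldness are independent by construction. A correlation between
them in physiological recordings is therefore informative. `alphasw`
implements the full analysis chain needed to study that relationship in the
alpha band (8–12 Hz): signal conditioning, three complementary FC
estimators, proportional-density graph construction, small-world metrics
with Maslov–Sneppen nulls, and the study-level correlation analysis with
Bonferroni control — together with a synthetic cohort generator that
provides ground truth none of the real-data studies can offer.

## Signal conditioning

Recordings enter as samples × channels matrices with a sampling rate.
The conditioning chain is `bandpass()` → `downsample()` →
`segment_recording()` → common-average re-referencing, in that order.

* **Band-pass**: Butterworth of order 4 (a common EEG choice; the order is
  a package decision, exposed as an argument), applied forward–backward so
  the filter is zero-phase and the effective attenuation is the squared
  design response. Zero-phase filtering matters here: a phase-distorting
  filter would contaminate the imaginary part of coherency.
* **Downsampling** to 200 Hz is plain decimation. No separate anti-alias
  filter is used because the signal has already been confined to ≤ 12 Hz,
  far below the new 100 Hz Nyquist frequency.
* **Segmentation** cuts consecutive, non-overlapping 4096-sample
  (20.48 s) blocks and keeps the first 10 clean ones. Visual artifact
  screening is replaced by an optional per-segment absolute-amplitude
  threshold (`max_abs`), disabled by default for synthetic data.
* **Re-referencing** subtracts the instantaneous channel mean. A
  source-model-based reference (such as reference electrode
  standardization) needs a head model and lies outside this package's
  scope; the common average is the standard model-free alternative and is
  idempotent, which the tests verify.

## The three connectivity estimators

**Magnitude-squared coherence (MSC).** Auto- and cross-spectra are
estimated by Welch averaging with a symmetric Hann window of 512 samples
and 50% overlap (15 blocks per 4096-sample segment);
`MSC(f) = |S_ij|² / (S_ii S_jj)` is computed per frequency bin and averaged
over bins with 8 ≤ f ≤ 12 Hz (edges inclusive — the least-assumption
reading of the band). MSC is linear and maximally sensitive to zero-lag
dependence, including volume conduction. Note its finite-sample chance
level: with K averaged blocks, independent signals give MSC ≈ 1/K, not 0.

**Imaginary part of coherency (ICOH).** The imaginary part of
`S_ij / sqrt(S_ii S_jj)`, averaged over the same band. Any zero-lag mixture
of a source has a real coherency, so ICOH is blind to volume conduction by
construction. The paper-facing convention choice: the band average is
taken first and its absolute value is stored as the edge weight. This
preserves cancellation of sign-alternating bins while producing the
non-negative edges that graph thresholding needs. Signed per-bin values are
an alternative convention; the band-average-then-modulus form was chosen
because thresholding operates on a single scalar per pair.

**Synchronization likelihood (SL).** A time-domain measure of generalized
synchronization: each channel is time-delay embedded, recurrences of the
embedded state are detected within a Theiler corridor `w1 < |k−j| ≤ w2`,
and SL is the probability that recurrences of two channels coincide.
Parameters derive from the band by the standard frequency heuristic
(`sl_parameters()`): lag `L = round(fs/(3 f_hi))`, dimension
`m = round(3 f_hi/f_lo + 1)`, inner window `w1 = round(2 fs/f_lo)`, outer
window `w2 = w1 + nrec/pref − 1`. For 200 Hz and 8–12 Hz with
`pref = 0.01`, `nrec = 10` this gives L = 6, m = 6, w1 = 50, w2 = 1049.
The critical distance is chosen by rank (the ⌈pref·n⌉-th nearest candidate,
ties included), giving exact recurrence-fraction control without iterative
threshold search; reference indices with fewer than `nrec` candidates are
dropped; truncated windows near the segment edges are allowed. Pair values
are symmetrized by averaging the two normalizations. Independent channels
then sit near `pref` and identical channels at exactly 1 — both covered by
tests, along with agreement to 1e-12 with a naive double-loop reference
implementation. The core is implemented in C++ (recurrence rows as 64-bit
masks) because the computation is O(channels² · n²).

Per subject, each measure is computed on every segment and segments are
combined by the element-wise median (mean of the central two for even
counts), making the subject matrix robust to occasional atypical segments.

## Graphs and small-world metrics

`threshold_by_density()` keeps the `round(d · n(n−1)/2)` strongest pairs as
unweighted edges, so every subject's graph has the same edge count and
metric differences reflect topology, not overall FC level — the reason a
correlation between mean FC and the normalized metrics is non-trivial.
Ties at the cutoff are broken by channel-pair index (deterministic;
real-valued FC makes ties measure-zero). The analysis grid is 10% to 50%
density in 5% steps (9 densities), a commonly analyzed range in which
alpha-band graphs stay connected while sparse enough to show structure.

Clustering coefficient `C` (mean local clustering, 0 for nodes of degree
< 2) and characteristic path length `L` (mean shortest-path length over
ordered reachable pairs) are computed via igraph and validated against
exhaustive triangle-counting and breadth-first-search oracles on all small
graphs. Small-worldness is `SW = (C/C_rand)/(L/L_rand)` with `C_rand`,
`L_rand` means over `n_null = 10` Maslov–Sneppen rewirings (degree
sequence preserved exactly; 10 attempted swaps per edge). The paper-facing
constants `n_null` and the swap factor are unreported in the literature the
package follows; 10/10 is standard practice and both are arguments.
`C_rand` averages all null realizations, including those with zero
clustering; if every one of the first `n_null` draws is triangle-free —
which happens for very sparse graphs whose degree sequences rarely close
triangles — sampling continues until a triangle-bearing realization
appears, so the ratio stays defined without discarding the zeros that
genuinely belong to the null distribution. An input graph with zero
clustering short-circuits to `SW = 0`. Disconnected graphs average
reachable pairs only and emit a warning rather than returning infinity.

## Study-level statistics

For each measure × density cell, the Pearson correlation across subjects
between mean FC (upper-triangle mean of the subject matrix) and SW is
computed with the two-sided t-test p-value. The family-wise error is
controlled by Bonferroni over all cells: 3 measures × 9 densities = 27
tests, so α = 0.05/27 ≈ 0.0019, equivalently a critical magnitude
`critical_r(0.05/27, 80) ≈ 0.34` at 80 subjects. The implementation
computes the significance flag from both criteria and asserts their
agreement. Small-worldness values of different measures are compared per
density with Wilcoxon's rank-sum test (midranks, tie-corrected variance,
continuity correction; an exact enumeration oracle backs the tests at
small n). Whether the 27-test family should also cover the rank-sum
comparisons is ambiguous in the source literature; the family size is
therefore an explicit argument with default 27.

## The synthetic cohort generator

No public dataset accompanies the analysis this package systematizes, and
no generative description of the recordings exists; the generator is
therefore a stand-in, designed so that every downstream stage has ground
truth, and labelled as such. Its defaults emulate the study scale: 80
subjects × 30 channels × 10 segments of 4096 samples at 200 Hz.

Each subject owns a Watts–Strogatz structural graph: ring lattice with `k`
neighbours, of whose edges exactly `round(beta_s · E)` are rewired to
random endpoints (the derandomized count removes binomial noise from a
controlled covariate). `beta_s` spans `beta_range = c(0.02, 0.8)` — from
lattice through small-world to random, which is what small-worldness
responds to — and is drawn from a symmetric Beta(0.4, 0.4) over that
range: the U shape places more subjects near the two topological extremes,
widening the small-worldness contrast the cohort expresses, which at the
16-node validation scale would otherwise be thin relative to
graph-to-graph noise.
Channel signals are built from band-limited Gaussian sources (the same
Butterworth design as preprocessing, so band-limiting is testable: less
than 5% of power falls outside 6–14 Hz) with four interaction terms:

* a **symmetric zero-lag coupling backbone** on structural edges in the
  lower alpha sub-band (8–9.4 Hz) — zero-phase synchrony, visible to MSC
  and SL, invisible to ICOH. Rewired (long-range) edges get weight 1.15
  because lattice edges are additionally reinforced by shared-neighbour
  coherence; the calibration makes both edge classes comparably detectable
  so the thresholded graph reflects topology rather than edge class;
* a **directed lagged coupling** on structural edges in the upper sub-band
  (9.4–12 Hz): each edge passes one endpoint's upper-band source to the
  other with a delay. The delay makes the interaction visible to ICOH with
  equal strength on every edge; the influence is one-directional because a
  symmetric exchange at equal lag has conjugate phase terms that cancel
  and would leave no imaginary-coherency signature at all;
* a **global in-phase common rhythm** replacing a fraction of each
  channel's lower-band private variance (a whole-array alpha generator) —
  raises every pair's zero-phase coherence equally without changing
  channel power;
* **unstructured instantaneous leakage** (`mixing_strength`) emulating
  volume conduction, plus white measurement noise.

Placing the two interaction types in separate sub-bands is the generator's
central design decision. In a shared band the zero-lag and lagged
components interfere in the cross-spectrum (their phasors add), so any
knob that moves one contaminates the other's measure; in disjoint bands
each estimator's frequency bins contain a single interaction type and the
couplings can be controlled independently. This is a deliberate
idealization — real alpha interactions are not band-segregated — and is
one of the listed limitations.

**Linked and null cohorts.** A second per-subject quantity, the
connectivity driver `d_s ∈ [0, 1]`, sets how strong measured connectivity
is, through three pathways chosen to move the *level* of connectivity
while leaving the *ranking* of channel pairs — and hence the thresholded
graph and its small-worldness — as untouched as the estimators allow:

* the depth of a global slow (~0.2 Hz) amplitude co-modulation
  (0 → 0.45), an arousal-like waxing and waning shared by all channels.
  This is the principal driver: joint amplitude dynamics raise the
  recurrence-based measure most strongly (synchronization likelihood
  roughly doubles across the driver range), lift coherence magnitude
  through the heteroscedasticity of Welch blocks, and touch the imaginary
  coherency only mildly — while preferring no channel pair over another;
* the common-rhythm fraction (0 → 0.15), a direct zero-phase coherence
  lift for the amplitude-based measures;
* the interaction delay, shortened from 6 to 5 samples (30 → 25 ms),
  nudging the interaction phase toward quadrature at the upper-band
  carrier and so scaling the imaginary coherency's mean.

The coupling gains themselves stay fixed at a level where edge detection
is saturated for every subject — a driver that scaled the couplings would
make strongly connected subjects also the cleanly *measured* ones,
dragging small-worldness along with connectivity and manufacturing an
association even in the null cohort. In `"linked"` mode `d_s = beta_s`
(rescaled), building in a negative FC–SW association: more randomly wired
subjects are also more strongly connected. In `"null"` mode `d_s` is an
independent uniform draw and no association exists. The
`generate_er_weight_cohort()` path provides the fully random reference:
symmetric Uniform(0, 1) weight matrices whose mean edge weight is
independent of SW by construction.

During generator development the couplings were calibrated once, at a
reduced cohort scale, to sit in the regime where all three estimators
detect structural edges near-saturated across the whole driver range;
the chosen defaults are fixed thereafter. Earlier, simpler designs (a
single gain rule scaling lagged coupling) were rejected because a
gain-driven cohort couples edge detectability to the driver: subjects with
stronger coupling get cleaner graphs, which drags small-worldness along
with connectivity and manufactures an association even in the null mode —
exactly the artifact the null cohort exists to exclude.

**What passing tests do and do not show.** The generator produces
stationary, Gaussian, band-segregated linear interactions with a fixed
per-subject topology. Real EEG has nonstationary power, broadband and
non-Gaussian structure, genuinely mixed zero-lag/lagged interactions, and
volume conduction with electrode-geometry structure. End-to-end recoveries
on this cohort therefore validate the pipeline's statistical machinery and
sign conventions, not the physiological claim itself.

The choice of drivers is itself a result. For the imaginary coherency and
synchronization likelihood, a pairwise coupling's band-averaged strength
is simultaneously its contribution to mean connectivity and its detection
margin over the estimator noise floor (≈ 0.07–0.09 for a 7-block Welch
estimate; ≈ `pref` for SL), so driving mean FC through coupling strength
inevitably drives graph quality too. The amplitude-co-modulation pathway
escapes that bind because it operates on all pairs at once, below the
level of pairwise ranking — which is why it, and not a gain rule, carries
the cohort's connectivity contrast.

## Problem sizes and numerical choices

The validation suite runs the full pipeline on cohorts of 80 subjects with
16 channels and 3 segments of 2048 samples (with `k = 4`, preserving the
structural edge density of the 30-channel, `k = 8` default), a size at
which the whole suite completes in minutes while the statistical criteria
(|r| > 0.34 at n = 80) remain exactly those of the full-scale study. At
2048 samples the Welch estimate averages 7 blocks, so the MSC chance floor
is ≈ 0.14 — the dominant finite-sample effect at this scale and the reason
the generator's couplings are calibrated to keep structural edges well
above it. Edge counts and embedding parameters round half away from zero
for cross-platform determinism; integer seeds fan out to per-subject and
per-stage child seeds so cohorts are bit-reproducible and subject-level
work could be parallelized without changing results.

## Known limitations

* Common-average re-referencing, not a source-model reference.
* The amplitude-threshold artifact screen is a stand-in for expert visual
  inspection.
* The ICOH absolute-band-average convention is one of several defensible
  readings (see above).
* The generator's band-segregated linear couplings are an idealization;
  its parameters are package choices, not fitted to any recording.
* Characteristic path length on disconnected graphs averages reachable
  pairs, which understates distances relative to harmonic-mean
  (efficiency) conventions.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 12, n_channels = 16, n_segments = 2,
                    segment_len = 2048, k = 4, mode = "linked", seed = 1)
cohort <- generate_study_cohort(spec)
study <- run_study(cohort, seed = 2)
summary(study)
plot(study)
```
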