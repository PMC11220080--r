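---
title: "Methods: consensus rhythm detection and differential rhythmicity across omics layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus rhythm detection and differential rhythmicity across omics layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmrewrite)
```

## The problem

Circadian studies of the same tissue at several molecular layers —
transcript abundance, whole-cell protein abundance, nuclear protein
abundance — ask three questions this package answers in sequence:

1. **Which series are rhythmic?** Per series, per condition, on a sparse
   design (typically 8 circadian timepoints at 3-h spacing, triplicate
   animals, constant darkness).
2. **How does an environmental perturbation re-write rhythmicity?**
   Per series, comparing a standard entrainment condition (STD) against an
   environmental circadian disruption condition (ECD): loss (LOR), gain
   (GOR), or retention (ROR) of rhythm, with the phase shift for retained
   rhythms.
3. **Where does rhythmicity arise?** Joining call sets at the gene level
   across layers to partition the contributions of transcription,
   post-transcription and post-translation (e.g. nuclear-rhythmic proteins
   that are not rhythmic at the whole-cell level must have acquired their
   rhythm post-translationally).

## Rhythm detection model

### Parametric arm: cosinor F-test

For log2 abundance $y_i$ at circadian time $t_i$ we fit

$$y_i = M + a\cos(2\pi t_i/T) + b\sin(2\pi t_i/T) + \varepsilon_i$$

by least squares with the period fixed at $T = 24$ h (the pipeline tests
circadian rhythmicity only; period scanning is out of scope). The
amplitude is the half peak-to-trough height $A = \sqrt{a^2+b^2}$ (log2
units), the acrophase is $\hat\phi = \frac{T}{2\pi}\operatorname{atan2}(b, a)$
mapped to $[0, 24)$, and significance is the F-test of the harmonic pair
against the intercept-only model with $(2, n-3)$ degrees of freedom.
Replicates enter as independent observations at their timepoint; no
replicate averaging is performed (averaging is a caller-side choice and
would change the test's effective $n$).

### Nonparametric arm: rank-template permutation test

For each template phase on the sampling grid (one per distinct timepoint)
we compute Kendall's $\tau_b$ between the series and a period-24 cosine
peaking at that phase; the statistic is the maximum $\tau$ over templates,
with ties broken toward the earliest CT. The null distribution permutes
timepoint labels with replicate triplets kept intact — respecting the
design's exchangeable unit, the timepoint block — and the p-value uses the
add-one estimator $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$,
which is valid (never anti-conservative) at any number of permutations.
An exact mode enumerates all $8! = 40320$ block orderings for the 8-point
grid and is used as the oracle in the tests.

Implementation note: because only block labels move, Kendall numerators
for every permutation and template reduce to inner products with a single
per-series $8\times 8$ block-comparison matrix, and the $\tau_b$ tie
corrections are permutation-invariant. This makes a 2000-permutation scan
of a 1000-series matrix take seconds rather than hours, with no
approximation.

### Consensus rule

A series is called rhythmic only when **both** detectors are significant
at $\alpha = 0.05$ — on Benjamini–Hochberg q-values (computed within the
analysis set) for transcript sets, and on raw p-values for protein sets.
The asymmetry mirrors the much larger multiplicity of transcript sets;
both choices are per-layer configurable. The two detectors are deliberately
different in kind (parametric waveform fit vs rank concordance), so the
AND-rule trades recall for a low false-positive rate; the consensus set is
provably a subset of each single-detector set.

## Differential rhythmicity

With per-condition consensus calls on the same series universe,
classification is the four-way partition LOR / GOR / ROR / NRB
(non-rhythmic in both). For ROR series the phase shift is the circular
difference $\Delta\phi = \phi_{ECD} - \phi_{STD}$ mapped to $(-12, 12]$;
**advance means negative** $\Delta\phi$ (the ECD peak comes earlier,
matching the advancing direction of the disruption's light schedule), and
shifts are classed against the sampling resolution with strict inequality
(a 3.0-h shift on a 3-h grid is "unshifted"). Re-writing is summarized over
the union of series rhythmic in either condition:
$\text{pct rewritten} = 100\,(n_{LOR}+n_{GOR})/(n_{LOR}+n_{GOR}+n_{ROR})$.

Headline percentages use half-up rounding to integers (one decimal where
conventionally printed) so that published count tables reproduce published
percentages deterministically; `round()`'s round-half-to-even would not.

## Layer overlap and contribution partitioning

Genes enter the joined universe when a transcript series and at least one
protein series were quantified. A gene is rhythmic at a layer if **any**
of its series there is consensus-rhythmic (transcript-to-gene maps are
many-to-one); each overlap percentage is computed within its stated
denominator and restricted to genes with both layers involved quantified.
The contribution chain multiplies two links — the share of rhythmic
nuclear proteins also rhythmic at the whole-cell level, and the share of
rhythmic whole-cell proteins with rhythmic transcripts — to estimate the
share of the rhythmic nuclear proteome traceable to rhythmic transcripts.
Chaining integer-rounded links can differ from chaining raw counts in the
last decimal (6% × 48% = 2.9%, while unrounded counts can give 2.8%); the
function documents and the tests pin the rounded-input convention.

Tie conventions where the underlying convention is not otherwise fixed,
chosen once and pinned by tests: a transcript–protein phase difference of
exactly 0 or 12 h counts as *lag*; equal amplitudes count as
*protein-lower* (strict `>` for protein-higher).

## TMT bridge normalization and filters

Plexed protein intensities are normalized by dividing every channel by the
per-series mean of that plex's bridge (spike) channels, then dropping the
bridges and concatenating plexes on their shared series. The output is
relative abundance (each series' values divided by its bridge level), which
makes the procedure exactly invariant to per-plex scale factors — the
property the synthetic plex generator round-trips in the tests.

Transcript series are filtered before detection: keep iff total raw count
≥ 50 across the combined 48-sample design AND detected (count > 0) in
≥ 32 of 48 samples. Both boundaries keep; "detection" means strictly
positive; a series failing both rules is tallied once, under low
abundance. The 50-count rule is read as a summed count across all samples
(the most literal reading of a per-series abundance threshold); both
thresholds are arguments, so a per-sample-mean reading or a rescaled
protein-layer variant is a one-line change.

## Synthetic data generator

`sim_config()` / `generate_multiomics()` emulate the targeted study
design: 8 timepoints × 3 replicates × 2 conditions × 3 layers. Per
(gene, layer) a change class is drawn from a configurable mixture over
{LOR, GOR, ROR-stable, ROR-advance, NRB}; rhythmic series follow the
cosinor model on the log2 scale with Gaussian noise; transcripts are
back-transformed to counts (`round(2^x - 1)`, floored at 0) with Bernoulli
dropout, proteins stay as linear intensities. Default parameters:

| parameter | default | meaning |
|---|---|---|
| `change_design` | per-layer mixtures from published liver multi-omics counts (RNA 26%/16% rhythmic STD/ECD; TE 3.9%/12.4%; NE 9.3%/4.9%) | class probabilities |
| `amplitude_mean`, `sd`, `floor` | 0.5, 0.2, 0.2 | log2 half-amplitude draw `max(floor, N(mean, sd))` |
| `phase_dist` | RNA uniform; TE bimodal CT7/CT17; NE unimodal CT20 (wrapped normal, sd 1.5 h) | acrophase distributions per layer |
| `advance_hours` | 6 | ECD phase advance for ROR-advance series |
| `noise_sd` | 0.2 | log2 measurement noise sd |
| `baseline_mean`, `sd` | 8, 1.5 | log2 mesor |
| `dropout_rate` | 0 | probability a transcript count is zeroed (off by default: technical zeros are implausible at the default count scale, and one zeroed count is an ~8-log2-unit outlier; set it when simulating low-abundance series for the detection filter) |

Per-layer noise magnitudes and the mesor scale are free parameters of the
generator, not estimates of any particular dataset: the study design the
generator copies does not publish them. Phase distributions use wrapped
normals rather than von Mises — at the 1–2 h spreads involved the two are
visually indistinguishable, and the wrapped normal needs no special
functions. For retained rhythms the STD amplitude is reused under ECD so
that phase-shift recovery is not confounded by amplitude changes.

Two sampling modes: `"quota"` (largest-remainder integer quotas; realized
class counts match the design exactly — the default, and what the
recovery tests rely on) and `"binomial"` (independent class draws). All
randomness flows from the single config seed.

`generate_tmt_plexes()` multiplies each plex (bridges included) by a
shared log-normal factor and sets bridge channels to the per-series grand
mean times that factor; `bridge_normalize()` therefore recovers relative
abundance exactly at any jitter, and the identity round-trip holds exactly
for unit-grand-mean input.

**What the generator does not emulate:** count overdispersion beyond the
round-after-exponentiation model (a negative-binomial layer would be the
escape hatch), abundance-dependent dropout, peptide-level missingness
patterns, correlated noise between layers of the same gene, and
non-sinusoidal waveforms. Passing recovery tests on this generator
therefore demonstrates correctness of the pipeline's logic and estimators
under the stated model, not detector performance on real data — in
particular the rank test's advantage on asymmetric waveforms is never
exercised here.

## Benchmark and problem sizes

The recovery benchmark used by the tests and the acceptance script is a
1000-gene quota design with balanced classes (LOR 0.2 / GOR 0.2 /
ROR-stable 0.2 / ROR-advance 0.1 / NRB 0.3 — balanced so every class has
enough members for a stable per-class agreement rate), strong effects
(amplitude ≥ 0.5 log2 units, noise sd 0.2), a 6-h advance, and no
dropout. Dropout is excluded from detector benchmarks deliberately: a
zeroed count at a high mesor is an ~8-log2-unit outlier that measures
robustness to missingness, not rhythm detection; the filter stage, not the
detector, owns that problem. Under these conditions the per-gene phase
error is ~0.4 h, so the 95th percentile of the ROR shift-recovery error
sits near 1.2 h — individual genes can exceed any fixed bound, which is
why the recovery claim is a population quantile, not a per-gene one.
Detection uses 2000 permutations (permutation p-value floor 1/2001,
comfortably below the BH-adjusted threshold at these set sizes); the null
calibration uses 1000 flat Gaussian series. These sizes make the full
suite run in well under a minute on one core.

## Numerical choices

- Permutation p-values use the add-one estimator; comparisons of
  permutation statistics to the observed statistic subtract 1e-9 before
  `>=` so exact ties (the statistics are ratios of integers to a shared
  denominator) count as exceedances.
- Template tie structure: cosine values that differ by less than 1e-9 are
  treated as tied when building sign matrices and tie corrections,
  matching the exact symmetry of the cosine on the regular grid.
- Degenerate series: a constant series gets amplitude 0, F = 0, p = 1 in
  the cosinor and tau = 0, p = 1 in the rank test; its acrophase is
  undefined and never consumed (it can never be consensus-rhythmic).
- The pooled-variance (Student) t-test is the default population
  comparison, Welch behind a flag; zero pooled variance is handled
  explicitly (equal means: t = 0, p = 1; unequal: p at the double floor).
- p-values are floored at `.Machine$double.xmin` so they stay in (0, 1].

## Limitations

- Period is fixed; damped or multi-harmonic waveforms are not modelled.
- The consensus AND-rule is conservative by design; absolute rhythmic
  fractions depend strongly on n_perm, set size (through BH) and the
  q-vs-p choice, which is why the package's quantitative claims are about
  recovery of designed truth and printed-count arithmetic, not about
  reproducing a particular study's gene lists from raw data.
- Gene-level joining uses the ANY rule and a single representative series
  (most significant) for phase/amplitude; isoform-level resolution is out
  of scope.
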