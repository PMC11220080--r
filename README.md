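# rhythmrewrite

Comparative circadian rhythmicity analysis for multi-omics abundance time
series, for chronobiologists comparing how an environmental perturbation
(shiftwork/jetlag-style circadian disruption, ECD) re-writes the rhythmic
landscape of a tissue relative to standard entrainment (STD) across three
molecular layers: transcripts (RNA), whole-cell proteins (TE) and nuclear
proteins (NE).

## What it computes

**Consensus rhythm detection.** A series at circadian times $t_i$ (log2
scale) is fit by the cosinor model

$$y_i = M + a\cos(2\pi t_i/24) + b\sin(2\pi t_i/24) + \varepsilon_i,$$

giving mesor $M$, half peak-to-trough amplitude $A=\sqrt{a^2+b^2}$,
acrophase $\hat\phi = \tfrac{24}{2\pi}\operatorname{atan2}(b,a)$, and an
F-test p-value with $(2, n-3)$ df. Independently, a rank-based detector
takes the maximum Kendall $\tau_b$ between the series and cosine
templates peaking at each sampled timepoint, with a replicate-block
permutation p-value. A series is rhythmic only if **both** detectors are
significant at 0.05 — on BH q-values for transcript sets, raw p-values
for protein sets.

**Differential rhythmicity.** Between conditions each series is LOR
(rhythmic under STD only), GOR (ECD only), ROR (both; with circular phase
shift $\Delta\phi\in(-12,12]$, advance = negative, classed against the
3-h sampling resolution) or NRB (neither). Re-writing over the union of
rhythmic series is $100(n_{LOR}+n_{GOR})/(n_{LOR}+n_{GOR}+n_{ROR})$.

**Layer partitioning.** Gene-level joins across layers give the overlap
percentages (e.g. the share of nuclear-rhythmic genes not rhythmic at the
whole-cell level — rhythmicity acquired post-translationally), the
transcript-to-nuclear contribution chain, phase lead/lag ratios and
amplitude-ratio classifications.

Plus: TMT bridge-channel normalization, transcript detection filters
(total count ≥ 50, detected in ≥ 32 of 48 samples), population statistics
(cumulative daily abundance change, pooled t-tests, phase histograms),
and a ground-truthed synthetic generator emulating the full
8 timepoints × 3 replicates × 2 conditions × 3 layers design.

## Worked example

```r
library(rhythmrewrite)

cfg <- sim_config(n_genes = 400, seed = 11)          # published-study-style design
pc  <- pipeline_config(sim = cfg, n_perm = 2000, seed = 11)
rep <- run_pipeline(pc)
print(rep)
```

```
== Comparative circadian rhythmicity report ==
Series filter: 400/400 kept (0 low abundance, 0 low detection)

[RNA]
Rhythm re-writing: LOR 61 + GOR 11 + ROR 20 = 92 rhythmic in either condition
  re-written (LOR+GOR): 78% of the union
  phase-shifted ROR beyond resolution: 6 (7% of the union)

[TE]
Rhythm re-writing: LOR 16 + GOR 50 + ROR 2 = 68 rhythmic in either condition
  re-written (LOR+GOR): 97% of the union
  phase-shifted ROR beyond resolution: 1 (1% of the union)

[NE]
Rhythm re-writing: LOR 37 + GOR 20 + ROR 3 = 60 rhythmic in either condition
  re-written (LOR+GOR): 95% of the union
  phase-shifted ROR beyond resolution: 1 (2% of the union)

Layer overlaps (STD, 400 genes joined):
  rhythmic mRNA with rhythmic TE protein: 7%
  rhythmic TE protein with rhythmic mRNA: 33%
  rhythmic TE protein with rhythmic NE:   11%
  rhythmic NE protein with rhythmic TE:   5%
  post-translationally acquired (NE-only): 38 genes
  transcript-to-nuclear contribution chain: 1.7%
...
```

Reading it: 400 genes were simulated per layer with class
mixtures; each `[layer]` block counts series that lost, gained or
retained rhythmicity between conditions and the re-written share of the
rhythmic union (the TE block's 97% means almost every rhythmic whole-cell
protein changed rhythmicity status under disruption). The overlap block
shows, within genes quantified at both layers, how little transcript
rhythmicity propagates to protein rhythmicity — the contribution chain
(here 1.7%) estimates the share of rhythmic nuclear proteins traceable to
a rhythmic transcript. `rep$headline` holds the same numbers as a flat
list, `report_json(rep, "report.json")` writes them.

Lower-level entry points: `detect_rhythms()` on one matrix,
`cosinor_fit()` / `rank_template_test()` on one series,
`classify_rhythm_change()`, `rewrite_summary()`, `join_layers()` /
`overlap_percentages()`, `bridge_normalize()`, `read_matrix()` /
`write_matrix()` for TSV/CSV matrices with sample metadata. The methods
vignette (`vignettes/circadian-rewriting.Rmd`) documents the models,
conventions and generator parameters.

Published count tables plug straight into the summary arithmetic:

```r
rewrite_summary(261, n_gor = 885, n_ror = 24)$pct_rewritten  # 98
contribution_chain(14, 27)                                   # 3.8
pct(285, 7314, 1)                                            # 3.9
```

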