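---
title: "Methods: season-specific co-expression networks from short developmental time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: season-specific co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonet)
```

## The analysis model

`seasonet` analyses per-gene expression time series measured across the
development of an organ under several (tissue, season) conditions. The data
model is deliberately modest: for each condition, a rectangular matrix of
non-negative relative intensities (genes × ordered timepoints), typically
derived from semi-quantitative RT-PCR bands normalized against a
constitutive reference gene in the same lane
(`normalize_intensity()` implements the clamp-then-divide rule
`max(raw − background, 0) / (reference − background)`; a band fainter than
the lane background is treated as no detectable expression, never as a
negative intensity).

Three assumptions underlie the whole chain:

1. *Expression profile reflects function*: a gene acting in the condition is
   either abundantly or dynamically expressed there.
2. *Co-expression approximates co-regulation*: correlated time courses over
   the growth period indicate participation in a shared regulatory regime.
3. *Direct regulation leaves promoter evidence*: a TF that directly drives a
   target should have its family's binding element in the target's promoter.

Each assumption is operationalised by one stage, and each stage is a pure
function from tables to tables, so the pipeline is deterministic end to end.

### The significance screen

For condition *c* with matrix *X* (genes × timepoints), define per gene the
series mean `mean_t` and series standard deviation `sd_t`, then across
genes the means and standard deviations of those two statistics. A gene is
**significant** when

- `mean_t >= mean_g(mean_t) + sd_g(mean_t)` (abundance), or
- `sd_t >= mean_g(sd_t) + sd_g(sd_t)` (variability),

with inclusive comparisons. This is a one-standard-deviation outlier rule
applied within each condition's own cohort — no replicates, p-values or
multiple-testing machinery, by design: with single-track series of ~8
points, a deterministic threshold rule is the honest statement of what the
data support. Two consequences worth knowing:

- The rule is invariant to shifting all values by a constant and to
  rescaling by any k > 0 (both sides of each comparison transform
  identically), so the choice of reference gene scale does not change the
  selection. This is property-tested.
- The screen is *relative*: a gene's call depends on which other genes were
  measured. Statistics are computed over all genes present in the
  condition's matrix (the natural reading when one assay family produced
  the whole panel); restricting the cohort changes the thresholds.

`sd_mode` selects sample (n−1, the default, matching spreadsheet `STDEV`
semantics) or population standard deviation, in both directions at once.

**Degenerate-input rule.** A perfectly flat gene (`sd_t = 0`) is never
selected by the variability criterion even when the variability threshold is
zero — an unvarying gene is not "highly fluctuated", and without the guard
an all-flat matrix would absurdly select every gene.

**Leaf exclusion.** Root-specific sets are root-condition sets minus
leaf-significant genes. The default is season-matched (wet root minus wet
leaf; each cultivation screened separately, which keeps the two crops'
different sampling calendars independent); `mode = "global"` subtracts the
union over seasons for a stricter notion of root specificity. Basis
annotations (which criterion fired) survive the subtraction.

### Co-expression networks and their comparison

Pairwise Pearson correlation is computed within each condition from that
condition's own series; cross-condition operations use edge identity only,
never pooled series — wet and dry crops are sampled on different calendars,
so pooling timepoints across them would be meaningless. Pairs reach the
network when `|PCC| >= 0.5` (inclusive, as a subjective but conventional
"moderate correlation" cutoff; configurable). A zero-variance gene has no
defined correlation: such pairs are excluded with a warning rather than
assigned 0, because 0 would silently assert independence.

Comparing the wet and dry networks of one tissue partitions the union of
their edge pairs into shared same-sign, shared sign-flipped
(`pcc_a * pcc_b < 0`), and unique pairs. A pair above threshold in one
network and below in the other is *unique*, not *flipped*: a sign flip is a
claim about both conditions and requires presence in both. The partition is
exact (the three categories touching a network sum to its edge count), and
this conservation is property-tested on random network pairs.

### TF-target networks and promoter evidence

The TRN keeps co-expression edges with at least one annotated TF endpoint,
oriented TF → target. Orientation is a hypothesis annotation — correlation
is symmetric — to be tested by promoter evidence, not a causal claim. TF-TF
pairs are kept, flagged, and listed in both orientations, since either
factor could regulate the other and the promoter scan can evaluate both
directions; nothing downstream forces a choice. Hub degree counts distinct
non-TF targets, with lexicographic tie-breaks for deterministic output.

Promoters cover up to `promoter_len = 2000` bp immediately 5' of the
**translation start site** (first CDS base of the gene's primary transcript,
the first mRNA listed in the GFF3). Anchoring at the TLS rather than the TSS
deliberately includes annotated 5'UTRs; 2000 bp is the span within which
plant cis-element searches conventionally operate. Regions truncate at the
contig boundary ("up to"), and are not trimmed at upstream neighbouring
genes by default (`trim_at_genes = TRUE` enables trimming).

Scanning is an exact degenerate-consensus match (15-letter IUPAC alphabet)
on both strands, overlapping matches included, implemented over
`Biostrings::matchPattern(fixed = FALSE)`. An `N` in the promoter matches
nothing — an unknown base is no evidence of a binding site. Offsets are
negative positions relative to the TLS (−1 = the base immediately upstream),
reported for the match's leftmost promoter base. Position weight matrices
are out of scope: the pipeline asks only presence/absence of a consensus,
which is what a confirmed/unconfirmed edge status needs.

An edge is *confirmed* when ≥ 1 element of the TF's family occurs in the
target's promoter, *unconfirmed* when none does (the signature of indirect
regulation through a mediator), and *no-promoter* when the target has no
extractable promoter — deliberately distinct from unconfirmed, since absent
evidence is not negative evidence.

## The synthetic study design

`generate_dataset()` is first-class, tested code that defines the study
conditions the pipeline is validated under. Defaults (all in
`synth_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 42 | panel size typical of a targeted RT-PCR study |
| `n_timepoints` | 8 | ordered developmental samplings per crop |
| `n_targets` | 8 | genes regulated by the hub driver |
| `leaf_decoy_count` | 3 | strongly expressed in all tissues incl. leaf |
| `noise_sd` | 0.25 | additive Gaussian noise, truncated at 0 |
| `driver_gain` | 3 | driver amplitude over normalized precipitation |
| `target_gain`, `target_baseline` | 1, 3.5 | target response and baseline |
| `background_level` | 0.2 | flat low expression of unregulated genes |
| `flip_fraction` | 0.6 | targets whose response sign flips between seasons |
| `promoter_len` | 2000 | planted promoter length (bp) |
| element | GCC-box `GCCGCC`, AP2/EREBP | planted cis-element |

Precipitation follows documented half-cosine ramps — wet season ~180 mm per
sampling interval decaying to 0, dry season rising 0 → ~60 mm (tropical
monsoon scale) — plus seeded Gaussian jitter (8/4 mm), clamped at 0; with
jitter removed the two ramps are exactly anti-correlated. The driver is
`driver_gain ×` normalized precipitation plus noise; each target is
`baseline + sign × target_gain × driver + noise` with a per-season sign.
`target_baseline ≥ target_gain × driver_gain` guarantees negatively
responding targets stay positive, so at `noise_sd = 0` every planted
correlation is exactly ±1 and recovery can be asserted exactly. Noise at
0.25 against a signal standard deviation of ~1 yields strong but imperfect
correlations — comfortably detectable at n = 8, as a targeted panel of a
hub's direct responders would be. Sign flips are planted between seasons
within a tissue (a `tissue_flip` mode exists, off by default). The
mini-genome gives each gene its own contig (alternating strands) with a
300-bp CDS and a full-length promoter; the planted element is inserted at a
seeded offset in each true target's promoter and scrubbed (by targeted
point mutation, on both strands) from every other promoter and from
non-planted regions, so motif presence exactly encodes direct targethood.
A `multi_gene_contigs` mode places all genes on one contig to exercise
boundary truncation; it disables element planting.

What the generator does *not* emulate — and therefore what passing recovery
tests do not show about real data: indirect regulatory cascades (every true
edge is driver→target), measurement saturation and gel-band nonlinearity,
batch or calendar effects between crops, correlated noise across genes,
multiple hubs, and promoters with the combinatorial element content of real
genomes. On real data the screen and threshold rule behave identically, but
interpretation of confirmed edges inherits all the usual caveats of
consensus-based binding-site prediction.

A realism floor is tested rather than assumed: with default noise,
background-background gene pairs exceed |PCC| ≥ 0.5 at the null rate implied
by series length 8 (about a fifth of pairs — short series produce many
spurious correlations, which is exactly why the screen must remove
background genes before network construction).

## Numerical and design choices

- Inclusive `>=` at both screen thresholds and the PCC cutoff.
- Sample sd is the default everywhere, switchable to population sd.
- Undefined correlations (flat series) propagate as `NA` and are excluded
  from networks with a warning; never coerced to 0.
- Network scope default `"subset"`: each condition's network is built over
  its own root-specific significant genes; `"union"` builds every network
  over the union of root-specific genes across conditions for overlay-style
  comparison. Both are exposed because with per-condition significance the
  choice genuinely changes which pairs can be compared; `subset` is the
  default since edges between genes not significant in a condition are not
  interpretable as that condition's regulatory regime.
- Missing timepoints are a hard error, not imputed: correlations and
  standard deviations on ~8-point series are too fragile for silent
  imputation.
- All randomness lives in the generator and is a pure function of its seed
  (`withr::with_seed`); the pipeline proper draws no random numbers, so a
  rerun on identical inputs reproduces the output tree byte for byte.
- Tie-breaks (hub ranking, hit ordering) are lexicographic for
  deterministic reports.
- Test problem sizes: oracle-equivalence sweeps use 200 random matrices of
  3–10 genes × 3–10 timepoints; the motif scanner is checked against a
  sliding-window oracle on 1000 random sequence/consensus pairs; stochastic
  recovery uses 20 seeds of the default design, with thresholds pinned from
  a prior 200-seed calibration (per-seed planted-edge recall ≥ 0.97,
  precision 1.0, driver top hub in all 200 runs).

## Limitations

- Thresholded correlation on short series is a screening heuristic, not an
  inference procedure: no edge confidence, no partial correlation, no
  causal direction. The TRN is a hypothesis set.
- The screen's cohort-relative thresholds mean results change if the gene
  panel changes; it cannot be compared across studies without re-screening.
- Consensus matching treats all family members as equivalent and ignores
  affinity; a confirmed edge means "a binding element exists", no more.
- Promoters are genomic upstream windows; enhancers, introns and distal
  elements are invisible to the scan.
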