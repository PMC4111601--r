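---
title: "Methods: three-channel expression integration in maturing and ischemic neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-channel expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioma)
```

## The analysis model

`trioma` analyses a three-channel microarray time course of primary
cortical neurons: an mRNA channel, a lncRNA channel and a miRNA channel,
profiled while the neurons mature (Days 2, 4, 6, 8) and while Day-6
neurons undergo oxygen–glucose deprivation (0, 2, 4 h OGD). The design has
no biological replication at the array level — RNA from four cultures is
pooled per timepoint — which shapes the statistics available: trends over
time rather than per-timepoint group comparisons, and t-tests with very
few observations.

### Normalization

Expression is normalized in two stages.

1. **Quantile normalization per chip** (`quantile_normalize()`): every
   sample is forced onto the reference distribution given by the row-wise
   mean of the sorted columns. Tied values receive the mean of the
   reference quantiles over their rank span — the standard tie convention,
   implemented via `limma::normalizeQuantiles(ties = TRUE)`. The operation
   is idempotent and equalizes the sorted column multisets exactly, which
   the tests check directly. The mRNA and lncRNA probes of this platform
   share a chip; `quantile_normalize()` takes whatever matrix it is given,
   so joint or separate normalization is the caller's choice (we default
   to separate matrices per channel).
2. **Baseline anchoring** (`compute_slr()`): every sample is divided by
   the condition's baseline sample (Day 2, or the 0 h control) and
   log2-transformed into the Signal Log Ratio. The baseline column is
   identically zero by construction; probes with non-positive intensities
   cannot enter the ratio and are dropped with a message rather than
   silently imputed.

The miRNA channel takes a different first stage
(`mirna_preprocess()`): probes are flagged *detected* when their mean
background-subtracted intensity reaches the floor of 300 intensity units
(inclusive at the boundary), and each sample is scaled by the geometric
mean of its endogenous-control probes. The geometric mean is our choice —
control scaling acts multiplicatively on a log2 scale, where the geometric
mean is the natural location estimate. Detection flags are computed before
control scaling, so they never depend on which controls are supplied. The
identity of the endogenous controls is a required user input; the platform
does not fix it.

### Differential calls and clustering

A probe is differentially expressed iff `|SLR|` strictly exceeds the cut
at one or more non-baseline timepoints: cut 1.0 (two-fold) for mRNA and
lncRNA, 0.6 for the compressed dynamic range of miRNA arrays. The strict
inequality matters at the boundary and makes the call monotone in the cut,
a property the tests exercise.

Heatmap structure uses average-linkage (UPGMA) agglomeration on Euclidean
distances over SLR profiles, via `stats::hclust`. We rely on `hclust`'s
deterministic internal ordering for tied merge distances rather than
imposing a bespoke tie rule: on continuous expression data exact ties have
measure zero, and the suite verifies agreement with a naive O(n³)
agglomeration oracle on random instances. `cut_tree()` cuts at the
smallest height yielding exactly *k* clusters and reports the achievable
counts when ties make a *k* unreachable. No default *k* is fixed: cluster
counts in this kind of analysis are chosen by inspection.

### lncRNA genomic orientation

`classify_locus()` assigns each lncRNA locus a class relative to the
coding gene models, on 0-based half-open coordinates (conversion from
GFF3/BED happens only at the I/O boundary, through `rtracklayer`):

* **sense / antisense overlap** — at least one shared base with a
  transcript span, same / opposite strand;
* **bidirectional** — no transcript overlap, opposite strand, TSS-to-TSS
  distance ≤ 1000 bp, transcripts pointing away from each other;
* **intergenic** — none of the above.

Two points were genuinely open and are fixed here as package conventions.
First, the *promoter* sub-region: a promoter (1000 bp upstream of the TSS,
strand-aware, configurable) lies outside the transcript span, so
"overlap confined to the promoter" cannot literally be a transcript
overlap. We therefore check transcript overlap first, then bidirectional
geometry, then promoter-only overlap. A consequence worth knowing: an
opposite-strand locus inside a promoter is necessarily divergent, so it
classifies as bidirectional, and promoter sub-regions only arise on the
same strand (or in convergent configurations beyond the window). Second,
"head to head within 1000 bp" is measured TSS-to-TSS, requiring
divergence and no overlap — the literal reading. The nearest qualifying
gene wins (overlaps at distance 0, then by gap), with ties broken by the
smaller gene id for determinism.

### Trend statistics and significance grades

`pearson_trend()` is the sample Pearson correlation between an SLR series
(including the baseline's anchored 0) and the timepoint coordinates; it is
invariant to affine changes of the time axis and returns an explicit
undefined marker (`NA`), never 0, for zero-variance series.

The t-test conventions are fixed to the study design of two post-baseline
observations:

* `one_sample_t()` — one-tailed in the direction of the observed mean
  deviation, df = 1, against μ = 0 (the baseline-anchored null). Grades:
  `*` for p < 0.10, `**` for p < 0.05. The one-tailed convention is what
  reproduces the published star pattern from the printed SLR pairs; a
  two-tailed df = 1 test does not. The tail is configurable.
* `two_sample_t_summary()` — pooled-variance Student t from mean ± SD
  summaries with n = 2 per group, two-tailed, df = 2, graded `#`/`##`.
  This reproduces 24 of the 25 published hash marks exactly from the
  2-decimal printed summaries; the single exception (the Ncam1 promoter
  lncRNA, printed `0.00 ± 0.10` with the strict mark) lands at p = 0.086
  from its rounded inputs — a printed-precision limitation the test suite
  pins down to the loose band rather than papering over.

No multiple-testing correction is applied, matching the source analysis;
`grade_significance()` accepts custom alpha levels if a corrected workflow
is wanted.

### The relationship classifier

For each mRNA–lncRNA pair, each condition contributes a verdict from the
two trend coefficients: **synergistic** when both signs are defined and
equal, **inverse** when defined and opposite, **undefined** when either
magnitude falls below the sign threshold τ. The final label requires
agreement across the maturation and injury conditions; every mixed or
undefined combination is **inconclusive**. This definition of
inconclusive is inferred, not published — it is the unique simple rule
consistent with all fourteen published labels.

τ = 0.1 by default. The value is pinned by the published labels
themselves: the only coefficient whose sign must be treated as
indeterminate is −0.04, while magnitudes ≥ 0.14 must keep their sign, so
any τ in (0.04, 0.14] reproduces the labels and 0.1 is the round choice.
It is configurable, and the suite checks that raising τ can only move
pairs toward inconclusive, never away from it.

### The shortlisting cascade

The funnel — dual-DE genes → enriched pathways → miRNA-targeted genes →
mature-phenotype genes (|SLR| > 1 on **both** Day 6 and Day 8; an
`either` mode is provided since "differentially expressed on days 6 and
8" admits both readings) → genes with a conclusive relationship → miRNAs
targeting ≥ 2 of them — is implemented as set operations whose
monotonicity the tests verify. Pathway enrichment is a one-sided
hypergeometric tail; the default EASE variant removes one success from the
overlap before the tail (an overlap of 0 scores exactly 1), the
conservative score popularized by annotation servers. Published pathway
p-values depend on a 2011-era annotation universe and are consumed as
data, not reproduced.

### qPCR quantification

`ddct_fold_change()` implements 2^−ΔΔCt with replicate-wise ΔCt
propagation. "Undetermined" wells are encoded as `NA` — a sentinel, never
a number — and are an error everywhere except `presence_call()`, which
maps them to the 40-cycle ceiling for its comparison. Presence requires
both a mean C_T at or below 35 (absence is strict >) and a pooled t-test
against the no-template control at p < 0.01. `housekeeping_stability()`
ranks candidate reference genes by pairwise cross-condition t-tests: a
candidate is stable when no pair differs at α = 0.05, and the stable
candidate with the smallest maximum |t| is chosen — the logic that
selects a GAPDH-like flat candidate over a β-actin-like candidate that
shifts between 2 h and 4 h OGD.

## The synthetic study

`synth_annotation()`, `synth_expression()` and `synth_ancillary()`
generate a self-consistent miniature of the study with planted ground
truth, sized to run the full pipeline in seconds (defaults: 50 genes, 500
lncRNA loci, 2000 mRNA probes, 200 miRNA probes — the scale used by the
test suite and chosen as a desk-scale replica of the design).

* The annotation generator lays out non-overlapping multi-exon genes on a
  toy chromosome and constructs each lncRNA to realize its planted
  orientation class and sub-region under the classifier's own geometry;
  the default class mix (60/20/13/7% intergenic/antisense/sense/
  bidirectional) matches the observed census of differentially expressed
  lncRNAs. Planted classes are recovered 100% by construction, which the
  suite asserts.
* The expression generator emits `baseline × 2^(trajectory(t) + ε)` with
  ε ~ N(0, noise_sd²), noise_sd = 0.1 by default — a noise level at which
  log-ratio spread between two samples is ≈ 0.14, small relative to the
  planted margins, emulating the reproducibility of pooled single-array
  measurements. DE probes draw trajectory amplitudes at least 0.4 above
  the SLR cut; flat probes stay below half of it. OGD trajectories negate
  the maturation slope, emulating the published sign reversal, and paired
  lncRNAs carry the sign structure their planted relationship label
  requires (inconclusive pairs are planted as cross-condition sign
  conflicts with strong trends, not as near-zero correlations, so their
  recovery is well-defined).
* The ancillary generator emits a miRNA target table (10 planted network
  miRNAs each covering ≥ 2 eligible genes, decoys covering ≤ 1), one
  planted enriched gene set among random background sets, and a noiseless
  qPCR table realizing a planted fold change via `Ct = a − log2(expr)`.

What the generator deliberately does **not** emulate: chip and batch
effects, dye bias, spatial artifacts, probe cross-hybridization, or a
realistic (majority-null) DE fraction — roughly half the planted probes
are differential, as in the profiled data. Two consequences follow.
First, all synthetic samples share a common scale, so planted-truth
recovery is measured on the baseline-ratio route
(`compute_slr()` → `call_differential()` / `pearson_trend()`); pushing
such data through quantile normalization first would *violate* that
procedure's unchanged-majority assumption and compress the planted
amplitudes, which is a property of the synthetic design, not of the
pipeline. Quantile normalization is validated by its own contract tests
instead. Second, passing recovery tests demonstrates the pipeline's
correctness on clean, planted structure — not its robustness to the array
artifacts real data carry.

## Numerical and degenerate-input conventions

* Zero-variance series: trend R is `NA` (undefined), never 0.
* Zero spread in a t-test: p = 1 when the means agree with the null,
  otherwise p is reported at the machine floor with a warning.
* Empty SLR matrices yield empty call tables; an empty census subset
  yields an empty census rather than a division error.
* Percentages are rounded to one decimal exactly as reported
  (`pct1()`), so published rates recompute from their own counts.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give bit-identical output.

## Known limitations

* Orientation classification is locus-level, not isoform-resolved, and
  has no enhancer/eRNA category.
* The maturation-side significance grades use Day 6/8 SLR values that are
  not shipped (they exist only in figure form), so only the injury-side
  grades are verified against reference values.
* Genome-wide detection and DE counts require the original arrays; the
  package recomputes their report arithmetic and reproduces the
  transcript-level tables, while genome-scale behaviour is covered by the
  synthetic study.
* qPCR quantification is efficiency-uncorrected (no Pfaffl/standard-curve
  support), matching the analysis it implements.
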