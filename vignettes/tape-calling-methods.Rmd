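---
title: "Calling transcriptionally active putative enhancers: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcriptionally active putative enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure and its assumptions

`tapecall` identifies enhancers by the conjunction of two signals: an
accessible chromatin site (an ATAC-seq peak) and locally bidirectional RNA
output (eRNA transcribed from both strands around the element's centre).
The cascade is a sequence of interval filters followed by a strand-ratio
classification:

| stage | rule | default |
|---|---|---|
| peak preprocessing | merge peaks with edge gap ≤ `merge_gap`, drop merged peaks shorter than `min_peak_len` | 1000 bp; 146 bp |
| ROC windows | fixed window `center ± roc_flank`, clipped to the chromosome | 500 bp |
| intergenic filter | distance to every gene body > `min_gene_dist`; no ncRNA overlap; no transcribed-block overlap | 1000 bp |
| transcribed blocks | pooled-coverage runs ≥ `block_min_cov` per base, merged within `block_merge_gap`, kept if longer than `block_min_len` (strict) | 1; 1000 bp; 100 bp |
| bidirectionality | `bidir_lower ≤ f ≤ bidir_upper` (inclusive) with pooled signal ≥ `min_total_signal` | 0.05–0.95; 10 |
| pairing | protein-coding TSS within `pairing_window` of the TAPE centre; high confidence iff global Pearson r > `r_high` (strict) | 1 Mb; 0.5 |
| differential | BH-adjusted q < `q_threshold`; region node assignment margin `z_margin` | 0.05; 0.5 SD |

The assumptions worth stating explicitly:

* **Coverage, not reads.** All quantification sums a per-base signal step
  function over intervals. Fractional signal is accepted; the
  bidirectionality fraction f = fwd/(fwd+rev) is well defined for any
  non-negative signal. `min_total_signal` (default 10 pooled units)
  suppresses classifications driven by a handful of stray units; setting
  it to 0 reproduces the unguarded rule.
* **Bounds are inclusive.** Whether the 5%/95% bidirectionality bounds
  include their endpoints is not decidable from the verbal rule alone; we
  fix inclusive as the default and expose strict bounds via
  `inclusive = FALSE`. The bounds are symmetric about 0.5, so relabelling
  strands maps f to 1 − f and preserves every classification — a property
  the test suite checks.
* **Gene distance is measured to gene bodies** by default; a TSS-anchored
  mode (`gene_anchor = "tss"`) exists because promoter-centric distance is
  the other defensible reading. Only the magnitude of the signed distance
  enters the filter.
* **ROC expansion is centre-anchored** (fixed 1-kb windows), which makes
  every downstream centre-anchored analysis (metaprofiles, pairing
  distances) unambiguous; an `edges ± flank` rule is available for users
  who prefer variable-width windows.
* **Merging bridges gaps ≤ the threshold.** "Closer than 1 kb" is applied
  as gap ≤ 1000 bp, consistently for peaks and transcribed blocks; output
  intervals are therefore separated by gaps strictly greater than the
  threshold.

## The statistical layer

**CPKM** is raw signal divided by (feature length in kb × library signal
in millions); the library size is the sample's total quantified signal.
CPKM preserves between-feature ratios within a sample, so Pearson
correlations across samples are unaffected by per-sample depth.

**Pairing** computes, for each TAPE–gene candidate within 1 Mb, the global
Pearson r across all samples and a per-region r from each region's samples
alone. Pairs whose global r is undefined (a partner with zero variance,
e.g. an all-zero gene) are removed — per-region undefined values only flag
the region entry. The high-confidence gate is strictly r > 0.5. The global
correlation pools both treatments by default (`global_treatments`),
matching replicate-level quantification over the full design; a
vehicle-only mode is available.

**The NB test** is a deliberately compact reimplementation of the
median-of-ratios / NB-GLM workflow: size factors by median-of-ratios over
features with no zero count (a positive-count fallback is available);
per-feature method-of-moments dispersion from pooled within-group variance
of normalized counts, floored at 1e-8, with an optional 50/50 blend toward
a fitted a/mean + b trend (off by default); per-feature NB GLM with
log link and size-factor offsets. The two-group Wald statistic is referred
to a **t distribution on the residual degrees of freedom of the dispersion
estimate** rather than a normal: with unmoderated dispersions estimated
from few replicates, the normal reference is anti-conservative (we measure
type-I ≈ 0.08 at nominal 0.05 with 6 + 6 samples), while the t reference
restores calibration (≈ 0.05, verified by a 2,000-feature null simulation
in the acceptance suite). The omnibus mode is a likelihood-ratio
chi-square with (groups − 1) df. Numerical parity with moderated
empirical-Bayes implementations is explicitly not a goal; directional and
rank agreement is.

**Region-selective calling** runs the omnibus test across the three
regions, z-scores each significant feature's per-region mean normalized
counts (mean 0, unit SD across the three values), clusters the z-vectors
(Euclidean distance, complete linkage) and cuts the dendrogram at the
largest merge-height gap (at least three nodes where possible, admitting
extra noise nodes). A node is assigned to a region only when its mean z
for that region exceeds both others by `z_margin` (default 0.5 SD):
two-region-high patterns, which an omnibus test flags but which are not
selective for a single region, land in unassignable nodes. A margin of 0
assigns every clustered feature; an infinite margin assigns none.

**Activity-dependent calling** is a vehicle-vs-KCl Wald contrast within
each region, with the per-feature dispersion estimated once from the full
region × treatment design (residual df = samples − cells) and shared
across the per-region contrasts — the usual multi-factor treatment of
dispersion, which matters here because each contrast alone has few
replicates. Significant features take an up/down label from the fold
change sign; the union over regions is the activity-dependent set.
Linked-gene summaries split that set by direction, attach each TAPE's top
r-global gene, and test the linked-gene mRNA log2 fold changes (and ATAC
changes at TAPEs and promoters, when supplied) against a theoretical
median of zero with a two-sided Wilcoxon signed-rank test — exact for
n ≤ 25 after zero removal, normal approximation with continuity correction
above.

## The synthetic-data generator

The generator produces everything the pipeline reads — GTF gene lines, an
ncRNA BED, chrom.sizes, per-region narrowPeak files, two bedGraphs per
sample, count matrices, a sample table — plus a truth table, all
deterministic under the config seed (byte-identical files for identical
configs; every stage derives its RNG stream from `seed` plus a fixed
offset).

**Layout.** Elements (genes 3–8 kb, ncRNAs 0.1–0.3 kb, enhancer/decoy/
silent peaks 0.25–0.45 kb, unannotated transcripts 1.5–2.5 kb) are packed
per chromosome with ≥ 3 kb between any two, which guarantees planted
enhancers survive the > 1 kb intergenic rule and never collide with
ncRNAs. Infeasible packings are an error, not a silent truncation.

**Signal model.** Each element's per-sample expected count is

    mean × (planted effect multiplier) × exp(latent) × exp(−Var/2)

with NB replicate noise (dispersion 0.02 — cultured-cell replicate noise
is largely technical) and, for enhancers and decoys, a binomial split of
the total into forward/reverse at the planted forward fraction. The latent
log expression has two components, both shared between an enhancer and its
linked gene through a Gaussian copula at `r_true` = 0.8:

* a **batch component** (SD 0.35) shared by the vehicle/KCl sister
  cultures of one region × replicate batch — real split-batch designs
  co-vary this way, it carries most of the enhancer–gene correlation, and
  it cancels exactly in every treatment contrast;
* an **independent per-sample component** (SD 0.28), the replicate-level
  biological noise the differential tests must overcome.

This decomposition is the result of an explicit design constraint: a
single per-sample latent large enough to drive r ≈ 0.8 correlations acts
as dispersion ≈ 1 in the DE tests and destroys their power, while latents
shared across whole treatment cells collapse the correlation stage's
effective sample size. Batch-level sharing resolves both.

**Planted effects.** Of 40 enhancers, 12 are region-selective — the
selected region boosted 8^(2/3) and the others suppressed 8^(−1/3), an
8-fold contrast centred geometrically so off-region signal stays
quantifiable; 9 are KCl-induced and 3 KCl-repressed 4-fold, in all three
regions (immediate-early-gene-like pan-neuronal responses); linked genes
inherit one quarter of each effect on the log scale, enough to make
linked-gene responses directional without making all same-class
enhancer–gene pairs collinear. Keeping mean enhancer output at 12
counts/sample bounds the pooled per-base eRNA density below the
transcribed-block threshold (min_cov = 1) even for induced enhancers — by
design the block filter must remove the planted unannotated transcripts
(density ≫ 1) and never the enhancers.

**Negatives.** 20 unidirectional decoys (f ∈ {0.01, 0.99}), 15 accessible
but silent sites, and 5 strongly transcribed unannotated regions, all with
ATAC peaks, exercise respectively the bidirectionality bounds, the
minimum-signal guard, and the block filter.

**What the generator does not emulate**, and what passing tests therefore
do not show about real data: mappability artefacts and read-level noise
(coverage is emitted as uniform density over emission windows, not
as piled-up reads); promoter-proximal eRNA/mRNA ambiguity (elements are
packed with clean margins); annotation errors beyond the planted
unannotated transcripts; chromatin-contact structure (pairing truth is
assigned, not looped); and the eRNA-before-mRNA induction kinetics, which
are outside the steady-state count model. Recovery rates on this fixture
are a correctness check of the implementation under its own assumptions,
not an accuracy claim for any tissue.

## Validation design and problem sizes

The test suite validates every operation against an independent oracle
written in a different idiom: quadratic fixpoint scans for merging,
per-base array paints for coverage and blocks, all-pairs scans for nearest
genes, a two-pass product-moment formula for correlation, a hand-rolled
step-up for BH, position-by-position IUPAC class checks for motif hits.
The acceptance suite runs the full cascade on 1,000 randomized layouts
(40-kb chromosome, 8–16 peaks, 2–4 genes, random stranded coverage in
quarter-unit values so thresholds are exact in binary) and requires exact
stage-by-stage agreement; recovers the planted structure of the default
fixture (seed 1); checks NB calibration on a 2,000-feature null; and
verifies byte-identical reruns. These sizes keep the default suite within
a few minutes on one CPU while the randomized-layout count stays high
enough to hit edge cases (empty stages, clipped windows, boundary
fractions).

## Known limitations

* Dispersion estimation is unmoderated; with fewer than three replicates
  per group the t reference is honest but weak. The trend blend helps
  only when many features share a mean–dispersion relationship.
* The largest-gap dendrogram cut is a heuristic; pathological z-vector
  configurations can split a true region node in two (the margin rule
  then still assigns both correctly, but node counts are not meaningful).
* Activity-dependent precision is bounded by the calibration of the NB
  test at n = 4 + 4; on the default fixture we observe precision around
  0.7–0.9 at recall ≥ 0.9.
* `distance_to_nearest` reports signed distances with positive =
  downstream; only |distance| is used by the filters.
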