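# tapecall

Genome-wide enhancer identification from chromatin accessibility and
bidirectional transcription, with correlation-based target-gene pairing and
negative-binomial differential calling — packaged with a fully seeded
synthetic-data generator so the entire pipeline is verifiable without any
sequencing data.

## The problem

Active enhancers sit in open chromatin and are transcribed in both
directions into short-lived enhancer RNAs (eRNAs). In neurons, eRNA levels
track enhancer activity more faithfully than chromatin accessibility alone,
and they respond to depolarisation within minutes. `tapecall` implements
the corresponding calling strategy for anyone with ATAC-seq peak calls and
strand-specific RNA coverage from matched samples — here motivated by
primary neuronal cultures from three brain regions (cortex, hippocampus,
striatum) treated with vehicle or KCl.

## The method

Starting from per-region ATAC-seq peaks and per-sample stranded RNA
coverage:

1. **ROCs** — per region, peaks with edge gaps ≤ 1 kb are merged and merged
   peaks shorter than 146 bp (one nucleosome) are discarded; survivors from
   all regions are unioned, and each peak becomes a fixed window of
   ±500 bp around its centre: a region of open chromatin.
2. **iROCs** — ROCs are kept only if they lie > 1 kb from every annotated
   gene body, overlap no small ncRNA (miRNA, rRNA, snoRNA, snRNA, tRNA),
   and overlap no contiguously transcribed block (pooled coverage runs
   > 100 bp after merging runs closer than 1 kb) — the guard against
   unannotated genes.
3. **TAPEs** — for each iROC the forward-strand fraction of pooled RNA
   signal, f = fwd / (fwd + rev), is computed across all samples; iROCs
   with 5% ≤ f ≤ 95% are transcriptionally active putative enhancers.
4. **Pairing** — every protein-coding TSS within 1 Mb of a TAPE centre is a
   candidate target; TAPE and gene CPKM (counts per kb per million) are
   correlated (Pearson) across all samples and within each region; pairs
   with undefined global r are dropped and pairs with r > 0.5 are
   high-confidence.
5. **Differential calling** — a compact NB framework (median-of-ratios
   size factors, method-of-moments dispersion, Wald t / LRT chi-square,
   Benjamini–Hochberg) finds region-selective TAPEs (omnibus test, then
   z-scored hierarchical clustering with margin-based node assignment) and
   activity-dependent TAPEs (vehicle vs KCl per region), and summarises
   linked-gene mRNA and ATAC responses with exact Wilcoxon signed-rank
   tests.

## Worked example

Simulate the packaged study conditions (3 chromosomes × 2 Mb, 60 genes, 40
planted enhancers, 20 unidirectional decoys, 3 regions × 2 treatments × 4
replicates) and run every stage:

```r
library(tapecall)
run_pipeline("all", pipeline_config(seed = 1), outdir = "demo",
             sim = sim_config(seed = 1))
```

The log reports the record-count funnel:

```
INFO [call-tapes] peaks=80 ROCs=80 iROCs=71 TAPEs=40
INFO [pair] candidates=593 scored=593 high_confidence=39 rank1_fraction=0.100
INFO [diff] region_selective=12 (assigned=12) activity=15
INFO [evaluate] sensitivity=1.000 specificity=1.000
```

80 accessible sites survive peak preprocessing; 71 are intergenic; exactly
the 40 planted bidirectional enhancers are called TAPEs (the 20
unidirectional decoys, 15 silent sites and 5 unannotated transcripts are
all rejected). `demo/metrics.json` then scores the run against the planted
truth:

```json
{"sensitivity":1, "specificity":1, "top1_recovery":0.867,
 "region_f1_macro":1, "activity_recall":1}
```

i.e. all planted enhancers recovered with no false calls, the true linked
gene is the top-correlated candidate for 87% of high-confidence TAPEs, all
region-selective enhancers are assigned to the right region, and every
KCl-responsive enhancer is detected in at least one region. Stage outputs
(`tapes.bed`, `pairs.tsv`, `region_selective.tsv`, `activity_tapes.tsv`,
`linked_response.tsv`, ...) are plain text beside the metrics.

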