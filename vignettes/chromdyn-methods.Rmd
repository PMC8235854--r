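---
title: "chromdyn: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromdyn: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains what each stage of the pipeline computes, which
assumptions it makes, why its defaults are what they are, and what the
synthetic-data generator does and does not emulate.

## Coordinates and inputs

All intervals are 0-based half-open after parsing, regardless of input
dialect. narrowPeak/broadPeak files follow the ENCODE column convention:
`signalValue` becomes the fold enrichment and the `qValue` column, stored
as −log10, becomes an FDR via `10^−q` (the ENCODE "missing" sentinel −1
maps to FDR 1, i.e. never passes a filter). The BED6+ dialect instead
takes plain fold-enrichment and FDR values from caller-named columns.
Gene tables must be stranded; the TSS is the start for `+` genes and the
end for `−` genes. Peaks may be unstranded. Differential-expression
tables are *inputs*: the package deliberately does not re-implement a DE
tool (the generator's Welch+BH tables are a labelled stand-in used only
for fixtures).

## Peak filtering and annotation

Quality filtering keeps peaks with `fdr < fdr_max` and
`fold_enrichment > fe_min`, both strict, mirroring how such thresholds
are printed (`FDR < 0.05`, `fold enrichment > 5` for a transcription
factor, `> 3.5` for histone marks). Strictness at the boundary matters
for reproducibility and is asserted in tests.

A peak is assigned to a gene when it overlaps, by ≥ 1 bp, either the
strand-aware upstream window of `upstream_bp` (default 5000 bp) ending at
the TSS, or the gene body `[start, end)`. Two open choices were resolved
as follows:

- *Gene body, not CDS.* Annotating lncRNAs requires a body definition
  that exists for non-coding genes, so the body is the full gene span.
- *Overlap, not summit.* Membership is interval overlap of ≥ 1 bp; no
  summit-based assignment is attempted, and a peak may link to several
  genes (gene-level summaries deduplicate by gene id). When a peak
  overlaps both zones of one gene, `gene_body` is recorded.

The location classifier is a deliberately simple fixed-priority ladder on
the peak midpoint — promoter ≤ 1 kb from a TSS, promoter 1–5 kb, gene
body, ≤ 5 kb downstream of a 3′ end, else distal intergenic. It is a
declared simplification of the full feature hierarchies of annotation
packages (exon/intron/UTR resolution is out of scope); every peak gets
exactly one category, so the counts form a partition.

## Bivalent domains and state dynamics

H3K4me3 and H3K27me3 peaks (pre-filtered) are pooled and merged
transitively to a fixed point, i.e. exactly what `bedtools merge` does on
the concatenated set. A merged region containing at least one source
peak of each mark is a bivalent domain; single-mark regions stay
`K4_only` or `K27_only`. Transitive merging means a K4–K27–K4 chain
collapses into one bivalent domain — the merge semantics treat
co-occupancy as a property of the merged region, not of individual peak
pairs.

Genes are classified per stage from the domains overlapping
`[tss − 2000, tss + 2000)`. The rule is exclusive: `bivalent` requires a
bivalent domain *and no single-mark domain* in the window; `K4_only` /
`K27_only` require only that mark and no bivalent domain; every other
configuration — mixed evidence or an empty window — is `other`. "Other"
therefore pools unmarked and ambiguous promoters; a gene absent from one
stage's annotation is also `other` rather than dropped, which keeps the
per-stage partitions comparable. Cross-stage dynamics are summarized as
per-gene state sequences, adjacent-stage transition tables, per-state
Venn overlaps, and the resolution set of genes bivalent at the first
stage and `K4_only` at every later stage; the associated percentage
reporter rounds to one decimal, matching how such fractions are printed.

## DEG integration

DEG filtering applies three strict criteria: `|log2FC| > 1`,
`FDR < 0.01`, and maximum FPKM `> 1` over every replicate of the two
contrasted stages ("at least one sample" is interpreted per replicate,
not per stage mean; the floor is configurable). A variant filter takes
raw p-values and linear fold changes (`p < 0.05`, `|FC| > 1.5`) for
experiments reported that way. Intersecting up-regulated DEGs with the
TF-bound set yields putative activated targets, down-regulated ones
putative repressed targets; the two labels partition the bound-DEG
intersection by construction.

## Expression patterns

Clustering operates on per-stage mean profiles of `log2(FPKM + 1)`,
z-scored per gene (sample standard deviation, n − 1). The log transform
and z-scaling are declared choices — they make profiles comparable in
shape rather than level, which is what stage-pattern discovery wants.
Euclidean k-means runs with `n_init = 50` seeded random restarts, keeps
the lowest within-cluster SS, and relabels clusters canonically (by
decreasing size, ties by centroid lexicographic order) so runs are
comparable. Constant-expression genes have undefined z-scores and are
excluded with a message. When exactly k genes remain the exact
one-gene-per-cluster solution is returned directly (the stock k-means
implementation rejects that boundary). `k` is a parameter with presets
of interest 10 (bound-lncRNA patterns) and 6 (resolved-bivalent-gene
patterns); automatic k selection is out of scope. Cell-type specificity
sorts each column of the per-gene Z-score matrix and takes the top
`top_n` (default 100), breaking ties by gene id so rankings are
reproducible.

## Guilt-by-association GSEA

For a lncRNA query, coding genes are ranked by Pearson correlation of
`log2(FPKM + 1)` across all samples, descending, ties broken by gene id;
zero-variance coding genes are excluded and a zero-variance query is an
error. The enrichment score is the classic weighted running sum: hits
advance by `|r|^p` (normalized over the in-set weights; `p = 1` by
default, and `p = 0` recovers the Kolmogorov–Smirnov statistic of the
hit positions), misses retreat by `1/(N − N_h)`; the ES is the deviation
of maximal magnitude, with exact ties resolved toward the positive
extreme. If all in-set weights are zero the hits fall back to equal
weights.

Significance uses **gene-set permutation**: `n_perm` (default 1000)
random same-size sets drawn from the ranked universe. Phenotype
permutation is not an option here — the ranking metric is a correlation
over a handful of samples — which matches standard preranked practice.
NES divides the ES by the mean |null ES| of matching sign (positive and
negative nulls normalized separately); the p-value is the fraction of
same-sign nulls at least as extreme. Across a (query × set) batch, the
FDR of an observed NES compares the sign-matched pooled null NES tail
with the observed NES tail, capped at 1. Entries with FDR < 0.25 enter
the association matrix. For permutations the ES is evaluated from hit
positions only (O(N_h) per permutation); its equivalence to the full
running sum is property-tested, and the full ES is additionally checked
against an independent preranked implementation.

Hypergeometric term enrichment is the upper tail P(X ≥ k) with set sizes
taken after intersection with a caller-supplied universe (the universe is
a required argument — whether it should be all annotated or all expressed
genes is a study-level decision), BH adjustment, and a default FDR < 0.05
cut.

## RIP-Seq screening

The enrichment test compares the IP count against a negative-binomial
null whose mean is the library-scaled control count. The fold change is
pseudocounted (default 1) and library-scaled (a flag disables scaling).
Because the control count is itself a noisy draw, treating it as the null
mean inflates the apparent overdispersion of the comparison; the paired
method-of-moments estimator absorbs this by estimating the *effective*
dispersion from the (IP, control) pairs directly, trimming the most
discrepant 10% of pairs so planted/true enrichment does not contaminate
the null moment. This whole test is a declared stand-in for
transcript-level NB peak callers that estimate per-transcript parameters
from matched RNA-Seq; the faithful part is the three-criteria decision
rule — fold change > 2, p < 0.01, RPKM > 1, all strict — which is applied
to whatever (fold change, p, RPKM) triples are supplied. ARE scanning
reports every (overlapping) occurrence of the DNA pentamer `ATTTA`,
case-insensitive, 0-based.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline is
validated under: three stages (NSC/OPC/NFO-like), 2,000 genes with 15%
lncRNAs on synthetic chromosomes with ≥ 10 kb spacing (so default
annotation windows never collide unless planted), four replicates per
stage, log-normal expression noise with sd 0.2 on the log2 scale,
promoter states drawn from an initial distribution and evolved by a
Markov transition matrix in which bivalency decays preferentially toward
`K4_only` as differentiation proceeds, 10% of genes TF-coupled at
|log2FC| = 3 split evenly between activation and repression, three
lncRNA-driven coexpression modules of 30 coding members at target
correlation 0.9, and 5% of transcripts RIP-enriched at 4-fold with NB
size 20.

Choices that deserve justification:

- *Four replicates.* The DE stand-in is a per-gene Welch t-test with BH
  adjustment — intentionally simple and fully auditable. Per-gene
  variance estimation from three replicates is noisy enough that a few
  percent of genuinely changed genes land above FDR 0.01 by unlucky
  draws; real DE tools moderate variance across genes to buy back that
  power. One extra replicate gives the unmoderated test equivalent
  power, so the planted |log2FC| = 3 signals are recoverable by design.
- *NB size 20.* RIP tag counts are modestly overdispersed relative to
  Poisson; heavier noise (size ≈ 5) makes a 4-fold enrichment
  statistically undetectable at p < 0.01 for low-expressed transcripts
  no matter the test, which would conflate generator noise with pipeline
  defects.
- *Peak geometry.* One peak per planted mark per gene, placed so that a
  bivalent gene's K4 and K27 peaks overlap each other within ± 2 kb of
  the TSS; multi-peak promoters are exercised only in targeted unit
  fixtures. Decoy peaks (failing either quality criterion) are added at
  a configurable rate, default off.
- *Module members* copy their driver's realized sample vector plus noise
  calibrated so the expected Pearson correlation equals the target
  (exactly 1 when the target is 1 and noise is 0).

What the generator does **not** emulate: read-level data (everything
starts from called peaks and FPKM), realistic peak shapes and widths,
count-level expression noise (noise is log-normal), correlated
replicates, batch effects, promoter CpG structure, or any genome
sequence. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct under its stated assumptions — not that the
thresholds are optimal for any particular real dataset.

## Numerical conventions

- All threshold comparisons are strict (`<`, `>`), matching printed
  criteria; boundary cases are tested.
- Running sums end at 0 within 1e−9; |ES| ≤ 1 always.
- Z-scores use the n − 1 standard deviation; constant rows are excluded
  rather than imputed.
- Cluster ids, ranked lists and RIP target tables all have deterministic
  tie-breaks (size/centroid, gene id, p-value then transcript id), so a
  fixed seed yields byte-identical outputs; `run_all()` writes no
  timestamps for the same reason.
- Problem sizes in the test-suite and acceptance runs (hundreds to 2,000
  genes, 100–1,000 permutations, 20 seed replicates) were chosen as the
  smallest sizes at which the planted effects are comfortably above
  their detection thresholds.

## Known limitations

- Bulk data only: bivalency calls average over cells; a promoter called
  bivalent may reflect a mixture of K4-only and K27-only subpopulations.
- The location ladder and the ± 2 kb promoter window are conventions;
  biology does not change at 2,000 bp.
- The RIP significance model is a stand-in (see above); its p-values are
  calibrated only in the sense the recovery tests verify.
- GSEA FDR across a batch needs a reasonably large (query × set) batch to
  be stable; for a handful of pairs the permutation p-value is the more
  interpretable quantity.
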