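---
title: "Measuring the impact of genome annotation choice on RNA-seq analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the impact of genome annotation choice on RNA-seq analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoimpact)
```

# Motivation and model

Public human gene catalogues differ widely in how many genes, isoforms
and exons they annotate, reflecting a spectrum from evidence-based,
manually curated models to prediction-heavy ones. `annoimpact`
operationalizes this spread as *annotation complexity* — proportional to
the three counts — and provides metrics that trace its consequences
through the three stages of an RNA-seq pipeline: read mapping,
expression quantification, and differential expression calling.

## Complexity ranking

Given complexity profiles for $k$ annotations, each category (genes,
isoforms, exons) is ranked by decreasing count (rank 1 = largest). The
complexity rank is the mean of the three category ranks; the final order
is ascending mean rank, ties broken by the ascending *mode* of the three
ranks, then by the gene rank, then by source name. Two numerical choices
were genuinely open:

* **Mode of three ranks.** When one value repeats it is the mode; when
  all three are distinct the mode is undefined and we use the median as
  the most central stand-in. The published six-catalogue comparison
  never reaches this fallback.
* **Exon counting.** `complexity_profile()` counts *distinct* exon
  coordinate tuples `(contig, start, end, strand)` by default, so an
  exon shared by many isoforms counts once — consistent with the
  exon-to-isoform ratios of the published summary counts. Set
  `distinct_exons = FALSE` to count exon rows instead.
* **Count ties.** Exact count ties within a category share the minimum
  rank (with a warning) and are ordered deterministically by source
  name; real catalogues essentially never tie exactly.

## Gene models and harmonization

Internally all coordinates are 0-based half-open; the GTF reader/writer
converts at the file boundary, which keeps interval arithmetic free of
off-by-one corrections. Annotations from different providers are made
comparable by `harmonize()`, which applies, in this fixed order:
contig-name translation (e.g. `"1"` to `"chr1"`), a contig whitelist
(dropping e.g. haplotype and mitochondrial contigs), an isoform biotype
blacklist (dropping small-RNA classes such as tRNA, miscRNA, scRNA,
snRNA), and a purge of genes left without isoforms. Translation runs
first so the whitelist acts in the target naming convention; the whole
operation is idempotent and reports per-rule removal counts. Because
providers disagree on which classes to carry, the blacklist is
user-configurable rather than fixed. The biotype itself is read from the
first available of the `gene_biotype`, `gene_type`, `transcript_type`
attributes, reflecting the dialects in circulation.

Gene symbols default to the `gene_name` attribute with `gene_id` as
fallback; cross-annotation gene sets are joined by symbol
(HGNC-style), matched case-sensitively after whitespace trimming.
A `transcript_id` reused by several genes is kept as distinct isoforms
with a warning; an incoherent isoform (exons on several contigs or
strands under one gene) is an error.

## Mapping metrics

`classify_mappings()` tallies one unit per read (single-end) or read
pair (paired-end). A unit's placement count per end is the aligner's
`NH` hit-count tag when present, otherwise the number of mapped records
for that end — aligners differ in which of the two they emit. Categories
follow directly: a pair with both ends placed is uniquely paired iff
both ends have exactly one placement; a pair with one placed end is a
(uniquely or non-uniquely mapped) singleton; otherwise unmapped.
"Mappable" is judged from flag bits only; no mapping-quality threshold
is applied.

`annotated_fraction()` asks whether a unit's *primary* placement
overlaps the annotation's exonic union by at least one base; secondary
and supplementary records are ignored to avoid double counting. For
pairs the default rule is *either* end overlapping (a fragment touching
an exon contributes to quantification); `rule = "both"` is available.
Percentages are over mapped units by default, with
`denominator = "all"` as an option. An empty union yields a warning and
0% annotated rather than an error.

## Quantification metrics

Stability is the average coefficient of variation: per condition, the
sample ($n-1$) standard deviation over that condition's replicates
divided by the replicate mean, averaged over elements, then averaged
over the two conditions. Elements absent (all-zero) in every replicate
are removed first. An element whose mean is zero in exactly one
condition has an undefined CV there; by default it is excluded from that
condition's average with $n$ reduced accordingly
(`zero_mean = "exclude"`), or it can contribute a CV of zero with $n$
fixed (`zero_mean = "zero"`). The metric is scale-free, so it is
comparable across count, TPM and FPKM units.

Note a small-sample caveat inherent to the estimator, not to its
implementation: for $n$ replicates the sample standard deviation is
biased low, $E[S] = c_4(n)\,\sigma$ with $c_4(3) \approx 0.886$, and the
ratio $S/\bar x$ inherits most of that bias. With 2–4 technical
replicates — the realistic regime for this design — the average CV
therefore sits systematically below the population noise CV by roughly
10–15%. This does not affect *comparisons* across annotations (all are
biased identically), which is how the metric is used, but absolute
recovery of a generator-configured CV at 3 replicates undershoots by
more than the bias-free Monte-Carlo error would suggest.

The present percentage is the fraction of subgroup elements with
nonzero expression in at least one replicate of either condition.
Subgroups (`subgroup_spec()`) restrict by gene symbol (common /
uncommon genes, given the cross-annotation intersection from
`common_genes()`) or keep everything (all genes, all isoforms).

## Concordance metrics

RNA-seq log2 fold-changes are `log2((m1 + c) / (m2 + c))` over condition
replicate means with pseudocount `c = 0` by default — no pseudocount is
assumed on the user's behalf; fold-changes that are infinite at `c = 0`
are dropped with a warning, and both-zero elements are dropped silently
with a count. The fold-change direction (which condition is the
numerator) must be pinned explicitly when the matrix's condition order
is not the intended one, since published tables mix both signs.

Against an RT-qPCR ground-truth table joined by symbol, the package
reports the average absolute deviation, the RMSE, and the correlation
coefficient (Pearson by default; Spearman behind `method =`, since
published usage of "correlation coefficient" is ambiguous). RT-qPCR
panels are pre-filtered with `qpcr_present_filter()`, keeping genes with
present calls in *all* replicates of both reference samples. Agreement
of differential-expression calls across annotations uses
`top_k_overlap()` on ranked gene lists (ranking itself, e.g. by edgeR,
is an upstream input). Report output is conventionally rounded to 3
decimals; all internal values are kept at full precision.

# The synthetic-data generator

The generator (`simulation_config()` plus the three `simulate_*`
functions) produces inputs with exactly the statistical structure the
metrics assume, plus truth sidecars sufficient to recompute every
downstream metric independently.

* **Annotations.** A core of `base_genes` (default 120) multi-exon genes
  is planted, with identical coordinates and symbols, in every
  annotation; per-annotation extras (genes and isoforms, at configured
  rates) create a controlled complexity spread. The default rates give
  roughly a two-fold gene-count spread across six sources, emulating the
  relative spread observed among the public human catalogues. The
  common-gene intersection is exactly the core by construction. Genes
  live in 1 kb slots on three toy contigs (120/100/80 kb), with ~600 bp
  spans of 2–4 exons of 80–140 bp; a configuration requesting more genes
  than the contigs have slots is an error.
* **Alignments.** Category composition is *designed, not drawn*: counts
  of unmapped (5%), singleton (10% of mapped), multi-mapped (15% of
  mapped) and exon-overlapping (80% of mapped) units are fixed by
  rounding, so e.g. an annotated fraction of 0.5 over 10,000 units
  yields exactly 50%. Reads are written as inspectable SAM text (2 x 101
  bp paired by default, 36 bp single-end supported) with flags and
  `NH` tags consistent with the truth labels; both ends of a pair share
  the annotated/un-annotated label so the either/both rules agree on
  truth. There is no sequence-level realism — no bases, qualities or
  splice-aware fragmentation — because the downstream metrics consume
  only placements and flags.
* **Expression.** Per-gene true means are log-normal (meanlog 4, sdlog
  1.5, a realistically heavy-tailed expression distribution); a
  configured fraction (default 10%) of elements is all-zero; replicate
  values are the condition mean times multiplicative log-normal noise
  parameterized so its coefficient of variation equals the configured
  `true_cv` (sdlog $=\sqrt{\ln(1+\mathrm{CV}^2)}$, unit mean) — noise
  that is non-negative and scale-free, matching how technical
  replicates behave. The first condition's mean is scaled by
  $2^{\mathrm{effect}}$ with effect $\sim N(0, 1)$; the matched
  RT-qPCR-style table is the true effect plus $N(0, 0.25^2)$ noise, and
  a per-replicate flag table plants exactly the present genes as
  all-present. Default replicates are 3 + 3 (the 2–4 range covers the
  published designs).

Each `simulate_*` call runs a single RNG stream seeded deterministically
from the configuration (`seed`, `seed + 1`, `seed + 2` for annotations,
alignments, expression respectively) with a fixed draw order, so a fixed
seed reproduces byte-identical outputs.

What passing tests on synthetic data do *not* show: the generator has no
mapping ambiguity arising from sequence similarity (multi-mapping is
assigned, not caused), no aligner-specific artifacts, no
normalization-induced coupling between genes, and no biological
variation — so results on real data can differ in magnitude even where
the metric implementations are exact.

# Problem sizes and verification

The test suite verifies interval-union coverage against a per-base
brute-force oracle on 10 kb contigs (50–60 random genes, all three
coverage levels), mapping classification against planted truth labels on
streams up to 10,000 paired units covering all five categories, CV and
presence recovery on matrices of up to 2,000 genes with 3 + 3
replicates, and the published six-catalogue summary table and
three-gene RT-qPCR fold-change table at their printed precision (two
published AAD cells sit at the edge of 3-decimal print precision and are
checked at ±0.001). These sizes were chosen to exercise every code path
with tight statistical tolerances while keeping the suite fast.

# Known limitations

* GFF3 input is not supported (GTF only), and no liftover between
  assemblies is provided; annotations must be on a shared assembly
  before comparison.
* Quantification itself (read counting, TPM/FPKM computation) and DE
  testing are upstream of this package and consumed as standard-format
  inputs.
* The average-CV estimator's small-sample bias (above) means absolute CV
  values at 2–3 replicates understate the population noise CV; use it
  comparatively.
* `harmonize()` does not attempt to reconcile gene *models* across
  annotations (merging isoforms, resolving symbol clashes); it only
  makes catalogues comparable at the contig/biotype level.
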