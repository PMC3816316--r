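# annoimpact

Quantifying how the choice of genome annotation affects RNA-seq
expression estimates.

## The problem

At least six gene catalogues are publicly available for the human genome
(AceView, Ensembl, H-InvDB, RefSeq, UCSC Known Genes, Vega), and they
disagree substantially: the largest annotates roughly three times as many
genes and six times as many isoforms as the smallest. Any RNA-seq analysis
must pick one of them, and the pick propagates through every downstream
stage — read mapping, expression quantification, and differential
expression calling.

`annoimpact` implements a complete assessment framework around the notion
of **annotation complexity**, defined as proportional to an annotation's
number of genes, isoforms and exons. Each category is ranked across
annotations by decreasing count (rank 1 = largest); the complexity rank of
annotation *j* is the mean of its three category ranks, with ties broken
by the mode of the ranks. The impact of complexity is then measured per
pipeline stage:

- **Mapping** — classification of reads / read pairs into mapping-outcome
  categories (uniquely mapped, non-uniquely mapped, unmapped; for pairs
  additionally uniquely/non-uniquely mapped singletons), and the split of
  mapped units into annotated vs. un-annotated genomic sequence.
- **Quantification** — stability of expression estimates across technical
  replicates, as the average coefficient of variation over elements *i*
  with replicate mean x̄ᵢ and sample standard deviation Sᵢ:

  AvgCV = ½ ( (1/n) Σᵢ Sᵢ/x̄ᵢ |cond₁ + (1/n) Σᵢ Sᵢ/x̄ᵢ |cond₂ )

  plus the percentage of *present* elements (nonzero in ≥ 1 replicate),
  over the subgroups all genes / common genes / uncommon genes / all
  isoforms, where common genes are the HGNC-symbol intersection across
  annotations.
- **Differential expression** — concordance of RNA-seq log₂ fold-changes
  with RT-qPCR ground truth: average absolute deviation
  AAD = (1/n) Σ |FC_RNA-seq − FC_RT-qPCR|, RMSE, the correlation
  coefficient, and the overlap of top-*k* differentially expressed genes
  between annotations.

A deterministic synthetic-data generator produces GTF annotations of
controlled complexity, SAM alignments with exact category composition,
and replicate expression matrices with known noise, effects and matched
RT-qPCR-style fold-changes — so the whole pipeline is testable against
planted ground truth without any external download.

## Worked example

```r
library(annoimpact)

# --- rank the six public human catalogues from their summary counts ----
tab <- read.delim(system.file("extdata", "human_annotation_summary.tsv",
                              package = "annoimpact"))
profiles <- lapply(seq_len(nrow(tab)), function(i)
  complexity_profile_counts(tab$source[i], tab$n_genes[i],
                            tab$n_isoforms[i], tab$n_exons[i]))
rank_complexity(profiles)
#>   source_name gene_rank isoform_rank exon_rank average_rank mode_rank final_rank
#> 1     AceView         1            1         1     1.000000         1          1
#> 2     H-InvDB         4            2         2     2.666667         2          2
#> 3     Ensembl         2            3         3     2.666667         3          3
#> 4        Vega         3            4         4     3.666667         4          4
#> 5        UCSC         5            5         5     5.000000         5          5
#> 6      RefSeq         6            6         6     6.000000         6          6
```

H-InvDB and Ensembl tie on average rank 2.67; the mode of their ranks
(2 vs. 3) puts H-InvDB ahead, giving the complexity order AceView,
H-InvDB, Ensembl, Vega, UCSC, RefSeq.

```r
# --- a synthetic pipeline run with planted ground truth ----------------
cfg  <- simulation_config(seed = 7, reads = list(n = 1000))
anns <- simulate_annotations(cfg)          # six annotations, 120-gene core
sim  <- simulate_alignments(cfg, anns$srcF)
classify_mappings(read_alignments(sim$sam))
#> MappingTally (paired-end, 1000 units)
#>   uniquely_paired                     727  ( 72.7%)
#>   non_uniquely_paired                 128  ( 12.8%)
#>   uniquely_mapped_singleton            81  (  8.1%)
#>   non_uniquely_mapped_singleton        14  (  1.4%)
#>   unmapped                             50  (  5.0%)

ex <- simulate_expression(cfg, anns$srcF)
average_cv(ex$matrix)        # replicate stability (Eq. above)
#> [1] 0.1678397
present_percentage(ex$matrix)
#> [1] 90

tbl <- fold_change_table(log2_fold_change(ex$matrix), ex$qpcr)
concordance_stats(tbl)
#> ConcordanceStats (n = 108)
#>   AAD  0.272
#>   RMSE 0.331
#>   r    0.946
```

The tally reproduces the generator's design exactly (5% unmapped, 15%
multi-mapped among mapped units, 10% singletons); the present percentage
recovers the planted 10% absent fraction; the concordance statistics
reflect the configured replicate CV of 0.2 and RT-qPCR noise SD of 0.25.

For real data, `parse_gtf()` + `harmonize()` ingest any GTF annotation,
`read_alignments()` ingests SAM/BAM, and `read_expression()` ingests
TSV expression tables; see the methods vignette
(`vignettes/annotation-impact.Rmd`) for the full model description.

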