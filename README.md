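# txatlas

Characterization of multi-tissue RNA-seq expression atlases.

When a transcriptome is profiled across many cell and tissue types — for
example a livestock atlas spanning intestinal tissues, immune cells and
reproductive tissue — the first questions are structural, not differential:
How much of the annotation is actually expressed, and of which biotypes?
Which genes and long non-coding RNAs are restricted to a single tissue? How
many isoforms does a typical gene use? And where do opposite-strand gene
pairs — overlapping antisense partners and head-to-head promoter pairs —
switch between co-expression and mono-expression across tissues? `txatlas`
answers these questions from two standard inputs: a GTF annotation and
transcript-level TPM (plus optional gene-level count) matrices with a
sample-to-tissue grouping.

## Methods at the core

* **Expression calling.** A feature is *expressed* in a tissue iff its
  replicate-averaged TPM is strictly greater than 0.5. Detection percentages
  are `100 · detected / annotated`, rounded half-away-from-zero to one
  decimal.
* **Normalization.** Median-of-ratios size factors: for sample *j*,
  `s_j = median_g ( K_gj / (∏_j K_gj)^(1/m) )` over features *g* with
  all-positive counts, rescaled to unit geometric mean.
* **Tissue specificity.** For a gene with cross-tissue profile *x*, let
  `p_i = x_i / Σx`. The Shannon entropy `H = −Σ p_i log2 p_i` (bits) is
  turned into a specificity score `S = log2(T) − H` over *T* tissues: a
  single-tissue gene scores `log2 T`, a uniformly expressed gene scores 0.
* **Opposite-strand geometry.** Antisense pairs are genes on opposite
  strands whose spans overlap by ≥ 1 bp (1-based inclusive:
  `min(end) − max(start) + 1`); head-to-head (H2H) pairs are opposite-strand
  genes whose TSSs lie within 1 kb (inclusive). Pairs are classified as
  PC–PC, PC–lncRNA, lncRNA–lncRNA or other, and per tissue as co-expressed
  (both members on), mono-expressed (exactly one) or silent.
* **Isoform statistics.** Expressed-isoform counts per gene per tissue, mean
  isoforms per expressed gene, a 1/2/3/4+ histogram, and the genes with ≥ 4
  expressed isoforms in *every* tissue.

A synthetic-data generator (`simulate_atlas()`) emulates the study design —
10 tissues in duplicate, mixed biotypes, planted antisense/H2H pairs,
planted 100× tissue-specific genes over negative-binomial noise, planted
high-isoform genes — and records complete ground truth, so every stage is
validated by parameter recovery.

## Worked example

```r
library(txatlas)
cfg <- generator_config(seed = 42)         # 10 tissues x 2 reps, 1000 genes
sim <- simulate_atlas(cfg)
res <- characterize_atlas(sim$annotation, sim$tpm, counts = sim$counts)
print(res)
#> atlas_characterization over 10 tissues at TPM threshold 0.5
#>   detected genes: 1000 / 1000 (100.0%)
#>   detected transcripts: 1233 / 1234 (99.9%)
#>   antisense-overlap pairs: 10 | head-to-head pairs: 5
#>   mean isoforms per expressed gene: 1.23 - 1.23
```

The 10 planted antisense pairs and 5 planted H2H pairs are found exactly;
the mean of ~1.23 isoforms per expressed gene reflects the generator's
mostly-single-isoform annotation. The specificity table ranks the planted
single-tissue genes first, each at the maximal score `log2(10) ≈ 3.32` bits:

```r
head(res$gene_specificity$table, 3)
#>   feature_id entropy    score rank
#> 1     G00005       0 3.321928    1
#> 2     G00046       0 3.321928    2
#> 3     G00081       0 3.321928    3
```

Detection arithmetic on real atlas-scale numbers — e.g. 17,872 detected of
24,356 annotated genes:

```r
detection_percentage(17872, 24356)
#> [1] 73.4
```

`write_characterization(res, sim$annotation, "out/")` exports all summary
tables as TSV plus BED-like pair intervals.

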