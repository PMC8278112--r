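---
title: "Characterizing a multi-tissue expression atlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a multi-tissue expression atlas: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txatlas)
```

# The problem

A transcriptome atlas profiles the same genome across many cell and tissue
types with replicated bulk RNA-seq. `txatlas` implements the descriptive
layer of such a study: which annotated genes and transcripts are expressed
where, of which biotypes, how tissue-restricted their expression is, how
many isoforms genes use, and how opposite-strand gene pairs behave across
tissues. It deliberately stops before differential expression and functional
enrichment, which belong to dedicated tools.

All genomic arithmetic uses the GTF-native convention — 1-based, inclusive
at both ends — end to end. Overlap length between two spans is
`min(end) − max(start) + 1`; output BED files alone convert to 0-based
half-open coordinates.

# Expression calling

Transcript-level TPM values are averaged arithmetically over each tissue's
replicates, and a feature is called expressed in a tissue iff that average
is **strictly greater than** the threshold (default 0.5 TPM). The boundary
matters and is pinned by tests: an average of exactly 0.5 is *not*
expressed. A gene is expressed iff at least one of its transcripts is,
unless a gene-level TPM matrix is supplied, which then takes precedence —
this makes the transcript-to-gene projection deterministic.

Detection percentages are `100 · detected / annotated`, rounded
half-away-from-zero to one decimal (`round_half_up()`); base R's
round-half-to-even would print 0.2 where this pipeline prints 0.3, so the
rule is explicit and tested.

# Count normalization

Cross-tissue comparisons of counts use median-of-ratios size factors,
computed from first principles rather than by calling an external package:
features with a zero count in any sample are excluded (their geometric mean
is zero), each remaining feature's counts are divided by its geometric mean
across samples, and the factor of sample *j* is the median of those ratios
in column *j*. Two numerical choices are deliberate:

* Factors are rescaled to unit geometric mean. The median-of-ratios formula
  fixes factors only up to scale; centering makes normalization idempotent
  (the factors of an already-normalized matrix are exactly 1, a tested
  identity) without changing any ratio between samples.
* The median is the ordinary sample median of ratios. Implementations that
  take the median in log space differ only when the usable feature count is
  even (geometric vs arithmetic mean of the two middle ratios); the test
  suite cross-checks against DESeq2's estimator on an odd-sized problem
  where both definitions coincide exactly.

A matrix in which *no* feature has all-positive counts has no
median-of-ratios factors; this is an error, and no pseudo-reference fallback
is attempted.

# Tissue specificity by Shannon entropy

For profile *x* over *T* tissues with `p = x / Σx`, the entropy
`H = −Σ p log2 p` is reported in bits (`0·log 0 = 0`). The specificity score
is `S = log2(T) − H`, so single-tissue expression scores `log2 T` and
uniform expression scores 0. Log base 2 is pinned for test exactness; any
base gives the same ranking.

"Most specific" is operationalized as highest *S* (equivalently lowest
entropy). The alternative reading — ranking by raw entropy — is exposed via
`direction = "least_specific"`, since descriptions of such rankings are
ambiguous between the two conventions; the two orderings are exact reverses
of each other up to the tie rule. Ties are broken lexicographically by
feature id so results are identical across platforms.

The intended input is the replicate-averaged, size-factor-normalized gene
count matrix; TPM profiles are accepted as an alternative when counts are
unavailable. Features with zero total expression are removed before scoring
(their entropy is undefined), and requesting more top features than exist
returns all of them with a warning.

Isoform-level specificity adds two filters before scoring: the parent gene
must be expressed in at least two tissues (otherwise every isoform of a
single-tissue gene would trivially top the ranking), and the isoform itself
must pass the expression call somewhere.

# Opposite-strand gene pairs

Two relations are detected between genes on the same chromosome and
opposite strands:

* **Antisense overlap** — spans overlap by ≥ 1 bp. The overlap substrate is
  the full gene span (TSS to TES): transcript-level or UTR-level overlap
  would require coordinates the pipeline does not otherwise model, so the
  span is the deliberate, simplest-consistent choice.
* **Head-to-head (H2H)** — TSSs within 1 kb, *inclusive* at exactly
  1000 bp. The TSS is the strand-dependent 5′ end of the span. No
  divergent-orientation requirement is imposed, because TSS proximity and
  opposite strandedness are the two defining criteria; orientation
  (divergent/convergent) is emitted as a column so users can filter. The
  same unordered pair may hold both relations; they are kept separately.

Pairs are unordered and stored with `gene_a < gene_b`; counts are counts of
*pairs*, so one gene in two overlaps contributes two pairs. Biotype
categories are PC–PC, PC–lncRNA and lncRNA–lncRNA, with every combination
involving any other biotype collapsed to "other"; unknown biotype strings
are an error rather than silently re-bucketed.

Overlap detection goes through an interval index (`GenomicRanges`); H2H
detection is a sorted TSS sweep. Either way the contract is exact equality
with an exhaustive all-pairs scan, which the test suite enforces on random
annotations of up to 500 genes across 20 seeds.

Per tissue, each pair is exactly one of co-expressed / mono-expressed /
silent — a partition identity the tests assert — and a pair is "unique" to a
tissue for a status iff it holds that status in exactly one tissue.

# Isoform statistics

Expressed-isoform counts per (gene, tissue) use the same strict call. The
per-tissue mean is taken over genes with **at least one expressed isoform**:
with zero-isoform genes in the denominator the familiar ~1.1–1.2
isoforms-per-gene figures of bulk atlases would be unreachable, so the
denominator choice is explicit. The histogram buckets 1, 2, 3 and 4+, and
"high-isoform genes" are those with ≥ k (default 4) expressed isoforms in
*every* tissue. Direct counting over annotated transcripts replaces any
assembly step; novel-isoform discovery is out of scope.

# The synthetic generator

`generator_config()` defaults encode the emulated study design: 10 tissues
(given the study's tissue names) × 2 replicates, 1000 genes on one synthetic
chromosome, biotype proportions protein_coding 0.69 / lncRNA 0.23 /
remainder split over the other 13 biotypes, isoform distribution
P(1, 2, 3, 4+) = (0.80, 0.15, 0.04, 0.01), 10 planted antisense pairs, 5
planted H2H pairs with TSS gaps drawn from 1–1000 bp, 3 planted
tissue-specific genes per tissue at 100× enrichment, negative-binomial
dispersion 0.1, and lognormal (meanlog log 50, sdlog 1) background means.

Design details that make ground truth exact rather than approximate:

* Layout places units (single genes, antisense pairs, H2H pairs) left to
  right with inter-unit gaps > 1 kb, so no accidental overlaps or TSS
  adjacencies can arise; generation asserts that the finders see exactly
  the planted pairs before returning.
* Planted antisense pairs overlap tail-to-tail with both members ≥ 1.5 kb
  long and overlap ≤ 1 kb, which keeps their TSSs > 1 kb apart — a
  divergently overlapping pair would otherwise also register as H2H and
  break exact H2H recovery.
* The 4+ isoform mass is realized by planting `round(0.01 · n_genes)`
  high-isoform genes (4–6 isoforms, near-uniform Dirichlet(10) usage, high
  mean everywhere); background genes draw 1–3 isoforms. Hence "genes with
  ≥ 4 isoforms in every tissue" has an exact expected answer.
* Tissue-specific genes are suppressed to a mean of 0.001 counts outside
  their target tissue (average TPM ≤ 0.5 there with ≥ 95% probability per
  gene) and raised to `2 × fold_enrichment` mean counts inside it, giving
  near-zero entropy. A single base mean literally multiplied by the fold
  change in one tissue could not satisfy both the on-tissue-called and
  off-tissue-silent contracts at once, so suppression and enrichment are
  parameterized separately.
* Transcript TPMs split gene counts over a per-gene Dirichlet usage simplex
  and normalize each sample to 10^6. Transcript lengths are treated as
  equal: length bias is irrelevant to what the downstream stages test.
* The annotation stream seeds with `seed` and the expression stream with
  `seed + 1`, so each generator stage is independently reproducible (same
  configuration ⇒ byte-identical GTF and identical matrices) while a full
  simulation remains a pure function of one seed.

What the generator does **not** emulate — and what passing recovery tests
therefore do not show about real data: genomic clustering of genes and
nested/multi-way overlaps, transcript-length and GC bias, library-size
variation between samples, partial detection (at the defaults essentially
the whole synthetic annotation is expressed, unlike the ~63–73% detection of
a real atlas), correlated replicates, and isoform switching between tissues
(usage is constant across tissues, so isoform specificity mirrors gene
specificity rather than having planted isoform-level truth).

# Problem sizes and runtime choices

The test suite and the acceptance script sweep 20 seeds of the default
1000-gene, 10×2-sample configuration for recovery checks, use 120-gene
4-tissue simulations for contract tests, and stress the pair finders against
brute force on random annotations of 50–500 genes; these sizes give stable
recovery statistics while keeping a full run in tens of seconds.

# Known limitations

* Strand vocabulary is strictly `+`/`−`; unstranded features are rejected.
* UTR-resolved overlap and exon-level models are not implemented; overlap
  is span-based by design (see above).
* Detection summaries at gene level depend on the annotation's
  transcript-to-gene mapping when only transcript TPMs are supplied.
* `sample_similarity()` operates on normalized counts or TPM as given;
  no variance-stabilizing transform is applied, which is an assumption
  rather than a reproduction of any particular tool's default.
* There is no shell entry point: the exported functions,
  `characterize_atlas()` and `write_characterization()` are the interface.
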