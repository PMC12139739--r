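---
title: "Evaluating single-cell long-read RNA-seq libraries with sclrqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating single-cell long-read RNA-seq libraries with sclrqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclrqc)
```

## The problem

Single-cell long-read RNA-seq (sclrRNA-seq) promises isoform-level
expression per cell, but droplet chemistries were optimised for short
fragments: reads are routinely far shorter than the transcripts they come
from, 3' chemistries suffer internal priming at A-rich internal sites, and
only a fraction of reads can be assigned to a specific transcript isoform.
Whether a library supports transcript-level analysis is therefore an
empirical question about that library. `sclrqc` computes the evaluation
quantities that answer it, directly from the tagged BAM files that
single-cell long-read preprocessing pipelines emit (cell barcode `CB`, UMI
`UB`, gene `GN` and transcript `TR` auxiliary tags), plus the downstream
usage/concordance summaries computed from the paired gene- and
transcript-level count matrices.

Every computation is exercised against a built-in simulator with known
ground truth, so the package is fully testable without sequencing data.

## Read-level QC

`scan_bam()` yields one row per primary record (secondary 0x100 and
supplementary 0x800 records are dropped) whose mean per-base phred quality
is strictly greater than `min_qscore = 7`. The quality statistic is the
arithmetic mean of the stored base qualities; upstream pipelines filter
nanopore reads at "quality over 7", and we apply the threshold strictly, so
a read at exactly 7 fails. Tag values `"-"` and `""` are sentinels for
"not assigned".

`read_length_summary()` reports mean, median and mode of query-sequence
lengths for four nested read classes: all primary reads, barcode-matched
reads, and (within the barcode-matched set) gene-tagged and
transcript-tagged reads. Read lengths are effectively continuous, so the
mode is only defined relative to a binning rule: we use 50 bp histogram
bins (configurable) and report the modal bin's midpoint, ties going to the
shortest bin.

`identification_rates()` gives the fraction of reads with a gene tag, with
a transcript tag, and with neither; gene-only, transcript and neither
partition the reads. `gene_read_fraction()` measures how much of the
library a target gene set consumes — in pancreatic islets the two insulin
genes can take a quarter of all reads, which motivates targeted depletion —
and `depletion_report()` compares a pre/post library pair:

- efficiency = 1 − (post target fraction) / (pre target fraction),
  reported as undefined when the pre fraction is zero;
- an off-target table of per-gene fraction changes, ranked by absolute
  change, which should be near zero for a specific depletion.

The default denominator is all quality-passing primary reads ("fraction of
total reads"); `denominator = "gene_tagged"` covers the alternative
reading. Note a subtlety of fraction-based efficiency: removing target
reads also shrinks the denominator, so removing 95% of a gene that held a
large share of the library yields an efficiency slightly below 0.95; the
two coincide as the target share becomes small.

`compare_read_lengths()` wraps the one-sided Wilcoxon rank-sum test
(normal approximation with tie correction — lengths are integers with
heavy ties) with the default alternative "the second library's reads are
stochastically longer".

## Transcript coverage metaplots

The coverage pipeline follows a fixed order, enforced by a `stage`
attribute on the matrix:

1. `dedup_reads()` — keep retained-cell barcodes, one read per
   (barcode, UMI), longest alignment wins, ties to the first read in
   coordinate order.
2. `transcript_coverage()` — per transcript, reads covering each
   spliced-mRNA position (pileup over the alignment's reference span;
   reads are transcript-space alignments, so positions are already
   strand-resolved, 5'→3').
3. `rescale_to_100()` — base `p` of a length-`L` transcript maps to bin
   `floor(p·100/L)`; the bin value is the mean of its bases. For `L < 100`
   empty bins are linearly interpolated between occupied neighbours.
4. `coverage_matrix()` — stack rows for transcripts with more than one
   exon. Single-exon transcripts are excluded throughout: their coverage
   shape cannot distinguish priming artifacts from annotation choices.
5. `normalize_and_softmax()` — divide by the library's retained read
   count, then softmax each row
   (`exp(x_i) / sum_j exp(x_j)` over the 100 bins).
6. `meta_coverage()` — column means over transcripts passing exon-count
   and length filters; the curve sums to 1.

Softmax is not scale-invariant, so depth normalisation before softmax
materially changes the output; the ordering is locked by a characterization
test. An all-zero transcript softmaxes to the uniform row (each bin 0.01)
and is flagged rather than dropped, which keeps matrices from different
samples row-compatible.

Two open choices were resolved as defaults with switches: the read-depth
denominator is the sample's total retained (post-dedup) read count, and
coverage uses all primary alignments rather than only
uniquely-assigned-transcript reads. Neither choice affects the simplex
invariants; both are documented at the function level.

A 5'-anchored chemistry piles softmax mass onto the first bins and a
3'-anchored one onto the last bins; internal priming moves mass toward the
centre. The package validates this signature on simulated libraries with a
sign test over the outer 25 bins of the two curves.

## Junction-bias classification

Transcript coordinates run 5'→3' along the spliced mRNA; for a minus-strand
transcript, position 0 is the end of the genomically last exon.
`extract_junctions()` places each exon-exon boundary at the offset of the
downstream-in-mRNA exon and attaches a genomic key
(chrom:donor-acceptor:strand), identical wherever the same splice event
recurs. A junction is *isoform-defining* (`unique_junctions()`) iff its key
occurs in exactly one transcript of its gene; uniqueness is deliberately
scoped within the gene, the only scoping under which "unique" implies
"identifies the isoform".

`classify_transcript()` bins a transcript by its unique junctions' relative
positions `r = position / length`: `r < 0.25` is the 5' region,
`r >= 0.75` the 3' region, the rest central (half-open boundaries, so a
junction at exactly 0.25 of the length is central). Occupancy of the end
regions decides the bin — `both_ends` when both are hit, an end bin when
exactly one is hit (end regions take precedence over central, which is the
residual category), `central` when only the middle is hit, `none` without
unique junctions. `strict = TRUE` disables precedence and emits composite
labels such as `five_prime+central`. `bias_table()` tabulates bins,
optionally weighted by per-transcript read counts, since bulk bias
summaries can be dominated by a few highly expressed transcripts.

## Pseudobulk usage and clustering concordance

`pseudobulk()` sums counts within (cell type × replicate) groups
(features × cells in, features × groups out; totals over labelled cells are
conserved exactly). `usage_fractions()` divides each transcript's
pseudobulk count by its gene's total within the group: per (group, gene)
the fractions form a simplex, and genes with zero counts in a group are
flagged absent instead of zero-divided. These fractions are the
differential-transcript-usage quantity; the statistical testing itself
(DRIMSeq-style models, DESeq2, batch correction) is out of scope — this
package produces the matrices those tools consume.

`confusion_matrix()` cross-tabulates two labelings over their shared
barcodes. `concordance_scores()` turns the matrix into per-class scores by
matching each column class (transcript-based cluster) to a row class
(gene-based cluster). The field reports concordance without fixing a
matching rule, so we define it explicitly: default `argmax` matching is
many-to-one (each transcript-cluster takes the gene-cluster it shares most
cells with; ties resolve toward the larger gene-cluster, then
lexicographically — deterministic), which scores two subclusters of one
gene-cluster at 100% each; the `hungarian` alternative (optimal one-to-one
assignment) leaves surplus classes unmatched with `NA`. Both directions of
normalisation are available by transposing the inputs.

## The simulator

`generate_transcriptome()` builds a deterministic toy annotation: each gene
owns an exon scaffold, transcripts take the first scaffold exon plus a
random subset of the rest, so multi-transcript genes share exons and
skipped exons create isoform-defining junctions; both strands are always
represented. `simulate_reads()` draws reads under a `library_profile()`:

- retained length ~ Normal(`truncation_mean_bp`, `truncation_sd_bp`)
  clipped to `[1, L]`, anchored at the configured capture end — the
  simplest model that reproduces the observed 5'/3' metaplot asymmetry;
- with probability `internal_priming_rate` the read instead starts at a
  uniform internal position and runs to the 3' end, emulating oligo-dT
  mispriming;
- barcodes are drawn uniformly from the whitelist; UMIs are unique per
  read unless a collision rate is set (collisions reuse a previous UMI of
  the same cell, so deduplication is testable in both regimes);
- gene tags are emitted at `gene_tag_rate` and transcript tags at marginal
  rate `transcript_tag_rate`, nested so a transcript tag never occurs
  without a gene tag;
- an optional dominant gene receives an exact Bernoulli fraction of reads,
  emulating the insulin situation;
- base qualities are constant (default Q12), so the Q>7 filter can be
  exercised from both sides;
- reads are written as ungapped transcript-space alignments (one reference
  per transcript), since every downstream computation here operates on
  transcriptome alignments; expression weights default to lognormal(0, 1)
  draws, a simple skewed expression distribution.

`simulate_count_matrices()` draws per-cell transcript counts multinomially
from cluster-specific weights (gene expression × within-gene proportions),
derives the gene matrix by exact aggregation, plants cluster structure via
marker genes (4-fold, 10% of genes per cluster by default) and plants pure
usage shifts via `effects` — named genes get different transcript
proportions in named clusters while the gene-level expectation stays flat
(effect genes are excluded from marker selection).

All randomness flows through one seeded generator per call
(`withr::with_seed`), so identical seeds give byte-identical GTF/TSV
outputs and identical BAM record streams; the caller's RNG state is never
touched.

What the simulator does not emulate: nanopore base-calling error profiles,
PCR amplification noise, spliced genomic alignment, barcode sequencing
errors, or empty droplets. Passing tests therefore validate the
*computations* — counting, normalisation, classification, aggregation,
matching — not the upstream pipeline behaviour on real noisy data.

## Numerical choices and problem sizes

Simplex checks use a 1e-9 tolerance; softmax uses the standard max-shift
for numerical stability. The package's own validation runs at sizes chosen
to keep binomial/multinomial noise well inside the asserted tolerances:
100,000 reads for the dominant-gene fraction (3 binomial sd ≈ 0.4
percentage points), 20,000 reads for tag-rate recovery, 5,000 reads per arm
for the chemistry-separation sign test and the rank-sum comparison (100
seeded repetitions), and 300 cells × 4,000 counts for usage-swap recovery
within 0.02.

## Limitations

- Coverage currently counts reads over their full alignment reference
  span; CIGAR deletions are included, soft-clips excluded. Split/spliced
  transcript-space alignments are not expected.
- `classify_transcript()` takes annotated junctions; read-supported novel
  junction discovery is out of scope.
- Concordance is a descriptive matching score, not a statistical test of
  clustering agreement.
- The knee-point style cell calling of droplet pipelines is not
  reimplemented; retained-cell sets are inputs.
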