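# sclrqc

Quality control and isoform-usage analytics for single-cell long-read
RNA-seq (sclrRNA-seq), computed directly from the tagged BAM files and
count matrices that single-cell long-read preprocessing pipelines produce.

Long-read droplet libraries rarely deliver full-length transcripts: reads
are truncated, 3' chemistries suffer internal priming, and only a fraction
of reads can be assigned to a specific isoform. `sclrqc` quantifies how a
library actually performs:

- **Tag-stratified read lengths** — mean / median / modal-bin length for
  all primary reads, barcode-matched reads, gene-tagged (`GN`) and
  transcript-tagged (`TR`) reads, after the strict mean-base-quality > 7
  filter; one-sided Wilcoxon rank-sum comparison between libraries.
- **Identification rates** — fractions of reads with a gene tag, a
  transcript tag, or neither.
- **Targeted depletion** — share of reads consumed by a target gene set
  (e.g. insulin in islets) and depletion efficiency
  `1 − post_fraction / pre_fraction` with an off-target shift table.
- **Coverage metaplots** — per-transcript coverage in spliced-mRNA
  coordinates, rescaled to 100 relative positions, depth-normalised, then
  row-wise softmax (`exp(x_i)/Σ_j exp(x_j)`, each transcript summing to 1),
  averaged into a metagene curve over multi-exon transcripts with optional
  exon-count and length filters. 5'- vs 3'-anchored chemistries enrich
  opposite ends of the curve; internal priming fills the centre.
- **Junction bias** — isoform-defining splice junctions (genomic junction
  unique within its gene) classified by relative position: 5' (first 25%
  of the transcript), 3' (last 25%), central, both ends, or none.
- **Pseudobulk usage & concordance** — counts aggregated per
  (cell type × replicate); per-gene transcript-usage fractions (the
  differential-transcript-usage quantity, a simplex per group × gene);
  confusion matrices and argmax/Hungarian concordance scores between
  gene-level and transcript-level clusterings.
- **A seeded simulator** — toy GTF annotations, tagged transcript-space
  BAMs with controllable truncation (5'/3'-anchored, internal priming),
  tag rates, a dominant gene, UMI collisions, and paired gene/transcript
  count matrices with planted clusters and pure usage shifts — every
  analysis is testable against known ground truth, offline.

## Worked example

```r
library(sclrqc)

txome <- generate_transcriptome(n_genes = 8, transcripts_per_gene = c(2, 3),
                                exons_per_transcript = c(2, 6), seed = 42)
profile <- library_profile("five_prime", truncation_mean_bp = 500,
                           truncation_sd_bp = 150, gene_tag_rate = 0.75,
                           transcript_tag_rate = 0.5,
                           dominant_gene_id = "GENE003",
                           dominant_gene_fraction = 0.25, seed = 42)
sim <- simulate_reads(txome, profile, n_reads = 20000)

reads <- scan_bam(sim$bam, barcode_set = profile$barcode_whitelist)
read_length_summary(reads)
#>   class                 n mean_bp median_bp mode_bp
#> 1 all_primary       20000    475.       469     425
#> 2 barcode_matched   20000    475.       469     425
#> 3 gene_tagged       15041    475.       470     425
#> 4 transcript_tagged 10031    475.       470     425

identification_rates(reads)
#>       n frac_gene_identified frac_transcript_identified frac_gene_only frac_neither
#> 1 20000                0.752                      0.502          0.250        0.248

gene_read_fraction(reads, "GENE003")$fraction
#> [1] 0.1947    # 25% of reads from GENE003 x 75% gene-tag rate
```

The read-length table shows what the library delivers per tag class (the
modal 50 bp bin midpoint is 425 bp here, against a 500 bp truncation mean);
the identification rates say that 75% of reads were assigned a gene but
only 50% a transcript — the gap that decides whether isoform-level
analysis is feasible. The dominant-gene share recovers
fraction × tag rate, the read-level quantity a depletion step would target.

Continuing to the coverage metaplot and junction bias:

```r
dd <- dedup_reads(reads, cells = profile$barcode_whitelist)
sm <- normalize_and_softmax(coverage_matrix(transcript_coverage(dd, txome), txome),
                            nrow(dd))
mc <- meta_coverage(sm, txome)
sum(mc$value[1:25]); sum(mc$value[76:100])
#> [1] 0.255     # 5' quarter of the curve
#> [1] 0.245     # 3' quarter
bias_table(classify_transcripts(txome))
#>   bin             n fraction
#> 1 five_prime      3    0.158
#> 2 three_prime     2    0.105
#> 3 central         7    0.368
#> 4 both_ends       2    0.105
#> 5 none            5    0.263
```

Softmax curves are near-uniform by construction (each transcript
contributes a simplex over 100 bins), so chemistry differences appear as a
small but systematic tilt — compare libraries with the sign test over the
outer 25 bins rather than by eye.

A command-line interface wrapping these functions ships in
`inst/cli/sclrqc.R` (`simulate`, `qc`, `coverage`, `bias`, `usage`,
`concordance` subcommands); given the same seed and configuration it
produces byte-identical outputs.

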