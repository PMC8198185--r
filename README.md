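# repairprime

Integrative analysis of nucleotide excision repair (XR-seq), gene
expression (RNA-seq) and chromatin accessibility (ATAC-seq) in a paired
cisplatin-sensitive / cisplatin-resistant cell-line system — for
computational biologists who want the downstream statistics of such a
study as tested, reusable R functions rather than one-off scripts.

## What it computes

Cisplatin forms bulky adducts, mostly at G-G dinucleotides, that are
removed by nucleotide excision repair as ~26-nt excised oligomers. XR-seq
sequences those oligomers, so each read marks a repaired lesion on a
specific strand. At a gene, reads on the strand opposite the annotated
gene strand lie on the transcribed (template) strand and report
transcription-coupled repair (TCR); same-strand reads report the
non-transcribed strand (global genome repair, GGR, has no strand bias).
The package quantifies this balance, relates repair to transcription and
accessibility, and calls genes "primed" for the cisplatin response in the
resistant line. Its core statistics:

* **TCR bias** — per-gene transcribed/non-transcribed strand counts, a
  paired Wilcoxon signed-rank test with Bonferroni correction, and the
  *TCR index*: median per-gene log2((TS + 0.5)/(NTS + 0.5)).
* **Strand-specific metaprofiles** — TSS-anchored (3 kb upstream / 5 kb
  downstream, 40-bp bins) and peak-anchored (length-scaled body, 3-kb
  flanks, 30-bp bins) mean signal per billion mapped reads with 95% CIs.
* **Negative-binomial differential expression** — median-of-ratios size
  factors, moderated method-of-moments dispersions, per-gene NB Wald
  tests, Benjamini–Hochberg adjustment, and classification at
  |log2FC| >= 1 and adjusted p < 0.05.
* **Reproducible ATAC peaks** — a pooled peak is kept only when every
  replicate's merged peaks cover strictly more than 50% of it; plus
  shared/unique peak-set comparison between conditions.
* **Primed genes** — the intersection of genes upregulated after
  treatment in the sensitive line with genes elevated at baseline in the
  resistant line, and the candidate subset with basal RPKM > 70.
* **Cross-assay correlations** — Spearman (repair vs expression over
  genes, repair vs accessibility over peaks) and windowed Pearson
  replicate correlation (700-bp windows).

A synthetic-data module (`sim_config()`, `simulate_genome()`,
`simulate_xrseq_reads()`, `simulate_rnaseq_counts()`,
`simulate_atac_replicates()`) generates genomes, reads, counts and
replicate peak sets with the statistical structure the analysis assumes,
together with ground truth, so every recovery claim is testable.

Everything is built on `GRanges`; inputs are BED6 (reads, genes, peaks),
TSV (counts, metadata), and flat key-value config files; outputs are TSV
tables, BED/bedGraph tracks, and a machine-readable summary.

## Worked example

The bundled configuration simulates a small two-cell-line study (60
genes, two 400-kb chromosomes, 10k repair reads per line with TCR
fractions 0.5/0.8, triplicate RNA-seq with 8 primed genes planted, 40
ATAC peaks) and runs the full chain:

```r
library(repairprime)
cfg <- system.file("extdata", "example_config.tsv", package = "repairprime")
summary <- run_pipeline(cfg, "example_run")
str(summary[c("tcr_index_sensitive", "tcr_index_resistant",
              "n_up_treatment", "n_primed", "n_peaks_control",
              "rho_repair_expression")])
#> $ tcr_index_sensitive  : num 3.36
#> $ tcr_index_resistant  : num 5.33
#> $ n_up_treatment       : int 16
#> $ n_primed             : int 8
#> $ n_peaks_control      : int 32
#> $ rho_repair_expression: num 0.656
```

Reading the output: the resistant line, simulated with a higher TCR
mixture fraction, shows the larger TCR index (5.33 vs 3.36 — its median
gene has ~40-fold versus ~10-fold more transcribed-strand repair reads);
16 genes are called upregulated after treatment, all 8 planted primed
genes are recovered at the intersection of the two contrasts; repair
correlates positively with expression across genes (Spearman rho = 0.66).
`example_run/` contains the full tables (DE results, strand counts,
profiles, peak comparisons, primed-gene records), BED/bedGraph tracks,
a resolved config copy, and `summary.tsv`; every file header records the
package version, config fingerprint and seed, and reruns with the same
config are byte-identical apart from the timing log.

## Package layout

* `R/intervals.R`, `R/genome.R` — strand-aware interval algebra (BED
  coordinates at the surface, `GRanges` inside).
* `R/simulate.R` — the synthetic-data generators and their configuration.
* `R/xrseq.R` — read filtering, TS/NTS assignment, the TCR bias test,
  metaprofiles, normalized tracks.
* `R/rnaseq.R` — counting, RPKM, the NB differential-expression chain,
  gene-length tests.
* `R/atac.R` — reproducible-peak merging and peak-set comparison.
* `R/prime.R` — primed-gene calling, candidate filtering, correlations.
* `R/pipeline.R`, `R/io.R` — the end-to-end driver and file formats.
* `vignettes/repairprime-methods.Rmd` — the model, its assumptions, all
  tunable parameters, and known limitations.
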