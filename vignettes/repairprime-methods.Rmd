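---
title: "Methods: strand-resolved repair, expression and accessibility integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-resolved repair, expression and accessibility integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairprime)
```

## The scientific setting

Cisplatin kills tumour cells by forming bulky intrastrand crosslinks,
predominantly at G-G dinucleotides. These adducts are removed by nucleotide
excision repair (NER), which excises a ~26-nt oligomer containing the
damage. NER has two damage-recognition routes: global genome repair (GGR),
which finds lesions anywhere and shows no strand preference, and
transcription-coupled repair (TCR), which is triggered by a stalled RNA
polymerase and therefore repairs the transcribed (template) strand of
active genes preferentially.

XR-seq sequences the excised oligomers, so each read marks a repair event
on a specific strand. At an annotated gene, reads on the strand *opposite*
the gene's annotated strand lie on the template strand and report TCR;
same-strand reads report the non-transcribed strand. The ratio of the two
is therefore a direct readout of the TCR/GGR balance, and comparing it
between a cisplatin-sensitive cell line and its resistant derivative asks
whether resistance is accompanied by a shift between the two repair
routes. The package integrates this repair readout with RNA-seq
differential expression (to find genes induced by cisplatin, and genes
constitutively elevated in the resistant line — "primed" genes) and with
ATAC-seq accessibility (GGR tracks open chromatin).

## Interval algebra

All coordinates facing the user are BED-convention (0-based, half-open);
internally every interval is a `GRanges` (1-based, closed) and the
conversion happens exactly once, in `bed_ranges()` and the BED I/O
functions. Overlap always means >= 1 bp; the one deliberate exception is
`overlap_fraction(a, b)`, the fraction of `a` covered by `b`, which is
asymmetric by design and is what the reproducible-peak rule consumes.

`nonoverlapping_tss_regions()` builds the strand-aware window spanning 3 kb
upstream and 5 kb downstream of each TSS and **drops both** members of any
overlapping window pair. Truncating instead of dropping would keep more
genes but make bins near the clash asymmetric between genes; dropping is
conservative and keeps every retained window geometrically identical.
Windows that would extend past a chromosome end are dropped for the same
reason.

The entire module is tested against per-base boolean-occupancy oracles
(naive loops over small genomes) on thousands of randomized instances;
agreement is exact, not approximate.

## Strand-resolved repair quantification

`filter_reads()` applies the post-alignment hygiene appropriate to
excision-repair libraries: reads on chrY/chrM are removed, exact
duplicates (same chromosome, start, end, strand) are collapsed to one, and
reads of 50 nt and longer are removed as untrimmed adapter artifacts —
genuine excision products are ~26 nt, so full-length reads indicate
read-through. The length cutoff is exposed (`max_length = Inf` keeps
everything) because the filtering convention differs between labs.

`tcr_bias_test()` is a paired Wilcoxon signed-rank test of per-gene
(TS, NTS) counts, with zero-difference pairs dropped and a normal
approximation with tie correction beyond 25 informative pairs. If every
pair is tied the test is degenerate; the function returns p = 1 with a
warning rather than failing, which is the behaviour a pipeline wants on a
pathological input. Bonferroni multiplication uses a caller-supplied
number of contrasts, because the number of panels displayed together is a
display decision, not a property of one test. The accompanying effect
size, the *TCR index*, is the median per-gene
`log2((TS + 0.5) / (NTS + 0.5))`; the Haldane–Anscombe pseudocount keeps
zero-count strands finite and makes the index antisymmetric under strand
swap.

Metaprofiles (`tss_metaprofile()`, `peak_profile()`) bin read midpoints.
The midpoint is taken `floor((width - 1) / 2)` bases inward from the
read's **5' end**, not as the floor of the arithmetic centre: for
even-length reads the latter choice is not symmetric under mirroring the
genome, whereas the 5'-anchored midpoint makes the TSS profile exactly
invariant under a coordinate flip with strand exchange (a property the
test suite checks bitwise). Signals are scaled to reads per billion mapped
reads; per-bin shading is a normal-approximation 95% confidence interval
for the cross-gene (or cross-peak) mean. Peak profiles rescale each peak
body into a fixed number of bins and report per-nominal-bin units so
bodies of different widths remain comparable with the fixed-width flanks.

## Differential expression

The DE chain is deliberately simple and fully specified:

1. **Size factors** — median-of-ratios over genes with nonzero counts in
   every sample, rescaled to geometric mean 1.
2. **Dispersion** — per-gene method-of-moments on normalized counts,
   `alpha = max(0, (s2 - m) / m^2)` with `s2` the pooled within-group
   residual variance, then moderated as
   `0.25 * alpha_gene + 0.75 * mean(alpha)`. The strong moderation and the
   untrimmed centre are calibration choices: at 2–3 replicates the raw
   moment estimate has ~4 residual degrees of freedom and is heavily
   right-skewed, so a trimmed centre is biased low and per-gene noise
   leaks into the Wald denominator; with the chosen weights the raw
   p-value rate at the 0.05 level on null NB data (2000 genes, 3 vs 3,
   dispersion 0.1) stays within [0.047, 0.063] across seeds in our
   simulations. The weight is exposed (`shrink`).
3. **Wald test** — per-gene NB maximum likelihood of the two group means
   at fixed dispersion and size factors (iteratively reweighted, a dozen
   vectorized iterations), `log2fc = log2(qB / qA)` with a pseudo-mean of
   0.5 normalized counts substituted for an all-zero group, standard
   error from the observed Fisher information of the log-mean, two-sided
   normal p-value. Genes with base mean < 1 are labelled `low_count` and
   excluded from testing and from the multiple-testing burden.
4. **BH adjustment** and **classification** at log2FC >= 1 (<= -1) and
   adjusted p < 0.05 — the boundaries are inclusive for the fold change
   and strict for the adjusted p, and are used identically in every
   contrast.

Numeric parity with external DE tools is a non-goal; calibration and
recovery are the contract. A test does cross-check size factors and
fold-change estimates against DESeq2 on a small simulated matrix, as an
independent reference, and agreement is close (correlation > 0.98 on
log2FC) without being bit-identical.

`length_distribution_test()` compares the gene lengths of a DE class
against all annotated genes by a two-sided Wilcoxon rank-sum test. The
background deliberately includes the class members — it is "class versus
annotation", the comparison a reader of a length-distribution figure
expects, not "class versus complement".

## Reproducible ATAC peaks and the primed-gene call

`reproducible_peaks()` keeps a pooled peak only when **every** replicate's
merged peak coverage spans **strictly more than** 50% of it. Reading the
rule as coverage of the pooled peak (rather than per-peak-pair overlap)
makes it independent of how a replicate fragments its calls and makes the
rule monotone: adding coverage to a replicate can never remove a retained
peak. The strictness of the boundary matters and is pinned by tests
(exactly 50% excludes).

A **primed gene** is one classified `up` in the treatment contrast within
the sensitive line *and* `up` in the resistant-versus-sensitive untreated
baseline contrast, both at the same thresholds; the primed set is exactly
the intersection of the two up-sets. Candidates additionally require mean
basal RPKM in untreated resistant samples strictly above 70. A looser
fold-only mode for the baseline condition is not enabled by default: using
the same classified threshold on both contrasts keeps the definition
symmetric and reproducible.

Cross-assay agreement is summarized by Spearman correlations (repair vs
expression over genes, repair vs accessibility over peaks) with average
ranks for ties and the usual t-approximation for the p-value, and by
windowed Pearson correlation between replicates (700-bp windows).

## The synthetic-data generators

The generators produce data with the statistical structure the analysis
assumes, plus ground truth, so every recovery claim in the test suite is
checked against known labels.

* **Genome** — i.i.d. sequence with `P(G) = sqrt(gg_rate)` so the expected
  G-G dinucleotide density equals `gg_rate` (default 0.042, the density
  implied by a ~41% GC human-like composition). Because cisplatin damage
  is approximately uniform in G-G density, damage is *implicit*: repair
  reads are drawn directly from the repair mixture rather than via an
  explicit damage-then-repair two-step, which collapses to the same
  read-level distribution. Genes get log-normal lengths (median 2 kb at
  desk scale), uniform non-overlapping placement, Bernoulli(0.5) strands,
  and a margin that keeps all TSS windows inside the chromosome.
* **Repair reads** — a two-component mixture with weight `theta`: TCR
  (gene sampled proportional to expression, position uniform in the body,
  strand = template strand) and GGR (position sampled proportional to
  accessibility — weight 10 inside peaks by default, only the ordering
  matters for the correlation properties — strand Bernoulli(0.5)). The
  per-read component is recorded. No quantitative `theta` is claimed for
  any real cell line; tests assert calibration at `theta = 0`,
  monotonicity of the TCR index in `theta`, and the forced 100% TS
  fraction at `theta = 1`.
* **RNA-seq counts** — four conditions (sensitive/resistant x
  control/cisplatin), NB with a common dispersion, log-normal baseline
  expression and log-normal library factors (sd 0.1) to exercise size
  factor estimation. Primed genes gain the treatment effect in
  sensitive-treated and the baseline elevation in both resistant
  conditions; additional up/down genes respond in sensitive-treated only.
  With `down_by_length` the downregulated set is sampled with probability
  proportional to gene length — the damage-load proxy: longer genes are
  likelier to carry a polymerase-blocking adduct — which is what makes
  the recovered down class significantly longer than background, the
  qualitative structure the analysis is meant to detect.
* **ATAC replicates** — true peaks of fixed width placed with at least
  3 kb of clear flank on each side (merged reproducible peaks are
  typically isolated; without the spacing, neighbouring peaks contaminate
  profile flanks and the measured enrichment is biased). Each replicate
  detects each true peak with probability `p_detect`, jitters both
  boundaries by rounded N(0, `jitter_sd`), and adds Poisson false peaks;
  the pooled call uses detection probability 1 with the same jitter, so
  that a perfect-detection, zero-jitter configuration reproduces the true
  peak set exactly.

What the generators do **not** model: sequencing errors and base
qualities, fragment-length structure beyond in-peak enrichment,
gene-level dispersion trends (dispersion is shared), multi-factor designs
and batch effects, and alignment artifacts. Passing tests therefore
demonstrate correctness and calibration of the downstream analysis, not
robustness to upstream noise sources.

## Determinism and problem sizes

Every generator seeds its own stream from `config$seed` plus a fixed
small offset, so a single seed makes the full pipeline a pure function of
its configuration: rerunning `run_pipeline()` with the same config yields
byte-identical outputs (only the timing log differs), and every output
file header records the tool version, a config fingerprint, and the seed.

Default problem sizes are desk-scale by design — a 2 x 2 Mb genome, 300
genes, tens of thousands of reads, 3 replicates per condition, 150 peaks
— large enough that the statistical checks in the test suite (type-I
rates within a few points of nominal, recovery of planted effects,
10x enrichment within the profile CI) are stable under their fixed seeds,
and small enough that the full suite runs in minutes. The calibration
claims quoted above were measured at those sizes; none of them are
assertions about any particular real dataset.

## Known limitations

* The Wald test is a two-group comparison; there are no GLMs, interaction
  terms, or outlier refitting. Contrasts that need covariates are out of
  scope.
* The dispersion model is moment-based with a single global shrinkage
  target; data with a strong mean-dispersion trend would be better served
  by a trend-fitted estimator.
* `nonoverlapping_tss_regions()` drops both members of a clash, so dense
  annotations retain few windows; this is intentional (see above) but
  means TSS profiles describe isolated genes only.
* The per-chromosome variant of per-billion normalization is not the
  default; `normalize_track()` normalizes by genome-wide mapped reads,
  standard practice for browser tracks.
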