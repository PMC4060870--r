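---
title: "Methods: cellular dissection of bulk skin transcriptomes"
author: "celldissect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cellular dissection of bulk skin transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each stage of the
pipeline, the parameters that matter, the design choices made where several
reasonable definitions exist, and what the synthetic-data tests do and do
not establish about real data.

## Detection and the expression substrate

The package operates downstream of normalization: inputs are gene × sample
matrices of log2 expression (one representative probe set per gene) plus
per-sample detection calls. Where probe-level data are available, a
detection call comes from a one-sided Wilcoxon signed-rank test of paired
perfect-match versus mismatch probe intensities (`detect_above_background()`),
using the exact null distribution for up to 25 probe pairs; tied or zero
differences fall back to the usual normal approximation, and an all-zero
difference vector returns p = 1 with a degeneracy flag. The test depends
only on PM − MM, so it is invariant to additive shifts common to both
probes. A gene is *skin-expressed* when detected in at least 10% of all
PP and PN biopsies combined; the boundary is inclusive. Batch-level
normalization itself (RMA and its QC metrics) is out of scope — QC enters
only as a per-sample metric table consumed by `qc_trim()`, which removes
`floor(fraction * n)` samples per tail per metric (default 2.5% per tail)
and unions the removal sets.

## Paired differential expression

Per patient, the fold-change of a gene is FC = 2^(PP − PN); the reported
statistic is the median FC over patients, with per-study medians retained.
Significance uses a Wilcoxon test with FDR control by Benjamini–Hochberg.
Two test modes exist because the natural reading of a rank-sum test
conflicts with the paired design: `rank_sum` (the default) compares the PP
sample group against the PN group, while `signed_rank` tests the per-patient
paired differences against zero. Both are exposed; neither is asserted to
be uniquely correct, and on the synthetic cohorts their operating
characteristics are nearly identical because pairing effects cancel in the
group contrast. A DEG call requires *three* simultaneous conditions:
q < 0.05, median FC strictly beyond the threshold (1.50 up, 0.67 down), and
a consistent direction of the median FC within every contributing study.
The *universal* response set further demands a strictly directional
per-patient FC in every patient — a patient at FC exactly 1 excludes the
gene.

## Candidate cell types

Relative expression is each gene's linear expression divided by its median
in normal skin (`normalize_to_reference()`), so 1.0 means "at skin level".
Assignment restricts first to *eligible* cell types — detection frequency
at least 10% in that type — and then takes the argmax of median relative
expression; with no eligible type the gene is `UNASSIGNED`. The
alternative order (argmax first, then unassign if under-detected) is
available via `eligibility = "after"`, but eligibility-first matches the
definition of "unassigned" as *not detected in ≥ 10% of samples for any
type*. Ties break by higher detection frequency, then lexicographically —
all tie-breaks in the package are deterministic and documented this way
(probe sets: id order; samples: sample-id order). Assignment specificity is
the *largest* p-value among the 9 two-sided rank-sum comparisons of the
assigned type's samples against each competitor: significance means even
the closest competitor differs. The test is two-sided; direction is already
implied by the argmax.

## Set statistics

The area statistic walks a ranked gene list, accumulating the fraction of
a gene set encountered, and averages the vertical gap between this curve
and the diagonal. It is exactly antisymmetric under rank reversal and
equals a location-normalized Mann–Whitney shift, so its p-value is the
two-sided rank-sum test of member versus non-member ranks; the sign of the
area carries the direction. Degenerate sets (empty, or the whole universe)
return area 0 and p 1 with a flag rather than an error. Bootstrap nulls
draw gene sets of the observed size without replacement and use add-one
p-values, `(1 + #{null ≥ obs}) / (n_boot + 1)`, so no empirical p is ever
zero. Fisher enrichment of assignments reports the sample cross-product
odds ratio (transposition-invariant) with the exact two-sided p.

## Signatures

A cell-type signature takes the k genes (default 250) with the largest
positive specificity margin — median log2 expression in the type minus the
best competing median — among genes detected in ≥ 10% of the type's
samples, weighted proportionally to the margin and normalized to sum 1.
The proportional-weight rule is this package's concrete choice for the
loosely specified idea that the most type-specific genes should carry the
greatest weight; it is linear, scale-free and has no extra parameters. A
patient's score is the weighted mean of log2 fold-changes over the
signature (so no change scores 0 and up/down are symmetric; a linear-scale
mode exists behind a flag), with significance from a rank-sum test of
signature versus non-signature fold-changes within that patient. When a
compendium cannot supply k positive-margin genes the builder raises a
shortfall error naming the available count; the pipeline builds signatures
with `allow_fewer = TRUE` and uses what exists. Hierarchical clustering
wraps `stats::hclust` (Euclidean/complete for patients,
Spearman-distance/average for genes); a constant row under the Spearman
metric is an error, not a silent NA.

## Co-expression networks and the knee

Partners of a target gene are ranked by Spearman correlation across the
candidate cell type's samples, keeping only r_s > 0. The network size N is
the knee of the descending correlation curve: plot (i/m, r_i^p / r_1^p)
for i = 1..m and take the rank minimizing Euclidean distance to the
origin. The axis normalization — rank fraction on x, power-transformed
correlation normalized by the top value on y — is this package's
definition of the otherwise underspecified "distance to the origin"; the
exponent p = 7 sharpens the bend but never changes the ranking itself.
Ties go to the smallest rank, and a single positive correlation gives
N = 1. Which genes are eligible for ranking is caller-supplied; the
pipeline uses genes expressed in both skin and the candidate cell type.

## Motif scanning and enrichment

PWMs are column-stochastic probability matrices with a total pseudocount
of 0.01 per column distributed according to the background frequencies
(A/C/G/T = 0.30/0.20/0.20/0.30, the intergenic composition the generators
also draw from). Windows are scored as summed log2 odds against that
background; a match requires at least 80% of the motif's maximum
achievable score. The 80% criterion is applied on the log-odds scale by
default, with a probability-scale variant (min–max normalized) behind
`score_scale = "prob"`. Both strands are scanned by scoring the
reverse-complement matrix at forward offsets, so all coordinates are
forward, 0-based, half-open. Windows containing `N` or soft-masked
(lower-case) bases are skipped. Overlapping matches of the same motif are
merged strand-agnostically and counted once; abutting (non-overlapping)
matches stay separate. One numerical subtlety: the maximum score is
accumulated column-by-column in the same order as window scores, so a
consensus window reaches the bound bit-exactly and `threshold_fraction = 1`
behaves as expected.

Enrichment of a motif in foreground versus background sequences is a
logistic regression of foreground membership on the per-sequence merged
match count with a penalized cubic-spline smooth on log10 sequence length
(GCV-selected smoothness, optionally a second smooth on GC). Only the
model family — semiparametric logistic with a smooth length adjustment —
is fixed; with fewer than 10 distinct lengths the smooth is unidentifiable
and the model reduces to plain logistic regression, recorded in the
result's `model` column. The statistic is the Wald z of the count
coefficient; motifs absent from every sequence return z = 0, p = 1,
flagged degenerate.

## Variants

LD uses squared Pearson correlation of genotype dosages (composite LD);
phased data should be collapsed to dosages first. Partners require
r² strictly above 0.90; monomorphic variants are excluded with a warning.
Allele effects rebuild the ±(L−1) window around a SNP under each allele
and take each allele's best window score fraction over both strands.
Classification is oriented by the *risk* allele: `abrogates` means the
non-risk allele has a match and the risk allele does not, `engenders` the
converse, `retained`/`none` when both or neither match — so a degenerate
ref = alt variant can never be an effect, and swapping allele labels
together with the risk orientation maps abrogates to engenders exactly.
Windows crossing a sequence boundary raise a truncated-window error rather
than silently scoring a shorter window. All SNP × motif pairs are
classified; enrichment enters only at the ranking stage, where changing
pairs are ordered by the motif's z (ties: smaller p, then motif id).
Candidate genes for a locus are the overlapping genes plus the nearest
gene on each side.

## The synthetic-data module

The generators are first-class, tested code and define the study
conditions: 60 patients in 3 study batches, 1000 genes with 5% planted up
and 5% down at a 2-fold shift, 0.3 log2 units of noise, per-gene baselines
uniform on 4–10 with 5% near-silent "off" genes; a 10-type compendium with
50 samples per type, 10% planted markers at a 2 log2-unit margin, and one
30-gene latent-factor co-expression module whose hub doubles as the
analysis target; ~300 intergenic sequences (lengths 0.5–1.5 × 500 bp,
background 0.30/0.20/0.20/0.30) with consensus occurrences of a 21-motif
dictionary planted at 0.5/kb — 4× that rate for the causal motif in
module-adjacent sequences — plus deliberately broken occurrences that the
engender-type causal SNP completes; and 60 SNPs in 5-SNP LD blocks over
100 individuals, with haplotypes copying block founders at a 0.005
per-site flip rate. Causal SNPs are verified with the package's own
scanner at generation time, so the planted answer is guaranteed
recoverable in principle. Detection couples to expression through a
logistic link, `plogis(1.5 * (expr − 6))`, reproducing the
expression-dependence of detection without modelling probe chemistry.
All randomness flows from one integer seed through derived sub-seeds; no
global RNG state leaks.

What the generator does *not* emulate: probe-level chemistry beyond the
optional PM/MM table, heavy-tailed expression noise, correlated gene-gene
structure outside the planted module, realistic haplotype diversity beyond
block LD, indels, and dinucleotide sequence composition. Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every property of real microarray or sequence
data.

## Problem sizes and runtime choices

The test suite exercises the full study conditions where the property
being checked needs them (DEG recovery over 20 cohorts of 60 patients;
a 10 × 50 compendium for assignment and specificity; 20 end-to-end
pipeline runs for causal-pair recovery) and smaller fixtures (200 genes,
20 patients, 10-sample types) where the property is structural rather than
statistical. Monte-Carlo checks use 100–1000 replicates chosen so that
binomial noise is well inside the asserted bands. The acceptance script
mirrors these sizes and completes in a few minutes on one core.

## Known limitations

Expression inputs are trusted to be comparably normalized across batches.
The rank-sum/signed-rank ambiguity in the paired test is resolved by
configuration, not by fiat. The GAM enrichment model fixes one smooth
covariate (length, optionally GC); other confounders (mappability, repeat
density) would need to be added by the caller. Indels and multi-allelic
variants are out of scope for allele-effect classification. The
inflammation tri-partition of patients is expressible as a cut on the
count of significant immune signatures but no canonical thresholds are
claimed.
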