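# celldissect

Cellular dissection of bulk skin-disease transcriptomes and prioritization
of regulatory variants at intergenic susceptibility loci.

## The problem

Bulk biopsies of inflamed skin mix signals from keratinocytes, fibroblasts
and half a dozen infiltrating immune cell types. Given paired lesional (PP)
and uninvolved (PN) biopsies from the same patients, this package answers,
in order:

1. **Which genes respond to disease?** Detection-aware paired differential
   expression: per-patient fold-changes FC = 2^(PP − PN) on log2 expression,
   Wilcoxon tests across patients, Benjamini–Hochberg FDR, and a
   cross-study consistency filter (a gene is called up only when
   FC > 1.50, FDR < 0.05, *and* its median FC exceeds 1 in every
   contributing study; down is the mirror image at FC < 0.67).
2. **Which cell type does each gene come from?** Against a multi-cell-type
   expression compendium normalized to normal skin, each gene's candidate
   cell type is the one with the highest median relative expression among
   types where the gene is detected in ≥ 10% of samples; a max-p rank-sum
   statistic over the 9 competing types quantifies specificity, and an
   area-type enrichment statistic (mean deviation between a gene set's
   cumulative-overlap curve and the diagonal — a normalized Mann–Whitney
   shift) with bootstrap nulls summarizes set-level structure. Weighted
   marker signatures score each patient's per-cell-type response.
3. **Which regulatory variant is doing the work?** For a suspected target
   gene near an intergenic risk locus: find its candidate cell type, build
   its local co-expression network (Spearman r_s ranking with the knee of
   the r_s^7 curve setting the network size N), test each of a dictionary
   of PWMs for enrichment in sequences adjacent to network genes
   (semiparametric generalized additive logistic model, smooth in
   log10 length; Wald z), expand the GWAS lead SNP to its LD partners
   (dosage r² > 0.90), classify each linked SNP × motif pair as
   *engendering* or *abrogating* a motif match (match ⇔ log-odds score ≥
   80% of the motif's maximum, either strand, overlaps merged), and rank
   the changing pairs by the motif's enrichment z.

Every input the pipeline needs can be simulated by the built-in
synthetic-data module with planted ground truth (planted fold-changes,
cell-type markers, a latent-factor co-expression module, motif occurrences,
LD blocks, and causal SNPs verified at generation time), so the whole
analysis is testable end to end with no external data.

## Worked example

```r
library(celldissect)

inp <- generate_synthetic_inputs(synth_config(seed = 1))
res <- run_full_analysis(inp)
print(res)
#> <dissection_result>
#>   skin-expressed genes: 897
#>   DEGs: 49 up / 42 down; 30 universal up
#>   candidate cell type: neutrophil | network size: 27
#>   LD partners: 5 | prioritized SNP-motif pairs: 3

res$prioritized[, c("rank", "variant_id", "motif_id", "effect", "z", "q")]
#> # A tibble: 3 x 6
#>    rank variant_id motif_id effect         z          q
#> 1     1 rs0001     motif_01 abrogates 5.32   0.00000214
#> 2     2 rs0002     motif_01 engenders 5.32   0.00000214
#> 3     3 rs0005     motif_11 abrogates 0.0735 0.994
```

Reading the output: of 1000 simulated genes, 897 pass the 10% detection
filter; 49 are called PP-increased (the generator planted 50 at 2-fold) and
30 of those rise in every single patient. The analysis target gene is
assigned to neutrophils, its co-expression network keeps 27 partners at the
knee cutoff, and the lead SNP expands to 5 linked variants. Of all
SNP × motif pairs, three change a motif match; the two planted causal SNPs
(rs0001 destroying, rs0002 creating a match to the foreground-enriched
motif_01, z = 5.3) outrank the chance hit on an unenriched motif
(z ≈ 0.07). `autoplot()` methods draw the network knee, enrichment z
profile, signature-score map and enrichment curves; `tidy()`/`glance()`
return tibbles for downstream use.

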