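# crcminer

Integrative discovery of **core regulatory circuitries (CRCs)** in cancer:
subtype-selective transcription-factor (TF) dependencies are called from
genome-scale CRISPR gene-effect screens and intersected with the
superenhancer (SE) landscape, with enhancer–gene assignment by a modified
**activity-by-contact (ABC)** procedure driven by HiChIP loops and
H3K27ac/ATAC activity. The package targets computational biologists working
with DepMap-style screens, H3K27ac ChIP-seq/SE catalogs, HiChIP loop calls
and expression cohorts — the AML/KMT2A-rearranged setting is the motivating
use case, but nothing is lineage-specific.

## What it computes

**Selective dependencies.** Gene effects are on the control-anchored scale
(0 = nonessential controls, −1 = common-essential median). A gene is a
selective dependency of an annotated in-group when (1) its dependency
probability exceeds 0.5 in ≥ 3 in-group lines, (2) it is not common
essential (rank in the 90th-percentile least-dependent line below the
central minimum of the rank histogram), and (3) it is *enriched*
(empirical-Bayes moderated linear model; BH q < 0.05 with negative effect
size) or *skewed*:

    normLRT = 2 (ℓ̂_skew-t − ℓ̂_normal) ≥ 100, with mean effect < median

where ℓ̂ are maximized log-likelihoods of an Azzalini–Capitanio skew-t and a
normal fit to the gene's effects across lines.

**SE landscape.** Per-sample SE calls are union-merged, quantified,
median-normalized per sample, replicate-averaged, and filtered by
recurrence; spike-in (exogenous chromatin) scaling, subtype differentials,
dependency correlation and correlation-based sample clustering are included.

**ABC assignment.** Loops with one anchor within 5 kb of a TSS are scored as

    ABC = loop frequency × √(H3K27ac × ATAC)

over the distal anchor (± 2.5 kb), trimmed (TSS–TSS loops, blacklist
overlap, scores below the genome-wide 89th percentile), stitched into
regions, and kept as region–gene associations when the region's normalized
H3K27ac signal correlates with the gene's expression (Pearson r > 0.3 in
either of two cohorts), then merged with proximity assignments.

**Companion statistics.** A myeloid/lymphoid differentiation index (top-19
markers by pooled-variance separation index; summed, sign-adjusted,
max-|z|-scaled z-scores) and a Fisher exact colocalization test for
3D-aggregated microscopy puncta against a nuclear volume-fraction null.

A synthetic-data module (`sim_gene_effect()`, `sim_regulatory_locus()`,
`sim_reference_expression()`, `sim_puncta_field()`) generates every input
with planted ground truth.

## Worked example

```r
library(crcminer)

# a synthetic screen: 200 genes x 30 lines, 10-line AML in-group,
# 5 planted selective and 5 common-essential genes
ge  <- sim_gene_effect(seed = 42)
scr <- run_dependency_screen(ge, in_group = ge$annotations$lineage == "AML")
subset(scr$calls, selected)
#>    gene n_dependent_ingroup is_common_essential is_enriched is_skewed selected
#> 1 G0001                  10               FALSE        TRUE     FALSE     TRUE
#> 2 G0002                  10               FALSE        TRUE     FALSE     TRUE
#> 3 G0003                  10               FALSE        TRUE     FALSE     TRUE
#> 4 G0004                  10               FALSE        TRUE     FALSE     TRUE
#> 5 G0005                  10               FALSE        TRUE     FALSE     TRUE
```

All five planted selective genes are recovered: each is a dependency
(probability > 0.5) in all 10 in-group lines, none was caught by the
common-essential rank filter, and each is a moderated-model enriched
dependency (at 30 lines the normLRT route rarely fires; it matters at
screen scale, where 769 lines give left-skew mixtures normLRT ≫ 100).

```r
# a toy regulatory locus: 20 true enhancer-gene loops among 200 decoys
loc <- sim_regulatory_locus(seed = 42)
ph  <- data.frame(loc$pooled_track[c("chrom", "start", "end")],
                  value = loc$pooled_track$h3k27ac)
pa  <- ph; pa$value <- loc$pooled_track$atac
abc <- run_abc(loc$loops, loc$tss, loc$blacklist, ph, pa,
               loc$tracks, loc$expr, loc$cohorts)
abc$counts
#>   candidates      tss_tss    blacklist        score      regions associations
#>          220          220          220           25           25           22

head(abc$associations, 3)
#>   region_id    gene r_cohort1 r_cohort2 source
#> 1    R00001 GENE001 0.9168678 0.9205426    abc
#> 2    R00011 GENE001 0.8683407 0.8427109    abc
#> 3    R00002 GENE002 0.9028353 0.8947518    abc
```

The 89th-percentile score trim reduces 220 candidate loops to 25; the
expression-correlation gate (r > 0.3 in either 12-sample cohort) keeps 22
associations — all 20 planted links (the r ≈ 0.9 entries above reflect the
planted activity–expression coupling of 0.9) plus 2 decoys, i.e. recall
1.0 at precision 0.91. Intersecting selective TFs with SE-associated TFs
(`intersect_core()`) then yields the core TF table with provenance flags.

See the vignette (`vignettes/crc-discovery.Rmd`) for the model details,
parameter meanings and the design decisions behind each stage.

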