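# hmcscape

Integrative analysis of 5-hydroxymethylcytosine (5-hmC) landscapes in
cardiomyocyte development and pathological hypertrophy.

5-hmC is the oxidation product of 5-methylcytosine produced by TET
dioxygenases. Profiled by antibody enrichment (hMeDIP-seq), it marks gene
bodies of actively expressed genes and a subset of active enhancers, and it
redistributes as cardiomyocytes mature from embryonic (E14.5) to neonatal to
adult states and again under pressure overload (TAC). `hmcscape` implements
the full downstream analysis of such a study for R users who have read
placements and peak calls in hand: replicate-consistent peak handling,
coverage quantification, differential-enrichment calling, expression
association, enhancer stratification and stage clustering — plus a seeded
synthetic-study generator with machine-readable ground truth, so every stage
is testable without any sequencing data.

## What it computes

* **Interval algebra** (`bed_intersect`, `bed_subtract`, `bed_merge`,
  `bed_multi_intersect`) with exact base-level semantics on 0-based
  half-open BED coordinates; consensus peaks are the peak base pairs shared
  by both biological replicates (`consensus_peaks`), and stage-common
  intervals are the multi-way intersection (`common_peaks`).
* **Annotation** of any base or peak midpoint into
  promoter > TTS-flank > exon > intron > intergenic, with promoters defined
  as TSS ± 1 kb (`annotate_position`, `peak_annotation_distribution`), and
  per-gene position classes (promoter-only / gene-body-only / both / none,
  `classify_genes_by_position`).
* **Coverage quantities**: gene-body counts and RPKM
  (`rpkm = count / (gene_length_kb × library_size_millions)`), optionally
  restricted to enriched regions; 100-kb chromosome bins;
  length-scaled metagene profiles; anchor-centred profiles (±5 kb, 200-bp
  bins) in RPM; replicate Pearson correlations.
* **Differential hydroxymethylation**: genome-wide windowed counts (250 bp,
  midpoint assignment), a common-dispersion negative-binomial exact test in
  the Robinson–Smyth style (`nb_exact_test`; the φ = 0 limit reproduces the
  two-sided binomial exact test to machine precision), method-of-moments
  dispersion estimation from replicate variability
  (`estimate_common_dispersion`), and merging of significant windows into
  DhMRs at P ≤ 0.05 (`call_dhmrs`), with Benjamini–Hochberg correction
  available and recommended for recovery benchmarks. DhMRs are integrated
  with differential expression (q ≤ 0.05) on gene bodies, with genes
  carrying both gains and losses excluded from either "solely" set
  (`dhmr_expression_overlap`).
* **Association statistics**: an exact-enumeration Mann–Whitney U test for
  small groups with a tie-corrected normal approximation otherwise
  (`mann_whitney`); expression by position class; gene-body 5-hmC across
  expression quartiles (RPKM ≥ 1) with a seeded permutation trend test;
  histone co-marking contrasts; CpG-demethylation grouping at
  Δ ≤ −1/−10/−15/−20 percentage points; repeat-class reads-in-peaks.
* **Enhancers**: H3K27ac consensus peaks not overlapping any exon or
  promoter window are putative enhancers; they are stratified by 5-hmC
  overlap, assigned their single nearest gene (midpoint-to-TSS), contrasted
  for nearest-gene expression, overlapped with phastCons elements
  (score > 600), and followed through knockdown-induced 5-hmC loss.
* **Clustering**: complete-linkage hierarchical clustering (1 − Pearson),
  a from-scratch SOTA (self-organizing tree algorithm) implementation, and
  the dual-evidence stage co-clustering rule: a gene belongs to a stage only
  if its expression argmax and its genic 5-hmC argmax agree and are unique.

Results are plain tibbles throughout; fitted objects have `tidy()` /
`glance()` methods and `autoplot()` views.

## Worked example

Generate the default synthetic study (4 conditions × 2 IP replicates plus
input controls on a 4-Mb toy genome with 300 genes) and run the whole
pipeline:

```r
library(hmcscape)

ds <- synth_generate(synth_config(seed = 42), "demo-study")
#> <synthetic dataset> demo-study: 26 files, 300 genes

report <- run_pipeline(run_config("demo-study", seed = 7))
#> <pipeline report> demo-study/report
#>   239 DhMRs, 600 enhancers, 96 co-clustered genes

report$replicate_correlation
#>   condition pearson
#> 1 E14.5       0.842
#> 2 neonatal    0.777
#> 3 adult       0.674
#> 4 TAC         0.678

dplyr::filter(report$expression_by_class, condition == "adult")
#>   class               n median median_all      u     p_value condition
#> 1 promoter_only      45   2.80       5.71  3440  0.000000113 adult
#> 2 gb_only            71  14.3        5.71 14732. 0.000000511 adult
#> 3 promoter_and_gb    67  11.7        5.71 13810. 0.00000169  adult

glance(report$quartile_trend)
#>   n_genes trend_rho  trend_p
#> 1     281     0.744 0.000500
```

Reading the output: replicate agreement on genic RPKM is Pearson's ρ per
condition (shallow toy libraries; deeper libraries push it toward 1). Genes
with gene-body 5-hmC (`gb_only`, `promoter_and_gb`) have median expression
well above the all-genes median (14.3 and 11.7 vs 5.7 RPKM) with
Mann–Whitney p ≪ 0.01, while the promoter-only class sits below it — the
planted couplings the generator emulates. The quartile trend (median
gene-body 5-hmC rising monotonically across expression quartiles,
permutation p = 5 × 10⁻⁴) reproduces the coverage–expression relationship at
the gene level, and the 96 co-clustered genes are those whose expression and
genic 5-hmC peak at the same stage.

Every table is also written under `demo-study/report/` with a provenance
footer, together with `summary.json` and a deterministic run log; re-running
with the same seeds reproduces the report byte for byte.

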