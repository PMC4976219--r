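---
title: "Methods: models, parameters and design choices in hmcscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in hmcscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hmcscape` re-implements, as a tested pipeline, the downstream analysis of
an antibody-enrichment hydroxymethylome (hMeDIP-seq) study of cardiomyocyte
development and hypertrophy: four biological states (embryonic E14.5,
neonatal, adult, and pressure-overload TAC), two IP replicates per state
plus input controls, matched RNA expression, histone-mark peak calls,
repeat and conservation annotation, and CpG-methylation deltas. This
vignette explains the statistical models, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the choices were genuinely open.

## Coordinates and interval semantics

All coordinates are 0-based half-open (BED convention) everywhere in the
package; GTF input is converted on read. Interval sets are plain tibbles
(`chrom`, `start`, `end`). The set operations — intersection, subtraction,
merge, multi-way intersection — have exact base-level semantics: the result
is the merged interval form of the corresponding per-base boolean
operation. Adjacent intervals (`[0,10)`, `[10,20)`) merge; zero-length
intervals are rejected at construction. The kernels delegate to IRanges,
and the test suite checks every operation against an independent per-base
boolean-vector oracle on hundreds of random instances.

Two interval sets with no shared chromosome name are allowed (their
intersection is empty) unless their names collide after stripping a `chr`
prefix — `chr1` against `1` is diagnosed as a namespace mismatch, since
silently returning an empty result for that case hides a data-preparation
error.

## Gene models and annotation

A gene model is the transcribed span TSS→TTS with exons. The TSS is
strand-aware: the leftmost transcribed base on `+`, the rightmost on `-`
(UCSC convention; the choice matters for every promoter window). Promoters
are TSS ± 1 kb and TTS flanks are TTS ± 1 kb, both clipped at chromosome
ends. A base is annotated with the single highest-precedence category among
promoter > TTS-flank > exon > intron > intergenic. UTRs are not separated
from other exonic sequence: the exon/UTR subdivision is not reconstructible
from the source material, so the package deliberately collapses them rather
than guess. Peaks are annotated by their midpoint base, mirroring the
behaviour of the annotation tooling this class of study uses; a
whole-peak overlap mode is available as a diagnostic.

For the per-gene position classes, the gene body is the transcribed span
*minus* the promoter window. This makes promoter and gene-body evidence
disjoint, which the "exclusively at promoters" class logically requires;
the alternative (body = full span) would make `promoter_only` nearly
impossible for short genes. A gene is classed by the pair of indicators
(any peak base in the promoter?, any in the body?), with ≥ 1 bp overlap
counting.

## Coverage quantities

Fragment-to-feature counting uses ≥ 1 bp overlap with multi-assignment: a
fragment spanning two genes counts for both. Where exclusivity matters —
100-kb chromosome bins and the differential windows — fragments are
assigned by midpoint, so totals are conserved. RPKM is
`count / (gene_length_kb × library_size_millions)`; the library size comes
from the sample manifest, not the loaded fragment count, so subsampled
fixtures stay calibrated. Gene-body quantification can be restricted to
fragments inside a supplied peak set ("reads falling into peaks"); this is
the mode used for enrichment-level tables and the stage co-clustering,
while raw coverage uses all fragments. Profiles (metagene and
anchor-centred) are arithmetic means over anchors in reads-per-million;
minus-strand genes are orientation-flipped; genes shorter than the body bin
count are skipped with a warning; anchor bins that fall off a chromosome
end contribute zero while remaining in the denominator.

## The windowed negative-binomial exact test

Differential hydroxymethylation is called on fixed-width windows (default
250 bp, the fragment scale; the original tool chain does not state its
window, so the width is exposed). Counts are scaled to the geometric-mean
library, pooled within condition, and each window's pooled total is split
between conditions; the two-sided p-value sums, over the conditional null
distribution of that split under a common dispersion φ, all outcomes no
more probable than the observed one. With φ = 0 this *is* the two-sided
binomial exact test (verified to 10⁻⁹ on the full grid of totals ≤ 100);
with φ > 0 the pooled counts follow the Robinson–Smyth small-sample
convolution (a sum of n NB(μ, φ) variables is NB(nμ, φ/n)). The 0.5
pseudo-count appears only in the log fold change, never in the test.
Group-label swap negates logFC and leaves p unchanged, and p is
non-increasing as the split becomes more extreme at fixed total — both
property-tested.

The common dispersion is estimated from replicate variability by pooled
method of moments. For each condition with replicates, each window
contributes its sample mean and variance of library-adjusted counts, and

φ̂ = max(0, Σ(s² − x̄) / Σ(x̄² − x̄/n)),

with the small-sample correction φ = r/(1 − r/n) applied to the ratio r.
The denominator term x̄/n removes the E[x̄²] bias, so the estimator is
nearly unbiased at n = 2 and returns 0 (Poisson) for under-dispersed data.
A per-window average of max(0, (s² − x̄)/x̄²) — the more obvious estimator —
is badly upward-biased at n = 2 because the max() rectifies sampling noise;
the pooled form avoids that without trimming tricks. Windows in the extreme
5% tails of the mean distribution can be trimmed as a guard against outlier
regions (on by default); with no replicate structure anywhere the estimator
warns and returns a configurable prior.

Windows with p ≤ α (default 0.05, the raw-p rule of the original analysis)
and a common direction merge into DhMRs across gaps of at most one
non-significant window; each record keeps the minimum constituent p and the
count-weighted mean logFC. No fold-change filter is applied: the source
material states only the p rule. **Benjamini–Hochberg mode**
(`call_dhmrs(..., adjust = TRUE)`) is available and is what the package's
own recovery benchmarks use: with ~32,000 windows genome-wide, a calibrated
test at raw p ≤ 0.05 admits ~5% of null windows by construction, so
region-level precision above 0.8 is arithmetically impossible without
multiplicity control. The default remains raw-p for fidelity; the
benchmark uses the recommended mode.

Gene-level differential expression reuses the same exact test on gene
counts with BH correction and a q ≤ 0.05 call, as a stand-in when only
synthetic counts exist; real analyses can supply any DE table with
`gene_id`, `log2fc`, `q`, `direction`.

## Association layer

The Mann–Whitney U test enumerates the exact permutation distribution of U
(ties handled via mid-ranks) whenever the number of group-A/group-B
arrangements is at most 20,000 — which covers all 8-vs-8 and smaller
problems — and otherwise uses the normal approximation with tie-corrected
variance and a 0.5 continuity correction. Exactness against brute-force
enumeration is asserted for all group sizes up to 8 in the tests.

Expression quartiles are computed over expressed genes only (RPKM ≥ 1),
with ties broken by stable input order so the quartiles always partition
the gene set into parts differing by at most one gene. The monotone-trend
p-value is a seeded permutation test (default 10,000 permutations) on the
Spearman correlation between expression rank and gene-body coverage,
one-sided for an increasing trend; a named asymptotic test was deliberately
avoided because the permutation version is exact at small n and makes no
distributional assumption. Degenerate input (constant coverage) returns a
flat table and p = 1.

CpG-demethylation groups use the thresholds Δ ≤ −1, −10, −15, −20
percentage points (adult minus neonatal) and are nested/cumulative by
default, matching the threshold notation (a gene at Δ = −12 belongs to the
−1 and −10 groups); an exclusive-bin mode is provided because the grouping
convention is ambiguous in the source. The "deeper coverage, greater
expression" relationship has no stated binning; it is exposed through the
quartile machinery rather than a bespoke decile table.

## Enhancers

Putative enhancers are H3K27ac replicate-consensus peaks that overlap no
exon and no promoter window by even 1 bp; intronic overlap does not
exclude. Stratification is by ≥ 1 bp overlap with 5-hmC consensus peaks.
Nearest-gene assignment minimizes |enhancer midpoint − TSS| with ties going
to the lexicographically smaller gene id (deterministic); an edge-to-edge
distance mode is available. The expression contrast counts each enhancer's
nearest gene once per enhancer by default (deduplication configurable).
Conservation overlap retains elements with score strictly above 600 and
reports the fraction of enhancers per status overlapping at least one.
The knockdown analysis intersects fetal 5-hmC⁺ enhancers with
loss-direction DhMRs from the same two-condition machinery (the
knockdown contrast needs no special casing) and contrasts the affected
nearest genes between control and knockdown.

## Clustering

Hierarchical clustering is complete linkage on 1 − Pearson distance by
default (Euclidean selectable), via `stats::hclust`, returning the ordered
matrix for heat maps and a Newick rendering; the test suite verifies the
merge-height sequence against a brute-force O(n³) agglomerator. Heat-map
normalization divides each row by its median ("median-normalized values");
a row-z mode exists.

SOTA is implemented from its published description: a binary tree of cells
starting from one sibling pair at the data mean, sequential presentation of
rows to the winning terminal cell (winner rate 0.01, mother 0.005, sister
0.001 — the algorithm's original defaults; the source names only the tool),
splitting of the most variable cell when its resource (mean member-to-
centroid distance) exceeds the variability threshold, and termination when
all terminal cells satisfy the threshold or the cycle budget (1,000) is
spent, with a convergence flag either way. The procedure is fully
deterministic given row order and parameters; both initial daughters start
at the node centroid and differentiate through the winner/sister update
asymmetry. If the whole data set already satisfies the threshold the tree
never leaves the root, so an infinite threshold yields one cluster. The
number of clusters found on real data is data-dependent by design; the
algorithm, not any particular partition, is the deliverable, and the
dendrogram cut height for subset extraction is exposed as a parameter
rather than guessed.

Stage co-clustering assigns a gene to a stage only when the argmax of its
expression profile and the argmax of its genic reads-in-peaks profile
coincide and are unique; ties or disagreement leave the gene unassigned.
Because the rule depends only on per-row argmaxes it is invariant under any
per-row strictly increasing transform of either matrix, which is
property-tested.

## The synthetic-study generator

`synth_config()` / `synth_generate()` produce a complete toy study with
ground truth: a toy genome (default 2 × 2 Mb), 300 gene models (BED12),
per-condition expression (RPKM) and NB RNA counts, per-sample fragment
placements (BED) with a manifest, per-replicate 5-hmC and H3K27ac peak
calls jittered ±50 bp at the edges, uniform input controls, repeats
(LINE/SINE/LTR), conserved elements, and per-gene methylation deltas.
Identical seeds give byte-identical bundles.

What it emulates, and how the knobs map to the study's observations:

* **Gene-body coupling** (`coupling_strength`, default 1): every gene's
  background gene-body rate rises monotonically with its expression rank;
  additionally a fraction of genes (`frac_gb_marked`, 0.35) carry
  peak-level gene-body enrichment, sampled with weight
  exp(8 × coupling × mean-expression rank) so the marked classes separate
  strongly from the all-genes median, as in the study's boxplots. The
  promoter-only subset (0.15) is drawn from the below-median expression
  stratum (mild repression) — but only when coupling is on; with
  `coupling_strength = 0` every choice is uniform and nothing is planted,
  which is what the null-calibration tests rely on.
* **Stage specificity** (`frac_stage_specific`, 0.2; `stage_boost`, 4):
  stage genes are boosted in both expression and genic 5-hmC at their
  stage, and are members of the gene-body-marked set by construction —
  planting dual evidence is what makes co-clustering recovery well defined.
* **Planted DhMRs** (`n_planted_dhmrs`, `dhmr_fold`, `dhmr_width`):
  intergenic regions whose *total* fragment rate (the genome background is
  subtracted underneath) steps by exactly `dhmr_fold` at an assigned
  transition; gains rise after it, losses fall.
* **Enhancers** (`n_enhancers`, `frac_hmc_pos` = 0.3, `enhancer_boost` = 2):
  placed ≥ 2 kb from genes; the 5-hmC⁺ subset carries a co-located 5-hmC
  peak, multiplies its nearest gene's expression by the boost, and
  co-locates with high-scoring conserved elements at elevated probability.
* **Hypertrophy remodelling**: half of the LINE repeats gain TAC-specific
  5-hmC (`tac_repeat_gain`), giving the repeat analyses signal.
* **Demethylation**: Δ methylation is drawn with a negative slope against
  neonatal gene-body 5-hmC (`methylation_slope`), so deeper demethylation
  associates with higher neonatal coverage.
* **Replicate noise** (`rep_sigma`, default 0.08): fragments are Poisson
  per region with a lognormal per-region, per-replicate rate multiplier.
  The generator's noise model is deliberately *not* the analysis model (NB
  with common dispersion), so recovery tests are honest; the lognormal
  jitter induces NB-like overdispersion with
  φ ≈ exp(σ²) − 1 ≈ 0.0064 at the default. Background fragments are
  generated over 10-kb blocks so this overdispersion is homogeneous across
  the genome, consistent with a common-dispersion analysis. The default σ
  corresponds to an 8% coefficient of variation per region and replicate,
  in line with the replicate consistency such studies report; materially
  larger values make nominal 2-fold regions fluctuate enough
  (region-coherent noise) that no calibrated caller can recover them
  reliably at 30× depth.

What it does **not** emulate: mappability and GC/CpG-density bias (the
coupling-normalization of dedicated MeDIP tools is out of scope and noted
as a divergence), sequencing errors, fragment-length variation (all
fragments are 250 bp, the sonication mode), chromatin contact structure,
and any sequence content — the analysis is purely positional. Passing
recovery tests therefore show that the algorithms are correct on data
matching their assumptions, not that real libraries are free of those
biases.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 500 random instances
(≤ 200 intervals on a 50-kb toy genome) for the interval oracle; 10,000
windows for test calibration and dispersion recovery; a 2-Mb genome at 30×
fragment depth with 50 planted 2-fold regions for DhMR recovery; the
default 4-Mb/300-gene study for association, enhancer and co-clustering
recovery; 100 single-condition null studies for class-association
calibration and 200 for trend-p uniformity; 10,000 permutations for planted
trend tests and 1,000 for each null run. These sizes keep each check
statistically meaningful at desk scale; all of them are parameters, not
constants.

## Known limitations

* The raw-p DhMR rule is reproduced faithfully but is anti-conservative at
  genome scale; use the BH mode for any precision-sensitive application.
* The NB exact test pools replicates within condition after mean scaling;
  designs with strongly unequal within-condition libraries would be better
  served by quantile-adjusted pooling, which is not implemented.
* `estimate_common_dispersion` assumes a single shared φ; a trended (mean-
  dependent) dispersion is not modelled.
* The nearest-gene rule is distance-to-TSS only; no expression-weighted or
  contact-informed assignment.
* Input controls are carried through the manifest and validated, but the
  default profiles are raw IP RPM (as in the figures this mirrors);
  IP/input ratio profiles are optional, not default.
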