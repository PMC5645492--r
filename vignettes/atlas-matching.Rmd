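---
title: "Rank-difference matching of transcriptomes to a reference brain atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-difference matching of transcriptomes to a reference brain atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell populations differentiated in vitro — for example iPSC-derived
neurons — need independent molecular validation of two claims: *what* they
are (anatomical identity) and *how mature* they are (developmental stage).
A region-annotated reference expression atlas of the human brain provides
both axes at once: expression profiles of hundreds of micro-dissected
regions, grouped into gross anatomical structures (brain stem, cortex,
cerebellum), measured in adult and fetal donors.

Direct comparison of a bulk RNA-seq query against microarray-based atlas
intensities is confounded by platform, unit and batch. `atlasmatch`
therefore compares **ranks**: any monotone distortion between platforms
leaves the analysis unchanged.

## The matching procedure

For a query expression vector and an atlas restricted to one developmental
stage:

1. **Filter.** Keep atlas regions assayed in at least `min_samples` samples
   and probes called expressed (intensity above `detection_threshold`) in at
   least `min_samples` samples. Regions are filtered before probes so the
   operation is idempotent.
2. **Harmonize.** Map probes to gene symbols, collapse multi-probe genes
   (mean by default), intersect with the query's gene universe to obtain a
   shared index of G genes.
3. **Average and rank.** Replicate query columns are CPM-normalized and
   averaged; each region's samples at the stage are averaged. Both profiles
   are rank-transformed (ascending, average ranks at ties), so each is a
   vector of ranks in [1, G].
4. **Rank differences.** For region r, `d_r(g) = |rank_query(g) -
   rank_region_r(g)|`. A perfectly matching region has all-zero differences;
   the largest possible difference is G − 1. A signed variant is available
   behind `match_config(signed_diff = TRUE)` for diagnostics.
5. **Score.** Each region's G differences are tested against a pooled
   background of all other regions' differences at the same stage with a
   one-sided Wilcoxon rank-sum test (alternative: the region's differences
   are smaller). The score is −log10 p, capped at 320. The background is
   subsampled to `background_cap` × G values (default cap 10) under the
   configuration seed, keeping the test O(G) per region and reproducible.
6. **Aggregate to structures.** Per structure, the pooled per-gene rank
   differences of member regions are tested against those of non-member
   regions (one-sided Wilcoxon, member differences smaller), each side
   subsampled to at most G values. Reported as −log10 p.
7. **Compare stages.** Steps 3–6 are repeated per stage; the stage at which
   the true structure scores highest estimates the developmental maturity of
   the query.

### Why the structure score uses pooled rank differences

An obvious aggregation — a rank-sum test of member regions' −log10 p values
against non-members' — uses only the *ordering* of region scores within one
stage. At atlas sizes of a few dozen regions that ordering frequently
becomes complete (every member outranks every non-member) at more than one
stage; the statistic then sits at its hard ceiling at both, and the
cross-stage comparison degenerates to a coin flip. Testing the pooled
per-gene differences keeps magnitude information, varies smoothly across
stages, and uses exactly the same test family as the region score. Each side
is capped at G values so the structure score carries the same information
scale as a single region test rather than growing with the number of
regions.

### The Wilcoxon rank-sum implementation

The p-value is exact — by enumeration of all `choose(n, nx)` label
assignments of the observed, possibly tied, pooled rank multiset — whenever
the pooled size is at most `exact_limit` (default 20), and a normal
approximation with tie correction and 0.5 continuity correction otherwise.
Enumeration handles ties exactly, which the classical exact distribution
does not; the normal branch is computed on the log scale so extreme tails
(−log10 p up to the 320 cap) do not underflow.

## Normalization toolbox

* `compute_cpm()` — counts per million, optionally with per-sample scale
  factors; columns sum to 10^6 when factors are 1.
* `compute_rpkm()` — reads per kilobase per million mapped reads; requires
  gene lengths in bp.
* `tmm_factors()` — trimmed mean of M-values scale factors: 30% two-sided
  trim on log-ratios, 5% on average intensities, precision-weighted mean of
  the surviving log-ratios, factors rescaled to geometric mean 1. The
  precision weights are evaluated on the proportion scale (equivalently, at
  a common nominal depth): this keeps the factors exactly invariant to
  rescaling any single library, and coincides with the classical
  depth-dependent weights whenever library sizes are equal. The reference
  sample defaults to the one whose upper-quartile expression is closest to
  the mean upper-quartile.
* `log2_transform()`, `median_center()`, `average_replicates()` — display
  and aggregation transforms. The conventional order is log2 first
  (pseudocount 1 for display matrices), then gene-wise median centering.
  Because the matching pipeline is rank-based, none of these change region
  scores; they matter for the DE stage and for exported matrices.

## Differential expression stage

`de_test()` is deliberately simple and labelled "approximate limma-voom":
genes are kept when at least one group shows CPM ≥ 1 in every replicate,
counts are TMM-normalized, transformed to `log2((count + 0.5) /
(effective libsize + 1) * 1e6)`, and tested with a per-gene pooled-variance
two-sample t-test (df = n1 + n2 − 2). No precision weights and no
empirical-Bayes moderation are applied — at triplicate sample sizes the
plain t-test is calibrated (its raw-p false-positive rate at alpha 0.01 sits
within binomial bounds in the test suite) though less powerful than a
moderated fit. Genes with pooled variance below `var_floor` (default 1e-8)
are floored and flagged rather than dropped.

Significance uses the Benjamini–Hochberg adjusted p below `alpha` (default
0.01) **and** |log2 fold change| at least `lfc_threshold`. The default
threshold is 1.5 in log2 units; a plain 1.5-fold cutoff corresponds to
`lfc_threshold = log2(1.5)` ≈ 0.585. Both conventions appear in practice and
the choice is exposed rather than hidden.

## What the synthetic generator emulates

`generate_atlas()` produces a desk-scale surrogate of a region-annotated
atlas on the log2 intensity scale:

* 2,000 probes; 30 regions grouped 5/20/5 into brain stem, cortex and
  cerebellum — echoing the 59/362/80 imbalance of the real resource at
  1/15 the region count;
* three stages (adult, 15–16 pcw, 21–22 pcw), two donors per stage, one
  sample per region per donor per stage;
* per-probe baseline ~ Normal(7, 2) (log-normal intensities);
* disjoint signature sets: 50 probes per region elevated by `region_effect`
  (default 2.0 log2 units), 50 probes per structure elevated by
  `structure_effect` (1.0), 100 stage-variable probes per stage shifted by
  ±`stage_effect` (1.0) with a fixed random sign per (structure, stage) —
  developmental change is structure-specific, which is what makes maturity
  identifiable at all: a shift shared by every region is cancelled exactly
  by the within-stage background;
* a persistent per-region Normal(0, 0.3) deviation on every probe — regions
  have idiosyncratic transcriptome-wide character, so structure-level
  separation stays partial, as observed in real atlas scores;
* per-sample Normal(0, 0.5) measurement noise;
* per-region 3-D coordinates clustered around a centroid per structure.

`generate_query()` converts a region's mean log2 profile at a stage into
negative-binomial counts (variance μ + φμ², default φ = 0.1, expected
library size 10^6, three replicates), exercising the cross-platform
microarray-vs-counts comparison end to end. `generate_de_counts()` plants a
known set of shifted genes for DE calibration.

What the generator does **not** emulate: probe-level microarray artifacts,
batch and dissection effects, spatial autocorrelation between neighbouring
voxels, and realistic co-expression structure (genes are independent given
the design). Passing recovery tests therefore demonstrate that the pipeline
recovers planted signal of realistic magnitude under honest noise — not
that it is robust to every failure mode of real cross-study data.

## Numerical and design choices

* Rank differences are absolute values by default; the signed variant is a
  config flag. Median absolute rank difference is reported per region as a
  scale-free match summary.
* Exact Wilcoxon enumeration up to pooled n = 20 (`exact_limit`); beyond
  that the tie- and continuity-corrected normal approximation, computed in
  log space.
* −log10 p capped at 320 (double underflow).
* Background subsampling uses a fixed configuration seed; repeated runs of
  the same configuration are byte-identical, including through the CLI.
* "Expressed" for atlas intensities means strictly above
  `detection_threshold` (default 0); the atlas values themselves are taken
  as given (already normalized by their provider).
* Probe-to-gene collapsing is the mean across probes (median via config).
* Stage labels outside the declared set are rejected at load time rather
  than silently grouped.
* Simulation sizes in the test suite (20 seeds for recovery, 100
  permutations for null calibration, 10 seeds × 2,000 genes for DE
  calibration) were chosen to give stable pass/fail behaviour at desk scale.

## Worked example

```{r, eval = FALSE}
library(atlasmatch)

syn <- generate_atlas(generator_config(seed = 1))
query <- generate_query(syn, region = "R26", stage = "pcw21_22", seed = 2)

fit <- atlas_match(query, syn$atlas)
summary(fit)
plot(fit)

# exports corresponding to score tables, flattened heatmaps and 3-D
# voxel projections
write_match_report(fit, "match_out")
adult <- fit$regions[fit$regions$stage == "adult" & fit$regions$query == "query", ]
```

## Known limitations

* The per-region null (pooled differences of all other regions at the same
  stage) measures *relative* match strength within the atlas; scores are not
  comparable across atlases with different region sets.
* Region p-values share a common query and background and are therefore
  dependent; they are scores for ranking regions, not independent tests, and
  no multiplicity correction is applied to the per-region table.
* The DE stage trades power for transparency; for production differential
  expression use a moderated-variance fit.
* With very small atlases (a handful of regions) the exact Wilcoxon branch
  puts a floor under attainable p-values; region ordering remains valid but
  score magnitudes saturate.
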