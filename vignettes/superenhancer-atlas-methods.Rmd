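---
title: "Building a superenhancer atlas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a superenhancer atlas: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seatlas)
```

# The problem

H3K27ac marks active enhancers, and in developing tissue the strongest
regulatory regions are not single enhancers but dense clusters of them —
superenhancers — whose aggregate signal dwarfs that of typical enhancers.
An atlas built across many samples of one developing tissue can then be
partitioned by cross-tissue sharing: regions also called in broad
any-tissue compendia, regions shared only with another embryonic tissue,
and regions unique to the tissue under study. The fully noncoding
tissue-specific regions, particularly those inside gene deserts, are
candidates for long-range regulation of developmental genes and are
prioritized here by in-vivo validated-element support.

`seatlas` implements this workflow end to end on ordinary text inputs
(segment BEDs, bedGraphs, flat gene tables, BED catalogs) with a seeded
synthetic generator standing in for a real multi-sample ChIP-seq atlas.

# Coordinate conventions

Everything inside the package is 0-based half-open (BED convention); a
region covers bases `start .. end-1`. Genome-browser coordinates quoted in
papers are 1-based inclusive; conversion happens only at the I/O boundary.
The TSS of a minus-strand gene is `end - 1`, the last base of the half-open
span, matching browser behavior. The distance between a region and a TSS
is the interval gap with the TSS treated as the 1-bp interval
`[tss, tss+1)`, so an immediately adjacent TSS has distance zero. Malformed
input lines are fatal with a line number — silent data loss is worse than
failure in a pipeline.

# Per-sample calling

## Active-state filtering

Chromatin-state segmentations label each segment with a state; only active
regulatory states enter the calling. The package ships the two active-state
lists it was designed around (`ACTIVE_STATES_25` for 25-state
segmentations, `ACTIVE_STATES_18` for 18-state ones); any custom set can be
supplied through `rose_config(active_states = ...)`.

## Stitching

Active segments closer than the stitch distance are merged transitively
into one candidate region. The default of 12,500 bp is the established
rank-ordering convention: enhancer clusters operate as units at the
10-kb scale, while independent loci rarely sit closer. The gap is measured
end-to-start on the half-open convention, so bookended segments (gap 0)
always merge. Stitching is implemented on `GenomicRanges::reduce` with the
gap rule mapped onto `min.gapwidth`, and is checked in the tests against an
O(n²) transitive-closure oracle.

## Signal quantification

The score of a stitched region is the member-restricted sum of per-base
(H3K27ac − input) coverage, floored at zero. Member restriction (rather
than integrating over the whole stitched span) keeps long sparse clusters
from accumulating background between members; input subtraction removes
copy-number and accessibility bias in spirit, without modeling either
explicitly. Whether signals should additionally be length-normalized is a
genuinely open choice; the unnormalized sum is used because the rank-order
cutoff is scale-invariant and normalization would reward fragmentation.
The floor applies per region, after subtraction.

## The slope = 1 cutoff

Signals are sorted ascending and both axes rescaled to the unit square.
On this curve the cutoff is the tangent point of a slope-1 line supporting
the curve from below — equivalently `argmin_i (y_i - x_i)`. For convex
("hockey stick") curves this is exactly the point where the rank curve's
slope passes 1; for non-convex curves the argmin formulation remains
well-defined and the tests compare it against a brute-force scan over all
candidate tangent points. Two degenerate situations need explicit rules:

* **ties** in `y_i - x_i` break toward the *largest* index, the more
  conservative cutoff (fewer superenhancer calls); a perfectly linear
  signal vector therefore yields zero superenhancers;
* **all-equal signals** make the scaling denominator zero; the cutoff is
  then defined as the maximum, again yielding zero superenhancers rather
  than a division by zero.

`is_super` is strict inequality (`signal > cutoff_signal`), so the tangent
region itself is typical. Ranks (1 = strongest) break signal ties by
coordinates so output order is deterministic.

A promoter-exclusion option (`tss_exclusion_bp`) removes active segments
fully contained within a window around any TSS before stitching. It
defaults to off: whether to use it depends on whether the segmentation
already separates promoter from enhancer states, and the default
active-state lists do.

# Atlas construction

Per-sample superenhancers merge into "distinct regions" by single-linkage
union: any calls sharing at least one base join transitively, and the
atlas region is the union span with the union of supporting samples.
Single-linkage with any-overlap is the most inclusive rule consistent with
counting distinct regions; a reciprocal-overlap variant can be emulated by
raising `min_overlap_frac` in classification, and the merge rule is
deliberately isolated in `merge_distinct()` so alternatives can be
compared. Bookended calls do not merge (they share no base).

Classification is a precedence rule, not a multi-label assignment: overlap
with any general catalog wins (*shared*), then any embryonic catalog
(*embryonic*), else *tissue-specific*. This mirrors a three-way partition
in which "embryonic" means "shared only with embryonic reference tissue".
The overlap criterion defaults to ≥ 1 bp — the most inclusive reading —
with an optional minimum fraction of the atlas region's length.

# Annotation and statistics

Gene overlap is span intersection (≥ 1 bp); TSS encompassment is
`start <= tss < end`. Class-wise proportions of TSS-encompassing regions
are compared pairwise (three 2×2 tables, no omnibus test) with the Pearson
chi-squared statistic under Yates continuity correction,

$$\chi^2 = \frac{N\,(\max(0, |ad-bc| - N/2))^2}{(a+b)(c+d)(a+c)(b+d)},$$

with the two-tailed p-value from the upper tail of χ²(1). Tables with a
zero margin or a non-positive expected count are reported *untestable*
rather than silently switched to another test, because the analysis is
defined in terms of this statistic. The null calibration test in the suite
confirms the correction is conservative (rejection ≤ nominal at α = 0.05
over 10,000 simulated null tables of n = 200 per group).

Enrichment is a plain hypergeometric upper tail per term with
Benjamini–Hochberg adjustment across terms. Term maps are user-supplied
two-column files; no ontology database ships with the package, and no
ontology-graph propagation is performed — the engine, not a term
collection, is the deliverable. `bh_adjust()` validates its input and
delegates to `stats::p.adjust(method = "BH")`; the tests pin it against a
hand-written step-up procedure.

# Gene deserts and prioritization

A desert is a maximal interval of at least 500 kb (inclusive boundary)
containing no *protein-coding* gene span. Full gene spans, not TSSs, bound
deserts, because the definition is about absent coding sequence; noncoding
genes inside a gap do not disqualify it. Telomeric gaps count, with the
missing flank recorded as `NA`. A noncoding region is *in* a desert only
when fully contained (the region is the object being localized), while a
validated element *supports* a desert on any overlap (the element is
evidence), so an element spanning a boundary counts in both deserts.
Flanking-gene counts are deduplicated across regions — two adjacent
regions sharing a flank contribute three genes, not four. Desert ranking
is lexicographic: positives in the target tissue, then tested elements,
then coordinates.

The package ships a published desert table as a fixture
(`load_desert_fixture()`). The printed table gives desert intervals and
positive element ids but no element coordinates, so the accompanying
element catalog is synthetic: intervals constructed inside the
corresponding desert, positivity following the table, plus four
constructed tested-negative elements in the chromosome 7 desert. Assembly
labels are treated as opaque text; the package never converts coordinates
between assemblies.

# The synthetic generator

`sim_config()` defaults define the conditions the rest of the package is
tested under, chosen to emulate a real embryonic H3K27ac atlas at desk
scale:

| parameter | default | rationale |
|---|---|---|
| samples | 17 | a realistic multi-stage embryonic atlas |
| genome | 2 × 12 Mb | smallest geometry holding all planted structure |
| clusters | 50 typical + 10 super | minority of supers, as on real rank curves |
| segments per cluster | 4–6 of 1–2 kb | enhancer-segment scale |
| intra-cluster gaps | 0.5–5 kb | below the 12.5 kb stitch distance |
| inter-cluster gaps | ≥ 20 kb | above it, so clusters never co-stitch |
| signal means (per bp) | typical 5, super 50, input 1 | 10× super/typical ratio |
| bin noise sd | 1.0 | moderate bin-level variability |
| sharing fractions | 0.6 / 0.2 / 0.2 | shared / embryonic / specific mix |
| deserts | 3 × 700 kb | above the 500 kb rule |
| elements | 24, half positive | desert-resident evidence |

Coverage is emitted in fixed 50-bp bins over cluster members only
(implicit zero elsewhere), which keeps files small and re-reading exact.
Signal is planted at cluster level — every member of a super cluster
shares the elevated mean — so the sample's rank curve has the hockey-stick
shape the cutoff assumes. Each emitted file draws from its own random
stream derived from `(seed, file role)`, so adding samples or catalogs
never perturbs previously generated files, and a given configuration is
byte-reproducible. Desert boundaries are pinned by sentinel protein-coding
genes ending/starting exactly at the planted edges, and the rest of the
gene tiling is dense enough that only planted gaps reach desert length, so
`find_deserts()` recovers the manifest deserts exactly. Desert-resident
noncoding genes are kept near the desert edge so the centrally planted
noncoding cluster keeps a realistic (~200 kb) distance to its nearest TSS.

What the generator does *not* emulate: read-level noise and peak-calling
artifacts, H3K27ac spatial autocorrelation, replicate and batch structure,
copy-number variation, or the long-tailed size distribution of real
superenhancers. Passing planted-truth recovery therefore demonstrates that
the algorithms are implemented correctly and are stable under bin-level
noise — not that the pipeline's biological calls on real data are correct.

Scale: with the default configuration the generator writes ~1.3 MB of text
in ~2 s and the full pipeline runs in ~8 s; the noise-robustness benchmark
in the test suite uses 10 seeds at 4 samples each, since per-sample recall
does not depend on the number of samples.

# Orchestration

`run_pipeline()` executes call → merge → classify → annotate → deserts →
prioritize, validating that every referenced file exists before any stage
runs, writing each stage's table under `out_dir` (the per-sample call
tables are sufficient to resume the merge stage, which the tests verify),
and emitting a `report.json` with the headline numbers. Errors halt the
run with the failing stage named. All randomness lives in the generator;
the pipeline itself is deterministic, and rerunning on identical inputs
reproduces every output byte. The numbered scripts under `analysis/`
present the same stages as a narrative workflow.

# Known limitations

* The merge rule (any-overlap single linkage) can chain loosely
  overlapping calls across samples into one long region; alternative
  reciprocal-overlap merging is not built in.
* Signal scores are unnormalized sums; comparing absolute scores across
  samples with very different sequencing depths requires prior scaling of
  the tracks.
* The chi-squared comparison requires adequately filled 2×2 tables; small
  atlases (like the default synthetic one) frequently yield untestable or
  null results, which the report marks rather than replaces.
* bigWig/BAM inputs are out of scope; tracks must be provided as bedGraph.
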