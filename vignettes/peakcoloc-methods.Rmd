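---
title: "peakcoloc: models, null hypotheses, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakcoloc: models, null hypotheses, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcoloc)
```

## The problem

Two ChIP-seq experiments on the same cells yield two peak sets — two
collections of genomic intervals. "Do the factors interact on DNA?" hides
two distinct statistical questions. The *site-sharing* question asks, for
each individual query region, whether its proximity to the reference set is
more extreme than random placement predicts; the answer is summarized as
the Overlap Correlation Value (OCV). The *spatial-correlation* question
asks whether the two sets as wholes are arranged non-independently along
the chromosomes. The package computes both, because the biologically
interesting case is precisely when they disagree: factors whose regions
cluster in the same neighbourhoods (significant spatial correlation)
without co-occupying most individual sites (low OCV).

## Coordinate model

Intervals are 0-based, half-open `[start, end)` throughout — in memory, in
BED files, and in every formula. Two consequences are load-bearing:

* a printed region `chr1:7507615-7508428` has length exactly
  `end - start` = 813 bp;
* *book-ended* intervals (`a.end == b.start`) share no base pair and do
  not intersect, but their edge-to-edge gap is 0. We accept this
  measure-zero wrinkle ("gap 0" is implied by, but does not imply,
  intersection) rather than special-casing the gap formula
  `max(0, b.start - a.end, a.start - b.end)`.

Merging unions book-ended intervals (gap 0 counts as contiguous), so
coverage and projection arithmetic never see 1-bp slivers. At chromosome
edges, summit-centred resizing clamps rather than drops, so paired
analyses keep their region counts aligned. Chromosomes absent from the
declared genome layout are rejected by default (opt-in drop-with-warning):
a silent coordinate-space mismatch is the classic interval-analysis bug.
The median of an even-sized length sample is the mean of the two central
values.

## The per-region proximity p-value

For a query region q of length L whose nearest reference region lies at
edge-to-edge gap d, the p-value is the probability that a random placement
does at least as well:

* **placement space**: all integer starts s such that `[s, s+L)` fits on
  its chromosome *and* the placed midpoint `s + floor(L/2)` lies inside
  the domain, pooled by summation over every domain chromosome;
* **event**: the placed interval's gap to the nearest reference region is
  ≤ d.

Both counts are computed in closed form: the event region on the start
axis is the union over reference regions `[r1, r2)` of
`[r1 - L - d, r2 + d + 1)`, merged and intersected with the valid-start
space. The arithmetic is integer-exact, so the implementation is tested
for *equality* (not approximate agreement) against exhaustive enumeration
of every placement on toy chromosomes.

Choices worth recording, since the underlying idea admits variants:

* **Length-matched null.** The null interval has the query's own length,
  not a point. Long regions reach further, and their p-values must account
  for it.
* **Domain membership by midpoint**, applied to query *and* reference
  regions. One unambiguous rule for regions straddling window edges,
  used identically in domain sweeps and region-to-gene association. The
  result object records `reference_filtered = TRUE` because restricting
  only the query would be a defensible alternative.
* **p ∈ (0, 1]** always: the observed placement is itself in the event
  set, so the numerator is ≥ 1. A query on a chromosome with no in-domain
  reference region gets p = 1 (every placement trivially ties an infinite
  gap) rather than an error, but an entirely reference-free domain is an
  error.
* **OCV threshold** α = 0.05, compared strictly (`p < α`). OCV is exactly
  `#{p < α} / n_in_domain`.

This is a faithful reimplementation of the published *description* of the
per-region interval statistic, not a port of any external tool's code;
bit-identical agreement with such tools is explicitly not claimed.

## The spatial test battery

All permutation tests share one null: each query region is independently
re-placed uniformly on its own chromosome (start uniform on
`[0, chrom_len - L]`), lengths and chromosome assignments preserved,
self-overlap allowed, reference fixed. This is the simplest exchangeable
null; sharing it across tests makes their p-values comparable. Which set
is shuffled matters — the battery shuffles the *query*, and the tests are
therefore asymmetric even when the statistic (Jaccard) is symmetric.
Permutation p-values use the plus-one estimator
`(1 + #{null ≥ obs}) / (1 + n_perm)`, bounded below by `1/(n_perm+1)` and
never 0. The default `n_perm = 10000` matches common practice for genomic
Monte Carlo testing; tests accept smaller values for desk-scale runs.
Attraction-sided p-values are primary (the scientific question is
convergence); the projection test also reports a doubled two-sided value.

Test-specific notes:

* **Relative distance**: for each query midpoint flanked on both sides by
  reference midpoints, `r = min(d_left, d_right) / (d_left + d_right)` is
  Uniform(0, 0.5) under independence. Chromosome-edge midpoints without
  both flanks are dropped and counted (no wraparound — circularization is
  meaningless on linear chromosomes). The KS p-value is asymptotic, with a
  `small_sample` flag below n = 35; integer coordinates can create ties in
  r, which make the KS test mildly conservative.
* **Absolute distance**: mean distance between query midpoints and their
  nearest reference midpoints; query chromosomes with no reference region
  are dropped with a warning.
* **Projection**: the count of query midpoints inside the merged reference
  coverage is Binomial(n, c) with c the whole-genome coverage fraction;
  whole-genome (not domain-restricted) coverage is used.
* **Master seeding**: `run_all_spatial_tests()` derives per-test sub-seeds
  from the master seed by fixed offsets (+101, +211, +307), so adding or
  removing a test never perturbs another's stream; per-test failures are
  captured as error records without aborting the batch.

## TSS domains and region-to-gene association

TSS windows are strand-aware and half-open after mapping: for a `+` gene,
window `(-500, +500)` becomes `[tss-500, tss+500)` — exactly 1,000 bp.
Regulatory domains follow the basal-plus-extension rule: a basal window
(default 5 kb upstream / 1 kb downstream, strand-aware) extended on each
side to the nearer of 1 Mb from the TSS or the adjacent gene's basal
boundary, never shrinking below the gene's own basal window. Basal windows
of distinct genes may overlap; extensions stop only at neighbouring basal
boundaries; TSS ties break by gene id. Gene input is a 4-column TSS table
rather than BED6 gene bodies, because the TSS convention inside BED6 is
ambiguous; the `tss_from_bed6()` converter takes `start` (`+` strand) or
`end` (`-` strand) as the TSS. Edge cases beyond the stated rule
(unstranded genes, exotic overlaps) are this package's own choices and
documented as such.

## What the synthetic generator does and does not emulate

`simulate_pair()` produces paired cistromes on a default toy genome of 5
chromosomes × 20 Mb (large enough that ~2,000 peaks of ~1.5 kb cover
< 3% of it, matching the sparse-coverage regime of real cistromes, small
enough for fast permutation). Region lengths are log-normal — the natural
two-parameter family with mean > median, as both emulated peak-size
summaries show — with `meanlog = log(median)` and
`sdlog = sqrt(2 log(mean/median))` derived in closed form from a target
(mean, median). The presets target (median 1336, mean 1508) bp for the
long-fragment factor and (median 529, mean 601) bp for the short one; the
scaled-down two-factor preset `paper_mimic` uses 2,000 reference / 1,800
query regions, co-location fraction 0.25, and centre-offset SD 150 bp
(small relative to peak widths, so tied pairs nearly always overlap —
what "bound at the same site" should mean). The proximal scenario places
tied queries at `reference.end + Exp(mean 500 bp)`: near, never
overlapping.

Known departures from real data, hence what a green test does *not*
establish:

* placement is uniform per chromosome — no mappability holes, chromatin
  accessibility structure, or clustering of unrelated peaks; the null
  calibration results certify the mathematics under this null, not under
  real genomic heterogeneity;
* the log-normal reproduces a target mean/median but is heavier-tailed
  than real peak-width distributions: the long-factor preset puts ~72% of
  lengths above 1 kb where the emulated data showed ~94% — matching both
  summaries *and* the tail would need a third parameter the summaries do
  not constrain;
* chance overlap of tied/untied mixtures is estimated empirically by
  f = 0 reruns, not analytically; ground-truth labels are part of the
  generator contract so tests never re-infer them.

## Scope of validation

The interval engine and the proximity p-value are validated by equality
against brute-force oracles (all-pairs scans, per-base coverage,
exhaustive placement enumeration). The test battery's type-I error is
checked by simulation: under the null generator, each test's rejection
rate at α = 0.05 must lie within binomial 99% bounds over 500 replicates,
and per-region p-values must be approximately uniform. Power properties
are asserted structurally: in the proximal scenario the distance-based
tests reject while base-pair-sharing statistics (interval count, Jaccard,
projection) stay at chance — those statistics *cannot* register
attraction for constructed non-overlap, which is the very dichotomy the
package exists to expose. One acceptance test intentionally asserts the
stronger claim that all five tests reject there; its three failing
sub-assertions are kept visible as documentation of this geometric fact
rather than silenced.

No quantitative claim about any real cistrome pair is asserted anywhere:
the emulated study's headline numbers derive from raw sequencing data
without a printed accession, so the acceptance report contains no
paper-value targets, and all validation is against oracles, analytic
limits, and the generator's stated world.
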