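---
title: "Two-dimensional pooled sequencing: model, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-dimensional pooled sequencing: model, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolpin)
```

## The problem and the design

Deep targeted resequencing of hundreds of individuals is the natural follow-up
to an association signal: the variants that matter are rare, so every sample
must be sequenced deeply, but preparing an indexed library per sample defeats
the cost advantage of pooling. One-dimensional pooling is cheap but anonymous —
a variant call cannot be traced to the carrier.

`poolpin` implements the two-dimensional compromise. Samples are arranged into
matrices of `n_rows x n_cols` (the canonical configuration is four 12 x 12
matrices over 576 samples) and DNA is pooled twice: every grid row is one pool
and every grid column is another, so each sample is sequenced in exactly one
row pool and one column pool, and a heterozygous carrier contributes an
expected allele fraction of `1/(2 * pool size)` — 1/24 for 12-sample pools —
to each of them. Calling variants independently in all `n_rows + n_cols` pools
of a matrix and intersecting the observations gives per-variant classes:

* **pinnable** — observed in exactly one row and one or more columns (or
  exactly one column and one or more rows). The carriers are the samples at
  the grid intersections; the call is traced to named individuals.
* **multiple** — observed in more than one row *and* more than one column.
  Exact carriers are unidentifiable, but every observed row or column holds at
  least one carrier and the intersection set is a superset of the carriers.
* **singleton** — observed on one axis only. Impossible if both of the
  carrier's pools behaved: every sample is sequenced twice, so a singleton is
  a false positive in the observed pool or a false negative in an intersecting
  pool. The class exists to be filtered, and that filtering is the main
  accuracy benefit of the second dimension.
* **missing coverage** — too many pools lacked usable coverage at the site to
  distinguish the classes.

## The per-pool caller

Calling is purely count-based, from pileup-style per-position base counts.
Three quantities decide the call for each (position, alternate allele) pair:

1. **Quality-filtered depth.** Only bases with Phred quality ≥ 30 count
   (`min_base_quality`); fractions divide by this filtered depth. A position
   with fewer than `min_depth = 200` filtered reads is `insufficient` — the
   floor guarantees each of the 12 individuals in the pool at least
   `floor(200/12) = 16` reads under even pooling.
2. **Start-point-bias score.** PCR duplicates cannot be removed in pooled data
   (duplicate removal would distort the very allele fractions being measured),
   so duplication is detected instead: with `d_i` reads beginning at the i-th
   distinct start point, the score is the effective number of start points,
   `(sum d_i)^2 / sum d_i^2` (an inverse Simpson index). It is 1 when all
   reads share a single start point and rises to `n` for an even split over
   `n` starts. Positions scoring below `min_start_point_score = 1.25` are
   `insufficient`. When the input pileup carries no start-point annotation the
   filter is not evaluable and is treated as passing — the score exists to
   catch start-point bias, which cannot be assessed without the data.
3. **Alternate-allele fraction** `f`, partitioned strictly into four states:
   `f > 1%` is a *confident variant*; `0.5% < f ≤ 1%` a *potential variant*;
   `0.1% ≤ f ≤ 0.5%` a *potential reference* call; `f < 0.1%` a *confident
   reference* call. Boundary values are assigned to the lower tier (exactly
   1% is only *potential*), and the 0.1–0.5% band belongs to
   *potential reference*; the caller's tests verify that exactly one state
   fires for every (depth, count) pair and that the state is monotone in the
   alternate count.

Reference-state calls are retained deliberately: knowing a variant is *absent*
from a pool is what makes the intersection argument work. Masked positions
(BED exclusion masks, e.g. repeat or self-chain tracks) are skipped before any
call is made. Each alternate allele at a position is called independently, and
indel alleles (keyed by their pileup `+SEQ`/`-SEQ` strings) flow through the
same fraction thresholds.

## Classification rules and their order

Per matrix, the per-variant vector over all pools is classified in a fixed
order: (1) a variant with no *confident* observation anywhere is discarded —
potential-only evidence is too weak to enter any class; (2) if more than
`max_insufficient_pools` pools are `insufficient` the variant is
`missing_coverage`; (3) otherwise the observed sets (confident or potential
observations) decide pinnable / multiple / singleton as above. The default
`max_insufficient_pools = 2` means three or more insufficient pools block
classification; the knob is exposed because one could also argue for a
threshold of "more than three", and the choice measurably shifts the
missing-coverage tally in low-coverage data. A variant observed in two or
more rows and no column is still a singleton — the definition bounds only the
axis, not the multiplicity.

Across matrices, identity is the variant key (chrom, pos, ref, alt); the
class is a per-matrix attribute. A key classified differently in two matrices
contributes to both classes' unique tallies, and its matrices-observed count
uses every matrix where it was emitted. Known-site annotation (any VCF of
catalogued sites) reports, per class, the percentage of unique keys present
in the catalogue — a useful proxy for how common each class's variants are in
the population, and historically the evidence that singletons are mostly
artefacts.

## The synthetic generator

The generator exists because the classifier's guarantees are combinatorial
and can be verified exactly against a known truth. It emulates:

* **Genotypes.** Per site an alternate-allele frequency is drawn from a
  configurable spectrum (point mass, uniform, or beta); each sample is
  binomial(2, f). The default point mass at 0.5% puts most matrices in the
  0–3 carrier regime where pinnable calls live.
* **Pooling.** A pool's expected alternate fraction is the weighted mean of
  its members' allele dosages — `k/24` for `k` alternate copies among 12
  equally pooled samples. An optional weight vector models uneven pooling.
* **Depth.** Negative binomial with mean `mean_depth` (default 4,320, the
  per-pool average of a sequenced matrix's column set) and size parameter
  `depth_dispersion` (default 20, coefficient of variation ≈ 22%).
* **Errors.** Each read miscalls with probability `error_rate`, uniformly to
  the three other bases. Simulated base qualities are all above the q30
  filter, so the filter is exercised by hand-built pileup fixtures instead.
* **Start points.** A Poisson number of distinct start points (mean
  `start_points`, default 50, floored at 2) with multinomial multiplicities;
  a degenerate single-start mode exists to exercise the bias filter.
* **Injected faults.** Per (pool, site), false-negative dropout erases a
  truly present variant from one pool and false-positive injection plants an
  above-threshold count — both create the singleton-class events the design
  exists to expose. `inject_dropout()` does the same surgically.

Determinism: one master seed; every pool draws from a substream derived
deterministically from the seed and the pool's identity, so identical
configurations are bit-identical regardless of evaluation order.

What the generator does **not** emulate: read-level artefacts (alignment
error, mapping ambiguity, strand effects), capture bias along the target,
correlated errors at difficult motifs, index hopping between barcoded pools,
and contamination. Passing the noiseless recovery tests therefore
demonstrates the *combinatorial* correctness of calling plus deconvolution —
that true single-axis carrier sets are recovered exactly and no spurious
singletons arise from the machinery itself — not robustness to every failure
mode of real libraries. The fault-injection tests cover the designed failure
modes (dropout, spurious calls) one at a time.

## Numerical and interface choices

* Grid indices and pileup/VCF positions are 1-based; BED masks are 0-based
  half-open. Mask membership is resolved through interval overlap
  (`GenomicRanges`), and overlapping mask intervals are allowed.
* Samples fill matrices row-major. Any bijection is equivalent for the
  method; fixing one makes manifests reproducible.
* Pileup files are the classic 6-column samtools dialect. Start-point groups
  are encoded by `^` markers on the first read of each group — a column whose
  first read carries no marker is treated as lacking start information.
  Deletion placeholders (`*`) consume a quality character but are never
  counted as alleles; indels are keyed by their upper-cased pileup string
  with no left-alignment (realignment is upstream of this package).
* The depth grid used by the caller's partition test (depths 0–400, all
  alternate counts) covers every threshold boundary exactly once; simulation
  scales in the test-suite and acceptance script (600–1,000 sites, four
  matrices, depth 4,000) are chosen so binomial noise at a 1/24 fraction is
  ≥ 10 standard deviations clear of the 1% threshold, making the expected
  recovery rate exactly 100%.

## Limitations

Multiples are identifiable only up to their intersection superset — more
pooling dimensions, not deeper sequencing, would be needed to pin common
variants. Two simultaneous faults at one site (e.g. dropout in both of a
carrier's pools) erase the variant entirely rather than flagging it. The
caller's fixed fraction tiers assume pools of equal size; markedly uneven
pooling shifts a carrier's expected fraction and is modelled in the
generator, but the thresholds themselves are not weight-aware.
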