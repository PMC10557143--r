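---
title: "Methods: screening ChIP-seq peak sets for R-loop and G-quadruplex co-localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening ChIP-seq peak sets for R-loop and G-quadruplex co-localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakcoloc)
```

## The problem

R-loops (RNA:DNA hybrids with a displaced DNA strand) and DNA
G-quadruplexes (G4s) are non-canonical nucleic-acid structures that
co-occur preferentially in the promoters of active human genes. A simple
and effective way to discover proteins that bind these structures in
chromatin is a co-occupancy screen: take many transcription-factor (TF)
ChIP-seq peak sets, intersect each with genome-wide R-loop maps (R-ChIP)
and G4 maps (BG4 ChIP), and ask what percentage of each protein's binding
sites coincides with each structure. Proteins whose binding sites overlap
*both* structure classes at high percentage are candidate structure-binding
proteins; across hundreds of proteins the two percentage vectors are
strongly positively correlated, reflecting the co-enrichment of the two
structures themselves.

`peakcoloc` implements that screen and its companion analyses — promoter
annotation of peaks, signal aggregation around peak centers, scaled-gene
metagene profiles, region densities, RPKM-style normalization and exon
exclusion-ratio summaries — as ordinary tidyverse-style functions over
tibbles, plus a seeded synthetic-data generator that makes the whole
pipeline testable end-to-end without any external download.

## Overlap semantics

Every coordinate in the package is 0-based half-open (the BED convention of
all input formats). Two intervals overlap iff they are on the same
chromosome, compared as exact strings, and share at least one base:
`a.start < b.end && b.start < a.end`. Abutting intervals do not overlap.

`intersect_report_a(a, b)` reproduces the record-level reporting semantics
of `bedtools intersect -wa -u` with its default 1-bp minimum overlap: each
record of `a` is reported at most once, in input order, iff it overlaps at
least one record of `b`. No overlap fraction is applied and duplicate
records in `a` are reported independently; whether the original screens
deduplicated within a peak file is not documented upstream, so this package
deliberately does not deduplicate and leaves that to the caller. Queries
run through `GenomicRanges::findOverlaps`; the test suite holds this
against a brute-force all-pairs scan on a thousand random instances.

The overlap percentage for a protein is
`100 * |intersect_report_a(peaks, structures)| / |peaks|`, undefined (an
error, never an imputed zero) for an empty peak set.

## The screen

`run_screen()` computes, per protein, the overlap counts and percentages
against the R-loop and G4 sets and their joint count, then the Pearson
product-moment correlation between the G4 and R-loop percentage vectors
across proteins. "Pearson" is a deliberate reading: a correlation
coefficient quoted without an estimator name on a scatter plot of
percentages is conventionally the product-moment `r`. The correlation is
reported only when there are at least three retained proteins and both
columns have nonzero variance; otherwise it is `NA` with a classed warning,
never a silently propagated `NaN`.

`rank_candidates()` orders proteins by `min(pct_rloop, pct_g4)` descending.
The upstream description of interesting candidates is only "high overlap
with both"; the minimum of the two percentages is this package's concrete
choice of ranking statistic because it rewards proteins high on *both*
axes, and it is exposed as an ordinary column so users can re-rank freely.

## Promoter annotation

The promoter window of a gene is anchored at its TSS, strand-aware:
`[tss - upstream, tss + downstream)` in the gene's own orientation, clipped
to the chromosome. The default of −1000/+500 bp is a common convention,
chosen once here because published screens of this kind rarely state their
promoter definition (nor the annotation build behind it), which makes
externally reported promoter-localization percentages qualitative context
at best; this package's own acceptance checks are against fractions it
plants itself. Classification precedence is promoter >
genic > intergenic, membership is existential (≥ 1 bp of the full peak, or
of the 1-bp summit with `by_summit = TRUE`), and overlapping windows from
different genes are intentionally not merged — merging cannot change an
existential test and unmerged windows keep their gene attribution.

## Signal profiles

A coverage track is a per-chromosome step function (sorted, non-overlapping
steps; gaps mean zero). The value of a bin is the *length-weighted mean* of
the step function over the bin, with the full bin width as denominator.
A mean, not a sum, because it makes a constant track yield an exactly
constant curve at any bin size; whether the original aggregation plots used
mean or sum per bin is unstated, so the choice is documented here and the
bin size is a parameter.

* `aggregate_profile()` tiles `[center − window, center + window)` around
  each anchor (peak summit when called, else the floored midpoint) into
  `bin_size` bins; defaults 2,000 bp / 50 bp follow the conventions of the
  standard deep-sequencing profilers. Anchors whose window leaves the
  chromosome are dropped entirely and counted, never zero-padded, to avoid
  deflating curve edges.
* `metagene_profile()` scales each gene body into `body_bins` equal-length
  coordinate slices (boundaries `start + floor(j*L/body_bins)`) with
  fixed-size flank bins on both sides (defaults: 2,000 bp flanks, 100 body
  bins, 50 bp flank bins). Bins are always computed in genomic order and
  the per-gene vector is reversed for minus-strand genes, which makes a
  gene and its exact coordinate mirror produce bit-identical curves.
* `region_density()` computes `signal / (kb of region) / (total/1e6)`, and
  `rpkm_normalize()` the same normalization for read counts over a genome
  tiling — both plain formulas checked against naive recomputation.
* `exclusion_ratio()` is `exclusion / (inclusion + exclusion)`; with both
  operands zero the ratio is missing, never zero. `ratio_table()` averages
  per-replicate ratios and reports SEM = sd/√n over replicates (matching
  per-lane gel quantification with n = 3), rather than pooling counts.
  Group testing is intentionally out of scope.

## The synthetic-data generator

The generator emulates the *structure* of the real inputs: many TF peak
sets whose overlap fractions with two structure peak sets are heterogeneous
and mutually correlated; structure peaks enriched in strand-aware promoter
windows and co-occurring with each other; coverage with bumps at peak
centers; a polymerase-like track with distinct promoter and gene-body
levels.

Its key property is **exact planting**. Rather than drawing per-peak
Bernoulli memberships, it fixes counts (`round(n * f)`) and realizes them
geometrically: a peak that must overlap set X but not set Y is placed
wholly inside a piece of `reduce(X) \ reduce(Y)`; background peaks are
placed wholly inside the complement of all structure and promoter regions
(an exclusion mask). Placement inside a piece guarantees ≥ 1 bp overlap
with some member of X and zero overlap with Y, so planted counts are exact
with no sampling error — the acceptance surface tests identities, not
approximations. The generator re-derives every planted count from its own
output with the package's overlap engine before returning, and
`simulate_scenario()` additionally re-reads the *written files* and
re-screens them, so the JSON ledger is guaranteed consistent with the
emitted bytes.

Default study conditions, fixed once: a 2 × 10 Mb toy genome; 500
non-overlapping genes of 5–15 kb; 1,000 peaks per structure set with 70%
planted promoter localization and 50% G4-in-R-loop co-occurrence; 50
proteins × 500 peaks with per-protein R-loop fractions uniform on
[0.05, 0.9] and the planted relation
`f_g4 = clamp(0.8 * f_rloop + 0.05 + N(0, 0.05), 0, 1)`; peak widths
discretized-lognormal with median 300 bp (a plausible ChIP-seq peak
scale). Coverage bumps are Gaussians of amplitude 10 and σ = 150 bp at
structure peak centers on a background of 5 with additive noise of sd 1,
binned at 50 bp; the polymerase-style track plants promoter and body
plateau levels at 3 and 1. The nonzero background exists so that clamping
the noisy track at zero (coverage cannot be negative) introduces no
measurable bias; bump tails are evaluated out to 8σ, beyond which the
omitted mass is below 1.5e-13 of the amplitude and therefore negligible
against every agreement tolerance used. One global random stream per
scenario, set from the single integer seed, makes every emitted byte a
deterministic function of that seed.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: sequence content (no G-rich motifs, no real
G4-forming potential), read-level noise and mappability artifacts, peak
callers' width/summit behavior, chromatin-state spatial correlation beyond
promoter enrichment, inter-protein correlation structure beyond the single
planted linear relation, and any biological causality. The acceptance
checks demonstrate that the *computations* are exact and stable, not that
the biology would reproduce.

## Numerical and degenerate-input choices

* Percentages and ratios are held at full double precision internally;
  TSV output rounds percentages to 4 decimals (the precision style of the
  quantities the screen reports), with the correlation written at full
  precision in a metadata line.
* Zero-length intervals are rejected at validation, not special-cased in
  queries; empty `b` sets give empty intersections; empty query sets make
  ratio statistics errors, not zeros.
* Midpoints of even-length peaks use the floor; candidate-ranking ties
  break alphabetically; `which.max` ties (exactly symmetric curves) resolve
  to the leftmost of the two central bins.
* Problem sizes throughout the tests and the acceptance script — 50 × 500
  screens, 1,000-instance oracle sweeps, 200-anchor profiles, 500-gene
  metagenes — were chosen as the smallest sizes at which every planted
  quantity is still recovered at its stated tolerance with wide margin;
  they are the package's default study conditions, not estimates of any
  published dataset's scale.

## Known limitations

* No overlap-significance testing (permutation or shuffling nulls): the
  screen reports descriptive percentages, as the method it implements does.
* bigWig I/O is out of scope; tracks travel as bedGraph. BAM-level
  processing, peak calling and alignment are likewise upstream of this
  package.
* The correlation is computed over whatever proteins survive the
  zero-peak filter; with very few proteins it is reported but fragile, and
  the record count always travels with it.
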