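---
title: "Representing and querying pairwise genomic interactions"
author: "loopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representing and querying pairwise genomic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkit)
```

## The data model

Chromosome conformation assays (Hi-C, ChIA-PET, capture Hi-C) report
*pairwise* interactions: each observation connects two genomic intervals,
the **anchors**, and carries a measurement such as a read-pair count. The
natural home of such data is the two-dimensional **interaction space**,
where the point $(x, y)$ denotes a contact between loci $x$ and $y$.
`loopkit` provides three coupled containers for this space:

* **`RegionSet`** — a strictly sorted, deduplicated list of reference
  regions. Every coordinate in the package is stored here exactly once.
* **`InteractionTable`** — parallel vectors of *anchor indices*
  $(a_1[i], a_2[i])$ pointing into the `RegionSet`, plus per-interaction
  metadata columns and free-form global metadata. Because loop anchors
  recur across many interactions (a promoter contacting dozens of
  enhancers, bins of a contact map), indexing a shared region store
  reduces both memory use and computation: a per-region quantity is
  computed once over the (small) reference set and fanned out by index.
* **`AssaySet`** — an `InteractionTable` plus any number of
  interaction × sample matrices (counts, normalized intensities, ...) and
  a sample-metadata table, so that experimental data and coordinates
  subset together.
* **`ContactMatrix`** — the same interaction space as a grid: row and
  column index vectors into a `RegionSet` and a value grid with an
  explicit empty-cell marker, in a dense or sparse backend.

Coordinates are **0-based half-open** throughout, the native convention
of BEDPE/BED, so files round-trip bit-exactly; any 1-based display is
presentation only. Zero-width regions are rejected at validation because
their overlap semantics are ambiguous. Strand is stored (it is part of
region identity for deduplication) but ignored by every overlap and
distance computation, since none of the supported methods are
strand-conditional.

### Canonical order and strictness

The reference set is sorted by chromosome, then start, then end, then
strand ($+$, $-$, $.$). Chromosome order is lexicographic by default —
`chr10` before `chr2` — because it is deterministic without a genome
file; an explicit `chrom_levels` vector can be supplied at construction
and then governs all sorting for that object. The sort order of the
reference set was a genuinely open choice; lexicographic was selected as
the one reproducible everywhere, and every ordering-sensitive operation
funnels through it.

An interaction is undirected, so `(a, b)` and `(b, a)` describe the same
contact. Rather than a separate type, a `strict` flag requests the
canonical representation $a_1 \le a_2$ at construction, and
`swap_anchors()` canonicalizes any table after the fact. Duplicate
detection (`interaction_duplicated()`) deliberately compares *stored*
pairs only; symmetric duplicates are found by the explicit two-step
recipe `swap_anchors()` then `interaction_duplicated()`, which keeps each
primitive deterministic and composable.

## Overlap semantics

All overlap machinery reduces to one predicate, `region_overlap()`: two
regions overlap when they share a chromosome and either their
intersection is at least `minoverlap` (default 1) bases, or — only when
`minoverlap` is 1 — the gap between them is at most `maxgap` (default 0).
With half-open intervals, abutting regions have a gap of zero and so
count as overlapping under the defaults. The defaults give plain
intersection semantics; the two knobs exist because practitioners often
want "within N bp of" queries against loop anchors.

On top of this sit the one- and two-dimensional queries:

* `overlaps_any_region()` — 1D: either anchor hits the subject.
* `overlaps_pair()` — 2D: one anchor hits region A *and* the other hits
  region B, in either assignment (so the query is symmetric in A and B).
* `overlaps_interactions()` — 2D between two tables. "Corresponding
  anchors" admits two readings: slot-matched only, or either pairing.
  The permissive either-pairing reading is the default, because anchor
  order is storage detail for undirected contacts; `match_slots = TRUE`
  selects the stricter behavior for callers who maintain a meaningful
  slot convention.
* `link_overlaps()` — given one or two sets of regions of interest,
  reports `(interaction, subject1, subject2)` triplets: gene–gene
  contacts from one set, gene–enhancer contacts from two. In single-set
  mode triplets are canonicalized (`subject1 <= subject2`) and
  deduplicated; self-pairs (both anchors in the same subject) are kept,
  since dropping them is a one-line filter but recovering them is not.

Internally the engines are vectorized per-chromosome cross products —
adequate for the annotation-scale queries the package targets — and the
test suite holds every query equal to an exhaustive brute-force
evaluation of the stated predicate on seeded random fixtures.

## Distances, bounding boxes, linearization

`pair_distance()` computes the linear-genome separation of the two
anchors per interaction, the quantity inspected when fitting
distance-dependent contact decay. Three modes: `mid` (absolute difference
of interval midpoints $(start+end)/2$; may be half-integral and is
reported as-is), `gap` (bases strictly between the anchors, clamped at
0), and `span` (total footprint, `max(end) - min(start)`). For disjoint
cis pairs `span = gap + width1 + width2` exactly. Inter-chromosomal pairs
have no linear distance: every mode returns `NA` there, and `is_intra()`
exposes the cis/trans flag directly.

`bounding_box()` summarizes a group of interactions by the minimal
axis-aligned rectangle containing them in interaction space. Rows are
first canonicalized with `swap_anchors()` so "slot 1" is well defined;
each slot of a group must then lie on one chromosome (mixed groups are an
error naming the group). Minimality is literal: shrinking any box edge by
one base excludes at least one member anchor.

`linearize()` converts interaction data to a 4C-like view. Given a bait
region, interactions with a 1D bait overlap are selected and, per
interaction, the anchor *not* overlapping the bait is reported together
with that interaction's assay rows — a per-region signal track on the
linear genome describing contact strength with the bait. Interactions
whose anchors *both* overlap the bait have no unambiguous non-bait
anchor; fabricating one silently would invent signal, so such rows are
dropped by default and `keep_double = TRUE` opts into keeping them
(reporting the canonical lower-sorted anchor). Multiple interactions may
project onto the same region; rows are carried over one-to-one, never
aggregated, because aggregation policy (sum? mean? max?) belongs to the
caller. Bait overlap uses the default `maxgap = 0`, `minoverlap = 1`.

## The matrix view

`inflate()` fills a `ContactMatrix` from an `InteractionTable` given
caller-supplied row and column region lists (typically `tile_genome()`
bins); `deflate()` is the inverse, emitting one interaction per non-empty
cell with the value as a `value` metadata column. Cell matching is by
*exact coordinate identity* in either anchor order — not by overlap.
Binning anchors onto a grid is left to the caller precisely so that
inflate/deflate form a lossless pair. Because either-order matching fills
both symmetric cells of a square grid, the round trip is completed by
`swap_anchors()` + duplicate removal + `canonical_sort()`, which the test
suite verifies reproduces the source (anchor, value) multiset exactly.

Numerical conventions worth stating:

* The empty-cell marker is distinct from numeric zero. Dense matrices use
  `NA`; a stored 0 is a real measurement.
* The sparse backend (`Matrix::sparseMatrix`) represents empty as
  absence, so a stored zero would be indistinguishable from an empty
  cell. To keep the backends logically equivalent, zeros are rejected in
  the sparse backend at validation; dense is the right backend for data
  with meaningful zeros.
* Several interactions can legitimately map to one cell (duplicate rows,
  identical anchors). The behavior is undefined in the abstract, so it is
  a parameter: `combine = "error"` (default, safest), `"sum"`, or
  `"first"`.
* Matrices are not forced symmetric; symmetric duplicates are reconciled
  downstream by the canonical recipe above.

## Input and output

`read_bedpe()`/`write_bedpe()` implement strict tab-separated BEDPE with
0-based half-open coordinates taken verbatim: columns 7–10
(name/score/strand1/strand2) become metadata when present, `.` maps to
`NA`, columns beyond 10 are preserved as opaque `extra*` columns, and the
writer emits exactly the columns present so that files round-trip
byte-identically. Strands from a BEDPE are kept as metadata columns
rather than written into the anchor regions, leaving region identity
purely positional for imported data. `read_bed()`/`write_bed()` cover
BED3/BED4 annotation and bait files; `write_bedgraph()` exports a
`LinearTrack` one file per assay per sample; contact matrices serialize
as COO triplet text or dense TSV. Output numbers print as integers when
whole and with one decimal when half-integral (midpoint distances), which
keeps goldens byte-stable.

A thin command-line wrapper, `cli_main()` (installed as `exec/loopkit`),
exposes `convert`, `overlap`, `linearize`, `dist`, `bbox` and `simulate`
subcommands; each is a direct call into the functions above, prints
tab-separated text on stdout, and the tests pin CLI output to the
corresponding library results.

## The synthetic-data generator

`simulate_interaction_data()` generates the seeded fixtures used
throughout the tests and the reproduction script. It emulates the two
gross features of real interaction data that the package's methods
exercise: a cis/trans mixture and distance-dependent cis signal decay.
Anchors are fixed-width 1 kb windows placed uniformly on a three-
chromosome toy genome (1 Mb / 0.8 Mb / 0.5 Mb by default); each
interaction is intra-chromosomal with probability 0.8, a typical cis
fraction for Hi-C libraries. Counts are negative-binomial with dispersion
0.5 (`rnbinom` size 2); the cis mean is $10 \cdot (1 + d/1000)^{-e}$ with
$d$ the mid-to-mid distance in bp and $e$ the decay exponent (default 1),
i.e. a power-law decay in kilobase units anchored at a base mean of 10
for adjacent windows, and the trans mean is a constant 1. The kilobase
scaling is this package's choice of distance unit: it puts short-range
pairs at the base mean and megabase-range pairs near zero, giving count
matrices that look like sparse Hi-C data. One integer seed drives a
single private RNG stream (the caller's `.Random.seed` is saved and
restored), so identical seeds give byte-identical objects on any
platform.

What the generator does *not* emulate: TADs and compartments,
restriction-fragment structure, mappability and GC biases, or library-
size differences between samples. Tests passing on these fixtures
therefore demonstrate the correctness of the data model and its queries
— index bookkeeping, overlap semantics, round trips — not the
biological fidelity of any downstream analysis. Only sign and ordering
properties of the stochastic outputs are ever asserted (e.g. a negative
Spearman correlation between distance and mean cis count at $n = 2000$),
never exact stochastic values.

## Problem sizes and limitations

The suite runs brute-force oracle comparisons at up to 200 interactions
× 50 subjects per fixture (20 seeded fixtures per query type), distance
closed forms at 1,000 random pairs, bounding-box minimality on 100 random
groups, and BEDPE round trips at 1,000 rows — sizes at which exhaustive
all-pairs evaluation is exact and fast. The package itself targets
annotation-scale data (loop calls, capture designs, binned toy matrices):
the overlap engines are per-chromosome vectorized cross products, not
interval trees, and `overlaps_interactions()` materializes an $n_1 \times
n_2$ logical grid, so genome-wide fragment-level Hi-C (millions of pairs)
is out of scope. Also deliberately out of scope: fitting the
distance-decay trend itself, matrix balancing/normalization, statistical
testing of differential interactions, strand-aware overlaps, and binary
Hi-C container formats (`.hic`, `.cool`).
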