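# loopkit

Infrastructure for **pairwise genomic interaction data** — the output of
Hi-C, ChIA-PET, capture Hi-C and related chromosome conformation assays.
These experiments report contacts between pairs of genomic intervals
("anchors"), which do not fit the interval-plus-measurement containers
used for linear genomic data. `loopkit` supplies the missing data model
and its low-level method surface, for analysts working with loop calls
and binned contact data and for developers building higher-level tools
on top of a shared representation.

## The model

An interaction set is stored in three coupled pieces:

* **`RegionSet`** — a sorted, deduplicated reference list of regions
  (0-based half-open coordinates, the BEDPE convention). Every distinct
  coordinate is stored once.
* **`InteractionTable`** — parallel anchor-index vectors
  *(a₁\[i\], a₂\[i\])* into the `RegionSet`, one pair per interaction,
  plus per-interaction metadata. Point *(x, y)* of the resulting
  "interaction space" is a contact between loci *x* and *y*.
* **`AssaySet`** — an `InteractionTable` plus named interaction × sample
  data matrices (counts, intensities) and sample metadata;
  **`ContactMatrix`** is the same space as a dense or sparse grid whose
  rows/columns also index the `RegionSet`.

On top of the containers sit the field's standard queries: 1D overlap
(either anchor hits a region), 2D overlap (the anchors hit two given
regions, or the anchors of another interaction), region linking
(gene–gene / gene–enhancer triplets via `link_overlaps`), anchor
distances (`mid`/`gap`/`span`, `NA` for trans pairs), minimum bounding
boxes for interaction groups, bait-centric `linearize()` to a 4C-like
track, lossless `inflate()`/`deflate()` between list and matrix views,
BEDPE/BED/bedGraph interchange, a CLI, and a seeded synthetic-data
generator.

## Worked example

Link an enhancer to its target genes through loop calls, then take a
virtual-4C cross-section around a promoter:

```r
library(loopkit)

genes <- gregions(c("chr1", "chr1"), c(1000, 40000), c(3000, 42000),
                  name = c("geneA", "geneB"))
enh   <- gregions("chr1", 25000, 26000, name = "enh1")
loops <- make_interactions(
  gregions("chr1", c(1500, 41000, 1500), c(2500, 41800, 2500)),
  gregions("chr1", c(25200, 25300, 90000), c(26000, 25900, 91000)),
  metadata = data.frame(name = c("L1", "L2", "L3")))
loops
#> InteractionTable with 3 interaction(s) over 5 region(s)
#>            anchor1          anchor2 name
#> 1   chr1:1500-2500 chr1:25200-26000   L1
#> 2 chr1:41000-41800 chr1:25300-25900   L2
#> 3   chr1:1500-2500 chr1:90000-91000   L3

link_overlaps(loops, genes, enh)
#>   interaction subject1 subject2
#> 1           1        1        1
#> 2           2        2        1
```

Loops L1 and L2 connect the enhancer (subject2 = 1) to geneA and geneB
respectively; L3 touches neither subject set. Anchor midpoint distances
in bp (all pairs are cis here, so none are `NA`):

```r
pair_distance(loops, "mid")
#> [1] 23600 15800 88500
```

Attach counts for two samples and linearize around the geneA promoter:
interactions with exactly one anchor in the bait are kept and their
*other* anchor becomes a row of the track, data carried over unchanged:

```r
aset  <- make_assay_set(loops, list(counts = matrix(c(12, 8, 3, 9, 11, 2), ncol = 2)))
track <- linearize(aset, gregions("chr1", 0, 5000))
regions(track)
#>   chrom start   end strand
#> 1  chr1 25200 26000      .
#> 2  chr1 90000 91000      .
get_assay(track)
#>      [,1] [,2]
#> [1,]   12    9
#> [2,]    3    2
```

So the promoter contacts the enhancer with counts 12 and 9, and an
unannotated distal locus with counts 3 and 2; L2 (no bait overlap) is
excluded. See the vignette (`vignettes/interaction-data-model.Rmd`) for
the overlap semantics, the matrix backends and the design rationale.

A command-line wrapper is installed at `exec/loopkit`:

```sh
loopkit dist --bedpe loops.bedpe --mode gap
loopkit overlap --bedpe loops.bedpe --bed genes.bed --bed2 enhancers.bed --mode link
loopkit simulate --n 1000 --seed 7 > sim.bedpe
```

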