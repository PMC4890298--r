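test_that("region_overlap handles containment, abutment and gaps", {
  a <- gregions("chr1", 100, 200)
  expect_true(region_overlap(a, gregions("chr1", 150, 160)))
  # abutting half-open intervals have gap 0, accepted at maxgap = 0
  expect_true(region_overlap(a, gregions("chr1", 200, 300)))
  expect_false(region_overlap(a, gregions("chr1", 210, 220), maxgap = 9))
  expect_true(region_overlap(a, gregions("chr1", 210, 220), maxgap = 10))
  expect_false(region_overlap(a, gregions("chr2", 100, 200)))
  # minoverlap > 1 disables the gap clause entirely
  expect_false(region_overlap(a, gregions("chr1", 200, 300),
                              minoverlap = 2))
  expect_false(region_overlap(a, gregions("chr1", 199, 300),
                              minoverlap = 2))
  expect_true(region_overlap(a, gregions("chr1", 198, 300),
                             minoverlap = 2))
  expect_error(region_overlap(a, a, maxgap = -1), "maxgap")
  expect_error(region_overlap(a, a, minoverlap = 0), "minoverlap")
})

test_that("one-dimensional overlaps report each (query, subject) pair once", {
  t <- make_interactions(gregions("chr1", 100, 200),
                         gregions("chr1", 500, 600))
  expect_same_hits(overlaps_any_region(t, gregions("chr1", 550, 560)),
                   data.frame(query = 1L, subject = 1L))
  expect_equal(nrow(overlaps_any_region(t, gregions("chr1", 250, 300))),
               0L)
  # both anchors hit the same subject -> one hit
  expect_same_hits(overlaps_any_region(t, gregions("chr1", 0, 1000)),
                   data.frame(query = 1L, subject = 1L))
})

test_that("paired-region overlap accepts either anchor assignment", {
  t <- make_interactions(gregions("chr1", 100, 200),
                         gregions("chr1", 500, 600))
  gene <- gregions("chr1", 150, 160)
  enhancer <- gregions("chr1", 550, 560)
  expect_true(overlaps_pair(t, gene, enhancer))
  expect_true(overlaps_pair(t, enhancer, gene))
  # a one-dimensional hit alone is not a two-dimensional overlap
  expect_false(overlaps_pair(t, gene, gregions("chr1", 900, 950)))
  trans <- make_interactions(gregions("chr1", 100, 200),
                             gregions("chr2", 500, 600))
  expect_true(overlaps_pair(trans, gregions("chr2", 550, 560),
                            gregions("chr1", 150, 160)))
})

test_that("interaction-vs-interaction overlap honours either pairing and the slot-matched flag", {
  t1 <- make_interactions(gregions("chr1", 100, 200),
                          gregions("chr1", 500, 600))
  expect_same_hits(overlaps_interactions(t1, t1),
                   data.frame(query = 1L, subject = 1L))
  flipped <- make_interactions(gregions("chr1", 500, 600),
                               gregions("chr1", 100, 200))
  expect_same_hits(overlaps_interactions(t1, flipped),
                   data.frame(query = 1L, subject = 1L))
  expect_equal(nrow(overlaps_interactions(t1, flipped,
                                          match_slots = TRUE)), 0L)
  # overlap in only one slot is not enough
  half <- make_interactions(gregions("chr1", 150, 250),
                            gregions("chr1", 900, 950))
  expect_equal(nrow(overlaps_interactions(t1, half)), 0L)
})

test_that("overlap queries match the exhaustive oracle on random fixtures", {
  for (seed in 1:4) {
    set.seed(seed)
    t <- rand_table(60, max_pos = 4000)
    subjects <- rand_regions(20, max_pos = 4000)
    mg <- sample(c(0, 5, 50), 1)
    mo <- sample(c(1, 1, 25), 1)
    expect_same_hits(overlaps_any_region(t, subjects, mg, mo),
                     bf_overlaps_any(t, subjects, mg, mo))
    ra <- subjects[1, , drop = FALSE]
    rb <- subjects[2, , drop = FALSE]
    expect_equal(overlaps_pair(t, ra, rb, mg, mo),
                 bf_overlaps_pair(t, ra, rb, mg, mo))
    t2 <- rand_table(40, max_pos = 4000)
    expect_same_hits(overlaps_interactions(t, t2, mg, mo),
                     bf_overlaps_interactions(t, t2, mg, mo))
    expect_same_hits(link_overlaps(t, subjects, NULL, mg, mo),
                     bf_link_overlaps(t, subjects, NULL, mg, mo))
  }
})

test_that("interaction overlap hits transpose between the two tables", {
  set.seed(5)
  t1 <- rand_table(50, max_pos = 3000)
  t2 <- rand_table(50, max_pos = 3000)
  fwd <- overlaps_interactions(t1, t2)
  rev <- overlaps_interactions(t2, t1)
  expect_same_hits(sort_pairs(data.frame(query = rev$subject,
                                         subject = rev$query)), fwd)
})

test_that("region linking finds gene/enhancer triplets in both modes", {
  t <- make_interactions(gregions("chr1", 100, 200),
                         gregions("chr1", 500, 600))
  genes <- gregions("chr1", 150, 160)
  enhancers <- gregions("chr1", 550, 560)
  expect_same_hits(link_overlaps(t, genes, enhancers),
                   data.frame(interaction = 1L, subject1 = 1L,
                              subject2 = 1L))
  single <- link_overlaps(t, rbind(genes, enhancers))
  expect_same_hits(single, data.frame(interaction = 1L, subject1 = 1L,
                                      subject2 = 2L))
  expect_equal(nrow(link_overlaps(t, gregions("chr2", 0, 100))), 0L)
  # self-pairs are kept when both anchors hit the same subject
  wide <- gregions("chr1", 0, 1000)
  expect_same_hits(link_overlaps(t, wide),
                   data.frame(interaction = 1L, subject1 = 1L,
                              subject2 = 1L))
})

test_that("pair_distance implements the mid/gap/span closed forms", {
  t <- make_interactions(gregions("chr1", 100, 200),
                         gregions("chr1", 300, 400))
  expect_equal(pair_distance(t, "mid"), 200)
  expect_equal(pair_distance(t, "gap"), 100)
  expect_equal(pair_distance(t, "span"), 300)
  over <- make_interactions(gregions("chr1", 100, 300),
                            gregions("chr1", 200, 400))
  expect_equal(pair_distance(over, "gap"), 0)
  trans <- make_interactions(gregions("chr1", 100, 200),
                             gregions("chr2", 100, 200))
  expect_true(all(is.na(c(pair_distance(trans, "mid"),
                          pair_distance(trans, "gap"),
                          pair_distance(trans, "span")))))
  # half-integral midpoints are reported as-is
  odd <- make_interactions(gregions("chr1", 0, 5),
                           gregions("chr1", 10, 20))
  expect_equal(pair_distance(odd, "mid"), 12.5)
  expect_error(pair_distance(t, "hypotenuse"))
})

test_that("distance identities hold on random pairs and survive anchor swaps", {
  set.seed(13)
  t <- rand_table(400)
  cis <- is_intra(t)
  gap <- pair_distance(t, "gap")
  span <- pair_distance(t, "span")
  a <- anchors(t)
  w1 <- a$first$end - a$first$start
  w2 <- a$second$end - a$second$start
  disjoint <- cis & gap > 0
  expect_true(any(disjoint))
  expect_equal(span[disjoint], (gap + w1 + w2)[disjoint])
  expect_identical(is.na(gap), !cis)
  s <- swap_anchors(t)
  for (mode in c("mid", "gap", "span")) {
    expect_equal(pair_distance(s, mode), pair_distance(t, mode))
  }
  subjects <- rand_regions(10)
  expect_same_hits(overlaps_any_region(s, subjects),
                   overlaps_any_region(t, subjects))
})

test_that("bounding boxes span exactly their members", {
  t <- make_interactions(
    gregions(c("chr1", "chr1"), c(100, 150), c(200, 250)),
    gregions(c("chr2", "chr2"), c(300, 100), c(400, 150)))
  bb <- bounding_box(t, c("g", "g"))
  expect_equal(bb$chrom1, "chr1")
  expect_equal(c(bb$start1, bb$end1), c(100, 250))
  expect_equal(c(bb$start2, bb$end2), c(100, 400))
  expect_equal(bb$n_members, 2L)

  single <- bounding_box(t[1], "solo")
  expect_equal(c(single$start1, single$end1, single$start2, single$end2),
               c(100, 200, 300, 400))

  mixed <- make_interactions(
    gregions(c("chr1", "chr3"), c(0, 0), c(10, 10)),
    gregions(c("chr2", "chr2"), c(0, 0), c(10, 10)))
  expect_error(bounding_box(mixed, c("bad", "bad")), "bad")
})

test_that("bounding boxes are minimal on random canonical groups", {
  set.seed(17)
  for (rep in 1:20) {
    k <- sample(2:8, 1)
    # trans group: slot chromosomes fixed, row order scrambled
    a1 <- rand_regions(k, chroms = "chr1")
    a2 <- rand_regions(k, chroms = "chr2")
    flip <- sample(c(TRUE, FALSE), k, replace = TRUE)
    t <- make_interactions(rbind(a1[!flip, ], a2[flip, ]),
                           rbind(a2[!flip, ], a1[flip, ]))
    bb <- bounding_box(t, rep("g", k))
    expect_equal(bb$start1, min(a1$start))
    expect_equal(bb$end1, max(a1$end))
    expect_equal(bb$start2, min(a2$start))
    expect_equal(bb$end2, max(a2$end))
    # every member inside; any 1 bp shrink excludes a member
    expect_true(all(a1$start >= bb$start1 & a1$end <= bb$end1))
    expect_true(all(a2$start >= bb$start2 & a2$end <= bb$end2))
    expect_true(any(a1$start == bb$start1) && any(a1$end == bb$end1))
    expect_true(any(a2$start == bb$start2) && any(a2$end == bb$end2))
  }
})

test_that("1D overlap pairs agree with IRanges on a shared-semantics case", {
  set.seed(19)
  a <- rand_regions(80, chroms = "chr1")
  b <- rand_regions(30, chroms = "chr1")
  # plain intersection >= 1 bp: exclude abutment to match strict overlap
  got <- loopkit:::overlap_pairs(a, b, maxgap = 0, minoverlap = 1)
  got <- got[(pmin(a$end[got$i], b$end[got$j]) -
                pmax(a$start[got$i], b$start[got$j])) >= 1, ]
  ir <- IRanges::findOverlaps(
    IRanges::IRanges(a$start + 1, a$end),
    IRanges::IRanges(b$start + 1, b$end))
  want <- data.frame(i = S4Vectors::queryHits(ir),
                     j = S4Vectors::subjectHits(ir))
  expect_same_hits(sort_pairs(got), sort_pairs(want))
})
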