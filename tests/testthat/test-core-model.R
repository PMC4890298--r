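test_that("build_region_set sorts, deduplicates and maps every input back", {
  r <- gregions(c("chr1", "chr1", "chr1"), c(20, 1, 20), c(30, 10, 30))
  b <- build_region_set(r)
  expect_equal(regions(b$region_set)$start, c(1, 20))
  expect_equal(b$index_map, c(2L, 1L, 2L))

  empty <- build_region_set(gregions(character(0), numeric(0), numeric(0)))
  expect_equal(length(empty$region_set), 0L)
  expect_equal(empty$index_map, integer(0))

  # lexicographic chromosome order: chr10 sorts before chr2
  r2 <- gregions(c("chr2", "chr1", "chr10"), c(0, 50, 0), c(5, 60, 5))
  b2 <- build_region_set(r2)
  expect_equal(regions(b2$region_set)$chrom, c("chr1", "chr10", "chr2"))
  expect_equal(b2$index_map, c(3L, 1L, 2L))

  # identity: mapped indices resolve to the exact input coordinates
  got <- regions(b2$region_set)[b2$index_map, , drop = FALSE]
  rownames(got) <- NULL
  expect_identical(got, r2)
})

test_that("build_region_set is invariant under input permutation", {
  set.seed(11)
  for (rep in 1:5) {
    r <- rand_regions(40)
    perm <- sample(nrow(r))
    b1 <- build_region_set(r)
    b2 <- build_region_set(r[perm, , drop = FALSE])
    expect_identical(regions(b1$region_set), regions(b2$region_set))
    expect_identical(b1$index_map[perm], b2$index_map)
  }
})

test_that("an explicit chromosome order governs sorting", {
  r <- gregions(c("chr2", "chr1", "chr10"), c(0, 50, 0), c(5, 60, 5))
  b <- build_region_set(r, chrom_levels = c("chr1", "chr2", "chr10"))
  expect_equal(regions(b$region_set)$chrom, c("chr1", "chr2", "chr10"))
  expect_error(build_region_set(r, chrom_levels = c("chr1", "chr2")),
               "chr10")
})

test_that("invalid regions are rejected with the offending position", {
  expect_error(gregions("chr1", 10, 10), "region 1")
  expect_error(gregions(c("chr1", "chr1"), c(0, 5), c(10, 3)), "region 2")
  expect_error(gregions("chr1", -1, 10), "non-negative")
  expect_error(gregions("", 0, 10), "non-empty")
  expect_error(gregions("chr1", 0, 10, strand = "*"), "strand")
})

test_that("make_interactions stores anchors losslessly and strict mode swaps", {
  a1 <- gregions("chr1", 1, 10)
  a2 <- gregions("chr1", 20, 30)
  t <- make_interactions(a1, a2)
  expect_equal(length(t@region_set), 2L)
  expect_equal(anchor_ids(t), list(anchor1 = 1L, anchor2 = 2L))

  t_rev <- make_interactions(a2, a1, strict = TRUE)
  expect_equal(anchor_ids(t_rev), list(anchor1 = 1L, anchor2 = 2L))

  expect_error(make_interactions(rand_regions(2), rand_regions(3)),
               "length")
})

test_that("anchors/make_interactions round-trips arbitrary input", {
  set.seed(23)
  for (rep in 1:5) {
    a1 <- rand_regions(60)
    a2 <- rand_regions(60)
    t <- make_interactions(a1, a2)
    got <- anchors(t)
    expect_identical(got$first, a1)
    expect_identical(got$second, a2)
    expect_identical(anchors(t, "first"), a1)
    expect_identical(anchors(t, "second"), a2)
  }
  t0 <- make_interactions(rand_regions(0), rand_regions(0))
  expect_equal(nrow(anchors(t0, "first")), 0L)
  expect_error(anchors(t0, "nope"))
})

test_that("swap_anchors canonicalizes pairs without touching anything else", {
  set.seed(31)
  t <- rand_table(50)
  s <- swap_anchors(t)
  expect_true(all(s@anchor1 <= s@anchor2))
  expect_identical(s@metadata, t@metadata)
  expect_identical(regions(s), regions(t))
  # unordered pair identity preserved per row
  expect_identical(pmin(s@anchor1, s@anchor2), pmin(t@anchor1, t@anchor2))
  expect_identical(pmax(s@anchor1, s@anchor2), pmax(t@anchor1, t@anchor2))
  expect_identical(swap_anchors(s), s)
})

test_that("concat unions region sets and preserves resolved coordinates", {
  set.seed(41)
  t1 <- rand_table(20)
  t2 <- rand_table(15)
  both <- concat_interactions(t1, t2)
  expect_equal(length(both), 35L)
  a <- anchors(both)
  a1 <- anchors(t1); a2 <- anchors(t2)
  expect_identical(a$first, rbind(a1$first, a2$first))
  expect_identical(a$second, rbind(a1$second, a2$second))
  # shared regions stored once
  expect_equal(anyDuplicated(loopkit:::region_key(regions(both))), 0L)

  empty <- rand_table(0)
  back <- concat_interactions(empty, t1)
  expect_identical(anchors(back), anchors(t1))
  expect_identical(back@metadata, t1@metadata)

  t3 <- rand_table(5, metadata = FALSE)
  expect_error(concat_interactions(t1, t3), "metadata")
})

test_that("canonical_sort matches a brute-force comparison sort and is stable", {
  set.seed(53)
  for (rep in 1:5) {
    t <- rand_table(80, max_pos = 300, max_width = 50)  # force ties
    cs <- canonical_sort(t)
    # brute-force: order by pair with stable ties via row number
    key <- order(t@anchor1, t@anchor2, seq_along(t@anchor1))
    expect_identical(cs$permutation, key)
    expect_identical(anchors(cs$table),
                     anchors(t[cs$permutation]))
    sorted_pairs <- cbind(cs$table@anchor1, cs$table@anchor2)
    expect_true(all(diff(order(sorted_pairs[, 1], sorted_pairs[, 2])) == 1))
  }
  t <- rand_table(10)
  once <- canonical_sort(t)$table
  expect_identical(canonical_sort(once)$permutation, seq_len(10L))
})

test_that("duplicate flags use stored pairs; swap first for symmetric dups", {
  reg <- gregions(c("chr1", "chr1"), c(1, 20), c(10, 30))
  t <- make_interactions(reg[c(1, 1, 2), ], reg[c(2, 2, 1), ])
  expect_equal(interaction_duplicated(t), c(FALSE, TRUE, FALSE))
  expect_equal(interaction_duplicated(swap_anchors(t)),
               c(FALSE, TRUE, TRUE))
  expect_equal(interaction_duplicated(rand_table(0)), logical(0))
})

test_that("strict mode survives construction, concat and subsetting", {
  set.seed(61)
  t1 <- rand_table(30, strict = TRUE)
  t2 <- rand_table(30, strict = TRUE)
  expect_true(all(t1@anchor1 <= t1@anchor2))
  both <- concat_interactions(t1, t2)
  expect_true(both@strict)
  expect_true(all(both@anchor1 <= both@anchor2))
  sub <- both[sample(length(both), 10)]
  expect_true(sub@strict)
  expect_true(all(sub@anchor1 <= sub@anchor2))
})

test_that("row subsetting keeps metadata aligned and rejects bad indices", {
  set.seed(71)
  t <- rand_table(12)
  sub <- t[c(3, 3, 1)]
  expect_equal(length(sub), 3L)
  expect_equal(sub@metadata$name, t@metadata$name[c(3, 3, 1)])
  expect_identical(anchors(sub, "first"),
                   anchors(t, "first")[c(3, 3, 1), , drop = FALSE] |>
                     (\(d) { rownames(d) <- NULL; d })())
  expect_error(t[100], "out of bounds")
})
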