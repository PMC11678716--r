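test_that("intersect reports overlapping pairs with half-open semantics", {
  a <- gi("chr1", 100, 200)
  b <- gi("chr1", 150, 250)
  hits <- intersect_intervals(a, b)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$overlap, 50L)

  # half-open abutment is not an overlap
  expect_equal(nrow(intersect_intervals(gi("chr1", 100, 200),
                                        gi("chr1", 200, 300))), 0L)
  # but a window of 0 admits it
  expect_equal(window_join(gi("chr1", 100, 200),
                           gi("chr1", 200, 300), 0)$gap, 0L)

  expect_error(intersect_intervals(a, b, min_overlap = 0), "min_overlap")
})

test_that("window_join computes edge-to-edge gaps", {
  a <- gi("chr1", 1000, 1100)
  b <- gi("chr1", 5000, 5100)
  w <- window_join(a, b, 10000)
  expect_equal(nrow(w), 1L)
  expect_equal(w$gap, 3900L)
  expect_equal(nrow(window_join(a, b, 3000)), 0L)
  # different chromosomes never pair
  expect_equal(nrow(window_join(a, gi("chr2", 1000, 1100), 1e6)), 0L)
})

test_that("coverage_fraction merges overlapping cover intervals", {
  a <- gi("chr1", 0, 100)
  expect_equal(coverage_fraction(a, gi("chr1", 50, 150)), 0.5)
  expect_equal(coverage_fraction(a, gi(character(), integer(), integer())), 0)
  expect_equal(coverage_fraction(a, gi(c("chr1", "chr1"), c(10, 40),
                                       c(60, 90))), 0.8)
})

test_that("malformed intervals are rejected with the offending record named", {
  expect_error(gi("chr1", c(0, 50), c(10, 50)), "record 2")
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 4))
  expect_error(validate_intervals(gr, "baits"), "malformed interval in baits")
})

test_that("stratify_by_distance assigns the smallest qualifying bound", {
  baits <- gi("chr1", 1000, 1100)
  targets <- gi(c("chr1", "chr1"), c(5000, 26000), c(5100, 26100))
  s <- stratify_by_distance(baits, targets, bounds = c(0, 10000, 20000, 30000))
  expect_equal(s$gap, c(3900L, 24900L))
  expect_equal(s$stratum, c(10000, 30000))

  # an overlapping pair lands in stratum 0 only
  s0 <- stratify_by_distance(gi("chr1", 100, 300), gi("chr1", 250, 400),
                             bounds = c(0, 10000))
  expect_equal(s0$stratum, 0)
  expect_equal(nrow(s0), 1L)

  expect_error(stratify_by_distance(baits, targets, bounds = c(10000, 10000)),
               "strictly increasing")
})

test_that("interval operations agree with brute-force oracles", {
  set.seed(42)
  bounds <- c(0, 2000, 5000, 10000)
  for (rep in 1:40) {
    a <- random_bed(sample(1:60, 1))
    b <- random_bed(sample(1:60, 1))
    ga <- bed_gr(a); gb <- bed_gr(b)

    got <- intersect_intervals(ga, gb)
    want <- bf_intersect(a, b)
    expect_equal(pair_key(got, c("a_idx", "b_idx", "overlap")),
                 pair_key(want, c("a_idx", "b_idx", "overlap")))

    d <- sample(c(0, 500, 5000), 1)
    got_w <- window_join(ga, gb, d)
    want_w <- bf_window(a, b, d)
    expect_equal(pair_key(got_w, c("a_idx", "b_idx", "gap")),
                 pair_key(want_w, c("a_idx", "b_idx", "gap")))

    expect_equal(coverage_fraction(ga, gb), bf_coverage(a, b))

    got_s <- stratify_by_distance(ga, gb, bounds)
    want_s <- bf_stratify(a, b, bounds)
    expect_equal(pair_key(got_s, c("bait_idx", "target_idx", "gap", "stratum")),
                 pair_key(want_s, c("bait_idx", "target_idx", "gap",
                                    "stratum")))
  }
})

test_that("intersect is symmetric under transposition", {
  set.seed(7)
  a <- bed_gr(random_bed(40)); b <- bed_gr(random_bed(40))
  ab <- intersect_intervals(a, b)
  ba <- intersect_intervals(b, a)
  expect_equal(pair_key(ab, c("a_idx", "b_idx")),
               sort(paste(ba$b_idx, ba$a_idx, sep = "|")))
})

test_that("coverage is monotone in the cover set and split-invariant", {
  set.seed(11)
  a <- bed_gr(random_bed(30))
  b1 <- random_bed(20); b2 <- random_bed(10)
  cov1 <- coverage_fraction(a, bed_gr(b1))
  cov12 <- coverage_fraction(a, bed_gr(rbind(b1, b2)))
  expect_true(all(cov12 >= cov1 - 1e-12))

  # splitting a cover interval at an interior point changes nothing
  long <- data.frame(chrom = "chrA", start = 1000L, end = 5000L)
  split2 <- data.frame(chrom = "chrA", start = c(1000L, 3000L),
                       end = c(3000L, 5000L))
  expect_equal(coverage_fraction(a, bed_gr(long)),
               coverage_fraction(a, bed_gr(split2)))
})

test_that("strata partition the full window result", {
  set.seed(99)
  bounds <- c(0, 1000, 3000, 8000)
  for (rep in 1:20) {
    a <- bed_gr(random_bed(40)); b <- bed_gr(random_bed(40))
    s <- stratify_by_distance(a, b, bounds)
    w <- window_join(a, b, max(bounds))
    # disjoint strata: every pair appears exactly once
    expect_false(any(duplicated(paste(s$bait_idx, s$target_idx))))
    # union equals the single max-bound window
    expect_equal(pair_key(s, c("bait_idx", "target_idx", "gap")),
                 pair_key(data.frame(bait_idx = w$a_idx, target_idx = w$b_idx,
                                     gap = w$gap),
                          c("bait_idx", "target_idx", "gap")))
    # stratum is the smallest admitting bound
    expect_true(all(s$gap <= s$stratum))
    prev <- c(-1, bounds)[match(s$stratum, bounds)]
    expect_true(all(s$gap > prev))
  }
})
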