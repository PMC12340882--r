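test_that("merge unions, sorts and rejects invalid intervals", {
  expect_equal(nrow(regions_merge(NULL)$intervals), 0)

  r <- regions_merge(data.frame(seq = "chr1", start = c(0, 5), end = c(10, 20)))
  expect_equal(r$intervals$start, 0)
  expect_equal(r$intervals$end, 20)

  r <- regions_merge(data.frame(seq = "chr1", start = c(0, 10, 30),
                                end = c(10, 20, 40)))
  expect_equal(r$intervals$start, c(0, 30)) # abutting intervals merge
  expect_equal(r$intervals$end, c(20, 40))

  expect_error(regions_merge(data.frame(seq = "chr1", start = 5, end = 5)),
               "invalid interval")
  expect_error(region_set(data.frame(seq = "chr1", start = 0, end = 200),
                          seqlengths = c(chr1 = 100)), "exceeds")
})

test_that("complement works within declared lengths and is an involution", {
  lens <- c(chr1 = 100)
  empty <- region_set(NULL, lens)
  expect_equal(regions_complement(empty)$intervals$end, 100)
  full <- region_set(data.frame(seq = "chr1", start = 0, end = 100), lens)
  expect_equal(nrow(regions_complement(full)$intervals), 0)

  r <- region_set(data.frame(seq = "chr1", start = c(10, 50), end = c(20, 60)),
                  lens)
  cc <- regions_complement(r)
  expect_equal(cc$intervals$start, c(0, 20, 60))
  expect_equal(cc$intervals$end, c(10, 50, 100))
  expect_identical(regions_complement(cc)$intervals, r$intervals)

  expect_error(regions_complement(region_set(
    data.frame(seq = "chrX", start = 0, end = 5))), "lengths")
})

test_that("subtract and intersect behave as set operations", {
  a <- region_set(data.frame(seq = "chr1", start = 0, end = 100))
  b <- region_set(data.frame(seq = "chr1", start = 40, end = 60))
  d <- regions_subtract(a, b)
  expect_equal(d$intervals$start, c(0, 60))
  expect_equal(d$intervals$end, c(40, 100))
  expect_equal(nrow(regions_subtract(a, a)$intervals), 0)
  expect_identical(regions_subtract(a, region_set(NULL))$intervals,
                   a$intervals)

  x <- region_set(data.frame(seq = "chr1", start = 0, end = 50))
  y <- region_set(data.frame(seq = "chr1", start = 25, end = 75))
  expect_equal(regions_intersect(x, y)$intervals$start, 25)
  expect_equal(regions_intersect(x, y)$intervals$end, 50)
  z <- region_set(data.frame(seq = "chr1", start = 80, end = 90))
  expect_equal(nrow(regions_intersect(x, z)$intervals), 0)
  expect_identical(regions_intersect(x, x)$intervals, x$intervals)
  # sequences present only in b are ignored
  w <- region_set(data.frame(seq = "chr2", start = 0, end = 10))
  expect_identical(regions_subtract(x, w)$intervals, x$intervals)
})

test_that("minimum-length filter keeps intervals of exactly min_len", {
  r <- region_set(data.frame(seq = "chr1", start = c(0, 100),
                             end = c(49, 150)))
  f <- regions_filter_min_length(r, 50)
  expect_equal(f$intervals$start, 100) # 49 < 50 dropped, 50 kept
  expect_identical(regions_filter_min_length(r, 1)$intervals, r$intervals)
  expect_equal(nrow(regions_filter_min_length(region_set(NULL), 50)$intervals), 0)
})

test_that("interval algebra agrees with a per-base bitmap oracle", {
  set.seed(101)
  lens <- c(a = 3000, b = 1200)
  for (rep in 1:25) {
    da <- rand_interval_df(sample(1:15, 1), lens)
    db <- rand_interval_df(sample(1:15, 1), lens)
    a <- region_set(da, lens); b <- region_set(db, lens)
    ba <- bitmap_from_df(da, lens); bb <- bitmap_from_df(db, lens)
    expect_regions_equal_bitmap(a, ba)
    expect_regions_equal_bitmap(regions_subtract(a, b),
                                mapply(function(x, y) x & !y, ba, bb,
                                       SIMPLIFY = FALSE))
    expect_regions_equal_bitmap(regions_intersect(a, b),
                                mapply(`&`, ba, bb, SIMPLIFY = FALSE))
    expect_regions_equal_bitmap(regions_complement(a),
                                lapply(ba, `!`))
    # De Morgan: complement of the union = intersection of complements
    u <- region_set(rbind(da, db), lens)
    lhs <- regions_complement(u)
    rhs <- regions_intersect(regions_complement(a), regions_complement(b))
    expect_identical(lhs$intervals, rhs$intervals)
    # width conservation: |a| = |a & b| + |a \ b|
    expect_equal(region_width(a),
                 region_width(regions_intersect(a, b)) +
                   region_width(regions_subtract(a, b)))
  }
})
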