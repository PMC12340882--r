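test_that("exact engine finds stated placements", {
  h <- find_hits_exact("ACGTA", coll1("TTACGTATT"), 0, "forward")
  expect_equal(h$start, 2)
  expect_equal(h$dist, 0)

  h <- find_hits_exact("ACGTA", coll1("TTACCTATT"), 1, "forward")
  expect_true(any(h$start == 2 & h$dist == 1)) # one substitution

  h <- find_hits_exact("AAAAA", coll1("TTTTT"), 0, "both")
  expect_equal(h$strand, "-")
  expect_equal(h$start, 0)

  expect_error(find_hits_exact("ACGNA", coll1("ACGTA"), 1), "ambiguous")
  expect_error(find_hits_exact("ACGTA", coll1("ACGTA"), 5), "max_d")
})

test_that("per-start distances match a naive full-DP oracle", {
  set.seed(21)
  for (rep in 1:40) {
    L <- sample(20:60, 1)
    k <- sample(5:12, 1)
    d <- sample(0:3, 1)
    txt <- rand_dna(L)
    q <- if (runif(1) < 0.5) rand_dna(k) else {
      s <- sample(1:(L - k + 1), 1)
      substr(txt, s, s + k - 1)
    }
    h <- find_hits_exact(q, coll1(txt), d, "forward")
    o <- naive_hits(q, txt, d)
    expect_equal(h$start, o$start)
    expect_equal(h$dist, o$dist)
    # end-to-end alignment length bound
    if (nrow(h) > 0) expect_true(all(abs((h$end - h$start) - k) <= h$dist))
  }
})

test_that("seeded engine reproduces the exact engine", {
  set.seed(22)
  for (rep in 1:150) {
    L <- sample(100:3000, 1)
    k <- sample(c(11, 31), 1)
    d <- sample(0:min(7, k - 1), 1)
    txt <- rand_dna(L)
    q <- if (runif(1) < 0.6) {
      s <- sample(1:(L - k + 1), 1)
      km <- substr(txt, s, s + k - 1)
      nmut <- sample(0:min(d + 1, 3), 1)
      if (nmut > 0) {
        for (p in sample(k, nmut)) {
          orig <- substr(km, p, p)
          km <- paste0(substr(km, 1, p - 1), sample(setdiff(DNA, orig), 1),
                       substr(km, p + 1, k))
        }
      }
      km
    } else rand_dna(k)
    coll <- coll1(txt)
    expect_identical(find_hits_seeded(q, coll, d),
                     find_hits_exact(q, coll, d))
  }
})

test_that("self hits, strand symmetry and radius monotonicity hold", {
  set.seed(23)
  txt <- rand_dna(2000)
  coll <- coll1(txt)
  for (rep in 1:10) {
    s <- sample(1:(2000 - 31), 1)
    q <- substr(txt, s, s + 30)
    h <- collapse_hits(find_hits_seeded(q, coll, 2), 2)
    fw <- h[h$strand == "+", ]
    expect_true(any(fw$start <= s - 1 & fw$end >= s - 1 & fw$dist == 0))
    # radius monotonicity on collapsed counts
    h0 <- collapse_hits(find_hits_seeded(q, coll, 0), 0)
    expect_true(nrow(h) >= nrow(h0))
  }
  # reverse-complementing the assembly flips strand labels bijectively
  q <- substr(txt, 100, 130)
  h1 <- find_hits_seeded(q, coll, 1)
  h2 <- find_hits_seeded(q, coll1(revcomp(txt)), 1)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
  expect_equal(sum(h1$strand == "-"), sum(h2$strand == "+"))
  # collapsed loci correspond one-to-one with flipped strands
  c1 <- collapse_hits(h1, 1); c2 <- collapse_hits(h2, 1)
  expect_equal(nrow(c1), nrow(c2))
  expect_equal(sort(c1$dist), sort(c2$dist))
})

test_that("collapse groups alignment jitter but keeps distant tandem copies", {
  hits <- data.frame(assembly = 0L, seq = "s", strand = "+",
                     start = c(100, 101), end = c(131, 132),
                     dist = c(1L, 0L))
  c1 <- collapse_hits(hits, 3)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$start, 101) # minimum distance wins
  hits$start <- c(100, 110); hits$dist <- c(0L, 0L)
  expect_equal(nrow(collapse_hits(hits, 3)), 2) # gap 10 > 3
  expect_equal(nrow(collapse_hits(hits[0, ], 3)), 0)
  # brute-force grouping oracle on random start sets
  set.seed(24)
  for (rep in 1:20) {
    st <- sort(sample(0:300, sample(2:20, 1)))
    d <- sample(1:5, 1)
    hh <- data.frame(assembly = 0L, seq = "s", strand = "+", start = st,
                     end = st + 20, dist = 0L)
    expect_equal(nrow(collapse_hits(hh, d)), sum(diff(st) > d) + 1)
  }
})
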