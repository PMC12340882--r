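toy_params <- function(...) {
  args <- list(k = 31, w = 10, c = 1.01, d1 = 1, d2 = 2, hamming_d = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(mask_params, args)
}

test_that("parameter invariants are enforced", {
  expect_error(mask_params(d1 = 3, d2 = 2), "d2 > d1")
  expect_error(mask_params(c = 1), "c > 1")
  expect_error(mask_params(k = 5, d2 = 7), "k > d2")
  p <- mask_params()
  expect_equal(p$k, 151L)
  expect_equal(p$w, 10L)
  expect_equal(p$c, 1.01)
})

test_that("position sampling covers the grid plus the tail", {
  expect_equal(sample_positions(20, 5, 10), c(0, 10, 15))
  expect_equal(sample_positions(151, 151, 10), 0)
  expect_equal(sample_positions(100, 151, 10), integer())
  # tail rule: the last k-mer always reaches the sequence end
  set.seed(51)
  for (rep in 1:20) {
    L <- sample(151:2000, 1); k <- sample(c(31, 151), 1); w <- sample(5:20, 1)
    p <- sample_positions(L, k, w)
    expect_true(all(diff(p) > 0))
    expect_equal(p[length(p)], L - k)
    expect_true(all(p + k <= L))
  }
})

test_that("k-mer classification applies the two conditions and N rule", {
  set.seed(52)
  txt <- rand_dna(1200)
  coll <- genome_collection(list(c(chr1 = txt)))
  p <- toy_params()
  # single-genome degenerate case: 1 hit < c*N = 1.01
  v <- classify_kmer(coll, "chr1", 500, p)
  expect_equal(v$status, "unique")
  expect_equal(v$ref_hits_d1, 1)

  # two reference copies at distance <= d1 fail condition 1
  dup <- rand_dna(100)
  coll2 <- genome_collection(list(c(chr1 = paste0(
    rand_dna(300), dup, rand_dna(300), dup, rand_dna(300)))))
  v <- classify_kmer(coll2, "chr1", 330, p)
  expect_equal(v$status, "fail_ref_multi")

  # N-containing k-mers are ambiguous
  collN <- genome_collection(list(c(chr1 = paste0(rand_dna(300), "N",
                                                  rand_dna(300)))))
  v <- classify_kmer(collN, "chr1", 290, p)
  expect_equal(v$status, "fail_ambiguous_base")
})

test_that("pangenome threshold count < c*N is strict and real-valued", {
  # N genomes and one extra copy in one sample: count N+1 vs c*N
  set.seed(53)
  locus <- rand_dna(80)
  flank <- function() rand_dna(60, c("A", "C", "G"))
  ref <- paste0(rand_dna(250), flank(), locus, flank(), rand_dna(250))
  guard <- strrep("T", 10)
  carrier <- paste0(ref, rand_dna(40), guard, locus, guard, rand_dna(40))
  N <- 5
  mk <- function(with_extra) {
    asm <- c(list(c(chr1 = ref)),
             replicate(N - 2, list(c(chr1 = ref))),
             list(c(chr1 = if (with_extra) carrier else ref)))
    genome_collection(asm)
  }
  pos <- 250 + 60 + 20 # inside the locus
  # threshold 1.01*5 = 5.05: N+1 = 6 >= 5.05 fails; N = 5 passes
  v1 <- classify_kmer(mk(TRUE), "chr1", pos, toy_params())
  expect_equal(v1$status, "fail_pan_excess")
  v2 <- classify_kmer(mk(FALSE), "chr1", pos, toy_params())
  expect_equal(v2$status, "unique")
  # a tolerant c admits the extra copy: 6 < 1.3*5 = 6.5
  v3 <- classify_kmer(mk(TRUE), "chr1", pos, toy_params(c = 1.3))
  expect_equal(v3$status, "unique")
})

test_that("failing footprints are masked and easy regions derived", {
  set.seed(54)
  p <- toy_params()
  # repeat-free reference, N = 1: the whole covered genome is easy
  txt <- rand_dna(1000)
  coll <- genome_collection(list(c(chr1 = txt)))
  len <- derive_lenient(coll, p)
  expect_equal(len$intervals$start, 0)
  expect_equal(len$intervals$end, 1000)

  # reference shorter than k is untestable, never easy
  collS <- genome_collection(list(c(chr1 = rand_dna(20))))
  expect_equal(nrow(derive_lenient(collS, p)$intervals), 0)

  # a planted exact duplication removes both copies' footprints
  dup <- rand_dna(150)
  txt2 <- paste0(rand_dna(700), dup, rand_dna(700), dup, rand_dna(700))
  coll2 <- genome_collection(list(c(chr1 = txt2)))
  res <- easy_regions(coll2, p)
  bm <- bitmap_from_regions(res$lenient, c(chr1 = nchar(txt2)))
  expect_true(all(!bm$chr1[(700 + 31):(700 + 150 - 31)]))
  expect_true(all(!bm$chr1[(1550 + 31):(1550 + 150 - 31)]))
  # masked interval is the union of failing [i, i+k) footprints
  expect_true(all((res$verdicts$status == "unique") |
                    (res$verdicts$position + 31 <= nchar(txt2))))
})

test_that("strict excises long LCRs only and stays within lenient", {
  set.seed(55)
  p <- toy_params()
  # two distinct break characters on each side keep 1 bp gapless shifts of
  # the run at Hamming distance >= 2, so it stays in the lenient set
  mk <- function(runlen, motif = "A", bl = "CG", br = "GC") {
    run <- substr(strrep(motif, runlen), 1, runlen)
    paste0(rand_dna(399), bl, run, br, rand_dna(399))
  }
  # 30 bp poly-A: kept in lenient, excised from strict
  txt <- mk(30)
  coll <- genome_collection(list(c(chr1 = txt)))
  res <- easy_regions(coll, p)
  expect_equal(region_width(res$lenient), nchar(txt))
  expect_equal(region_width(regions_subtract(res$lenient, res$strict)), 30)

  # boundary: 19 bp dinucleotide run excised, 18 bp retained
  res19 <- easy_regions(genome_collection(list(c(chr1 = mk(19, "AC")))), p)
  expect_equal(region_width(regions_subtract(res19$lenient, res19$strict)), 19)
  res18 <- easy_regions(genome_collection(list(c(chr1 = mk(18, "AC")))), p)
  expect_identical(res18$strict$intervals, res18$lenient$intervals)

  # no long LCR: strict equals lenient
  txt3 <- rand_dna(900)
  res3 <- easy_regions(genome_collection(list(c(chr1 = txt3))), p)
  expect_identical(res3$strict$intervals, res3$lenient$intervals)
})

test_that("exact and seeded engines derive identical easy regions", {
  cfg <- sim_config(seed = 88, ref_len = 8000, n_samples = 3, k = 31)
  sim <- simulate_pangenome(cfg)
  p <- sim_params(cfg)
  r_seed <- easy_regions(sim$collection, p, engine = "seeded")
  r_exact <- easy_regions(sim$collection, p, engine = "exact")
  expect_identical(r_seed$lenient$intervals, r_exact$lenient$intervals)
  expect_identical(r_seed$strict$intervals, r_exact$strict$intervals)
  expect_identical(r_seed$verdicts, r_exact$verdicts)
})

test_that("derived regions obey the structural invariants", {
  set.seed(56)
  cfg <- sim_config(seed = 77, ref_len = 12000, n_samples = 5, k = 31)
  sim <- simulate_pangenome(cfg)
  p <- sim_params(cfg)
  res <- easy_regions(sim$collection, p)
  # strict is a per-base subset of lenient
  expect_equal(region_width(regions_subtract(res$strict, res$lenient)), 0)
  # no easy interval shorter than the minimum length
  widths <- res$lenient$intervals$end - res$lenient$intervals$start
  expect_true(all(widths >= p$min_region_len))
  widths <- res$strict$intervals$end - res$strict$intervals$start
  expect_true(all(widths >= p$min_region_len))
  # easy regions never exceed the covered footprint
  cov <- region_set(data.frame(seq = "chr1", start = 0,
                               end = sim$truth$ref_len),
                    c(chr1 = sim$truth$ref_len))
  expect_equal(region_width(regions_subtract(res$lenient, cov)), 0)
  # deterministic: identical inputs give byte-identical BED output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed(res$lenient, f1)
  res2 <- easy_regions(sim$collection, p)
  write_bed(res2$lenient, f2)
  expect_identical(readLines(f1), readLines(f2))
})
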