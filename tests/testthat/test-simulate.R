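test_that("simulation is seed-deterministic and honors trivial configs", {
  cfg <- sim_config(seed = 9, ref_len = 8000, n_samples = 3, k = 31,
                    features = list())
  s1 <- simulate_pangenome(cfg)
  s2 <- simulate_pangenome(cfg)
  expect_identical(s1$collection$assemblies, s2$collection$assemblies)
  # no features, no noise: all assemblies identical to the reference
  expect_true(all(vapply(s1$collection$assemblies, identical,
                         logical(1), s1$collection$assemblies[[1]])))
  exp <- expected_regions(s1$truth, sim_params(cfg))
  expect_equal(region_width(exp$lenient), 8000)
  expect_identical(exp$strict$intervals, exp$lenient$intervals)
})

test_that("truth classes follow the planted feature logic", {
  cfg <- sim_config(seed = 10, ref_len = 20000, n_samples = 19, k = 31)
  sim <- simulate_pangenome(cfg)
  cls <- truth_classes(sim$truth, sim_params(cfg))
  get <- function(kind, which = 1) cls$expected_class[cls$kind == kind][which]
  expect_equal(get("ref_duplication", 1), "masked_by_cond1")   # divergence 0
  expect_equal(get("ref_duplication", 2), "masked_by_cond1")   # divergence d1
  expect_equal(get("sample_duplication", 1), "masked_by_cond2") # 1 carrier
  expect_equal(get("sample_duplication", 2), "easy")            # 0 carriers
  expect_equal(get("sample_deletion"), "easy")
  expect_equal(get("tandem_repeat"), "masked_by_cond1")
  lcr <- cls[cls$kind == "lcr_run", ]
  expect_equal(lcr$expected_class[(lcr$end - lcr$start) > 18],
               rep("masked_by_lcr", 2))
  expect_equal(lcr$expected_class[(lcr$end - lcr$start) <= 18], "easy")
})

test_that("carrier divergence stays within the stated edit budget", {
  cfg <- sim_config(seed = 12, ref_len = 20000, n_samples = 6, k = 31,
                    features = list(list(kind = "ref_duplication", len = 124,
                                         divergence = 1)))
  sim <- simulate_pangenome(cfg)
  f <- sim$truth$features
  locus <- substr(sim$truth$ref, f$start + 1, f$end)
  h <- find_hits_seeded(substr(locus, 1, 31), sim$collection, 1,
                        strand_mode = "forward")
  h <- collapse_hits(h, 1)
  # each genome carries exactly two copies within edit distance 1
  expect_equal(nrow(h), 2 * n_genomes(sim$collection))
})

test_that("deletions remove the locus without masking it", {
  cfg <- sim_config(seed = 13, ref_len = 12000, n_samples = 6, k = 31,
                    features = list(list(kind = "sample_deletion", len = 124,
                                         n_carriers = 3)))
  sim <- simulate_pangenome(cfg)
  f <- sim$truth$features
  q <- substr(sim$truth$ref, f$start + 31, f$start + 61)
  h <- collapse_hits(find_hits_seeded(q, sim$collection, 2), 2)
  expect_equal(nrow(h), n_genomes(sim$collection) - 3) # absent in carriers
  res <- easy_regions(sim$collection, sim_params(cfg))
  bm <- bitmap_from_regions(res$lenient, c(chr1 = sim$truth$ref_len))
  expect_true(all(bm$chr1[(f$start + 1):f$end])) # still easy
})

test_that("pipeline reproduces expected regions under SNP noise", {
  cfg <- sim_config(seed = 14, ref_len = 20000, n_samples = 5, k = 31,
                    snp_rate = 0.001)
  sim <- simulate_pangenome(cfg)
  params <- sim_params(cfg)
  exp <- expected_regions(sim$truth, params)
  res <- easy_regions(sim$collection, params)
  # sample SNPs can only remove pangenome hits, never add them, so the
  # derived sets still match the construction exactly
  expect_identical(res$lenient$intervals, exp$lenient$intervals)
  expect_identical(res$strict$intervals, exp$strict$intervals)
})

test_that("written fixture sets are consistent and re-readable", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 15, ref_len = 12000, n_samples = 3, k = 31)
  sim <- simulate_pangenome(cfg)
  write_pangenome(sim, dir)
  ref <- read_fasta(file.path(dir, "ref.fa"))
  expect_identical(ref[["chr1"]], sim$truth$ref)
  expect_equal(length(list.files(file.path(dir, "samples"))), 3)
  lenient <- read_bed(file.path(dir, "expected.lenient.bed"))
  exp <- expected_regions(sim$truth, sim_params(cfg))
  expect_identical(lenient$intervals, exp$lenient$intervals)
})
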