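test_that("allelic match fraction counts discordant overlap markers", {
  # 10 markers; S1/S2 agree on 5 of 10 in the overlap
  calls <- rbind(c(rep(0L, 10)),
                 c(rep(0L, 5), rep(2L, 5)))
  gm <- mk_gm(calls, spacing = 10000, ids = c("S1", "S2"))
  a <- mk_seg("S1", "1", 10000, 100000)
  b <- mk_seg("S2", "1", 10000, 100000)
  expect_equal(allelic_match_fraction(a, b, gm), 0.5)
  # identical calls across the whole overlap
  gm2 <- mk_gm(rbind(rep(0L, 10), rep(0L, 10)), ids = c("S1", "S2"))
  expect_equal(allelic_match_fraction(a, b, gm2), 1.0)
})

test_that("markers with a missing call in either individual are skipped", {
  calls <- rbind(c(0L, NA, 0L, 2L),
                 c(0L, 2L, NA, 0L))
  gm <- mk_gm(calls, spacing = 10000, ids = c("S1", "S2"))
  a <- mk_seg("S1", "1", 10000, 40000)
  b <- mk_seg("S2", "1", 10000, 40000)
  # comparable markers: 1 (match) and 4 (mismatch)
  expect_equal(allelic_match_fraction(a, b, gm), 0.5)
  # vacuous match when nothing is comparable
  gm_na <- mk_gm(rbind(c(0L, NA), c(NA, 0L)), ids = c("S1", "S2"))
  a2 <- mk_seg("S1", "1", 10000, 20000)
  b2 <- mk_seg("S2", "1", 10000, 20000)
  expect_equal(allelic_match_fraction(a2, b2, gm_na), 1.0)
})

test_that("non-overlapping segments are a fatal error", {
  gm <- mk_gm(matrix(0L, 2, 10), ids = c("S1", "S2"))
  expect_error(allelic_match_fraction(mk_seg("S1", "1", 10000, 20000),
                                      mk_seg("S2", "1", 50000, 60000), gm),
               "overlap")
  expect_error(allelic_match_fraction(mk_seg("S1", "1", 10000, 20000),
                                      mk_seg("S2", "2", 10000, 20000), gm),
               "chromosome")
})

test_that("pooling joins matching overlaps and separates the rest", {
  n <- 200
  hom <- rep(0L, n)
  alt <- rep(2L, n)
  gm <- mk_gm(rbind(hom, hom, alt), spacing = 10000,
              ids = c("S1", "S2", "S3"))
  segs <- rbind(mk_seg("S1", "1", 10000, 2000000, 200),
                mk_seg("S2", "1", 10000, 2000000, 200),
                mk_seg("S3", "1", 10000, 2000000, 200))
  pooled <- pool_segments(segs, gm)
  expect_equal(pooled$pool_id[1], pooled$pool_id[2])   # identical genotypes
  expect_false(pooled$pool_id[3] == pooled$pool_id[1]) # 0% match
  # different chromosomes never pool
  gm2 <- mk_gm(rbind(hom, hom), ids = c("S1", "S2"))
  segs2 <- rbind(mk_seg("S1", "1", 10000, 2000000, 200),
                 mk_seg("S2", "2", 10000, 2000000, 200))
  expect_equal(length(unique(pool_segments(segs2, gm2)$pool_id)), 2)
})

test_that("a 50% match stays below the 95% threshold and splits pools", {
  half <- c(rep(0L, 100), rep(2L, 100))
  gm <- mk_gm(rbind(rep(0L, 200), half), spacing = 10000,
              ids = c("S1", "S2"))
  segs <- rbind(mk_seg("S1", "1", 10000, 2000000, 200),
                mk_seg("S2", "1", 10000, 2000000, 200))
  expect_equal(length(unique(pool_segments(segs, gm)$pool_id)), 2)
  # the same pair pools under a permissive threshold
  expect_equal(length(unique(pool_segments(segs, gm,
                                           match_threshold = 0.4)$pool_id)), 1)
})

test_that("consensus is the member intersection with the stated filters", {
  n <- 400
  gm <- mk_gm(matrix(0L, 2, n), spacing = 10000, ids = c("S1", "S2"))
  segs <- rbind(mk_seg("S1", "1", 1000000, 3000000),
                mk_seg("S2", "1", 2000000, 4000000))
  cons <- consensus_roh(segs, gm)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start_bp, 2000000)
  expect_equal(cons$end_bp, 3000000)
  expect_equal(cons$n_snps, sum(gm$markers$pos >= 2e6 & gm$markers$pos <= 3e6))
  expect_equal(cons$n_members, 2)
  # singleton pools are never emitted
  expect_equal(nrow(consensus_roh(segs[1, ], gm)), 0)
  # an intersection at or below 100 kb is dropped
  segs_short <- rbind(mk_seg("S1", "1", 1000000, 2050000),
                      mk_seg("S2", "1", 2000000, 3000000))
  expect_equal(nrow(consensus_roh(segs_short, gm)), 0)
})

test_that("phenotype annotation splits members into cases and controls", {
  gm <- mk_gm(matrix(0L, 3, 300), spacing = 10000,
              ids = c("S1", "S2", "S3"))
  st <- data.frame(sample_id = c("S1", "S2", "S3"),
                   phenotype = c(1, 0, 1))
  segs <- rbind(mk_seg("S1", "1", 1e6, 2.5e6),
                mk_seg("S2", "1", 1.2e6, 2.6e6),
                mk_seg("S3", "1", 1.1e6, 2.4e6))
  cons <- consensus_roh(segs, gm, st)
  expect_equal(cons$n_case_members, 2)
  expect_equal(cons$n_control_members, 1)
  expect_equal(cons$n_case_members + cons$n_control_members,
               cons$n_members)
})

shared_sim <- function(seed) {
  simulate_cohort(sim_config(
    n_cases = 15, n_controls = 15, seed = seed,
    chromosomes = c(`1` = 20e6, `2` = 15e6), marker_spacing_bp = 10000,
    tract_rate = 2, missing_rate = 0.01,
    shared_tracts = data.frame(
      chrom = c("1", "2"), start = c(4e6, 2e6), end = c(7e6, 4.5e6),
      n_cases = c(6, 4), n_controls = c(3, 4))))
}

test_that("pool partition is independent of input ordering", {
  set.seed(77)
  sim <- shared_sim(5)
  segs <- call_roh_cohort(sim$gm)
  cons_a <- consensus_roh(segs, sim$gm, sim$sample_table)
  shuffled <- segs[sample(nrow(segs)), ]
  cons_b <- consensus_roh(shuffled, sim$gm, sim$sample_table)
  rownames(cons_a) <- rownames(cons_b) <- NULL
  expect_gt(nrow(cons_a), 0)
  expect_equal(cons_a[c("chrom", "start_bp", "end_bp", "n_members")],
               cons_b[c("chrom", "start_bp", "end_bp", "n_members")])
})

test_that("every consensus interval lies inside every member segment", {
  sim <- shared_sim(13)
  segs <- call_roh_cohort(sim$gm)
  pooled <- pool_segments(segs, sim$gm)
  cons <- derive_consensus(pooled, sim$gm, sim$sample_table)
  expect_gt(nrow(cons), 0)
  for (i in seq_len(nrow(cons))) {
    mem <- pooled[pooled$pool_id == cons$pool_id[i], ]
    expect_true(all(mem$start_bp <= cons$start_bp[i]))
    expect_true(all(mem$end_bp >= cons$end_bp[i]))
  }
})

test_that("stricter consensus filters select a subset of the default set", {
  sim <- shared_sim(29)
  segs <- call_roh_cohort(sim$gm)
  pooled <- pool_segments(segs, sim$gm)
  loose <- derive_consensus(pooled, sim$gm, min_snps = 3)
  strict <- derive_consensus(pooled, sim$gm, min_snps = 100)
  key <- function(x) paste(x$chrom, x$start_bp, x$end_bp)
  expect_true(all(key(strict) %in% key(loose)))
  expect_lte(nrow(strict), nrow(loose))
})
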