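test_that("interval intersection matches a per-bp scan oracle", {
  a <- data.frame(chrom = "1", start = 100, end = 200)
  b <- data.frame(chrom = "1", start = 150, end = 250)
  got <- intersect_intervals(a, b)
  expect_equal(got, data.frame(chrom = "1", start = 150L, end = 200L))
  # disjoint sets are empty
  expect_equal(nrow(intersect_intervals(
    a, data.frame(chrom = "1", start = 300, end = 400))), 0)
  expect_equal(nrow(intersect_intervals(
    a, data.frame(chrom = "2", start = 100, end = 200))), 0)
  # randomized sets against the bp-scan oracle
  set.seed(41)
  for (case in 1:25) {
    rand_set <- function() {
      n <- sample(1:8, 1)
      s <- sample(1:4500, n, TRUE)
      data.frame(chrom = sample(c("1", "2"), n, TRUE), start = s,
                 end = pmin(5000, s + sample(0:600, n, TRUE)))
    }
    a <- rand_set(); b <- rand_set()
    got <- intersect_intervals(a, b)
    rownames(got) <- NULL
    want <- oracle_intersect_bp(a, b)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$chrom, want$chrom)
    }
  }
})

test_that("interval intersection is commutative and idempotent", {
  set.seed(43)
  s <- sample(1:4000, 6, TRUE)
  a <- data.frame(chrom = "1", start = s, end = s + sample(50:500, 6, TRUE))
  s2 <- sample(1:4000, 6, TRUE)
  b <- data.frame(chrom = "1", start = s2, end = s2 + sample(50:500, 6, TRUE))
  ab <- intersect_intervals(a, b)
  ba <- intersect_intervals(b, a)
  rownames(ab) <- rownames(ba) <- NULL
  expect_equal(ab, ba)
  if (nrow(ab)) {
    again <- intersect_intervals(ab, ab)
    rownames(again) <- NULL
    expect_equal(again, ab)
  }
})

inbred_map_sim <- function(seed = 97) {
  # two shared tracts: a "risk" tract carried mostly by cases and a
  # balanced "neutral" tract; a 4 Mb tract on a 60 Mb genome gives
  # carriers F_ROH ~ 0.067, far above the 0.0156 inbred cutoff
  simulate_cohort(sim_config(
    n_cases = 40, n_controls = 40, seed = seed,
    chromosomes = c(`1` = 30e6, `2` = 30e6), marker_spacing_bp = 10000,
    tract_rate = 0.3, genotyping_error_rate = 0, missing_rate = 0,
    shared_tracts = data.frame(
      chrom = c("1", "2"), start = c(10e6, 12e6), end = c(14e6, 16e6),
      n_cases = c(12, 8), n_controls = c(2, 8))))
}

test_that("the inbred map keeps only regions shared by inbred cases", {
  sim <- inbred_map_sim()
  segs <- call_roh_cohort(sim$gm)
  prof <- summarize_homozygosity(segs, sim$gm$sample_ids,
                                 autosomal_kb = sim$truth$genome_kb)
  map <- build_inbred_map(prof, sim$sample_table, segs, sim$gm)
  expect_gt(nrow(map), 0)
  # every map region comes from >= 2 inbred cases
  inbred_cases <- prof$individual_id[
    classify_inbred(prof$froh) &
      prof$individual_id %in%
        sim$sample_table$sample_id[sim$sample_table$phenotype == 1]]
  for (i in seq_len(nrow(map))) {
    members <- strsplit(map$members[i], ",")[[1]]
    expect_gte(length(members), 2)
    expect_true(all(members %in% inbred_cases))
    expect_gt(map$n_snps[i], 100)
    expect_gt(map$length_kb[i], 100)
  }
  # with an impossible cutoff the map is empty, with a warning
  expect_warning(
    empty <- build_inbred_map(prof, sim$sample_table, segs, sim$gm,
                              cutoff = 0.9),
    "fewer than 2")
  expect_equal(nrow(empty), 0)
})

test_that("prioritization keeps risk regions and drops protective ones", {
  gm <- mk_gm(matrix(0L, 2, 3000), spacing = 10000, ids = c("S1", "S2"))
  inbred <- data.frame(pool_id = 1:2, chrom = "1",
                       start_bp = c(2e6, 10e6), end_bp = c(6e6, 14e6),
                       n_members = c(3L, 3L))
  whole <- data.frame(chrom = "1", start_bp = c(2.5e6, 10.5e6),
                      end_bp = c(5.5e6, 13.5e6), beta = c(0.5, -0.2),
                      converged = TRUE)
  pr <- prioritize_regions(inbred, whole, gm)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$start_bp, 2.5e6)
  expect_equal(pr$end_bp, 5.5e6)
  expect_equal(pr$whole_set_beta, 0.5)
  # a beta at the threshold is not kept (strict >)
  whole$beta <- c(0.03, 0.5)
  pr2 <- prioritize_regions(inbred, whole, gm)
  expect_equal(pr2$start_bp, 10.5e6)
})

test_that("prioritized fragments respect the length and SNP filters", {
  gm <- mk_gm(matrix(0L, 2, 3000), spacing = 10000, ids = c("S1", "S2"))
  inbred <- data.frame(pool_id = 1L, chrom = "1", start_bp = 2e6,
                       end_bp = 6e6, n_members = 2L)
  # overlap of only 90 kb: below the 100 kb floor
  whole <- data.frame(chrom = "1", start_bp = 5.91e6, end_bp = 8e6,
                      beta = 0.5, converged = TRUE)
  expect_equal(nrow(prioritize_regions(inbred, whole, gm)), 0)
})

test_that("locus annotation flags overlap within the configured flank", {
  regions <- data.frame(chrom = "1", start_bp = c(1e6, 5e6),
                        end_bp = c(2e6, 6e6))
  loci <- data.frame(chrom = "1", start = 2.1e6, end = 2.2e6)
  ann0 <- annotate_loci(regions, loci)
  expect_equal(ann0$near_locus, c(FALSE, FALSE))
  ann <- annotate_loci(regions, loci, flank_bp = 150000)
  expect_equal(ann$near_locus, c(TRUE, FALSE))
})

test_that("WES variant filtering applies each rule of the strategy", {
  vcf <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, "S1", list(
    c("1", 6000000, "v1", "A", "G", ".", "PASS", "AF=0.001", "GT", "1/1"),
    c("1", 6100000, "v2", "A", "G", ".", "PASS", "AF=0.001", "GT", "0/1"),
    c("1", 6200000, "v3", "A", "G", ".", "PASS", "AF=0.02", "GT", "1/1"),
    c("1", 9000000, "v4", "A", "G", ".", "PASS", "AF=0.001", "GT", "1/1"),
    c("1", 6300000, "v5", "A", "G", ".", "PASS", ".", "GT", "1/1"),
    c("2", 6000000, "v6", "A", "G", ".", "PASS", "AF=0.001", "GT", "1/1")))
  segs <- mk_seg("S1", "1", 5e6, 8e6)
  got <- filter_wes_variants(vcf, segs, maf_max = 0.01,
                             freq_fields = "AF")
  # manual rule-by-rule count: v2 is het, v3 too common, v4 outside the
  # ROH, v6 on a chromosome without a ROH; v1 and v5 (novel) survive
  expect_equal(got$id, c("v1", "v5"))
  expect_equal(got$population_maf, c(0.001, 0))
  expect_equal(got$roh_start_bp, c(5e6, 5e6))
  # restricting to prioritized regions drops candidates outside them
  reg <- data.frame(chrom = "1", start_bp = 6.25e6, end_bp = 6.5e6)
  got_reg <- filter_wes_variants(vcf, segs, 0.01, "AF", regions = reg)
  expect_equal(got_reg$id, "v5")
  expect_error(filter_wes_variants(vcf, segs, 0.01, "BOGUS"), "BOGUS")
})

test_that("an implanted rare recessive variant survives the full path", {
  sim <- inbred_map_sim(seed = 131)
  segs <- call_roh_cohort(sim$gm)
  prof <- summarize_homozygosity(segs, sim$gm$sample_ids,
                                 autosomal_kb = sim$truth$genome_kb)
  cons <- consensus_roh(segs, sim$gm, sim$sample_table)
  assoc <- consensus_assoc(cons, segs, sim$sample_table)
  map <- build_inbred_map(prof, sim$sample_table, segs, sim$gm)
  pr <- prioritize_regions(map, assoc, sim$gm)
  expect_gt(nrow(pr), 0)
  # the case-enriched tract on chromosome 1 is prioritized...
  expect_true(any(pr$chrom == "1" & pr$start_bp < 14e6 & pr$end_bp > 10e6))
  # ...and a rare hom-alt variant inside it, carried by an inbred case
  # with a called ROH there, reaches the candidate list
  carrier <- strsplit(sim$truth$shared_tracts$carriers[1], ",")[[1]][1]
  vcf <- tempfile(fileext = ".vcf")
  write_toy_vcf(vcf, carrier, list(
    c("1", 12000000, "rsX", "C", "T", ".", "PASS", "AF=0.0005", "GT",
      "1/1")))
  cand <- filter_wes_variants(vcf, segs, 0.01, "AF", regions = pr)
  expect_equal(cand$id, "rsX")
  expect_equal(cand$individual_id, carrier)
})
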