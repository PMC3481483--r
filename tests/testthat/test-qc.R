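test_that("saturation is 1 when both halves produce proportional bin vectors", {
  g <- toy_genome(list(c1 = strrep("A", 5000)))
  # 200 copies of one interval: any bipartition yields proportional vectors
  rs <- toy_reads("c1", rep(600, 200), rep(1400, 200))
  sat <- saturation_analysis(rs, g, bin_size = 500, seed = 4)
  expect_equal(sat$saturation, 1)
  expect_equal(sat$estimated_saturation, 1)
})

test_that("saturation is deterministic under a seed", {
  g <- toy_genome(list(c1 = strrep("A", 20000)))
  rs <- random_reads(300, 20000, seed = 2)
  s1 <- saturation_analysis(rs, g, seed = 11)
  s2 <- saturation_analysis(rs, g, seed = 11)
  expect_identical(s1$curve, s2$curve)
  expect_identical(s1$estimated_saturation, s2$estimated_saturation)
  expect_equal(nrow(s1$curve), 10L)
  expect_true(all(diff(s1$curve$fraction) > 0))
})

test_that("zero-variance count vectors flag saturation as not computable", {
  g <- toy_genome(list(c1 = strrep("A", 600))) # single bin: zero variance
  rs <- toy_reads("c1", c(10, 100), c(46, 136))
  sat <- saturation_analysis(rs, g, bin_size = 1000, seed = 1)
  expect_true(is.na(sat$saturation))
  expect_error(saturation_analysis(toy_reads("c1", 1, 37), g), "at least 2")
})

test_that("deeper libraries do not lower estimated saturation (over seeds)", {
  # heterogeneous (capture-biased) coverage: depth should drive the half-vs-
  # half correlation upward; uniform libraries have no signal to saturate
  cfg <- sim_config(genome_length = 2e5, n_islands = 10, n_reads = 1000,
                    enrichment_strength = 2, seed = 61)
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim$genome, sim$islands, cfg)
  diffs <- vapply(1:5, function(seed) {
    cfg_big <- sim_config(genome_length = 2e5, n_islands = 10, n_reads = 10000,
                          enrichment_strength = 2, seed = 61)
    small <- remove_duplicates(simulate_reads(sim$genome, meth, cfg,
                                              seed = seed))
    big <- remove_duplicates(simulate_reads(sim$genome, meth, cfg_big,
                                            seed = seed + 50))
    s_small <- saturation_analysis(small, sim$genome,
                                   seed = seed)$estimated_saturation
    s_big <- saturation_analysis(big, sim$genome,
                                 seed = seed)$estimated_saturation
    s_big - s_small
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gte(sum(diffs > 0), 4)
})

test_that("cpg_enrichment is exact on hand-built genomes", {
  g <- toy_genome(list(c1 = "CGCGCGCG"))
  idx <- index_cpg_sites(g)
  rs <- toy_reads("c1", 0, 8)
  expect_equal(cpg_enrichment(rs, g, idx, extension = 0), 1)
  # CpG-rich half vs empty half: reads on the rich half only
  g2 <- toy_genome(list(c1 = paste0(strrep("CG", 2500), strrep("A", 5000))))
  idx2 <- index_cpg_sites(g2)
  rs2 <- toy_reads("c1", 0, 5000)
  expect_equal(cpg_enrichment(rs2, g2, idx2, extension = 0), 2)
  expect_true(is.na(cpg_enrichment(toy_reads(character(0), integer(0),
                                             integer(0)), g2, idx2)))
})

test_that("capture-biased libraries enrich more than uniform ones, increasing in strength", {
  cfg_base <- sim_config(genome_length = 3e5, n_islands = 15, n_reads = 30000,
                         seed = 21)
  g <- simulate_genome(cfg_base)
  idx <- index_cpg_sites(g$genome)
  meth <- simulate_methylome(g$genome, g$islands, cfg_base)
  enr <- vapply(c(0, 0.5, 2), function(s) {
    cfg <- sim_config(genome_length = 3e5, n_islands = 15, n_reads = 30000,
                      enrichment_strength = s, seed = 22)
    rs <- remove_duplicates(simulate_reads(g$genome, meth, cfg, seed = 22))
    cpg_enrichment(rs, g$genome, idx)
  }, numeric(1))
  expect_true(all(diff(enr) > 0))
  expect_lt(abs(enr[1] - 1), 0.1)
})

test_that("cpg_coverage counts sites covered at depth and respects bounds", {
  g <- toy_genome(list(c1 = paste0(strrep("A", 100), "CG", strrep("A", 98))))
  idx <- index_cpg_sites(g)
  # five distinct 5' keys all overlapping the single CpG at 100
  rs <- toy_reads("c1", c(80, 85, 90, 95, 99), c(116, 121, 126, 131, 135))
  expect_equal(cpg_coverage(rs, g, idx, extension = 0, depth = 5), 1)
  expect_equal(cpg_coverage(rs, g, idx, extension = 0, depth = 6), 0)
  empty <- toy_reads(character(0), integer(0), integer(0))
  expect_equal(cpg_coverage(empty, g, idx), 0)
  g0 <- toy_genome(list(c1 = strrep("A", 100)))
  expect_true(is.na(cpg_coverage(rs, g0, index_cpg_sites(g0))))
})

test_that("cpg_coverage is monotone in library size and antitone in depth", {
  g <- toy_genome(list(c1 = random_dna(20000, seed = 31)))
  idx <- index_cpg_sites(g)
  rs_all <- random_reads(400, 20000, seed = 32)
  half <- methcapr:::new_reads(rs_all$reads[1:200, ])
  cov_half <- cpg_coverage(half, g, idx)
  cov_all <- cpg_coverage(rs_all, g, idx)
  expect_lte(cov_half, cov_all)
  expect_lte(cpg_coverage(rs_all, g, idx, depth = 6), cov_all)
})

test_that("alignment_rate is the unique/pass-filter ratio with guards", {
  expect_equal(alignment_rate(1e6, 6e5), 0.6)
  expect_equal(alignment_rate(500, 500), 1)
  expect_equal(alignment_rate(500, 0), 0)
  expect_error(alignment_rate(0, 0), "n_pass_filter")
  expect_error(alignment_rate(10, 20), "exceeds")
})

test_that("exclusion policy flips at the documented thresholds", {
  base <- tibble::tibble(sample = "s", alignment_rate = 0.7, saturation = 0.8,
                         cpg_enrichment = 2.5, cpg_coverage_5x = 0.2)
  # single failure (enrichment 1.3 < 1.4): retained
  one <- base; one$cpg_enrichment <- 1.3
  expect_false(qc_flag(one)$excluded)
  expect_equal(qc_flag(one)$n_failed, 1)
  # two failures (enrichment 1.3, saturation 0.4): excluded
  two <- one; two$saturation <- 0.4
  expect_true(qc_flag(two)$excluded)
  # boundary values pass (comparison is >=)
  at <- tibble::tibble(sample = "s", alignment_rate = 0.5, saturation = 0.5,
                       cpg_enrichment = 1.4, cpg_coverage_5x = 0.05)
  expect_equal(qc_flag(at)$n_failed, 0)
  expect_false(qc_flag(at)$excluded)
  # just below the enrichment and saturation cutoffs fails
  below <- at; below$cpg_enrichment <- 1.3999; below$saturation <- 0.4999
  expect_equal(qc_flag(below)$n_failed, 2)
  expect_true(qc_flag(below)$excluded)
})

test_that("not-computable metrics count as failures", {
  m <- tibble::tibble(sample = "s", alignment_rate = NA_real_,
                      saturation = NA_real_, cpg_enrichment = 2.5,
                      cpg_coverage_5x = 0.2)
  flagged <- qc_flag(m)
  expect_equal(flagged$n_failed, 2)
  expect_true(flagged$excluded)
})

test_that("compute_qc assembles a full report with tidy/glance support", {
  cfg <- sim_config(genome_length = 1e5, n_islands = 5, n_reads = 5000, seed = 41)
  g <- simulate_genome(cfg)
  idx <- index_cpg_sites(g$genome)
  meth <- simulate_methylome(g$genome, g$islands, cfg)
  rs1 <- remove_duplicates(simulate_reads(g$genome, meth, cfg, seed = 42))
  rs2 <- remove_duplicates(simulate_reads(g$genome, meth, cfg, seed = 43))
  qc <- compute_qc(list(a = rs1, b = rs2), g$genome, idx, seed = 5)
  expect_equal(qc$sample, c("a", "b"))
  expect_true(all(qc$cpg_enrichment > 1))
  expect_true(all(!qc$excluded))
  expect_equal(nrow(tidy(qc)), 8)
  expect_equal(glance(qc)$n_samples, 2)
})
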