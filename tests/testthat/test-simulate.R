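test_that("simulated genomes place non-overlapping islands with ordered density", {
  cfg <- sim_config(genome_length = 1e5, n_islands = 3, island_length = 2000,
                    seed = 51)
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  sim <- simulate_genome(cfg, fasta_path = fa, bed_path = bed)
  isl <- read_features(bed, "island")
  expect_equal(nrow(isl), 3L)
  ord <- order(isl$start)
  expect_true(all(isl$end[ord][-3] <= isl$start[ord][-1]))
  g <- load_genome(fa)
  idx <- index_cpg_sites(g)
  dens_of <- function(s, e) {
    sum(idx$positions$chr1 >= s & idx$positions$chr1 < e) / (e - s)
  }
  island_dens <- mean(mapply(dens_of, isl$start, isl$end))
  background_dens <- dens_of(0, isl$start[ord][1])
  expect_gt(island_dens, 3 * background_dens)
  # configured slot densities are realised (non-CG slots cannot form CGs)
  expect_equal(island_dens * 2, cfg$island_cpg_density, tolerance = 0.15)
})

test_that("genome simulation is byte-deterministic under the seed", {
  cfg <- sim_config(genome_length = 5e4, n_islands = 2, seed = 52)
  f1 <- tempfile(); f2 <- tempfile()
  simulate_genome(cfg, fasta_path = f1)
  simulate_genome(cfg, fasta_path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("methylome compartment probabilities behave at the extremes and in expectation", {
  cfg1 <- sim_config(genome_length = 5e4, n_islands = 2,
                     methylation_prob_island = 1,
                     methylation_prob_background = 0, seed = 53)
  sim <- simulate_genome(cfg1)
  idx <- index_cpg_sites(sim$genome)
  meth <- simulate_methylome(sim$genome, sim$islands, cfg1)
  expect_true(all(meth$in_island))
  in_island_total <- sum(vapply(seq_len(nrow(sim$islands)), function(i)
    sum(idx$positions$chr1 >= sim$islands$start[i] &
          idx$positions$chr1 < sim$islands$end[i]), numeric(1)))
  expect_equal(nrow(meth), in_island_total) # every island CpG methylated
  cfg0 <- sim_config(genome_length = 5e4, n_islands = 2,
                     methylation_prob_island = 0,
                     methylation_prob_background = 0, seed = 53)
  expect_equal(nrow(simulate_methylome(sim$genome, sim$islands, cfg0)), 0L)
  # binomial check at p = 0.5
  cfg5 <- sim_config(genome_length = 5e4, n_islands = 2,
                     methylation_prob_island = 0.5,
                     methylation_prob_background = 0, seed = 54)
  m5 <- simulate_methylome(sim$genome, sim$islands, cfg5)
  phat <- nrow(m5) / in_island_total
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / in_island_total))
})

test_that("uniform libraries have uniform starts; enriched ones target islands", {
  cfg <- sim_config(genome_length = 2e5, n_islands = 10, n_reads = 20000,
                    enrichment_strength = 0, seed = 55)
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim$genome, sim$islands, cfg)
  rs <- simulate_reads(sim$genome, meth, cfg)
  slice <- findInterval(rs$reads$start, seq(0, 2e5, length.out = 21),
                        rightmost.closed = TRUE)
  gof <- suppressWarnings(stats::chisq.test(table(factor(slice, levels = 1:20))))
  expect_gt(gof$p.value, 0.001)
  cfg_cap <- sim_config(genome_length = 2e5, n_islands = 10, n_reads = 20000,
                        enrichment_strength = 2, seed = 55)
  rs_cap <- simulate_reads(sim$genome, meth, cfg_cap, seed = 56)
  frac_island <- function(r) {
    hit <- rep(FALSE, nrow(r$reads))
    for (i in seq_len(nrow(sim$islands))) {
      hit <- hit | (r$reads$start < sim$islands$end[i] &
                      r$reads$end > sim$islands$start[i])
    }
    mean(hit)
  }
  island_frac <- sum(sim$islands$end - sim$islands$start) / 2e5
  expect_gt(frac_island(rs_cap), 2 * island_frac)
})

test_that("injected duplicates collapse to the independent distinct-key count", {
  cfg <- sim_config(genome_length = 1e5, n_islands = 5, n_reads = 10000,
                    duplicate_rate = 0.5, seed = 57)
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim$genome, sim$islands, cfg)
  rs <- simulate_reads(sim$genome, meth, cfg)
  dd <- remove_duplicates(rs)
  key <- paste(rs$reads$chrom, rs$reads$strand,
               ifelse(rs$reads$strand == "+", rs$reads$start, rs$reads$end))
  expect_equal(dd$n_after_dedup, length(unique(key)))
  # roughly half the reads are copies
  expect_lt(dd$n_after_dedup, 0.75 * cfg$n_reads)
})

test_that("simulated SAM and BED files re-import to the same readset", {
  cfg <- sim_config(genome_length = 5e4, n_islands = 3, n_reads = 500, seed = 58)
  sim <- simulate_genome(cfg)
  meth <- simulate_methylome(sim$genome, sim$islands, cfg)
  sam <- tempfile(fileext = ".sam")
  bed <- tempfile(fileext = ".bed")
  rs <- simulate_reads(sim$genome, meth, cfg, sam_path = sam, bed_path = bed)
  from_sam <- import_alignments(sam, "sam", genome = sim$genome)
  from_bed <- import_alignments(bed, "bed", genome = sim$genome)
  ord <- function(r) r$reads[order(r$reads$start, r$reads$strand), ]
  expect_equal(ord(from_sam), ord(rs))
  expect_equal(ord(from_bed), ord(rs))
})

test_that("cohorts wire groups, manifests, and differential islands", {
  cfg <- sim_config(genome_length = 1e5, n_islands = 10, n_reads = 4000,
                    seed = 59)
  out <- tempfile()
  cohort <- simulate_cohort(
    cfg, groups = list(A = list(n = 3),
                       B = list(n = 3, methylation_prob_island = 0.05)),
    n_diff = 4, out_dir = out)
  expect_equal(nrow(cohort$manifest), 6L)
  expect_true(all(file.exists(cohort$manifest$sam)))
  expect_true(all(file.exists(cohort$manifest$bed)))
  expect_equal(length(cohort$diff_islands), 4L)
  tracks <- lapply(cohort$readsets, function(rs)
    count_bins(remove_duplicates(rs), cohort$genome, 500, 300))
  groups <- stats::setNames(cohort$manifest$group, cohort$manifest$sample)
  fm <- extract_feature_counts(tracks, cohort$islands, groups = groups)
  a_mean <- rowMeans(fm$values[, cohort$manifest$sample[1:3]])
  b_mean <- rowMeans(fm$values[, cohort$manifest$sample[4:6]])
  diff_rows <- rownames(fm$values) %in% cohort$diff_islands
  expect_true(all(a_mean[diff_rows] > b_mean[diff_rows]))
  # non-differential islands show no systematic ordering of comparable size
  expect_lt(mean(abs(a_mean[!diff_rows] - b_mean[!diff_rows])),
            mean(a_mean[diff_rows] - b_mean[diff_rows]) / 2)
})
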