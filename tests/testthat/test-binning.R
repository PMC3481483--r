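test_that("count_bins counts each extended read in every overlapped bin", {
  g <- toy_genome(list(c1 = strrep("A", 2000)))
  bt <- count_bins(toy_reads("c1", 100, 136, "+"), g, bin_size = 500,
                   extension = 300)
  expect_equal(bt$counts$c1, c(1L, 0L, 0L, 0L))
  bt2 <- count_bins(toy_reads("c1", 400, 436, "+"), g, 500, 300)
  expect_equal(bt2$counts$c1, c(1L, 1L, 0L, 0L)) # [400,700) spans the boundary
  bt0 <- count_bins(toy_reads(character(0), integer(0), integer(0)), g, 500, 300)
  expect_equal(bt0$counts$c1, integer(4))
  expect_equal(bt0$total_reads, 0L)
  expect_equal(bt0$rpm$c1, numeric(4))
})

test_that("rpm scaling follows counts * 1e6 / total_reads", {
  g <- toy_genome(list(c1 = strrep("A", 1000)))
  bt <- count_bins(toy_reads("c1", 10, 46, "+"), g, 500, 0)
  bt$total_reads <- 2e6
  bt$counts$c1 <- c(10L, 0L)
  bt <- scale_rpm(bt)
  expect_equal(bt$rpm$c1, c(5, 0))
  bt$total_reads <- 1
  bt$counts$c1 <- c(1L, 0L)
  expect_equal(scale_rpm(bt)$rpm$c1, c(1e6, 0))
})

test_that("count_bins agrees with a brute-force any-overlap oracle", {
  for (seed in 1:3) {
    g <- toy_genome(list(c1 = random_dna(50000, seed = seed)))
    rs <- random_reads(400, 50000, seed = seed + 100)
    bt <- count_bins(rs, g, bin_size = 500, extension = 300)
    ext <- extend_reads(rs, 300, g)
    nb <- ceiling(50000 / 500)
    oracle <- integer(nb)
    for (b in seq_len(nb)) {
      lo <- (b - 1L) * 500L
      hi <- min(b * 500L, 50000L)
      oracle[b] <- sum(ext$reads$start < hi & ext$reads$end > lo)
    }
    expect_identical(bt$counts$c1, oracle)
  }
})

test_that("with extension <= bin_size total counts stay within [n, 2n]", {
  g <- toy_genome(list(c1 = strrep("A", 30000)))
  rs <- random_reads(500, 30000, seed = 9)
  bt <- count_bins(rs, g, bin_size = 500, extension = 300)
  total <- sum(bt$counts$c1)
  expect_gte(total, 500)
  expect_lte(total, 1000)
})

test_that("feature extraction sums rpm over overlapped bins", {
  g <- toy_genome(list(c1 = strrep("A", 1000)))
  bt <- count_bins(toy_reads("c1", 0, 36), g, 500, 0)
  bt$rpm$c1 <- c(5, 3)
  fs <- methcapr:::new_features(
    tibble::tibble(chrom = "c1", start = c(0L, 250L), end = c(500L, 750L),
                   name = c("a", "b")), "toy")
  fm <- extract_feature_counts(list(s1 = bt), fs)
  expect_equal(unname(fm$values[, "s1"]), c(5, 8))
  # all-zero track
  bt$rpm$c1 <- c(0, 0)
  expect_equal(unname(extract_feature_counts(list(s1 = bt), fs)$values[, 1]),
               c(0, 0))
})

test_that("bin-aligned tiling loci conserve total rpm", {
  g <- toy_genome(list(c1 = random_dna(20000, seed = 5)))
  rs <- random_reads(300, 20000, seed = 6)
  bt <- count_bins(rs, g, 500, 300)
  starts <- seq(0L, 19500L, by = 500L)
  fs <- methcapr:::new_features(
    tibble::tibble(chrom = "c1", start = starts, end = starts + 500L,
                   name = paste0("t", seq_along(starts))), "tile")
  fm <- extract_feature_counts(list(s = bt), fs)
  expect_equal(sum(fm$values), sum(bt$rpm$c1))
})

test_that("mismatched bin sizes and unknown chromosomes are rejected", {
  g <- toy_genome(list(c1 = strrep("A", 1000)))
  bt1 <- count_bins(toy_reads("c1", 0, 36), g, 500, 0)
  bt2 <- count_bins(toy_reads("c1", 0, 36), g, 250, 0)
  fs <- methcapr:::new_features(
    tibble::tibble(chrom = "c1", start = 0L, end = 100L, name = "a"), "toy")
  expect_error(extract_feature_counts(list(a = bt1, b = bt2), fs), "bin_size")
  fs2 <- methcapr:::new_features(
    tibble::tibble(chrom = "cX", start = 0L, end = 100L, name = "a"), "toy")
  expect_error(extract_feature_counts(list(a = bt1), fs2), "missing from track")
})

test_that("aggregate summaries match direct formulas", {
  fm1 <- toy_fmatrix(matrix(4, 1, 1))
  s1 <- aggregate_feature_summary(fm1)
  expect_equal(s1$samples$sum, 4)
  expect_equal(s1$samples$mean, 4)
  expect_equal(s1$samples$median, 4)
  fm2 <- toy_fmatrix(matrix(c(2, 2, 2), 1, 3))
  expect_equal(aggregate_feature_summary(fm2)$loci$cv, 0)
  fm3 <- toy_fmatrix(matrix(c(2, 4, 6), 1, 3))
  s3 <- aggregate_feature_summary(fm3)
  expect_equal(s3$loci$mean, 4)
  expect_equal(s3$loci$cv, sd(c(2, 4, 6)) / 4)
})

test_that("binary counts codec round-trips and validates integrity", {
  g <- toy_genome(list(c1 = random_dna(3000, seed = 2),
                       c2 = random_dna(1200, seed = 3)))
  rs <- remove_duplicates(toy_reads(rep(c("c1", "c2"), c(30, 10)),
                                    c(seq(0, 2900, length.out = 30),
                                      seq(0, 1100, length.out = 10)),
                                    c(seq(36, 2936, length.out = 30),
                                      seq(36, 1136, length.out = 10))))
  bt <- count_bins(rs, g, 500, 300)
  f1 <- tempfile()
  write_counts(bt, f1)
  bt2 <- read_counts(f1)
  expect_identical(bt2$counts, bt$counts)
  expect_identical(bt2$chroms$name, bt$chroms$name)
  expect_equal(bt2$total_reads, bt$total_reads)
  expect_equal(unlist(bt2$rpm), unlist(bt$rpm), tolerance = 1e-6)
  # a second write of the re-read track is byte-identical (f32 fixed point)
  f2 <- tempfile()
  write_counts(bt2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("codec rejects bad magic, corruption, and truncation", {
  g <- toy_genome(list(chr_long_name = strrep("A", 2000)))
  bt <- count_bins(toy_reads("chr_long_name", 0, 36), g, 500, 0)
  f <- tempfile()
  write_counts(bt, f)
  r <- readBin(f, "raw", file.size(f))
  bad <- r; bad[1] <- as.raw(0)
  writeBin(bad, f)
  expect_error(read_counts(f), "magic")
  corrupt <- r; corrupt[40] <- xor(corrupt[40], as.raw(255))
  writeBin(corrupt, f)
  expect_error(read_counts(f), "checksum")
  trunc <- r[1:(length(r) - 30)]
  writeBin(c(trunc, methcapr:::pack_uint(methcapr:::crc32(trunc), 4)), f)
  expect_error(read_counts(f), "truncated.*chr_long_name")
})
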