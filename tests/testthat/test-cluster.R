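test_that("locus filtering applies strict mean and CV thresholds", {
  v <- rbind(constant = c(2, 2, 2),      # cv 0
             strong = c(2, 10, 24),      # mean 12, cv = sd/mean ~ 0.92
             weak = c(0.1, 0.2, 0.3))
  fm <- toy_fmatrix(v)
  expect_equal(rownames(filter_loci(fm, 0, 0)$values), c("strong", "weak"))
  expect_equal(rownames(filter_loci(fm, 10, 0.5)$values), "strong")
  # mean 12 > 10 but cv ~0.92 not > 5: the canonical (10, 5) criteria drop it
  expect_equal(nrow(filter_loci(fm, 10, 5)$values), 0L)
  big <- toy_fmatrix(rbind(x = c(0.1, 36, 0.1, 0.1))) # mean ~9, cv > 1.9
  expect_equal(nrow(filter_loci(big, 10, 5)$values), 0L)
})

test_that("rescaling divides by the locus mean and is idempotent", {
  fm <- toy_fmatrix(rbind(a = c(2, 4, 6), b = c(5, 5, 5)))
  r1 <- rescale_loci(fm)
  expect_equal(unname(r1$values["a", ]), c(0.5, 1, 1.5))
  expect_equal(unname(r1$values["b", ]), c(1, 1, 1))
  expect_equal(rescale_loci(r1)$values, r1$values)
  expect_error(rescale_loci(toy_fmatrix(rbind(z = c(0, 0)))), "non-positive")
})

test_that("rescaled rows keep their CV (scale-invariance of CV)", {
  withr::with_seed(3, v <- matrix(rlnorm(50 * 6), 50, 6))
  fm <- filter_loci(toy_fmatrix(v), 0, 0)
  cv_before <- apply(fm$values, 1, function(x) sd(x) / mean(x))
  r <- rescale_loci(fm)
  expect_equal(unname(rowMeans(r$values)), rep(1, nrow(r$values)))
  cv_after <- apply(r$values, 1, function(x) sd(x) / mean(x))
  expect_equal(cv_after, cv_before)
})

test_that("pearson_distance matches 1 - r with guards", {
  v <- cbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8), s3 = c(4, 3, 2, 1))
  d <- as.matrix(pearson_distance(toy_fmatrix(v)))
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 2)
  expect_equal(d["s2", "s3"], 1 - cor(v[, 2], v[, 3]))
  bad <- cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))
  expect_error(pearson_distance(toy_fmatrix(bad)), "zero-variance.*s1")
})

test_that("McQuitty agglomeration follows the WPGMA recurrence", {
  d <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  hc <- hierarchical_cluster(as.dist(d))
  expect_equal(hc$height, c(1, 4)) # merge (a,b) at 1; d(ab, c) = (4+4)/2
  expect_equal(sort(unname(cutree(hc, 2))), c(1, 1, 2))
  # duplicate points merge first at height 0
  d2 <- matrix(c(0, 0, 3, 0, 0, 3, 3, 3, 0), 3, 3)
  expect_equal(hierarchical_cluster(as.dist(d2))$height[1], 0)
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("hierarchical_cluster equals stats::hclust on random matrices", {
  for (seed in 1:8) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(5 * 4), 5, 4)
      d <- dist(x)
    })
    for (method in c("mcquitty", "average", "single", "complete")) {
      mine <- hierarchical_cluster(d, method = method)
      ref <- stats::hclust(d, method = method)
      expect_equal(mine$height, ref$height, tolerance = 1e-12)
      for (k in 2:4) {
        part_mine <- cutree(mine, k)
        part_ref <- cutree(ref, k)
        # same partition up to label renumbering
        expect_equal(unname(table(part_mine, part_ref) > 0) %*% rep(1, k),
                     matrix(1, k, 1))
      }
    }
  }
})

test_that("bootstrap support finds well-separated clusters and is seeded", {
  withr::with_seed(5, {
    v <- cbind(matrix(rnorm(40 * 3, mean = 10), 40, 3),
               matrix(rnorm(40 * 3, mean = 0), 40, 3))
    v[1:20, 1:3] <- v[1:20, 1:3] + 40 # loci high in group 1
    v[21:40, 4:6] <- v[21:40, 4:6] + 40
  })
  colnames(v) <- paste0("s", 1:6)
  fm <- toy_fmatrix(abs(v))
  b1 <- bootstrap_support(fm, B = 100, seed = 9)
  sup <- attr(b1, "support")
  expect_true(all(sup$bp >= 0 & sup$bp <= 1))
  top2 <- sup$bp[sup$n_leaves == 3]
  expect_true(all(top2 >= 0.95))
  b2 <- bootstrap_support(fm, B = 100, seed = 9)
  expect_identical(attr(b2, "support"), sup)
})

test_that("multiscale bootstrap fits AU values within [0, 1]", {
  withr::with_seed(6, v <- matrix(rlnorm(60 * 5), 60, 5))
  fm <- toy_fmatrix(v)
  hc <- bootstrap_support(fm, B = 40, seed = 2, scales = seq(0.6, 1.4, 0.2))
  sup <- attr(hc, "support")
  expect_false(all(is.na(sup$au)))
  expect_true(all(sup$au >= 0 & sup$au <= 1, na.rm = TRUE))
})

test_that("group tracking colours the reference cut and neutralises outsiders", {
  withr::with_seed(8, {
    v <- cbind(matrix(rlnorm(30 * 3, 2), 30, 3),
               matrix(rlnorm(30 * 3, 6), 30, 3))
  })
  colnames(v) <- paste0("s", 1:6)
  fm <- toy_fmatrix(v)
  hc <- hierarchical_cluster(pearson_distance(fm))
  colors <- track_groups(hc, k = 2)
  ref <- colors[colors$dendrogram == "reference", ]
  expect_setequal(ref$color, c("blue", "red"))
  # identity: tracking the reference in itself reproduces the cut
  cut <- cutree(hc, 2)
  expect_equal(length(unique(ref$color[cut[ref$sample] == 1])), 1L)
  expect_equal(length(unique(ref$color[cut[ref$sample] == 2])), 1L)
  # no leaf receives two colours
  expect_equal(anyDuplicated(ref$sample), 0L)
  # leaves outside the k largest of a finer cut go neutral
  colors3 <- track_groups(hc, k = 2, cut_size = 3)
  ref3 <- colors3[colors3$dendrogram == "reference", ]
  expect_true("black" %in% ref3$color)
  expect_equal(sort(unique(ref3$color)), c("black", "blue", "red"))
  # a second dendrogram missing one sample marks it by absence
  fm5 <- toy_fmatrix(v[, 1:5])
  hc5 <- hierarchical_cluster(pearson_distance(fm5))
  both <- track_groups(hc, k = 2, others = list(alt = hc5))
  expect_equal(sum(both$dendrogram == "alt"), 5L)
  expect_error(track_groups(hc, k = 10), "exceeds")
})

test_that("newick export round-trips through an independent parser", {
  skip_if_not_installed("ape")
  withr::with_seed(4, v <- matrix(rlnorm(40 * 5), 40, 5))
  colnames(v) <- paste0("s", 1:5)
  fm <- toy_fmatrix(v)
  hc <- bootstrap_support(fm, B = 30, seed = 3)
  nwk <- export_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("s", 1:5))
  expect_equal(phy$Nnode, 4)
  # leaf-to-leaf path heights match the dendrogram's cophenetic distances
  coph_hc <- as.matrix(stats::cophenetic(hc))
  coph_phy <- ape::cophenetic.phylo(phy)[rownames(coph_hc), colnames(coph_hc)]
  expect_equal(coph_phy, 2 * coph_hc, tolerance = 1e-6)
})

test_that("end-to-end subtype recovery across seeds reaches high purity", {
  purities <- vapply(1:5, function(seed) {
    cfg <- sim_config(genome_length = 2e5, n_islands = 20, n_reads = 8000,
                      seed = seed * 100)
    cohort <- simulate_cohort(
      cfg, groups = list(hyper = list(n = 4),
                         hypo = list(n = 4, methylation_prob_island = 0.05)),
      n_diff = 12, seed = seed * 100)
    idx <- index_cpg_sites(cohort$genome)
    tracks <- lapply(cohort$readsets,
                     function(rs) count_bins(remove_duplicates(rs),
                                             cohort$genome, 500, 300))
    groups <- stats::setNames(cohort$manifest$group, cohort$manifest$sample)
    fm <- extract_feature_counts(tracks, cohort$islands, groups = groups)
    fm <- rescale_loci(filter_loci(fm, 0.5, 0.1))
    hc <- hierarchical_cluster(pearson_distance(fm))
    cut <- cutree(hc, 2)
    purity <- mean(vapply(split(groups[names(cut)], cut), function(g)
      max(table(g)) / length(g), numeric(1)))
    purity
  }, numeric(1))
  expect_gte(mean(purities), 0.9)
})
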