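# fixtures are built in code; nothing binary ships with the package

toy_genome <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))),
             fa)
  load_genome(fa)
}

toy_reads <- function(chrom, start, end, strand = "+", ...) {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) strand <- character(0)
  methcapr:::new_reads(
    tibble::tibble(chrom = rep_len(chrom, n), start = as.integer(rep_len(start, n)),
                   end = as.integer(rep_len(end, n)),
                   strand = rep_len(strand, n)),
    ...
  )
}

random_reads <- function(n, chrom_len, chrom = "c1", read_len = 36, seed = 1) {
  withr::with_seed(seed, {
    s <- sample.int(chrom_len - read_len, n, replace = TRUE) - 1L
    toy_reads(chrom, s, s + read_len,
              sample(c("+", "-"), n, replace = TRUE))
  })
}

random_dna <- function(len, seed = 1) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
}

toy_fmatrix <- function(values, groups = NULL, chrom = "c1") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("locus_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  loci <- tibble::tibble(chrom = chrom,
                         start = (seq_len(nrow(values)) - 1L) * 1000L,
                         end = seq_len(nrow(values)) * 1000L,
                         name = rownames(values))
  methcapr:::new_fmatrix(values, loci, groups = groups, feature_class = "toy")
}

# independent oracle: exhaustive enumeration of the rank-sum null
exact_wilcoxon_oracle <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  null_w <- apply(combos, 2, function(idx) {
    sum(ranks[idx]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(null_w <= w_obs), mean(null_w >= w_obs)))
}

# writes a small SAM file; rows = list of c(qname, flag, rname, pos1, mapq, seq)
toy_sam <- function(rows, chroms = c(c1 = 1000L)) {
  path <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
  body <- vapply(rows, function(r) {
    seq <- r[[6]]
    paste(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], paste0(nchar(seq), "M"),
          "*", 0, 0, seq, strrep("I", nchar(seq)), sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  path
}
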