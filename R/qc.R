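#' QC thresholds and exclusion policy
#'
#' Enrichment below 1.4 and saturation below 0.5 mark failing captures;
#' alignment-rate and 5x CpG-coverage cutoffs are laboratory conventions with
#' no published fixed value, so they are plain configuration here. A sample is
#' excluded when it fails more than `max_failures` metrics (default: failing
#' two or more excludes; valid samples occasionally fail a single one).
#' Comparison is `>=`, so a metric exactly at its threshold passes.
#'
#' @param min_enrichment Minimum CpG enrichment (default 1.4).
#' @param min_saturation Minimum saturation correlation (default 0.5).
#' @param min_alignment_rate Minimum unique-alignment rate (default 0.5;
#'   configurable convention).
#' @param min_cpg_coverage_5x Minimum 5x CpG coverage fraction (default 0.05;
#'   configurable convention).
#' @param max_failures Highest tolerated number of failed metrics (default 1).
#' @return An `mc_thresholds` list.
#' @export
qc_thresholds <- function(min_enrichment = 1.4, min_saturation = 0.5,
                          min_alignment_rate = 0.5, min_cpg_coverage_5x = 0.05,
                          max_failures = 1) {
  check_scalar_num(min_enrichment, "min_enrichment", min = 0)
  check_scalar_num(min_saturation, "min_saturation", min = 0)
  check_scalar_num(min_alignment_rate, "min_alignment_rate", min = 0)
  check_scalar_num(min_cpg_coverage_5x, "min_cpg_coverage_5x", min = 0)
  check_scalar_num(max_failures, "max_failures", min = 0, max = 3)
  structure(list(min_enrichment = min_enrichment, min_saturation = min_saturation,
                 min_alignment_rate = min_alignment_rate,
                 min_cpg_coverage_5x = min_cpg_coverage_5x,
                 max_failures = as.integer(max_failures)),
            class = "mc_thresholds")
}

#' Saturation analysis of library complexity
#'
#' Estimates the reproducibility of a library by a Pearson correlation of
#' binned coverage: the deduplicated reads are split at random into two
#' halves, each half is binned, and the correlation between the two count
#' vectors is followed along an increasing subsample grid. `saturation` is the
#' correlation of the full halves; `estimated_saturation` projects to double
#' the library size by resampling each half with replacement to the full
#' library size before binning. Reads are binned unextended.
#'
#' @param rs Deduplicated `mc_reads` with at least 2 reads.
#' @param genome `mc_genome`.
#' @param bin_size Bin width (default 500).
#' @param n_steps Number of subsample fractions (grid ends at 1).
#' @param seed Integer seed fixing the bipartition and resampling.
#' @return An `mc_saturation` list: `$saturation`, `$estimated_saturation`
#'   (either may be `NA` when a count vector has zero variance, which QC
#'   treats as a failing metric), and `$curve`, a tibble of
#'   `fraction`, `r`.
#' @export
saturation_analysis <- function(rs, genome, bin_size = 500, n_steps = 10,
                                seed = 1L) {
  stopifnot(inherits(rs, "mc_reads"))
  n <- nrow(rs$reads)
  if (n < 2L) stop("saturation analysis needs at least 2 reads", call. = FALSE)
  chroms <- genome$chroms
  chroms$n_bins <- as.integer(ceiling(chroms$length / bin_size))
  vec_of <- function(idx) {
    unlist(bin_count_vectors(rs$reads[idx, , drop = FALSE], chroms, bin_size),
           use.names = FALSE)
  }
  safe_cor <- function(a, b) {
    sa <- stats::sd(a)
    sb <- stats::sd(b)
    if (is.na(sa) || is.na(sb) || sa == 0 || sb == 0) NA_real_
    else stats::cor(a, b)
  }
  withr::with_seed(seed, {
    perm <- sample.int(n)
    a_idx <- perm[seq_len(n %/% 2L)]
    b_idx <- perm[(n %/% 2L + 1L):n]
    fracs <- seq_len(n_steps) / n_steps
    curve_r <- vapply(fracs, function(f) {
      na <- max(1L, floor(f * length(a_idx)))
      nb <- max(1L, floor(f * length(b_idx)))
      safe_cor(vec_of(a_idx[seq_len(na)]), vec_of(b_idx[seq_len(nb)]))
    }, numeric(1))
    a_big <- sample(a_idx, n, replace = TRUE)
    b_big <- sample(b_idx, n, replace = TRUE)
    est <- safe_cor(vec_of(a_big), vec_of(b_big))
    structure(
      list(saturation = curve_r[n_steps],
           estimated_saturation = est,
           curve = tibble(fraction = fracs, r = curve_r)),
      class = "mc_saturation"
    )
  })
}

#' @export
print.mc_saturation <- function(x, ...) {
  cat(sprintf("<mc_saturation> observed %.3f, estimated %.3f (%d grid points)\n",
              x$saturation, x$estimated_saturation, nrow(x$curve)))
  invisible(x)
}

#' @method tidy mc_saturation
#' @export
tidy.mc_saturation <- function(x, ...) x$curve

#' CpG enrichment of a read library
#'
#' Ratio of the relative CpG dinucleotide frequency interrogated by the
#' (extended) reads to the relative CpG frequency of the reference genome:
#' `(sum of CpGs inside read intervals / sum of interval lengths) /
#' (total CpGs / genome length)`. A dimer must lie fully inside a read
#' interval to count (straddle off). Values near or below 1 indicate
#' non-captured input; successful capture typically scores 2-3.5.
#'
#' @param rs Non-empty `mc_reads`.
#' @param genome `mc_genome`.
#' @param cpg_index [index_cpg_sites()] result for `genome`.
#' @param extension Read extension applied if `rs` is unextended (default 300).
#' @return Enrichment ratio, or `NA` for an empty readset (not computable).
#' @export
cpg_enrichment <- function(rs, genome, cpg_index, extension = 300) {
  stopifnot(inherits(rs, "mc_reads"))
  if (nrow(rs$reads) == 0L) return(NA_real_)
  if (rs$extension == 0L && extension > 0) rs <- extend_reads(rs, extension, genome)
  r <- rs$reads
  total_cpg_in_reads <- 0
  for (ch in unique(r$chrom)) {
    pos <- cpg_index$positions[[ch]]
    rows <- r$chrom == ch
    if (is.null(pos) || length(pos) == 0L) next
    # CpGs with start <= p <= end-2 (dimer inside interval)
    cnt <- findInterval(r$end[rows] - 2L, pos) - findInterval(r$start[rows] - 1L, pos)
    total_cpg_in_reads <- total_cpg_in_reads + sum(cnt)
  }
  read_freq <- total_cpg_in_reads / sum(as.numeric(r$end - r$start))
  genome_freq <- cpg_index$total_cpg / sum(as.numeric(genome$chroms$length))
  read_freq / genome_freq
}

#' CpG coverage rate at a depth
#'
#' Fraction of all genomic CpG sites overlapped by at least `depth` (extended)
#' reads; the default depth of 5 gives the "CpG coverage rate (5x)".
#'
#' @param rs An `mc_reads`.
#' @param genome `mc_genome`.
#' @param cpg_index [index_cpg_sites()] result.
#' @param extension Read extension applied if `rs` is unextended.
#' @param depth Minimum coverage (default 5).
#' @return Fraction in `[0,1]`, or `NA` when the genome has no CpGs.
#' @export
cpg_coverage <- function(rs, genome, cpg_index, extension = 300, depth = 5) {
  stopifnot(inherits(rs, "mc_reads"))
  check_scalar_num(depth, "depth", min = 1)
  if (cpg_index$total_cpg == 0L) return(NA_real_)
  if (nrow(rs$reads) == 0L) return(0)
  if (rs$extension == 0L && extension > 0) rs <- extend_reads(rs, extension, genome)
  covered <- 0
  for (ch in names(cpg_index$positions)) {
    pos <- cpg_index$positions[[ch]]
    if (length(pos) == 0L) next
    rows <- rs$reads$chrom == ch
    if (!any(rows)) next
    ss <- sort(rs$reads$start[rows])
    ee <- sort(rs$reads$end[rows])
    dep <- findInterval(pos, ss) - findInterval(pos, ee)
    covered <- covered + sum(dep >= depth)
  }
  covered / cpg_index$total_cpg
}

#' Unique-alignment rate
#'
#' @param n_pass_filter Pass-filter read count from the sequencer (> 0).
#' @param n_unique_aligned Uniquely aligned read count.
#' @return `n_unique_aligned / n_pass_filter`.
#' @export
alignment_rate <- function(n_pass_filter, n_unique_aligned) {
  check_scalar_num(n_pass_filter, "n_pass_filter", min = 1)
  check_scalar_num(n_unique_aligned, "n_unique_aligned", min = 0)
  if (n_unique_aligned > n_pass_filter) {
    stop("n_unique_aligned exceeds n_pass_filter", call. = FALSE)
  }
  n_unique_aligned / n_pass_filter
}

#' Apply the QC exclusion policy to a metrics table
#'
#' A metric passes when it is `>=` its threshold; a missing (`NA`,
#' not-computable) metric counts as a failure. A sample is excluded when its
#' failure count exceeds `thresholds$max_failures` (defaults: fail two or
#' more of the four metrics).
#'
#' @param metrics Tibble with columns `sample`, `alignment_rate`,
#'   `saturation`, `cpg_enrichment`, `cpg_coverage_5x`. Pass the estimated
#'   (projected full-depth) saturation here for thresholding.
#' @param thresholds An [qc_thresholds()] object.
#' @return An `mc_qc` tibble: the metrics plus per-metric `pass_*` flags,
#'   `n_failed`, and `excluded`.
#' @export
qc_flag <- function(metrics, thresholds = qc_thresholds()) {
  needed <- c("sample", "alignment_rate", "saturation", "cpg_enrichment",
              "cpg_coverage_5x")
  missing <- setdiff(needed, names(metrics))
  if (length(missing)) {
    stop("metrics table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- as_tibble(metrics)
  pass <- function(x, thr) !is.na(x) & x >= thr
  out$pass_alignment <- pass(out$alignment_rate, thresholds$min_alignment_rate)
  out$pass_saturation <- pass(out$saturation, thresholds$min_saturation)
  out$pass_enrichment <- pass(out$cpg_enrichment, thresholds$min_enrichment)
  out$pass_coverage <- pass(out$cpg_coverage_5x, thresholds$min_cpg_coverage_5x)
  out$n_failed <- rowSums(!cbind(out$pass_alignment, out$pass_saturation,
                                 out$pass_enrichment, out$pass_coverage))
  out$excluded <- out$n_failed > thresholds$max_failures
  structure(out, thresholds = thresholds, class = c("mc_qc", class(out)))
}

#' Compute all four QC metrics for a set of samples
#'
#' Convenience wrapper running [saturation_analysis()], [cpg_enrichment()],
#' [cpg_coverage()] and [alignment_rate()] per sample and flagging with
#' [qc_flag()]. Estimated saturation is used for thresholding; the observed
#' half-vs-half value is reported alongside.
#'
#' @param readsets Named list of deduplicated `mc_reads`.
#' @param genome `mc_genome`.
#' @param cpg_index [index_cpg_sites()] result.
#' @param bin_size,extension Binning parameters shared with the main analysis.
#' @param thresholds [qc_thresholds()].
#' @param seed Base seed; sample `i` uses `seed + i` for its saturation split.
#' @return An `mc_qc` tibble (see [qc_flag()]) with additional columns
#'   `n_pass_filter`, `n_unique`, `n_dedup`, `saturation_observed`.
#' @export
compute_qc <- function(readsets, genome, cpg_index, bin_size = 500,
                       extension = 300, thresholds = qc_thresholds(),
                       seed = 1L) {
  stopifnot(length(readsets) >= 1L, !is.null(names(readsets)))
  rows <- lapply(names(readsets), function(nm) {
    rs <- readsets[[nm]]
    sat <- saturation_analysis(rs, genome, bin_size = bin_size,
                               seed = seed + match(nm, names(readsets)))
    ar <- if (is.na(rs$n_pass_filter) || rs$n_pass_filter <= 0) NA_real_ else
      alignment_rate(rs$n_pass_filter, rs$n_unique_aligned)
    tibble(
      sample = nm,
      n_pass_filter = rs$n_pass_filter,
      n_unique = rs$n_unique_aligned,
      n_dedup = if (is.na(rs$n_after_dedup)) nrow(rs$reads) else rs$n_after_dedup,
      alignment_rate = ar,
      saturation_observed = sat$saturation,
      saturation = sat$estimated_saturation,
      cpg_enrichment = cpg_enrichment(rs, genome, cpg_index, extension),
      cpg_coverage_5x = cpg_coverage(rs, genome, cpg_index, extension)
    )
  })
  qc_flag(bind_rows(rows), thresholds)
}

#' @method tidy mc_qc
#' @export
tidy.mc_qc <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[, c("sample", "alignment_rate", "saturation",
                                       "cpg_enrichment", "cpg_coverage_5x")],
                      -"sample", names_to = "metric", values_to = "value")
}

#' @method glance mc_qc
#' @export
glance.mc_qc <- function(x, ...) {
  tibble(n_samples = nrow(x), n_excluded = sum(x$excluded),
         n_single_failure = sum(x$n_failed == 1))
}

#' Write a QC summary table
#'
#' @param qc An `mc_qc` tibble.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(qc, path) {
  write_tsv_quiet(as_tibble(qc), path)
  invisible(path)
}
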