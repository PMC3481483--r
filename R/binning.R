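#' Count extended reads into fixed-width genomic bins
#'
#' Every extended read increments each bin its interval overlaps by exactly 1
#' (any-overlap counting: fragments covering a bin contribute to it). A 500 bp
#' default bin gives sufficient resolution while smoothing statistically.
#'
#' @param rs A deduplicated `mc_reads`. If `rs` has not been extended yet and
#'   `extension > 0`, [extend_reads()] is applied first.
#' @param genome `mc_genome` defining the bin grid.
#' @param bin_size Bin width in bases (default 500).
#' @param extension Read extension (average fragment size), default 300.
#' @return An `mc_bintrack`: list with `$bin_size`, `$extension`,
#'   `$total_reads`, `$chroms` (tibble `name`, `length`, `n_bins`), `$counts`
#'   and `$rpm` (named lists of per-chromosome vectors; bin `i` covers
#'   `[i*bin_size, min((i+1)*bin_size, length))`).
#' @export
count_bins <- function(rs, genome, bin_size = 500, extension = 300) {
  stopifnot(inherits(rs, "mc_reads"), inherits(genome, "mc_genome"))
  check_scalar_num(bin_size, "bin_size", min = 1)
  if (rs$extension == 0L && extension > 0) {
    rs <- extend_reads(rs, extension, genome)
  }
  missing <- setdiff(unique(rs$reads$chrom), genome$chroms$name)
  if (length(missing)) {
    stop("reads on chromosome absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chroms <- genome$chroms
  chroms$n_bins <- as.integer(ceiling(chroms$length / bin_size))
  counts <- bin_count_vectors(rs$reads, chroms, bin_size)
  bt <- structure(
    list(bin_size = as.integer(bin_size), extension = rs$extension,
         total_reads = nrow(rs$reads), chroms = chroms,
         counts = counts, rpm = NULL),
    class = "mc_bintrack"
  )
  scale_rpm(bt)
}

# shared kernel: reads data frame -> named list of per-chromosome count vectors
bin_count_vectors <- function(reads, chroms, bin_size) {
  out <- vector("list", nrow(chroms))
  names(out) <- chroms$name
  for (i in seq_len(nrow(chroms))) {
    nb <- chroms$n_bins[i]
    r <- reads[reads$chrom == chroms$name[i], , drop = FALSE]
    if (nrow(r) == 0L) {
      out[[i]] <- integer(nb)
      next
    }
    b0 <- r$start %/% bin_size
    b1 <- (r$end - 1L) %/% bin_size
    idx <- sequence(nvec = b1 - b0 + 1L, from = b0 + 1L)
    out[[i]] <- tabulate(idx, nbins = nb)
  }
  out
}

#' Scale bin counts to reads per million
#'
#' `rpm[i] = counts[i] * 1e6 / total_reads`; an empty track has rpm 0
#' everywhere.
#'
#' @param bt An `mc_bintrack`.
#' @return The track with `$rpm` recomputed.
#' @export
scale_rpm <- function(bt) {
  stopifnot(inherits(bt, "mc_bintrack"))
  bt$rpm <- lapply(bt$counts, function(cnt) {
    if (bt$total_reads > 0) cnt * 1e6 / bt$total_reads else numeric(length(cnt))
  })
  bt
}

#' @export
print.mc_bintrack <- function(x, ...) {
  cat(sprintf("<mc_bintrack> bin %d bp, extension %d, %s reads, %d chromosome(s)\n",
              x$bin_size, x$extension, format(x$total_reads, big.mark = ","),
              nrow(x$chroms)))
  invisible(x)
}

#' Extract feature-level rpm values into a loci x samples matrix
#'
#' The value of a locus in a sample is the sum of rpm over every bin the
#' locus interval overlaps (partial overlaps count fully; the rule is simple
#' and conservative and is documented so users can compare).
#'
#' @param tracks Named list of `mc_bintrack`s, one per sample, sharing
#'   `bin_size`.
#' @param fs An `mc_features`.
#' @param sample_ids Sample names (defaults to `names(tracks)`).
#' @param groups Optional named character vector mapping sample id to group.
#' @return An `mc_fmatrix`: list with `$values` (loci x samples matrix),
#'   `$loci` tibble, `$samples`, `$groups`, `$feature_class`.
#' @export
extract_feature_counts <- function(tracks, fs, sample_ids = names(tracks),
                                   groups = NULL) {
  stopifnot(length(tracks) >= 1L)
  if (is.null(sample_ids) || any(!nzchar(sample_ids))) {
    stop("tracks must be named or sample_ids supplied", call. = FALSE)
  }
  sizes <- vapply(tracks, function(t) t$bin_size, integer(1))
  if (length(unique(sizes)) != 1L) {
    stop("all BinTracks must share bin_size; got ",
         paste(unique(sizes), collapse = ", "), call. = FALSE)
  }
  bs <- sizes[[1L]]
  vals <- matrix(0, nrow = nrow(fs), ncol = length(tracks),
                 dimnames = list(fs$name, sample_ids))
  for (j in seq_along(tracks)) {
    bt <- tracks[[j]]
    cs_by_chrom <- lapply(bt$rpm, function(r) c(0, cumsum(r)))
    for (ch in unique(fs$chrom)) {
      if (!ch %in% names(cs_by_chrom)) {
        stop("locus chromosome missing from track '", sample_ids[j], "': ", ch,
             call. = FALSE)
      }
      rows <- which(fs$chrom == ch)
      nb <- bt$chroms$n_bins[match(ch, bt$chroms$name)]
      b0 <- pmin(fs$start[rows] %/% bs, nb - 1L)
      b1 <- pmin((fs$end[rows] - 1L) %/% bs, nb - 1L)
      cs <- cs_by_chrom[[ch]]
      vals[rows, j] <- cs[b1 + 2L] - cs[b0 + 1L]
    }
  }
  new_fmatrix(vals, loci = as_tibble(fs)[, c("chrom", "start", "end", "name")],
              groups = groups,
              feature_class = attr(fs, "feature_class") %||% "feature")
}

new_fmatrix <- function(values, loci, groups = NULL, feature_class = "feature") {
  stopifnot(nrow(values) == nrow(loci))
  if (!is.null(groups)) {
    groups <- groups[colnames(values)]
    if (anyNA(groups)) {
      stop("every sample needs a group label; missing: ",
           paste(colnames(values)[is.na(groups)], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(values = values, loci = loci, samples = colnames(values),
         groups = groups, feature_class = feature_class),
    class = "mc_fmatrix"
  )
}

#' @export
print.mc_fmatrix <- function(x, ...) {
  cat(sprintf("<mc_fmatrix> '%s': %d loci x %d samples%s\n", x$feature_class,
              nrow(x$values), ncol(x$values),
              if (is.null(x$groups)) "" else
                sprintf(" (%d groups)", length(unique(x$groups)))))
  invisible(x)
}

#' Long-format view of a feature matrix
#'
#' @param x An `mc_fmatrix`.
#' @param ... Unused.
#' @return Tibble with columns `locus`, `sample`, `group`, `rpm`.
#' @export
as_tibble.mc_fmatrix <- function(x, ...) {
  long <- tibble(
    locus = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    rpm = as.vector(x$values)
  )
  long$group <- if (is.null(x$groups)) NA_character_ else unname(x$groups[long$sample])
  long[, c("locus", "sample", "group", "rpm")]
}

#' Assign group labels to a feature matrix
#'
#' @param fm An `mc_fmatrix`.
#' @param groups Named character vector (sample id -> group) or a data frame
#'   with columns `sample` and `group`.
#' @return The matrix with `$groups` set.
#' @export
set_groups <- function(fm, groups) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample)
  }
  new_fmatrix(fm$values, fm$loci, groups = groups, feature_class = fm$feature_class)
}

locus_cv <- function(v) {
  m <- mean(v)
  if (m == 0) return(0)
  stats::sd(v) / m
}

#' Aggregate read-count summaries for a feature matrix
#'
#' @param fm An `mc_fmatrix` with at least one locus and sample.
#' @return List of two tibbles: `$samples` (sum, mean, median of locus rpm
#'   per sample) and `$loci` (mean, variance, CV across samples per locus).
#' @export
aggregate_feature_summary <- function(fm) {
  stopifnot(inherits(fm, "mc_fmatrix"))
  if (nrow(fm$values) == 0L || ncol(fm$values) == 0L) {
    stop("empty feature matrix", call. = FALSE)
  }
  v <- fm$values
  samples <- tibble(
    sample = colnames(v),
    sum = unname(colSums(v)),
    mean = unname(colMeans(v)),
    median = unname(apply(v, 2, stats::median))
  )
  loci <- tibble(
    locus = rownames(v),
    mean = unname(rowMeans(v)),
    variance = unname(apply(v, 1, stats::var)),
    cv = unname(apply(v, 1, locus_cv))
  )
  if (ncol(v) == 1L) loci$variance <- NA_real_
  structure(list(samples = samples, loci = loci), class = "mc_fsummary")
}
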