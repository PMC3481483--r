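#' Import aligned single-end reads from SAM or BED
#'
#' SAM files are converted and parsed via Rsamtools. Unmapped and secondary
#' records are always dropped; with `unique_only = TRUE` records with mapping
#' quality 0 (the usual multi-mapper convention) are dropped too. BED input is
#' trusted as already filtered to uniquely aligned reads, which is how such
#' files are produced upstream.
#'
#' @param path Path to a SAM (text) or 6-column BED file.
#' @param format `"sam"` or `"bed"`.
#' @param unique_only Drop SAM records with MAPQ 0?
#' @param genome Optional `mc_genome`; when supplied, read chromosomes are
#'   validated against it.
#' @param n_pass_filter Optional library-level count of pass-filter reads
#'   (from the sequencer run summary), used by [alignment_rate()].
#' @return An `mc_reads` object: list with `$reads` (tibble `chrom`, `start`,
#'   `end`, `strand`; 0-based half-open), `$n_pass_filter`,
#'   `$n_unique_aligned`, `$n_after_dedup` (NA until [remove_duplicates()]),
#'   and `$extension` (0 until [extend_reads()]).
#' @export
import_alignments <- function(path, format = c("sam", "bed"), unique_only = TRUE,
                              genome = NULL, n_pass_filter = NA_real_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  reads <- if (format == "sam") {
    read_sam_reads(path, unique_only)
  } else {
    read_bed_reads(path)
  }
  if (!is.null(genome)) {
    missing <- setdiff(unique(reads$chrom), genome$chroms$name)
    if (length(missing)) {
      stop("reads reference unknown chromosome(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  new_reads(reads, n_pass_filter = n_pass_filter,
            n_unique_aligned = nrow(reads))
}

new_reads <- function(reads, n_pass_filter = NA_real_, n_unique_aligned = nrow(reads),
                      n_after_dedup = NA_integer_, extension = 0L) {
  stopifnot(all(reads$start < reads$end))
  structure(
    list(reads = reads, n_pass_filter = n_pass_filter,
         n_unique_aligned = n_unique_aligned, n_after_dedup = n_after_dedup,
         extension = as.integer(extension)),
    class = "mc_reads"
  )
}

#' @export
print.mc_reads <- function(x, ...) {
  cat(sprintf("<mc_reads> %d reads (unique: %s, dedup: %s, extension: %d)\n",
              nrow(x$reads), format(x$n_unique_aligned), format(x$n_after_dedup),
              x$extension))
  invisible(x)
}

read_sam_reads <- function(path, unique_only) {
  bam <- tryCatch(
    Rsamtools::asBam(path, destination = tempfile("mc_sam"),
                     overwrite = TRUE, indexDestination = FALSE),
    error = function(e) stop("malformed SAM file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand", "qwidth",
                                        "mapq", "flag"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(res$pos) & bitwAnd(res$flag, 4L) == 0L &
    bitwAnd(res$flag, 256L) == 0L
  if (unique_only) keep <- keep & (is.na(res$mapq) | res$mapq > 0L)
  tibble(
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    end = res$pos[keep] - 1L + res$qwidth[keep],
    strand = ifelse(bitwAnd(res$flag[keep], 16L) != 0L, "-", "+")
  )
}

read_bed_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) {
    stop("BED read input requires 6 columns (strand); line ",
         which(lengths(fields) < 6L)[1L], call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinate on BED line ", which(is.na(start) | is.na(end))[1L],
         call. = FALSE)
  }
  strand <- vapply(fields, `[[`, "", 6L)
  if (!all(strand %in% c("+", "-"))) {
    stop("invalid strand on BED line ", which(!strand %in% c("+", "-"))[1L],
         call. = FALSE)
  }
  if (any(start >= end)) {
    stop("start >= end on BED line ", which(start >= end)[1L], call. = FALSE)
  }
  tibble(chrom = vapply(fields, `[[`, "", 1L), start = start, end = end,
         strand = strand)
}

five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end)
}

#' Remove PCR duplicates
#'
#' Keeps the first read per (chromosome, strand, 5' position) key — standard
#' PCR-duplicate semantics for single-end libraries. Must run before
#' [extend_reads()] since extension rewrites intervals. Idempotent.
#'
#' @param rs An `mc_reads`.
#' @return Deduplicated `mc_reads` with `$n_after_dedup` set.
#' @export
remove_duplicates <- function(rs) {
  stopifnot(inherits(rs, "mc_reads"))
  if (rs$extension > 0L) {
    stop("remove_duplicates() must be applied before extend_reads()", call. = FALSE)
  }
  key <- paste(rs$reads$chrom, rs$reads$strand, five_prime(rs$reads), sep = "\r")
  keep <- !duplicated(key)
  new_reads(rs$reads[keep, , drop = FALSE],
            n_pass_filter = rs$n_pass_filter,
            n_unique_aligned = rs$n_unique_aligned,
            n_after_dedup = sum(keep))
}

#' Extend reads to fragment length
#'
#' Replaces every read by the fragment-length interval anchored at its 5' end
#' and extending 3'-ward (plus strand: `[start, start + extension)`; minus
#' strand: `[end - extension, end)`), clipped to the chromosome. Extension 0
#' is a no-op.
#'
#' @param rs An `mc_reads`.
#' @param extension Fragment length in bases (>= read length), or 0.
#' @param genome `mc_genome` providing chromosome lengths for clipping.
#' @return Extended `mc_reads` with `$extension` set.
#' @export
extend_reads <- function(rs, extension, genome) {
  stopifnot(inherits(rs, "mc_reads"))
  check_scalar_num(extension, "extension", min = 0)
  if (extension == 0) return(rs)
  r <- rs$reads
  if (nrow(r) > 0L && extension < max(r$end - r$start)) {
    stop("extension (", extension, ") is shorter than the longest read (",
         max(r$end - r$start), ")", call. = FALSE)
  }
  lens <- genome$chroms$length[match(r$chrom, genome$chroms$name)]
  if (anyNA(lens)) {
    stop("unknown chromosome length for: ",
         r$chrom[is.na(lens)][1L], call. = FALSE)
  }
  plus <- r$strand == "+"
  new_start <- ifelse(plus, r$start, r$end - as.integer(extension))
  new_end <- ifelse(plus, r$start + as.integer(extension), r$end)
  r$start <- pmax(0L, as.integer(new_start))
  r$end <- pmin(lens, as.integer(new_end))
  new_reads(r, n_pass_filter = rs$n_pass_filter,
            n_unique_aligned = rs$n_unique_aligned,
            n_after_dedup = rs$n_after_dedup,
            extension = extension)
}
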