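#' Load a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into an in-memory genome object.
#' Sequences are uppercased and restricted to the alphabet `A, C, G, T, N`;
#' anything else is rejected with its position so malformed references fail
#' loudly rather than silently dropping CpG sites.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `mc_genome`: a list with `$seq` (a
#'   [Biostrings::DNAStringSet]) and `$chroms`, a tibble with columns
#'   `name` and `length`. Chromosomes keep file order.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(fasta_path)
  if (length(raw) == 0L) stop("FASTA contains no records: ", fasta_path, call. = FALSE)
  nms <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name in FASTA: ", nms[duplicated(nms)][1L], call. = FALSE)
  }
  chars <- toupper(as.character(raw))
  w <- nchar(chars)
  if (any(w == 0L)) {
    stop("empty FASTA record: ", nms[w == 0L][1L], call. = FALSE)
  }
  bad <- regexpr("[^ACGTN]", chars)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-ACGTN character in record '%s' at position %d", nms[i], bad[i]),
         call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- nms
  structure(
    list(seq = seqs,
         chroms = tibble(name = nms, length = as.integer(w))),
    class = "mc_genome"
  )
}

#' @export
print.mc_genome <- function(x, ...) {
  cat(sprintf("<mc_genome> %d chromosome(s), %s bases total\n",
              nrow(x$chroms), format(sum(x$chroms$length), big.mark = ",")))
  print(x$chroms, ...)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chroms$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom, call. = FALSE)
  genome$chroms$length[i]
}

#' Fetch genome sequence for an interval
#'
#' Coordinates are 0-based half-open (BED convention), as everywhere in this
#' package.
#'
#' @param genome An `mc_genome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval within the chromosome.
#' @return Uppercase DNA string.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  len <- chrom_length(genome, chrom)
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) outside chromosome %s (length %d)",
                 start, end, chrom, len), call. = FALSE)
  }
  as.character(Biostrings::subseq(genome$seq[[chrom]], start + 1L, end))
}

#' Index all CpG dinucleotides of a genome
#'
#' Records the 0-based start position of every plus-strand `CG` dimer per
#' chromosome. A CpG site is palindromic, so indexing one strand counts each
#' site exactly once; dimers containing `N` never match.
#'
#' @param genome An `mc_genome`.
#' @return An `mc_cpg_index`: list with `$positions` (named list of sorted
#'   0-based integer vectors), `$total_cpg`, and `$chrom_lengths`.
#' @export
index_cpg_sites <- function(genome) {
  hits <- Biostrings::vmatchPattern("CG", genome$seq)
  positions <- lapply(seq_along(hits), function(i) {
    as.integer(Biostrings::start(hits[[i]])) - 1L
  })
  names(positions) <- genome$chroms$name
  structure(
    list(positions = positions,
         total_cpg = sum(lengths(positions)),
         chrom_lengths = stats::setNames(genome$chroms$length, genome$chroms$name)),
    class = "mc_cpg_index"
  )
}

#' @export
print.mc_cpg_index <- function(x, ...) {
  cat(sprintf("<mc_cpg_index> %d CpG sites over %d chromosome(s)\n",
              x$total_cpg, length(x$positions)))
  invisible(x)
}

#' Count CpG dinucleotides within an interval
#'
#' With `straddle = TRUE` a CpG whose C lies in `[start, end)` counts even if
#' its G falls one base past `end` (used when classifying bins, crediting a
#' boundary-straddling dimer to the earlier bin). With `straddle = FALSE` the
#' whole dimer must fit inside the interval. A C on the final base of a
#' chromosome is never a site: the dimer does not exist in sequence.
#'
#' @param genome An `mc_genome`.
#' @param chrom,start,end 0-based half-open interval.
#' @param straddle Count dimers straddling `end`?
#' @param index Optional precomputed [index_cpg_sites()] result (recommended
#'   when calling repeatedly).
#' @return Integer count.
#' @export
cpg_content <- function(genome, chrom, start, end, straddle = TRUE, index = NULL) {
  len <- chrom_length(genome, chrom)
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) outside chromosome %s", start, end, chrom),
         call. = FALSE)
  }
  pos <- if (!is.null(index)) {
    index$positions[[chrom]]
  } else {
    m <- Biostrings::matchPattern("CG", genome$seq[[chrom]])
    as.integer(Biostrings::start(m)) - 1L
  }
  hi <- if (straddle) end - 1L else end - 2L
  if (hi < start) return(0L)
  sum(pos >= start & pos <= hi)
}

#' Read genomic feature annotations from BED
#'
#' Accepts BED3 or wider (tab-separated, 0-based half-open). `track`/`browser`
#' lines are skipped. Missing names are synthesised as
#' `<class>_<chrom>_<start>_<end>`; duplicate names are deterministically
#' suffixed so loci stay addressable.
#'
#' @param bed_path Path to a BED file.
#' @param feature_class Label for the class of loci (e.g. `"promoter"`,
#'   `"cpg_island"`, `"shore"`).
#' @return An `mc_features` tibble with columns `chrom`, `start`, `end`,
#'   `name` and attribute `feature_class`.
#' @export
read_features <- function(bed_path, feature_class = "feature") {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path, call. = FALSE)
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_features(tibble(chrom = character(), start = integer(),
                               end = integer(), name = character()),
                        feature_class))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop("BED line ", which(ncols < 3L)[1L], " has fewer than 3 columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s_chr <- vapply(fields, `[[`, "", 2L)
  e_chr <- vapply(fields, `[[`, "", 3L)
  if (any(grepl("[^0-9]", s_chr)) || any(grepl("[^0-9]", e_chr))) {
    bad <- which(grepl("[^0-9]", s_chr) | grepl("[^0-9]", e_chr))[1L]
    stop("non-integer coordinates on BED line ", bad, call. = FALSE)
  }
  start <- as.integer(s_chr)
  end <- as.integer(e_chr)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("BED line %d: start (%d) must be < end (%d)", bad, start[bad], end[bad]),
         call. = FALSE)
  }
  name <- ifelse(ncols >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 paste(feature_class, chrom, start, end, sep = "_"))
  name[!nzchar(name)] <- paste(feature_class, chrom, start, end, sep = "_")[!nzchar(name)]
  name <- make.unique(name, sep = "_")
  new_features(tibble(chrom = chrom, start = start, end = end, name = name),
               feature_class)
}

new_features <- function(tbl, feature_class) {
  structure(tbl, feature_class = feature_class,
            class = c("mc_features", class(tbl)))
}

#' @export
print.mc_features <- function(x, ...) {
  cat(sprintf("<mc_features> class '%s', %d loci\n",
              attr(x, "feature_class") %||% "feature", nrow(x)))
  NextMethod()
}

#' Attach a feature set to a genome, validating chromosomes
#'
#' @param fs An `mc_features`.
#' @param genome An `mc_genome`.
#' @return `fs`, invisibly, after validation.
#' @export
validate_features <- function(fs, genome) {
  missing <- setdiff(unique(fs$chrom), genome$chroms$name)
  if (length(missing)) {
    stop("feature chromosomes absent from genome: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  too_long <- fs$end > genome$chroms$length[match(fs$chrom, genome$chroms$name)]
  if (any(too_long)) {
    stop("feature extends past chromosome end: ", fs$name[too_long][1L], call. = FALSE)
  }
  invisible(fs)
}
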