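#' Simulation configuration
#'
#' Parameters of the synthetic MethylCap-seq study: a single-chromosome
#' reference with CpG-dense islands on a CpG-poor background, a methylome
#' assigning methylation per CpG by compartment, and a read library whose
#' fragment sampling weight grows with local methylated-CpG density
#' (`weight = 1 + enrichment_strength * methylated CpGs in the fragment
#' window`; strength 0 gives a uniform, non-captured "input" library).
#' Defaults emulate a 36-bp single-end capture experiment with ~300 bp
#' fragments on a 2 Mb toy genome with 100 one-kb islands.
#'
#' @param genome_length Genome size in bases.
#' @param n_islands Number of CpG islands.
#' @param island_length Island length in bases (even).
#' @param island_cpg_density,background_cpg_density Probability that a
#'   dinucleotide slot is a CpG, inside/outside islands.
#' @param methylation_prob_island,methylation_prob_background Per-CpG
#'   methylation probabilities by compartment.
#' @param enrichment_strength Capture strength (>= 0; 0 = input library).
#' @param n_reads Reads per library.
#' @param read_length Read length (default 36).
#' @param fragment_length Fragment length (default 300).
#' @param duplicate_rate Probability an emitted read is a PCR copy of an
#'   earlier one.
#' @param seed Master seed.
#' @return An `mc_simconfig` list.
#' @export
sim_config <- function(genome_length = 2e6, n_islands = 100,
                       island_length = 1000, island_cpg_density = 0.15,
                       background_cpg_density = 0.01,
                       methylation_prob_island = 0.8,
                       methylation_prob_background = 0.05,
                       enrichment_strength = 1, n_reads = 200000,
                       read_length = 36, fragment_length = 300,
                       duplicate_rate = 0, seed = 1L) {
  check_scalar_num(genome_length, "genome_length", min = 1000)
  check_scalar_num(n_islands, "n_islands", min = 0)
  check_scalar_num(island_length, "island_length", min = 2)
  for (p in c("island_cpg_density", "background_cpg_density",
              "methylation_prob_island", "methylation_prob_background",
              "duplicate_rate")) {
    check_scalar_num(get(p), p, min = 0, max = 1)
  }
  check_scalar_num(enrichment_strength, "enrichment_strength", min = 0)
  check_scalar_num(n_reads, "n_reads", min = 1)
  if (island_length %% 2 != 0) stop("island_length must be even", call. = FALSE)
  if (n_islands > 0 && n_islands * island_length > genome_length) {
    stop("islands do not fit in the genome without overlap", call. = FALSE)
  }
  if (fragment_length < read_length) {
    stop("fragment_length must be >= read_length", call. = FALSE)
  }
  structure(
    list(genome_length = genome_length, n_islands = n_islands,
         island_length = island_length,
         island_cpg_density = island_cpg_density,
         background_cpg_density = background_cpg_density,
         methylation_prob_island = methylation_prob_island,
         methylation_prob_background = methylation_prob_background,
         enrichment_strength = enrichment_strength, n_reads = n_reads,
         read_length = read_length, fragment_length = fragment_length,
         duplicate_rate = duplicate_rate, seed = as.integer(seed)),
    class = "mc_simconfig"
  )
}

# dinucleotide pairs used for non-CpG slots: never "CG", and never ending in
# "C" so no CG dimer can form across a slot boundary either -- the realised
# CpG density of a simulated sequence is then exactly the configured one
NON_CG_PAIRS <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(first = b, second = c("A", "G", "T"), stringsAsFactors = FALSE)
  p <- p[!(p$first == "C" & p$second == "G"), ]
  rownames(p) <- NULL
  p
}

#' Simulate a CpG-island genome
#'
#' Builds one chromosome from dinucleotide slots: each slot is `CG` with the
#' compartment's CpG density, otherwise a uniform non-CG pair. Islands are
#' placed one per equal-width segment at a random (even) offset, so they
#' never overlap. Deterministic under the seed.
#'
#' @param cfg An [sim_config()].
#' @param fasta_path,bed_path Optional output paths for the FASTA and the
#'   island BED.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return List: `$genome` (`mc_genome`), `$islands` (`mc_features`), plus
#'   `$fasta`/`$bed` paths when written.
#' @export
simulate_genome <- function(cfg, fasta_path = NULL, bed_path = NULL,
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "mc_simconfig"))
  n_slots <- cfg$genome_length %/% 2L
  withr::with_seed(seed, {
    island_slot <- rep(FALSE, n_slots)
    islands <- tibble(chrom = character(), start = integer(), end = integer(),
                      name = character())
    if (cfg$n_islands > 0) {
      seg_slots <- n_slots %/% cfg$n_islands
      isl_slots <- cfg$island_length %/% 2L
      offsets <- sample.int(seg_slots - isl_slots + 1L, cfg$n_islands,
                            replace = TRUE) - 1L
      starts_slot <- (seq_len(cfg$n_islands) - 1L) * seg_slots + offsets
      for (i in seq_len(cfg$n_islands)) {
        island_slot[(starts_slot[i] + 1L):(starts_slot[i] + isl_slots)] <- TRUE
      }
      islands <- tibble(chrom = "chr1",
                        start = as.integer(starts_slot * 2L),
                        end = as.integer((starts_slot + isl_slots) * 2L),
                        name = sprintf("island_%03d", seq_len(cfg$n_islands)))
    }
    dens <- ifelse(island_slot, cfg$island_cpg_density, cfg$background_cpg_density)
    is_cg <- runif(n_slots) < dens
    first <- character(n_slots)
    second <- character(n_slots)
    first[is_cg] <- "C"
    second[is_cg] <- "G"
    n_other <- sum(!is_cg)
    pick <- sample.int(nrow(NON_CG_PAIRS), n_other, replace = TRUE)
    first[!is_cg] <- NON_CG_PAIRS$first[pick]
    second[!is_cg] <- NON_CG_PAIRS$second[pick]
    seqchar <- paste(paste0(first, second), collapse = "")
    if (nchar(seqchar) < cfg$genome_length) { # odd genome length: pad with A
      seqchar <- paste0(seqchar, strrep("A", cfg$genome_length - nchar(seqchar)))
    }
  })
  seqs <- Biostrings::DNAStringSet(seqchar)
  names(seqs) <- "chr1"
  genome <- structure(
    list(seq = seqs, chroms = tibble(name = "chr1",
                                     length = as.integer(cfg$genome_length))),
    class = "mc_genome"
  )
  out <- list(genome = genome, islands = new_features(islands, "cpg_island"))
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(seqs, fasta_path)
    out$fasta <- fasta_path
  }
  if (!is.null(bed_path)) {
    write.table(islands, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    out$bed <- bed_path
  }
  out
}

#' Simulate a methylome
#'
#' Methylates each CpG independently with the probability of its compartment
#' (island vs background). Per-island probabilities can be overridden to
#' build group-specific hyper/hypomethylated loci.
#'
#' @param genome `mc_genome`.
#' @param islands `mc_features` of island coordinates.
#' @param cfg [sim_config()].
#' @param island_probs Optional numeric vector, one probability per island,
#'   overriding `cfg$methylation_prob_island` locus by locus.
#' @param seed Seed (defaults to `cfg$seed`).
#' @return An `mc_methylome` tibble: `chrom`, `pos` (0-based CpG starts),
#'   `in_island`.
#' @export
simulate_methylome <- function(genome, islands, cfg, island_probs = NULL,
                               seed = cfg$seed) {
  idx <- index_cpg_sites(genome)
  if (!is.null(island_probs) && length(island_probs) != nrow(islands)) {
    stop("island_probs must have one entry per island", call. = FALSE)
  }
  withr::with_seed(seed, {
    pieces <- lapply(names(idx$positions), function(ch) {
      pos <- idx$positions[[ch]]
      if (length(pos) == 0L) return(NULL)
      prob <- rep(cfg$methylation_prob_background, length(pos))
      inside_any <- rep(FALSE, length(pos))
      isl <- islands[islands$chrom == ch, , drop = FALSE]
      isl_ids <- which(islands$chrom == ch)
      for (i in seq_len(nrow(isl))) {
        inside <- pos >= isl$start[i] & pos < isl$end[i]
        prob[inside] <- if (is.null(island_probs)) cfg$methylation_prob_island
                        else island_probs[isl_ids[i]]
        inside_any <- inside_any | inside
      }
      keep <- runif(length(pos)) < prob
      tibble(chrom = ch, pos = pos[keep], in_island = inside_any[keep])
    })
    meth <- bind_rows(pieces)
  })
  structure(meth, class = c("mc_methylome", class(meth)))
}

#' Simulate a capture-enriched read library
#'
#' Samples fragment start positions with weight
#' `1 + enrichment_strength * (methylated CpGs in the fragment window)`,
#' emits a read of `read_length` from the fragment 5' end on a random strand,
#' optionally injects PCR duplicates, and (optionally) writes a valid
#' single-end SAM and a BED6. Deterministic under the seed. The weight model
#' is the simplest monotone stand-in for capture chemistry, not a claim about
#' MBD binding.
#'
#' @param genome `mc_genome`.
#' @param methylome `mc_methylome` from [simulate_methylome()].
#' @param cfg [sim_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @param sam_path,bed_path Optional output paths.
#' @return An `mc_reads` (with `$n_pass_filter = n_reads`); written file
#'   paths are attached as attributes `sam`/`bed` when requested.
#' @export
simulate_reads <- function(genome, methylome, cfg, seed = cfg$seed,
                           sam_path = NULL, bed_path = NULL) {
  stopifnot(inherits(cfg, "mc_simconfig"))
  lf <- cfg$fragment_length
  rl <- cfg$read_length
  withr::with_seed(seed, {
    # per-chromosome sliding-window counts of methylated CpGs -> weights
    per_chrom <- lapply(seq_len(nrow(genome$chroms)), function(i) {
      ch <- genome$chroms$name[i]
      len <- genome$chroms$length[i]
      if (len < lf) return(NULL)
      mp <- methylome$pos[methylome$chrom == ch]
      ind <- tabulate(mp + 1L, nbins = len)
      cs <- c(0, cumsum(ind))
      nw <- len - lf + 1L
      cnt <- cs[(lf + 1L):(len + 1L)] - cs[seq_len(nw)]
      list(chrom = ch, weights = 1 + cfg$enrichment_strength * cnt)
    })
    per_chrom <- per_chrom[!vapply(per_chrom, is.null, logical(1))]
    totals <- vapply(per_chrom, function(x) sum(x$weights), numeric(1))
    chrom_draw <- sample.int(length(per_chrom), cfg$n_reads, replace = TRUE,
                             prob = totals)
    frag_start <- integer(cfg$n_reads)
    for (i in seq_along(per_chrom)) {
      sel <- chrom_draw == i
      if (!any(sel)) next
      frag_start[sel] <- sample.int(length(per_chrom[[i]]$weights), sum(sel),
                                    replace = TRUE,
                                    prob = per_chrom[[i]]$weights) - 1L
    }
    chrom <- vapply(per_chrom, `[[`, "", "chrom")[chrom_draw]
    strand <- sample(c("+", "-"), cfg$n_reads, replace = TRUE)
    start <- ifelse(strand == "+", frag_start, frag_start + lf - rl)
    end <- start + rl
    if (cfg$duplicate_rate > 0 && cfg$n_reads > 1) {
      dup <- runif(cfg$n_reads) < cfg$duplicate_rate
      dup[1L] <- FALSE
      di <- which(dup)
      src <- floor(runif(length(di)) * (di - 1)) + 1
      chrom[di] <- chrom[src]
      start[di] <- start[src]
      end[di] <- end[src]
      strand[di] <- strand[src]
    }
  })
  reads <- tibble(chrom = chrom, start = as.integer(start),
                  end = as.integer(end), strand = strand)
  rs <- new_reads(reads, n_pass_filter = cfg$n_reads,
                  n_unique_aligned = cfg$n_reads)
  if (!is.null(sam_path)) {
    write_sam(rs, genome, sam_path)
    attr(rs, "sam") <- sam_path
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(reads$chrom, reads$start, reads$end,
                      paste0("read_", seq_len(nrow(reads))), 0L, reads$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    attr(rs, "bed") <- bed_path
  }
  rs
}

# minimal single-end SAM writer (valid @SQ header, FLAG 0/16, fixed CIGAR)
write_sam <- function(rs, genome, path) {
  r <- rs$reads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$chroms$name,
                       genome$chroms$length)), con)
  if (nrow(r) == 0L) return(invisible(path))
  seqs <- character(nrow(r))
  for (ch in unique(r$chrom)) {
    rows <- which(r$chrom == ch)
    views <- Biostrings::Views(genome$seq[[ch]], start = r$start[rows] + 1L,
                               end = r$end[rows])
    s <- as.character(views)
    minus <- r$strand[rows] == "-"
    if (any(minus)) {
      s[minus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(s[minus])))
    }
    seqs[rows] <- s
  }
  lines <- sprintf("read_%d\t%d\t%s\t%d\t42\t%dM\t*\t0\t0\t%s\t%s",
                   seq_len(nrow(r)), ifelse(r$strand == "-", 16L, 0L),
                   r$chrom, r$start + 1L, r$end - r$start, seqs,
                   strrep("I", r$end - r$start))
  writeLines(lines, con)
  invisible(path)
}

#' Simulate a multi-group cohort
#'
#' Shares one genome across all samples; designated differential islands get
#' group-specific methylation probabilities, all other islands keep the
#' baseline. Per-sample seeds are derived from the master seed so any single
#' library is regenerable in isolation.
#'
#' @param cfg Baseline [sim_config()].
#' @param groups Named list; each element a list with `n` (samples) and
#'   optionally `methylation_prob_island`, the probability this group uses at
#'   the differential islands.
#' @param n_diff Number of differential islands (sampled from all islands
#'   under the master seed; `0` for a null cohort).
#' @param out_dir When given, SAM and BED files are written here and listed
#'   in the manifest.
#' @param seed Master seed (defaults to `cfg$seed`).
#' @return List: `$genome`, `$islands`, `$diff_islands` (names),
#'   `$manifest` (tibble `sample`, `group`, `seed`, `n_reads`, `sam`, `bed`),
#'   `$readsets` (named list of `mc_reads`).
#' @export
simulate_cohort <- function(cfg, groups, n_diff = 0, out_dir = NULL,
                            seed = cfg$seed) {
  stopifnot(inherits(cfg, "mc_simconfig"), length(groups) >= 2L,
            !is.null(names(groups)))
  n_total <- sum(vapply(groups, function(g) g$n, numeric(1)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  derived <- withr::with_seed(seed, sample.int(2^31 - 2L, n_total + 2L))
  g <- simulate_genome(cfg, seed = derived[1L],
                       fasta_path = if (is.null(out_dir)) NULL else
                         file.path(out_dir, "genome.fa"),
                       bed_path = if (is.null(out_dir)) NULL else
                         file.path(out_dir, "islands.bed"))
  n_islands <- nrow(g$islands)
  diff_idx <- if (n_diff > 0) {
    withr::with_seed(derived[2L], sort(sample.int(n_islands, min(n_diff, n_islands))))
  } else integer(0)
  manifest <- list()
  readsets <- list()
  k <- 0L
  for (gname in names(groups)) {
    gspec <- groups[[gname]]
    gprob <- gspec$methylation_prob_island %||% cfg$methylation_prob_island
    island_probs <- rep(cfg$methylation_prob_island, n_islands)
    island_probs[diff_idx] <- gprob
    for (j in seq_len(gspec$n)) {
      k <- k + 1L
      sname <- sprintf("%s_%02d", gname, j)
      sseed <- derived[k + 2L]
      meth <- simulate_methylome(g$genome, g$islands, cfg,
                                 island_probs = island_probs, seed = sseed)
      sam <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(sname, ".sam"))
      bed <- if (is.null(out_dir)) NULL else file.path(out_dir, paste0(sname, ".bed"))
      rs <- simulate_reads(g$genome, meth, cfg, seed = sseed,
                           sam_path = sam, bed_path = bed)
      readsets[[sname]] <- rs
      manifest[[sname]] <- tibble(sample = sname, group = gname, seed = sseed,
                                  n_reads = cfg$n_reads,
                                  sam = sam %||% NA_character_,
                                  bed = bed %||% NA_character_)
    }
  }
  manifest <- bind_rows(manifest)
  if (!is.null(out_dir)) {
    write_tsv_quiet(manifest, file.path(out_dir, "manifest.tsv"))
  }
  list(genome = g$genome, islands = g$islands,
       diff_islands = g$islands$name[diff_idx],
       manifest = manifest, readsets = readsets)
}
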