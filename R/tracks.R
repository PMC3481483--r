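#' Midrank percentile ranks
#'
#' `rank(v) = (#values < v + 0.5 * #values == v) / n`; invariant under any
#' strictly increasing transform of the values, so downstream discretization
#' depends only on the ordering of rpm values, never their scale.
#'
#' @param values Non-empty numeric vector.
#' @return Ranks in `(0, 1)`, same length/order as `values`.
#' @export
percentile_rank <- function(values) {
  if (length(values) == 0L) stop("percentile_rank needs values", call. = FALSE)
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

#' Discretized percentile-rank heatmap track
#'
#' Percentile-ranks a sample's binned rpm values (per sample, genome-wide by
#' default, or over a supplied region set for locus views), discretizes into
#' `n_levels` levels (`level = min(floor(rank * L), L - 1)`), and attaches a
#' colour gradient. Stacking the rows of several samples yields the final
#' heatmap; each sample is ranked independently.
#'
#' @param bt An `mc_bintrack`.
#' @param n_levels Number of levels L (>= 2, default 10).
#' @param palette L hex colours, low to high (default white to red).
#' @param region Optional `mc_features`-like table restricting the ranking
#'   universe to bins overlapping those loci.
#' @return An `mc_heatmap` tibble: `chrom`, `start`, `end`, `level`, `color`;
#'   attributes `n_levels`, `palette`.
#' @export
export_heatmap_track <- function(bt, n_levels = 10, palette = NULL,
                                 region = NULL) {
  check_scalar_num(n_levels, "n_levels", min = 2)
  n_levels <- as.integer(n_levels)
  if (is.null(palette)) {
    palette <- grDevices::colorRampPalette(c("#FFFFFF", "#FF0000"))(n_levels)
  }
  if (length(palette) != n_levels) {
    stop("palette length (", length(palette), ") must equal n_levels (",
         n_levels, ")", call. = FALSE)
  }
  tbl <- bintrack_tibble(bt)
  if (!is.null(region)) {
    keep <- rep(FALSE, nrow(tbl))
    for (i in seq_len(nrow(region))) {
      keep <- keep | (tbl$chrom == region$chrom[i] &
                        tbl$start < region$end[i] & tbl$end > region$start[i])
    }
    tbl <- tbl[keep, , drop = FALSE]
    if (nrow(tbl) == 0L) stop("region overlaps no bins", call. = FALSE)
  }
  rk <- percentile_rank(tbl$rpm)
  level <- pmin(as.integer(floor(rk * n_levels)), n_levels - 1L)
  out <- tibble(chrom = tbl$chrom, start = tbl$start, end = tbl$end,
                level = level, color = palette[level + 1L])
  structure(out, n_levels = n_levels, palette = palette,
            class = c("mc_heatmap", class(out)))
}

#' Write a heatmap track to file
#'
#' @param track An `mc_heatmap` tibble.
#' @param path Output path (tab-separated `chrom start end level color`).
#' @return `path`, invisibly.
#' @export
write_heatmap_track <- function(track, path) {
  write_tsv_quiet(as_tibble(track), path)
  invisible(path)
}

#' Read track for browser display
#'
#' One record per distinct read position — `chrom`, `start`, `end`, the count
#' of reads sharing that exact position/strand, and the strand — sorted by
#' chromosome then start, so any input order yields an identical file.
#'
#' @param rs An `mc_reads` (pre- or post-deduplication; counts reflect
#'   whichever set is passed).
#' @param path Output path; `NULL` returns the tibble.
#' @return Tibble `chrom`, `start`, `end`, `count`, `strand` (invisibly when
#'   written). Written files carry a single header line.
#' @export
export_read_track <- function(rs, path = NULL) {
  stopifnot(inherits(rs, "mc_reads"))
  r <- rs$reads
  tbl <- r |>
    group_by(.data$chrom, .data$start, .data$end, .data$strand) |>
    summarise(count = dplyr::n(), .groups = "drop") |>
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  tbl <- tbl[, c("chrom", "start", "end", "count", "strand")]
  if (is.null(path)) return(tbl)
  write_tsv_quiet(tbl, path)
  invisible(tbl)
}

#' Export a bin track as bedGraph
#'
#' Standard 4-column bedGraph (0-based half-open) of per-bin counts or rpm,
#' compatible with the UCSC Genome Browser. Adjacent equal-valued bins can be
#' merged run-length style, and zero bins suppressed.
#'
#' @param bt An `mc_bintrack`.
#' @param path Output path; `NULL` returns the tibble.
#' @param value `"rpm"` or `"counts"`.
#' @param merge_adjacent Merge adjacent equal-valued bins?
#' @param drop_zero Omit zero-valued records?
#' @param name Track name for the header line.
#' @return Tibble `chrom`, `start`, `end`, `value` (invisibly when written).
#' @export
export_bedgraph <- function(bt, path = NULL, value = c("rpm", "counts"),
                            merge_adjacent = TRUE, drop_zero = FALSE,
                            name = "methcapr") {
  value <- match.arg(value)
  tbl <- bintrack_tibble(bt)
  tbl$value <- if (value == "rpm") tbl$rpm else tbl$count
  pieces <- lapply(split(tbl, factor(tbl$chrom, levels = unique(tbl$chrom))),
                   function(d) {
    if (merge_adjacent && nrow(d) > 1L) {
      run <- cumsum(c(TRUE, d$value[-1L] != d$value[-nrow(d)]))
      d <- tibble(chrom = d$chrom[1L],
                  start = as.integer(tapply(d$start, run, min)),
                  end = as.integer(tapply(d$end, run, max)),
                  value = as.numeric(tapply(d$value, run, `[`, 1L)))
    }
    d[, c("chrom", "start", "end", "value")]
  })
  out <- bind_rows(pieces)
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (drop_zero) out <- out[out$value != 0, , drop = FALSE]
  if (is.null(path)) return(out)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(out)
}
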