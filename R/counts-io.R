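# Binary counts codec.
#
# Layout (little-endian): magic "MCBC", version u8 (=1), bin_size u32,
# extension u32, total_reads u64, n_chrom u16; then per chromosome:
# name length u8 + name bytes, chrom_length u64, n_bins u32,
# counts u32[n_bins], rpm f32[n_bins]; trailing CRC32 (u32) over everything
# before it. rpm survives a round trip at 32-bit float precision; counts are
# exact.

MCBC_MAGIC <- charToRaw("MCBC")
MCBC_VERSION <- as.raw(1L)

#' Write a bin track to the binary counts format
#'
#' @param bt An `mc_bintrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_counts()] for the inverse; the two round-trip bit-exactly
#'   (rpm stored as 32-bit floats).
#' @export
write_counts <- function(bt, path) {
  stopifnot(inherits(bt, "mc_bintrack"))
  parts <- list(
    MCBC_MAGIC, MCBC_VERSION,
    pack_uint(bt$bin_size, 4L), pack_uint(bt$extension, 4L),
    pack_uint(bt$total_reads, 8L), pack_uint(nrow(bt$chroms), 2L)
  )
  for (i in seq_len(nrow(bt$chroms))) {
    nm <- bt$chroms$name[i]
    rpm32 <- writeBin(as.numeric(bt$rpm[[nm]]), raw(), size = 4L,
                      endian = "little")
    parts <- c(parts, list(
      as.raw(nchar(nm)), charToRaw(nm),
      pack_uint(bt$chroms$length[i], 8L), pack_uint(bt$chroms$n_bins[i], 4L),
      pack_uint(bt$counts[[nm]], 4L), rpm32
    ))
  }
  payload <- do.call(c, parts)
  out <- c(payload, pack_uint(crc32(payload), 4L))
  writeBin(out, path)
  invisible(path)
}

#' Read a bin track from the binary counts format
#'
#' Verifies magic bytes, version, and trailing CRC32; truncation errors name
#' the chromosome being read when possible.
#'
#' @param path Path to a file written by [write_counts()].
#' @return An `mc_bintrack`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 27L) stop("counts file truncated (header incomplete): ", path,
                            call. = FALSE)
  if (!identical(r[1:4], MCBC_MAGIC)) {
    stop("bad magic bytes: not a binary counts file: ", path, call. = FALSE)
  }
  if (r[5L] != MCBC_VERSION) {
    stop("unsupported counts format version: ", as.integer(r[5L]), call. = FALSE)
  }
  stored_crc <- unpack_uint(r[(length(r) - 3L):length(r)], 4L)
  payload <- r[seq_len(length(r) - 4L)]
  if (crc32(payload) != stored_crc) {
    stop("checksum mismatch in counts file: ", path, call. = FALSE)
  }
  pos <- 6L
  take <- function(n, what) {
    if (pos + n - 1L > length(payload)) {
      stop("counts file truncated while reading ", what, call. = FALSE)
    }
    chunk <- payload[pos:(pos + n - 1L)]
    pos <<- pos + n
    chunk
  }
  bin_size <- unpack_uint(take(4L, "bin_size"), 4L)
  extension <- unpack_uint(take(4L, "extension"), 4L)
  total_reads <- unpack_uint(take(8L, "total_reads"), 8L)
  n_chrom <- unpack_uint(take(2L, "chromosome count"), 2L)
  names_v <- character(n_chrom)
  lengths_v <- numeric(n_chrom)
  nbins_v <- integer(n_chrom)
  counts <- vector("list", n_chrom)
  rpm <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    nl <- as.integer(take(1L, "chromosome name")[1L])
    nm <- rawToChar(take(nl, "chromosome name"))
    names_v[i] <- nm
    lengths_v[i] <- unpack_uint(take(8L, paste0("length of ", nm)), 8L)
    nb <- unpack_uint(take(4L, paste0("bin count of ", nm)), 4L)
    nbins_v[i] <- as.integer(nb)
    counts[[i]] <- as.integer(unpack_uint(take(4L * nb, paste0("counts array of chromosome ", nm)), 4L))
    rpm[[i]] <- readBin(take(4L * nb, paste0("rpm array of chromosome ", nm)),
                        "numeric", n = nb, size = 4L, endian = "little")
  }
  names(counts) <- names_v
  names(rpm) <- names_v
  structure(
    list(bin_size = as.integer(bin_size), extension = as.integer(extension),
         total_reads = total_reads,
         chroms = tibble(name = names_v, length = as.integer(lengths_v),
                         n_bins = nbins_v),
         counts = counts, rpm = rpm),
    class = "mc_bintrack"
  )
}

#' Export a bin track as plain text
#'
#' Tab-separated `chrom, start, end, count, rpm`, one row per bin.
#'
#' @param bt An `mc_bintrack`.
#' @param path Output path; when `NULL` the tibble is returned instead.
#' @return The tibble (invisibly when written).
#' @export
export_counts_text <- function(bt, path = NULL) {
  tbl <- bintrack_tibble(bt)
  if (is.null(path)) return(tbl)
  write_tsv_quiet(tbl, path)
  invisible(tbl)
}

bintrack_tibble <- function(bt) {
  pieces <- lapply(seq_len(nrow(bt$chroms)), function(i) {
    nm <- bt$chroms$name[i]
    nb <- bt$chroms$n_bins[i]
    starts <- (seq_len(nb) - 1L) * bt$bin_size
    tibble(chrom = nm, start = starts,
           end = pmin(starts + bt$bin_size, bt$chroms$length[i]),
           count = bt$counts[[nm]], rpm = bt$rpm[[nm]])
  })
  bind_rows(pieces)
}
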