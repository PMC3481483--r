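# internal helpers: scalar checks, byte packing, CRC32 for the counts codec

check_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
         call. = FALSE)
  }
  invisible(x)
}

# little-endian unsigned integer packing; values held as doubles so u32/u64
# fields above .Machine$integer.max survive (counts and read totals)
pack_uint <- function(x, nbytes) {
  x <- as.numeric(x)
  if (any(x < 0) || any(x != floor(x))) stop("pack_uint: non-negative integers only")
  out <- raw(length(x) * nbytes)
  for (k in seq_len(nbytes)) {
    out[seq(k, by = nbytes, length.out = length(x))] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

unpack_uint <- function(r, nbytes) {
  m <- matrix(as.numeric(r), nrow = nbytes)
  as.numeric(256^(0:(nbytes - 1)) %*% m)
}

# table-driven CRC32 (IEEE 802.3 polynomial), bitwShift* are zero-filled so
# the signed int register behaves as uint32
crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    poly <- -306674912L # 0xEDB88320
    tab <- integer(256)
    for (i in 0:255) {
      cr <- i
      for (k in 1:8) {
        cr <- if (bitwAnd(cr, 1L) != 0L) bitwXor(bitwShiftR(cr, 1L), poly) else bitwShiftR(cr, 1L)
      }
      tab[i + 1L] <- cr
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  u <- as.numeric(crc)
  if (u < 0) u + 2^32 else u
}

write_tsv_quiet <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
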