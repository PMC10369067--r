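# Minimal ZIP archive support (stored entries only).
#
# The overlay bundle must be byte-identical across runs with the same seed,
# so entries are written uncompressed with a constant timestamp.  Reading
# supports only archives produced here (compression method 0).

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  for (n in 0:255) {
    c <- n
    for (i in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    crc <- bitwXor(crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

le_bytes <- function(value, n) {
  out <- raw(n)
  v <- value
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# DOS time/date fields, fixed so archives are reproducible (2020-01-01 00:00:00).
zip_dos_time <- le_bytes(0, 2)
zip_dos_date <- le_bytes(bitwOr(bitwShiftL(40L, 9L), bitwOr(bitwShiftL(1L, 5L), 1L)), 2)

#' Write a ZIP archive
#'
#' Writes named content to a ZIP file using the stored (uncompressed) method
#' with a constant timestamp, so the same content always yields the same
#' bytes.
#'
#' @param path Output file path.
#' @param entries Named list; names are archive member paths (forward
#'   slashes), values are character scalars or raw vectors.
#' @return `path`, invisibly.
#' @export
write_zip <- function(path, entries) {
  stopifnot(is.list(entries), length(entries) > 0, !is.null(names(entries)))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- numeric(length(entries))
  infos <- vector("list", length(entries))
  pos <- 0
  for (i in seq_along(entries)) {
    name <- names(entries)[i]
    data <- entries[[i]]
    if (is.character(data)) data <- charToRaw(paste(data, collapse = ""))
    stopifnot(is.raw(data))
    crc <- crc32(data)
    nameb <- charToRaw(name)
    header <- c(
      charToRaw("PK\x03\x04"),
      le_bytes(20, 2),            # version needed
      le_bytes(0, 2),             # flags
      le_bytes(0, 2),             # method: stored
      zip_dos_time, zip_dos_date,
      le_bytes(crc, 4),
      le_bytes(length(data), 4),  # compressed size
      le_bytes(length(data), 4),  # uncompressed size
      le_bytes(length(nameb), 2),
      le_bytes(0, 2)              # extra length
    )
    writeBin(header, con)
    writeBin(nameb, con)
    if (length(data)) writeBin(data, con)
    offsets[i] <- pos
    infos[[i]] <- list(name = nameb, crc = crc, size = length(data))
    pos <- pos + length(header) + length(nameb) + length(data)
  }
  cd_start <- pos
  cd_size <- 0
  for (i in seq_along(entries)) {
    inf <- infos[[i]]
    rec <- c(
      charToRaw("PK\x01\x02"),
      le_bytes(20, 2), le_bytes(20, 2),
      le_bytes(0, 2), le_bytes(0, 2),
      zip_dos_time, zip_dos_date,
      le_bytes(inf$crc, 4),
      le_bytes(inf$size, 4), le_bytes(inf$size, 4),
      le_bytes(length(inf$name), 2),
      le_bytes(0, 2), le_bytes(0, 2),  # extra, comment
      le_bytes(0, 2), le_bytes(0, 2),  # disk start, internal attrs
      le_bytes(0, 4),                  # external attrs
      le_bytes(offsets[i], 4)
    )
    writeBin(rec, con)
    writeBin(inf$name, con)
    cd_size <- cd_size + length(rec) + length(inf$name)
  }
  eocd <- c(
    charToRaw("PK\x05\x06"),
    le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(cd_size, 4), le_bytes(cd_start, 4),
    le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

read_le <- function(bytes, from, n) {
  sum(as.numeric(bytes[from:(from + n - 1)]) * 256^(0:(n - 1)))
}

#' Read a ZIP archive written by [write_zip()]
#'
#' @param path Archive path.
#' @return Named list of raw vectors, one per member.
#' @export
read_zip <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  sig <- charToRaw("PK\x05\x06")
  eocd <- NA
  for (i in seq(length(bytes) - 21, max(1, length(bytes) - 65557))) {
    if (identical(bytes[i:(i + 3)], sig)) { eocd <- i; break }
  }
  if (is.na(eocd)) stop("not a ZIP archive (no end-of-central-directory): ", path)
  n_entries <- read_le(bytes, eocd + 10, 2)
  cd_pos <- read_le(bytes, eocd + 16, 4) + 1
  out <- list()
  for (k in seq_len(n_entries)) {
    stopifnot(identical(bytes[cd_pos:(cd_pos + 3)], charToRaw("PK\x01\x02")))
    method <- read_le(bytes, cd_pos + 10, 2)
    size <- read_le(bytes, cd_pos + 24, 4)
    name_len <- read_le(bytes, cd_pos + 28, 2)
    extra_len <- read_le(bytes, cd_pos + 30, 2)
    comment_len <- read_le(bytes, cd_pos + 32, 2)
    local_off <- read_le(bytes, cd_pos + 42, 4) + 1
    name <- rawToChar(bytes[(cd_pos + 46):(cd_pos + 45 + name_len)])
    if (method != 0) stop("unsupported compression method for member ", name)
    lname_len <- read_le(bytes, local_off + 26, 2)
    lextra_len <- read_le(bytes, local_off + 28, 2)
    data_pos <- local_off + 30 + lname_len + lextra_len
    out[[name]] <- if (size > 0) bytes[data_pos:(data_pos + size - 1)] else raw(0)
    cd_pos <- cd_pos + 46 + name_len + extra_len + comment_len
  }
  out
}
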