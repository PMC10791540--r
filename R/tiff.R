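# Minimal baseline TIFF support: multi-page, grayscale, uncompressed strips,
# 8- or 16-bit unsigned samples, II or MM byte order. No pre-installed R
# package reads TIFF in this stack, so the subset needed for stacked CT
# exports is implemented here and cross-validated in the tests against an
# independent reader.

.tiff_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.tiff_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

# one 12-byte IFD entry; `value` already fits in 4 bytes (count 1 only)
.tiff_entry <- function(tag, type, value) {
  val <- if (type == 3L) c(.tiff_u16(value), as.raw(c(0L, 0L))) else .tiff_u32(value)
  c(.tiff_u16(tag), .tiff_u16(type), .tiff_u32(1L), val)
}

# pages: list of integer matrices (row 1 = top); values must fit in `bits`
tiff_write <- function(pages, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop_config("bits must be 8 or 16, got ", bits)
  bytes_pp <- bits / 8L
  maxv <- 2^bits - 1
  offset <- 8L  # after header
  chunks <- vector("list", length(pages))
  ifds <- vector("list", length(pages))
  ifd_offsets <- integer(length(pages))
  for (p in seq_along(pages)) {
    m <- pages[[p]]
    vals <- as.integer(round(t(m)))  # TIFF is row-major
    if (any(vals < 0L) || any(vals > maxv))
      stop_config("pixel values outside [0, ", maxv, "] for ", bits, "-bit TIFF")
    data <- writeBin(vals, raw(), size = bytes_pp, endian = "little")
    h <- nrow(m); w <- ncol(m)
    nbytes <- length(data)
    data_offset <- offset
    ifd_offsets[p] <- offset + nbytes
    entries <- c(
      .tiff_entry(256L, 4L, w),
      .tiff_entry(257L, 4L, h),
      .tiff_entry(258L, 3L, bits),
      .tiff_entry(259L, 3L, 1L),          # no compression
      .tiff_entry(262L, 3L, 1L),          # BlackIsZero
      .tiff_entry(273L, 4L, data_offset),
      .tiff_entry(277L, 3L, 1L),
      .tiff_entry(278L, 4L, h),
      .tiff_entry(279L, 4L, nbytes)
    )
    ifd <- c(.tiff_u16(9L), entries, .tiff_u32(0L))  # next-IFD patched below
    chunks[[p]] <- data
    ifds[[p]] <- ifd
    offset <- ifd_offsets[p] + length(ifd)
  }
  for (p in seq_len(length(pages) - 1L)) {
    nxt <- .tiff_u32(ifd_offsets[p + 1L])
    ifd <- ifds[[p]]
    ifd[(length(ifd) - 3L):length(ifd)] <- nxt
    ifds[[p]] <- ifd
  }
  out <- c(charToRaw("II"), .tiff_u16(42L), .tiff_u32(ifd_offsets[1L]))
  for (p in seq_along(pages)) out <- c(out, chunks[[p]], ifds[[p]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

.tiff_int <- function(bytes, offset, size, n, endian) {
  idx <- (offset + 1L):(offset + n * size)
  if (max(idx) > length(bytes)) stop_io("truncated TIFF: read past end of file")
  v <- readBin(bytes[idx], "integer", n = n, size = size,
               signed = size == 4L, endian = endian)
  if (size < 4L) v else v  # sizes here never exceed 2^31 in practice
}

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

# read one IFD entry's numeric values (BYTE/SHORT/LONG only)
.tiff_values <- function(bytes, entry_off, endian) {
  type <- .tiff_int(bytes, entry_off + 2L, 2L, 1L, endian)
  count <- .tiff_int(bytes, entry_off + 4L, 4L, 1L, endian)
  size <- .tiff_type_size[as.character(type)]
  if (is.na(size) || !type %in% c(1L, 3L, 4L)) return(NULL)
  total <- size * count
  voff <- if (total <= 4L) entry_off + 8L
          else .tiff_int(bytes, entry_off + 8L, 4L, 1L, endian)
  .tiff_int(bytes, voff, size, count, endian)
}

# returns list of integer matrices plus the bit depth as attribute "bits"
tiff_read <- function(path) {
  if (!file.exists(path)) stop_io("cannot read TIFF: no such file: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L) stop_io("corrupt TIFF (too short): ", path)
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop_io("corrupt TIFF (bad byte-order mark): ", path))
  if (.tiff_int(bytes, 2L, 2L, 1L, endian) != 42L)
    stop_io("corrupt TIFF (bad magic number): ", path)
  ifd_off <- .tiff_int(bytes, 4L, 4L, 1L, endian)
  pages <- list()
  bits_seen <- integer(0)
  while (ifd_off != 0L) {
    n_entries <- .tiff_int(bytes, ifd_off, 2L, 1L, endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      entry_off <- ifd_off + 2L + (e - 1L) * 12L
      tag <- .tiff_int(bytes, entry_off, 2L, 1L, endian)
      vals <- .tiff_values(bytes, entry_off, endian)
      if (!is.null(vals)) tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_io("TIFF missing required tag ", tag, ": ", path)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bits <- need(258L, 8L)[1L]
    if (need(259L, 1L) != 1L)
      stop_io("unsupported TIFF: compressed data in ", path)
    if (need(277L, 1L) != 1L)
      stop_io("unsupported TIFF: multi-sample pixels in ", path)
    if (!bits %in% c(8L, 16L))
      stop_io("unsupported TIFF bit depth ", bits, " in ", path)
    strip_off <- need(273L)
    strip_cnt <- need(279L, w * h * bits / 8L)
    bytes_pp <- bits / 8L
    vals <- integer(0)
    for (s in seq_along(strip_off)) {
      ns <- strip_cnt[min(s, length(strip_cnt))] / bytes_pp
      idx <- (strip_off[s] + 1L):(strip_off[s] + ns * bytes_pp)
      if (max(idx) > length(bytes)) stop_io("truncated TIFF strip in ", path)
      vals <- c(vals, readBin(bytes[idx], "integer", n = ns, size = bytes_pp,
                              signed = FALSE, endian = endian))
    }
    if (length(vals) != w * h)
      stop_io("TIFF strip sizes inconsistent with dimensions in ", path)
    if (bytes_pp == 4L) vals <- abs(vals)  # unreachable for 8/16-bit
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    bits_seen <- c(bits_seen, bits)
    ifd_off <- .tiff_int(bytes, ifd_off + 2L + n_entries * 12L, 4L, 1L, endian)
  }
  if (!length(pages)) stop_io("TIFF has no pages: ", path)
  structure(pages, bits = bits_seen)
}
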